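# Nonbonded force-field metadata for the explicit-solvent systems the
# synthetic generator emulates.  Stored as reference data only: the
# primitive-model engines in this package use hard cores plus Coulomb,
# never Lennard-Jones energetics.
#
# sigma_A / eps_kJmol: Lennard-Jones parameters; q_e: site charge in
# elementary charges; alpha_prime_A3: Drude polarizability volume.
# Sulfate geometry: rigid tetrahedron, S-O 1.52 A, O-O 2.49 A.

[[site]]
name = "SO4_S"
sigma_A = 3.55
eps_kJmol = 1.0465
q_e = 0
alpha_prime_A3 = 0

[[site]]
name = "SO4_S_shell"
sigma_A = 0.0
eps_kJmol = 0.0
q_e = 2
alpha_prime_A3 = 5

[[site]]
name = "SO4_O_mamatkulov"
sigma_A = 3.916
eps_kJmol = 0.1
q_e = -1
alpha_prime_A3 = 0

[[site]]
name = "SO4_O_cannon"
sigma_A = 3.15
eps_kJmol = 0.8368
q_e = -1
alpha_prime_A3 = 0

[[site]]
name = "M2p_small"
sigma_A = 2.6
eps_kJmol = 0.1
q_e = 2
alpha_prime_A3 = 0

[[site]]
name = "M2p_large"
sigma_A = 3.6
eps_kJmol = 0.1
q_e = 2
alpha_prime_A3 = 0
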
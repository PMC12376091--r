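# Primitive-model defaults for a divalent metal sulfate solution:
# sulfate hard-sphere diameter fixed at 4.6 A, relative permittivity of
# pure water at 25 C.  The cation diameter 2.4 A is a placeholder that
# the fitting routine replaces.

[model]
epsilon_r = 78.36
temperature_K = 298.15

[[species]]
name = "Mg"
charge = 2
diameter_A = 2.4
alpha_prime_A3 = 0

[[species]]
name = "SO4"
charge = -2
diameter_A = 4.6
alpha_prime_A3 = 5
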
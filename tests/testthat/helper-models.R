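# Shared fixtures, built in code.

# restricted 2:2 primitive model (equal 4.6 A diameters, water at 25 C)
rpm22 <- function() {
  pm_model(list(pm_species("M", 2, 4.6), pm_species("X", -2, 4.6)),
           epsilon_r = 78.36, temperature = 298.15)
}

# its charge-halved 1:1 variant
rpm11 <- function() scale_charges(rpm22(), 0.5)

# memoised expensive HNC solve of the 2:2 model at m = 0.5 (several
# tests inspect the same converged solution)
corr22_m05 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mod <- rpm22()
      st <- molality_to_state(mod, 0.5, c(M = 1, X = 1))
      cache <<- solve_hnc(mod, st, radial_grid(2^13, 0.025))
    }
    cache
  }
})

# synthetic rdf_result from a functional form g(r)
rdf_from_function <- function(gfun, bin_width = 0.05, r_max = 10,
                              rho_B = 0.01) {
  edges <- seq(0, r_max, by = bin_width)
  mids <- (edges[-1] + head(edges, -1)) / 2
  g <- gfun(mids)
  rdf_result(edges, g, counts = g * 100, rho_B = rho_B)
}
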
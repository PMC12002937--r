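# shared fixtures: calibrated parameter sets and small utilities

relErr <- function(x, ref) max(abs(x - ref) / pmax(abs(ref), 1e-12))

tiParams <- function() defaultParameters("Ti")
mg10Params <- function() defaultParameters("Mg-10Gd")
mg5Params <- function() defaultParameters("Mg-5Gd")

degMg10 <- function() degradationParams("surface_rate",
                                        r_prime = 0.062, d_prime = 0.068)
degMg5 <- function() degradationParams("surface_rate",
                                       r_prime = 1.104, d_prime = 0.040)

# draw admissible remodelling parameter sets from the calibration box;
# ranges are trimmed at the stiff extremes so property sampling stays fast
sampleRemodelling <- function(n, seed) {
  b <- parameterBounds("Mg")
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      remodellingParams(
        k1 = runif(1, b$k1[1], 5),
        v1 = runif(1, b$v1[1], 2),
        r1 = runif(1, b$r1[1], 5),
        k3 = runif(1, 0.1, b$k3[2]),
        r2 = runif(1, b$r2[1], b$r2[2]),
        m2 = runif(1, 0, b$m2[2]))
    })
  })
}

sampleDegradation <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      if (i %% 2 == 0)
        degradationParams("power_law", m1 = runif(1, 0, 1))
      else
        degradationParams("surface_rate",
                          r_prime = runif(1, 1e-4, 1.2),
                          d_prime = runif(1, 1e-4, 1))
    })
  })
}
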
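test_that("the surface reduces to deltaG0 at the reference point", {
  set.seed(5)
  for (i in 1:20) {
    p <- thermo_surface_params(deltaG0 = rnorm(1, 8), deltaS0 = rnorm(1, 0, 0.1),
                               deltaCp = rnorm(1), deltaV0 = rnorm(1, 0, 5),
                               deltaBeta = rnorm(1, 0, 3),
                               deltaAlpha = rnorm(1, 0, 5),
                               T0 = runif(1, 270, 310), P0 = runif(1, 1, 50))
    expect_equal(evaluate_surface(p, p$P0, p$T0), p$deltaG0)
  }
})

test_that("constant and single-term surfaces evaluate by hand", {
  flat <- thermo_surface_params(deltaG0 = 5)
  g <- planted_grid(flat)
  expect_equal(g$deltaG, rep(5, nrow(g)))
  # deltaG0 = 8, deltaV0 = 50 cm3/mol at dP = 100 MPa: 8 + 50*100*1e-3 = 13
  p <- thermo_surface_params(deltaG0 = 8, deltaV0 = 50, P0 = 5, T0 = 283.15)
  expect_equal(evaluate_surface(p, 105, 283.15), 13)
  expect_error(evaluate_surface(p, 10, -1), "positive")
})

test_that("intensity fractions map onto K and deltaG consistently", {
  ints <- data.frame(pressure_bar = c(50, 400, 800, 1600),
                     temperature_C = 25, replicate = 1L,
                     F = c(0, 1, 0.5, 0.75))
  # minmax: f = F here; the saturated endpoints are clipped with a warning
  expect_warning(g <- intensities_to_grid(ints), "clipped")
  expect_s3_class(g, "equilibrium_grid")
  # invariants: f = K/(1+K) and deltaG = -RT ln K
  expect_equal(g$f, g$K / (1 + g$K), tolerance = 1e-12)
  RT <- 8.314e-3 * g$temperature_K
  expect_equal(g$deltaG, -RT * log(g$K), tolerance = 1e-9)
  # midpoint: f = 0.5 -> K = 1 -> deltaG = 0
  mid <- g[g$pressure_bar == 800, ]
  expect_equal(mid$K, 1)
  expect_equal(mid$deltaG, 0)
  # saturated points are clipped to [eps, 1-eps]
  hi <- g[g$pressure_bar == 400, ]
  expect_equal(hi$f, 1 - 1e-4)
  expect_equal(hi$K, (1 - 1e-4) / 1e-4)
  # algebraic identity: K = 3 <-> f = 0.75
  k3 <- g[g$pressure_bar == 1600, ]
  expect_equal(k3$K, 3, tolerance = 1e-12)
})

test_that("reference normalisation recovers fractions exactly", {
  f_true <- c(0.2, 0.35, 0.6)
  Fa <- 900; Fb <- 300
  ints <- data.frame(pressure_bar = c(50, 400, 800), temperature_C = 10,
                     replicate = 1L, F = f_true * Fa + (1 - f_true) * Fb)
  g <- intensities_to_grid(ints, normalisation = "reference", F_a = Fa, F_b = Fb)
  expect_equal(g$f, f_true, tolerance = 1e-12)
})

test_that("degenerate and malformed intensity inputs are rejected", {
  flat <- data.frame(pressure_bar = c(50, 400), temperature_C = 10,
                     replicate = 1L, F = c(1, 1))
  expect_error(intensities_to_grid(flat), "degenerate")
  expect_error(intensities_to_grid(data.frame(pressure_bar = 1, F = 1)),
               "columns")
  one <- data.frame(pressure_bar = 50, temperature_C = 10, replicate = 1:3,
                    F = 1:3)
  expect_error(intensities_to_grid(one), "2 distinct")
})

test_that("noiseless planted surfaces are recovered to 1e-6 relative", {
  truth <- planted_surface()
  fit <- fit_surface(planted_grid(truth))
  pars <- c("deltaG0", "deltaS0", "deltaCp", "deltaV0", "deltaBeta", "deltaAlpha")
  for (p in pars)
    expect_equal(fit$params[[p]], truth[[p]], tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # covariance symmetric PSD
  expect_equal(fit$covariance, t(fit$covariance))
  expect_true(all(eigen(fit$covariance, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  # round trip: the fitted surface reproduces the grid
  g <- planted_grid(truth)
  expect_equal(evaluate_surface(fit$params, g$pressure_MPa, g$temperature_K),
               g$deltaG, tolerance = 1e-8)
})

test_that("a flat grid fits to a constant surface", {
  g <- planted_grid(thermo_surface_params(deltaG0 = 3.3))
  fit <- fit_surface(g)
  expect_equal(fit$params$deltaG0, 3.3, tolerance = 1e-10)
  for (p in c("deltaS0", "deltaCp", "deltaV0", "deltaBeta", "deltaAlpha"))
    expect_lt(abs(fit$params[[p]]), 1e-8)
})

test_that("weighted noisy fits are unbiased with calibrated intervals", {
  set.seed(101)
  truth <- planted_surface()
  g0 <- planted_grid(truth, sd = 0.1)
  est <- se <- numeric(100)
  for (r in 1:100) {
    g <- g0
    g$deltaG <- g$deltaG + rnorm(nrow(g), sd = 0.1)
    fit <- fit_surface(g)
    est[r] <- fit$params$deltaG0
    se[r] <- fit$param_sd[["deltaG0"]]
  }
  expect_lt(abs(mean(est) - truth$deltaG0), 0.05)
  cover <- mean(abs(est - truth$deltaG0) <= 2 * se)
  expect_gte(cover, 0.90)
})

test_that("fit preconditions and singular designs error informatively", {
  g <- planted_grid(planted_surface())
  expect_error(fit_surface(g[1:8, ]), "at least 10")
  # single pressure level: every pressure regressor is constant -> singular
  one_p <- g[g$pressure_bar == 50, ]
  one_p <- rbind(one_p, one_p, one_p)  # 15 rows, still one pressure
  expect_error(fit_surface(one_p), "singular|dependent")
  g2 <- g; g2$deltaG_sd <- 0
  expect_error(fit_surface(g2, weighted = TRUE), "deltaG_sd")
})

test_that("complex comparison tabulates estimates and zero flags", {
  tab1 <- compare_complexes(list(RQFi = fit_surface(planted_grid(planted_surface()))))
  expect_equal(nrow(tab1), 1L)
  expect_equal(tab1$deltaG0, 8.1, tolerance = 1e-8)

  # fabricated fits make the flag and sign logic deterministic: a value of
  # 0.5 with SE 1 is indistinguishable from zero, a value of 2 with SE 0.2
  # is not; planted deltaCp signs are carried through
  mk <- function(dCp, dV0, dV0_se) {
    structure(list(params = thermo_surface_params(deltaG0 = 8.8, deltaCp = dCp,
                                                  deltaV0 = dV0),
                   param_sd = c(deltaG0 = 0.1, deltaS0 = 0.02, deltaCp = 0.2,
                                deltaV0 = dV0_se, deltaBeta = 1, deltaAlpha = 3),
                   r_squared = 0.99),
              class = "surface_fit")
  }
  tab <- compare_complexes(list(a = mk(-0.6, 2, 0.2), b = mk(0.6, 0.5, 1)))
  expect_equal(tab$complex, c("a", "b"))
  expect_lt(tab$deltaCp[1], 0)
  expect_gt(tab$deltaCp[2], 0)
  expect_false(tab$deltaV0_zero[1])
  expect_true(tab$deltaV0_zero[2])
})
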
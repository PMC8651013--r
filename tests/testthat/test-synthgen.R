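state_a <- list(f_max = 100, lambda_max = 340, w = 60, b = 0.1)
state_b <- list(f_max = 60, lambda_max = 365, w = 70, b = -0.05)

test_that("spectra generation hits the pure-state limit and is seeded", {
  # deltaG -> very negative means K -> Inf, f -> 1: pure state A
  m <- two_state_spectral_model(state_a, state_b,
                                thermo_surface_params(deltaG0 = -500),
                                noise_sd = 0)
  s <- generate_spectra_matrix(m, default_pt_grid(n_replicates = 1L), seed = 1)
  wl <- sort(unique(s$wavelength_nm))
  A <- evaluate_skewed_gaussian(wl, 100, 340, 60, 0.1)
  one <- s[s$pressure_bar == 50 & s$temperature_C == 10, ]
  expect_equal(one$intensity, A)
  truth <- attr(s, "truth")
  expect_true(all(truth$f >= 0 & truth$f <= 1))
  # state fractions are conserved by construction: f + (1 - f) = 1
  expect_equal(truth$f + (1 - truth$f), rep(1, nrow(truth)))

  m2 <- two_state_spectral_model(state_a, state_b, planted_surface(),
                                 noise_sd = 2)
  s1 <- generate_spectra_matrix(m2, seed = 99)
  s2 <- generate_spectra_matrix(m2, seed = 99)
  expect_identical(s1$intensity, s2$intensity)
  s3 <- generate_spectra_matrix(m2, seed = 100)
  expect_false(identical(s1$intensity, s3$intensity))
})

test_that("spectra generator rejects bad grids and wavelengths", {
  m <- two_state_spectral_model(state_a, state_b, planted_surface())
  expect_error(generate_spectra_matrix(m, default_pt_grid()[0, ]), "empty")
  expect_error(generate_spectra_matrix(m, wavelengths = numeric(0)), "empty")
  expect_error(generate_spectra_matrix(m, wavelengths = c(330, 330)),
               "strictly increasing")
  expect_error(two_state_spectral_model(state_a, state_b, planted_surface(),
                                        noise_sd = -1), "noise_sd")
})

test_that("noiseless spectra round-trip recovers the planted surface", {
  truth <- planted_surface()
  m <- two_state_spectral_model(state_a, state_b, truth, noise_sd = 0)
  s <- generate_spectra_matrix(m, default_pt_grid(n_replicates = 1L), seed = 1)
  wl <- sort(unique(s$wavelength_nm))
  Fa <- integrate_intensity(emission_spectrum(
    wl, evaluate_skewed_gaussian(wl, 100, 340, 60, 0.1)))
  Fb <- integrate_intensity(emission_spectrum(
    wl, evaluate_skewed_gaussian(wl, 60, 365, 70, -0.05)))
  ints <- do.call(rbind, lapply(split_spectra(s), function(sp)
    data.frame(pressure_bar = sp$pressure_bar[1],
               temperature_C = sp$temperature_C[1],
               replicate = sp$replicate[1],
               F = integrate_intensity(sp))))
  grid <- intensities_to_grid(ints, normalisation = "reference",
                              F_a = Fa, F_b = Fb)
  fit <- fit_surface(grid)
  expect_lt(abs(fit$params$deltaG0 - truth$deltaG0), 0.01)
  for (p in c("deltaS0", "deltaCp", "deltaV0", "deltaBeta", "deltaAlpha"))
    expect_equal(fit$params[[p]], truth[[p]], tolerance = 1e-4)
})

test_that("toy structures have the promised geometry", {
  s <- generate_toy_structure(c(10, 10), "helix-pair")
  expect_equal(nrow(s$atoms), 20L)
  expect_equal(sort(unique(s$atoms$chain)), c("A", "B"))
  # identical helical phase: opposing same-index triplet centroids are
  # exactly the axis separation apart
  a <- as.matrix(s$atoms[s$atoms$chain == "A", c("x", "y", "z")])
  b <- as.matrix(s$atoms[s$atoms$chain == "B", c("x", "y", "z")])
  for (i in c(1, 4, 7)) {
    ca <- colMeans(a[i:(i + 2), ]); cb <- colMeans(b[i:(i + 2), ])
    expect_equal(sqrt(sum((ca - cb)^2)), 12)
  }
  one <- generate_toy_structure(1, "extended")
  expect_equal(unlist(one$atoms[1, c("x", "y", "z")], use.names = FALSE),
               c(0, 0, 0))
  expect_error(generate_toy_structure(10, "spiral"), "arg")
  expect_error(generate_toy_structure(0, "extended"), "at least 1")
})

test_that("trajectory generation is degenerate-safe, seeded, and correlated", {
  ref <- generate_toy_structure(c(4, 4), "extended")
  still <- planted_dynamics_model(ref, per_residue_sd = 0, n_frames = 5)
  tr <- generate_trajectory(still, seed = 1)
  ref_xyz <- as.vector(t(as.matrix(ref$atoms[c("x", "y", "z")])))
  for (f in seq_len(5))
    expect_equal(unname(tr$replicas[[1]][f, ]), ref_xyz)

  R <- diag(8); R[1, 2] <- R[2, 1] <- 0.7
  m <- planted_dynamics_model(ref, per_residue_sd = 0.5, correlation = R,
                              n_frames = 50000)
  tr <- generate_trajectory(m, seed = 3)
  # sample correlation of the x displacements matches the planted rho
  x1 <- tr$replicas[[1]][, 1]; x2 <- tr$replicas[[1]][, 4]
  expect_lt(abs(cor(x1, x2) - 0.7), 0.02)
  x3 <- tr$replicas[[1]][, 7]
  expect_lt(abs(cor(x1, x3)), 0.02)

  expect_identical(generate_trajectory(m, seed = 3)$replicas, tr$replicas)
})

test_that("sample covariance converges to the planted covariance", {
  ref <- generate_toy_structure(6, "extended")
  R <- 0.5^abs(outer(1:6, 1:6, `-`))
  m_small <- planted_dynamics_model(ref, 1, R, n_frames = 500)
  m_big <- planted_dynamics_model(ref, 1, R, n_frames = 20000)
  frob <- function(model) {
    tr <- generate_trajectory(model, seed = 21)
    X <- tr$replicas[[1]][, seq(1, 18, by = 3)]  # x components
    sqrt(sum((cor(X) - R)^2))
  }
  f_small <- frob(m_small); f_big <- frob(m_big)
  expect_lt(f_big, f_small)
  expect_lt(f_small, 0.35)
  expect_lt(f_big, 0.06)
})

test_that("PSD repair clips tiny negative eigenvalues and refuses large ones", {
  ref <- generate_toy_structure(3, "extended")
  # rank-deficient correlation with an eigenvalue at about -1e-9
  R <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3)
  ev <- eigen(R, symmetric = TRUE)
  R_bad <- ev$vectors %*% diag(c(2, 1, -1e-9)) %*% t(ev$vectors)
  R_bad <- (R_bad + t(R_bad)) / 2
  d <- sqrt(diag(R_bad)); R_bad <- R_bad / tcrossprod(d); diag(R_bad) <- 1
  if (min(eigen(R_bad, symmetric = TRUE)$values) < 0) {
    expect_message(planted_dynamics_model(ref, 1, R_bad, n_frames = 10),
                   "PSD repair")
  }
  R_worse <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(planted_dynamics_model(ref, 1, R_worse, n_frames = 10),
               "eigenvalue")
  expect_error(planted_dynamics_model(ref, 1, R - 2 * diag(3)), "diagonal")
  expect_error(planted_dynamics_model(ref, -1), "per_residue_sd")
})

test_that("replicas are independent draws", {
  ref <- generate_toy_structure(4, "extended")
  m <- planted_dynamics_model(ref, 0.5, n_frames = 100, n_replicas = 3)
  tr <- generate_trajectory(m, seed = 8)
  expect_false(identical(tr$replicas[[1]], tr$replicas[[2]]))
  expect_false(identical(tr$replicas[[2]], tr$replicas[[3]]))
})
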
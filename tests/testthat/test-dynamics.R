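# Superposition, covariance modes, fluctuation profiles, overlaps,
# correlations, RMSD and windowed RMSF.

test_that("superposition is exact on rigid copies and idempotent", {
  mc <- helix_mean_coords(10)
  ens <- generate_ensemble(ensemble_spec(5, 10, mean_coords = mc,
                                         rigid_jitter = c(0.4, 3), seed = 2))
  al <- superpose(ens)
  for (k in 2:5) {
    expect_lt(rmsd(frame_coords(al, 1), frame_coords(al, k), fit = FALSE),
              1e-6)
  }
  # idempotence
  al2 <- superpose(al)
  expect_lt(max(abs(al2$coords - al$coords)), 1e-8)
  # identical frames stay identical
  still <- coord_ensemble(list(mc, mc, mc))
  expect_lt(max(abs(superpose(still)$coords - still$coords)), 1e-9)
})

test_that("superposition agrees with an independent fitting implementation", {
  ens <- generate_ensemble(ensemble_spec(4, 8, isotropic_noise = 0.5,
                                         seed = 6))
  A <- frame_coords(ens, 1)
  B <- frame_coords(ens, 2)
  ours <- rmsd(B, A)
  theirs <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)  # bio3d rounds to 3 decimals
})

test_that("reflections are not absorbed: proper rotations only", {
  withr::with_seed(4, {
    A <- matrix(rnorm(15), 5, 3)
  })
  B <- A
  B[, 1] <- -B[, 1]             # mirror image of a chiral point set
  fit <- znfdyn:::kabsch_rotation(B, A)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)
  expect_gt(rmsd(B, A), 1e-3)
  # collinear selections are rejected
  line <- cbind(1:5, 0, 0)
  expect_error(znfdyn:::kabsch_rotation(line, line), "collinear")
})

test_that("covariance eigenvalues match a brute-force oracle and conserve the trace", {
  for (seed in 1:2) {
    ens <- generate_ensemble(ensemble_spec(60, 5, isotropic_noise = 0.8,
                                           seed = seed))
    sel <- seq_len(5)
    modes <- covariance_modes(ens, selection = sel)
    expect_equal(modes$values, oracle_cov_eigenvalues(ens, sel),
                 tolerance = 1e-10)
    expect_equal(sum(modes$values), modes$trace, tolerance = 1e-10)
  }
})

test_that("a planted mode is recovered in eigenvalue and direction", {
  fx <- planted_ensemble(5000, 10, variances = 4, seed = 19)
  al <- superpose(fx$ens)
  modes <- covariance_modes(al, selection = seq_len(10), n_modes = 5)
  expect_equal(modes$values[1], 4, tolerance = 0.4)
  expect_gt(abs(sum(modes$vectors[, 1] * fx$directions[, 1])), 0.99)
})

test_that("isotropic ensembles have a flat spectrum", {
  ens <- generate_ensemble(ensemble_spec(10000, 10, isotropic_noise = 1,
                                         seed = 27))
  modes <- covariance_modes(ens, selection = seq_len(10))
  nontrivial <- modes$values[modes$values > 1e-8]
  # superposition removes ~6 rigid degrees of freedom; compare the rest
  live <- head(sort(nontrivial, decreasing = TRUE), length(nontrivial) - 6)
  expect_lt(max(live) / min(live), 1.5)
})

test_that("mode fluctuation profiles are normalised and linear in the eigenvalue", {
  fx <- planted_ensemble(2000, 8, variances = c(4, 1), noise = 0.05,
                         seed = 33)
  modes <- covariance_modes(superpose(fx$ens), selection = seq_len(8))
  prof <- mode_fluctuations(modes, 1)
  expect_equal(sum(prof$value), modes$values[1], tolerance = 1e-10)
  expect_true(all(prof$value >= 0))
  doubled <- modes
  doubled$values[1] <- 2 * modes$values[1]
  expect_equal(mode_fluctuations(doubled, 1)$value, 2 * prof$value,
               tolerance = 1e-12)
  # eigenvector concentrated on one atom -> all other residues 0
  conc <- modes
  conc$vectors[, 1] <- 0
  conc$vectors[1, 1] <- 1
  p2 <- mode_fluctuations(conc, 1)
  expect_equal(sum(p2$value > 0), 1L)
  expect_equal(p2$value[1], conc$values[1])
})

test_that("mode overlap is 1 on itself, sign-invariant, and floored for random subspaces", {
  fx <- planted_ensemble(1000, 10, variances = c(9, 4, 1), noise = 0.1,
                         seed = 41)
  modes <- covariance_modes(superpose(fx$ens), selection = seq_len(10))
  self <- mode_overlap(modes, modes, k = 3)
  expect_equal(unname(diag(self$pairwise)), rep(1, 3), tolerance = 1e-10)
  expect_equal(self$rmsip, 1, tolerance = 1e-10)
  expect_equal(self$covariance_overlap, 1, tolerance = 1e-6)
  flipped <- modes
  flipped$vectors[, 2] <- -flipped$vectors[, 2]
  expect_equal(mode_overlap(modes, flipped, k = 3)$rmsip, 1,
               tolerance = 1e-10)
  # random orthonormal subspaces hover at the sqrt(k / 3m) floor
  m3 <- 30
  k <- 3
  vals <- withr::with_seed(55, {
    replicate(20, {
      A <- qr.Q(qr(matrix(rnorm(m3 * k), m3, k)))
      B <- qr.Q(qr(matrix(rnorm(m3 * k), m3, k)))
      sqrt(sum(crossprod(A, B)^2) / k)
    })
  })
  expect_equal(mean(vals), sqrt(k / m3), tolerance = 0.1)
  expect_error(mode_overlap(modes,
                            covariance_modes(superpose(fx$ens),
                                             selection = 1:5)),
               "different selections")
})

test_that("fluctuation correlation reproduces closed forms and the two-pass oracle", {
  p <- tibble::tibble(resno = 1:3, value = c(1, 2, 3))
  expect_equal(fluctuation_correlation(p, p)$r, 1)
  expect_equal(fluctuation_correlation(p, c(6, 5, 4))$r, -1)
  expect_equal(fluctuation_correlation(p, 2 * c(1, 2, 3) + 7)$r, 1)
  withr::with_seed(3, {
    x <- rnorm(50)
    y <- rnorm(50)
  })
  expect_equal(fluctuation_correlation(x, y)$r, oracle_pearson(x, y),
               tolerance = 1e-12)
  expect_error(fluctuation_correlation(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
  expect_error(fluctuation_correlation(1:3, 1:4), "equal length")
})

test_that("RMSD closed forms: identity, translation, two-atom hand case", {
  A <- helix_mean_coords(6)
  expect_equal(rmsd(A, A), 0, tolerance = 1e-12)
  expect_equal(rmsd(A, sweep(A, 2, c(3, -2, 7), `+`)), 0, tolerance = 1e-9)
  a <- rbind(c(0, 0, 0), c(1, 0, 0))
  b <- rbind(c(0, 0, 0), c(1, 1, 0))
  expect_equal(rmsd(a, b, fit = FALSE), sqrt(0.5))
})

test_that("windowed RMSF: static, hand oscillation, trace identity", {
  mc <- helix_mean_coords(6)
  still <- coord_ensemble(list(mc, mc, mc, mc))
  prof <- local_fluctuations(still, window = 1:6)
  expect_equal(prof$rmsf, rep(0, 6))
  # one atom oscillating +-d along x, others fixed (no refitting)
  d <- 0.7
  up <- mc; up[4, 1] <- mc[4, 1] + d
  dn <- mc; dn[4, 1] <- mc[4, 1] - d
  osc <- coord_ensemble(list(up, dn))
  prof2 <- local_fluctuations(osc, window = 1:6, superpose_first = FALSE)
  expect_equal(prof2$rmsf[4], d)
  expect_equal(prof2$rmsf[-4], rep(0, 5))
  # sum of squared RMSF equals the trace of the window covariance
  ens <- generate_ensemble(ensemble_spec(200, 6, mean_coords = mc,
                                         isotropic_noise = 0.5, seed = 12))
  prof3 <- local_fluctuations(ens, window = 1:6, superpose_first = FALSE)
  X <- znfdyn:::ensemble_matrix(ens)
  tr <- sum(colMeans(sweep(X, 2, colMeans(X))^2))
  expect_equal(sum(prof3$rmsf^2), tr, tolerance = 1e-10)
  expect_error(local_fluctuations(ens, window = 99), "Empty window")
})
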
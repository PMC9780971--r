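# Langevin pulling simulator and work/PMF analysis.

test_that("flat potential at negligible temperature tracks the anchor with vanishing work", {
  pe <- simulate_pull(pull_spec(
    pull_potential("flat"), spring_k = 5, velocity = 0.005,
    temperature = 1e-6, friction = 1, dt = 0.01,
    start_anchor = 0, end_anchor = 1, n_replicas = 2, seed = 1))
  final <- dplyr::slice_tail(dplyr::group_by(pe, replica), n = 1)
  expect_lt(max(abs(final$anchor - final$x)), 0.01)
  expect_lt(max(abs(final$work)), 0.01)
})

test_that("all replicas share the anchor schedule exactly but differ in work at T > 0", {
  pe <- simulate_pull(pull_spec(
    pull_potential("harmonic", k_well = 1), spring_k = 5, velocity = 0.05,
    temperature = 300, friction = 1, dt = 0.01,
    start_anchor = 0, end_anchor = 2, n_replicas = 4, seed = 2))
  sched <- split(pe$anchor, pe$replica)
  for (s in sched[-1]) expect_identical(s, sched[[1]])
  finals <- dplyr::slice_tail(dplyr::group_by(pe, replica), n = 1)$work
  expect_gt(sd(finals), 0)
  # seed determinism is bit-exact
  pe2 <- simulate_pull(pull_spec(
    pull_potential("harmonic", k_well = 1), spring_k = 5, velocity = 0.05,
    temperature = 300, friction = 1, dt = 0.01,
    start_anchor = 0, end_anchor = 2, n_replicas = 4, seed = 2))
  expect_identical(as.data.frame(pe), as.data.frame(pe2))
})

test_that("unstable integration steps are rejected with an explicit message", {
  expect_error(
    pull_spec(pull_potential("flat"), spring_k = 300, velocity = 0.1,
              dt = 0.01, friction = 1, start_anchor = 0, end_anchor = 1),
    "Unstable")
})

test_that("work accumulation matches closed forms and a quadrature oracle", {
  # F == 0 -> W == 0
  tr <- tibble::tibble(t = 0:10, anchor = seq(0, 1, by = 0.1), force = 0)
  expect_equal(accumulate_work(tr)$work, rep(0, 11))
  # constant force c over total span L -> W = c * L exactly
  tr2 <- tibble::tibble(t = 0:10, anchor = seq(0, 2, length.out = 11),
                        force = 3.5)
  expect_equal(dplyr::last(accumulate_work(tr2)$work), 3.5 * 2)
  # smooth analytic profile: halving the step shrinks the error ~4x
  f <- function(l) sin(1.3 * l) + 0.5 * l
  exact <- oracle_work(f, 0, 4)
  err <- vapply(c(0.1, 0.05), function(h) {
    l <- seq(0, 4, by = h)
    tr <- tibble::tibble(t = seq_along(l), anchor = l, force = f(l))
    abs(dplyr::last(accumulate_work(tr)$work) - exact)
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)
  # non-monotone anchors are rejected
  bad <- tibble::tibble(t = 1:3, anchor = c(0, 1, 0.5), force = 1)
  expect_error(accumulate_work(bad), "non-decreasing")
})

test_that("mean work profile: degenerate CI, hand arithmetic, order invariance", {
  grid <- seq(0, 1, by = 0.5)
  mk <- function(rep, w_final) {
    tibble::tibble(replica = rep, t = 0:2, anchor = grid,
                   x = grid, force = 1, work = c(0, w_final / 2, w_final))
  }
  ens <- znfdyn:::new_pulling_ensemble(dplyr::bind_rows(mk(1, 30), mk(2, 32)),
                                       temperature = 300)
  prof <- mean_work_profile(ens)
  expect_equal(prof$mean_work[3], 31)
  expect_equal(prof$ci_half[3], qt(0.975, 1) * sd(c(30, 32)) / sqrt(2))
  # identical replicas -> zero half-width
  ens2 <- znfdyn:::new_pulling_ensemble(dplyr::bind_rows(mk(1, 30), mk(2, 30)),
                                        temperature = 300)
  expect_equal(mean_work_profile(ens2)$ci_half, c(0, 0, 0))
  # replica order does not matter
  ens3 <- znfdyn:::new_pulling_ensemble(dplyr::bind_rows(mk(2, 32), mk(1, 30)),
                                        temperature = 300)
  expect_equal(mean_work_profile(ens3)$mean_work, prof$mean_work)
})

test_that("Jarzynski PMF: degenerate average, gauge, Jensen inequality", {
  grid <- seq(0, 2, by = 0.5)
  w <- c(0, 1, 2.5, 4, 6)
  mk <- function(rep, wk) tibble::tibble(replica = rep, t = seq_along(grid),
                                         anchor = grid, x = grid, force = 1,
                                         work = wk)
  same <- znfdyn:::new_pulling_ensemble(
    dplyr::bind_rows(mk(1, w), mk(2, w), mk(3, w)), temperature = 300)
  pmf <- jarzynski_pmf(same)
  expect_equal(pmf$pmf_jarzynski, w)
  expect_equal(pmf$pmf_jarzynski[1], 0)
  # random work ensembles respect Jensen pointwise
  withr::with_seed(7, {
    reps <- purrr::map(1:6, function(r) {
      mk(r, cumsum(c(0, abs(rnorm(4)))))
    })
  })
  ens <- znfdyn:::new_pulling_ensemble(dplyr::bind_rows(reps),
                                       temperature = 300)
  pmf2 <- jarzynski_pmf(ens)
  expect_true(all(pmf2$pmf_jarzynski <= pmf2$mean_work + 1e-9))
})

test_that("Gaussian work samples satisfy the cumulant identity", {
  kT <- kB_kcal() * 300
  withr::with_seed(10, w <- rnorm(1e4, mean = 5, sd = 1))
  jar <- jarzynski_estimate(w, 300)
  cum2 <- mean(w) - var(w) / (2 * kT)
  ew <- exp(-(w - mean(w)) / kT)
  se <- sd(ew) / (sqrt(length(w)) * mean(ew)) * kT
  expect_lt(abs(jar - cum2), 3 * se)
})

test_that("quasi-static harmonic pulling recovers the analytic free energy", {
  dg <- analytic_dg_harmonic(2, 0, 10, 0, 2)
  pe <- simulate_pull(pull_spec(
    pull_potential("harmonic", k_well = 2, x0 = 0), spring_k = 10,
    velocity = 0.02, temperature = 300, friction = 1, dt = 0.005,
    start_anchor = 0, end_anchor = 2, n_replicas = 30, seed = 14))
  g <- glance(jarzynski_pmf(pe))
  expect_lt(abs(g$delta_g_jarzynski - dg), 0.5 * kB_kcal() * 300)
})

test_that("slower pulling dissipates less on a velocity ladder", {
  dg <- analytic_dg_harmonic(2, 0, 10, 0, 2)
  final_err <- vapply(c(0.4, 0.1, 0.02), function(v) {
    pe <- simulate_pull(pull_spec(
      pull_potential("harmonic", k_well = 2, x0 = 0), spring_k = 10,
      velocity = v, temperature = 300, friction = 1, dt = 0.005,
      start_anchor = 0, end_anchor = 2, n_replicas = 50, seed = 15))
    mean(dplyr::slice_tail(dplyr::group_by(pe, replica), n = 1)$work) - dg
  }, numeric(1))
  # mean dissipated work is positive and decreases as pulling slows
  expect_true(all(diff(final_err) < 0))
  expect_gt(final_err[1], 0)
})

test_that("rupture points land on planted force peaks and respect policy", {
  lam <- seq(0, 20, by = 0.2)
  single <- tibble::tibble(anchor = lam,
                           force = exp(-((lam - 8.5) / 1.5)^2))
  rp1 <- detect_rupture(single, n_points = 1)
  expect_equal(rp1$distance_A, 8.5, tolerance = 0.2)
  double <- tibble::tibble(anchor = lam,
                           force = exp(-((lam - 8.5) / 1.5)^2) +
                             0.6 * exp(-((lam - 12) / 1)^2))
  rp2 <- detect_rupture(double, n_points = 2)
  expect_equal(rp2$label, c("RP1", "RP2"))
  expect_equal(rp2$distance_A, c(8.5, 12), tolerance = 0.2)
  expect_equal(rp2$distance_nm, rp2$distance_A / 10)
  # monotone decay has only a boundary maximum -> excluded
  decay <- tibble::tibble(anchor = lam, force = exp(-lam / 5))
  expect_equal(nrow(detect_rupture(decay)), 0L)
})

test_that("segment fluctuations partition frames and track a planted ramp", {
  mc <- helix_mean_coords(6)
  # amplitude ramps down over time: segment RMSF strictly decreasing
  frames <- withr::with_seed(20, {
    purrr::map(1:80, function(k) {
      amp <- 1.5 * (81 - k) / 80
      mc + matrix(rnorm(18, sd = amp), 6, 3)
    })
  })
  ens <- coord_ensemble(frames)
  seg <- segment_fluctuations(ens, window = 1:6, n_segments = 4)
  tot <- dplyr::summarise(dplyr::group_by(seg, segment),
                          s = sum(rmsf))$s
  expect_true(all(diff(tot) < 0))
  # reversed flag relabels the same blocks
  segr <- segment_fluctuations(ens, window = 1:6, n_segments = 4,
                               reversed = TRUE)
  totr <- dplyr::summarise(dplyr::group_by(segr, segment),
                           s = sum(rmsf))$s
  expect_equal(sort(tot), sort(totr))
  expect_true(all(diff(totr) > 0))
  # static trajectory -> all zero
  still <- coord_ensemble(rep(list(mc), 8))
  seg0 <- segment_fluctuations(still, window = 1:6, n_segments = 4)
  expect_equal(seg0$rmsf, rep(0, nrow(seg0)))
  # exact partition, uneven sizes allowed
  expect_error(segment_fluctuations(still, window = 1:6, n_segments = 9),
               "Fewer frames")
})
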
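# Independent brute-force oracles and tiny fixture builders shared by the
# test files.  These deliberately use naive algorithms (joint histograms,
# explicit outer products, two-pass formulas, rejection sampling) so they
# share no code path with the package implementations they check.

# brute-force MI (bits) between two character columns, pairwise-complete,
# pseudocount over the 20x20 joint table
oracle_mi_pair <- function(a, b, pseudocount = 0) {
  keep <- a != "-" & b != "-"
  a <- a[keep]
  b <- b[keep]
  aa <- znfdyn:::AA_ALPHABET
  joint <- matrix(0, 20, 20, dimnames = list(aa, aa))
  for (k in seq_along(a)) joint[a[k], b[k]] <- joint[a[k], b[k]] + 1
  p <- (joint + pseudocount) / (sum(joint) + 400 * pseudocount)
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  total <- 0
  for (x in 1:20) {
    for (y in 1:20) {
      if (p[x, y] > 0) {
        total <- total + p[x, y] * log2(p[x, y] / (pi_[x] * pj_[y]))
      }
    }
  }
  total
}

oracle_mi_matrix <- function(msa, pseudocount = 0) {
  m <- msa_matrix(msa)
  L <- ncol(m)
  out <- matrix(0, L, L)
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      out[i, j] <- out[j, i] <- oracle_mi_pair(m[, i], m[, j], pseudocount)
    }
  }
  out
}

# brute-force covariance eigenvalues of an ensemble over a selection:
# accumulate the 3m x 3m covariance frame by frame with explicit outer
# products (population normalisation)
oracle_cov_eigenvalues <- function(ens, selection) {
  f <- n_frames(ens)
  m <- length(selection)
  acc <- matrix(0, 3 * m, 3 * m)
  flat <- matrix(0, f, 3 * m)
  for (k in seq_len(f)) {
    fr <- frame_coords(ens, k)[selection, , drop = FALSE]
    flat[k, ] <- as.vector(t(fr))
  }
  mu <- colMeans(flat)
  for (k in seq_len(f)) {
    d <- flat[k, ] - mu
    acc <- acc + d %o% d
  }
  sort(eigen(acc / f, symmetric = TRUE)$values, decreasing = TRUE)
}

# textbook two-pass Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# rejection-sampling volume of (inclusion sphere) minus (blocker spheres);
# independent of the package's Monte-Carlo helper
oracle_mc_volume <- function(center, radius, blockers, n = 1e6, seed = 1) {
  withr::with_seed(seed, {
    pts <- matrix(runif(3 * n, -radius, radius), ncol = 3)
    pts <- sweep(pts, 2, center, `+`)
    inside <- rowSums(sweep(pts, 2, center)^2) <= radius^2
    for (b in blockers) {
      inside <- inside & rowSums(sweep(pts, 2, b$center)^2) > b$radius^2
    }
    (2 * radius)^3 * mean(inside)
  })
}

# dense-quadrature external work for an analytic force profile F(lambda)
oracle_work <- function(f, from, to) {
  stats::integrate(f, from, to, rel.tol = 1e-10)$value
}

# analytic free-energy difference for pulling a harmonic well (k_well, x0)
# with a harmonic spring k_s: two springs in series
analytic_dg_harmonic <- function(k_well, x0, k_s, anchor_from, anchor_to) {
  keff <- k_well * k_s / (k_well + k_s)
  0.5 * keff * ((anchor_to - x0)^2 - (anchor_from - x0)^2)
}

# small deterministic random alignment
random_msa <- function(n, L, seed) {
  withr::with_seed(seed, {
    as_msa(apply(matrix(sample(znfdyn:::AA_ALPHABET, n * L, replace = TRUE),
                        n, L), 1, paste0, collapse = ""))
  })
}

# planted-mode ensemble fixture used across dynamics tests
planted_ensemble <- function(n_frames, n_atoms, variances, noise = 0,
                             seed = 1, jitter = c(0, 0)) {
  mean_c <- helix_mean_coords(n_atoms)
  dirs <- withr::with_seed(seed + 1000L,
                           orthonormal_modes(mean_c, length(variances)))
  ens <- generate_ensemble(ensemble_spec(
    n_frames = n_frames, n_atoms = n_atoms, mean_coords = mean_c,
    planted_modes = list(directions = dirs, variances = variances),
    isotropic_noise = noise, rigid_jitter = jitter, seed = seed))
  list(ens = ens, directions = dirs, variances = variances,
       mean_coords = mean_c)
}
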
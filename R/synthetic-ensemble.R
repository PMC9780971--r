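# Low-rank-plus-noise synthetic coordinate ensembles with planted
# principal modes.  Frames are mean + sum_k sqrt(v_k) z_k d_k + isotropic
# noise, optionally followed by a per-frame rigid-body jitter; the planted
# directions and variances are the ground truth that essential-dynamics
# recovery is validated against.

#' Helix-like default mean structure
#'
#' A gently curved pseudo-C-alpha trace (radius 5 A, rise 1.5 A per
#' residue) used as the default mean; deliberately non-collinear so
#' rigid-body superposition is well-posed.
#'
#' @param n_atoms number of atoms.
#' @return `n_atoms x 3` coordinate matrix (angstrom).
#' @export
helix_mean_coords <- function(n_atoms) {
  i <- seq_len(n_atoms)
  cbind(x = 5 * cos(0.6 * i), y = 5 * sin(0.6 * i), z = 1.5 * i)
}

# orthonormal basis of the 6 rigid-body directions (3 translations +
# 3 infinitesimal rotations about the centroid) of a structure
rigid_body_basis <- function(mean_coords) {
  n <- nrow(mean_coords)
  ctr <- sweep(mean_coords, 2, colMeans(mean_coords))
  basis <- matrix(0, 3 * n, 6)
  for (ax in 1:3) basis[seq(ax, 3 * n, by = 3), ax] <- 1
  ex <- cbind(rep(0, n), -ctr[, 3], ctr[, 2])
  ey <- cbind(ctr[, 3], rep(0, n), -ctr[, 1])
  ez <- cbind(-ctr[, 2], ctr[, 1], rep(0, n))
  basis[, 4] <- as.vector(t(ex))
  basis[, 5] <- as.vector(t(ey))
  basis[, 6] <- as.vector(t(ez))
  qr.Q(qr(basis))
}

#' Random orthonormal mode directions
#'
#' Draws `k` random directions in the 3n-dimensional coordinate space and
#' orthonormalises them; with `exclude_rigid_body = TRUE` (default) the
#' six rigid-body degrees of freedom of `mean_coords` are projected out
#' first, so superposition cannot absorb planted variance.
#'
#' @param mean_coords `n x 3` mean structure.
#' @param k number of directions.
#' @param exclude_rigid_body project out translations/rotations first.
#' @return `3n x k` matrix with orthonormal columns.
#' @export
orthonormal_modes <- function(mean_coords, k, exclude_rigid_body = TRUE) {
  n3 <- 3L * nrow(mean_coords)
  if (k > n3 - 6L * exclude_rigid_body) abort("Too many modes requested.")
  D <- matrix(rnorm(n3 * k), n3, k)
  if (exclude_rigid_body) {
    R <- rigid_body_basis(mean_coords)
    D <- D - R %*% crossprod(R, D)
  }
  qr.Q(qr(D))
}

#' Specify a synthetic coordinate ensemble
#'
#' @param n_frames number of frames.
#' @param n_atoms number of atoms.
#' @param mean_coords `n_atoms x 3` mean structure (default
#'   [helix_mean_coords()]).
#' @param planted_modes `NULL`, or a list with `directions` (`3n x k`
#'   orthonormal matrix) and `variances` (strictly decreasing, A^2).
#' @param isotropic_noise isotropic per-coordinate variance (A^2); must be
#'   smaller than the smallest planted variance so recovery is well-posed.
#' @param rigid_jitter length-2 vector `c(max_rotation_rad,
#'   max_translation_A)` for per-frame rigid-body motion (default none).
#' @param atoms optional atom table (see [coord_ensemble()]).
#' @param seed integer seed.
#' @return an `ensemble_spec`.
#' @export
ensemble_spec <- function(n_frames, n_atoms, mean_coords = NULL,
                          planted_modes = NULL, isotropic_noise = 0,
                          rigid_jitter = c(0, 0), atoms = NULL, seed = 1L) {
  n_frames <- check_count(n_frames, "n_frames", 1L)
  n_atoms <- check_count(n_atoms, "n_atoms", 1L)
  mean_coords <- mean_coords %||% helix_mean_coords(n_atoms)
  mean_coords <- as.matrix(mean_coords)
  if (!all(dim(mean_coords) == c(n_atoms, 3L))) {
    abort("`mean_coords` must be an n_atoms x 3 matrix.")
  }
  check_scalar_number(isotropic_noise, "isotropic_noise", 0)
  if (length(rigid_jitter) != 2L || any(rigid_jitter < 0)) {
    abort("`rigid_jitter` must be c(max_rotation_rad, max_translation_A) >= 0.")
  }
  if (!is.null(planted_modes)) {
    D <- planted_modes$directions
    v <- planted_modes$variances
    if (!is.matrix(D) || nrow(D) != 3L * n_atoms || ncol(D) != length(v)) {
      abort("`planted_modes$directions` must be 3*n_atoms x k with one variance per column.")
    }
    if (max(abs(crossprod(D) - diag(ncol(D)))) > 1e-8) {
      abort("Planted directions must be mutually orthonormal (tolerance 1e-8).")
    }
    if (any(diff(v) >= 0)) abort("Planted variances must be strictly decreasing.")
    if (any(v <= 0)) abort("Planted variances must be positive.")
    if (isotropic_noise >= min(v)) {
      abort("`isotropic_noise` must be smaller than the smallest planted variance.")
    }
  }
  structure(list(n_frames = n_frames, n_atoms = n_atoms,
                 mean_coords = mean_coords, planted_modes = planted_modes,
                 isotropic_noise = isotropic_noise,
                 rigid_jitter = as.numeric(rigid_jitter), atoms = atoms,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

# uniform random rotation matrix scaled to angle <= max_angle
random_rotation <- function(max_angle) {
  axis <- rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  theta <- runif(1, 0, max_angle)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Generate a synthetic coordinate ensemble
#'
#' @param spec an [ensemble_spec()].
#' @return a `coord_ensemble`; deterministic given the spec seed.  The
#'   planted directions/variances are attached as attribute `"planted"`.
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  f <- spec$n_frames
  a <- spec$n_atoms
  mu <- as.vector(t(spec$mean_coords))    # x1 y1 z1 x2 ...
  with_seed(spec$seed, {
    X <- matrix(rep(mu, each = f), f, 3L * a)
    if (!is.null(spec$planted_modes)) {
      D <- spec$planted_modes$directions
      v <- spec$planted_modes$variances
      Z <- matrix(rnorm(f * length(v)), f, length(v))
      X <- X + Z %*% t(D %*% diag(sqrt(v), length(v)))
    }
    if (spec$isotropic_noise > 0) {
      X <- X + matrix(rnorm(f * 3L * a, sd = sqrt(spec$isotropic_noise)),
                      f, 3L * a)
    }
    coords <- array(0, dim = c(f, a, 3))
    jit <- any(spec$rigid_jitter > 0)
    for (k in seq_len(f)) {
      fr <- unflatten_frame(X[k, ])
      if (jit) {
        ctr <- colMeans(fr)
        R <- random_rotation(spec$rigid_jitter[1])
        tr <- runif(3, -spec$rigid_jitter[2], spec$rigid_jitter[2])
        fr <- sweep(sweep(fr, 2, ctr) %*% t(R), 2, ctr + tr, `+`)
      }
      coords[k, , ] <- fr
    }
    out <- coord_ensemble(coords, spec$atoms)
    attr(out, "planted") <- spec$planted_modes
    out
  })
}
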
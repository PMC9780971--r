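# Essential-dynamics machinery: iterative least-squares superposition
# (Kabsch with proper-rotation enforcement), covariance-mode
# decomposition, per-residue fluctuation profiles from single modes,
# RMSIP-style subspace overlaps, fluctuation-profile correlations, RMSD
# and windowed RMSF.
#
# Conventions: population (1/N) normalisation for covariances and
# fluctuation quantities; eigenvalues clamped at 0; eigenvector sign fixed
# so the largest-magnitude component is positive.

# optimal proper rotation R and translation aligning P onto Q (m x 3,
# row-vector convention: P_aligned = sweep(P, 2, cp) %*% R + cq)
kabsch_rotation <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  sv <- svd(Pc)
  if (nrow(P) < 3L || sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)) {
    abort("Degenerate (collinear) selection: superposition is ill-posed.")
  }
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, cp = cp, cq = cq)
}

apply_fit <- function(P, fit) {
  sweep(sweep(P, 2, fit$cp) %*% fit$R, 2, fit$cq, `+`)
}

#' Iteratively superpose an ensemble onto its mean structure
#'
#' Each frame is rigid-body fitted (optimal proper rotation plus
#' translation, least squares over `selection`) to the current reference;
#' the reference starts as the first frame and is refined to the ensemble
#' mean until the mean moves by less than `tol` or `max_iter` rounds.
#'
#' @param ens a `coord_ensemble` with at least 2 frames.
#' @param selection atom indices used for the fit (default all atoms).
#' @param max_iter maximum refinement rounds (default 10).
#' @param tol convergence threshold on the RMS shift of the mean
#'   structure, angstrom (default 1e-6).
#' @return the aligned `coord_ensemble`, with attributes `mean`
#'   (`n_atoms x 3` mean structure) and `iterations`.
#' @export
superpose <- function(ens, selection = NULL, max_iter = 10, tol = 1e-6) {
  stopifnot(inherits(ens, "coord_ensemble"))
  if (n_frames(ens) < 2L) abort("Need at least 2 frames to superpose.")
  selection <- selection %||% seq_len(n_atoms(ens))
  if (length(selection) == 0L) abort("Empty selection.")
  coords <- ens$coords
  f <- n_frames(ens)
  ref <- matrix(coords[1, selection, ], ncol = 3)
  for (iter in seq_len(max_iter)) {
    for (k in seq_len(f)) {
      fr <- matrix(coords[k, , ], ncol = 3)
      fit <- kabsch_rotation(matrix(coords[k, selection, ], ncol = 3), ref)
      coords[k, , ] <- apply_fit(fr, fit)
    }
    new_ref <- apply(coords[, selection, , drop = FALSE], c(2, 3), mean)
    shift <- sqrt(mean((new_ref - ref)^2))
    ref <- new_ref
    if (shift < tol) break
  }
  out <- coord_ensemble(coords, ens$atoms)
  attr(out, "mean") <- apply(coords, c(2, 3), mean)
  attr(out, "iterations") <- iter
  out
}

#' Covariance-mode (essential dynamics) decomposition
#'
#' Builds the positional covariance `C = <(x - <x>)(x - <x>)^T>` over the
#' selected coordinates of a superposed ensemble and eigendecomposes it.
#' Numerically negative eigenvalues are clamped to 0 and each
#' eigenvector's sign is fixed by making its largest-magnitude component
#' positive, so decompositions are reproducible.
#'
#' @param ens a superposed `coord_ensemble` (> 3 frames).
#' @param selection atom indices; default the C-alpha/N/C backbone.
#' @param n_modes number of leading modes to keep (default all `3m`);
#'   values above `3m` are clipped with a warning.
#' @return a `mode_set`: list with `values` (eigenvalues, A^2,
#'   descending), `vectors` (`3m x n_modes`, orthonormal columns), `mean`
#'   (`m x 3`), `selection`, `atoms` (selected atom table), `trace`
#'   (of the full covariance).
#' @export
covariance_modes <- function(ens, selection = NULL, n_modes = NULL) {
  stopifnot(inherits(ens, "coord_ensemble"))
  if (n_frames(ens) <= 3L) abort("Need more than 3 frames for a covariance decomposition.")
  selection <- selection %||% backbone_selection(ens)
  X <- ensemble_matrix(ens, selection)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nrow(X)
  m3 <- ncol(C)
  n_modes <- n_modes %||% m3
  if (n_modes > m3) {
    warn(sprintf("n_modes clipped from %d to 3m = %d.", n_modes, m3))
    n_modes <- m3
  }
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  for (k in seq_len(ncol(vecs))) {
    if (vecs[which.max(abs(vecs[, k])), k] < 0) vecs[, k] <- -vecs[, k]
  }
  structure(list(values = vals[seq_len(n_modes)],
                 vectors = vecs[, seq_len(n_modes), drop = FALSE],
                 mean = unflatten_frame(mu),
                 selection = selection,
                 atoms = ens$atoms[selection, , drop = FALSE],
                 trace = sum(diag(C))),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set> %d modes over %d atoms; top eigenvalues (A^2): %s\n",
              length(x$values), length(x$selection),
              paste(signif(head(x$values, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Per-residue fluctuation profile of a single mode
#'
#' Per-atom squared fluctuation along mode `k` is
#' `lambda_k * |v_k(atom)|^2`; per-residue values sum over that residue's
#' selected atoms, so the profile sums to the eigenvalue.
#'
#' @param modes a `mode_set`.
#' @param mode_index which mode (default 1, the dominant PC).
#' @return tibble with columns `resno`, `value` (A^2); attribute `source`.
#' @export
mode_fluctuations <- function(modes, mode_index = 1) {
  stopifnot(inherits(modes, "mode_set"))
  if (mode_index > length(modes$values)) {
    abort(sprintf("mode_index %d exceeds the %d available modes.",
                  mode_index, length(modes$values)))
  }
  v <- unflatten_frame(modes$vectors[, mode_index])
  per_atom <- modes$values[mode_index] * rowSums(v^2)
  resno <- modes$atoms$resno
  out <- tibble(resno = resno, value = per_atom) |>
    dplyr::group_by(.data$resno) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop")
  attr(out, "source") <- sprintf("mode %d", mode_index)
  out
}

#' Mode and subspace overlap between two decompositions
#'
#' Pairwise overlaps are `|v_a,i . v_b,j|`; the subspace overlap over the
#' top `k` modes is reported with three estimators: RMSIP
#' `sqrt(sum_ij (v_a,i . v_b,j)^2 / k)`, the Hess covariance overlap, and
#' the fraction of `a`'s top-`k` variance captured by `b`'s top-`k`
#' subspace.
#'
#' @param a,b `mode_set`s over identical selections (same `3m`).
#' @param k number of leading modes compared (default 10, clipped to what
#'   both sets hold).
#' @return an `overlap_report`: list with `pairwise` (k x k matrix),
#'   `rmsip`, `covariance_overlap`, `variance_capture`, `k`.
#' @export
mode_overlap <- function(a, b, k = 10) {
  stopifnot(inherits(a, "mode_set"), inherits(b, "mode_set"))
  if (nrow(a$vectors) != nrow(b$vectors)) {
    abort("Mode sets live on different selections; supply matching selections.")
  }
  k <- min(k, length(a$values), length(b$values))
  Va <- a$vectors[, seq_len(k), drop = FALSE]
  Vb <- b$vectors[, seq_len(k), drop = FALSE]
  P <- crossprod(Va, Vb)
  la <- a$values[seq_len(k)]
  lb <- b$values[seq_len(k)]
  num <- sum(la) + sum(lb) -
    2 * sum(tcrossprod(sqrt(la), sqrt(lb)) * P^2)
  cov_ov <- 1 - sqrt(pmax(num, 0) / (sum(la) + sum(lb)))
  var_cap <- sum(la * rowSums(P^2)) / sum(la)
  structure(list(pairwise = abs(P),
                 rmsip = sqrt(sum(P^2) / k),
                 covariance_overlap = cov_ov,
                 variance_capture = var_cap,
                 k = k),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> k = %d: RMSIP %.3f, covariance overlap %.3f, variance capture %.3f\n",
              x$k, x$rmsip, x$covariance_overlap, x$variance_capture))
  invisible(x)
}

#' Pearson correlation between two fluctuation profiles
#'
#' Profiles must already be aligned position-by-position (equal lengths;
#' cross-domain comparisons are aligned by an integer offset of their
#' residue windows before calling).
#'
#' @param p,q fluctuation profiles: tibbles with a `value` or `rmsf`
#'   column, or bare numeric vectors.
#' @return one-row tibble with `r` and `n`.
#' @export
fluctuation_correlation <- function(p, q) {
  pv <- profile_values(p)
  qv <- profile_values(q)
  if (length(pv) != length(qv)) {
    abort("Profiles must have equal length after window alignment.")
  }
  if (sd(pv) == 0 || sd(qv) == 0) {
    abort("Pearson r undefined: a profile has zero variance.")
  }
  tibble(r = cor(pv, qv), n = length(pv))
}

profile_values <- function(p) {
  if (is.data.frame(p)) {
    v <- if ("value" %in% names(p)) p$value else if ("rmsf" %in% names(p)) p$rmsf else NULL
    if (is.null(v)) abort("Profile tibble needs a `value` or `rmsf` column.")
    v
  } else {
    as.numeric(p)
  }
}

#' Least-squares superposed RMSD between two frames
#'
#' @param frame_a,frame_b `n x 3` coordinate matrices with matching atom
#'   counts (or `coord_ensemble`s with a frame index via `ia`/`ib`).
#' @param selection atom indices over which to fit and measure
#'   (default all).
#' @param fit superpose before measuring (default TRUE; FALSE gives the
#'   raw coordinate RMSD).
#' @return RMSD in angstrom.
#' @export
rmsd <- function(frame_a, frame_b, selection = NULL, fit = TRUE) {
  A <- as.matrix(frame_a)
  B <- as.matrix(frame_b)
  if (!all(dim(A) == dim(B))) abort("Mismatched atom counts in RMSD.")
  selection <- selection %||% seq_len(nrow(A))
  A <- A[selection, , drop = FALSE]
  B <- B[selection, , drop = FALSE]
  if (fit) A <- apply_fit(A, kabsch_rotation(A, B))
  sqrt(mean(rowSums((A - B)^2)))
}

#' Windowed per-residue RMSF
#'
#' Per-residue root-mean-square fluctuation about the mean structure,
#' restricted to the heavy atoms of a residue window, computed after
#' superposing the ensemble on the window's backbone (all window atoms
#' when no backbone names exist).  Per-atom mean-square fluctuations are
#' summed within each residue and square-rooted, so the squared profile
#' sums to the trace of the window covariance.
#'
#' @param ens a `coord_ensemble`.
#' @param window residue numbers of the window (vector or range).
#' @param superpose_first fit on the window backbone before measuring
#'   (default TRUE).
#' @return tibble with columns `resno`, `rmsf` (angstrom).
#' @export
local_fluctuations <- function(ens, window, superpose_first = TRUE) {
  stopifnot(inherits(ens, "coord_ensemble"))
  sel <- atom_selection(ens, resno = window, heavy_only = TRUE)
  if (length(sel) == 0L) abort("Empty window: no atoms in the requested residues.")
  if (superpose_first) {
    bb <- intersect(sel, atom_selection(ens, names = c("CA", "N", "C")))
    if (length(bb) < 3L) bb <- sel
    ens <- superpose(ens, selection = bb)
  }
  X <- ensemble_matrix(ens, sel)
  msf_coord <- colMeans(sweep(X, 2, colMeans(X))^2)
  per_atom <- rowSums(matrix(msf_coord, ncol = 3, byrow = TRUE))
  tibble(resno = ens$atoms$resno[sel], msf = per_atom) |>
    dplyr::group_by(.data$resno) |>
    dplyr::summarise(rmsf = sqrt(sum(.data$msf)), .groups = "drop")
}
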
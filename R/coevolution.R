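# Conservation and coevolution statistics over an alignment.
#
# Mutual information between column pairs is computed in bits from
# pairwise-complete joint counts over the 20-residue alphabet (gaps are
# excluded from pair counts; a column with > 50% gaps is masked and
# reported).  The average-product correction (APC) removes the entropic /
# phylogenetic background, and significance is assessed against a null
# built by independently permuting each column across sequences, with APC
# applied to every permuted replicate.  Per-residue summaries follow the
# cMI / pMI convention: cMI sums raw MI over partners whose Z-score
# exceeds a threshold (default 6.5), pMI averages the cMI of structural
# neighbours within a distance cutoff (default 5 A, minimal heavy-atom
# distances).

# integer-encode an alignment: 1..20 for residues, NA for gap
encode_msa <- function(msa) {
  m <- msa_matrix(msa)
  code <- match(m, AA_ALPHABET)
  dim(code) <- dim(m)
  code
}

# n x 20L one-hot matrix (gap rows contribute nothing); optional row weights
one_hot_msa <- function(code, weights = NULL) {
  n <- nrow(code)
  L <- ncol(code)
  X <- matrix(0, n, 20L * L)
  keep <- which(!is.na(code))
  rows <- ((keep - 1L) %% n) + 1L
  cols <- ((keep - 1L) %/% n)      # 0-based column
  val <- if (is.null(weights)) 1 else weights[rows]
  X[cbind(rows, cols * 20L + code[keep])] <- val
  X
}

#' Henikoff position-based sequence weights
#'
#' Each sequence's weight is the sum over columns of `1 / (r * s)` where
#' `r` is the number of distinct symbols in the column and `s` the count
#' of the sequence's own symbol; weights are normalised to sum to the
#' number of sequences.
#'
#' @param msa an `msa`.
#' @return numeric vector of per-sequence weights (sum = n_sequences).
#' @export
henikoff_weights <- function(msa) {
  m <- msa_matrix(msa)
  w <- numeric(nrow(m))
  for (l in seq_len(ncol(m))) {
    cnt <- table(m[, l])
    r <- length(cnt)
    w <- w + 1 / (r * as.numeric(cnt[m[, l]]))
  }
  w * nrow(m) / sum(w)
}

#' Per-column symbol frequencies
#'
#' Frequencies over the 21-symbol alphabet (20 residues + gap):
#' `(counts + pseudocount) / (total + 21 * pseudocount)` per column, with
#' optional per-sequence weights applied to the counts.
#'
#' @param msa an `msa`.
#' @param pseudocount non-negative pseudocount added to every cell
#'   (default 0.5).
#' @param weights optional per-sequence weights (e.g.
#'   [henikoff_weights()]); default unweighted.
#' @return a `col_freqs` object: 21 x L frequency matrix plus metadata.
#' @export
column_frequencies <- function(msa, pseudocount = 0.5, weights = NULL) {
  check_scalar_number(pseudocount, "pseudocount", 0)
  m <- msa_matrix(msa)
  n <- nrow(m)
  L <- ncol(m)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n)
  f <- matrix(0, 21L, L, dimnames = list(MSA_ALPHABET, NULL))
  for (l in seq_len(L)) {
    cnt <- vapply(MSA_ALPHABET,
                  function(a) sum(weights[m[, l] == a]), numeric(1))
    f[, l] <- (cnt + pseudocount) / (sum(cnt) + 21 * pseudocount)
  }
  structure(list(freq = f, pseudocount = pseudocount, weights = weights),
            class = "col_freqs")
}

#' Kullback-Leibler column conservation
#'
#' `kl[i] = sum_a p_i(a) log2(p_i(a) / q(a))` in bits, with `0 log 0 = 0`.
#' Gap frequency is dropped and the column renormalised over the 20
#' residues before comparison with the background.
#'
#' @param freqs a `col_freqs` from [column_frequencies()].
#' @param background strictly positive length-20 background distribution
#'   (default uniform, so a fully conserved column scores `log2(20)`).
#' @return tibble with columns `column`, `kl` (bits).
#' @export
kl_conservation <- function(freqs, background = NULL) {
  stopifnot(inherits(freqs, "col_freqs"))
  if (is.null(background)) background <- rep(1 / 20, 20)
  if (length(background) != 20L) abort("`background` must have length 20.")
  if (any(background <= 0)) abort("`background` must be strictly positive over the 20 amino acids.")
  background <- background / sum(background)
  p20 <- freqs$freq[AA_ALPHABET, , drop = FALSE]
  kl <- vapply(seq_len(ncol(p20)), function(l) {
    p <- p20[, l]
    tot <- sum(p)
    if (tot <= 0) return(NA_real_)
    p <- p / tot
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / background[nz]))
  }, numeric(1))
  tibble(column = seq_len(ncol(p20)), kl = kl)
}

# columns with gap fraction > 0.5 are masked from MI statistics
masked_columns <- function(code) {
  which(colMeans(is.na(code)) > 0.5)
}

# raw MI matrix from an integer-coded alignment (workhorse; also used on
# permuted replicates).  C = crossprod(one-hot) holds all pairwise joint
# counts; each 20x20 block is converted to bits.
mi_from_code <- function(code, pseudocount, weights = NULL,
                         masked = integer()) {
  L <- ncol(code)
  X <- one_hot_msa(code, if (is.null(weights)) NULL else sqrt(weights))
  C <- crossprod(X)
  mi <- matrix(0, L, L)
  live <- setdiff(seq_len(L), masked)
  for (ii in seq_along(live)) {
    i <- live[ii]
    bi <- (i - 1L) * 20L + 1:20
    for (jj in seq_len(ii - 1L)) {
      j <- live[jj]
      Nij <- C[bi, (j - 1L) * 20L + 1:20]
      tot <- sum(Nij)
      if (tot <= 0) next
      p <- (Nij + pseudocount) / (tot + 400 * pseudocount)
      pi_ <- rowSums(p)
      pj_ <- colSums(p)
      E <- tcrossprod(pi_, pj_)
      nz <- p > 0
      v <- sum(p[nz] * log2(p[nz] / E[nz]))
      mi[i, j] <- mi[j, i] <- max(v, 0)
    }
  }
  mi
}

#' Raw mutual information between alignment columns
#'
#' `MI(i, j) = sum_ab p_ij(a, b) log2(p_ij / (p_i p_j))` in bits, from
#' pairwise-complete joint counts (rows gapped in either column are
#' dropped for that pair); symmetric with zero diagonal.  Columns with
#' more than 50% gaps are masked (rows/columns set to 0) and recorded in
#' `attr(, "masked")`.
#'
#' @inheritParams column_frequencies
#' @return L x L numeric matrix (bits), attribute `masked`.
#' @export
mutual_information <- function(msa, pseudocount = 0.5, weights = NULL) {
  if (nrow(msa) < 2L) abort("Need at least 2 sequences for mutual information.")
  check_scalar_number(pseudocount, "pseudocount", 0)
  code <- encode_msa(msa)
  masked <- masked_columns(code)
  if (length(masked) > 0L) {
    warn(sprintf("Masking %d column(s) with > 50%% gaps from MI: %s",
                 length(masked), paste(masked, collapse = ", ")))
  }
  mi <- mi_from_code(code, pseudocount, weights, masked)
  attr(mi, "masked") <- masked
  mi
}

#' Average-product correction of an MI matrix
#'
#' `apc(i, j) = mi(i, j) - mean_i * mean_j / mean_all` with the means
#' taken over off-diagonal entries; when `mean_all` is 0 the correction
#' term is defined as 0.  Diagonal stays 0.
#'
#' @param raw_mi square symmetric matrix of raw MI values.
#' @return matrix of the same shape.
#' @export
apc_correct <- function(raw_mi) {
  if (!is.matrix(raw_mi) || nrow(raw_mi) != ncol(raw_mi)) {
    abort("`raw_mi` must be a square matrix.")
  }
  if (max(abs(raw_mi - t(raw_mi))) > 1e-8) abort("`raw_mi` must be symmetric.")
  L <- nrow(raw_mi)
  diag(raw_mi) <- 0
  mean_i <- rowSums(raw_mi) / (L - 1L)
  mean_all <- sum(raw_mi) / (L * (L - 1L))
  apc <- if (mean_all == 0) {
    raw_mi
  } else {
    raw_mi - tcrossprod(mean_i) / mean_all
  }
  diag(apc) <- 0
  apc
}

#' MI with APC correction and permutation Z-scores
#'
#' The null is built by independently permuting each column's residues
#' across sequences `n_permutations` times, recomputing the APC-corrected
#' MI on each replicate; `z = (apc_obs - mean_null) / sd_null` with the
#' null standard deviation floored at 1e-12.
#'
#' @inheritParams column_frequencies
#' @param n_permutations number of column permutations (>= 20, default 100).
#' @param seed integer seed for the permutation null.
#' @return an `mi_result`: list with `raw_mi`, `apc_mi`, `z` (L x L
#'   matrices), `n_permutations`, `seed`, `masked`.
#' @export
mi_zscores <- function(msa, n_permutations = 100, seed = 1L,
                       pseudocount = 0.5, weights = NULL) {
  n_permutations <- check_count(n_permutations, "n_permutations", 20L)
  code <- encode_msa(msa)
  n <- nrow(code)
  L <- ncol(code)
  masked <- masked_columns(code)
  raw <- mi_from_code(code, pseudocount, weights, masked)
  apc <- apc_correct(raw)
  s1 <- matrix(0, L, L)
  s2 <- matrix(0, L, L)
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      perm <- code
      for (l in seq_len(L)) perm[, l] <- code[sample.int(n), l]
      ap <- apc_correct(mi_from_code(perm, pseudocount, weights, masked))
      s1 <- s1 + ap
      s2 <- s2 + ap^2
    }
  })
  mu <- s1 / n_permutations
  sdv <- sqrt(pmax(s2 / n_permutations - mu^2, 0) *
                n_permutations / (n_permutations - 1L))
  z <- (apc - mu) / pmax(sdv, 1e-12)
  diag(z) <- 0
  structure(list(raw_mi = raw, apc_mi = apc, z = z,
                 n_permutations = n_permutations, seed = as.integer(seed),
                 masked = masked),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("<mi_result> %d columns, %d permutations, %d masked column(s)\n",
              nrow(x$raw_mi), x$n_permutations, length(x$masked)))
  cat(sprintf("  max raw MI %.3f bits, max |Z| %.2f\n",
              max(x$raw_mi), max(abs(x$z))))
  invisible(x)
}

#' Per-column cumulative mutual information (cMI)
#'
#' `cmi[i]` sums raw MI over partners `j` with `z(i, j) > z_threshold`;
#' 0 when no partner passes.
#'
#' @param mi an `mi_result` from [mi_zscores()].
#' @param z_threshold significance threshold on the permutation Z-score
#'   (default 6.5).
#' @return tibble with columns `column`, `cmi` (bits).
#' @export
cumulative_mi <- function(mi, z_threshold = 6.5) {
  stopifnot(inherits(mi, "mi_result"))
  pass <- mi$z > z_threshold
  diag(pass) <- FALSE
  tibble(column = seq_len(nrow(mi$raw_mi)),
         cmi = rowSums(mi$raw_mi * pass))
}

#' Structure-aware proximity MI (pMI)
#'
#' `pmi[i]` is the mean cMI over residues `j != i` whose minimal
#' heavy-atom distance to `i` is within `cutoff`; `NA` when a column has
#' no structural neighbour (or no structural mapping, i.e. an all-`NA`
#' row in the distance map).
#'
#' @param cmi tibble from [cumulative_mi()] (or a numeric cMI vector).
#' @param distance_map symmetric L x L matrix of minimal inter-residue
#'   heavy-atom distances in angstrom, rows/columns ordered as alignment
#'   columns (see [residue_distance_map()]); `NA` rows mark unmapped
#'   columns.
#' @param cutoff neighbour distance cutoff in angstrom (default 5).
#' @return tibble with columns `column`, `pmi`.
#' @export
proximity_mi <- function(cmi, distance_map, cutoff = 5.0) {
  vals <- if (is.data.frame(cmi)) cmi$cmi else as.numeric(cmi)
  L <- length(vals)
  if (!is.matrix(distance_map) || nrow(distance_map) != L ||
      ncol(distance_map) != L) {
    abort("`distance_map` must be an L x L matrix matching the cMI profile.")
  }
  check_scalar_number(cutoff, "cutoff", 0, strict_lower = TRUE)
  pmi <- vapply(seq_len(L), function(i) {
    d <- distance_map[i, ]
    nb <- which(!is.na(d) & d <= cutoff & seq_len(L) != i)
    if (length(nb) == 0L) NA_real_ else mean(vals[nb])
  }, numeric(1))
  unmapped <- which(vapply(seq_len(L), function(i)
    all(is.na(distance_map[i, -i])), logical(1)))
  if (length(unmapped) > 0L) {
    warn(sprintf("%d column(s) without structural mapping or neighbours reported as NA.",
                 length(unmapped)))
  }
  tibble(column = seq_len(L), pmi = pmi)
}

#' Significant coevolution network with percentile bands
#'
#' One row per unordered column pair with `z > z_threshold`, banded by the
#' percentile of its raw MI among passing edges: `top5` (top 5%),
#' `p70_95`, `below70` — the convention used for circos-style coevolution
#' wheels.
#'
#' @inheritParams cumulative_mi
#' @return tibble with columns `i`, `j`, `raw_mi`, `z`, `band`.
#' @export
coevolution_network <- function(mi, z_threshold = 6.5) {
  stopifnot(inherits(mi, "mi_result"))
  L <- nrow(mi$z)
  idx <- which(upper.tri(mi$z) & mi$z > z_threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(tibble(i = integer(), j = integer(), raw_mi = numeric(),
                  z = numeric(), band = character()))
  }
  edges <- tibble(i = idx[, 1], j = idx[, 2],
                  raw_mi = mi$raw_mi[idx], z = mi$z[idx])
  pct <- rank(edges$raw_mi, ties.method = "first") / nrow(edges)
  edges$band <- dplyr::case_when(
    pct > 0.95 ~ "top5",
    pct > 0.70 ~ "p70_95",
    TRUE ~ "below70")
  dplyr::arrange(edges, dplyr::desc(.data$raw_mi))
}
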
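# Synthetic alignment generator with planted conservation and coupling.
#
# Stands in for a curated Pfam family alignment: a background of
# independent draws from a residue frequency vector, on top of which
# selected columns are conserved with a given fidelity and selected column
# pairs covary through an explicit residue-to-residue bijection with a
# given coupling probability.  Ground truth is therefore known exactly,
# which is what the coevolution statistics are validated against.

#' Specify a synthetic alignment
#'
#' @param n_sequences number of aligned sequences.
#' @param length number of alignment columns.
#' @param background length-20 numeric vector of amino-acid frequencies
#'   (named with one-letter codes or in alphabetical order), summing to 1.
#'   Default uniform.
#' @param conserved_sites list of `list(column, residue, fidelity)`:
#'   `column` carries `residue` with probability `fidelity`, a background
#'   draw otherwise.
#' @param coupled_pairs list of `list(i, j, coupling, state_map)`:
#'   with probability `coupling` a row draws a residue `a` from the
#'   background restricted to `names(state_map)` for column `i` and places
#'   `state_map[[a]]` at column `j`; otherwise both columns are independent
#'   background draws.  `state_map` is a named character vector encoding a
#'   bijection between two residue subsets.
#' @param gap_fraction fraction of cells replaced by gaps, uniformly at
#'   random (default 0: gap-free alignments).
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @return an object of class `msa_spec`.
#' @export
msa_spec <- function(n_sequences, length, background = NULL,
                     conserved_sites = list(), coupled_pairs = list(),
                     gap_fraction = 0, seed = 1L) {
  n_sequences <- check_count(n_sequences, "n_sequences", 1L)
  length <- check_count(length, "length", 1L)
  if (is.null(background)) background <- rep(1 / 20, 20)
  if (base::length(background) != 20L || any(background < 0)) {
    abort("`background` must be 20 non-negative frequencies.")
  }
  if (abs(sum(background) - 1) > 1e-9) {
    abort("`background` must sum to 1 (tolerance 1e-9).")
  }
  if (is.null(names(background))) names(background) <- AA_ALPHABET
  background <- background[AA_ALPHABET]
  if (anyNA(background)) abort("`background` names must be the 20 amino acids.")
  check_scalar_number(gap_fraction, "gap_fraction", 0, 1)

  planted <- integer()
  for (s in conserved_sites) {
    s$column <- check_count(s$column, "conserved column", 1L)
    if (s$column > length) abort("Conserved column outside the alignment.")
    check_scalar_number(s$fidelity, "fidelity", 0, 1)
    if (!s$residue %in% AA_ALPHABET) abort("Conserved residue must be one of the 20 amino acids.")
    planted <- c(planted, s$column)
  }
  for (p in coupled_pairs) {
    p$i <- check_count(p$i, "coupled column i", 1L)
    p$j <- check_count(p$j, "coupled column j", 1L)
    if (p$i > length || p$j > length || p$i == p$j) {
      abort("Coupled columns must be distinct and within the alignment.")
    }
    check_scalar_number(p$coupling, "coupling", 0, 1)
    sm <- p$state_map
    if (is.null(names(sm)) || anyDuplicated(names(sm)) || anyDuplicated(sm) ||
        !all(c(names(sm), sm) %in% AA_ALPHABET)) {
      abort("`state_map` must be a bijection between amino-acid subsets (named character vector).")
    }
    planted <- c(planted, p$i, p$j)
  }
  if (anyDuplicated(planted)) {
    abort(sprintf(
      "Planted columns overlap (column %d used more than once); conserved and coupled columns must be disjoint.",
      planted[duplicated(planted)][1]))
  }
  structure(
    list(n_sequences = n_sequences, length = length, background = background,
         conserved_sites = conserved_sites, coupled_pairs = coupled_pairs,
         gap_fraction = gap_fraction, seed = as.integer(seed)),
    class = "msa_spec")
}

#' Generate a synthetic alignment with planted signal
#'
#' @param spec an [msa_spec()].
#' @return an `msa` tibble (`id`, `seq`); deterministic given the spec seed.
#' @export
generate_msa <- function(spec) {
  stopifnot(inherits(spec, "msa_spec"))
  n <- spec$n_sequences
  L <- spec$length
  bg <- spec$background
  with_seed(spec$seed, {
    m <- matrix(sample(AA_ALPHABET, n * L, replace = TRUE, prob = bg),
                nrow = n, ncol = L)
    for (s in spec$conserved_sites) {
      hit <- runif(n) < s$fidelity
      m[hit, s$column] <- s$residue
    }
    for (p in spec$coupled_pairs) {
      hit <- runif(n) < p$coupling
      k <- sum(hit)
      if (k > 0) {
        sub_bg <- bg[names(p$state_map)]
        sub_bg <- sub_bg / sum(sub_bg)
        a <- sample(names(p$state_map), k, replace = TRUE, prob = sub_bg)
        m[hit, p$i] <- a
        m[hit, p$j] <- unname(p$state_map[a])
      }
    }
    if (spec$gap_fraction > 0) {
      m[runif(n * L) < spec$gap_fraction] <- GAP_CHAR
    }
    new_msa(sprintf("synth%04d", seq_len(n)),
            apply(m, 1, paste0, collapse = ""))
  })
}
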
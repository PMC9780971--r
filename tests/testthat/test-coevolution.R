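# Conservation and coevolution statistics: frequencies, KL, MI and its
# brute-force oracle, APC, permutation Z-scores, cMI, pMI, network bands.

test_that("column frequencies follow the pseudocount formula", {
  msa <- as_msa(c("A", "C"))
  f0 <- column_frequencies(msa, pseudocount = 0)
  expect_equal(unname(f0$freq["A", 1]), 0.5)
  expect_equal(sum(f0$freq[, 1]), 1)
  f1 <- column_frequencies(msa, pseudocount = 1)
  expect_equal(unname(f1$freq["A", 1]), 2 / 23)
  expect_equal(unname(f1$freq["W", 1]), 1 / 23)
  expect_equal(sum(f1$freq[, 1]), 1)
  # single-residue column, no pseudocount
  f <- column_frequencies(as_msa(c("G", "G", "G")), pseudocount = 0)
  expect_equal(unname(f$freq["G", 1]), 1)
})

test_that("KL conservation has its closed-form extremes and is non-negative", {
  cons <- column_frequencies(as_msa(rep("W", 10)), pseudocount = 0)
  expect_equal(kl_conservation(cons)$kl, log2(20), tolerance = 1e-12)
  # column matching the background scores 0
  alphabet_col <- as_msa(znfdyn:::AA_ALPHABET)
  f <- column_frequencies(alphabet_col, pseudocount = 0)
  expect_equal(kl_conservation(f)$kl, 0, tolerance = 1e-12)
  # arbitrary columns are >= 0
  f2 <- column_frequencies(random_msa(30, 5, seed = 2), pseudocount = 0.5)
  expect_true(all(kl_conservation(f2)$kl >= 0))
  expect_error(kl_conservation(f2, background = c(0, rep(1, 19))),
               "strictly positive")
})

test_that("raw MI matches the brute-force joint-histogram oracle", {
  for (seed in 1:3) {
    msa <- random_msa(50, 6, seed = seed)
    for (pc in c(0, 0.5)) {
      expect_equal(mutual_information(msa, pseudocount = pc),
                   oracle_mi_matrix(msa, pseudocount = pc),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("MI closed forms, symmetry and non-negativity hold", {
  # duplicated 4-state equiprobable column pair -> exactly 2 bits
  msa <- as_msa(rep(c("AA", "CC", "DD", "EE"), each = 4))
  mi <- mutual_information(msa, pseudocount = 0)
  expect_equal(mi[1, 2], 2)
  expect_equal(mi, t(mi), ignore_attr = TRUE)
  expect_equal(diag(mi), c(0, 0))
  m2 <- mutual_information(random_msa(40, 8, seed = 4), pseudocount = 0.5)
  expect_true(all(m2 >= 0))
  expect_equal(m2, t(m2), ignore_attr = TRUE)
})

test_that("gap handling: pairwise-complete counts and >50% gap masking", {
  msa <- as_msa(c("A-", "AC", "AC", "A-", "A-"))
  # column 2 has 60% gaps -> masked
  expect_warning(mi <- mutual_information(msa), "Masking")
  expect_equal(attr(mi, "masked"), 2L)
  expect_true(all(mi == 0))
})

test_that("APC correction kills rank-one background and keeps zeros", {
  cmat <- matrix(0.7, 6, 6)
  diag(cmat) <- 0
  expect_equal(apc_correct(cmat), matrix(0, 6, 6))
  expect_equal(apc_correct(matrix(0, 4, 4)), matrix(0, 4, 4))
})

test_that("planted coupling is top-ranked by APC MI with Z > 6.5", {
  sm <- c(A = "R", C = "K", D = "E", E = "D")
  msa <- generate_msa(msa_spec(
    500, 12, coupled_pairs = list(list(i = 3, j = 9, coupling = 0.9,
                                       state_map = sm)),
    seed = 17))
  res <- mi_zscores(msa, n_permutations = 50, seed = 17)
  ap <- res$apc_mi
  diag(ap) <- -Inf
  top <- which(ap == max(ap), arr.ind = TRUE)[1, ]
  expect_setequal(unname(top), c(3L, 9L))
  expect_gt(res$z[3, 9], 6.5)
  # raw rank not better than apc rank for the planted pair
  rk <- function(m) {
    v <- m[upper.tri(m)]
    rank(-v)[which(upper.tri(m), arr.ind = TRUE)[, 1] == 3 &
               which(upper.tri(m), arr.ind = TRUE)[, 2] == 9]
  }
  expect_lte(rk(res$apc_mi), rk(res$raw_mi))
})

test_that("independent columns rarely reach extreme Z-scores", {
  msa <- generate_msa(msa_spec(300, 10, seed = 23))
  res <- mi_zscores(msa, n_permutations = 50, seed = 23)
  zs <- res$z[upper.tri(res$z)]
  expect_gte(mean(abs(zs) <= 4), 0.99)
})

test_that("cMI sums raw MI over significant partners and is monotone in the threshold", {
  fake <- structure(list(
    raw_mi = matrix(c(0, 0.8, 0, 0.8, 0, 0, 0, 0, 0), 3, 3),
    apc_mi = matrix(0, 3, 3),
    z = matrix(c(0, 8, 0, 8, 0, 0, 0, 0, 0), 3, 3),
    n_permutations = 100L, seed = 1L, masked = integer()),
    class = "mi_result")
  cmi <- cumulative_mi(fake, z_threshold = 6.5)
  expect_equal(cmi$cmi, c(0.8, 0.8, 0))
  expect_equal(cumulative_mi(fake, z_threshold = 10)$cmi, c(0, 0, 0))
  # raising the threshold never increases any cmi
  msa <- generate_msa(msa_spec(
    300, 8, coupled_pairs = list(list(i = 1, j = 5, coupling = 1,
                                      state_map = c(A = "C", C = "A"))),
    seed = 31))
  res <- mi_zscores(msa, n_permutations = 30, seed = 31)
  lo <- cumulative_mi(res, z_threshold = 3)$cmi
  hi <- cumulative_mi(res, z_threshold = 8)$cmi
  expect_true(all(hi <= lo + 1e-12))
})

test_that("pMI averages neighbour cMI within the cutoff and reports missing", {
  d <- matrix(c(0, 4, 8,
                4, 0, 8,
                8, 8, 0), 3, 3)
  cmi <- tibble::tibble(column = 1:3, cmi = c(0, 10, 99))
  pmi <- suppressWarnings(proximity_mi(cmi, d, cutoff = 5))
  expect_equal(pmi$pmi[1], 10)
  expect_equal(pmi$pmi[2], 0)
  expect_true(is.na(pmi$pmi[3]))
  # constant neighbours give that constant; bounded by neighbour range
  d2 <- matrix(2, 4, 4); diag(d2) <- 0
  cmi2 <- c(5, 5, 5, 0)
  pmi2 <- proximity_mi(cmi2, d2, cutoff = 5)
  expect_equal(pmi2$pmi[4], 5)
  for (i in 1:4) {
    nb <- setdiff(1:4, i)
    expect_gte(pmi2$pmi[i], min(cmi2[nb]))
    expect_lte(pmi2$pmi[i], max(cmi2[nb]))
  }
})

test_that("coevolution network bands passing pairs by raw-MI percentile", {
  L <- 40
  z <- matrix(0, L, L)
  raw <- matrix(0, L, L)
  pairs <- which(upper.tri(z), arr.ind = TRUE)[1:100, ]
  vals <- seq(0.01, 1, length.out = 100)
  for (k in 1:100) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    z[i, j] <- z[j, i] <- 10
    raw[i, j] <- raw[j, i] <- vals[k]
  }
  fake <- structure(list(raw_mi = raw, apc_mi = raw, z = z,
                         n_permutations = 100L, seed = 1L,
                         masked = integer()),
                    class = "mi_result")
  net <- coevolution_network(fake, z_threshold = 6.5)
  expect_equal(nrow(net), 100L)
  expect_equal(sum(net$band == "top5"), 5L)
  expect_equal(sum(net$band == "p70_95"), 25L)
  # each unordered pair appears once
  expect_equal(nrow(dplyr::distinct(net, i, j)), nrow(net))
  expect_true(all(net$i < net$j))
  # no passing pair -> empty edge list
  fake$z <- matrix(0, L, L)
  expect_equal(nrow(coevolution_network(fake)), 0L)
})

test_that("Henikoff weights upweight the minority sequence and normalise", {
  msa <- as_msa(c("AAAA", "AAAA", "CCCC"))
  w <- henikoff_weights(msa)
  expect_equal(sum(w), 3)
  expect_gt(w[3], w[1])
  expect_equal(w[1], w[2])
})
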
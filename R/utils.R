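# Internal constants and small helpers shared across modules.
#
# Unit conventions everywhere in the package: lengths in angstrom (A),
# time in picoseconds (ps), energies in kcal/mol, forces in kcal/mol/A,
# spring constants in kcal/mol/A^2, temperatures in kelvin.

# Boltzmann constant, kcal mol^-1 K^-1
.kB <- 0.0019872041

#' Boltzmann constant in package units
#'
#' @return kB in kcal mol^-1 K^-1.
#' @export
kB_kcal <- function() .kB

# 20 standard amino acids, one-letter codes, alphabetical
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
GAP_CHAR <- "-"
MSA_ALPHABET <- c(AA_ALPHABET, GAP_CHAR)

#' Unit conversions
#'
#' Distances are handled internally in angstrom and energies in kcal/mol;
#' pulling protocols in the literature are frequently quoted in nm and
#' nN/nm, so explicit converters are provided.
#'
#' `spring_nN_nm_to_kcal()` converts a spring constant in nN/nm (equal to
#' N/m) to kcal mol^-1 A^-2 via Avogadro's number.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
nm_to_angstrom <- function(x) 10 * x

#' @rdname units
#' @export
angstrom_to_nm <- function(x) x / 10

#' @rdname units
#' @export
spring_nN_nm_to_kcal <- function(x) x * (6.02214076e23 / 4184) * 1e-20

# stable log(sum(exp(x)))
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s (got %s).", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s (got %s).", name, lower, x))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %s (got %s).", name, upper, x))
  }
  invisible(x)
}

check_count <- function(x, name, minimum = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < minimum) {
    abort(sprintf("`%s` must be an integer >= %d.", name, minimum))
  }
  as.integer(x)
}

# seeded evaluation that does not disturb the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
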
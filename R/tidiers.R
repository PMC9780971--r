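# broom-style tidy()/glance() methods for the package's result objects.

#' Tidy a mode set
#'
#' @param x a `mode_set`.
#' @param ... unused.
#' @return tibble with one row per mode: `mode`, `eigenvalue` (A^2),
#'   `prop_variance`, `cum_variance` (fractions of the covariance trace).
#' @method tidy mode_set
#' @export
tidy.mode_set <- function(x, ...) {
  tibble(mode = seq_along(x$values),
         eigenvalue = x$values,
         prop_variance = x$values / x$trace,
         cum_variance = cumsum(x$values) / x$trace)
}

#' @rdname tidy.mode_set
#' @return for `glance()`: one-row tibble with `n_modes`, `n_atoms`,
#'   `total_variance` (covariance trace, A^2), `top_eigenvalue`.
#' @method glance mode_set
#' @export
glance.mode_set <- function(x, ...) {
  tibble(n_modes = length(x$values),
         n_atoms = length(x$selection),
         total_variance = x$trace,
         top_eigenvalue = x$values[1])
}

#' Tidy a PMF estimate
#'
#' @param x a `pmf_estimate`.
#' @param ... unused.
#' @return the profile tibble `(anchor, mean_work, ci_half,
#'   pmf_jarzynski, pmf_cumulant2, ess)` with a `distance_nm` column
#'   added.
#' @method tidy pmf_estimate
#' @export
tidy.pmf_estimate <- function(x, ...) {
  dplyr::mutate(as_tibble(x), distance_nm = angstrom_to_nm(.data$anchor),
                .after = "anchor")
}

#' @rdname tidy.pmf_estimate
#' @return for `glance()`: one-row tibble with the endpoint free-energy
#'   estimates (`delta_g_jarzynski`, `delta_g_cumulant2`,
#'   `final_mean_work`, kcal/mol), `n_replicas`, `temperature` and the
#'   minimum effective sample size along the profile.
#' @method glance pmf_estimate
#' @export
glance.pmf_estimate <- function(x, ...) {
  tb <- as_tibble(x)
  tibble(delta_g_jarzynski = tb$pmf_jarzynski[nrow(tb)],
         delta_g_cumulant2 = tb$pmf_cumulant2[nrow(tb)],
         final_mean_work = tb$mean_work[nrow(tb)],
         n_replicas = attr(x, "n_replicas"),
         temperature = attr(x, "temperature"),
         min_ess = min(tb$ess))
}

#' Tidy an MI result
#'
#' @param x an `mi_result`.
#' @param ... unused.
#' @return long tibble, one row per unordered column pair: `i`, `j`,
#'   `raw_mi`, `apc_mi`, `z`.
#' @method tidy mi_result
#' @export
tidy.mi_result <- function(x, ...) {
  idx <- which(upper.tri(x$raw_mi), arr.ind = TRUE)
  tibble(i = idx[, 1], j = idx[, 2],
         raw_mi = x$raw_mi[idx], apc_mi = x$apc_mi[idx], z = x$z[idx])
}

#' @rdname tidy.mi_result
#' @return for `glance()`: one-row tibble with `n_columns`,
#'   `n_permutations`, `n_masked`, `max_raw_mi`, `max_z`.
#' @method glance mi_result
#' @export
glance.mi_result <- function(x, ...) {
  tibble(n_columns = nrow(x$raw_mi),
         n_permutations = x$n_permutations,
         n_masked = length(x$masked),
         max_raw_mi = max(x$raw_mi),
         max_z = max(x$z))
}

#' Tidy a volume result
#'
#' @param x a `volume_result`.
#' @param ... unused.
#' @return per-frame series tibble when present, otherwise a one-row
#'   tibble with the single measurement.
#' @method tidy volume_result
#' @export
tidy.volume_result <- function(x, ...) {
  x$series %||% tibble(frame = 1L, volume = x$volume)
}

#' @rdname tidy.volume_result
#' @method glance volume_result
#' @export
glance.volume_result <- function(x, ...) {
  if (is.null(x$summary)) {
    tibble(mean = x$volume, min = x$volume, max = x$volume,
           n_frames = 1L, grid_spacing = x$grid_spacing)
  } else {
    tibble(mean = x$summary$mean, min = x$summary$min, max = x$summary$max,
           n_frames = nrow(x$series), grid_spacing = x$grid_spacing)
  }
}

#' Tidy an overlap report
#'
#' @param x an `overlap_report`.
#' @param ... unused.
#' @return long tibble of pairwise absolute eigenvector dot products.
#' @method tidy overlap_report
#' @export
tidy.overlap_report <- function(x, ...) {
  idx <- expand.grid(mode_a = seq_len(nrow(x$pairwise)),
                     mode_b = seq_len(ncol(x$pairwise)))
  tibble(mode_a = idx$mode_a, mode_b = idx$mode_b,
         overlap = x$pairwise[as.matrix(idx)])
}

#' @rdname tidy.overlap_report
#' @method glance overlap_report
#' @export
glance.overlap_report <- function(x, ...) {
  tibble(k = x$k, rmsip = x$rmsip,
         covariance_overlap = x$covariance_overlap,
         variance_capture = x$variance_capture)
}
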
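# Analysis of constant-velocity pulling work ensembles: work
# accumulation, mean-work profiles with Student-t confidence bands,
# Jarzynski and second-cumulant PMF estimates, rupture-point detection on
# the smoothed mean force, and segment-wise fluctuation profiles.
#
# Profiles are binned on the deterministic anchor schedule lambda (shared
# across replicas), the PMF is gauged to 0 at the first grid point, and
# the exponential average uses a log-sum-exp guard with an effective
# sample size diagnostic.

check_shared_schedule <- function(ens) {
  grids <- dplyr::group_split(dplyr::group_by(ens, .data$replica))
  ref <- grids[[1]]$anchor
  for (g in grids) {
    if (length(g$anchor) != length(ref) ||
        max(abs(g$anchor - ref)) > 1e-9) {
      abort("Replicas do not share the anchor schedule (tolerance 1e-9).")
    }
  }
  ref
}

#' Accumulate external work along a pulling trajectory
#'
#' `W(t_k)` is the cumulative trapezoid of `F d(lambda)` over the recorded
#' increments — the external work done by the moving anchor.  Applied per
#' replica; an existing `work` column is replaced.
#'
#' @param traj tibble with columns `t`, `anchor`, `force` and optionally
#'   `replica`.
#' @return the input with a `work` column (kcal/mol), `W = 0` at the first
#'   record of each replica.
#' @export
accumulate_work <- function(traj) {
  traj <- as_tibble(traj)
  if (!"replica" %in% names(traj)) traj$replica <- 1L
  out <- traj |>
    dplyr::group_by(.data$replica) |>
    dplyr::group_modify(function(d, key) {
      if (is.unsorted(d$t, strictly = TRUE)) {
        abort("`t` must be strictly increasing within a replica.")
      }
      dl <- diff(d$anchor)
      if (any(dl < 0)) abort("Anchor schedule must be non-decreasing.")
      d$work <- c(0, cumsum(0.5 * (head(d$force, -1) + tail(d$force, -1)) * dl))
      d
    }) |>
    dplyr::ungroup()
  out
}

#' Mean cumulative-work profile with 95% confidence band
#'
#' Per anchor grid point: the sample mean of work across replicas and the
#' Student-t 95% confidence half-width.  A single replica yields `NA`
#' half-widths.
#'
#' @param ens a `pulling_ensemble` (replicas on a shared anchor schedule,
#'   `work` present — see [accumulate_work()]).
#' @return tibble with columns `anchor`, `mean_work`, `sd_work`,
#'   `ci_half` (95% half-width), `n`.
#' @export
mean_work_profile <- function(ens) {
  check_shared_schedule(ens)
  as_tibble(ens) |>
    dplyr::group_by(.data$anchor) |>
    dplyr::summarise(
      mean_work = mean(.data$work),
      sd_work = if (dplyr::n() > 1) sd(.data$work) else NA_real_,
      n = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(ci_half = ifelse(.data$n > 1,
                                   qt(0.975, .data$n - 1) * .data$sd_work /
                                     sqrt(.data$n),
                                   NA_real_)) |>
    dplyr::arrange(.data$anchor) |>
    dplyr::select("anchor", "mean_work", "sd_work", "ci_half", "n")
}

#' Jarzynski estimate from a vector of work values
#'
#' `dG = -kB T log( mean(exp(-W / kB T)) )`, evaluated with a log-sum-exp
#' guard.
#'
#' @param works numeric vector of work values (kcal/mol).
#' @param temperature temperature (K).
#' @return free-energy estimate (kcal/mol).
#' @export
jarzynski_estimate <- function(works, temperature) {
  if (length(works) == 0L || !all(is.finite(works))) {
    abort("`works` must be a non-empty finite vector.")
  }
  kT <- .kB * temperature
  -kT * (log_sum_exp(-works / kT) - log(length(works)))
}

#' Jarzynski and second-cumulant PMF reconstruction
#'
#' Along the shared anchor grid: the mean-work profile with its 95%
#' confidence band, the Jarzynski exponential-average PMF
#' `dG(lambda) = -kB T ln <exp(-beta W(lambda))>` and the second-cumulant
#' (Gaussian) estimate `<W> - beta var(W) / 2`, both gauged to 0 at the
#' first grid point.  An effective-sample-size diagnostic
#' `1 / sum(wtilde^2)` of the normalised exponential weights is attached
#' per grid point (exponential averages over few replicas are noisy).
#'
#' @param ens a `pulling_ensemble` with a `work` column.
#' @param temperature temperature (K); defaults to the ensemble attribute.
#' @return a `pmf_estimate`: tibble `(anchor, mean_work, ci_half,
#'   pmf_jarzynski, pmf_cumulant2, ess)` with attributes `temperature`,
#'   `n_replicas`.
#' @export
jarzynski_pmf <- function(ens, temperature = NULL) {
  temperature <- temperature %||% attr(ens, "temperature")
  if (is.null(temperature)) abort("`temperature` must be supplied.")
  kT <- .kB * temperature
  check_shared_schedule(ens)
  nrep <- length(unique(ens$replica))
  prof <- as_tibble(ens) |>
    dplyr::group_by(.data$anchor) |>
    dplyr::summarise(
      mean_work = mean(.data$work),
      sd_work = if (dplyr::n() > 1) sd(.data$work) else 0,
      n = dplyr::n(),
      pmf_jarzynski = jarzynski_estimate(.data$work, temperature),
      ess = {
        lw <- -.data$work / kT
        wt <- exp(lw - log_sum_exp(lw))
        1 / sum(wt^2)
      },
      .groups = "drop") |>
    dplyr::arrange(.data$anchor) |>
    dplyr::mutate(
      ci_half = ifelse(.data$n > 1,
                       qt(0.975, .data$n - 1) * .data$sd_work / sqrt(.data$n),
                       NA_real_),
      pmf_cumulant2 = .data$mean_work -
        (.data$sd_work^2) / (2 * kT))
  prof <- prof |>
    dplyr::mutate(
      pmf_jarzynski = .data$pmf_jarzynski - .data$pmf_jarzynski[1],
      pmf_cumulant2 = .data$pmf_cumulant2 - .data$pmf_cumulant2[1],
      mean_work = .data$mean_work) |>
    dplyr::select("anchor", "mean_work", "ci_half", "pmf_jarzynski",
                  "pmf_cumulant2", "ess")
  structure(prof, class = c("pmf_estimate", class(tibble())),
            temperature = temperature, n_replicas = nrep)
}

# moving-average smoother, window an odd number of grid points
smooth_profile <- function(y, window) {
  if (window <= 1L) return(y)
  half <- floor(window / 2)
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

# topographic prominence of peak i in profile y
peak_prominence <- function(y, i) {
  n <- length(y)
  left <- if (i > 1) {
    j <- i - 1
    lo <- y[j]
    while (j > 1 && y[j] <= y[i]) {
      j <- j - 1
      lo <- min(lo, y[j])
    }
    lo
  } else y[i]
  right <- if (i < n) {
    j <- i + 1
    lo <- y[j]
    while (j < n && y[j] <= y[i]) {
      j <- j + 1
      lo <- min(lo, y[j])
    }
    lo
  } else y[i]
  y[i] - max(left, right)
}

#' Detect rupture points on the mean force profile
#'
#' Local maxima of the moving-average-smoothed mean force `F(lambda)`,
#' ranked by topographic prominence; boundary maxima are excluded.  The
#' top `n_points` are labelled `RP1`, `RP2`, ...
#'
#' @param ens a `pulling_ensemble`, or a tibble with columns `anchor` and
#'   `force` already averaged over replicas.
#' @param n_points maximum number of rupture points returned (default 2).
#' @param smooth_window moving-average window in grid points (default 5).
#' @return tibble with columns `label`, `distance_A`, `distance_nm`,
#'   `peak_force`, `prominence`; empty when the profile has no interior
#'   maximum.
#' @export
detect_rupture <- function(ens, n_points = 2, smooth_window = 5) {
  tab <- as_tibble(ens)
  if ("replica" %in% names(tab) && length(unique(tab$replica)) > 1) {
    tab <- tab |>
      dplyr::group_by(.data$anchor) |>
      dplyr::summarise(force = mean(.data$force), .groups = "drop")
  }
  tab <- dplyr::arrange(tab, .data$anchor)
  y <- smooth_profile(tab$force, smooth_window)
  n <- length(y)
  if (n < 3L) return(empty_rupture())
  cand <- which(vapply(2:(n - 1), function(i) {
    y[i] > y[i - 1] && y[i] >= y[i + 1]
  }, logical(1))) + 1L
  if (length(cand) == 0L) return(empty_rupture())
  prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
  ord <- order(prom, decreasing = TRUE)
  keep <- head(ord, n_points)
  keep <- keep[order(tab$anchor[cand[keep]])]
  tibble(label = paste0("RP", seq_along(keep)),
         distance_A = tab$anchor[cand[keep]],
         distance_nm = angstrom_to_nm(tab$anchor[cand[keep]]),
         peak_force = y[cand[keep]],
         prominence = prom[keep])
}

empty_rupture <- function() {
  tibble(label = character(), distance_A = numeric(),
         distance_nm = numeric(), peak_force = numeric(),
         prominence = numeric())
}

#' Segment-wise fluctuation profiles along a pulling trajectory
#'
#' Splits a time-ordered coordinate ensemble into `n_segments` equal
#' contiguous blocks and computes the windowed per-residue RMSF of each
#' block via [local_fluctuations()].  With `reversed = TRUE` the blocks
#' are relabelled last-to-first, ordering segments unbound -> bound for a
#' reversed (binding-direction) reading of an unbinding trajectory.
#'
#' @param ens a `coord_ensemble`, frames in time order.
#' @param window residue window passed to [local_fluctuations()].
#' @param n_segments number of blocks (default 4).
#' @param reversed relabel segments in reverse order (default FALSE).
#' @return tibble with columns `segment`, `resno`, `rmsf`; block sizes
#'   partition the frames exactly.
#' @export
segment_fluctuations <- function(ens, window, n_segments = 4,
                                 reversed = FALSE) {
  stopifnot(inherits(ens, "coord_ensemble"))
  n_segments <- check_count(n_segments, "n_segments", 1L)
  f <- n_frames(ens)
  if (f < n_segments) abort("Fewer frames than segments.")
  sizes <- rep(f %/% n_segments, n_segments)
  extra <- f %% n_segments
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bounds <- cumsum(c(0, sizes))
  labels <- if (reversed) rev(seq_len(n_segments)) else seq_len(n_segments)
  purrr::map_dfr(seq_len(n_segments), function(s) {
    idx <- (bounds[s] + 1L):bounds[s + 1L]
    block <- coord_ensemble(ens$coords[idx, , , drop = FALSE], ens$atoms)
    prof <- local_fluctuations(block, window,
                               superpose_first = length(idx) >= 2)
    dplyr::mutate(prof, segment = labels[s], .before = 1)
  }) |>
    dplyr::arrange(.data$segment, .data$resno)
}
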
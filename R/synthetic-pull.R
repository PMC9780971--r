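# Constant-velocity harmonic-spring pulling on analytic 1-D potentials,
# integrated with overdamped Langevin dynamics:
#
#   x <- x + dt * (-U'(x) + k_s (lambda(t) - x)) / gamma
#            + sqrt(2 kB T dt / gamma) * eta
#
# with the anchor schedule lambda(t) = start + v t.  Replicas start from
# an equilibrated distribution at the initial anchor (seeded burn-in at
# fixed anchor).  External work is accumulated as the trapezoid of
# F d(lambda) at every integration step, so recorded work is independent
# of the output stride.  Units: A, ps, kcal/mol.

#' Analytic 1-D pulling potentials
#'
#' * `harmonic`: `U(x) = k_well/2 (x - x0)^2`.
#' * `double_well`: quartic with minima at `minima = c(a, b)`, `U = 0` at
#'   both minima and `U = barrier` at the midpoint.
#' * `flat`: `U = 0`.
#'
#' @param type one of `"harmonic"`, `"double_well"`, `"flat"`.
#' @param k_well harmonic well stiffness (kcal/mol/A^2).
#' @param x0 harmonic well centre (A).
#' @param barrier double-well barrier height (kcal/mol).
#' @param minima double-well minima positions, length 2 (A).
#' @return a `pull_potential` (list with `U` and `dU` functions).
#' @export
pull_potential <- function(type = c("harmonic", "double_well", "flat"),
                           k_well = 1, x0 = 0, barrier = 3,
                           minima = c(0, 5)) {
  type <- match.arg(type)
  pot <- switch(type,
    flat = list(U = function(x) 0 * x, dU = function(x) 0 * x,
                stiffness = 0),
    harmonic = {
      check_scalar_number(k_well, "k_well", 0, strict_lower = TRUE)
      list(U = function(x) 0.5 * k_well * (x - x0)^2,
           dU = function(x) k_well * (x - x0),
           stiffness = k_well)
    },
    double_well = {
      check_scalar_number(barrier, "barrier", 0, strict_lower = TRUE)
      if (length(minima) != 2L || minima[2] <= minima[1]) {
        abort("`minima` must be two increasing positions.")
      }
      ctr <- mean(minima)
      d <- (minima[2] - minima[1]) / 2
      list(U = function(x) barrier * ((x - ctr)^2 - d^2)^2 / d^4,
           dU = function(x) 4 * barrier * ((x - ctr)^2 - d^2) * (x - ctr) / d^4,
           stiffness = 8 * barrier / d^2)
    })
  structure(c(pot, list(type = type,
                        params = list(k_well = k_well, x0 = x0,
                                      barrier = barrier, minima = minima))),
            class = "pull_potential")
}

#' Specify a constant-velocity pulling experiment
#'
#' @param potential a [pull_potential()].
#' @param spring_k pulling spring constant (kcal/mol/A^2).
#' @param velocity anchor velocity (A/ps).
#' @param temperature bath temperature (K).
#' @param friction friction coefficient gamma (kcal mol^-1 ps A^-2).
#' @param dt integration step (ps); rejected when
#'   `(spring_k + well stiffness) * dt / friction >= 1` (unstable).
#' @param start_anchor,end_anchor anchor schedule endpoints (A),
#'   `end_anchor > start_anchor`.
#' @param n_replicas number of independent pulls sharing the schedule.
#' @param stride record every `stride`-th integration step (default 10).
#' @param equilibration_steps burn-in steps at the initial anchor before
#'   pulling (default 2000), giving equilibrated initial conditions as
#'   the Jarzynski identity requires.
#' @param seed integer seed.
#' @return a `pull_spec`.
#' @export
pull_spec <- function(potential, spring_k, velocity, temperature = 300,
                      friction = 1, dt = 0.005, start_anchor = 0,
                      end_anchor = 10, n_replicas = 20, stride = 10,
                      equilibration_steps = 2000, seed = 1L) {
  stopifnot(inherits(potential, "pull_potential"))
  check_scalar_number(spring_k, "spring_k", 0, strict_lower = TRUE)
  check_scalar_number(velocity, "velocity", 0, strict_lower = TRUE)
  check_scalar_number(temperature, "temperature", 0, strict_lower = TRUE)
  check_scalar_number(friction, "friction", 0, strict_lower = TRUE)
  check_scalar_number(dt, "dt", 0, strict_lower = TRUE)
  if (end_anchor <= start_anchor) abort("`end_anchor` must exceed `start_anchor`.")
  n_replicas <- check_count(n_replicas, "n_replicas", 1L)
  stride <- check_count(stride, "stride", 1L)
  stiff <- spring_k + potential$stiffness
  if (stiff * dt / friction >= 1) {
    abort(sprintf(
      "Unstable integration: (spring_k + well stiffness) * dt / friction = %.3g >= 1; reduce dt.",
      stiff * dt / friction))
  }
  structure(list(potential = potential, spring_k = spring_k,
                 velocity = velocity, temperature = temperature,
                 friction = friction, dt = dt,
                 start_anchor = start_anchor, end_anchor = end_anchor,
                 n_replicas = n_replicas, stride = stride,
                 equilibration_steps = check_count(equilibration_steps,
                                                   "equilibration_steps", 0L),
                 seed = as.integer(seed)),
            class = "pull_spec")
}

#' Simulate a constant-velocity pulling ensemble
#'
#' All replicas share the anchor schedule exactly; the trajectory records
#' `(replica, t, anchor, x, force, work)` at the spec's stride (first and
#' last steps always included).  Force is `spring_k * (anchor - x)`;
#' work is the external work done by the moving anchor, accumulated by
#' trapezoid at full integration resolution.
#'
#' @param spec a [pull_spec()].
#' @return a `pulling_ensemble`: tibble
#'   `(replica, t, anchor, x, force, work)` with attributes
#'   `temperature`, `spec`.
#' @export
simulate_pull <- function(spec) {
  stopifnot(inherits(spec, "pull_spec"))
  ks <- spec$spring_k
  g <- spec$friction
  dt <- spec$dt
  kT <- .kB * spec$temperature
  n_steps <- ceiling((spec$end_anchor - spec$start_anchor) /
                       (spec$velocity * dt))
  lambda <- spec$start_anchor + spec$velocity * dt * (0:n_steps)
  rec <- unique(c(seq(1L, n_steps + 1L, by = spec$stride), n_steps + 1L))
  nr <- spec$n_replicas
  noise_sd <- sqrt(2 * kT * dt / g)
  dU <- spec$potential$dU
  with_seed(spec$seed, {
    x <- rep(spec$start_anchor, nr)
    for (k in seq_len(spec$equilibration_steps)) {
      x <- x + dt * (-dU(x) + ks * (lambda[1] - x)) / g +
        noise_sd * rnorm(nr)
    }
    X <- matrix(0, length(rec), nr)
    Fm <- matrix(0, length(rec), nr)
    Wm <- matrix(0, length(rec), nr)
    w <- numeric(nr)
    f_prev <- ks * (lambda[1] - x)
    ri <- 1L
    if (rec[1] == 1L) {
      X[1, ] <- x; Fm[1, ] <- f_prev; Wm[1, ] <- 0
      ri <- 2L
    }
    for (k in seq_len(n_steps)) {
      x <- x + dt * (-dU(x) + ks * (lambda[k] - x)) / g +
        noise_sd * rnorm(nr)
      f_now <- ks * (lambda[k + 1L] - x)
      w <- w + 0.5 * (f_prev + f_now) * (lambda[k + 1L] - lambda[k])
      f_prev <- f_now
      if (ri <= length(rec) && rec[ri] == k + 1L) {
        X[ri, ] <- x; Fm[ri, ] <- f_now; Wm[ri, ] <- w
        ri <- ri + 1L
      }
    }
    out <- tibble(
      replica = rep(seq_len(nr), each = length(rec)),
      t = rep(dt * (rec - 1L), times = nr),
      anchor = rep(lambda[rec], times = nr),
      x = as.vector(X),
      force = as.vector(Fm),
      work = as.vector(Wm))
    new_pulling_ensemble(out, spec$temperature, spec)
  })
}

new_pulling_ensemble <- function(tbl, temperature, spec = NULL) {
  structure(tbl, class = c("pulling_ensemble", class(tibble())),
            temperature = temperature, spec = spec)
}

#' Read/write pulling records as CSV
#'
#' Columns `replica, t, anchor, x, force` and optionally `work`.
#'
#' @param path file path.
#' @param temperature bath temperature (K) to attach on read.
#' @return a `pulling_ensemble` (read) or `path` invisibly (write).
#' @export
read_pulling_csv <- function(path, temperature = 300) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("replica", "t", "anchor", "x", "force")
  if (!all(need %in% names(tab))) {
    abort(sprintf("Pulling CSV must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  new_pulling_ensemble(as_tibble(tab), temperature)
}

#' @rdname read_pulling_csv
#' @param ens a `pulling_ensemble`.
#' @export
write_pulling_csv <- function(ens, path) {
  readr::write_csv(as_tibble(ens), path)
  invisible(path)
}
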
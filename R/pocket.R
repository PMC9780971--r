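# POVME-style grid-based occluded-volume measurement.  An axis-aligned
# lattice at the requested spacing, anchored at the first inclusion
# centre (translation-reproducible), covers the union bounding box of the
# inclusion spheres; points inside at least one inclusion sphere form the
# empty-pocket grid, and points within an atom's van der Waals radius
# (plus optional padding) are removed.  Volume = kept points x spacing^3.

# Bondi van der Waals radii (A)
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                 P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                 ZN = 1.39, MG = 1.73, "NA" = 2.27, K = 2.75, FE = 1.94,
                 CA = 2.31)

resolve_radii <- function(atoms) {
  if ("radius" %in% names(atoms) && !anyNA(atoms$radius)) {
    return(as.numeric(atoms$radius))
  }
  if (!"element" %in% names(atoms)) abort("Atoms need `element` or `radius`.")
  el <- toupper(atoms$element)
  r <- BONDI_RADII[el]
  if ("radius" %in% names(atoms)) {
    r[!is.na(atoms$radius)] <- atoms$radius[!is.na(atoms$radius)]
  }
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    abort(sprintf("No van der Waals radius for atom %d (element '%s'); supply `radius`.",
                  bad, el[bad]))
  }
  unname(r)
}

#' Construct a pocket scene
#'
#' @param atoms tibble of blocking atoms with columns `x`, `y`, `z` and
#'   either `element` (resolved against a Bondi radius table) or an
#'   explicit `radius` (A); may have zero rows.
#' @param inclusion tibble of inclusion spheres with columns `x`, `y`,
#'   `z`, `radius` (at least one row, positive radii).
#' @param grid_spacing lattice spacing in angstrom (default 1.0).
#' @param padding extra radius added to every atom when removing grid
#'   points (default 0).
#' @param contiguity keep only grid points flood-fill-connected
#'   (26-neighbourhood) to the inclusion centres (default FALSE).
#' @return a `pocket_scene`.
#' @export
pocket_scene <- function(atoms = NULL, inclusion, grid_spacing = 1.0,
                         padding = 0, contiguity = FALSE) {
  atoms <- as_tibble(atoms %||% tibble(x = numeric(), y = numeric(),
                                       z = numeric(), radius = numeric()))
  inclusion <- as_tibble(inclusion)
  if (nrow(inclusion) < 1L) abort("At least one inclusion sphere is required.")
  if (!all(c("x", "y", "z", "radius") %in% names(inclusion))) {
    abort("`inclusion` needs columns x, y, z, radius.")
  }
  if (any(inclusion$radius <= 0)) abort("Inclusion radii must be positive.")
  check_scalar_number(grid_spacing, "grid_spacing", 0, strict_lower = TRUE)
  check_scalar_number(padding, "padding", 0)
  if (nrow(atoms) > 0 && !any(c("radius", "element") %in% names(atoms))) {
    abort("`atoms` needs an `element` or `radius` column.")
  }
  structure(list(atoms = atoms, inclusion = inclusion,
                 grid_spacing = grid_spacing, padding = padding,
                 contiguity = contiguity),
            class = "pocket_scene")
}

#' Specify a toy pocket scene
#'
#' A single spherical inclusion region plus spherical blocking
#' pseudo-atoms with explicit radii — the synthetic fixture counterpart of
#' a real binding-pocket scene.
#'
#' @param inclusion_center length-3 centre of the inclusion sphere (A).
#' @param inclusion_radius inclusion sphere radius (A).
#' @param blockers list of `list(center, radius)` blocking pseudo-atoms.
#' @param grid_spacing lattice spacing (default 1.0 A).
#' @param seed integer seed (recorded; scene construction is
#'   deterministic).
#' @return a `pocket_scene_spec`.
#' @export
pocket_scene_spec <- function(inclusion_center = c(0, 0, 0),
                              inclusion_radius = 8,
                              blockers = list(), grid_spacing = 1.0,
                              seed = 1L) {
  check_scalar_number(inclusion_radius, "inclusion_radius", 0,
                      strict_lower = TRUE)
  for (b in blockers) {
    if (length(b$center) != 3L) abort("Blocker centres must be length-3.")
    check_scalar_number(b$radius, "blocker radius", 0, strict_lower = TRUE)
  }
  structure(list(inclusion_center = as.numeric(inclusion_center),
                 inclusion_radius = inclusion_radius, blockers = blockers,
                 grid_spacing = grid_spacing, seed = as.integer(seed)),
            class = "pocket_scene_spec")
}

#' Realise a pocket scene from its spec
#'
#' @param spec a [pocket_scene_spec()].
#' @return a `pocket_scene` whose blockers are pseudo-atoms carrying the
#'   given radii.
#' @export
build_pocket_scene <- function(spec) {
  stopifnot(inherits(spec, "pocket_scene_spec"))
  atoms <- purrr::map_dfr(spec$blockers, function(b) {
    tibble(x = b$center[1], y = b$center[2], z = b$center[3],
           radius = b$radius)
  })
  if (nrow(atoms) == 0L) {
    atoms <- tibble(x = numeric(), y = numeric(), z = numeric(),
                    radius = numeric())
  }
  pocket_scene(atoms = atoms,
               inclusion = tibble(x = spec$inclusion_center[1],
                                  y = spec$inclusion_center[2],
                                  z = spec$inclusion_center[3],
                                  radius = spec$inclusion_radius),
               grid_spacing = spec$grid_spacing)
}

#' Build the inclusion-region grid
#'
#' Lattice points at `grid_spacing`, anchored at the first inclusion
#' centre, covering the union bounding box of the inclusion spheres and
#' filtered to points inside at least one sphere.
#'
#' @param scene a `pocket_scene`.
#' @return numeric matrix of grid points (columns x, y, z).
#' @export
build_grid <- function(scene) {
  stopifnot(inherits(scene, "pocket_scene"))
  sp <- scene$grid_spacing
  inc <- scene$inclusion
  anchor <- as.numeric(inc[1, c("x", "y", "z")])
  lo <- c(min(inc$x - inc$radius), min(inc$y - inc$radius),
          min(inc$z - inc$radius))
  hi <- c(max(inc$x + inc$radius), max(inc$y + inc$radius),
          max(inc$z + inc$radius))
  axes <- purrr::map(1:3, function(d) {
    k <- seq(floor((lo[d] - anchor[d]) / sp), ceiling((hi[d] - anchor[d]) / sp))
    anchor[d] + sp * k
  })
  pts <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  inside <- rep(FALSE, nrow(pts))
  for (s in seq_len(nrow(inc))) {
    d2 <- (pts[, 1] - inc$x[s])^2 + (pts[, 2] - inc$y[s])^2 +
      (pts[, 3] - inc$z[s])^2
    inside <- inside | d2 <= inc$radius[s]^2
  }
  pts[inside, , drop = FALSE]
}

# 26-neighbour flood fill on kept lattice points, seeded at the voxels
# nearest the inclusion centres
contiguity_filter <- function(pts, scene) {
  if (nrow(pts) == 0L) return(logical(0))
  sp <- scene$grid_spacing
  ijk <- round(sweep(pts, 2, pts[1, ]) / sp)
  ijk <- sweep(ijk, 2, apply(ijk, 2, min))
  dims <- apply(ijk, 2, max) + 1L
  key <- ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])
  idx_of <- new.env(hash = TRUE, size = nrow(pts))
  for (i in seq_len(nrow(pts))) assign(as.character(key[i]), i, envir = idx_of)
  seeds <- vapply(seq_len(nrow(scene$inclusion)), function(s) {
    ctr <- as.numeric(scene$inclusion[s, c("x", "y", "z")])
    which.min(colSums((t(pts) - ctr)^2))
  }, integer(1))
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  visited <- rep(FALSE, nrow(pts))
  queue <- unique(seeds)
  visited[queue] <- TRUE
  while (length(queue) > 0L) {
    i <- queue[1]
    queue <- queue[-1]
    nb <- sweep(offsets, 2, as.numeric(ijk[i, ]), `+`)
    inb <- nb[, 1] >= 0 & nb[, 1] < dims[1] &
      nb[, 2] >= 0 & nb[, 2] < dims[2] &
      nb[, 3] >= 0 & nb[, 3] < dims[3]
    nbkey <- nb[inb, 1] + dims[1] * (nb[inb, 2] + dims[2] * nb[inb, 3])
    for (k in nbkey) {
      j <- mget(as.character(k), envir = idx_of, ifnotfound = list(NULL))[[1]]
      if (!is.null(j) && !visited[j]) {
        visited[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  visited
}

#' Measure the occluded pocket volume
#'
#' Grid points closer to an atom centre than that atom's radius (plus
#' scene padding) are removed; the remaining count times `spacing^3` is
#' the pocket volume.
#'
#' @param scene a `pocket_scene`.
#' @param frame optional `n_atoms x 3` matrix of alternative atom
#'   coordinates (e.g. one trajectory frame); defaults to the scene's
#'   atom coordinates.
#' @return a `volume_result`: list with `volume` (A^3), `n_points_kept`,
#'   `n_points_total`, `grid_spacing`.
#' @export
measure_volume <- function(scene, frame = NULL) {
  stopifnot(inherits(scene, "pocket_scene"))
  pts <- build_grid(scene)
  total <- nrow(pts)
  keep <- rep(TRUE, total)
  if (nrow(scene$atoms) > 0L) {
    xyz <- if (is.null(frame)) {
      as.matrix(scene$atoms[, c("x", "y", "z")])
    } else {
      frame <- as.matrix(frame)
      if (nrow(frame) != nrow(scene$atoms)) {
        abort("`frame` must supply coordinates for every scene atom.")
      }
      frame
    }
    rad <- resolve_radii(scene$atoms) + scene$padding
    for (a in seq_len(nrow(xyz))) {
      d2 <- (pts[, 1] - xyz[a, 1])^2 + (pts[, 2] - xyz[a, 2])^2 +
        (pts[, 3] - xyz[a, 3])^2
      keep <- keep & d2 >= rad[a]^2
    }
  }
  if (scene$contiguity && any(keep)) {
    kept_pts <- pts[keep, , drop = FALSE]
    keep[keep] <- contiguity_filter(kept_pts, scene)
  }
  structure(list(volume = sum(keep) * scene$grid_spacing^3,
                 n_points_kept = sum(keep), n_points_total = total,
                 grid_spacing = scene$grid_spacing),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("<volume_result> %.1f A^3 (%d / %d grid points at %.2f A)\n",
              x$volume, x$n_points_kept, x$n_points_total, x$grid_spacing))
  if (!is.null(x$series)) {
    cat(sprintf("  %d frames: mean %.1f, min %.1f, max %.1f A^3\n",
                nrow(x$series), x$summary$mean, x$summary$min, x$summary$max))
  }
  invisible(x)
}

#' Pocket volume along a coordinate ensemble
#'
#' Measures the scene per frame (the inclusion region is held fixed in
#' the superposed frame of reference) and attaches the per-frame series
#' plus a mean/min/max summary.
#'
#' @param scene a `pocket_scene` whose atoms correspond one-to-one to the
#'   ensemble's atoms.
#' @param ens a `coord_ensemble` carrying the scene's atoms.
#' @return a `volume_result` with `series` (tibble `frame`, `volume`) and
#'   `summary` (list `mean`, `min`, `max`).
#' @export
volume_series <- function(scene, ens) {
  stopifnot(inherits(scene, "pocket_scene"), inherits(ens, "coord_ensemble"))
  if (n_atoms(ens) != nrow(scene$atoms)) {
    abort("Ensemble atom count does not match the scene's atoms.")
  }
  vols <- vapply(seq_len(n_frames(ens)), function(k) {
    measure_volume(scene, frame = frame_coords(ens, k))$volume
  }, numeric(1))
  out <- measure_volume(scene, frame = frame_coords(ens, 1))
  out$series <- tibble(frame = seq_len(n_frames(ens)), volume = vols)
  out$summary <- list(mean = mean(vols), min = min(vols), max = max(vols))
  out$volume <- mean(vols)
  out
}

#' Monte-Carlo reference for a pocket volume
#'
#' Uniform rejection sampling over the bounding box of the inclusion
#' spheres — an independent oracle for the grid-based measurement.
#'
#' @param scene a `pocket_scene`.
#' @param n_samples number of sample points (default 1e6).
#' @param seed integer seed.
#' @return list with `volume` (A^3) and `se` (standard error).
#' @export
monte_carlo_volume <- function(scene, n_samples = 1e6, seed = 1L) {
  stopifnot(inherits(scene, "pocket_scene"))
  inc <- scene$inclusion
  lo <- c(min(inc$x - inc$radius), min(inc$y - inc$radius),
          min(inc$z - inc$radius))
  hi <- c(max(inc$x + inc$radius), max(inc$y + inc$radius),
          max(inc$z + inc$radius))
  box <- prod(hi - lo)
  with_seed(seed, {
    pts <- cbind(runif(n_samples, lo[1], hi[1]),
                 runif(n_samples, lo[2], hi[2]),
                 runif(n_samples, lo[3], hi[3]))
    inside <- rep(FALSE, n_samples)
    for (s in seq_len(nrow(inc))) {
      d2 <- (pts[, 1] - inc$x[s])^2 + (pts[, 2] - inc$y[s])^2 +
        (pts[, 3] - inc$z[s])^2
      inside <- inside | d2 <= inc$radius[s]^2
    }
    if (nrow(scene$atoms) > 0L) {
      rad <- resolve_radii(scene$atoms) + scene$padding
      for (a in seq_len(nrow(scene$atoms))) {
        d2 <- (pts[, 1] - scene$atoms$x[a])^2 +
          (pts[, 2] - scene$atoms$y[a])^2 +
          (pts[, 3] - scene$atoms$z[a])^2
        inside <- inside & d2 >= rad[a]^2
      }
    }
    p <- mean(inside)
    list(volume = box * p, se = box * sqrt(p * (1 - p) / n_samples))
  })
}
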
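# PDB structure handling (via bio3d) and the residue-residue minimal
# heavy-atom distance map consumed by proximity MI.

#' Read a (multi-model) PDB structure
#'
#' All MODEL blocks are parsed; ATOM and HETATM records are retained.
#' When altloc duplicates are present the highest-occupancy altloc is
#' kept (ties: first), and the element is inferred from the atom name
#' when the element column is blank.
#'
#' @param path PDB file path.
#' @return a `structure_model`: list with `atoms` (tibble: `serial`,
#'   `name`, `resid`, `resno`, `chain`, `element`, `x`, `y`, `z` of the
#'   first model) and `coords` (`n_models x n_atoms x 3` array).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- as_tibble(pdb$atom)
  if (nrow(at) == 0L) abort(sprintf("No ATOM records in %s", path))
  # altloc policy: keep highest occupancy per (chain, resno, atom name)
  alt_present <- "alt" %in% names(at) &&
    any(!is.na(at$alt) & nzchar(trimws(at$alt)))
  if (alt_present) {
    at$.row <- seq_len(nrow(at))
    at <- at |>
      dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$elety) |>
      dplyr::arrange(dplyr::desc(.data$o), .data$.row,
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$.row)
    keep_idx <- at$.row
    at$.row <- NULL
  } else {
    keep_idx <- seq_len(nrow(at))
  }
  elem <- if ("elesy" %in% names(at)) at$elesy else rep("", nrow(at))
  elem[is.na(elem)] <- ""
  blank <- !nzchar(trimws(elem))
  if (any(blank)) {
    elem[blank] <- substr(gsub("[^A-Za-z].*", "",
                               gsub("^[0-9]+", "", at$elety[blank])), 1, 1)
  }
  xyz <- pdb$xyz
  if (is.matrix(xyz)) {
    n_models <- nrow(xyz)
  } else {
    xyz <- matrix(xyz, nrow = 1)
    n_models <- 1L
  }
  cols <- as.vector(vapply(keep_idx, function(i) (i - 1L) * 3L + 1:3,
                           integer(3)))
  coords <- array(0, dim = c(n_models, length(keep_idx), 3))
  for (m in seq_len(n_models)) {
    coords[m, , ] <- matrix(xyz[m, cols], ncol = 3, byrow = TRUE)
  }
  atoms <- tibble(serial = at$eleno, name = at$elety, resid = at$resid,
                  resno = at$resno, chain = at$chain,
                  element = toupper(elem),
                  x = coords[1, , 1], y = coords[1, , 2], z = coords[1, , 3])
  structure(list(atoms = atoms, coords = coords), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d model(s), %d atoms, %d residues\n",
              dim(x$coords)[1], nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")]))))
  invisible(x)
}

#' Convert a structure's models to a coordinate ensemble
#' @param structure a `structure_model`.
#' @return a `coord_ensemble` (one frame per model).
#' @export
as_coord_ensemble <- function(structure) {
  stopifnot(inherits(structure, "structure_model"))
  coord_ensemble(structure$coords,
                 structure$atoms[, c("name", "resno", "chain", "element")])
}

#' Minimal inter-residue heavy-atom distance map
#'
#' `distance(i, j)` is the minimum over heavy-atom pairs of residues `i`
#' and `j` in the chosen model; symmetric with zero diagonal.  Residues
#' are ordered by (chain, residue number).
#'
#' @param structure a `structure_model`.
#' @param model_index which model to use (default 1).
#' @return symmetric numeric matrix with residue labels as dimnames.
#' @export
residue_distance_map <- function(structure, model_index = 1) {
  stopifnot(inherits(structure, "structure_model"))
  if (model_index > dim(structure$coords)[1]) abort("No such model.")
  at <- structure$atoms
  heavy <- toupper(at$element) != "H"
  xyz <- matrix(structure$coords[model_index, heavy, ], ncol = 3)
  res_key <- paste(at$chain[heavy], at$resno[heavy], sep = ":")
  keys <- unique(res_key)
  L <- length(keys)
  D <- matrix(0, L, L, dimnames = list(keys, keys))
  groups <- split(seq_len(nrow(xyz)), factor(res_key, levels = keys))
  full <- as.matrix(stats::dist(xyz))
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      D[i, j] <- D[j, i] <- min(full[groups[[i]], groups[[j]]])
    }
  }
  D
}

#' Derive a pocket inclusion sphere from a bound structure
#'
#' The pocket centre is the centre of mass of the heavy atoms of protein
#' residues lying within `cutoff` of the ligand (default 4.5 A, the
#' convention used to define a binding-pocket centre of mass for pulling
#' and volumetrics).
#'
#' @param structure a `structure_model`.
#' @param ligand_resid residue name(s) identifying the ligand.
#' @param cutoff contact cutoff in angstrom (default 4.5).
#' @param radius inclusion sphere radius (default 8 A).
#' @param grid_spacing lattice spacing (default 1.0 A).
#' @return a `pocket_scene` whose blockers are the pocket residues' heavy
#'   atoms.
#' @export
pocket_from_structure <- function(structure, ligand_resid, cutoff = 4.5,
                                  radius = 8, grid_spacing = 1.0) {
  at <- structure$atoms
  is_lig <- at$resid %in% ligand_resid
  if (!any(is_lig)) abort("No ligand atoms matched `ligand_resid`.")
  heavy <- toupper(at$element) != "H"
  lig <- as.matrix(at[is_lig & heavy, c("x", "y", "z")])
  prot <- which(!is_lig & heavy)
  pxyz <- as.matrix(at[prot, c("x", "y", "z")])
  mind <- apply(pxyz, 1, function(p) {
    sqrt(min(colSums((t(lig) - p)^2)))
  })
  pocket_res <- unique(at$resno[prot][mind <= cutoff])
  if (length(pocket_res) == 0L) abort("No pocket residues within the cutoff.")
  sel <- prot[at$resno[prot] %in% pocket_res]
  com <- colMeans(as.matrix(at[sel, c("x", "y", "z")]))
  pocket_scene(
    atoms = at[sel, c("x", "y", "z", "element")],
    inclusion = tibble(x = com[1], y = com[2], z = com[3], radius = radius),
    grid_spacing = grid_spacing)
}
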
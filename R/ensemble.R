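# Coordinate ensemble container (frames x atoms x 3, angstrom) with atom
# labels, plus readers/writers for multi-model PDB and the flat per-frame
# coordinate table (columns: frame, atom_index, x, y, z).

#' Construct a coordinate ensemble
#'
#' @param coords numeric array `n_frames x n_atoms x 3` (angstrom), or a
#'   list of `n_atoms x 3` frame matrices.
#' @param atoms optional tibble describing the atoms, with columns `name`
#'   (PDB atom name), `resno`, `chain`, `element`; defaults to a chain of
#'   C-alpha pseudo-atoms, one residue per atom.
#' @return a `coord_ensemble`.
#' @export
coord_ensemble <- function(coords, atoms = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    abort("`coords` must be an n_frames x n_atoms x 3 array.")
  }
  if (!all(is.finite(coords))) abort("Coordinates must be finite.")
  na <- dim(coords)[2]
  if (is.null(atoms)) {
    atoms <- tibble(name = "CA", resno = seq_len(na), chain = "A",
                    element = "C")
  }
  atoms <- as_tibble(atoms)
  if (nrow(atoms) != na) abort("`atoms` must have one row per atom.")
  for (col in c("name", "resno", "chain", "element")) {
    if (is.null(atoms[[col]])) {
      atoms[[col]] <- switch(col, name = "CA", resno = seq_len(na),
                             chain = "A", element = "C")
    }
  }
  structure(list(coords = coords, atoms = atoms), class = "coord_ensemble")
}

#' @export
print.coord_ensemble <- function(x, ...) {
  cat(sprintf("<coord_ensemble> %d frames x %d atoms (%d residues)\n",
              n_frames(x), n_atoms(x), length(unique(x$atoms$resno))))
  invisible(x)
}

#' Ensemble dimensions
#' @param ens a `coord_ensemble`.
#' @return integer count.
#' @export
n_frames <- function(ens) dim(ens$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(ens) dim(ens$coords)[2]

#' Extract one frame as an atoms x 3 matrix
#' @param ens a `coord_ensemble`.
#' @param i frame index.
#' @return numeric `n_atoms x 3` matrix.
#' @export
frame_coords <- function(ens, i) {
  matrix(ens$coords[i, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

# frames x 3m matrix over selected atoms, coordinates interleaved per atom
# (x1, y1, z1, x2, ...)
ensemble_matrix <- function(ens, selection = NULL) {
  selection <- selection %||% seq_len(n_atoms(ens))
  sub <- ens$coords[, selection, , drop = FALSE]
  f <- dim(sub)[1]
  m <- dim(sub)[2]
  out <- matrix(0, f, 3L * m)
  out[, seq(1, 3 * m, by = 3)] <- sub[, , 1]
  out[, seq(2, 3 * m, by = 3)] <- sub[, , 2]
  out[, seq(3, 3 * m, by = 3)] <- sub[, , 3]
  out
}

# inverse of ensemble_matrix for a single flattened frame
unflatten_frame <- function(v) {
  matrix(v, ncol = 3, byrow = TRUE, dimnames = list(NULL, c("x", "y", "z")))
}

#' Select atom indices by name, residue window and chain
#'
#' @param ens a `coord_ensemble`.
#' @param names atom names to keep (e.g. `c("CA", "N", "C")` for the
#'   backbone); `NULL` keeps all.
#' @param resno residue numbers to keep (vector or range); `NULL` keeps all.
#' @param chain chain identifiers to keep; `NULL` keeps all.
#' @param heavy_only drop atoms whose element is `H`.
#' @return integer vector of atom indices.
#' @export
atom_selection <- function(ens, names = NULL, resno = NULL, chain = NULL,
                           heavy_only = FALSE) {
  keep <- rep(TRUE, n_atoms(ens))
  at <- ens$atoms
  if (!is.null(names)) keep <- keep & at$name %in% names
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (heavy_only) keep <- keep & toupper(at$element) != "H"
  which(keep)
}

#' Backbone (C-alpha, N, C) atom indices
#' @param ens a `coord_ensemble`.
#' @return integer vector; all atoms (with a warning) when no backbone
#'   names are present, so synthetic pseudo-atom ensembles work unchanged.
#' @export
backbone_selection <- function(ens) {
  idx <- atom_selection(ens, names = c("CA", "N", "C"))
  if (length(idx) == 0L) {
    warn("No CA/N/C atoms found; using all atoms as the backbone selection.")
    idx <- seq_len(n_atoms(ens))
  }
  idx
}

#' Read/write the flat per-frame coordinate table
#'
#' The table has columns `frame`, `atom_index`, `x`, `y`, `z`
#' (whitespace- or comma-delimited on read; written as CSV).
#'
#' @param path file path.
#' @param atoms optional atom table passed to [coord_ensemble()].
#' @return a `coord_ensemble` (read) or `path` invisibly (write).
#' @export
read_coord_table <- function(path, atoms = NULL) {
  tab <- readr::read_table(path, col_names = TRUE, show_col_types = FALSE)
  if (ncol(tab) == 1L) {
    tab <- readr::read_csv(path, show_col_types = FALSE)
  }
  need <- c("frame", "atom_index", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    abort(sprintf("Coordinate table must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  tab <- dplyr::arrange(tab, .data$frame, .data$atom_index)
  fr <- sort(unique(tab$frame))
  na <- length(unique(tab$atom_index))
  if (nrow(tab) != length(fr) * na) {
    abort("Coordinate table is ragged: every frame must list every atom.")
  }
  coords <- array(0, dim = c(length(fr), na, 3))
  xyz <- as.matrix(tab[, c("x", "y", "z")])
  for (k in seq_along(fr)) {
    coords[k, , ] <- xyz[tab$frame == fr[k], , drop = FALSE]
  }
  coord_ensemble(coords, atoms)
}

#' @rdname read_coord_table
#' @param ens a `coord_ensemble`.
#' @export
write_coord_table <- function(ens, path) {
  f <- n_frames(ens)
  a <- n_atoms(ens)
  tab <- tibble(
    frame = rep(seq_len(f), each = a),
    atom_index = rep(seq_len(a), times = f),
    x = as.vector(aperm(ens$coords[, , 1, drop = FALSE], c(2, 1, 3))),
    y = as.vector(aperm(ens$coords[, , 2, drop = FALSE], c(2, 1, 3))),
    z = as.vector(aperm(ens$coords[, , 3, drop = FALSE], c(2, 1, 3))))
  readr::write_csv(tab, path)
  invisible(path)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens a `coord_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ens, path) {
  xyz <- ensemble_matrix(ens)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = ens$atoms$resno,
                   resid = rep("ALA", n_atoms(ens)),
                   elety = ens$atoms$name,
                   chain = ens$atoms$chain)
  invisible(path)
}
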
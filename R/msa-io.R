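# MSA container and alignment readers/writers.
#
# An `msa` is a tibble with columns `id` and `seq` (equal-length aligned
# strings over the 20 amino acids plus '-'), carrying class "msa" so
# downstream statistics can validate their input cheaply.

new_msa <- function(ids, seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1])[1]
    abort(sprintf(
      "Alignment is ragged: row %d ('%s') has %d columns, expected %d.",
      bad, ids[bad], lens[bad], lens[1]))
  }
  if (length(seqs) == 0L || lens[1] == 0L) {
    abort("Alignment is empty.")
  }
  out <- tibble(id = unname(as.character(ids)),
                seq = unname(toupper(seqs)))
  class(out) <- c("msa", class(out))
  out
}

#' Coerce aligned sequences to an `msa`
#'
#' Symbols outside the 20 amino acids and the gap character `-` (including
#' `.`, `X`, `B`, `Z`) are mapped to gaps with a warning, matching the
#' policy of alignment servers that restrict to the canonical alphabet.
#'
#' @param x character vector of aligned sequences (equal lengths), possibly
#'   named, or a character matrix of single residues.
#' @param ids optional sequence identifiers.
#' @return an `msa` tibble with columns `id`, `seq`.
#' @export
as_msa <- function(x, ids = NULL) {
  if (is.matrix(x)) x <- apply(x, 1, paste0, collapse = "")
  ids <- ids %||% names(x) %||% paste0("seq", seq_along(x))
  x <- toupper(x)
  x <- gsub(".", "-", x, fixed = TRUE)
  chars <- unique(strsplit(paste0(x, collapse = ""), "")[[1]])
  alien <- setdiff(chars, MSA_ALPHABET)
  if (length(alien) > 0L) {
    warn(sprintf("Mapping non-standard symbols to gap: %s",
                 paste(alien, collapse = ", ")))
    for (a in alien) x <- gsub(a, GAP_CHAR, x, fixed = TRUE)
  }
  new_msa(ids, x)
}

#' Number of columns of an alignment
#' @param msa an `msa`.
#' @return integer column count.
#' @export
msa_length <- function(msa) nchar(msa$seq[1])

#' Alignment as a residue character matrix
#' @param msa an `msa`.
#' @return n_sequences x length character matrix.
#' @export
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$seq, ""))
  rownames(m) <- msa$id
  m
}

#' Read a multiple sequence alignment
#'
#' FASTA is parsed with [bio3d::read.fasta()]; Stockholm is parsed
#' directly (annotation `#=..` lines skipped, `.` and lowercase insertion
#' states normalised to gaps/uppercase, multi-block files supported).
#'
#' @param path file path.
#' @param format `"auto"` (sniff first non-blank line), `"fasta"` or
#'   `"stockholm"`.
#' @return an `msa` tibble.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))]
    if (length(first) == 0L) abort(sprintf("Empty alignment file: %s", path))
    format <- if (grepl("^# STOCKHOLM", first[1])) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    fa <- bio3d::read.fasta(path)
    as_msa(apply(fa$ali, 1, paste0, collapse = ""), ids = fa$id)
  } else {
    read_stockholm(path)
  }
}

read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqs <- list()
  order_ids <- character()
  for (ln in lines) {
    ln <- trimws(ln, which = "right")
    if (!nzchar(ln) || startsWith(ln, "#") || ln == "//") next
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) != 2L) {
      abort(sprintf("Malformed Stockholm sequence line: '%s'", ln))
    }
    id <- parts[1]
    if (!id %in% order_ids) order_ids <- c(order_ids, id)
    seqs[[id]] <- paste0(seqs[[id]] %||% "", parts[2])
  }
  if (length(seqs) == 0L) abort(sprintf("No sequences found in %s", path))
  as_msa(unlist(seqs[order_ids]), ids = order_ids)
}

#' Write an alignment as FASTA
#' @param msa an `msa`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  ali <- msa_matrix(msa)
  bio3d::write.fasta(seqs = ali, ids = msa$id, file = path)
  invisible(path)
}
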
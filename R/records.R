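#' Protein sequence records
#'
#' A `protein_record` is an identified amino-acid sequence using the 20
#' standard one-letter codes plus `X`, with 1-based residue numbering.
#' Collections of records are plain named lists keyed by record id.
#'
#' @param id Single non-empty string, unique within a collection.
#' @param residues Amino-acid sequence as a single string; upper-cased on
#'   construction.
#' @return An object of class `protein_record` with fields `id` and
#'   `residues`.
#' @examples
#' protein_record("CYP76AH15", "MAEL")
#' @export
protein_record <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues)) {
    stop("empty sequence for record '", id, "'", call. = FALSE)
  }
  bad <- setdiff(strsplit(residues, "")[[1]], AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("record '", id, "' contains non-amino-acid characters: ",
         paste(sort(unique(bad)), collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, residues = residues), class = "protein_record")
}

# 20 standard residues plus X for unknowns
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, " (", nchar(x$residues), " aa)\n", sep = "")
  invisible(x)
}

#' Sequence length of a protein record
#' @param record A [protein_record()].
#' @return Integer number of residues.
#' @export
record_length <- function(record) nchar(record$residues)

#' Residue(s) at 1-based positions
#' @param record A [protein_record()].
#' @param positions Integer vector of 1-based positions.
#' @return Character vector of one-letter codes.
#' @export
residue_at <- function(record, positions) {
  stopifnot(all(positions >= 1L), all(positions <= record_length(record)))
  vapply(positions, function(p) substr(record$residues, p, p), character(1))
}

#' Read protein sequences from FASTA
#'
#' Reads via Biostrings and validates the result: ids must
#' be unique, sequences non-empty and restricted to the 20 standard
#' one-letter codes plus X. Header descriptions after the first whitespace
#' are dropped.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return Named list of [protein_record()] objects, keyed by id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  # read unrestricted, then validate: gives errors that name the offending
  # characters rather than Biostrings' lookup-table failure
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  records <- lapply(seq_along(set), function(i) {
    protein_record(ids[i], as.character(set[[i]]))
  })
  stats::setNames(records, ids)
}

#' Write protein records to FASTA
#'
#' @param records Named list of [protein_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::AAStringSet(
    vapply(records, function(r) r$residues, character(1))
  )
  names(set) <- vapply(records, function(r) r$id, character(1))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
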
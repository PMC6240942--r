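#' Alignment parameter set
#'
#' Scoring scheme for global protein alignment: a substitution matrix and
#' affine gap penalties. A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param matrix Substitution matrix name available from Biostrings
#'   (default "BLOSUM62") or a numeric matrix with residue dimnames.
#' @param gap_open Gap opening penalty (positive; default 10).
#' @param gap_extend Per-residue gap extension penalty (positive;
#'   default 0.5).
#' @return List of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "align_params")
}

substitution_matrix <- function(params) {
  if (is.matrix(params$matrix)) return(params$matrix)
  get(utils::data(list = params$matrix, package = "Biostrings",
                  envir = environment()))
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment (end gaps penalised) under affine gap
#' penalties, delegated to [Biostrings::pairwiseAlignment()]. The returned
#' object carries an explicit column map: one row per alignment column with
#' the 1-based residue position on each side, `NA` for a gap.
#'
#' @param a,b [protein_record()] objects.
#' @param params An [align_params()] scoring scheme.
#' @return Object of class `pairwise_alignment` with fields `id_a`, `id_b`,
#'   `aligned_a`, `aligned_b` (gapped strings), `columns` (data.frame
#'   `pos_a`, `pos_b`), `score` and `params`.
#' @examples
#' a <- protein_record("a", "MKV")
#' b <- protein_record("b", "MV")
#' global_align(a, b)
#' @export
global_align <- function(a, b, params = align_params()) {
  stopifnot(inherits(a, "protein_record"), inherits(b, "protein_record"))
  mat <- substitution_matrix(params)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    type = "global", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  alignment_from_gapped(a$id, b$id, ga, gb,
                        score = Biostrings::score(aln), params = params)
}

#' Build a pairwise_alignment from gapped strings
#'
#' Low-level constructor used by [global_align()], the simulators and
#' tests. Gap characters are `-`.
#'
#' @param id_a,id_b Sequence ids.
#' @param gapped_a,gapped_b Equal-length aligned strings with `-` gaps.
#' @param score Alignment score (optional).
#' @param params Scoring parameters used (optional).
#' @return A `pairwise_alignment` object.
#' @export
alignment_from_gapped <- function(id_a, id_b, gapped_a, gapped_b,
                                  score = NA_real_, params = NULL) {
  ca <- strsplit(gapped_a, "")[[1]]
  cb <- strsplit(gapped_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  if (any(ca == "-" & cb == "-")) {
    stop("alignment contains a gap/gap column", call. = FALSE)
  }
  pos_a <- ifelse(ca == "-", NA_integer_, cumsum(ca != "-"))
  pos_b <- ifelse(cb == "-", NA_integer_, cumsum(cb != "-"))
  structure(
    list(id_a = id_a, id_b = id_b, aligned_a = gapped_a,
         aligned_b = gapped_b,
         columns = data.frame(pos_a = as.integer(pos_a),
                              pos_b = as.integer(pos_b)),
         score = score, params = params),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> ", x$id_a, " vs ", x$id_b, ", ",
      nrow(x$columns), " columns, score ", format(x$score), "\n", sep = "")
  invisible(x)
}

#' Percent identity over all alignment columns
#'
#' Identical-residue columns divided by all columns; gap-containing
#' columns count as mismatches.
#'
#' @param alignment A `pairwise_alignment`.
#' @return Percentage in `[0, 100]`.
#' @export
alignment_identity <- function(alignment) {
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  100 * sum(ca == cb & ca != "-") / length(ca)
}

# orient an alignment so that `id` is the "a" side
orient_alignment <- function(alignment, id) {
  if (alignment$id_a == id) return(alignment)
  if (alignment$id_b != id) {
    stop("sequence '", id, "' is not part of alignment ",
         alignment$id_a, " vs ", alignment$id_b, call. = FALSE)
  }
  structure(
    list(id_a = alignment$id_b, id_b = alignment$id_a,
         aligned_a = alignment$aligned_b, aligned_b = alignment$aligned_a,
         columns = data.frame(pos_a = alignment$columns$pos_b,
                              pos_b = alignment$columns$pos_a),
         score = alignment$score, params = alignment$params),
    class = "pairwise_alignment"
  )
}
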
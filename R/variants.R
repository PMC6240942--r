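#' Protein variant notation
#'
#' Variants are written as whitespace-separated edits. A substitution is
#' `<ref><position><new>` (e.g. `A99I`: replace A at 99 with I). A segment
#' swap is `<position><ref-segment>::<new-segment>` (e.g. `473DDP::EL`:
#' replace the segment DDP starting at 473 with EL -- a net deletion of
#' one residue). Positions refer to the unedited sequence and must be
#' strictly increasing across edits.
#'
#' @param text Variant string, e.g. `"A99I S235G Y236F"`.
#' @return Object of class `variant_spec`: a data.frame `edits` with
#'   columns `type` ("sub" or "swap"), `position`, `ref`, `new`.
#' @examples
#' parse_variant("A99I S235G Y236F")
#' parse_variant("473DDP::EL")
#' @export
parse_variant <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  if (length(tokens) == 0L || !nzchar(tokens[1])) {
    stop("empty variant text", call. = FALSE)
  }
  edits <- lapply(tokens, parse_variant_token)
  edits <- do.call(rbind, edits)
  if (anyDuplicated(edits$position)) {
    stop("duplicate edit position(s): ",
         paste(unique(edits$position[duplicated(edits$position)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(edits$position, strictly = TRUE)) {
    stop("edit positions must be strictly increasing: '", text, "'",
         call. = FALSE)
  }
  structure(list(edits = edits), class = "variant_spec")
}

parse_variant_token <- function(token) {
  if (grepl("^[A-Z][0-9]+[A-Z]$", token)) {
    pos <- as.integer(gsub("[A-Z]", "", token))
    data.frame(type = "sub", position = pos,
               ref = substr(token, 1L, 1L),
               new = substr(token, nchar(token), nchar(token)),
               stringsAsFactors = FALSE)
  } else if (grepl("^[0-9]+[A-Z]+::[A-Z]+$", token)) {
    pos <- as.integer(sub("^([0-9]+).*$", "\\1", token))
    segs <- strsplit(sub("^[0-9]+", "", token), "::", fixed = TRUE)[[1]]
    data.frame(type = "swap", position = pos, ref = segs[1], new = segs[2],
               stringsAsFactors = FALSE)
  } else {
    stop("malformed variant token: '", token, "'", call. = FALSE)
  }
}

#' Canonical text rendering of a variant
#'
#' Inverse of [parse_variant()]: `render_variant(parse_variant(x))` is the
#' canonical form of `x` (single spaces, edits in position order).
#'
#' @param spec A `variant_spec`.
#' @return Single string.
#' @export
render_variant <- function(spec) {
  e <- spec$edits
  paste(ifelse(e$type == "sub",
               paste0(e$ref, e$position, e$new),
               paste0(e$position, e$ref, "::", e$new)),
        collapse = " ")
}

#' @export
print.variant_spec <- function(x, ...) {
  cat("<variant_spec> ", render_variant(x), "\n", sep = "")
  invisible(x)
}

#' Apply a variant to a protein sequence
#'
#' Edits are applied right-to-left so that earlier positions are
#' unaffected by length changes. Every reference residue or segment is
#' checked against the sequence first; a mismatch is an error naming the
#' position and the expected and found residues.
#'
#' @param record [protein_record()] to edit.
#' @param spec A `variant_spec` or variant text (parsed on the fly).
#' @return New [protein_record()] with id
#'   `"<id> <canonical variant text>"`.
#' @examples
#' wt <- protein_record("p", "MAKL")
#' apply_variant(wt, "A2I")
#' @export
apply_variant <- function(record, spec) {
  if (is.character(spec)) spec <- parse_variant(spec)
  e <- spec$edits
  res <- record$residues
  # validate all refs against the *original* sequence first
  for (i in seq_len(nrow(e))) {
    seg <- substr(res, e$position[i], e$position[i] + nchar(e$ref[i]) - 1L)
    if (e$position[i] + nchar(e$ref[i]) - 1L > nchar(res) ||
        seg != e$ref[i]) {
      stop("at position ", e$position[i], ": expected ", e$ref[i],
           " found ", seg, call. = FALSE)
    }
  }
  for (i in rev(seq_len(nrow(e)))) {
    before <- substr(res, 1L, e$position[i] - 1L)
    after <- substr(res, e$position[i] + nchar(e$ref[i]), nchar(res))
    res <- paste0(before, e$new[i], after)
  }
  protein_record(paste(record$id, render_variant(spec)), res)
}

#' Inverse of a variant
#'
#' Swaps each edit's reference and replacement, re-coordinated to the
#' edited sequence, so that applying the result to the edited record
#' restores the original residues.
#'
#' @param spec A `variant_spec`.
#' @return A `variant_spec` applicable to the edited sequence.
#' @export
invert_variant <- function(spec) {
  e <- spec$edits
  shift <- 0L
  rows <- lapply(seq_len(nrow(e)), function(i) {
    pos <- e$position[i] + shift
    shift <<- shift + nchar(e$new[i]) - nchar(e$ref[i])
    type <- if (nchar(e$ref[i]) == 1L && nchar(e$new[i]) == 1L) "sub"
            else "swap"
    data.frame(type = type, position = pos, ref = e$new[i], new = e$ref[i],
               stringsAsFactors = FALSE)
  })
  structure(list(edits = do.call(rbind, rows)), class = "variant_spec")
}
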
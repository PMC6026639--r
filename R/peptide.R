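#' @keywords internal
"_PACKAGE"

## The 20 standard one-letter amino-acid codes, the alphabet every engine
## in the package consumes. "X" is tolerated only in aligned panels.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Peptide sequences
#'
#' A `peptide` is an identified string of one-letter amino-acid codes, the
#' basic unit consumed by the scoring engines. Lowercase input is uppercased;
#' any character outside the 20 standard codes (optionally plus `X`) is
#' rejected.
#'
#' @param residues a single string of one-letter codes, or a character vector
#'   of single letters.
#' @param id short text label.
#' @param description optional free-text description.
#' @param allow_x tolerate the nonstandard code `X` (used for aligned panels;
#'   sequences containing `X` cannot be scored).
#'
#' @return An object of class `peptide`: a character scalar (the residue
#'   string) with attributes `id` and `description`.
#' @examples
#' h <- peptide("KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY", id = "hIAPP")
#' nchar(h)
#' @export
peptide <- function(residues, id = "peptide", description = NULL,
                    allow_x = FALSE) {
  if (length(residues) > 1L) residues <- paste(residues, collapse = "")
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("peptide must contain at least one residue")
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  ok <- AA_STANDARD
  if (allow_x) ok <- c(ok, "X")
  bad <- which(!chars %in% ok)
  if (length(bad)) {
    stop(sprintf("illegal residue code '%s' at position %d of '%s'",
                 chars[bad[1L]], bad[1L], id))
  }
  structure(residues, id = as.character(id),
            description = description, class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf(">%s (%d aa)\n%s\n", attr(x, "id"), nchar(x),
              unclass(x)))
  invisible(x)
}

## Residue vector of a peptide (or plain string).
pep_chars <- function(x) strsplit(toupper(as.character(x)), "", fixed = TRUE)[[1L]]

pep_id <- function(x) {
  id <- attr(x, "id")
  if (is.null(id)) "peptide" else id
}

as_peptide <- function(x, id = "peptide", allow_x = FALSE) {
  if (inherits(x, "peptide")) x else peptide(x, id = id, allow_x = allow_x)
}

#' Parse single-substitution variant notation
#'
#' Parses the field's XnY notation for single-residue substitutions (e.g.
#' `"F23R"` or the underscore form `"F_23_R"`): wild residue, 1-based
#' position, substitute residue.
#'
#' @param text a character vector of variant strings.
#' @return A data frame of class `variant_spec` with columns `wild`
#'   (character), `position` (integer) and `substitute` (character), one row
#'   per input string.
#' @examples
#' parse_variant(c("F_23_R", "V17D"))
#' @export
parse_variant <- function(text) {
  text <- trimws(as.character(text))
  m <- regmatches(text, regexec("^([A-Za-z])_?([0-9]+)_?([A-Za-z])$", text))
  bad <- which(vapply(m, length, 1L) != 4L)
  if (length(bad)) {
    stop(sprintf("malformed variant notation '%s' (expected e.g. 'F23R' or 'F_23_R')",
                 text[bad[1L]]))
  }
  wild <- toupper(vapply(m, `[`, "", 2L))
  pos <- as.integer(vapply(m, `[`, "", 3L))
  sub <- toupper(vapply(m, `[`, "", 4L))
  for (letters in list(wild, sub)) {
    unk <- which(!letters %in% AA_STANDARD)
    if (length(unk)) {
      stop(sprintf("unknown residue letter '%s' in variant '%s'",
                   letters[unk[1L]], text[unk[1L]]))
    }
  }
  if (any(pos < 1L)) stop("variant position must be >= 1")
  same <- which(wild == sub)
  if (length(same)) {
    stop(sprintf("degenerate variant '%s': wild residue equals substitute",
                 text[same[1L]]))
  }
  structure(data.frame(wild = wild, position = pos, substitute = sub,
                       stringsAsFactors = FALSE),
            class = c("variant_spec", "data.frame"))
}

#' Canonical variant notation
#'
#' @param spec a `variant_spec` data frame (see [parse_variant()]).
#' @return Character vector in canonical separator-free form, e.g. `"F23R"`.
#' @export
format_variant <- function(spec) {
  paste0(spec$wild, spec$position, spec$substitute)
}

#' Apply substitutions to a reference peptide
#'
#' Applies a set of single-residue substitutions to a reference sequence.
#' Positions must be pairwise distinct and each wild residue must match the
#' reference; length is always preserved (no indels). The returned id records
#' the applied variants in canonical notation, sorted by position, as
#' `"refid|F23R+V17D"`-style provenance.
#'
#' @param reference a [peptide()] (or plain sequence string).
#' @param variants a `variant_spec` data frame, a character vector of variant
#'   notations, or an empty vector/NULL for the identity.
#' @return A new `peptide`.
#' @examples
#' h <- peptide("KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY", id = "hIAPP")
#' apply_variants(h, "F23R")
#' @export
apply_variants <- function(reference, variants = NULL) {
  reference <- as_peptide(reference)
  if (is.null(variants) || (is.character(variants) && length(variants) == 0L)) {
    return(reference)
  }
  if (is.character(variants)) variants <- parse_variant(variants)
  if (inherits(variants, "variant_spec") && nrow(variants) == 0L) {
    return(reference)
  }
  chars <- pep_chars(reference)
  n <- length(chars)
  if (anyDuplicated(variants$position)) {
    stop(sprintf("duplicate substitution position %d",
                 variants$position[duplicated(variants$position)][1L]))
  }
  if (any(variants$position > n)) {
    stop(sprintf("position %d exceeds reference length %d",
                 max(variants$position), n))
  }
  found <- chars[variants$position]
  mism <- which(found != variants$wild)
  if (length(mism)) {
    i <- mism[1L]
    stop(sprintf("wild-residue mismatch at position %d: variant expects '%s' but reference '%s' has '%s'",
                 variants$position[i], variants$wild[i],
                 pep_id(reference), found[i]))
  }
  chars[variants$position] <- variants$substitute
  ord <- order(variants$position)
  tag <- paste(format_variant(variants[ord, , drop = FALSE]), collapse = "+")
  peptide(paste(chars, collapse = ""),
          id = paste0(pep_id(reference), "|", tag),
          description = attr(reference, "description"))
}
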
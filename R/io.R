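#' Read peptide sequences from FASTA
#'
#' Standard FASTA via seqinr, with validation: lowercase is uppercased, stop
#' (`*`) and gap characters are rejected, duplicate ids and empty files are
#' errors. Order-preserving.
#'
#' @param path FASTA file.
#' @param allow_x tolerate `X` residues (aligned panels).
#' @return Named list of [peptide()] objects.
#' @export
read_fasta <- function(path, allow_x = FALSE) {
  if (!file.exists(path)) stop(sprintf("FASTA file '%s' does not exist", path))
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       forceDNAtolower = FALSE),
    error = function(e) stop(sprintf("cannot parse FASTA '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (!length(recs)) stop(sprintf("FASTA file '%s' contains no sequences", path))
  ids <- vapply(recs, function(r) attr(r, "name"), "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop(sprintf("duplicate sequence id '%s' in '%s'", dup[1L], path))
  }
  out <- lapply(seq_along(recs), function(i) {
    ann <- attr(recs[[i]], "Annot")
    desc <- sub("^>\\S*\\s*", "", ann)
    peptide(as.character(recs[[i]]), id = ids[i],
            description = if (nzchar(desc)) desc else NULL,
            allow_x = allow_x)
  })
  names(out) <- ids
  out
}

#' Write peptide sequences as canonical FASTA
#'
#' @param seqs a list of [peptide()] objects (or a single one).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "peptide")) seqs <- list(seqs)
  seqinr::write.fasta(lapply(seqs, function(s) unclass(s)[[1L]]),
                      names = vapply(seqs, pep_id, ""),
                      file.out = path, nbchar = 60, as.string = TRUE)
  invisible(path)
}

## Single tabular dialect of the package: tab-delimited, header row, "." for
## not-applicable, no quoting, no locale-dependent formatting.
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) {
    out <- trimws(formatC(x, format = "g", digits = 12))
    out[is.na(x)] <- NA
    out
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".", ...)
}

#' Per-variant annotation fixture
#'
#' Loads the packaged per-variant annotation table (externally computed
#' PASTA pairing energies and the organisms carrying each variant) keyed by
#' canonical variant notation, for merging into scan reports. These columns
#' are pass-through annotations only; nothing in the package computes them.
#'
#' @param path fixture path; defaults to the installed copy.
#' @return Data frame with columns `variants`, `pasta`, `organisms`.
#' @export
variant_annotations <- function(path = system.file("extdata",
                                                   "variant_annotations.tsv",
                                                   package = "amylscan")) {
  if (!nzchar(path) || !file.exists(path)) stop("annotation fixture not found")
  read_tsv(path, comment.char = "#")
}
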
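#' Aligned sequence panels
#'
#' A panel is a reference peptide plus member sequences of identical length
#' (already aligned, gap-free). Members may contain the nonstandard code `X`;
#' such positions are flagged in catalogs and excluded from scoring.
#'
#' @param reference a [peptide()].
#' @param members list of [peptide()] objects, all the same length as the
#'   reference.
#' @param provenance free-text note on where the panel came from.
#' @return An object of class `sequence_panel`.
#' @export
sequence_panel <- function(reference, members, provenance = "") {
  reference <- as_peptide(reference)
  n <- nchar(reference)
  members <- lapply(members, as_peptide, allow_x = TRUE)
  for (m in members) {
    if (nchar(m) != n) {
      stop(sprintf("panel member '%s' has length %d, reference '%s' has %d",
                   pep_id(m), nchar(m), pep_id(reference), n))
    }
  }
  structure(list(reference = reference, members = members,
                 provenance = provenance), class = "sequence_panel")
}

#' @export
print.sequence_panel <- function(x, ...) {
  cat(sprintf("Sequence panel: %d members of length %d (reference %s)\n",
              length(x$members), nchar(x$reference), pep_id(x$reference)))
  invisible(x)
}

#' Per-position variant catalogs
#'
#' A catalog records, for every position of a reference sequence, the set of
#' substitute residues observed across a panel together with their occurrence
#' counts. Entries whose substitute is the nonstandard code `X` are kept (they
#' contribute to occurrence totals) but flagged `nonstandard` and skipped by
#' the scanning engine.
#'
#' @param reference a [peptide()].
#' @param entries data frame with columns `position`, `substitute`, `count`
#'   (positive integers), one row per (position, substitute).
#' @param provenance free-text note.
#' @return An object of class `variant_catalog`.
#' @export
variant_catalog <- function(reference, entries, provenance = "") {
  reference <- as_peptide(reference)
  chars <- pep_chars(reference)
  if (nrow(entries)) {
    entries$position <- as.integer(entries$position)
    entries$count <- as.integer(entries$count)
    if (any(entries$position < 1L | entries$position > length(chars))) {
      stop("catalog entry position out of range of the reference")
    }
    if (any(entries$count < 1L)) stop("catalog counts must be positive integers")
    same <- entries$substitute == chars[entries$position]
    if (any(same)) {
      stop(sprintf("catalog entry at position %d substitutes the reference residue itself",
                   entries$position[which(same)[1L]]))
    }
    if (anyDuplicated(entries[c("position", "substitute")])) {
      stop("duplicate (position, substitute) catalog entry")
    }
    entries$wild <- chars[entries$position]
    entries$nonstandard <- !entries$substitute %in% AA_STANDARD
    entries <- entries[order(entries$position, entries$substitute),
                       c("position", "wild", "substitute", "count", "nonstandard")]
    rownames(entries) <- NULL
  } else {
    entries <- data.frame(position = integer(), wild = character(),
                          substitute = character(), count = integer(),
                          nonstandard = logical())
  }
  structure(list(reference = reference, entries = entries,
                 provenance = provenance), class = "variant_catalog")
}

#' @export
print.variant_catalog <- function(x, ...) {
  tot <- catalog_totals(x)
  cat(sprintf("Variant catalog on %s (%d aa): %d distinct variants, %d occurrences\n",
              pep_id(x$reference), nchar(x$reference),
              tot[["distinct_variants"]], tot[["total_occurrences"]]))
  cons <- conserved_positions(x)
  cat(sprintf("  conserved positions (%d): %s\n", length(cons),
              paste(cons, collapse = " ")))
  invisible(x)
}

#' Build a variant catalog from an aligned panel
#'
#' For each position, every member residue differing from the reference
#' becomes a catalog entry whose count is the number of members carrying it;
#' positions where no member differs are conserved.
#'
#' @param panel a [sequence_panel()].
#' @return A [variant_catalog()].
#' @examples
#' ref <- peptide("ACDEF", id = "ref")
#' panel <- sequence_panel(ref, list(peptide("ACDEF"), peptide("AVDEF"),
#'                                   peptide("AVDEF")))
#' catalog_from_panel(panel)$entries
#' @export
catalog_from_panel <- function(panel) {
  stopifnot(inherits(panel, "sequence_panel"))
  ref <- pep_chars(panel$reference)
  n <- length(ref)
  if (!length(panel$members)) stop("panel has no members")
  mat <- do.call(rbind, lapply(panel$members, pep_chars))
  rows <- list()
  for (p in seq_len(n)) {
    col <- mat[, p]
    diff <- col[col != ref[p]]
    if (length(diff)) {
      tab <- table(diff)
      rows[[length(rows) + 1L]] <- data.frame(
        position = p, substitute = names(tab), count = as.integer(tab))
    }
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), substitute = character(), count = integer())
  variant_catalog(panel$reference, entries,
                  provenance = sprintf("derived from panel of %d members",
                                       length(panel$members)))
}

#' Catalog totals
#'
#' @param catalog a [variant_catalog()].
#' @return Named integer vector: `distinct_variants` (number of distinct
#'   (position, substitute) entries) and `total_occurrences` (sum of counts).
#' @export
catalog_totals <- function(catalog) {
  c(distinct_variants = nrow(catalog$entries),
    total_occurrences = as.integer(sum(catalog$entries$count)))
}

#' Occurrence concentration within a region
#'
#' Sums occurrence counts over a closed 1-based position interval and reports
#' the fraction of all occurrences it holds.
#'
#' @param catalog a [variant_catalog()].
#' @param start,end closed interval bounds, `1 <= start <= end <= length`.
#' @return List with `occurrences` (count in region) and `fraction` (ratio to
#'   the catalog total, full precision).
#' @export
region_concentration <- function(catalog, start, end) {
  n <- nchar(catalog$reference)
  if (!(start >= 1 && start <= end && end <= n)) {
    stop(sprintf("region [%d, %d] is not a valid closed interval within 1..%d",
                 start, end, n))
  }
  total <- sum(catalog$entries$count)
  if (total == 0L) {
    stop("region fraction is undefined for an empty catalog")
  }
  inside <- catalog$entries$position >= start & catalog$entries$position <= end
  occ <- as.integer(sum(catalog$entries$count[inside]))
  list(occurrences = occ, fraction = occ / total)
}

#' Conserved positions
#'
#' Positions of the reference with no catalog entry, sorted ascending.
#'
#' @param catalog a [variant_catalog()].
#' @return Integer vector.
#' @export
conserved_positions <- function(catalog) {
  setdiff(seq_len(nchar(catalog$reference)),
          sort(unique(catalog$entries$position)))
}

#' Read / write a catalog as TSV
#'
#' Long-form catalog interchange: columns `position`, `ref_residue`,
#' `substitute`, `count`, one row per (position, substitute). The reader and
#' writer are inverse bijections.
#'
#' @param path file path.
#' @param reference the reference [peptide()] (the TSV stores only entries).
#' @return [read_catalog_tsv()] returns a [variant_catalog()];
#'   [write_catalog_tsv()] is called for its side effect.
#' @export
read_catalog_tsv <- function(path, reference) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("integer", "character", "character",
                                         "integer"))
  need <- c("position", "ref_residue", "substitute", "count")
  if (!identical(names(df), need)) {
    stop(sprintf("catalog TSV '%s' must have columns %s", path,
                 paste(need, collapse = ", ")))
  }
  reference <- as_peptide(reference)
  chars <- pep_chars(reference)
  mism <- which(df$ref_residue != chars[df$position])
  if (length(mism)) {
    stop(sprintf("catalog TSV row %d: ref_residue '%s' does not match reference position %d ('%s')",
                 mism[1L], df$ref_residue[mism[1L]], df$position[mism[1L]],
                 chars[df$position[mism[1L]]]))
  }
  variant_catalog(reference, df[c("position", "substitute", "count")],
                  provenance = path)
}

#' @rdname read_catalog_tsv
#' @param catalog a [variant_catalog()].
#' @export
write_catalog_tsv <- function(catalog, path) {
  e <- catalog$entries
  write_tsv(data.frame(position = e$position, ref_residue = e$wild,
                       substitute = e$substitute, count = e$count), path)
}

#' The packaged cross-species amylin variant catalog
#'
#' Loads the catalog of residue variants observed across 240 cross-species
#' amylin sequences: 113 distinct per-position substitutions of the human
#' 37-mer, 1,640 variant occurrences in total, heavily concentrated in the
#' 17-31 segment. The packaged fixture stores, per position, the observed
#' substitute residues and the position's total occurrence count; since
#' per-variant splits are not part of the published table, each position's
#' total is distributed as evenly as possible across its variants (deterministic,
#' earlier-listed variants take the remainder) - a synthetic allocation that
#' leaves every per-position and whole-catalog statistic unchanged. The single
#' nonstandard entry (L27X) is retained with its mass but never scored.
#'
#' @param path fixture path; defaults to the installed copy.
#' @return A [variant_catalog()] on the human amylin reference.
#' @examples
#' cat240 <- amylin_catalog()
#' catalog_totals(cat240)
#' @export
amylin_catalog <- function(path = system.file("extdata", "amylin_variants_240species.tsv",
                                              package = "amylscan")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("variant-catalog fixture not found")
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c("integer", "character", "character",
                                         "integer", "integer"))
  need <- c("position", "ref_residue", "substitutes", "n_variants",
            "total_occurrences")
  if (!identical(names(df), need)) {
    stop(sprintf("corrupt catalog fixture '%s': expected columns %s", path,
                 paste(need, collapse = ", ")))
  }
  ref <- iapp_sequences()$hIAPP
  rows <- list()
  for (i in seq_len(nrow(df))) {
    subs <- strsplit(df$substitutes[i], ",", fixed = TRUE)[[1L]]
    subs <- subs[nzchar(subs)]
    if (length(subs) != df$n_variants[i]) {
      stop(sprintf("corrupt catalog fixture row %d (position %d): %d variant cells but n_variants = %d",
                   i, df$position[i], length(subs), df$n_variants[i]))
    }
    if (!length(subs)) next
    total <- df$total_occurrences[i]
    base <- total %/% length(subs)
    counts <- rep(base, length(subs))
    extra <- total - base * length(subs)
    if (extra > 0L) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    rows[[length(rows) + 1L]] <- data.frame(position = df$position[i],
                                            substitute = subs, count = counts)
  }
  variant_catalog(ref, do.call(rbind, rows),
                  provenance = "cross-species amylin catalog (240 sequences)")
}
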
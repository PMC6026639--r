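## Fast path shared by the scanners: na4vss / hot-spot statistics computed
## directly on the a3v vector (identical arithmetic to aggrescan(), without
## re-validating strings for every candidate).
score_from_a3v <- function(v, chars, scale) {
  n <- length(v)
  w <- scale$window(n)
  half <- (w - 1L) %/% 2L
  padded <- c(rep(0, half), v, rep(0, half))
  cs <- c(0, cumsum(padded))
  a4 <- (cs[(1L:n) + 2L * half + 1L] - cs[1L:n]) / w
  hot <- a4 > scale$hst & chars != "P"
  r <- rle(hot)
  runs <- r$values & r$lengths >= 5L
  list(na4vss = 100 * mean(a4),
       n_hot_spots = sum(runs),
       hot_spot_residues = sum(r$lengths[runs]))
}

scan_pool <- function(catalog) {
  e <- catalog$entries
  pool <- e[!e$nonstandard, c("wild", "position", "substitute")]
  if (any(e$nonstandard)) {
    skipped <- e[e$nonstandard, ]
    warning(sprintf("skipping %d nonstandard catalog variant(s): %s",
                    nrow(skipped),
                    paste0(skipped$wild, skipped$position, skipped$substitute,
                           collapse = ", ")))
  }
  rownames(pool) <- NULL
  class(pool) <- c("variant_spec", "data.frame")
  pool
}

build_scan_table <- function(reference, combos, pool, scale, k) {
  ref_chars <- pep_chars(reference)
  ref_a3v <- a3v_values(reference, scale)
  ref_kd <- unname(KYTE_DOOLITTLE[ref_chars])
  ref_stats <- score_from_a3v(ref_a3v, ref_chars, scale)
  ref_gravy <- mean(ref_kd)

  m <- length(combos)
  variants <- character(m); seqs <- character(m)
  score <- numeric(m); grv <- numeric(m)
  nhs <- integer(m); hsr <- integer(m)
  first_pos <- integer(m); first_sub <- character(m)
  for (i in seq_len(m)) {
    idx <- combos[[i]]
    rows <- pool[idx, , drop = FALSE]
    ord <- order(rows$position)
    rows <- rows[ord, , drop = FALSE]
    chars <- ref_chars; v <- ref_a3v; kdv <- ref_kd
    chars[rows$position] <- rows$substitute
    v[rows$position] <- unname(scale$a3v[rows$substitute])
    kdv[rows$position] <- KYTE_DOOLITTLE[rows$substitute]
    st <- score_from_a3v(v, chars, scale)
    variants[i] <- paste(format_variant(rows), collapse = "+")
    seqs[i] <- paste(chars, collapse = "")
    score[i] <- st$na4vss; grv[i] <- mean(kdv)
    nhs[i] <- st$n_hot_spots; hsr[i] <- st$hot_spot_residues
    first_pos[i] <- rows$position[1L]; first_sub[i] <- rows$substitute[1L]
  }
  ord <- order(score, first_pos, first_sub)
  records <- data.frame(
    rank = seq_len(m),
    variants = variants[ord],
    sequence = seqs[ord],
    na4vss = score[ord],
    delta_na4vss = score[ord] - ref_stats$na4vss,
    gravy = grv[ord],
    n_hot_spots = nhs[ord],
    hot_spot_residues = hsr[ord],
    hotspot_deleted = hsr[ord] < ref_stats$hot_spot_residues,
    class = ifelse(score[ord] < ref_stats$na4vss, "lower", "higher"),
    stringsAsFactors = FALSE
  )
  structure(list(
    reference = list(id = pep_id(reference), na4vss = ref_stats$na4vss,
                     gravy = ref_gravy,
                     hot_spot_residues = ref_stats$hot_spot_residues,
                     n_hot_spots = ref_stats$n_hot_spots),
    k = k,
    records = records
  ), class = "scan_table")
}

#' Single-substitution scan
#'
#' Applies every scorable catalog variant to the reference, one at a time,
#' scores each candidate (Na4vSS, GRAVY, hot spots) and returns the table
#' sorted ascending by Na4vSS (ties broken by first substituted position, then
#' substitute letter). Nonstandard (X) catalog entries are skipped with a
#' warning.
#'
#' @param reference a [peptide()]; must equal the catalog's reference.
#' @param catalog a [variant_catalog()].
#' @param scale a [aggrescan_scale()].
#' @return An object of class `scan_table`: reference scores plus one record
#'   per variant with columns `rank`, `variants`, `sequence`, `na4vss`,
#'   `delta_na4vss`, `gravy`, `n_hot_spots`, `hot_spot_residues`,
#'   `hotspot_deleted` (strictly fewer hot-spot residues than the reference)
#'   and `class` (`"lower"`/`"higher"`, strict comparison with the reference
#'   Na4vSS).
#' @export
single_scan <- function(reference, catalog, scale = aggrescan_scale()) {
  reference <- as_peptide(reference)
  if (unclass(reference)[[1L]] != unclass(catalog$reference)[[1L]]) {
    stop("scan reference does not match the catalog reference sequence")
  }
  pool <- scan_pool(catalog)
  combos <- as.list(seq_len(nrow(pool)))
  build_scan_table(reference, combos, pool, scale, k = 1L)
}

#' Multi-substitution scan
#'
#' Enumerates every k-combination of pool variants at pairwise-distinct
#' positions, applies each combination to the reference and scores it.
#' Exhaustive by design; a configurable combination budget guards the
#' combinatorial blow-up with a deterministic error rather than silent
#' truncation.
#'
#' @inheritParams single_scan
#' @param k number of simultaneous substitutions, `k >= 2`.
#' @param pool optional `variant_spec` data frame (or character vector of
#'   variant notations) restricting the candidate variants; defaults to all
#'   scorable catalog variants.
#' @param max_combinations combination budget.
#' @return A `scan_table` (see [single_scan()]).
#' @examples
#' \dontrun{
#' multi_scan(iapp_sequences()$hIAPP, amylin_catalog(), k = 2,
#'            pool = c("V17D", "F23R"))
#' }
#' @export
multi_scan <- function(reference, catalog, k, pool = NULL,
                       scale = aggrescan_scale(),
                       max_combinations = 3e5) {
  reference <- as_peptide(reference)
  if (k < 2L) stop("multi_scan requires k >= 2; use single_scan for k = 1")
  if (is.null(pool)) {
    if (unclass(reference)[[1L]] != unclass(catalog$reference)[[1L]]) {
      stop("scan reference does not match the catalog reference sequence")
    }
    pool <- scan_pool(catalog)
  } else {
    if (is.character(pool)) pool <- parse_variant(pool)
    chars <- pep_chars(reference)
    mism <- which(chars[pool$position] != pool$wild)
    if (length(mism)) {
      stop(sprintf("pool variant %s does not match the reference at position %d",
                   format_variant(pool[mism[1L], ]), pool$position[mism[1L]]))
    }
  }
  if (k > length(unique(pool$position))) {
    stop(sprintf("k = %d exceeds the %d distinct variant positions in the pool",
                 k, length(unique(pool$position))))
  }
  cmb <- utils::combn(nrow(pool), k)
  keep <- apply(cmb, 2L, function(idx) !anyDuplicated(pool$position[idx]))
  cmb <- cmb[, keep, drop = FALSE]
  if (ncol(cmb) > max_combinations) {
    stop(sprintf("scan would require %d combinations, above the budget of %d; restrict the pool or raise max_combinations",
                 ncol(cmb), max_combinations))
  }
  combos <- lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  build_scan_table(reference, combos, pool, scale, k = as.integer(k))
}

#' Classify scan records against a threshold
#'
#' Counts records whose Na4vSS lies strictly below a threshold; comparisons
#' use full-precision values (rounding is display only).
#'
#' @param table a `scan_table`.
#' @param threshold scalar threshold, or `"reference"` for the table's
#'   reference Na4vSS.
#' @return List with `n_lower` (count) and `pct_lower` (percentage of
#'   records, rounded half-up to the nearest integer).
#' @export
classify_vs_reference <- function(table, threshold = "reference") {
  if (identical(threshold, "reference")) threshold <- table$reference$na4vss
  n <- nrow(table$records)
  if (n == 0L) stop("classification is undefined for an empty scan table")
  n_lower <- sum(table$records$na4vss < threshold)
  list(n_lower = as.integer(n_lower),
       pct_lower = round_half_up(100 * n_lower / n))
}

#' Recompute hot-spot deletion flags
#'
#' Marks each record as deleting hot spots when its total hot-spot residue
#' coverage is strictly below the coverage of a reference profile.
#'
#' @param table a `scan_table`.
#' @param reference_profile an [aggrescan()] profile computed with the same
#'   scale.
#' @return The table with its `hotspot_deleted` column refreshed.
#' @export
hotspot_deletion_flags <- function(table, reference_profile) {
  table$records$hotspot_deleted <-
    table$records$hot_spot_residues < reference_profile$hot_spot_residues
  table
}

#' Pearson correlation with explicit guards
#'
#' Sample Pearson correlation of two numeric vectors. Constant input is an
#' explicit error, not a silent zero or NA.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return The correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("pearson requires at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson is undefined for a constant vector")
  }
  stats::cor(x, y, method = "pearson")
}

#' @export
print.scan_table <- function(x, ...) {
  cat(sprintf("Substitution scan (k = %d) against %s: %d candidates\n",
              x$k, x$reference$id, nrow(x$records)))
  cat(sprintf("  reference Na4vSS %.1f | GRAVY %.2f | %d hot-spot residues\n",
              round_half_up(x$reference$na4vss, 1),
              round_half_up(x$reference$gravy, 2),
              x$reference$hot_spot_residues))
  cl <- classify_vs_reference(x)
  cat(sprintf("  %d (%d%%) candidates score strictly below the reference\n",
              cl$n_lower, cl$pct_lower))
  top <- utils::head(x$records[c("rank", "variants", "na4vss", "delta_na4vss",
                                 "gravy", "hotspot_deleted")], 5L)
  top$na4vss <- round_half_up(top$na4vss, 1)
  top$delta_na4vss <- round_half_up(top$delta_na4vss, 1)
  top$gravy <- round_half_up(top$gravy, 2)
  print(top, row.names = FALSE)
  invisible(x)
}

#' @export
summary.scan_table <- function(object, ...) {
  cl <- classify_vs_reference(object)
  list(k = object$k,
       n_candidates = nrow(object$records),
       reference = object$reference,
       n_lower = cl$n_lower,
       pct_lower = cl$pct_lower,
       n_hotspot_deleting = sum(object$records$hotspot_deleted),
       na4vss_range = range(object$records$na4vss))
}

#' Write a scan report as TSV
#'
#' Deterministic tab-delimited report, one row per record; optional
#' annotation columns (e.g. externally computed PASTA energies, organism
#' lists) are merged by the `variants` key, with `"."` for records without an
#' annotation.
#'
#' @param table a `scan_table`.
#' @param path output path.
#' @param annotations optional data frame with a `variants` column plus
#'   annotation columns.
#' @export
write_scan_tsv <- function(table, path, annotations = NULL) {
  df <- table$records
  if (!is.null(annotations)) {
    if (!"variants" %in% names(annotations)) {
      stop("annotations must contain a 'variants' key column")
    }
    df <- merge(df, annotations, by = "variants", all.x = TRUE, sort = FALSE)
    df <- df[order(df$rank), ]
  }
  first <- c("rank", "variants", "sequence", "na4vss", "delta_na4vss",
             "gravy", "n_hot_spots", "hot_spot_residues", "hotspot_deleted",
             "class")
  df <- df[c(first, setdiff(names(df), first))]
  write_tsv(df, path)
}
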
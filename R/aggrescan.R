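#' Windowed aggregation-propensity profile (a4v)
#'
#' Computes the per-residue windowed aggregation propensity: position `i`
#' carries the sum of the intrinsic a3v values of the residues within the
#' sliding window centred at `i`, divided by the full window size. Neighbours
#' falling outside the sequence contribute zero (the peptide is treated as
#' embedded in a propensity-neutral context), so terminal positions are pulled
#' towards zero; this zero-padded convention is the one that reproduces the
#' published amylin reference scores (see the vignette).
#'
#' @param seq a [peptide()] or sequence string.
#' @param scale a [aggrescan_scale()].
#' @return Numeric vector of a4v values, one per residue.
#' @examples
#' a4v_profile("IIIIIIIII")
#' @export
a4v_profile <- function(seq, scale = aggrescan_scale()) {
  v <- a3v_values(seq, scale)
  n <- length(v)
  w <- scale$window(n)
  half <- (w - 1L) %/% 2L
  ## zero-padded running sum over the window, denominator fixed at w
  padded <- c(rep(0, half), v, rep(0, half))
  cs <- c(0, cumsum(padded))
  (cs[(1L:n) + 2L * half + 1L] - cs[1L:n]) / w
}

## Per-residue a3v lookup with a named error for unscorable residues.
a3v_values <- function(seq, scale = aggrescan_scale()) {
  chars <- pep_chars(seq)
  bad <- which(!chars %in% names(scale$a3v))
  if (length(bad)) {
    stop(sprintf("unscorable residue '%s' at position %d of '%s'",
                 chars[bad[1L]], bad[1L], pep_id(seq)))
  }
  unname(scale$a3v[chars])
}

#' Normalised a4v sequence sum (Na4vSS)
#'
#' The single summary score used to rank sequences: the sum of the windowed
#' a4v profile normalised to 100 residues, `100 * mean(a4v)`. More negative
#' values mean lower aggregation propensity.
#'
#' @inheritParams a4v_profile
#' @return A scalar, full precision (printed comparisons round half-up to one
#'   decimal).
#' @examples
#' h <- peptide("KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY", id = "hIAPP")
#' round(na4vss(h), 1)
#' @export
na4vss <- function(seq, scale = aggrescan_scale()) {
  100 * mean(a4v_profile(seq, scale))
}

#' Aggregation hot spots
#'
#' Hot spots are maximal runs of at least `min_run` consecutive positions
#' whose a4v value lies strictly above the hot-spot threshold, with prolines
#' excluded: a proline never belongs to a hot spot and terminates any run.
#'
#' @param seq a [peptide()] or sequence string.
#' @param a4v optionally a precomputed [a4v_profile()] for `seq`.
#' @param scale a [aggrescan_scale()].
#' @param min_run minimum run length (default 5, the AGGRESCAN rule).
#' @return A data frame with columns `start` and `end` (closed 1-based
#'   intervals, disjoint and sorted); zero rows when there is no hot spot.
#' @examples
#' find_hot_spots("IIIIIIIIII")
#' @export
find_hot_spots <- function(seq, a4v = NULL, scale = aggrescan_scale(),
                           min_run = 5L) {
  if (is.null(a4v)) a4v <- a4v_profile(seq, scale)
  chars <- pep_chars(seq)
  hot <- a4v > scale$hst & chars != "P"
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start = starts[keep], end = ends[keep])
}

#' Score a peptide
#'
#' Bundles the windowed profile, the Na4vSS summary score and hot-spot
#' detection into one record.
#'
#' @inheritParams a4v_profile
#' @return An object of class `aggrescan_profile` with elements `id`,
#'   `sequence`, `length`, `a3v`, `a4v`, `hot_spots` (data frame of closed
#'   intervals), `n_hot_spots`, `hot_spot_residues` (total residues covered)
#'   and `na4vss`.
#' @examples
#' p <- aggrescan(peptide("KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY", id = "hIAPP"))
#' p
#' @export
aggrescan <- function(seq, scale = aggrescan_scale()) {
  seq <- as_peptide(seq)
  a3 <- a3v_values(seq, scale)
  a4 <- a4v_profile(seq, scale)
  hs <- find_hot_spots(seq, a4v = a4, scale = scale)
  structure(list(
    id = pep_id(seq),
    sequence = unclass(seq)[[1L]],
    length = length(a3),
    a3v = a3,
    a4v = a4,
    hot_spots = hs,
    n_hot_spots = nrow(hs),
    hot_spot_residues = if (nrow(hs)) sum(hs$end - hs$start + 1L) else 0L,
    na4vss = 100 * mean(a4)
  ), class = "aggrescan_profile")
}

#' @export
print.aggrescan_profile <- function(x, ...) {
  cat(sprintf("Aggregation profile of %s (%d aa)\n", x$id, x$length))
  cat(sprintf("  Na4vSS: %.1f\n", round_half_up(x$na4vss, 1)))
  if (x$n_hot_spots) {
    iv <- paste(sprintf("%d-%d", x$hot_spots$start, x$hot_spots$end),
                collapse = ", ")
    cat(sprintf("  hot spots (%d): %s  [%d residues]\n",
                x$n_hot_spots, iv, x$hot_spot_residues))
  } else {
    cat("  hot spots: none\n")
  }
  invisible(x)
}

#' @export
as.data.frame.aggrescan_profile <- function(x, ...) {
  chars <- strsplit(x$sequence, "", fixed = TRUE)[[1L]]
  in_hs <- rep(FALSE, x$length)
  for (i in seq_len(x$n_hot_spots)) {
    in_hs[x$hot_spots$start[i]:x$hot_spots$end[i]] <- TRUE
  }
  data.frame(position = seq_len(x$length), residue = chars,
             a3v = x$a3v, a4v = x$a4v, in_hot_spot = in_hs)
}

#' Plot an aggregation profile
#'
#' Draws the a4v profile against position, marks the hot-spot threshold and
#' shades hot-spot intervals.
#'
#' @param x an `aggrescan_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.aggrescan_profile <- function(x, ...) {
  graphics::plot(seq_len(x$length), x$a4v, type = "l", xlab = "position",
                 ylab = "a4v", main = x$id, ...)
  graphics::abline(h = aggrescan_scale()$hst, lty = 2, col = "grey40")
  for (i in seq_len(x$n_hot_spots)) {
    graphics::rect(x$hot_spots$start[i] - 0.5, graphics::par("usr")[3],
                   x$hot_spots$end[i] + 0.5, graphics::par("usr")[4],
                   col = grDevices::adjustcolor("red", 0.15), border = NA)
  }
  invisible(x)
}

#' Export a per-residue profile as TSV
#'
#' Writes one row per residue with columns
#' `position`, `residue`, `a3v`, `a4v`, `in_hot_spot` (header row mandatory).
#'
#' @param profile an [aggrescan()] result.
#' @param path output file path.
#' @export
write_profile_tsv <- function(profile, path) {
  write_tsv(as.data.frame(profile), path)
}
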
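#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the sequence. Reported values are
#' conventionally rounded half-up to two decimals; the return value is full
#' precision.
#'
#' @param seq a [peptide()] or sequence string.
#' @return A scalar.
#' @examples
#' gravy("GGGGG") # the Kyte-Doolittle value of glycine
#' @export
gravy <- function(seq) {
  chars <- pep_chars(seq)
  bad <- which(!chars %in% names(KYTE_DOOLITTLE))
  if (length(bad)) {
    stop(sprintf("unscorable residue '%s' at position %d of '%s'",
                 chars[bad[1L]], bad[1L], pep_id(seq)))
  }
  mean(KYTE_DOOLITTLE[chars])
}

#' Ionisation model for peptide net charge
#'
#' pKa values for the terminal groups and the ionisable side chains, EMBOSS
#' defaults. Cysteines are treated as free thiols (no disulfide correction).
#'
#' @param pka named numeric vector; names `nterm`, `cterm` and the one-letter
#'   codes of the ionisable side chains. Basic groups: `nterm`, K, R, H;
#'   acidic: `cterm`, D, E, C, Y.
#' @return An object of class `charge_model`.
#' @export
charge_model <- function(pka = c(nterm = 8.6, cterm = 3.6,
                                 K = 10.8, R = 12.5, H = 6.5,
                                 D = 3.9, E = 4.1, C = 8.5, Y = 10.1)) {
  if (any(pka <= 0 | pka >= 14)) stop("all pKa values must lie in (0, 14)")
  basic <- c("nterm", "K", "R", "H")
  acidic <- c("cterm", "D", "E", "C", "Y")
  if (!all(c(basic, acidic) %in% names(pka))) {
    stop("pka must name nterm, cterm and the ionisable side chains D,E,C,Y,H,K,R")
  }
  structure(list(pka = pka, basic = basic, acidic = acidic),
            class = "charge_model")
}

#' Henderson-Hasselbalch net charge
#'
#' Net electrostatic charge of the peptide at a given pH, in elementary-charge
#' units: the sum over basic groups of `1/(1 + 10^(pH - pKa))` minus the sum
#' over acidic groups of `1/(1 + 10^(pKa - pH))`, termini included.
#'
#' @param seq a [peptide()] or sequence string.
#' @param ph pH value(s) in `[0, 14]`; vectorised.
#' @param model a [charge_model()].
#' @return Net charge, one value per `ph`.
#' @examples
#' round(net_charge("FGAILSSTNVGSNTY", 7)) # the C-terminal amylin fragment
#' @export
net_charge <- function(seq, ph = 7, model = charge_model()) {
  if (any(ph < 0 | ph > 14)) stop("ph must lie in [0, 14]")
  chars <- pep_chars(seq)
  counts <- table(factor(chars, levels = AA_STANDARD))
  groups <- c(nterm = 1, cterm = 1, counts[c("K", "R", "H", "D", "E", "C", "Y")])
  names(groups) <- c("nterm", "cterm", "K", "R", "H", "D", "E", "C", "Y")
  vapply(ph, function(p) {
    pos <- sum(groups[model$basic] / (1 + 10^(p - model$pka[model$basic])))
    neg <- sum(groups[model$acidic] / (1 + 10^(model$pka[model$acidic] - p)))
    pos - neg
  }, numeric(1L))
}

#' Isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge is zero. The charge is
#' strictly decreasing in pH and spans a sign change over `[0, 14]` (the two
#' termini are always present), so the root is unique; it is located by
#' bisection.
#'
#' @inheritParams net_charge
#' @param tol bisection tolerance on pH (default 1e-4).
#' @return The pI, in pH units.
#' @examples
#' isoelectric_point("GGG") # midpoint of the two terminal pKa values
#' @export
isoelectric_point <- function(seq, model = charge_model(), tol = 1e-4) {
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(seq, mid, model) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Hydrophobic moment
#'
#' Eisenberg's measure of amphipathicity: the magnitude of the vector sum of
#' per-residue hydrophobicities placed at successive rotations of
#' `angle_deg` degrees, divided by the number of residues. The default angle
#' of 100 degrees probes alpha-helical periodicity; 180 degrees probes
#' beta-strand periodicity.
#'
#' @param seq a [peptide()] or sequence string.
#' @param angle_deg periodicity angle in degrees.
#' @param scale named per-residue hydrophobicity values (Eisenberg consensus
#'   by default).
#' @return The per-residue moment, a nonnegative scalar.
#' @examples
#' hydrophobic_moment("AA", angle_deg = 180) # opposed vectors cancel
#' @export
hydrophobic_moment <- function(seq, angle_deg = 100, scale = EISENBERG) {
  chars <- pep_chars(seq)
  bad <- which(!chars %in% names(scale))
  if (length(bad)) {
    stop(sprintf("unscorable residue '%s' at position %d of '%s'",
                 chars[bad[1L]], bad[1L], pep_id(seq)))
  }
  h <- scale[chars]
  delta <- (seq_along(h) - 1L) * angle_deg * pi / 180
  sqrt(sum(h * cos(delta))^2 + sum(h * sin(delta))^2) / length(h)
}

#' Physicochemical profile of a peptide
#'
#' Bundles the descriptors paired with aggregation scores: GRAVY hydropathy,
#' net charge at a reference pH, isoelectric point and hydrophobic moment.
#'
#' @param seq a [peptide()] or sequence string.
#' @param ph pH at which the reported net charge is evaluated.
#' @param angle_deg periodicity angle for the hydrophobic moment.
#' @param model a [charge_model()].
#' @return An object of class `physchem_profile` with elements `id`, `length`,
#'   `gravy`, `charge` (the value at `ph`), `ph`, `pi`, `mu_h`, `angle_deg`
#'   and `charge_at` (the charge evaluator, a function of pH).
#' @examples
#' physchem(peptide("KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY", id = "hIAPP"))
#' @export
physchem <- function(seq, ph = 7, angle_deg = 100, model = charge_model()) {
  seq <- as_peptide(seq)
  structure(list(
    id = pep_id(seq),
    length = nchar(seq),
    gravy = gravy(seq),
    charge = net_charge(seq, ph, model),
    ph = ph,
    pi = isoelectric_point(seq, model),
    mu_h = hydrophobic_moment(seq, angle_deg),
    angle_deg = angle_deg,
    charge_at = function(p) net_charge(seq, p, model)
  ), class = "physchem_profile")
}

#' @export
print.physchem_profile <- function(x, ...) {
  cat(sprintf("Physicochemical profile of %s (%d aa)\n", x$id, x$length))
  cat(sprintf("  GRAVY: %.2f\n", round_half_up(x$gravy, 2)))
  cat(sprintf("  net charge at pH %.1f: %+.2f (rounds to %+d)\n",
              x$ph, x$charge, round_half_up(x$charge)))
  cat(sprintf("  pI: %.2f\n", x$pi))
  cat(sprintf("  hydrophobic moment (%g deg): %.3f\n", x$angle_deg, x$mu_h))
  invisible(x)
}

#' Physicochemical report over several sequences
#'
#' @param seqs a list of [peptide()] objects (e.g. from [read_fasta()]).
#' @param ph pH for the net-charge column.
#' @return A data frame with columns `id`, `length`, `gravy`, `charge`,
#'   `pi`, `muH_100`.
#' @export
physchem_report <- function(seqs, ph = 7) {
  rows <- lapply(seqs, function(s) {
    p <- physchem(s, ph = ph)
    data.frame(id = p$id, length = p$length, gravy = p$gravy,
               charge = p$charge, pi = p$pi, muH_100 = p$mu_h)
  })
  do.call(rbind, rows)
}
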
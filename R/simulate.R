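#' Built-in amylin study sequences
#'
#' The named peptide set used throughout the package: the human amylin
#' (hIAPP) 37-mer, rat amylin (rIAPP, derived from hIAPP by the six
#' human-to-rat substitutions H18R, F23L, A25P, I26V, S28P, S29P), the
#' N-terminal 1-20 fragment, the natively aggregation-prone C-terminal 23-37
#' fragment, its F23R variant fragment, and the amyloid-beta 25-35
#' aggregative-core control.
#'
#' @return Named list of [peptide()] objects: `hIAPP`, `rIAPP`,
#'   `N_terminal_1_20`, `C_native`, `F23R_fragment`, `abeta_core`.
#' @examples
#' iapp_sequences()$C_native
#' @export
iapp_sequences <- function() {
  h <- peptide("KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY", id = "hIAPP",
               description = "human islet amyloid polypeptide (amylin), 37 aa")
  r <- apply_variants(h, c("H18R", "F23L", "A25P", "I26V", "S28P", "S29P"))
  r <- peptide(unclass(r)[[1L]], id = "rIAPP",
               description = "rat amylin (six substitutions in 18-29)")
  list(
    hIAPP = h,
    rIAPP = r,
    N_terminal_1_20 = peptide(substr(h, 1, 20), id = "N_terminal_1_20",
                              description = "hIAPP 1-20 fragment"),
    C_native = peptide("FGAILSSTNVGSNTY", id = "C_native",
                       description = "hIAPP 23-37 C-terminal fragment"),
    F23R_fragment = peptide("RGAILSSTNVGSNTY", id = "F23R_fragment",
                            description = "hIAPP 23-37 fragment, F23R variant"),
    abeta_core = peptide("GSNKGAIIGLM", id = "abeta_core",
                         description = "amyloid-beta 25-35 aggregative core")
  )
}

#' Configuration for synthetic cross-species panels
#'
#' Describes a position-specific substitution model over a reference peptide:
#' every panel member is drawn independently, and each of its positions is
#' sampled from the position's substitution distribution (residual mass goes
#' to the reference residue). Conserved positions carry zero substitution
#' mass. Fixed seed implies byte-identical panels.
#'
#' @param reference a [peptide()].
#' @param n panel size (number of member sequences).
#' @param substitutions data frame with columns `position`, `substitute`,
#'   `prob`; probabilities at each position must sum to at most 1.
#'   `X` is an allowed substitute (sampled literally, flagged downstream).
#' @param conserved integer positions whose substitution mass must be zero.
#' @param seed integer random seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(reference, n, substitutions,
                              conserved = integer(), seed = 1L) {
  reference <- as_peptide(reference)
  L <- nchar(reference)
  stopifnot(n >= 1)
  if (nrow(substitutions)) {
    substitutions$position <- as.integer(substitutions$position)
    if (any(substitutions$position < 1L | substitutions$position > L)) {
      stop("substitution position out of range of the reference")
    }
    if (any(substitutions$prob < 0)) stop("substitution probabilities must be >= 0")
    mass <- tapply(substitutions$prob, substitutions$position, sum)
    over <- names(mass)[mass > 1 + 1e-12]
    if (length(over)) {
      stop(sprintf("substitution probability mass exceeds 1 at position %s",
                   over[1L]))
    }
    bad <- intersect(unique(substitutions$position[substitutions$prob > 0]),
                     as.integer(conserved))
    if (length(bad)) {
      stop(sprintf("conserved position %d carries nonzero substitution mass",
                   bad[1L]))
    }
  }
  structure(list(reference = reference, n = as.integer(n),
                 substitutions = substitutions,
                 conserved = as.integer(conserved),
                 seed = as.integer(seed),
                 generator = "R sample(), Mersenne-Twister, per-position draws"),
            class = "simulation_config")
}

#' Generate a synthetic aligned panel
#'
#' Draws `n` member sequences from the position-specific substitution model
#' of a [simulation_config()]. Deterministic for a fixed seed; positions are
#' sampled independently (no covariation between sites).
#'
#' @param config a [simulation_config()].
#' @return A [sequence_panel()].
#' @examples
#' cfg <- simulation_config(peptide("ACDEF"), n = 5,
#'                          substitutions = data.frame(position = 3,
#'                                                     substitute = "G",
#'                                                     prob = 0.5),
#'                          seed = 42)
#' generate_panel(cfg)
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ref <- pep_chars(config$reference)
  L <- length(ref)
  n <- config$n
  mat <- matrix(rep(ref, each = n), nrow = n)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  subs <- config$substitutions
  if (nrow(subs)) {
    for (p in sort(unique(subs$position))) {
      e <- subs[subs$position == p, ]
      residual <- 1 - sum(e$prob)
      mat[, p] <- sample(c(e$substitute, ref[p]), n, replace = TRUE,
                         prob = c(e$prob, residual))
    }
  }
  members <- lapply(seq_len(n), function(i) {
    peptide(paste(mat[i, ], collapse = ""),
            id = sprintf("member_%04d", i), allow_x = TRUE)
  })
  sequence_panel(config$reference, members,
                 provenance = sprintf("synthetic panel, seed %d", config$seed))
}

#' Simulation config mirroring the 240-species catalog
#'
#' Builds a [simulation_config()] whose per-position substitution
#' probabilities are the packaged catalog's occurrence counts divided by the
#' panel denominator of 240 sequences; the highly conserved positions
#' (2, 12, 16 on the amylin reference) carry zero mass. The nonstandard X
#' record keeps its mass so that simulated catalogs can reproduce the
#' full occurrence total.
#'
#' @param n panel size (default 240, the study condition).
#' @param seed random seed.
#' @param catalog source [variant_catalog()] (default [amylin_catalog()]).
#' @return A [simulation_config()].
#' @export
catalog_config <- function(n = 240, seed = 1L, catalog = amylin_catalog()) {
  e <- catalog$entries
  simulation_config(catalog$reference, n = n,
                    substitutions = data.frame(position = e$position,
                                               substitute = e$substitute,
                                               prob = e$count / 240),
                    conserved = conserved_positions(catalog),
                    seed = seed)
}

#' Read / write simulation configs as JSON
#'
#' @param config a [simulation_config()].
#' @param path JSON file path.
#' @return [read_sim_config()] returns a [simulation_config()].
#' @export
write_sim_config <- function(config, path) {
  jsonlite::write_json(list(
    reference = list(id = pep_id(config$reference),
                     residues = unclass(config$reference)[[1L]]),
    n = config$n,
    substitutions = config$substitutions,
    conserved = config$conserved,
    seed = config$seed,
    generator = config$generator
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  simulation_config(peptide(x$reference$residues, id = x$reference$id),
                    n = x$n,
                    substitutions = as.data.frame(x$substitutions),
                    conserved = if (length(x$conserved)) x$conserved else integer(),
                    seed = x$seed)
}
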
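test_that("the built-in study sequences match their definitions", {
  sq <- iapp_sequences()
  expect_equal(nchar(sq$hIAPP), 37)
  expect_equal(unclass(sq$C_native)[[1]], "FGAILSSTNVGSNTY")
  expect_equal(unclass(sq$F23R_fragment)[[1]], "RGAILSSTNVGSNTY")
  expect_equal(unclass(sq$abeta_core)[[1]], "GSNKGAIIGLM")
  expect_equal(unclass(sq$N_terminal_1_20)[[1]], "KCNTATCATQRLANFLVHSS")
  # rat amylin is the human sequence under the six rat substitutions
  expect_identical(unclass(sq$rIAPP)[[1]],
                   unclass(apply_variants(sq$hIAPP,
                                          c("H18R", "F23L", "A25P",
                                            "I26V", "S28P", "S29P")))[[1]])
})

test_that("zero substitution mass reproduces the reference exactly", {
  cfg <- simulation_config(peptide("ACDEF"), n = 1,
                           substitutions = data.frame(position = integer(),
                                                      substitute = character(),
                                                      prob = numeric()),
                           seed = 9)
  panel <- generate_panel(cfg)
  expect_equal(length(panel$members), 1)
  expect_equal(unclass(panel$members[[1]])[[1]], "ACDEF")
})

test_that("panels are byte-identical under a fixed seed and differ across seeds", {
  cfg <- catalog_config(n = 60, seed = 77)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  seq_of <- function(p) vapply(p$members, function(m) unclass(m)[[1]], "")
  expect_identical(seq_of(a), seq_of(b))
  cfg2 <- catalog_config(n = 60, seed = 78)
  expect_false(identical(seq_of(a), seq_of(generate_panel(cfg2))))
})

test_that("config validation rejects excess probability mass and conserved leakage", {
  ref <- peptide("ACDEF")
  expect_error(simulation_config(ref, 5,
                                 data.frame(position = c(2, 2),
                                            substitute = c("V", "L"),
                                            prob = c(0.7, 0.6))),
               "mass exceeds 1 at position 2")
  expect_error(simulation_config(ref, 5,
                                 data.frame(position = 2, substitute = "V",
                                            prob = 0.1),
                                 conserved = 2L),
               "conserved position 2")
})

test_that("forced conserved positions stay conserved in derived catalogs", {
  panel <- generate_panel(catalog_config(n = 120, seed = 3))
  cat <- catalog_from_panel(panel)
  expect_true(all(c(2L, 12L, 16L) %in% conserved_positions(cat)))
})

test_that("the catalog-derived config mirrors the per-position variant structure", {
  cfg <- catalog_config(n = 240, seed = 1)
  s29 <- cfg$substitutions[cfg$substitutions$position == 29, ]
  expect_equal(sort(s29$substitute), c("A", "H", "L", "P", "T"))
  expect_equal(nrow(cfg$substitutions[cfg$substitutions$position == 2, ]), 0)
  # expected occurrences over the whole panel at n = 240
  expect_equal(240 * sum(cfg$substitutions$prob), 1640, tolerance = 1e-9)
})

test_that("catalog building recovers planted variant counts within binomial error", {
  cfg <- catalog_config(n = 240, seed = 20260926)
  cat <- catalog_from_panel(generate_panel(cfg))
  planted <- merge(cfg$substitutions, cat$entries,
                   by = c("position", "substitute"), all.x = TRUE)
  planted$count[is.na(planted$count)] <- 0L
  expected <- 240 * planted$prob
  sd3 <- 3 * sqrt(240 * planted$prob * (1 - planted$prob))
  # with 113 planted variants, allow at most one 3-sigma excursion
  # (expected false-alarm count at 3 SD is ~0.3)
  expect_lte(sum(abs(planted$count - expected) > sd3), 1)
  # every variant expected at least 5 times is actually observed
  expect_true(all(planted$count[expected >= 5] > 0))
  # and nothing outside the planted sets appears
  key <- function(df) paste(df$position, df$substitute)
  expect_true(all(key(cat$entries) %in% key(cfg$substitutions)))
})

test_that("empirical substitution frequencies converge to the configured probabilities", {
  ref <- peptide("ACDEFGHIKL", id = "ref")
  subs <- data.frame(position = c(3, 3, 7, 9),
                     substitute = c("G", "A", "W", "P"),
                     prob = c(0.3, 0.1, 0.05, 0.5))
  cfg <- simulation_config(ref, n = 10000, substitutions = subs, seed = 55)
  cat <- catalog_from_panel(generate_panel(cfg))
  obs <- merge(subs, cat$entries, by = c("position", "substitute"))
  freq <- obs$count / 10000
  se3 <- 3 * sqrt(obs$prob * (1 - obs$prob) / 10000)
  expect_equal(nrow(obs), 4)
  expect_true(all(abs(freq - obs$prob) <= se3))
})

test_that("simulation configs survive a JSON round-trip", {
  cfg <- catalog_config(n = 30, seed = 12)
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(unclass(back$reference)[[1]], unclass(cfg$reference)[[1]])
  expect_equal(back$n, cfg$n)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$conserved, cfg$conserved)
  expect_equal(back$substitutions$prob, cfg$substitutions$prob,
               tolerance = 1e-12)
  # identical panels from the original and round-tripped configs
  a <- generate_panel(cfg); b <- generate_panel(back)
  expect_identical(vapply(a$members, unclass, ""),
                   vapply(b$members, unclass, ""))
})
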
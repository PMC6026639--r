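scan_fixture <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tab <<- suppressWarnings(single_scan(hIAPP, amylin_catalog()))
    }
    tab
  }
})

test_that("the single scan scores every standard catalog variant exactly once", {
  expect_warning(single_scan(hIAPP, amylin_catalog()),
                 "skipping 1 nonstandard.*L27X")
  tab <- scan_fixture()
  expect_equal(nrow(tab$records), 112)
  expect_false(any(grepl("X", tab$records$variants)))
  # best and worst candidates
  expect_equal(tab$records$variants[1], "V17D")
  expect_equal(amylscan:::round_half_up(tab$records$na4vss[1], 1), -14.8)
  expect_equal(tab$records$variants[112], "N22I")
  expect_equal(amylscan:::round_half_up(tab$records$na4vss[112], 1), 2.9)
})

test_that("scan records agree exactly with rescoring the mutated sequence", {
  tab <- scan_fixture()
  set.seed(41)
  for (i in sample(nrow(tab$records), 15)) {
    rec <- tab$records[i, ]
    p <- aggrescan(apply_variants(hIAPP, rec$variants))
    expect_identical(rec$sequence, p$sequence)
    expect_equal(rec$na4vss, p$na4vss, tolerance = 0)
    expect_equal(rec$n_hot_spots, p$n_hot_spots)
    expect_equal(rec$hot_spot_residues, p$hot_spot_residues)
    expect_equal(rec$delta_na4vss, p$na4vss - tab$reference$na4vss,
                 tolerance = 0)
    expect_equal(rec$gravy, gravy(p$sequence), tolerance = 1e-12)
    expect_equal(rec$class,
                 if (p$na4vss < tab$reference$na4vss) "lower" else "higher")
  }
})

test_that("scan tables are sorted ascending with deterministic tie-breaks", {
  tab <- scan_fixture()
  expect_true(!is.unsorted(tab$records$na4vss))
  tab2 <- suppressWarnings(single_scan(hIAPP, amylin_catalog()))
  expect_identical(tab$records, tab2$records)
})

test_that("classification against thresholds is strict and rounds half-up", {
  tab <- scan_fixture()
  ref <- classify_vs_reference(tab)
  expect_equal(ref$n_lower, 54L)
  expect_equal(ref$pct_lower, 48)
  pram <- classify_vs_reference(tab, -6.6)
  expect_equal(pram$n_lower, 31L)
  expect_equal(classify_vs_reference(tab, -Inf)$n_lower, 0L)
  empty <- tab; empty$records <- tab$records[0, ]
  expect_error(classify_vs_reference(empty), "undefined for an empty")
})

test_that("scan reference mismatch is an error", {
  expect_error(single_scan(peptide("ACDEF"), amylin_catalog()),
               "does not match the catalog reference")
})

test_that("double scans enumerate distinct-position pairs and reproduce the top designs", {
  cat240 <- amylin_catalog()
  one <- multi_scan(hIAPP, cat240, k = 2, pool = c("V17D", "F23R"))
  expect_equal(nrow(one$records), 1)
  expect_equal(one$records$variants, "V17D+F23R")
  expect_equal(amylscan:::round_half_up(one$records$na4vss, 1), -22.9)
  three <- multi_scan(hIAPP, cat240, k = 2,
                      pool = c("V17D", "F23R", "L27H"))
  expect_equal(nrow(three$records), 3)
  expect_equal(three$records$variants[1:2], c("V17D+F23R", "V17D+L27H"))
  expect_equal(amylscan:::round_half_up(three$records$na4vss[2], 1), -21.3)
  # two variants at the same position never pair
  same <- multi_scan(hIAPP, cat240, k = 2,
                     pool = c("F23R", "F23G", "V17D"))
  expect_equal(nrow(same$records), 2)
  expect_false(any(grepl("F23R\\+F23G|F23G\\+F23R", same$records$variants)))
})

test_that("pair counts match explicit enumeration on the full catalog pool", {
  cat240 <- amylin_catalog()
  pool <- cat240$entries[!cat240$entries$nonstandard, ]
  m <- nrow(pool)
  expected <- choose(m, 2) -
    sum(vapply(split(pool, pool$position),
               function(g) choose(nrow(g), 2), numeric(1)))
  tab <- suppressWarnings(multi_scan(hIAPP, cat240, k = 2,
                                     max_combinations = 1e4))
  expect_equal(nrow(tab$records), expected)
})

test_that("multi-scan guards: k bounds, pool mismatch, combination budget", {
  cat240 <- amylin_catalog()
  expect_error(multi_scan(hIAPP, cat240, k = 1), "requires k >= 2")
  expect_error(multi_scan(hIAPP, cat240, k = 2, pool = c("A17D", "F23R")),
               "does not match the reference")
  expect_error(multi_scan(hIAPP, cat240, k = 2, pool = c("V17D", "F23R"),
                          max_combinations = 0), "budget")
  expect_error(multi_scan(hIAPP, cat240, k = 3,
                          pool = c("V17D", "F23R")), "distinct variant positions")
})

test_that("pair effects are additive when substitutions are separated by more than a window", {
  # positions 17 and 23 are 6 apart, beyond the reach of a 5-residue window,
  # so the double's delta is exactly the sum of the single deltas
  tab <- scan_fixture()
  d17 <- tab$records$delta_na4vss[tab$records$variants == "V17D"]
  d23 <- tab$records$delta_na4vss[tab$records$variants == "F23R"]
  dd <- multi_scan(hIAPP, amylin_catalog(), k = 2,
                   pool = c("V17D", "F23R"))$records$delta_na4vss
  expect_equal(dd, d17 + d23, tolerance = 1e-12)
})

test_that("hot-spot deletion flags compare residue coverage against the reference", {
  tab <- scan_fixture()
  ref_profile <- aggrescan(hIAPP)
  tab <- hotspot_deletion_flags(tab, ref_profile)
  rec <- function(v) tab$records[tab$records$variants == v, ]
  expect_true(rec("F23R")$hotspot_deleted)
  expect_true(rec("V17D")$hotspot_deleted)
  # the aggregation-increasing variant broadens rather than deletes hot spots
  expect_gte(rec("N22I")$hot_spot_residues, ref_profile$hot_spot_residues)
  expect_false(rec("N22I")$hotspot_deleted)
})

test_that("pearson matches the textbook oracle and refuses degenerate input", {
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1), 1, tolerance = 1e-12)
  expect_equal(pearson(x, -x), -1, tolerance = 1e-12)
  set.seed(43)
  for (rep in 1:20) {
    a <- rnorm(20); b <- rnorm(20)
    expect_equal(pearson(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  }
  expect_error(pearson(rep(1, 5), 1:5), "constant vector")
  expect_error(pearson(1:2, 1:2), "at least 3")
  expect_error(pearson(1:4, 1:5), "equal length")
})

test_that("aggregation and hydropathy correlate strongly across the single scan", {
  tab <- scan_fixture()
  r <- pearson(tab$records$na4vss, tab$records$gravy)
  expect_gt(r, 0.8)
})

test_that("scan reports are byte-identical across runs and merge annotations", {
  tab <- scan_fixture()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_scan_tsv(tab, p1)
  write_scan_tsv(suppressWarnings(single_scan(hIAPP, amylin_catalog())), p2)
  expect_identical(readLines(p1), readLines(p2))
  ann <- variant_annotations()
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_scan_tsv(tab, p3, annotations = ann)
  df <- read.delim(p3, na.strings = ".")
  expect_true(all(c("pasta", "organisms") %in% names(df)))
  expect_equal(df$pasta[df$variants == "F23R"], -3.88)
  expect_true(anyNA(df$pasta))
  expect_equal(df$rank, sort(df$rank))
})
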
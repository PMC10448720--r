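test_that("curve-fit reader round-trips, handles empty and no-response rows", {
  fits <- make_fits(c("C1", "C1", "C2"), c("A1", "A2", "A1"),
                    top = c(50, NA, 80), slope = c(1.2, NA, 2),
                    ac50 = c(0.5, NA, 10), curve_error = c(0.1, 0.2, 0.3),
                    hit_call = c(1L, 0L, 1L))
  path <- write_fits_csv(fits)
  back <- read_curve_fits(path)
  expect_equal(as.data.frame(back)[names(fits)], fits,
               ignore_attr = TRUE)

  empty <- read_curve_fits(write_fits_csv(fits[0, ]))
  expect_equal(nrow(empty), 0)

  # blank / unparseable parameters load as no-response, with a message
  raw <- tempfile(fileext = ".csv")
  writeLines(c("chem_id,assay_id,top,slope,ac50_uM,curve_error,hit_call",
               "C1,A1,,,,0.1,0",
               "C2,A1,oops,1,2,0.2,1"), raw)
  expect_message(nr <- read_curve_fits(raw), "no-response")
  expect_true(all(is.na(nr$top) & is.na(nr$slope) & is.na(nr$ac50)))

  writeLines("chem_id,assay_id,top", raw)
  expect_error(read_curve_fits(raw), "slope")
})

test_that("concentration units are converted at the boundary", {
  raw <- tempfile(fileext = ".csv")
  writeLines(c("chem_id,assay_id,top,slope,ac50_nM,curve_error,hit_call",
               "C1,A1,1,1,500,0.1,1"), raw)
  expect_equal(read_curve_fits(raw)$ac50, 0.5)
  writeLines(c("chem_id,css95_mM", "C1,2"), raw)
  expect_equal(read_css(raw)$css95, 2000)
})

test_that("select_best_fit picks lowest curve error with documented tie-breaks", {
  g <- make_fits("C1", "A1", top = 1:3, slope = 1, ac50 = c(5, 2, 9),
                 curve_error = c(0.3, 0.1, 0.5))
  expect_equal(select_best_fit(g)$curve_error, 0.1)
  expect_equal(select_best_fit(g[1, ])$top, 1)
  expect_error(select_best_fit(g[0, ]), "empty")

  tie <- make_fits("C1", "A1", top = 1:2, slope = 1, ac50 = c(9, 2),
                   curve_error = 0.2)
  expect_equal(select_best_fit(tie)$ac50, 2)
  tie2 <- make_fits("C1", "A1", top = 1:2, slope = 1, ac50 = 2,
                    curve_error = 0.2)
  expect_equal(select_best_fit(tie2)$top, 1)  # input order breaks it
})

test_that("select_best_fits is idempotent and permutation-invariant", {
  set.seed(42)
  fits <- make_fits(rep(sprintf("C%d", 1:5), each = 6),
                    rep(rep(c("A1", "A2"), each = 3), 5),
                    top = runif(30, 1, 100), slope = runif(30, 0.5, 4),
                    ac50 = 10^runif(30, -3, 2),
                    curve_error = round(runif(30), 3), hit_call = 1L)
  best <- select_best_fits(fits)
  expect_equal(nrow(best), 10)
  expect_equal(select_best_fits(best), best)
  for (rep_i in 1:5) {
    perm <- fits[sample(nrow(fits)), ]
    pb <- select_best_fits(perm)
    expect_equal(pb[order(pb$chem_id, pb$assay_id),
                    c("chem_id", "assay_id", "curve_error", "ac50")],
                 best[order(best$chem_id, best$assay_id),
                      c("chem_id", "assay_id", "curve_error", "ac50")],
                 ignore_attr = TRUE)
  }
})

test_that("label, KE-assignment and Css readers enforce their invariants", {
  p <- tempfile(fileext = ".csv")

  # 5 assays over 2 KEs -> groups of sizes {3, 2}
  write.csv(data.frame(assay_id = sprintf("A%d", 1:5),
                       ke_id = c("K1", "K1", "K1", "K2", "K2"),
                       ke_name = "x"), p, row.names = FALSE)
  km <- read_ke_assignments(p)
  expect_equal(sort(as.integer(table(km$ke_id))), c(2, 3))
  write.csv(data.frame(assay_id = c("A1", "A1"), ke_id = c("K1", "K2"),
                       ke_name = "x"), p, row.names = FALSE)
  expect_error(read_ke_assignments(p), "conflicting")

  write.csv(data.frame(chem_id = c("C1", "C2"), css95_uM = c(1, -2)),
            p, row.names = FALSE)
  expect_error(read_css(p), "C2")

  write.csv(data.frame(chem_id = "C1", hepatotoxic = 0,
                       hepatocellular = 1, hepatobiliary = 0),
            p, row.names = FALSE)
  expect_error(read_labels(p), "consistency")

  # round-trip identity for labels, KE map, Css, SMILES
  lab <- data.frame(chem_id = c("C1", "C2"), hepatotoxic = c(1, 0),
                    hepatocellular = c(1, 0), hepatobiliary = c(0, 0),
                    stringsAsFactors = FALSE)
  write_table(lab, p)
  expect_equal(read_labels(p), lab, ignore_attr = TRUE)
  css <- data.frame(chem_id = "C1", css95 = 3.25,
                    stringsAsFactors = FALSE)
  write_table(css, p)
  expect_equal(read_css(p), css, ignore_attr = TRUE)
  sm <- data.frame(chem_id = "C1", smiles = "CCO",
                   stringsAsFactors = FALSE)
  write_table(sm, p)
  expect_equal(read_smiles(p), sm, ignore_attr = TRUE)
})
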
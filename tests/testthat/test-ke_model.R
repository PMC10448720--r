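g10 <- build_grid()

# Two-assay toy world: constant surfaces so means are exact by hand.
const_surface <- function(assay_id, chem_vals, grid = g10) {
  m <- matrix(rep(unlist(chem_vals), each = length(grid$conc)),
              nrow = length(chem_vals), byrow = TRUE)
  rownames(m) <- names(chem_vals)
  structure(list(assay_id = assay_id, values = m,
                 chem_ids = names(chem_vals)),
            class = "response_surface")
}

test_that("compose_ke_curve averages member assays with zero fill", {
  s1 <- const_surface("A1", c(C1 = 0.2, C2 = 1))
  s2 <- const_surface("A2", c(C1 = 0.6))
  surf <- list(A1 = s1, A2 = s2)

  # single-assay KE equals that assay's normalized row
  expect_equal(compose_ke_curve("A1", surf, "C1", g10),
               rep(0.2, 111))
  # mean of 0.2 and 0.6 is 0.4
  expect_equal(compose_ke_curve(c("A1", "A2"), surf, "C1", g10),
               rep(0.4, 111))
  # untested in A2 -> zero substituted: (1 + 0)/2
  expect_equal(compose_ke_curve(c("A1", "A2"), surf, "C2", g10),
               rep(0.5, 111))
  # untested everywhere -> zero curve
  expect_equal(compose_ke_curve(c("A1", "A2"), surf, "C9", g10),
               numeric(111))
  expect_error(compose_ke_curve(character(0), surf, "C1", g10),
               "zero assays")
  # permutation invariance in assay order
  expect_equal(compose_ke_curve(c("A2", "A1"), surf, "C1", g10),
               compose_ke_curve(c("A1", "A2"), surf, "C1", g10))
})

test_that("raising one assay response never lowers the KE curve or score", {
  set.seed(4)
  vals <- matrix(runif(222), 2, 111, dimnames = list(c("C1", "C2")))
  s1 <- structure(list(assay_id = "A1", values = vals,
                       chem_ids = c("C1", "C2")),
                  class = "response_surface")
  s2 <- const_surface("A2", c(C1 = 0.3, C2 = 0.1))
  base <- compose_ke_curve(c("A1", "A2"), list(A1 = s1, A2 = s2),
                           "C1", g10)
  up <- s1
  up$values["C1", 40] <- up$values["C1", 40] + 0.5
  bumped <- compose_ke_curve(c("A1", "A2"), list(A1 = up, A2 = s2),
                             "C1", g10)
  expect_true(all(bumped >= base))
  expect_gte(ke_score(bumped, g10), ke_score(base, g10))
})

test_that("ke_score is the width-normalized log-domain trapezoid", {
  expect_equal(ke_score(numeric(111), g10), 0)
  expect_equal(ke_score(rep(1, 111), g10), 1)
  set.seed(11)
  for (i in 1:10) {
    curve <- pmin(1, pmax(0, cumsum(rnorm(111, 0.01, 0.05))))
    expect_equal(ke_score(curve, g10),
                 oracle_fine_auc(curve, g10, factor = 1000),
                 tolerance = 1e-6)
  }
  expect_error(ke_score(numeric(10), g10), "grid")
})

test_that("scale_scores and rank_chemicals behave as documented", {
  expect_equal(scale_scores(c(a = 0.2, b = 0.1, c = 0)),
               c(a = 1, b = 0.5, c = 0))
  expect_equal(scale_scores(c(x = 0, y = 0)), c(x = 0, y = 0))
  expect_equal(unname(scale_scores(c(only = 0.03))), 1)
  # idempotence
  s <- scale_scores(c(a = 0.4, b = 0.2))
  expect_equal(scale_scores(s), s)

  expect_equal(rank_chemicals(c(A = 0.1, B = 0.9, C = 0.5)),
               c("B", "C", "A"))
  expect_equal(rank_chemicals(c(Z = 0.5, A = 0.5, M = 0.5)),
               c("A", "M", "Z"))           # ties: chem_id ascending
  expect_equal(rank_chemicals(c(A = 0, B = 1, C = 1)),
               c("B", "C", "A"))
})

test_that("ke_score_table keeps all values in [0,1] with max 1 per live KE", {
  set.seed(5)
  b <- generate(generator_config(n_chemicals = 40, n_assays = 12,
                                 n_kes = 3, seed = 5))
  surf <- build_surfaces(b$curve_fits, g10)
  st <- ke_score_table(b$ke_map, surf, sort(unique(b$labels$chem_id)),
                       g10)
  expect_true(all(st$raw_auc >= 0 & st$raw_auc <= 1))
  expect_true(all(st$scaled_score >= 0 & st$scaled_score <= 1))
  for (ke in unique(st$ke_id)) {
    s <- st$scaled_score[st$ke_id == ke]
    if (any(s > 0)) expect_equal(max(s), 1)
  }
  # sum mode also respects the bound via rescaling
  st2 <- ke_score_table(b$ke_map, surf, sort(unique(b$labels$chem_id)),
                        g10, mode = "sum")
  expect_true(all(st2$raw_auc >= 0 & st2$raw_auc <= 1))
})

test_that("ke_roc_auc equals exhaustive pairwise concordance", {
  expect_equal(ke_roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(ke_roc_auc(rep(0.3, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  s6 <- c(0.9, 0.4, 0.4, 0.3, 0.2, 0.8)
  l6 <- c(1, 1, 0, 0, 1, 0)
  expect_equal(ke_roc_auc(s6, l6), oracle_roc_auc(s6, l6))
  expect_error(ke_roc_auc(1:4, rep(1, 4)), "positive and one negative")

  set.seed(3)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    lab <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    expect_identical(ke_roc_auc(sc, lab), oracle_roc_auc(sc, lab))
  }
})
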
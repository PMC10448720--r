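test_that("contingency counts hand-assigned chemicals correctly", {
  hits <- data.frame(chem_id = c("C1", "C2", "C3", "C4"),
                     hit_call = c(1, 1, 0, 0))
  labs <- data.frame(chem_id = c("C1", "C2", "C3", "C4"),
                     hepatotoxic = c(1, 1, 1, 0),
                     hepatocellular = c(1, 0, 1, 0),
                     hepatobiliary = c(0, 1, 0, 0))
  tab <- contingency(hits, labs, "hepatocellular")
  expect_equal(unname(tab), matrix(c(1, 1, 1, 1), 2))
  tab2 <- contingency(hits, labs, "hepatotoxic")
  expect_equal(unname(tab2), matrix(c(2, 1, 0, 1), 2))

  # disjoint id sets -> all-zero table
  far <- data.frame(chem_id = c("X1", "X2"), hit_call = c(1, 0))
  expect_equal(sum(contingency(far, labs, "hepatotoxic")), 0)

  expect_error(contingency(rbind(hits, hits[1, ]), labs, "hepatotoxic"),
               "duplicated")
})

test_that("fisher_exact matches hand-enumerated tables and flags degeneracy", {
  r <- fisher_exact(matrix(c(5, 5, 5, 5), 2, byrow = TRUE))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)

  # [[3,1],[1,3]]: full enumeration over k = 0..4 gives 34/70
  r2 <- fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(r2$p_value, 34 / 70)
  expect_equal(r2$odds_ratio, 9)

  # [[10,0],[0,10]]: only the two extreme tables are as extreme
  r3 <- fisher_exact(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_equal(r3$p_value, 2 / choose(20, 10))
  expect_equal(r3$odds_ratio, Inf)

  degen <- fisher_exact(matrix(c(0, 0, 3, 7), 2, byrow = TRUE))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)
  expect_equal(degen$odds_ratio, 1)

  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("fisher_exact equals exhaustive enumeration on small tables", {
  # spot-check grid here; the exhaustive n <= 30 sweep runs in the
  # acceptance suite
  set.seed(1)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 3), 2)
    expect_equal(fisher_exact(tab)$p_value,
                 oracle_fisher_p(tab[1, 1], tab[1, 2],
                                 tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
  }
})

test_that("bh_select implements the step-up rule", {
  expect_true(bh_select(0.01, fdr = 0.15))
  expect_equal(bh_select(c(0.5, 0.6)), c(FALSE, FALSE))
  # thresholds {0.05, 0.10, 0.15}: first two selected
  expect_equal(bh_select(c(0.01, 0.02, 0.9)), c(TRUE, TRUE, FALSE))
  expect_length(bh_select(numeric(0)), 0)
  expect_error(bh_select(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("bh_select properties: cap at fdr, monotone in fdr, matches p.adjust", {
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    for (fdr in c(0.05, 0.15, 0.5)) {
      sel <- bh_select(p, fdr)
      expect_true(all(p[sel] <= fdr))
      expect_equal(sel, p.adjust(p, "BH") <= fdr)
    }
    expect_true(all(bh_select(p, 0.05) <= bh_select(p, 0.25)))
  }
})

test_that("assay selection respects degeneracy, direction and permutations", {
  set.seed(21)
  n <- 80
  labs <- data.frame(chem_id = sprintf("C%03d", 1:n),
                     hepatotoxic = rbinom(n, 1, 0.5))
  labs$hepatocellular <- labs$hepatotoxic * rbinom(n, 1, 0.8)
  labs$hepatobiliary <- labs$hepatotoxic * rbinom(n, 1, 0.5)

  # one strongly associated assay, four null assays
  hit_prob <- function(aid, tox) if (aid == "A1") 0.05 + 0.7 * tox else 0.05
  fits <- do.call(rbind, lapply(sprintf("A%d", 1:5), function(aid) {
    active <- rbinom(n, 1, hit_prob(aid, labs$hepatocellular))
    make_fits(labs$chem_id, aid,
              top = ifelse(active == 1, 50, NA),
              slope = ifelse(active == 1, 1, NA),
              ac50 = ifelse(active == 1, 1, NA),
              curve_error = 0.1, hit_call = active)
  }))
  sel <- select_relevant_assays(fits, labs)
  expect_true("A1" %in% sel$union)
  expect_true(all(sel$results$selected[sel$results$assay_id == "A1"] |
                    sel$results$endpoint[sel$results$assay_id == "A1"] ==
                    "hepatobiliary"))
  # permuting chemical order changes nothing
  perm <- fits[sample(nrow(fits)), ]
  sel2 <- select_relevant_assays(perm, labs)
  expect_equal(sel2$results, sel$results)

  # all labels identical -> degenerate tables, nothing selected
  same <- labs
  same$hepatotoxic <- same$hepatocellular <- same$hepatobiliary <- 1
  sel3 <- select_relevant_assays(fits, same)
  expect_length(sel3$union, 0)

  # selection is never negative-direction (OR <= 1 excluded)
  expect_true(all(sel$results$odds_ratio[sel$results$selected] > 1))
})
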
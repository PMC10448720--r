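#' @title Selecting hepatotoxicity-associated assays
#' @description Assays whose binary hit calls are significantly and
#'   positively associated with hepatocellular and/or hepatobiliary
#'   toxicity are identified with Fisher's exact test, controlling the
#'   false discovery rate per endpoint with the Benjamini-Hochberg
#'   step-up procedure (default FDR 0.15).
#' @name assay_select
NULL

#' Build a 2x2 hit-call x toxicity contingency table
#'
#' Only chemicals present in both inputs, with a non-missing hit call
#' and a non-missing endpoint label, contribute. Cell layout:
#' rows = active/inactive, columns = toxic/nontoxic.
#'
#' @param hit_calls data.frame `chem_id`, `hit_call` (0/1), unique ids.
#' @param labels Label table (see [read_labels()]).
#' @param endpoint `"hepatocellular"`, `"hepatobiliary"`, or
#'   `"hepatotoxic"`.
#' @return 2x2 integer matrix with dimnames.
#' @export
contingency <- function(hit_calls, labels,
                        endpoint = c("hepatocellular", "hepatobiliary",
                                     "hepatotoxic")) {
  endpoint <- match.arg(endpoint)
  if (anyDuplicated(hit_calls$chem_id))
    stop("duplicated chem_id in hit_calls")
  if (anyDuplicated(labels$chem_id))
    stop("duplicated chem_id in labels")
  m <- merge(hit_calls[, c("chem_id", "hit_call")],
             labels[, c("chem_id", endpoint)], by = "chem_id")
  m <- m[!is.na(m$hit_call) & !is.na(m[[endpoint]]), , drop = FALSE]
  act <- factor(m$hit_call, levels = c(1, 0),
                labels = c("active", "inactive"))
  tox <- factor(m[[endpoint]], levels = c(1, 0),
                labels = c("toxic", "nontoxic"))
  tab <- table(act, tox)
  matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The p-value is the sum of hypergeometric probabilities, conditional
#' on the margins, of all tables at most as probable as the observed
#' one (the standard two-sided convention, with a relative slack of
#' 1e-7 on the density comparison). The odds ratio is the sample
#' cross-product ratio a*d / (b*c), reported as `Inf` when b*c = 0 and
#' a*d > 0. A table with any zero margin carries no information: p = 1,
#' odds ratio 1, and `degenerate = TRUE`.
#'
#' @param table 2x2 matrix of nonnegative integer counts
#'   (`[a b; c d]`, rows = active/inactive, cols = toxic/nontoxic).
#' @return List with `odds_ratio`, `p_value`, `degenerate`.
#' @export
fisher_exact <- function(table) {
  x <- as.vector(t(table))            # a, b, c, d
  if (length(x) != 4 || any(is.na(x)) || any(x < 0) ||
      any(x != round(x)))
    stop("table must be 2x2 nonnegative integers")
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  n <- a + b + c_ + d
  r1 <- a + b; c1 <- a + c_
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n)
    return(list(odds_ratio = 1, p_value = 1, degenerate = TRUE))
  or <- if (b * c_ == 0) {
    if (a * d > 0) Inf else 1
  } else (a * d) / (b * c_)
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  k <- lo:hi
  dens <- stats::dhyper(k, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  p <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  list(odds_ratio = or, p_value = p, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up selection
#'
#' Sort p-values ascending, find the largest rank i with
#' p(i) <= i * fdr / m, and select everything at or below that rank.
#'
#' @param p_values Numeric vector in \[0,1\].
#' @param fdr Target false discovery rate (default 0.15).
#' @return Logical vector, same order as `p_values`.
#' @export
bh_select <- function(p_values, fdr = 0.15) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p_values must lie in [0,1]")
  m <- length(p_values)
  if (m == 0) return(logical(0))
  ord <- order(p_values)
  ps <- p_values[ord]
  ok <- which(ps <= seq_len(m) * fdr / m)
  sel <- logical(m)
  if (length(ok)) sel[ord[seq_len(max(ok))]] <- TRUE
  sel
}

#' Select assays associated with hepatotoxicity endpoints
#'
#' For every assay, builds the hit-call contingency table against each
#' endpoint (hepatocellular, hepatobiliary), runs Fisher's exact test,
#' applies BH selection within each endpoint separately, and retains
#' only positive associations (odds ratio > 1). Chemicals lacking a
#' given endpoint label are excluded from that endpoint's tables only.
#'
#' @param fits Curve-fit table; hit calls are taken from the best fit
#'   per chemical x assay.
#' @param labels Label table (see [read_labels()]).
#' @param fdr BH false discovery rate per endpoint (default 0.15).
#' @param endpoints Endpoints to test.
#' @return List with `results` (data.frame: `assay_id,endpoint,a,b,c,d,
#'   odds_ratio,p_value,selected`), per-endpoint selected sets,
#'   `union`, and `intersection` of assay ids.
#' @export
select_relevant_assays <- function(fits, labels, fdr = 0.15,
                                   endpoints = c("hepatocellular",
                                                 "hepatobiliary")) {
  best <- select_best_fits(fits)
  assays <- sort(unique(best$assay_id))
  rows <- list()
  for (ep in endpoints) {
    res <- lapply(assays, function(aid) {
      hc <- best[best$assay_id == aid, c("chem_id", "hit_call")]
      tab <- contingency(hc, labels, ep)
      ft <- fisher_exact(tab)
      data.frame(assay_id = aid, endpoint = ep,
                 a = tab[1, 1], b = tab[1, 2],
                 c = tab[2, 1], d = tab[2, 2],
                 odds_ratio = ft$odds_ratio, p_value = ft$p_value,
                 degenerate = ft$degenerate, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$selected <- bh_select(res$p_value, fdr) &
      !res$degenerate & res$odds_ratio > 1
    rows[[ep]] <- res
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  sets <- lapply(rows, function(r) r$assay_id[r$selected])
  list(results = results,
       by_endpoint = sets,
       union = sort(Reduce(union, sets)),
       intersection = sort(Reduce(intersect, sets)))
}
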
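# Fixture builders and independent oracles shared across tests.

make_fits <- function(chem_id, assay_id, top = NA_real_,
                      slope = NA_real_, ac50 = NA_real_,
                      curve_error = 0.1, hit_call = 0L) {
  data.frame(chem_id = chem_id, assay_id = assay_id, top = top,
             slope = slope, ac50 = ac50, curve_error = curve_error,
             hit_call = hit_call, stringsAsFactors = FALSE)
}

write_fits_csv <- function(fits, path = tempfile(fileext = ".csv")) {
  ketox::write_table(fits, path)
  path
}

# --- independent oracles ----------------------------------------------

# Fisher two-sided p by full hypergeometric enumeration with choose(),
# written from the definition (conditional on margins, sum of all
# tables no more probable than the observed one).
oracle_fisher_p <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  r1 <- a + b
  c1 <- a + c_
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  dens <- vapply(ks, function(k)
    choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1), numeric(1))
  obs <- dens[ks == a]
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# ROC AUC by exhaustive enumeration of all (positive, negative) pairs.
oracle_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Straightforward reference Butina: recompute unassigned-neighbor
# counts each round with explicit loops; same tie-break contract
# (largest neighborhood, then smallest chem_id).
oracle_butina <- function(fps, cutoff = 0.70) {
  ids <- names(fps)
  n <- length(ids)
  sim <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- union(fps[[i]], fps[[j]])
    sim[i, j] <- if (length(u) == 0) 1 else
      length(intersect(fps[[i]], fps[[j]])) / length(u)
  }
  assigned <- rep(FALSE, n)
  rows <- NULL
  k <- 0
  while (!all(assigned)) {
    best <- NA; best_n <- -1
    for (i in order(ids)) {             # id order resolves ties
      if (assigned[i]) next
      cnt <- 0
      for (j in seq_len(n))
        if (j != i && !assigned[j] && sim[i, j] >= cutoff)
          cnt <- cnt + 1
      if (cnt > best_n) { best <- i; best_n <- cnt }
    }
    members <- best
    for (j in seq_len(n))
      if (j != best && !assigned[j] && sim[best, j] >= cutoff)
        members <- c(members, j)
    assigned[members] <- TRUE
    k <- k + 1
    rows <- rbind(rows, data.frame(cluster_id = k,
                                   chem_id = ids[members],
                                   centroid = ids[best],
                                   stringsAsFactors = FALSE))
  }
  rownames(rows) <- NULL
  rows
}

# Trapezoid quadrature of the piecewise-linear interpolant of `curve`
# on a grid refined `factor`-fold, optionally truncated at log10 cut.
oracle_fine_auc <- function(curve, grid, factor = 1000,
                            cut = NULL) {
  lg <- grid$log10_conc
  fine <- seq(lg[1], lg[length(lg)], length.out =
                (length(lg) - 1) * factor + 1)
  vals <- stats::approx(lg, curve, xout = fine)$y
  if (!is.null(cut)) {
    vals[fine > cut] <- NA
    keep <- !is.na(vals)
    if (!any(keep)) return(0)
    fine2 <- fine[keep]; v2 <- vals[keep]
    if (cut > fine2[length(fine2)] && cut < lg[length(lg)]) {
      fine2 <- c(fine2, cut)
      v2 <- c(v2, stats::approx(lg, curve, xout = cut)$y)
    }
    fine <- fine2; vals <- v2
  }
  sum(diff(fine) * (head(vals, -1) + tail(vals, -1)) / 2) /
    (lg[length(lg)] - lg[1])
}

# Small random fingerprint sets for clustering property tests.
random_fps <- function(n, n_bits = 64, density = 0.3) {
  fps <- lapply(seq_len(n), function(i)
    sort(which(stats::runif(n_bits) < density)))
  names(fps) <- sprintf("M%02d", seq_len(n))
  fps
}
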
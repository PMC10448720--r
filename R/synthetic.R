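#' @title Synthetic HTS hepatotoxicity datasets with known ground truth
#' @description Generates a complete, internally consistent input
#'   bundle -- curve fits with hit calls, hepatotoxicity labels, Css
#'   values, SMILES, and assay-to-KE assignments -- with known
#'   ground-truth assay-toxicity associations and an optional
#'   toxicokinetic modulation mechanism, so every pipeline stage can be
#'   validated without external downloads.
#' @name synthetic
NULL

#' Configuration for the synthetic generator
#'
#' Defaults encode the statistical world the pipeline assumes: low
#' (5%) baseline HTS hit rates, a strong activation-probability lift
#' (+0.25) for truly associated assays among chemicals positive for
#' the matching endpoint, class prevalences matching the reference
#' hepatotoxicity composition (68% hepatotoxic; of those 81%
#' hepatocellular, 61% hepatobiliary, 57% both), AC50 log-uniform over
#' the 11 grid decades, Hill tops uniform in (0, 100], slopes uniform
#' in \[0.5, 4\], and log10 Css normal with mean 1 and sd 1.5 (median
#' 10 uM, spanning the sub-nM to tens-of-mM range seen in
#' toxicokinetic predictions).
#'
#' @param n_chemicals,n_assays,n_kes Panel dimensions.
#' @param frac_associated Fraction of assays truly associated with
#'   toxicity (default 0.10).
#' @param baseline_hit_rate Activation probability for non-associated
#'   assays, and for associated assays among unaffected chemicals.
#' @param effect_size Additive lift in activation probability for
#'   associated assays among chemicals positive for the matching
#'   endpoint.
#' @param p_hepatotoxic Provisional hepatotoxicant prevalence.
#' @param p_cell_only,p_bil_only,p_both Mechanism split among
#'   provisional hepatotoxicants (remainder: mechanism unknown).
#' @param tested_fraction Probability a chemical was tested in a given
#'   assay (untested pairs emit no row).
#' @param top_max,slope_range,ac50_log10_range Hill parameter laws.
#' @param css_log10_mean,css_log10_sd Log10-normal Css law (uM).
#' @param tk_modulation If `TRUE`, the final toxicity label requires
#'   both activity and bioavailability: a designated fraction of
#'   provisionally toxic, active chemicals is assigned a Css below its
#'   activity onset (minimum AC50 among active assays) and relabeled
#'   nontoxic ("TK-rescued").
#' @param tk_rescue_fraction Fraction of provisionally toxic active
#'   chemicals designated for rescue when `tk_modulation` is on.
#' @param n_fits_per_active Curve fits emitted per active pair (the
#'   true parameters carry the lowest curve error).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_chemicals = 500L, n_assays = 100L,
                             n_kes = 10L, frac_associated = 0.10,
                             baseline_hit_rate = 0.05,
                             effect_size = 0.25,
                             p_hepatotoxic = 0.68,
                             p_cell_only = 287 / 1200,
                             p_bil_only = 44 / 1200,
                             p_both = 682 / 1200,
                             tested_fraction = 0.90,
                             top_max = 100,
                             slope_range = c(0.5, 4),
                             ac50_log10_range = c(-6, 5),
                             css_log10_mean = 1, css_log10_sd = 1.5,
                             tk_modulation = FALSE,
                             tk_rescue_fraction = 0.25,
                             n_fits_per_active = 3L,
                             seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$frac_associated, cfg$baseline_hit_rate, cfg$effect_size,
             cfg$p_hepatotoxic, cfg$p_cell_only, cfg$p_bil_only,
             cfg$p_both, cfg$tested_fraction, cfg$tk_rescue_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities and fractions must lie in [0,1]")
  if (cfg$p_cell_only + cfg$p_bil_only + cfg$p_both > 1)
    stop("mechanism split exceeds 1")
  if (any(c(cfg$n_chemicals, cfg$n_assays, cfg$n_kes,
            cfg$n_fits_per_active) < 1))
    stop("n_chemicals, n_assays, n_kes, n_fits_per_active must be >= 1")
  if (cfg$baseline_hit_rate + cfg$effect_size > 1)
    stop("baseline_hit_rate + effect_size exceeds 1")
  class(cfg) <- "generator_config"
  cfg
}

# Built-in valid SMILES library: scaffold families x (linker,terminal)
# tails. Pairs are unique by construction; families give Butina
# clustering real structure to find.
.smiles_library <- function(n) {
  scaffolds <- c(
    benzene       = "c1ccc(%s)cc1",
    toluene       = "Cc1ccc(%s)cc1",
    phenol        = "Oc1ccc(%s)cc1",
    aniline       = "Nc1ccc(%s)cc1",
    chlorobenzene = "Clc1ccc(%s)cc1",
    cyclohexane   = "C1CCC(%s)CC1",
    naphthalene   = "c1ccc2cc(%s)ccc2c1",
    pyridine      = "c1ccc(%s)nc1",
    benzoic_acid  = "OC(=O)c1ccc(%s)cc1",
    benzonitrile  = "N#Cc1ccc(%s)cc1",
    benzyl_alcohol = "OCc1ccc(%s)cc1")
  linkers <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC")
  terminals <- c("", "O", "N", "Cl", "C(=O)O", "OC", "C#N", "C(F)(F)F")
  combos <- expand.grid(scaffold = names(scaffolds), linker = linkers,
                        terminal = terminals, stringsAsFactors = FALSE)
  # cycle scaffolds fastest so consecutive chemicals span families
  combos <- combos[order(combos$linker, combos$terminal), ]
  if (n > nrow(combos))
    stop("built-in SMILES library supports at most ", nrow(combos),
         " chemicals")
  combos <- combos[seq_len(n), ]
  data.frame(
    smiles = sprintf(scaffolds[combos$scaffold],
                     paste0(combos$linker, combos$terminal)),
    family = combos$scaffold, stringsAsFactors = FALSE)
}

#' Generate a synthetic dataset bundle
#'
#' @param config A [generator_config()].
#' @return List of class `synthetic_bundle` with tables `curve_fits`,
#'   `labels`, `css`, `ke_map`, `smiles` (all in the shapes the
#'   `read_*` readers expect) and `truth` (see [ground_truth()]).
#' @export
generate <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old))
  set.seed(config$seed)

  n_c <- config$n_chemicals
  n_a <- config$n_assays
  chem_ids <- sprintf("CHEM%04d", seq_len(n_c))
  assay_ids <- sprintf("ASSAY%03d", seq_len(n_a))
  ke_ids <- sprintf("KE%02d", seq_len(config$n_kes))

  # assay -> KE map (every KE nonempty when n_assays >= n_kes)
  ke_of <- sample(rep_len(ke_ids, n_a))
  ke_map <- data.frame(assay_id = assay_ids, ke_id = ke_of,
                       ke_name = paste("key event", ke_of),
                       stringsAsFactors = FALSE)

  # ground-truth associated assays, each tied to one or both endpoints
  n_assoc <- round(config$frac_associated * n_a)
  assoc <- sort(sample(assay_ids, n_assoc))
  assoc_ep <- sample(c("hepatocellular", "hepatobiliary", "both"),
                     n_assoc, replace = TRUE)
  assoc_cell <- assoc[assoc_ep %in% c("hepatocellular", "both")]
  assoc_bil <- assoc[assoc_ep %in% c("hepatobiliary", "both")]

  # provisional labels with mechanism split
  toxic <- stats::rbinom(n_c, 1, config$p_hepatotoxic)
  mech <- rep("none", n_c)
  n_tox <- sum(toxic == 1)
  p_rest <- max(0, 1 - config$p_cell_only - config$p_bil_only -
                  config$p_both)
  mech[toxic == 1] <- sample(
    c("cell", "bil", "both", "none"), n_tox, replace = TRUE,
    prob = c(config$p_cell_only, config$p_bil_only, config$p_both,
             p_rest))
  cell <- as.integer(toxic == 1 & mech %in% c("cell", "both"))
  bil <- as.integer(toxic == 1 & mech %in% c("bil", "both"))

  # activity: per chemical x assay activation probability
  p_act <- matrix(config$baseline_hit_rate, n_c, n_a,
                  dimnames = list(chem_ids, assay_ids))
  lift_cell <- outer(cell == 1, assay_ids %in% assoc_cell)
  lift_bil <- outer(bil == 1, assay_ids %in% assoc_bil)
  p_act[lift_cell | lift_bil] <-
    config$baseline_hit_rate + config$effect_size
  tested <- matrix(stats::runif(n_c * n_a) < config$tested_fraction,
                   n_c, n_a)
  active <- tested & matrix(stats::runif(n_c * n_a), n_c, n_a) < p_act

  # Hill parameters for active pairs
  idx <- which(active, arr.ind = TRUE)
  n_act <- nrow(idx)
  true_top <- stats::runif(n_act, 0, config$top_max)
  true_top <- pmax(true_top, 1e-6 * config$top_max)  # top > 0
  true_slope <- stats::runif(n_act, config$slope_range[1],
                             config$slope_range[2])
  true_ac50 <- 10^stats::runif(n_act, config$ac50_log10_range[1],
                               config$ac50_log10_range[2])

  # Css and TK modulation
  css95 <- 10^stats::rnorm(n_c, config$css_log10_mean,
                           config$css_log10_sd)
  onset <- rep(Inf, n_c) # min AC50 among a chemical's active assays
  if (n_act > 0) {
    mins <- tapply(true_ac50, idx[, 1], min)
    onset[as.integer(names(mins))] <- mins
  }
  tk_rescued <- rep(FALSE, n_c)
  final_toxic <- toxic
  if (config$tk_modulation) {
    eligible <- which(toxic == 1 & is.finite(onset))
    n_resc <- round(config$tk_rescue_fraction * length(eligible))
    designated <- sort(eligible[sample.int(length(eligible), n_resc)])
    # assign Css 1-3 decades below the activity onset (floor: grid min)
    css95[designated] <- pmax(
      onset[designated] * 10^-stats::runif(n_resc, 1, 3), 1e-6 / 2)
    rescued <- toxic == 1 & is.finite(onset) & css95 < onset
    final_toxic[rescued] <- 0L
    cell[rescued] <- 0L
    bil[rescued] <- 0L
    tk_rescued <- rescued
  }

  labels <- data.frame(chem_id = chem_ids, hepatotoxic = final_toxic,
                       hepatocellular = cell, hepatobiliary = bil,
                       stringsAsFactors = FALSE)

  # curve-fit rows: inactive tested pairs get one flat no-response row;
  # active pairs get n_fits_per_active fits, true parameters scoring
  # the lowest curve error
  inact <- which(tested & !active, arr.ind = TRUE)
  fits_inactive <- data.frame(
    chem_id = chem_ids[inact[, 1]], assay_id = assay_ids[inact[, 2]],
    top = NA_real_, slope = NA_real_, ac50 = NA_real_,
    curve_error = round(stats::runif(nrow(inact), 0.01, 0.1), 4),
    hit_call = 0L, stringsAsFactors = FALSE)
  k <- config$n_fits_per_active
  fits_active <- data.frame(
    chem_id = rep(chem_ids[idx[, 1]], each = k),
    assay_id = rep(assay_ids[idx[, 2]], each = k),
    top = rep(true_top, each = k),
    slope = rep(true_slope, each = k),
    ac50 = rep(true_ac50, each = k),
    curve_error = NA_real_, hit_call = 1L, stringsAsFactors = FALSE)
  if (n_act > 0) {
    alt <- rep(seq_len(k), times = n_act) > 1
    # decoy fits: jittered parameters, strictly worse error
    fits_active$top[alt] <- fits_active$top[alt] *
      stats::runif(sum(alt), 0.5, 1.5)
    fits_active$slope[alt] <- pmax(
      fits_active$slope[alt] * stats::runif(sum(alt), 0.5, 1.5), 0.1)
    fits_active$ac50[alt] <- fits_active$ac50[alt] *
      10^stats::runif(sum(alt), -0.5, 0.5)
    err <- stats::runif(n_act, 0.05, 0.15)
    fits_active$curve_error <- as.vector(vapply(seq_len(n_act),
      function(i) c(err[i],
                    sort(stats::runif(k - 1, 0.2, 1))), numeric(k)))
    fits_active$curve_error <- round(fits_active$curve_error, 4)
  }
  curve_fits <- rbind(fits_active, fits_inactive)
  curve_fits <- curve_fits[order(curve_fits$chem_id,
                                 curve_fits$assay_id), ]
  rownames(curve_fits) <- NULL

  lib <- .smiles_library(n_c)
  structure(list(
    curve_fits = curve_fits,
    labels = labels,
    css = data.frame(chem_id = chem_ids, css95 = css95,
                     stringsAsFactors = FALSE),
    ke_map = ke_map,
    smiles = data.frame(chem_id = chem_ids, smiles = lib$smiles,
                        stringsAsFactors = FALSE),
    truth = list(
      associated_assays = assoc,
      associated_hepatocellular = assoc_cell,
      associated_hepatobiliary = assoc_bil,
      provisional_toxic = chem_ids[toxic == 1],
      tk_rescued = chem_ids[tk_rescued],
      activity_onset = stats::setNames(onset, chem_ids),
      smiles_family = stats::setNames(lib$family, chem_ids),
      config = config)),
    class = "synthetic_bundle")
}

#' Ground truth of a synthetic bundle
#'
#' @param bundle A `synthetic_bundle` from [generate()].
#' @return List: `associated_assays` (and per-endpoint subsets),
#'   `tk_rescued` chemicals, per-chemical `activity_onset` (minimum
#'   AC50 among active assays, uM), SMILES scaffold families, and the
#'   generating config.
#' @export
ground_truth <- function(bundle) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  bundle$truth
}

#' Score an assay selection against ground truth
#'
#' @param selected Character vector of selected assay ids.
#' @param truth Output of [ground_truth()].
#' @param all_assays All candidate assay ids.
#' @return List with `sensitivity` (truth recovered) and `fdr`
#'   (selected that are not true; 0 when nothing selected).
#' @export
recovery_score <- function(selected, truth, all_assays) {
  tp <- length(intersect(selected, truth$associated_assays))
  list(sensitivity = tp / length(truth$associated_assays),
       fdr = if (length(selected)) 1 - tp / length(selected) else 0)
}

#' Write a synthetic bundle to disk as reader-compatible CSV files
#'
#' Writes `curve_fits.csv`, `labels.csv`, `css.csv`, `ke_map.csv`,
#' `smiles.csv` and `truth.json` under `dir`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(bundle$curve_fits, file.path(dir, "curve_fits.csv"))
  write_table(bundle$labels, file.path(dir, "labels.csv"))
  write_table(bundle$css, file.path(dir, "css.csv"))
  write_table(bundle$ke_map, file.path(dir, "ke_map.csv"))
  write_table(bundle$smiles, file.path(dir, "smiles.csv"))
  truth <- bundle$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
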
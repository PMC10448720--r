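#' @title Key-event curves and scores
#' @description A key event (KE) groups assays sharing a biological
#'   target or mechanism. A chemical's KE curve is the composite of its
#'   normalized responses across the KE's assays over the shared
#'   concentration grid; its KE score is the normalized area under that
#'   curve in the log10-concentration domain, scaled within the KE so
#'   the most active chemical scores 1.
#' @name ke_model
NULL

#' Compose a chemical's KE curve from member-assay surfaces
#'
#' Default aggregation is the arithmetic mean over the KE's assays of
#' the chemical's normalized response at each grid point, with zeros
#' substituted for assays where the chemical is untested; this keeps
#' every KE curve value in \[0,1\]. The alternative `"sum"` mode adds
#' the member responses and rescales the whole KE by the maximum curve
#' value observed across chemicals (see [compose_ke_curves()]).
#'
#' @param assay_ids Assays belonging to the KE (at least one).
#' @param surfaces Named list of `response_surface` (from
#'   [build_surfaces()]); KE members missing from this list count as
#'   untested (zero) for every chemical.
#' @param chem_id Chemical to compose.
#' @param grid The shared `conc_grid`.
#' @return Numeric KE-curve vector over the grid (mean mode: in \[0,1\]).
#' @export
compose_ke_curve <- function(assay_ids, surfaces, chem_id, grid) {
  if (length(assay_ids) == 0)
    stop("KE with zero assays is undefined")
  acc <- numeric(length(grid$conc))
  for (aid in assay_ids) {
    s <- surfaces[[aid]]
    if (!is.null(s) && chem_id %in% s$chem_ids)
      acc <- acc + s$values[match(chem_id, s$chem_ids), ]
    # untested chemical or absent assay contributes zeros
  }
  unname(acc) / length(assay_ids)
}

#' KE curves for all chemicals of one KE
#'
#' @param assay_ids Assays of the KE.
#' @param surfaces Named list of `response_surface`.
#' @param chem_ids Chemicals to include (rows of the result).
#' @param grid The shared `conc_grid`.
#' @param mode `"mean"` (default; curves bounded by construction) or
#'   `"sum"` (raw additive curves rescaled by the KE-wide maximum so the
#'   \[0,1\] bound still holds).
#' @return Matrix, one row per chemical (rownames = `chem_ids`).
#' @export
compose_ke_curves <- function(assay_ids, surfaces, chem_ids, grid,
                              mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  curves <- t(vapply(chem_ids, function(cid)
    compose_ke_curve(assay_ids, surfaces, cid, grid),
    numeric(length(grid$conc))))
  rownames(curves) <- chem_ids
  if (mode == "sum") {
    curves <- curves * length(assay_ids)
    m <- max(curves, 0)
    if (m > 0) curves <- curves / m
  }
  curves
}

#' Area under a KE curve (raw KE score)
#'
#' Trapezoidal integral of the curve against log10(concentration),
#' normalized by the total grid width of 11 decades, so a constant-1
#' curve scores exactly 1 and a flat curve scores 0.
#'
#' @param curve KE-curve vector on the shared grid.
#' @param grid The `conc_grid` the curve lives on.
#' @return Raw AUC in \[0,1\] for curves in \[0,1\].
#' @export
ke_score <- function(curve, grid) {
  lg <- grid$log10_conc
  if (length(curve) != length(lg))
    stop("curve length does not match grid")
  sum(diff(lg) * (utils::head(curve, -1) + utils::tail(curve, -1)) / 2) /
    (lg[length(lg)] - lg[1])
}

#' Scale raw KE scores within one KE
#'
#' Divides by the within-KE maximum so the most active chemical scores
#' exactly 1; an all-zero KE stays all-zero.
#'
#' @param raw Named numeric vector of raw AUCs for one KE.
#' @return Scaled scores in \[0,1\].
#' @export
scale_scores <- function(raw) {
  m <- max(raw, 0)
  if (m > 0) raw / m else raw * 0
}

#' Score every chemical against every KE
#'
#' @param ke_map KE assignment table (see [read_ke_assignments()]),
#'   typically restricted to the selected assays.
#' @param surfaces Named list of `response_surface`.
#' @param chem_ids Chemicals to score.
#' @param grid The shared `conc_grid`.
#' @param mode Aggregation mode passed to [compose_ke_curves()].
#' @return data.frame `chem_id,ke_id,raw_auc,scaled_score`.
#' @export
ke_score_table <- function(ke_map, surfaces, chem_ids,
                           grid = build_grid(), mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  out <- lapply(split(ke_map$assay_id, ke_map$ke_id), function(aids) aids)
  res <- lapply(names(out), function(ke) {
    curves <- compose_ke_curves(out[[ke]], surfaces, chem_ids, grid, mode)
    raw <- apply(curves, 1, ke_score, grid = grid)
    data.frame(chem_id = chem_ids, ke_id = ke, raw_auc = unname(raw),
               scaled_score = unname(scale_scores(raw)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res[order(res$ke_id, res$chem_id), ]
}

#' Rank chemicals within a KE by scaled score
#'
#' Descending score; ties broken by chem_id ascending.
#'
#' @param scores Named numeric vector (names = chem_id) of scaled
#'   scores for one KE.
#' @return Character vector of chem_ids, most active first.
#' @export
rank_chemicals <- function(scores) {
  names(scores)[order(-scores, names(scores))]
}

#' ROC AUC of KE scores against hepatotoxicity labels
#'
#' Computed as the Mann-Whitney concordance probability: the fraction
#' of (toxic, nontoxic) pairs where the toxic chemical has the higher
#' score, counting ties as half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = hepatotoxic), same length.
#' @return AUC in \[0,1\].
#' @export
ke_roc_auc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC AUC undefined: need at least one positive and one negative")
  # rank-sum form of the Mann-Whitney U statistic, ties get midranks
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Per-KE ROC summary
#'
#' @param score_table Output of [ke_score_table()].
#' @param labels Label table (see [read_labels()]).
#' @return data.frame `ke_id,n_pos,n_neg,roc_auc` (NA when one class is
#'   absent).
#' @export
ke_roc_table <- function(score_table, labels) {
  res <- lapply(split(score_table, score_table$ke_id), function(st) {
    m <- merge(st, labels[, c("chem_id", "hepatotoxic")], by = "chem_id")
    m <- m[!is.na(m$hepatotoxic), ]
    n_pos <- sum(m$hepatotoxic == 1)
    n_neg <- sum(m$hepatotoxic == 0)
    auc <- if (n_pos > 0 && n_neg > 0)
      ke_roc_auc(m$scaled_score, m$hepatotoxic) else NA_real_
    data.frame(ke_id = st$ke_id[1], n_pos = n_pos, n_neg = n_neg,
               roc_auc = auc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
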
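#' @title Toxicokinetic overlay of KE curves
#' @description In vitro activity only matters in vivo up to the
#'   concentration the body actually reaches. The bioavailable
#'   ("realized") portion of a KE curve is its area restricted to
#'   concentrations at or below the chemical's 95th-percentile
#'   steady-state plasma concentration (Css), on the same normalized
#'   log10 scale as the full KE score.
#' @name tk_overlay
NULL

#' Realized (bioavailable) portion of a KE score
#'
#' Trapezoidal integral of the KE curve over concentrations <= Css,
#' in the log10 domain, normalized by the full 11-decade grid width,
#' with linear interpolation to the exact Css cut point. Css at or
#' above the grid maximum realizes the full score; Css at or below the
#' grid minimum realizes nothing.
#'
#' @param curve KE-curve vector on the shared grid.
#' @param css Steady-state plasma concentration in uM (> 0).
#' @param grid The `conc_grid`.
#' @return List with `raw_auc`, `realized_auc`, `realized_fraction`
#'   (realized/raw, 0 when raw = 0).
#' @export
realized_ke_score <- function(curve, css, grid) {
  if (!is.numeric(css) || length(css) != 1 || is.na(css) || css <= 0)
    stop("css must be a single concentration > 0")
  lg <- grid$log10_conc
  if (length(curve) != length(lg)) stop("curve length does not match grid")
  width <- lg[length(lg)] - lg[1]
  raw <- ke_score(curve, grid)
  cut <- log10(css)
  if (cut >= lg[length(lg)]) {
    realized <- raw
  } else if (cut <= lg[1]) {
    realized <- 0
  } else {
    i <- findInterval(cut, lg)            # lg[i] <= cut < lg[i+1]
    seg <- if (i > 1)
      sum(diff(lg[1:i]) * (curve[1:(i - 1)] + curve[2:i]) / 2) else 0
    # partial trapezoid up to the interpolated value at the cut
    f <- (cut - lg[i]) / (lg[i + 1] - lg[i])
    v_cut <- curve[i] + f * (curve[i + 1] - curve[i])
    seg <- seg + (cut - lg[i]) * (curve[i] + v_cut) / 2
    realized <- seg / width
  }
  list(raw_auc = raw, realized_auc = realized,
       realized_fraction = if (raw > 0) realized / raw else 0)
}

#' Realized-activity table for all chemicals and KEs
#'
#' @param ke_map KE assignment table.
#' @param surfaces Named list of `response_surface`.
#' @param css Css table (see [read_css()]); chemicals without a Css are
#'   omitted.
#' @param chem_ids Chemicals to evaluate (default: those with Css).
#' @param grid The shared `conc_grid`.
#' @param mode Aggregation mode (see [compose_ke_curves()]).
#' @return data.frame `chem_id,ke_id,css95,raw_auc,realized_auc,
#'   realized_fraction`.
#' @export
realized_activity_table <- function(ke_map, surfaces, css,
                                    chem_ids = css$chem_id,
                                    grid = build_grid(),
                                    mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  chem_ids <- intersect(chem_ids, css$chem_id)
  kes <- split(ke_map$assay_id, ke_map$ke_id)
  res <- lapply(names(kes), function(ke) {
    curves <- compose_ke_curves(kes[[ke]], surfaces, chem_ids, grid, mode)
    rows <- lapply(chem_ids, function(cid) {
      c95 <- css$css95[match(cid, css$chem_id)]
      r <- realized_ke_score(curves[cid, ], c95, grid)
      data.frame(chem_id = cid, ke_id = ke, css95 = c95,
                 raw_auc = r$raw_auc, realized_auc = r$realized_auc,
                 realized_fraction = r$realized_fraction,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Flag chemicals whose in vitro activity is toxicokinetically
#' unrealizable
#'
#' A chemical is flagged when, across every KE where it shows activity
#' (raw AUC > 0), the realized fraction stays below the threshold: its
#' concentration-response lies essentially above the plasma
#' concentration it can reach. Chemicals with zero activity everywhere
#' are never flagged (inert, not TK-limited).
#'
#' @param activities Output of [realized_activity_table()].
#' @param threshold Realized-fraction cutoff (default 0.05).
#' @return Character vector of flagged chem_ids (sorted).
#' @export
flag_unrealizable <- function(activities, threshold = 0.05) {
  act <- activities[activities$raw_auc > 0, , drop = FALSE]
  if (nrow(act) == 0) return(character(0))
  mx <- tapply(act$realized_fraction, act$chem_id, max)
  sort(names(mx)[mx < threshold])
}
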
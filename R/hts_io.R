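#' @title Tabular input/output for the hepatotoxicity pipeline
#' @description Readers and writers for the five tabular inputs: HTS
#'   curve-fit summaries, hepatotoxicity labels, assay-to-key-event
#'   assignments, steady-state plasma concentrations (Css), and SMILES.
#'   All concentrations are carried internally in uM; readers convert a
#'   declared unit suffix (`_uM`, `_nM`, `_mM`) once at the boundary.
#' @name hts_io
NULL

# unit suffix -> factor to uM
.unit_to_uM <- c(nM = 1e-3, uM = 1, mM = 1e3)

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

.require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("format error in ", path, ": missing required column(s): ",
         paste(missing, collapse = ", "))
}

# Find a concentration column `base` with a unit suffix; return the
# values converted to uM. E.g. base "ac50" matches ac50_uM / ac50_nM.
.conc_col_uM <- function(df, base, path) {
  pat <- paste0("^", base, "_(", paste(names(.unit_to_uM), collapse = "|"),
                ")$")
  hit <- grep(pat, names(df), value = TRUE)
  if (length(hit) != 1)
    stop("format error in ", path, ": missing required column: ",
         base, "_<unit> (uM/nM/mM)")
  unit <- sub(pat, "\\1", hit)
  suppressWarnings(as.numeric(df[[hit]])) * .unit_to_uM[[unit]]
}

.as_num <- function(x) suppressWarnings(as.numeric(x))
.as_binary <- function(x, what) {
  v <- .as_num(x)
  bad <- !is.na(v) & !(v %in% c(0, 1))
  if (any(bad)) stop(what, " must be 0/1; offending values: ",
                     paste(unique(x[bad]), collapse = ", "))
  v
}

#' Read an HTS curve-fit summary table
#'
#' One row per chemical x assay x fit. Rows whose parameter columns
#' (top, slope, ac50) fail to parse as numbers are loaded with the
#' parameters absent, which downstream means "no response" (flat
#' curve); a message reports how many rows were affected.
#'
#' @param path CSV with header
#'   `chem_id,assay_id,top,slope,ac50_uM,curve_error,hit_call`
#'   (the ac50 unit suffix may be `_nM`/`_uM`/`_mM`).
#' @return data.frame of class `curve_fits` with columns `chem_id`,
#'   `assay_id`, `top`, `slope`, `ac50` (uM), `curve_error`, `hit_call`.
#'   An empty file yields an empty table (not an error).
#' @export
read_curve_fits <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, c("chem_id", "assay_id", "top", "slope",
                      "curve_error", "hit_call"), path)
  out <- data.frame(
    chem_id = as.character(df$chem_id),
    assay_id = as.character(df$assay_id),
    top = .as_num(df$top),
    slope = .as_num(df$slope),
    ac50 = if (nrow(df)) .conc_col_uM(df, "ac50", path) else {
      .conc_col_uM(df, "ac50", path); numeric(0)
    },
    curve_error = .as_num(df$curve_error),
    hit_call = .as_binary(df$hit_call, "hit_call"),
    stringsAsFactors = FALSE
  )
  bad_ac50 <- !is.na(out$ac50) & out$ac50 <= 0
  if (any(bad_ac50)) {
    # nonpositive AC50 cannot parameterize a Hill curve: no response
    out$ac50[bad_ac50] <- NA_real_
  }
  noresp <- is.na(out$top) | is.na(out$slope) | is.na(out$ac50)
  # absent parameters are no-response, not an error
  out$top[noresp] <- NA_real_
  out$slope[noresp] <- NA_real_
  out$ac50[noresp] <- NA_real_
  if (any(noresp))
    message(sum(noresp), " fit row(s) with absent/unparseable parameters ",
            "loaded as no-response")
  class(out) <- c("curve_fits", class(out))
  out
}

#' Select the best-scoring fit within one chemical x assay group
#'
#' The fit with the lowest curve error wins. Ties are broken by the
#' smaller AC50 (absent AC50 sorts last), then by input row order, so
#' the resolution is deterministic and permutation-invariant up to the
#' documented tie-break.
#'
#' @param fits data.frame of fits sharing one `chem_id` and `assay_id`.
#' @return The selected single-row data.frame.
#' @export
select_best_fit <- function(fits) {
  if (is.null(fits) || nrow(fits) == 0)
    stop("select_best_fit: empty fit group")
  if (length(unique(fits$chem_id)) > 1 || length(unique(fits$assay_id)) > 1)
    stop("select_best_fit: group spans multiple chem/assay ids")
  err <- fits$curve_error
  err[is.na(err)] <- Inf
  ac <- fits$ac50
  ac[is.na(ac)] <- Inf
  i <- order(err, ac, seq_len(nrow(fits)))[1]
  fits[i, , drop = FALSE]
}

#' Resolve every chemical x assay group to its best fit
#'
#' @param fits A `curve_fits` table (possibly several fits per pair).
#' @return A `curve_fits` table with one row per chemical x assay.
#' @export
select_best_fits <- function(fits) {
  key <- paste(fits$chem_id, fits$assay_id, sep = "\r")
  err <- fits$curve_error
  err[is.na(err)] <- Inf
  ac <- fits$ac50
  ac[is.na(ac)] <- Inf
  # stable sort by (key, error, ac50, input order), keep first per key
  ord <- order(key, err, ac, seq_len(nrow(fits)))
  keep <- ord[!duplicated(key[ord])]
  out <- fits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read the hepatotoxicity label table
#'
#' @param path CSV with header
#'   `chem_id,hepatotoxic,hepatocellular,hepatobiliary`; the two
#'   mechanism columns may be blank (unknown).
#' @return data.frame with one row per chemical. A mechanism label of 1
#'   with `hepatotoxic = 0` is a consistency error; duplicated chem_ids
#'   are an error.
#' @export
read_labels <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, c("chem_id", "hepatotoxic"), path)
  if (!"hepatocellular" %in% names(df)) df$hepatocellular <- NA
  if (!"hepatobiliary" %in% names(df)) df$hepatobiliary <- NA
  out <- data.frame(
    chem_id = as.character(df$chem_id),
    hepatotoxic = .as_binary(df$hepatotoxic, "hepatotoxic"),
    hepatocellular = .as_binary(df$hepatocellular, "hepatocellular"),
    hepatobiliary = .as_binary(df$hepatobiliary, "hepatobiliary"),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(out$chem_id)
  if (any(dup))
    stop("duplicate chem_id in label table: ",
         paste(unique(out$chem_id[dup]), collapse = ", "))
  mech <- (out$hepatocellular %in% 1) | (out$hepatobiliary %in% 1)
  bad <- mech & !is.na(out$hepatotoxic) & out$hepatotoxic == 0
  if (any(bad))
    stop("label consistency error (mechanism label without hepatotoxic=1): ",
         paste(out$chem_id[bad], collapse = ", "))
  out
}

#' Read the assay-to-key-event assignment table
#'
#' Each assay maps to exactly one key event (KE); an assay listed twice
#' with conflicting KE ids is a format error (exact duplicate rows are
#' collapsed).
#'
#' @param path CSV with header `assay_id,ke_id,ke_name`.
#' @return data.frame `assay_id`, `ke_id`, `ke_name`, one row per assay.
#' @export
read_ke_assignments <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, c("assay_id", "ke_id"), path)
  if (!"ke_name" %in% names(df)) df$ke_name <- ""
  out <- unique(data.frame(
    assay_id = as.character(df$assay_id),
    ke_id = as.character(df$ke_id),
    ke_name = as.character(df$ke_name),
    stringsAsFactors = FALSE
  ))
  dup <- duplicated(out$assay_id)
  if (any(dup))
    stop("format error: assay_id mapped to conflicting ke_id: ",
         paste(unique(out$assay_id[dup]), collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Read the steady-state plasma concentration (Css) table
#'
#' Css is the 95th-percentile steady-state plasma concentration at a
#' 1 mg/kg/day oral dose, produced by external toxicokinetic software
#' and consumed here as data.
#'
#' @param path CSV with header `chem_id,css95_uM` (unit suffix may be
#'   `_nM`/`_mM`).
#' @return data.frame `chem_id`, `css95` (uM, all > 0). Rows with
#'   nonpositive or unparseable Css are rejected with an error naming
#'   the chemicals.
#' @export
read_css <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, "chem_id", path)
  css <- if (nrow(df)) .conc_col_uM(df, "css95", path) else {
    .conc_col_uM(df, "css95", path); numeric(0)
  }
  out <- data.frame(chem_id = as.character(df$chem_id), css95 = css,
                    stringsAsFactors = FALSE)
  bad <- is.na(out$css95) | out$css95 <= 0
  if (any(bad))
    stop("invalid css95 (must be > 0) for chem_id: ",
         paste(out$chem_id[bad], collapse = ", "))
  dup <- duplicated(out$chem_id)
  if (any(dup))
    stop("duplicate chem_id in Css table: ",
         paste(unique(out$chem_id[dup]), collapse = ", "))
  out
}

#' Read a SMILES table
#'
#' @param path CSV with header `chem_id,smiles`.
#' @return data.frame `chem_id`, `smiles`.
#' @export
read_smiles <- function(path) {
  df <- .read_csv(path)
  .require_cols(df, c("chem_id", "smiles"), path)
  out <- data.frame(chem_id = as.character(df$chem_id),
                    smiles = as.character(df$smiles),
                    stringsAsFactors = FALSE)
  dup <- duplicated(out$chem_id)
  if (any(dup))
    stop("duplicate chem_id in SMILES table: ",
         paste(unique(out$chem_id[dup]), collapse = ", "))
  out
}

#' Write a pipeline table back to CSV
#'
#' Writes RFC-4180 CSV with the same column conventions the readers
#' expect, so read and write round-trip field for field. Concentration
#' columns are written with their uM suffix.
#'
#' @param x Table to write (curve fits, labels, KE map, Css, SMILES, or
#'   any result data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  x <- as.data.frame(x)
  nm <- names(x)
  nm[nm == "ac50"] <- "ac50_uM"
  nm[nm == "css95"] <- "css95_uM"
  names(x) <- nm
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
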
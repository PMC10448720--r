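#' Dataset composition summary of a hepatotoxicity label table
#'
#' Counts and percentages describing how a screened chemical library
#' overlaps a reference hepatotoxicity database and how the
#' hepatotoxicants split by mechanism: library coverage, hepatotoxicant
#' prevalence, and the hepatocellular / hepatobiliary / both-mechanism
#' fractions among hepatotoxicants.
#'
#' @param labels Label table (see [read_labels()]) for the chemicals
#'   found in the screening library.
#' @param database_size Total number of chemicals in the reference
#'   hepatotoxicity database (default: `nrow(labels)`, i.e. full
#'   coverage).
#' @return data.frame `quantity,numerator,denominator,percent` with
#'   rows `in_library`, `hepatotoxic`, `hepatocellular`,
#'   `hepatobiliary`, `both_mechanisms`.
#' @export
label_composition <- function(labels, database_size = nrow(labels)) {
  n_lib <- nrow(labels)
  n_tox <- sum(labels$hepatotoxic == 1, na.rm = TRUE)
  n_cell <- sum(labels$hepatotoxic == 1 & labels$hepatocellular == 1,
                na.rm = TRUE)
  n_bil <- sum(labels$hepatotoxic == 1 & labels$hepatobiliary == 1,
               na.rm = TRUE)
  n_both <- sum(labels$hepatotoxic == 1 & labels$hepatocellular == 1 &
                  labels$hepatobiliary == 1, na.rm = TRUE)
  num <- c(n_lib, n_tox, n_cell, n_bil, n_both)
  den <- c(database_size, n_lib, n_tox, n_tox, n_tox)
  data.frame(
    quantity = c("in_library", "hepatotoxic", "hepatocellular",
                 "hepatobiliary", "both_mechanisms"),
    numerator = num, denominator = den,
    percent = 100 * num / den, stringsAsFactors = FALSE)
}

#' Key-event multiplicity summary
#'
#' How many assays each KE groups, and what fraction of KEs contain
#' more than one assay.
#'
#' @param ke_map KE assignment table (see [read_ke_assignments()]).
#' @return List with `n_assays`, `n_kes`, `assays_per_ke` (named
#'   integer vector), `n_multi` (KEs with >1 assay), and
#'   `percent_multi`.
#' @export
ke_multiplicity <- function(ke_map) {
  sizes <- table(ke_map$ke_id)
  list(n_assays = nrow(ke_map),
       n_kes = length(sizes),
       assays_per_ke = stats::setNames(as.integer(sizes), names(sizes)),
       n_multi = sum(sizes > 1),
       percent_multi = 100 * sum(sizes > 1) / length(sizes))
}
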
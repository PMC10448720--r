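#' Benchmark composition of the reference hepatotoxicity database
#'
#' The screening-library overlap and mechanism split reported for the
#' 2171-chemical human hepatotoxicity reference database: 1762
#' chemicals found in the HTS library; 1200 of those hepatotoxic; among
#' the hepatotoxicants 969 hepatocellular, 726 hepatobiliary, 682 both.
#' Used as a benchmark input for composition summaries; the chemical
#' identities are synthetic placeholders.
#'
#' @return List with `database_size` and a label table (as from
#'   [read_labels()]) realizing the counts exactly.
#' @export
reference_label_table <- function() {
  n_lib <- 1762L; n_tox <- 1200L
  n_both <- 682L; n_cell <- 969L; n_bil <- 726L
  cell_only <- n_cell - n_both            # 287
  bil_only <- n_bil - n_both              # 44
  neither <- n_tox - cell_only - bil_only - n_both  # 187
  mech <- c(rep("both", n_both), rep("cell", cell_only),
            rep("bil", bil_only), rep("none", neither))
  labels <- data.frame(
    chem_id = sprintf("REF%04d", seq_len(n_lib)),
    hepatotoxic = rep(c(1L, 0L), c(n_tox, n_lib - n_tox)),
    hepatocellular = c(as.integer(mech %in% c("both", "cell")),
                       rep(0L, n_lib - n_tox)),
    hepatobiliary = c(as.integer(mech %in% c("both", "bil")),
                      rep(0L, n_lib - n_tox)),
    stringsAsFactors = FALSE)
  list(database_size = 2171L, labels = labels)
}

#' Benchmark assay-to-KE assignment realizing the reported multiplicity
#'
#' A KE map with 157 assays over 52 key events, 22 of which group more
#' than one assay and the largest of which groups 59 (the reported
#' distribution extremes); assay identities are synthetic placeholders.
#'
#' @return KE assignment table (as from [read_ke_assignments()]).
#' @export
reference_ke_map <- function() {
  sizes <- c(59L, 28L, rep(2L, 20L), rep(1L, 30L))  # sums to 157
  ke_ids <- sprintf("KE%02d", seq_along(sizes))
  data.frame(assay_id = sprintf("REFASSAY%03d", seq_len(sum(sizes))),
             ke_id = rep(ke_ids, sizes),
             ke_name = rep(paste("key event", ke_ids), sizes),
             stringsAsFactors = FALSE)
}
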
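#' @title Chemical structure handling
#' @description Morgan (circular, ECFP4-equivalent) fingerprints,
#'   Tanimoto similarity, Butina sphere-exclusion clustering at a 70%
#'   similarity cutoff, hepatotoxicant-enriched cluster detection, and
#'   Lipinski-type descriptors. SMILES parsing, canonicalization,
#'   fingerprinting and descriptor calculation are delegated to the
#'   RDKit toolkit through a bundled Python helper; similarity,
#'   clustering and enrichment logic are implemented here.
#' @name chem
NULL

# Invoke the RDKit helper on a chem_id/smiles table; returns the parsed
# JSON records. Fingerprint bits come back 1-based.
.chem_backend <- function(smiles_df, radius = 2L, n_bits = 2048L) {
  script <- system.file("python", "chem_backend.py", package = "ketox")
  if (script == "") stop("chem_backend.py not found in installed package")
  if (Sys.which("python") == "")
    stop("structure handling requires 'python' with RDKit on the PATH")
  tsv <- tempfile(fileext = ".tsv")
  on.exit(unlink(tsv))
  writeLines(paste(smiles_df$chem_id, smiles_df$smiles, sep = "\t"), tsv)
  out <- suppressWarnings(
    system2("python", c(shQuote(script), shQuote(tsv), radius, n_bits),
            stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("RDKit backend failed (exit ", status, ")")
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

#' Morgan fingerprints for a set of SMILES
#'
#' Structures are canonicalized first, so identical molecules written
#' as different SMILES yield identical fingerprints.
#'
#' @param smiles_df data.frame `chem_id`, `smiles` (see
#'   [read_smiles()]).
#' @param radius Circular-substructure radius (default 2, ECFP4).
#' @param n_bits Folded fingerprint length (default 2048).
#' @return A `fingerprint_set`: named list of sorted 1-based on-bit
#'   integer vectors, with attributes `n_bits` and `canonical` (named
#'   character vector of canonical SMILES).
#' @export
morgan_fingerprints <- function(smiles_df, radius = 2L, n_bits = 2048L) {
  recs <- .chem_backend(smiles_df, radius, n_bits)
  bad <- vapply(recs, function(r) !isTRUE(r$ok), logical(1))
  if (any(bad))
    stop("unparseable SMILES for chem_id: ",
         paste(vapply(recs[bad], `[[`, "", "chem_id"), collapse = ", "))
  fps <- lapply(recs, function(r) as.integer(unlist(r$bits)))
  names(fps) <- vapply(recs, `[[`, "", "chem_id")
  attr(fps, "n_bits") <- as.integer(n_bits)
  attr(fps, "canonical") <-
    stats::setNames(vapply(recs, `[[`, "", "canonical"), names(fps))
  class(fps) <- "fingerprint_set"
  fps
}

#' Lipinski-type descriptors from SMILES
#'
#' Molecular weight, logP (Crippen estimate), hydrogen-bond donors and
#' acceptors, rotatable bonds, ring count, and heavy-atom count --
#' the oral-bioavailability descriptors used as bioavailability
#' features in Model 2.
#'
#' @param smiles_df data.frame `chem_id`, `smiles`.
#' @return data.frame, one row per chemical: `chem_id,mw,logp,hbd,hba,
#'   rotatable_bonds,rings,heavy_atoms`.
#' @export
lipinski_descriptors <- function(smiles_df) {
  recs <- .chem_backend(smiles_df)
  bad <- vapply(recs, function(r) !isTRUE(r$ok), logical(1))
  if (any(bad))
    stop("unparseable SMILES for chem_id: ",
         paste(vapply(recs[bad], `[[`, "", "chem_id"), collapse = ", "))
  do.call(rbind, lapply(recs, function(r) data.frame(
    chem_id = r$chem_id, mw = r$mw, logp = r$logp, hbd = r$hbd,
    hba = r$hba, rotatable_bonds = r$rotatable_bonds, rings = r$rings,
    heavy_atoms = r$heavy_atoms, stringsAsFactors = FALSE)))
}

#' Tanimoto similarity of two fingerprints
#'
#' Intersection over union of on-bits. Two empty fingerprints are
#' defined as identical (similarity 1).
#'
#' @param a,b Integer vectors of on-bit positions.
#' @return Similarity in \[0,1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(1)
  i <- length(intersect(a, b))
  i / (length(a) + length(b) - i)
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fps A `fingerprint_set` or plain named list of on-bit vectors.
#' @return Symmetric matrix with unit diagonal.
#' @export
tanimoto_matrix <- function(fps) {
  n <- length(fps)
  sim <- diag(1, n)
  dimnames(sim) <- list(names(fps), names(fps))
  if (n < 2) return(sim)
  sizes <- lengths(fps)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- length(intersect(fps[[i]], fps[[j]]))
      u <- sizes[i] + sizes[j] - both
      sim[i, j] <- sim[j, i] <-
        if (u == 0) 1 else both / u
    }
  }
  sim
}

#' Butina sphere-exclusion clustering
#'
#' Neighbors are molecules with similarity >= the cutoff. Iteratively,
#' the unassigned molecule with the most unassigned neighbors becomes a
#' cluster centroid (ties broken by lexicographically smallest
#' chem_id); the centroid and its unassigned neighbors form the
#' cluster; repeat until everything is assigned. Singletons are
#' allowed. Deterministic and invariant to input order.
#'
#' @param fps A `fingerprint_set` or named list of on-bit vectors.
#' @param similarity_cutoff Tanimoto cutoff (default 0.70, i.e. >= 70%
#'   similarity).
#' @return data.frame `cluster_id,chem_id,centroid` -- a partition of
#'   the input; every member has similarity >= cutoff to its centroid.
#' @export
butina_cluster <- function(fps, similarity_cutoff = 0.70) {
  if (length(fps) == 0) stop("need at least one fingerprint")
  ids <- names(fps)
  sim <- tanimoto_matrix(fps)
  nbr <- sim >= similarity_cutoff
  diag(nbr) <- FALSE
  unassigned <- rep(TRUE, length(ids))
  rows <- list()
  k <- 0L
  while (any(unassigned)) {
    counts <- colSums(nbr[unassigned, , drop = FALSE]) # unassigned nbrs
    counts[!unassigned] <- -1
    cand <- which(counts == max(counts))
    centroid <- cand[order(ids[cand])][1]
    members <- c(centroid, which(nbr[centroid, ] & unassigned))
    unassigned[members] <- FALSE
    k <- k + 1L
    rows[[k]] <- data.frame(cluster_id = k, chem_id = ids[members],
                            centroid = ids[centroid],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hepatotoxicant-enriched clusters and their KE-score signatures
#'
#' A cluster is enriched when strictly more than 2/3 of its members
#' that carry liver data are hepatotoxicants. Clusters with no labeled
#' member have an undefined fraction (NA) and are never enriched. When
#' a KE score table is supplied, the per-cluster mean scaled score of
#' each KE (zeros included for inactive members) is attached.
#'
#' @param assignments Output of [butina_cluster()].
#' @param labels Label table (see [read_labels()]).
#' @param score_table Optional output of [ke_score_table()].
#' @param enrich_fraction Strict enrichment threshold (default 2/3).
#' @return List with `clusters` (data.frame `cluster_id,centroid,size,
#'   n_with_liver_data,hepatotoxicant_fraction,enriched`) and, when
#'   scores are given, `mean_scores` (matrix cluster x KE).
#' @export
enriched_clusters <- function(assignments, labels, score_table = NULL,
                              enrich_fraction = 2 / 3) {
  per <- lapply(split(assignments, assignments$cluster_id), function(cl) {
    lab <- labels$hepatotoxic[match(cl$chem_id, labels$chem_id)]
    n_lab <- sum(!is.na(lab))
    frac <- if (n_lab > 0) sum(lab == 1, na.rm = TRUE) / n_lab else NA_real_
    data.frame(cluster_id = cl$cluster_id[1], centroid = cl$centroid[1],
               size = nrow(cl), n_with_liver_data = n_lab,
               hepatotoxicant_fraction = frac,
               enriched = !is.na(frac) && frac > enrich_fraction,
               stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, per)
  rownames(clusters) <- NULL
  out <- list(clusters = clusters)
  if (!is.null(score_table)) {
    kes <- sort(unique(score_table$ke_id))
    cl_list <- split(assignments, assignments$cluster_id)
    ms <- matrix(0, length(cl_list), length(kes),
                 dimnames = list(names(cl_list), kes))
    for (ci in seq_along(cl_list)) {
      cl <- cl_list[[ci]]
      for (ke in kes) {
        s <- score_table$scaled_score[score_table$ke_id == ke &
               score_table$chem_id %in% cl$chem_id]
        s <- c(s, rep(0, nrow(cl) - length(s)))  # unscored members = 0
        ms[ci, ke] <- mean(s)
      }
    }
    out$mean_scores <- ms
  }
  out
}
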
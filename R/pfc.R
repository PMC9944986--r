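#' Proteoform clusters (PfCs)
#'
#' After alignment and recalibration, PrSMs that agree in accession,
#' precursor mass and retention time are treated as repeated observations
#' of one proteoform.  Single-linkage clustering (within accession; two
#' PrSMs link when their masses agree within a ppm tolerance of the
#' smaller mass and their RTs within an RT tolerance) yields "proteoform
#' clusters".  Clusters below a minimum size are pooled into a noise
#' cluster (id suffix `"_0"`) and excluded from quantitation.  Each
#' cluster is represented by the proteoform string backed by the most
#' PrSMs (ties to the lowest E-value).
#'
#' @name pfc
NULL

# Single-linkage connected components under an arbitrary pairwise link
# predicate, via union-find.  O(n^2) in the per-accession stratum size,
# which is small in practice.
single_linkage_components <- function(n, link) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (link(i, j)) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Cluster PrSMs into proteoform clusters
#'
#' PrSMs are partitioned by accession and single-linkage clustered: two
#' PrSMs link iff their mass difference is within `mass_tol_ppm` (of the
#' smaller mass) and their RT difference within `rt_tol_min`.  Clusters
#' with fewer than `min_size` members are pooled into the noise cluster,
#' whose id carries the reserved `"_0"` suffix.
#'
#' @param prsms Aligned, recalibrated PrSM tibble.
#' @param mass_tol_ppm Mass linkage tolerance (ppm, inclusive).
#' @param rt_tol_min RT linkage tolerance (minutes, inclusive).
#' @param min_size Minimum PrSMs per retained cluster.
#' @param mass_col Mass used for clustering: the experimental
#'   `"precursor_mass"` (default) or the engine's `"adjusted_mass"`, which
#'   trades deisotoping-error redundancy for reporting variance.
#' @return `prsms` with columns `pfc_id` and `is_noise` added.  Every PrSM
#'   belongs to exactly one cluster (possibly noise).
#' @export
cluster_prsms <- function(prsms, mass_tol_ppm = 15, rt_tol_min = 4,
                          min_size = 3, mass_col = "precursor_mass") {
  n <- nrow(prsms)
  prsms$pfc_id <- character(n)
  prsms$is_noise <- logical(n)
  if (n == 0) return(prsms)
  mass <- prsms[[mass_col]]
  # fall back to the experimental mass where the engine reports none
  if (mass_col != "precursor_mass") {
    mass[is.na(mass)] <- prsms$precursor_mass[is.na(mass)]
  }
  rt <- prsms$rt_min
  counter <- 0L
  for (acc in unique(prsms$accession)) {
    idx <- which(prsms$accession == acc)
    m <- mass[idx]; r <- rt[idx]
    comp <- single_linkage_components(length(idx), function(i, j) {
      ppm_between(m[i], m[j]) <= mass_tol_ppm && abs(r[i] - r[j]) <= rt_tol_min
    })
    for (k in sort(unique(comp))) {
      members <- idx[comp == k]
      if (length(members) < min_size) {
        prsms$pfc_id[members] <- "pfc_0"
        prsms$is_noise[members] <- TRUE
      } else {
        counter <- counter + 1L
        prsms$pfc_id[members] <- paste0("pfc_", counter)
      }
    }
  }
  prsms
}

#' Select the representative PrSM of one cluster
#'
#' Among the distinct proteoform strings in the cluster, the one backed by
#' the most PrSMs represents the cluster; ties break to the proteoform
#' whose best E-value is lowest.  The representative record is that
#' proteoform's lowest-E-value PrSM.
#'
#' @param members PrSM tibble holding the members of one cluster.
#' @return A single-row tibble (the representative PrSM).
#' @export
select_representative <- function(members) {
  stopifnot(nrow(members) >= 1)
  stats_tbl <- members |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$proteoform) |>
    dplyr::summarise(n = dplyr::n(), best_e = min(.data$evalue),
                     best_row = .data$.row[which.min(.data$evalue)],
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$best_e)
  members[stats_tbl$best_row[1], ]
}

#' Summarize clusters with their representatives
#'
#' @param prsms Output of [cluster_prsms()].
#' @return One row per cluster (noise included): `pfc_id`, `accession`,
#'   `is_noise`, `n_members`, and the representative's fields prefixed
#'   as-is (`proteoform`, `precursor_mass`, `rt_min`, `evalue`, ...).
#'   The representative of the noise cluster is its lowest-E-value PrSM.
#' @export
summarize_pfcs <- function(prsms) {
  stopifnot("pfc_id" %in% names(prsms))
  ids <- unique(prsms$pfc_id)
  rows <- lapply(ids, function(id) {
    members <- prsms[prsms$pfc_id == id, ]
    rep <- select_representative(members)
    rep$pfc_id <- id
    rep$n_members <- nrow(members)
    rep
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$is_noise, .data$pfc_id)
}

#' Filter PrSMs at the protein-level FDR
#'
#' Retains records of proteins whose protein-level q-value is at or below
#' the threshold.  When the table only carries PrSM/proteoform-level
#' q-values, the protein-level q-value is approximated as the minimum
#' q-value over the protein's records (each protein's best-supported
#' identification decides the protein).
#'
#' @param prsms PrSM tibble with a `qvalue` column.
#' @param threshold Global FDR threshold (default 0.01, i.e. <1% FDR).
#' @param strict Error when no q-values are present (otherwise the table
#'   passes through unfiltered with a warning).
#' @return The filtered tibble; the number of removed rows is reported.
#' @export
filter_protein_fdr <- function(prsms, threshold = 0.01, strict = TRUE) {
  if (all(is.na(prsms$qvalue))) {
    if (strict) format_error("no q-value column available for FDR filtering")
    warning("no q-values present; protein-level FDR filter skipped")
    return(prsms)
  }
  protein_q <- prsms |>
    dplyr::group_by(.data$accession) |>
    dplyr::summarise(protein_q = suppressWarnings(min(.data$qvalue, na.rm = TRUE)),
                     .groups = "drop")
  keep_acc <- protein_q$accession[protein_q$protein_q <= threshold]
  out <- prsms[prsms$accession %in% keep_acc & !is.na(prsms$qvalue) &
                 prsms$qvalue <= threshold, ]
  message("protein-level FDR <= ", threshold, ": kept ", nrow(out), " of ",
          nrow(prsms), " records")
  out
}

#' Five-level ambiguity classification of proteoform identifications
#'
#' Grades each representative identification across four ambiguity
#' attributes of the consortium classification scheme: PTM localization
#' (A), PTM identity (B), amino-acid sequence (C; always unambiguous
#' here, as the engines report a definite backbone), and gene of origin
#' (D).  An unknown (bare) mass shift leaves both the PTM identity and
#' its localization undetermined, so it sets A and B together; a named
#' PTM without a confident single-residue site sets A alone.  No flag is
#' level "1"; exactly one flag is the matching "2A".."2D"; k >= 2 flags
#' give level `as.character(1 + k)` (up to "5").
#'
#' @param representatives Representative PrSM tibble (e.g. from
#'   [summarize_pfcs()]), with the `modifications` list-column.
#' @param gene_map Optional accession-to-gene tibble with columns
#'   `accession` and `gene`; an accession mapping to more than one gene is
#'   gene-ambiguous.  Without a map the gene flag stays `FALSE`.
#' @return `representatives` with logical columns `ptm_localization_ambiguous`,
#'   `ptm_identity_ambiguous`, `sequence_ambiguous`, `gene_ambiguous` and
#'   the character column `level`.
#' @export
classify_level <- function(representatives, gene_map = NULL) {
  mods <- representatives$modifications
  unknown <- has_unknown_mass_shift(mods)
  unlocalized_named <- vapply(mods, function(m) {
    any(!is.na(m$name) & !m$localized)
  }, logical(1))
  loc_amb <- unknown | unlocalized_named
  id_amb <- unknown
  seq_amb <- rep(FALSE, nrow(representatives))
  if (!is.null(gene_map)) {
    n_genes <- gene_map |>
      dplyr::distinct(.data$accession, .data$gene) |>
      dplyr::count(.data$accession)
    gene_amb <- representatives$accession %in%
      n_genes$accession[n_genes$n > 1]
  } else {
    gene_amb <- rep(FALSE, nrow(representatives))
    message("no accession-to-gene map supplied; gene ambiguity not assessed")
  }
  flags <- cbind(A = loc_amb, B = id_amb, C = seq_amb, D = gene_amb)
  k <- rowSums(flags)
  level <- character(nrow(flags))
  level[k == 0] <- "1"
  single <- which(k == 1)
  level[single] <- paste0("2", colnames(flags)[apply(flags[single, , drop = FALSE], 1, which)])
  level[k >= 2] <- as.character(1 + k[k >= 2])
  representatives$ptm_localization_ambiguous <- loc_amb
  representatives$ptm_identity_ambiguous <- id_amb
  representatives$sequence_ambiguous <- seq_amb
  representatives$gene_ambiguous <- gene_amb
  representatives$level <- level
  representatives
}
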
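#' Cross-run feature alignment, feature grouping, and ID attachment
#'
#' Quantitation is carried by deconvoluted MS1 intact-mass features.  Per
#' FAIMS CV, features are aligned across runs (match-between-runs style:
#' the run with the most features seeds a master list, remaining runs are
#' greedily matched within mass/RT tolerances, unmatched features append
#' new rows; a sample missing a feature stays NA).  All CVs are then
#' concatenated and features are grouped by chained mass and RT
#' tolerances into "feature groups", the unit of quantitation.  Collapsed
#' identifications from both search engines are matched to feature groups
#' by accurate mass (allowing +/- 1 and 2 isotope-spacing shifts for
#' deisotoping errors) and RT, and conflicts are resolved by explicit
#' priority rules.
#'
#' @name grouping
NULL

#' Align MS1 features across runs within each CV
#'
#' A minimal match-between-runs aligner standing in for an external
#' alignment tool: per CV the run with the most features provides the
#' master list; every other run's features are matched to master rows by
#' best ppm error subject to `mass_tol_ppm` and `rt_tol_min`, each feature
#' and each master row used at most once; unmatched features are appended
#' as new master rows.  Missing run/row combinations are NA.
#'
#' @param features MS1-feature tibble across runs (RTs already warped to
#'   the reference timeline, masses recalibrated).
#' @param mass_tol_ppm Mass tolerance in ppm (inclusive).
#' @param rt_tol_min RT tolerance in minutes (inclusive).
#' @return A tibble with one row per aligned feature, columns `cv`,
#'   `mono_mass`, `rt_apex` (master values) and one abundance column per
#'   sample named `ab_<run_id>`.
#' @export
align_features_across_runs <- function(features, mass_tol_ppm = 15,
                                       rt_tol_min = 4) {
  samples <- sort(unique(features$run_id))
  cvs <- sort(unique(features$cv), na.last = TRUE)
  out <- list()
  for (s in cvs) {
    in_cv <- if (is.na(s)) is.na(features$cv) else !is.na(features$cv) & features$cv == s
    fcv <- features[in_cv, ]
    counts <- table(fcv$run_id)
    ids <- sort(names(counts))
    master_run <- ids[which.max(counts[ids])]
    mf <- fcv[fcv$run_id == master_run, ]
    master <- tibble::tibble(cv = mf$cv, mono_mass = mf$mono_mass,
                             rt_apex = mf$rt_apex)
    ab <- matrix(NA_real_, nrow = nrow(mf), ncol = length(samples),
                 dimnames = list(NULL, samples))
    ab[, master_run] <- mf$abundance
    for (run in setdiff(ids, master_run)) {
      tf <- fcv[fcv$run_id == run, ]
      # candidate pairs within tolerance, best |ppm| first, greedy unique
      cand <- expand.grid(i = seq_len(nrow(master)), j = seq_len(nrow(tf)))
      dppm <- abs(ppm_error(tf$mono_mass[cand$j], master$mono_mass[cand$i]))
      drt <- abs(tf$rt_apex[cand$j] - master$rt_apex[cand$i])
      keep <- dppm <= mass_tol_ppm & drt <= rt_tol_min
      cand <- cand[keep, , drop = FALSE]
      cand <- cand[order(dppm[keep]), , drop = FALSE]
      used_i <- logical(nrow(master)); used_j <- logical(nrow(tf))
      for (r in seq_len(nrow(cand))) {
        i <- cand$i[r]; j <- cand$j[r]
        if (!used_i[i] && !used_j[j]) {
          ab[i, run] <- tf$abundance[j]
          used_i[i] <- TRUE; used_j[j] <- TRUE
        }
      }
      if (any(!used_j)) {
        extra <- which(!used_j)
        master <- dplyr::bind_rows(master, tibble::tibble(
          cv = tf$cv[extra], mono_mass = tf$mono_mass[extra],
          rt_apex = tf$rt_apex[extra]))
        ab_extra <- matrix(NA_real_, nrow = length(extra), ncol = length(samples),
                           dimnames = list(NULL, samples))
        ab_extra[, run] <- tf$abundance[extra]
        ab <- rbind(ab, ab_extra)
      }
    }
    colnames(ab) <- paste0("ab_", colnames(ab))
    out[[length(out) + 1]] <- dplyr::bind_cols(master, tibble::as_tibble(ab))
  }
  dplyr::bind_rows(out)
}

#' Chained mass grouping of a sorted mass list
#'
#' Walking the masses in ascending order, a mass joins the current group
#' iff its gap to the immediately preceding mass is at most `tol_da` Da
#' AND at most `tol_ppm` ppm (of the preceding mass); otherwise it starts
#' a new group.  Equivalent to single-linkage on a line.
#'
#' @param masses Numeric vector, sorted ascending.
#' @param tol_da Absolute gap tolerance in Da (inclusive).
#' @param tol_ppm Relative gap tolerance in ppm (inclusive).
#' @return Integer group index per mass (1-based, increasing).
#' @export
assign_mass_groups <- function(masses, tol_da = 1.0, tol_ppm = 15) {
  n <- length(masses)
  if (n == 0) return(integer(0))
  if (is.unsorted(masses)) stop("masses must be sorted ascending")
  gaps <- diff(masses)
  new_group <- gaps > tol_da | gaps > tol_ppm * 1e-6 * masses[-n]
  cumsum(c(1L, as.integer(new_group)))
}

#' Chained RT grouping of a sorted RT list
#'
#' As [assign_mass_groups()] but on retention times with a single absolute
#' gap tolerance.
#'
#' @param rts Numeric vector of retention times (minutes), sorted
#'   ascending.
#' @param tol_min Gap tolerance in minutes (inclusive).
#' @return Integer group index per RT.
#' @export
assign_rt_groups <- function(rts, tol_min = 4) {
  n <- length(rts)
  if (n == 0) return(integer(0))
  if (is.unsorted(rts)) stop("rts must be sorted ascending")
  cumsum(c(1L, as.integer(diff(rts) > tol_min)))
}

#' Build feature groups from aligned features of all CVs
#'
#' Aligned features (all CVs concatenated) are sorted low-to-high by mass
#' and mass-grouped by the chained 1 Da / 15 ppm rule; within each mass
#' group they are sorted by RT and RT-grouped by the chained 4 min rule.
#' Each (mass group, RT group) cell is one feature group, summarized by
#' member count, the maximum (consensus) monoisotopic mass, the mean RT,
#' and per-sample median intensity over its member features.
#'
#' @param aligned Output of [align_features_across_runs()].
#' @param mass_tol_da,mass_tol_ppm Chained mass-grouping tolerances.
#' @param rt_tol_min Chained RT-grouping tolerance.
#' @return A list with `groups` (one row per feature group: `group_id`,
#'   `mass_group`, `rt_group`, `n_features`, `consensus_mass`, `mean_rt`
#'   and the `ab_*` sample medians) and `members` (the input rows with
#'   `mass_group`, `rt_group`, `group_id` attached).
#' @export
build_feature_groups <- function(aligned, mass_tol_da = 1.0,
                                 mass_tol_ppm = 15, rt_tol_min = 4) {
  ab_cols <- grep("^ab_", names(aligned), value = TRUE)
  aligned <- dplyr::arrange(aligned, .data$mono_mass)
  aligned$mass_group <- assign_mass_groups(aligned$mono_mass,
                                           tol_da = mass_tol_da,
                                           tol_ppm = mass_tol_ppm)
  aligned <- aligned |>
    dplyr::group_by(.data$mass_group) |>
    dplyr::arrange(.data$rt_apex, .by_group = TRUE) |>
    dplyr::mutate(rt_group = assign_rt_groups(.data$rt_apex,
                                              tol_min = rt_tol_min)) |>
    dplyr::ungroup() |>
    dplyr::mutate(group_id = paste0("fg_", .data$mass_group, "_", .data$rt_group))
  groups <- aligned |>
    dplyr::group_by(.data$group_id, .data$mass_group, .data$rt_group) |>
    dplyr::summarise(
      n_features = sum(!is.na(dplyr::pick(dplyr::all_of(ab_cols)))),
      consensus_mass = max(.data$mono_mass),
      mean_rt = mean(.data$rt_apex),
      dplyr::across(dplyr::all_of(ab_cols),
                    ~ if (all(is.na(.x))) NA_real_ else stats::median(.x, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mass_group, .data$rt_group)
  list(groups = groups, members = aligned)
}

#' Collapse redundant identifications per engine
#'
#' TopPIC-style identifications are collapsed by proteoform cluster (one
#' entry per PfC, noise included, represented by the cluster
#' representative); second-engine identifications are collapsed by
#' (accession, monoisotopic mass rounded to 2 decimals).  In both cases
#' only the top-scored (lowest E-value) record represents the key.
#'
#' @param pfc_summary Representative-per-cluster tibble from
#'   [summarize_pfcs()] (may be `NULL`).
#' @param tdportal_prsms Second-engine PrSM tibble (may be `NULL`).
#' @return A tibble of collapsed IDs: `source`, `key`, `accession`,
#'   `annotation`, `mass`, `rt`, `evalue`, `has_unknown_shift`,
#'   `is_noise`.
#' @export
collapse_ids <- function(pfc_summary = NULL, tdportal_prsms = NULL) {
  out <- list()
  if (!is.null(pfc_summary) && nrow(pfc_summary)) {
    out$toppic <- tibble::tibble(
      source = "toppic",
      key = pfc_summary$pfc_id,
      accession = pfc_summary$accession,
      annotation = pfc_summary$proteoform,
      mass = pfc_summary$precursor_mass,
      rt = pfc_summary$rt_min,
      evalue = pfc_summary$evalue,
      has_unknown_shift = pfc_summary$has_unknown_shift,
      is_noise = pfc_summary$is_noise
    )
  }
  if (!is.null(tdportal_prsms) && nrow(tdportal_prsms)) {
    td <- tdportal_prsms |>
      dplyr::mutate(.key = paste0(.data$accession, "|",
                                  sprintf("%.2f", round(.data$precursor_mass, 2)))) |>
      dplyr::group_by(.data$.key) |>
      dplyr::slice_min(.data$evalue, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    out$tdportal <- tibble::tibble(
      source = "tdportal",
      key = td$.key,
      accession = td$accession,
      annotation = ifelse(is.na(td$proteoform), td$.key, td$proteoform),
      mass = td$precursor_mass,
      rt = td$rt_min,
      evalue = td$evalue,
      has_unknown_shift = td$has_unknown_shift,
      is_noise = FALSE
    )
  }
  if (!length(out)) {
    return(tibble::tibble(source = character(), key = character(),
                          accession = character(), annotation = character(),
                          mass = double(), rt = double(), evalue = double(),
                          has_unknown_shift = logical(), is_noise = logical()))
  }
  dplyr::bind_rows(out)
}

#' Match collapsed IDs to feature groups, tolerating deisotoping errors
#'
#' An ID matches a feature group iff, for some shift `k` in `shifts`,
#' `|ppm(id_mass + k * isotope_spacing, consensus_mass)| <= mass_tol_ppm`
#' and `|id_rt - mean_rt| <= rt_tol_min`.  For each (ID, group) pair the
#' preferred shift is 0, then increasing `|k|` (+ before -), reflecting
#' that deconvolution off-by-one/two errors are isotope-spacing multiples.
#'
#' @param ids Collapsed-ID tibble from [collapse_ids()].
#' @param groups Feature-group tibble (`groups` element of
#'   [build_feature_groups()]).
#' @param mass_tol_ppm,rt_tol_min Matching tolerances (inclusive).
#' @param isotope_spacing_da Isotope spacing in Da.
#' @param max_shift Largest |k| tried.
#' @return A candidate tibble: `group_id`, one row per matching (ID,
#'   group) pair with `id_index` (row of `ids`), `shift`, `ppm`, `delta_rt`.
#' @export
match_ids_to_groups <- function(ids, groups, mass_tol_ppm = 15,
                                rt_tol_min = 4,
                                isotope_spacing_da = ISOTOPE_SPACING_DA,
                                max_shift = 2) {
  # shift preference: 0, then |k| ascending (+ before -)
  shifts <- c(0, as.vector(t(cbind(seq_len(max_shift), -seq_len(max_shift)))))
  res <- list()
  for (i in seq_len(nrow(ids))) {
    drt <- abs(ids$rt[i] - groups$mean_rt)
    ok_rt <- which(drt <= rt_tol_min)
    if (!length(ok_rt)) next
    best_shift <- rep(NA_integer_, length(ok_rt))
    best_ppm <- rep(NA_real_, length(ok_rt))
    for (k in shifts) {
      pe <- ppm_error(ids$mass[i] + k * isotope_spacing_da,
                      groups$consensus_mass[ok_rt])
      hit <- is.na(best_shift) & abs(pe) <= mass_tol_ppm
      best_shift[hit] <- k
      best_ppm[hit] <- pe[hit]
    }
    found <- which(!is.na(best_shift))
    if (length(found)) {
      res[[length(res) + 1]] <- tibble::tibble(
        group_id = groups$group_id[ok_rt[found]],
        id_index = i,
        shift = best_shift[found],
        ppm = best_ppm[found],
        delta_rt = drt[ok_rt[found]]
      )
    }
  }
  if (!length(res)) {
    return(tibble::tibble(group_id = character(), id_index = integer(),
                          shift = integer(), ppm = double(),
                          delta_rt = double()))
  }
  dplyr::bind_rows(res)
}

#' Resolve competing identifications for one feature group
#'
#' When several IDs match the same feature group, the winner is chosen by
#' lexicographic priority: (1) IDs without unknown modifications beat IDs
#' with them; (2) non-noise proteoform clusters beat the noise cluster;
#' (3) smaller E-value; remaining ties break to the smaller |mass shift|,
#' then engine order (toppic before tdportal), then stable input order.
#'
#' @param candidates Candidate rows for one group (from
#'   [match_ids_to_groups()], already joined with the ID columns
#'   `has_unknown_shift`, `is_noise`, `evalue`, `source`).
#' @return The single winning row.
#' @export
resolve_conflicts <- function(candidates) {
  stopifnot(nrow(candidates) >= 1)
  ord <- order(candidates$has_unknown_shift,   # FALSE first
               candidates$is_noise,            # FALSE first
               candidates$evalue,
               abs(candidates$shift),
               match(candidates$source, c("toppic", "tdportal")),
               seq_len(nrow(candidates)))
  candidates[ord[1], ]
}

#' Attach winning identifications to feature groups
#'
#' Runs [match_ids_to_groups()] and applies [resolve_conflicts()] per
#' group.  A feature group carries at most one winning ID; a collapsed ID
#' may annotate several groups in distinct RT windows.
#'
#' @inheritParams match_ids_to_groups
#' @return A list with `groups` (the input `groups` with `id_source`,
#'   `id_key`, `accession`, `annotation`, `id_evalue`,
#'   `id_has_unknown_shift`, `id_shift`, `id_ppm` attached; NA where no ID
#'   matched) and `candidates` (the full audit trail of matches).
#' @export
annotate_feature_groups <- function(groups, ids, mass_tol_ppm = 15,
                                    rt_tol_min = 4,
                                    isotope_spacing_da = ISOTOPE_SPACING_DA,
                                    max_shift = 2) {
  cand <- match_ids_to_groups(ids, groups, mass_tol_ppm = mass_tol_ppm,
                              rt_tol_min = rt_tol_min,
                              isotope_spacing_da = isotope_spacing_da,
                              max_shift = max_shift)
  cand <- dplyr::bind_cols(
    cand,
    ids[cand$id_index, c("source", "key", "accession", "annotation",
                         "evalue", "has_unknown_shift", "is_noise")]
  )
  winners <- cand |>
    dplyr::group_by(.data$group_id) |>
    dplyr::group_modify(~ resolve_conflicts(.x)) |>
    dplyr::ungroup()
  groups$id_source <- NA_character_
  groups$id_key <- NA_character_
  groups$accession <- NA_character_
  groups$annotation <- NA_character_
  groups$id_evalue <- NA_real_
  groups$id_has_unknown_shift <- NA
  groups$id_shift <- NA_integer_
  groups$id_ppm <- NA_real_
  m <- match(winners$group_id, groups$group_id)
  groups$id_source[m] <- winners$source
  groups$id_key[m] <- winners$key
  groups$accession[m] <- winners$accession
  groups$annotation[m] <- winners$annotation
  groups$id_evalue[m] <- winners$evalue
  groups$id_has_unknown_shift[m] <- winners$has_unknown_shift
  groups$id_shift[m] <- as.integer(winners$shift)
  groups$id_ppm[m] <- winners$ppm
  list(groups = groups, candidates = cand)
}
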
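#' End-to-end pipeline orchestration
#'
#' Config-driven driver running the full integration in a fixed stage
#' order: read -> protein-FDR filter -> RT alignment / mass recalibration
#' -> PfC clustering -> ambiguity classification -> cross-run feature
#' alignment -> feature grouping -> ID collapsing -> ID-to-group matching
#' with conflict resolution -> quantitation (filter, normalize, log2,
#' impute) -> differential testing -> PCA.  Every stage logs input/output
#' record counts; identical config and seed give identical outputs.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' All tolerances default to the matching values used throughout the
#' workflow: 15 ppm mass and 4 min RT tolerances, 1 Da mass-group chain
#' window, isotope spacing 1.00235 Da with shifts up to +/-2, minimum 3
#' PrSMs per proteoform cluster, minimum 2 samples per quantifiable
#' proteoform, 1% protein-level FDR, and downshifted-normal imputation
#' with width 0.3 and downshift 1.8.
#'
#' @param ... Overrides for individual entries.
#' @return A named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    toppic = NULL,            # path(s) to TopPIC-style PrSM tables
    tdportal = NULL,          # path(s) to TDPortal-style tables
    features = NULL,          # paths to per-run/per-CV feature tables
    sample_groups = NULL,     # named vector sample -> region
    group_a = NULL,           # defaults to first two group labels
    group_b = NULL,
    mass_tol_ppm = 15,
    rt_tol_min = 4,
    mass_group_da = 1.0,
    isotope_spacing = 1.00235,
    max_shift = 2,
    min_prsm = 3,
    min_samples = 2,
    fdr = 0.01,
    impute_width = 0.3,
    impute_downshift = 1.8,
    loess_span = 0.5,
    cluster_mass_col = "precursor_mass",  # or "adjusted_mass"
    var_equal = TRUE,
    seed = 1L,
    out_dir = NULL
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(ov)] <- ov
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [default_config()].
#' @return A validated config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) format_error(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  if (!is.null(y$sample_groups)) y$sample_groups <- unlist(y$sample_groups)
  do.call(default_config, y)
}

validate_config <- function(cfg) {
  num_keys <- c("mass_tol_ppm", "rt_tol_min", "mass_group_da",
                "isotope_spacing", "min_prsm", "min_samples", "fdr",
                "impute_width", "impute_downshift", "loess_span")
  for (k in num_keys) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      stop("config error: '", k, "' must be a positive number")
    }
  }
  for (k in c("toppic", "tdportal", "features")) {
    for (f in cfg[[k]]) {
      if (!file.exists(f)) {
        stop("config error: ", k, " file not found: ", f)
      }
    }
  }
  invisible(cfg)
}

#' Run the full integration pipeline
#'
#' @param config A config list ([default_config()]) or the path of a YAML
#'   config file.
#' @return A list with `quant_table` (annotations + imputed log2
#'   abundances + statistics), `differential`, `pca`, `pfc_summary`,
#'   `feature_groups`, `calibration`, `log` (stage-count records) and
#'   `config`.  When `config$out_dir` is set, `quant_table.tsv`,
#'   `differential.tsv`, `pca_scores.tsv`, `feature_groups.tsv`,
#'   `pfc_summary.tsv` and `pipeline_log.txt` are written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_config(config)
  log_lines <- character(0)
  note <- function(stage, ...) {
    line <- paste0("[", stage, "] ", paste0(..., collapse = ""))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## read
  toppic <- run_stage("read", {
    dplyr::bind_rows(lapply(config$toppic, read_toppic_prsms))
  })
  tdportal <- run_stage("read", {
    if (is.null(config$tdportal)) NULL else
      dplyr::bind_rows(lapply(config$tdportal, read_tdportal_table))
  })
  features <- run_stage("read", {
    dplyr::bind_rows(lapply(config$features, read_promex_features))
  })
  note("read", nrow(toppic), " TopPIC PrSMs, ",
       if (is.null(tdportal)) 0 else nrow(tdportal), " TDPortal records, ",
       nrow(features), " MS1 features")

  ## protein-level FDR filter
  n0 <- nrow(toppic)
  toppic <- run_stage("fdr_filter",
                      suppressMessages(filter_protein_fdr(toppic, config$fdr)))
  if (!is.null(tdportal)) {
    n0td <- nrow(tdportal)
    tdportal <- run_stage("fdr_filter",
                          suppressMessages(filter_protein_fdr(tdportal, config$fdr)))
    note("fdr_filter", "TDPortal ", n0td, " -> ", nrow(tdportal))
  }
  note("fdr_filter", "TopPIC ", n0, " -> ", nrow(toppic))

  ## alignment + recalibration on the pooled PrSMs
  all_prsms <- dplyr::bind_rows(toppic, tdportal)
  cal <- run_stage("calibrate", calibrate_runs(
    all_prsms, features, span = config$loess_span))
  note("calibrate", "reference run ", cal$reference_run, "; ",
       nrow(cal$models), " run/CV models, median |ppm offset| ",
       sprintf("%.2f", stats::median(abs(cal$models$ppm_offset))))
  toppic <- cal$prsms[cal$prsms$engine == "toppic", ]
  tdportal <- cal$prsms[cal$prsms$engine == "tdportal", ]
  features <- cal$features

  ## PfC clustering + representatives + classification
  toppic <- run_stage("cluster_pfcs", cluster_prsms(
    toppic, mass_tol_ppm = config$mass_tol_ppm,
    rt_tol_min = config$rt_tol_min, min_size = config$min_prsm,
    mass_col = config$cluster_mass_col))
  pfc_summary <- run_stage("cluster_pfcs", summarize_pfcs(toppic))
  note("cluster_pfcs", sum(!pfc_summary$is_noise), " PfCs + ",
       sum(toppic$is_noise), " PrSMs pooled as noise")
  gene_map <- dplyr::distinct(
    dplyr::bind_rows(toppic, tdportal)[, c("accession", "gene")])
  pfc_summary <- run_stage("classify", suppressMessages(
    classify_level(pfc_summary, gene_map = gene_map)))
  note("classify", "levels: ",
       paste(names(table(pfc_summary$level)), table(pfc_summary$level),
             sep = "=", collapse = ", "))

  ## cross-run feature alignment and grouping
  aligned <- run_stage("align_features", align_features_across_runs(
    features, mass_tol_ppm = config$mass_tol_ppm,
    rt_tol_min = config$rt_tol_min))
  note("align_features", nrow(features), " features -> ", nrow(aligned),
       " aligned rows")
  fg <- run_stage("group_features", build_feature_groups(
    aligned, mass_tol_da = config$mass_group_da,
    mass_tol_ppm = config$mass_tol_ppm, rt_tol_min = config$rt_tol_min))
  note("group_features", nrow(fg$groups), " feature groups")

  ## collapse + match + resolve
  ids <- run_stage("collapse_ids", collapse_ids(pfc_summary, tdportal))
  note("collapse_ids", nrow(ids), " collapsed IDs (",
       sum(ids$source == "toppic"), " TopPIC, ",
       sum(ids$source == "tdportal"), " TDPortal)")
  ann <- run_stage("match_ids", annotate_feature_groups(
    fg$groups, ids, mass_tol_ppm = config$mass_tol_ppm,
    rt_tol_min = config$rt_tol_min,
    isotope_spacing_da = config$isotope_spacing,
    max_shift = config$max_shift))
  note("match_ids", sum(!is.na(ann$groups$annotation)), " of ",
       nrow(ann$groups), " feature groups annotated")

  ## quantitation
  sample_groups <- config$sample_groups
  if (is.null(sample_groups)) {
    stop("config error: sample_groups mapping is required")
  }
  qm <- run_stage("quant", suppressMessages(
    quant_from_groups(ann$groups, sample_groups)))
  qm <- run_stage("quant", suppressMessages(
    filter_min_samples(qm, config$min_samples)))
  note("quant", nrow(qm$abundance),
       " quantifiable proteoforms after min-samples filter")
  qm <- run_stage("quant", normalize_median(qm))
  qm <- run_stage("quant", log2_transform(qm))
  qm_imp <- run_stage("quant", impute_downshifted(
    qm, width = config$impute_width, downshift = config$impute_downshift,
    seed = config$seed))

  ## statistics
  groups_ab <- unique(unname(sample_groups))
  group_a <- if (is.null(config$group_a)) groups_ab[1] else config$group_a
  group_b <- if (is.null(config$group_b)) groups_ab[2] else config$group_b
  diff_tbl <- run_stage("ttest", ttest_unpaired(
    qm_imp, group_a, group_b, var_equal = config$var_equal))
  note("ttest", sum(diff_tbl$p_value < 0.05, na.rm = TRUE),
       " proteoforms at p < 0.05 (", group_a, " vs ", group_b, ")")
  pca <- run_stage("pca", run_pca(qm_imp))
  note("pca", "PC1 ", sprintf("%.1f%%", 100 * pca$var_explained[1]),
       ", PC2 ", sprintf("%.1f%%", 100 * pca$var_explained[2]),
       " variance explained")

  quant_table <- as_quant_table(qm_imp, diff_tbl)
  result <- list(quant_table = quant_table, differential = diff_tbl,
                 pca = pca, pfc_summary = pfc_summary,
                 feature_groups = ann$groups, candidates = ann$candidates,
                 calibration = cal$models, quant_matrix = qm_imp,
                 log = log_lines, config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_quant_table(quant_table, file.path(config$out_dir, "quant_table.tsv"))
    write_quant_table(diff_tbl, file.path(config$out_dir, "differential.tsv"))
    write_quant_table(pca$scores, file.path(config$out_dir, "pca_scores.tsv"))
    write_quant_table(
      dplyr::select(ann$groups, -dplyr::any_of("modifications")),
      file.path(config$out_dir, "feature_groups.tsv"))
    write_quant_table(
      dplyr::select(pfc_summary, -dplyr::any_of("modifications")),
      file.path(config$out_dir, "pfc_summary.tsv"))
    writeLines(log_lines, file.path(config$out_dir, "pipeline_log.txt"))
  }
  invisible(result)
}

#' Compare pipeline output against a synthetic ground truth
#'
#' @param result Output of [run_pipeline()].
#' @param truth A `tdp_truth` object (or the path of a `truth.json`
#'   written by [write_synthetic_tables()]).
#' @return A list: `n_true`, `n_quantified`, `n_matched` (quantified rows
#'   whose annotation equals a true proteoform), `sign_accuracy` (share of
#'   regulated, matched proteoforms whose estimated log2 fold change has
#'   the true sign) and `median_abs_log2fc_error`.
#' @export
evaluate_against_truth <- function(result, truth) {
  if (is.character(truth)) {
    tj <- jsonlite::read_json(truth, simplifyVector = TRUE)
    pf <- tibble::as_tibble(tj$proteoforms)
  } else {
    pf <- truth$proteoforms
  }
  qt <- result$differential
  # deisotoping errors can split one proteoform over several feature
  # groups; evaluate the dominant (most-member) group per annotation
  if ("n_features" %in% names(qt)) {
    qt <- qt |>
      dplyr::group_by(.data$annotation) |>
      dplyr::slice_max(.data$n_features, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  m <- match(qt$annotation, pf$proteoform)
  matched <- !is.na(m)
  reg <- matched & pf$log2fc[m] != 0
  sign_ok <- sign(qt$log2fc[reg]) == sign(pf$log2fc[m[reg]])
  list(
    n_true = nrow(pf),
    n_quantified = nrow(result$differential),
    n_matched = sum(matched),
    sign_accuracy = if (any(reg)) mean(sign_ok) else NA_real_,
    median_abs_log2fc_error =
      stats::median(abs(qt$log2fc[reg] - pf$log2fc[m[reg]]))
  )
}
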
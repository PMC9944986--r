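#' Proteoform abundance matrix: normalization, imputation, statistics
#'
#' Annotated feature groups become a proteoform x sample abundance matrix
#' that moves through a one-way sequence of stages:
#' raw -> (min-samples filter) -> median normalization -> log2 ->
#' downshifted-normal imputation -> unpaired t-test / PCA.
#' The object records its stage so the operations cannot be applied out
#' of order.
#'
#' @name quant
NULL

#' Construct a quantitation matrix
#'
#' @param abundance Numeric matrix, rows = proteoforms (feature groups),
#'   columns = samples; NA marks a feature not observed in that sample.
#' @param annotations Tibble with one row per matrix row (e.g. `group_id`,
#'   `annotation`, `accession`, ...).
#' @param sample_groups Named character vector mapping each sample
#'   (column name) to its group label (e.g. region `"cortex"` /
#'   `"hypothalamus"`).
#' @param stage Processing stage, `"raw"` for freshly built matrices.
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(abundance, annotations, sample_groups,
                         stage = "raw") {
  stopifnot(is.matrix(abundance), nrow(annotations) == nrow(abundance),
            all(colnames(abundance) %in% names(sample_groups)))
  qm <- list(abundance = abundance,
             annotations = tibble::as_tibble(annotations),
             sample_groups = sample_groups[colnames(abundance)],
             stage = stage)
  class(qm) <- "quant_matrix"
  qm
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat("<quant_matrix>", nrow(x$abundance), "proteoforms x",
      ncol(x$abundance), "samples, stage:", x$stage, "\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", names(table(x$sample_groups)),
                                 table(x$sample_groups)), collapse = ", "), "\n")
  cat("  missing:", sum(is.na(x$abundance)), "of",
      length(x$abundance), "cells\n")
  invisible(x)
}

#' Build a quantitation matrix from annotated feature groups
#'
#' Only feature groups carrying an identification are quantifiable; rows
#' without an annotation are dropped (with a count reported).
#'
#' @param groups Annotated feature-group tibble
#'   ([annotate_feature_groups()] `$groups`).
#' @param sample_groups Named sample-to-region map, see [quant_matrix()].
#' @param annotated_only Keep only rows with an attached ID.
#' @return A `quant_matrix` at stage `"raw"`.
#' @export
quant_from_groups <- function(groups, sample_groups, annotated_only = TRUE) {
  ab_cols <- grep("^ab_", names(groups), value = TRUE)
  if (annotated_only) {
    drop_n <- sum(is.na(groups$annotation))
    if (drop_n) message("dropping ", drop_n, " feature group(s) without an ID")
    groups <- groups[!is.na(groups$annotation), ]
  }
  ab <- as.matrix(groups[, ab_cols])
  colnames(ab) <- sub("^ab_", "", ab_cols)
  quant_matrix(ab, groups[, setdiff(names(groups), ab_cols)], sample_groups)
}

stopifnot_stage <- function(qm, expected) {
  if (!qm$stage %in% expected) {
    stop("quant_matrix is at stage '", qm$stage, "'; expected ",
         paste(expected, collapse = " or "))
  }
}

#' Drop proteoforms observed in too few samples
#'
#' @param qm A `quant_matrix` (pre-imputation).
#' @param k Minimum number of samples with an observed value.
#' @return The filtered `quant_matrix`; removals are reported.
#' @export
filter_min_samples <- function(qm, k = 2) {
  stopifnot_stage(qm, c("raw", "normalized", "log2"))
  n_obs <- rowSums(!is.na(qm$abundance))
  keep <- n_obs >= k
  message("min-samples filter (>= ", k, "): kept ", sum(keep), " of ",
          length(keep), " proteoforms")
  qm$abundance <- qm$abundance[keep, , drop = FALSE]
  qm$annotations <- qm$annotations[keep, , drop = FALSE]
  qm
}

#' Normalize abundances to the median of each sample
#'
#' Each sample's observed abundances are divided by that sample's median
#' and rescaled by the grand median of the sample medians, so the overall
#' intensity scale is preserved and all sample medians are equal
#' afterwards.
#'
#' @param qm A `quant_matrix` at stage `"raw"`.
#' @return The matrix at stage `"normalized"`.
#' @export
normalize_median <- function(qm) {
  stopifnot_stage(qm, "raw")
  med <- apply(qm$abundance, 2, stats::median, na.rm = TRUE)
  grand <- stats::median(med)
  qm$abundance <- sweep(qm$abundance, 2, med, "/") * grand
  qm$stage <- "normalized"
  qm
}

#' Log2-transform abundances
#'
#' @param qm A `quant_matrix` at stage `"raw"` or `"normalized"`.
#' @return The matrix at stage `"log2"`.
#' @export
log2_transform <- function(qm) {
  stopifnot_stage(qm, c("raw", "normalized"))
  qm$abundance <- log2(qm$abundance)
  qm$stage <- "log2"
  qm
}

#' Impute missing values from a downshifted normal distribution
#'
#' Missing log2 intensities of each sample are drawn from
#' `Normal(mu_s - downshift * sigma_s, (width * sigma_s)^2)`, where `mu_s`
#' and `sigma_s` are the mean and standard deviation of the sample's
#' observed log2 intensities.  The draw is deterministic given `seed`.
#'
#' @param qm A `quant_matrix` at stage `"log2"`.
#' @param width Width factor of the imputation distribution (default 0.3).
#' @param downshift Downshift in sample standard deviations (default 1.8).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return The matrix at stage `"imputed"` (no missing values remain).
#' @export
impute_downshifted <- function(qm, width = 0.3, downshift = 1.8,
                               seed = NULL) {
  stopifnot_stage(qm, "log2")
  draw <- function() {
    for (s in seq_len(ncol(qm$abundance))) {
      x <- qm$abundance[, s]
      miss <- is.na(x)
      if (!any(miss)) next
      mu <- mean(x[!miss])
      sigma <- stats::sd(x[!miss])
      if (!is.finite(sigma)) sigma <- 0
      qm$abundance[miss, s] <<- stats::rnorm(sum(miss),
                                             mean = mu - downshift * sigma,
                                             sd = width * sigma)
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  qm$stage <- "imputed"
  qm
}

#' Row-wise unpaired t-tests between two sample groups
#'
#' Two-sample two-sided t-test per proteoform on (imputed) log2 values.
#' The log2 fold change is the mean of `group_a` minus the mean of
#' `group_b`.  The equal-variance (Student) form is the default; Welch is
#' available via `var_equal = FALSE`.
#'
#' @param qm A `quant_matrix` at stage `"imputed"` (or `"log2"` with
#'   complete rows).
#' @param group_a,group_b Group labels from `qm$sample_groups`.
#' @param var_equal Pool the variances (Student's t).
#' @param adjust Also report Benjamini-Hochberg adjusted q-values.
#' @return A tibble: the annotation columns plus `log2fc`, `t`, `df`,
#'   `p_value` (and `q_value`).
#' @export
ttest_unpaired <- function(qm, group_a, group_b, var_equal = TRUE,
                           adjust = TRUE) {
  stopifnot_stage(qm, c("log2", "imputed"))
  a_cols <- names(qm$sample_groups)[qm$sample_groups == group_a]
  b_cols <- names(qm$sample_groups)[qm$sample_groups == group_b]
  stopifnot(length(a_cols) >= 2, length(b_cols) >= 2)
  res <- apply(qm$abundance, 1, function(x) {
    a <- x[a_cols]; b <- x[b_cols]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      return(c(log2fc = mean(a) - mean(b), t = NA, df = NA, p = NA))
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate (noise-free) rows: no within-group variance
      d <- mean(a) - mean(b)
      df0 <- length(a) + length(b) - 2
      if (d == 0) return(c(log2fc = 0, t = 0, df = df0, p = 1))
      return(c(log2fc = d, t = sign(d) * Inf, df = df0, p = 0))
    }
    tt <- stats::t.test(a, b, var.equal = var_equal)
    c(log2fc = mean(a) - mean(b), t = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value)
  })
  out <- dplyr::bind_cols(
    qm$annotations,
    tibble::tibble(log2fc = unname(res["log2fc", ]),
                   t = unname(res["t", ]),
                   df = unname(res["df", ]),
                   p_value = unname(res["p", ]))
  )
  if (adjust) out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' PCA of samples in proteoform-abundance space
#'
#' Standard PCA on the sample x proteoform matrix with proteoforms
#' (variables) mean-centered.  For non-imputed data
#' (`use = "pairwise"`), the sample covariance matrix is computed with
#' pairwise-complete observations on row-centered abundances and
#' eigen-decomposed, so missing values need no imputation.
#'
#' @param qm A `quant_matrix` at stage `"log2"` or `"imputed"`.
#' @param n_comp Number of components to return.
#' @param use `"complete"` (requires no missing values) or `"pairwise"`.
#' @return A list with `scores` (tibble: `sample`, `group`, `PC1`, ...)
#'   and `var_explained` (fraction per component).
#' @export
run_pca <- function(qm, n_comp = 2, use = c("complete", "pairwise")) {
  stopifnot_stage(qm, c("log2", "imputed"))
  use <- match.arg(use)
  X <- qm$abundance
  if (use == "complete") {
    if (anyNA(X)) stop("missing values present; impute first or use = \"pairwise\"")
    pc <- stats::prcomp(t(X), center = TRUE, scale. = FALSE)
    n_comp <- min(n_comp, ncol(pc$x))
    scores <- pc$x[, seq_len(n_comp), drop = FALSE]
    ve <- pc$sdev^2 / sum(pc$sdev^2)
  } else {
    Xc <- X - rowMeans(X, na.rm = TRUE)
    S <- stats::cov(Xc, use = "pairwise.complete.obs")
    S[is.na(S)] <- 0
    eg <- eigen(S, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    n_comp <- min(n_comp, ncol(S))
    scores <- eg$vectors[, seq_len(n_comp), drop = FALSE] %*%
      diag(sqrt(ev[seq_len(n_comp)]), n_comp)
    rownames(scores) <- colnames(X)
    ve <- ev / sum(ev)
  }
  colnames(scores) <- paste0("PC", seq_len(n_comp))
  list(
    scores = dplyr::bind_cols(
      tibble::tibble(sample = rownames(scores),
                     group = unname(qm$sample_groups[rownames(scores)])),
      tibble::as_tibble(scores)
    ),
    var_explained = ve
  )
}

#' Flatten a quantitation matrix (plus statistics) to a writable table
#'
#' @param qm A `quant_matrix`.
#' @param stats_tbl Optional differential-statistics tibble from
#'   [ttest_unpaired()] (same row order).
#' @return A tibble: annotation columns, per-sample abundances, then any
#'   statistics columns.
#' @export
as_quant_table <- function(qm, stats_tbl = NULL) {
  ab <- tibble::as_tibble(qm$abundance)
  out <- dplyr::bind_cols(qm$annotations, ab)
  if (!is.null(stats_tbl)) {
    extra <- setdiff(names(stats_tbl), names(out))
    out <- dplyr::bind_cols(out, stats_tbl[, extra])
  }
  out
}
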
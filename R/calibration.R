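#' Retention-time alignment and mass recalibration
#'
#' Runs are aligned to a reference run using shared identified proteoforms
#' as anchors: for each proteoform observed in both runs, the apex PrSM
#' (most intense, falling back to best E-value) gives one (target RT,
#' reference RT) pair.  A LOESS regression of reference RT on target RT is
#' the warp; the median ppm discrepancy of anchor masses is the per-run
#' recalibration offset.  Open-modification search engines occasionally
#' report erroneous mass shifts, so both fits are robust to outliers.
#'
#' @name calibration
NULL

#' Choose the reference run for alignment
#'
#' The run with the largest number of PrSMs; ties break to the
#' lexicographically smallest run id.
#'
#' @param prsms Internal PrSM tibble covering one or more runs.
#' @return The reference `run_id` (character scalar).
#' @export
select_reference_run <- function(prsms) {
  stopifnot(nrow(prsms) >= 1)
  counts <- table(prsms$run_id)
  ids <- sort(names(counts))
  ids[which.max(counts[ids])]
}

# anchor key identifying "the same proteoform" across runs: the engine's
# proteoform string when available (run-invariant), otherwise the mass
# rounded to 2 decimals.  The observed precursor mass is not usable as a
# key because per-run ppm offsets move it by more than the rounding
# granularity at intact-protein masses.
anchor_key <- function(prsms) {
  mass_key <- sprintf("%.2f", round(prsms$precursor_mass, 2))
  pf <- prsms$proteoform
  paste(prsms$accession,
        ifelse(!is.na(pf) & nzchar(pf), pf, mass_key), sep = "|")
}

# apex PrSM per key: maximal reported precursor intensity when available,
# otherwise minimal E-value.
apex_per_key <- function(prsms) {
  prsms$.key <- anchor_key(prsms)
  prsms |>
    dplyr::group_by(.data$.key) |>
    dplyr::arrange(dplyr::desc(!is.na(.data$intensity)),
                   dplyr::desc(.data$intensity), .data$evalue,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Build calibration anchors between two runs
#'
#' @param ref_prsms PrSMs of the reference run.
#' @param target_prsms PrSMs of the run to be aligned.
#' @return A tibble with one row per proteoform observed in both runs:
#'   `key`, `rt_ref`, `rt_target`, `mass_ref`, `mass_target`.  Fewer than
#'   5 anchors triggers a warning (the warp then falls back to identity).
#' @export
build_anchors <- function(ref_prsms, target_prsms) {
  ra <- apex_per_key(ref_prsms)
  ta <- apex_per_key(target_prsms)
  shared <- intersect(ra$.key, ta$.key)
  ra <- ra[match(shared, ra$.key), ]
  ta <- ta[match(shared, ta$.key), ]
  anchors <- tibble::tibble(
    key = shared,
    rt_ref = ra$rt_min, rt_target = ta$rt_min,
    mass_ref = ra$precursor_mass, mass_target = ta$precursor_mass
  )
  if (nrow(anchors) < 5) {
    warning("only ", nrow(anchors),
            " calibration anchor(s); alignment will fall back to identity")
  }
  anchors
}

#' Fit a LOESS retention-time warp from anchors
#'
#' Fits reference RT as a LOESS function of target RT (locally linear,
#' robustness iterations against outlier anchors).  Outside the anchor
#' span the warp continues linearly with the boundary slope.  With fewer
#' than `min_anchors` usable anchors, or degenerate anchors (no RT
#' spread), the identity warp is returned with a warning.
#'
#' @param anchors Anchor tibble from [build_anchors()].
#' @param span LOESS span (fraction of anchors per local fit).
#' @param degree LOESS polynomial degree.
#' @param iterations Robustness (re-weighting) iterations.
#' @param min_anchors Minimum anchors required for a fit.
#' @return An object of class `rt_warp`: callable via [warp_rt()], with
#'   fields `identity`, `n_anchors`, `range`, and `median_abs_residual`
#'   (minutes) as a residual diagnostic.
#' @export
fit_rt_warp <- function(anchors, span = 0.5, degree = 1, iterations = 2,
                        min_anchors = 5) {
  ok <- is.finite(anchors$rt_ref) & is.finite(anchors$rt_target)
  anchors <- anchors[ok, ]
  degenerate <- nrow(anchors) > 1 &&
    isTRUE(stats::sd(anchors$rt_target) < 1e-9)
  if (nrow(anchors) < min_anchors || degenerate) {
    if (degenerate) warning("degenerate anchors (no RT spread); identity warp")
    w <- list(identity = TRUE, n_anchors = nrow(anchors),
              range = range(anchors$rt_target, 0, 200),
              median_abs_residual = NA_real_)
    class(w) <- "rt_warp"
    return(w)
  }
  # keep at least ~12 anchors in each local window so the local fit is
  # well conditioned when anchors are few
  span <- max(span, min(1, 12 / nrow(anchors)))
  quiet_fit <- function(family, iter) {
    withCallingHandlers(
      stats::loess(rt_ref ~ rt_target, data = anchors, span = span,
                   degree = degree, family = family,
                   control = stats::loess.control(
                     surface = "direct", iterations = iter)),
      warning = function(w) {
        # numerical chatter from near-duplicate anchor RTs; the robust
        # fit itself is fine
        if (grepl("pseudoinverse|neighborhood radius|reciprocal condition|singularities",
                  conditionMessage(w))) invokeRestart("muffleWarning")
      })
  }
  # the robust (symmetric) fit degenerates when anchors are exactly
  # collinear (all residuals zero); fall back to least squares then
  fit <- tryCatch(quiet_fit("symmetric", iterations + 1),
                  error = function(e) quiet_fit("gaussian", 1))
  rng <- range(anchors$rt_target)
  # boundary slopes for linear continuation beyond the anchor span
  eps <- max(diff(rng) * 0.01, 1e-3)
  p <- function(x) quiet_loess_predict(fit, x)
  slope_lo <- (p(rng[1] + eps) - p(rng[1])) / eps
  slope_hi <- (p(rng[2]) - p(rng[2] - eps)) / eps
  resid <- anchors$rt_ref - p(anchors$rt_target)
  w <- list(identity = FALSE, fit = fit, range = rng,
            value_lo = p(rng[1]), value_hi = p(rng[2]),
            slope_lo = slope_lo, slope_hi = slope_hi,
            n_anchors = nrow(anchors),
            median_abs_residual = stats::median(abs(resid)))
  class(w) <- "rt_warp"
  w
}

quiet_loess_predict <- function(fit, x) {
  withCallingHandlers(
    as.numeric(stats::predict(fit, newdata = data.frame(rt_target = x))),
    warning = function(w) {
      if (grepl("pseudoinverse|neighborhood radius|reciprocal condition|singularities",
                conditionMessage(w))) invokeRestart("muffleWarning")
    })
}

#' Identity retention-time warp
#' @return An `rt_warp` mapping every RT to itself.
#' @export
identity_warp <- function() {
  w <- list(identity = TRUE, n_anchors = 0L, range = c(0, Inf),
            median_abs_residual = 0)
  class(w) <- "rt_warp"
  w
}

#' Apply a retention-time warp to a vector of RTs
#'
#' @param warp An `rt_warp` from [fit_rt_warp()] or [identity_warp()].
#' @param rt Numeric vector of retention times (minutes, target-run scale).
#' @return Warped RTs on the reference-run scale.
#' @export
warp_rt <- function(warp, rt) {
  stopifnot(inherits(warp, "rt_warp"))
  if (isTRUE(warp$identity)) return(rt)
  out <- quiet_loess_predict(warp$fit, rt)
  lo <- rt < warp$range[1]
  hi <- rt > warp$range[2]
  out[lo] <- warp$value_lo + (rt[lo] - warp$range[1]) * warp$slope_lo
  out[hi] <- warp$value_hi + (rt[hi] - warp$range[2]) * warp$slope_hi
  out
}

#' @export
print.rt_warp <- function(x, ...) {
  if (isTRUE(x$identity)) {
    cat("<rt_warp> identity (", x$n_anchors, "anchors )\n")
  } else {
    cat("<rt_warp> LOESS on", x$n_anchors, "anchors, span",
        sprintf("[%.2f, %.2f] min,", x$range[1], x$range[2]),
        "median |residual|", sprintf("%.3f min\n", x$median_abs_residual))
  }
  invisible(x)
}

#' Warp the retention-time fields of a record table
#'
#' PrSM tables have their `rt_min` warped; feature tables have `rt_apex`,
#' `rt_start` and `rt_end` warped.  No other field changes and the row
#' count is conserved.
#'
#' @param records Internal PrSM or MS1-feature tibble.
#' @param warp An `rt_warp`.
#' @return `records` with aligned RTs.
#' @export
apply_rt_warp <- function(records, warp) {
  if ("rt_min" %in% names(records)) {
    records$rt_min <- warp_rt(warp, records$rt_min)
  }
  for (col in c("rt_apex", "rt_start", "rt_end")) {
    if (col %in% names(records)) records[[col]] <- warp_rt(warp, records[[col]])
  }
  records
}

#' Estimate a per-run constant ppm mass offset from anchors
#'
#' The median, over anchors, of the ppm error of the target mass against
#' the reference mass.  The median keeps a single wild anchor (e.g. a
#' mis-assigned mass shift) from moving the estimate.
#'
#' @param anchors Anchor tibble from [build_anchors()].
#' @return Offset in ppm (0 when no anchors).
#' @export
estimate_ppm_offset <- function(anchors) {
  if (nrow(anchors) == 0) return(0)
  stats::median(ppm_error(anchors$mass_target, anchors$mass_ref), na.rm = TRUE)
}

#' Remove a constant ppm offset from the mass fields of a table
#'
#' Masses become `mass * (1 - ppm_offset * 1e-6)`.  Applied to
#' `precursor_mass` and `adjusted_mass` for PrSM tables and `mono_mass`
#' for feature tables; everything else is untouched.
#'
#' @param records Internal PrSM or MS1-feature tibble.
#' @param ppm_offset Offset in ppm as estimated by [estimate_ppm_offset()].
#' @return `records` with recalibrated masses.
#' @export
recalibrate_masses <- function(records, ppm_offset) {
  f <- 1 - ppm_offset * 1e-6
  for (col in c("precursor_mass", "adjusted_mass", "mono_mass")) {
    if (col %in% names(records)) records[[col]] <- records[[col]] * f
  }
  records
}

#' Align and recalibrate a multi-run PrSM set and its feature tables
#'
#' Convenience driver: selects the reference run, and for every other run
#' builds anchors, fits the RT warp, estimates the ppm offset, and applies
#' both to that run's PrSMs (and, when supplied, its MS1 features).  Runs
#' are handled per FAIMS CV independently when `per_cv = TRUE` and the
#' tables carry a `cv` column, mirroring acquisition files split by CV.
#'
#' @param prsms PrSM tibble across runs (one engine or both).
#' @param features Optional MS1-feature tibble across the same runs.
#' @param span,degree,iterations LOESS parameters, see [fit_rt_warp()].
#' @param per_cv Align each CV stratum independently.
#' @param recalibrate_engines Engines whose PrSM masses carry the
#'   instrument's per-run error and are recalibrated.  Engines reporting
#'   theoretical (database) proteoform masses only get their RTs warped.
#'   Feature masses are always recalibrated.
#' @return A list with `prsms`, `features` (or `NULL`), `reference_run`,
#'   and `models`: one row per run (x CV) with `ppm_offset`, `n_anchors`
#'   and `median_abs_residual`.
#' @export
calibrate_runs <- function(prsms, features = NULL, span = 0.5, degree = 1,
                           iterations = 2, per_cv = TRUE,
                           recalibrate_engines = "toppic") {
  ref_run <- select_reference_run(prsms)
  strata <- if (per_cv && "cv" %in% names(prsms) && !all(is.na(prsms$cv))) {
    sort(unique(prsms$cv))
  } else {
    NA_integer_
  }
  models <- list()
  out_prsms <- prsms
  out_features <- features
  for (s in strata) {
    in_stratum <- if (is.na(s)) rep(TRUE, nrow(prsms)) else !is.na(prsms$cv) & prsms$cv == s
    ref <- prsms[in_stratum & prsms$run_id == ref_run, ]
    for (run in setdiff(sort(unique(prsms$run_id[in_stratum])), ref_run)) {
      sel <- in_stratum & prsms$run_id == run
      anchors <- suppressWarnings(build_anchors(ref, prsms[sel, ]))
      warp <- suppressWarnings(fit_rt_warp(anchors, span = span,
                                           degree = degree,
                                           iterations = iterations))
      # mass offset from experimental-mass engines only (theoretical
      # masses carry no per-run error and would dilute the estimate)
      if ("engine" %in% names(prsms)) {
        mass_anchors <- suppressWarnings(build_anchors(
          ref[ref$engine %in% recalibrate_engines, ],
          prsms[sel & prsms$engine %in% recalibrate_engines, ]))
      } else {
        mass_anchors <- anchors
      }
      offset <- estimate_ppm_offset(mass_anchors)
      warped <- apply_rt_warp(prsms[sel, ], warp)
      recal <- if ("engine" %in% names(warped))
        warped$engine %in% recalibrate_engines else rep(TRUE, nrow(warped))
      warped[recal, ] <- recalibrate_masses(warped[recal, ], offset)
      out_prsms[sel, ] <- warped
      if (!is.null(features)) {
        fsel <- features$run_id == run &
          (if (is.na(s)) TRUE else !is.na(features$cv) & features$cv == s)
        out_features[fsel, ] <-
          recalibrate_masses(apply_rt_warp(features[fsel, ], warp), offset)
      }
      models[[length(models) + 1]] <- tibble::tibble(
        run_id = run, cv = s, ppm_offset = offset,
        n_anchors = warp$n_anchors,
        median_abs_residual = warp$median_abs_residual,
        identity = warp$identity
      )
    }
  }
  list(prsms = out_prsms, features = out_features, reference_run = ref_run,
       models = if (length(models)) dplyr::bind_rows(models) else
         tibble::tibble(run_id = character(), cv = integer(),
                        ppm_offset = double(), n_anchors = integer(),
                        median_abs_residual = double(), identity = logical()))
}
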
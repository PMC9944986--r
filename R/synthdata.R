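#' Ground-truthed synthetic data generator
#'
#' Emulates the statistical structure the pipeline assumes, so every stage
#' is testable without raw data: a two-region study (default 5 cortex vs 4
#' hypothalamus samples), runs split by FAIMS CV (-30/-40/-50 V), smooth
#' monotone RT drift between runs (affine warp plus noise), per-run ppm
#' mass offsets, off-by-one deisotoping errors at a stated rate,
#' log-normal abundances with group fold changes, missing features, and
#' two search engines observing partially overlapping proteoform subsets.
#' All randomness flows from one seed; per-stage substreams are derived
#' deterministically from it, so regenerating with the same seed
#' reproduces identical tables.
#'
#' @name synthdata
NULL

random_sequence <- function(n_res) {
  paste(sample(names(AA_MONO_MASS), n_res, replace = TRUE), collapse = "")
}

make_proteoform_string <- function(seq, kind, shift = NULL) {
  body <- switch(kind,
    none = seq,
    named = {
      pos <- sample(nchar(seq) - 2, 1) + 1
      paste0(substr(seq, 1, pos - 1), "(", substr(seq, pos, pos), ")[Acetyl]",
             substr(seq, pos + 1, nchar(seq)))
    },
    named_unlocalized = {
      # scope spans several residues: PTM known, site not confident
      pos <- sample(nchar(seq) - 4, 1) + 1
      paste0(substr(seq, 1, pos - 1), "(", substr(seq, pos, pos + 2),
             ")[Phospho]", substr(seq, pos + 3, nchar(seq)))
    },
    unknown = paste0(seq, "[", sprintf("%+.3f", shift), "]")
  )
  paste0("M.", body, ".A")
}

#' Generate the ground truth of a synthetic two-region study
#'
#' Defaults mirror the study design the pipeline targets: 5 + 4 samples
#' over two brain regions, three FAIMS CVs, proteoform masses log-uniform
#' in 3.5-30 kDa, elution between 10 and 120 min, ~30% of proteoforms
#' carrying an unknown mass shift, and each engine observing ~70% of the
#' proteoforms.
#'
#' @param n_proteoforms Number of true proteoforms.
#' @param n_samples Named integer vector: samples per region.
#' @param seed Integer seed (all downstream simulation derives from it).
#' @param mass_range Mass range in Da (log-uniform).
#' @param min_mass_sep_da Minimum spacing enforced between true masses, so
#'   distinct proteoforms are identifiable under the 1 Da grouping rule.
#' @param rt_range True elution-time range in minutes.
#' @param abundance_meanlog,abundance_sdlog Log-normal base abundance.
#' @param frac_regulated Fraction of proteoforms with a region effect.
#' @param effect_log2fc Magnitude of the region effect (log2; sign random).
#' @param cvs FAIMS compensation voltages.
#' @param frac_unknown_shift Fraction of proteoforms whose identification
#'   carries an unknown (bare) mass shift.
#' @param frac_named_ptm Fraction with a localized named PTM (a further
#'   small fraction of these is reported unlocalized).
#' @param p_toppic,p_tdportal Probability that each engine identifies a
#'   proteoform (independent draws give partial overlap).
#' @param rt_slope_sd,rt_intercept_sd Per-run affine RT drift parameters.
#' @param ppm_offset_sd Per-run mass offset (ppm, normal).
#' @param dropout Probability a (proteoform, sample) is not detected.
#' @param deisotoping_rate Probability a feature's reported mass is off by
#'   one isotope spacing.
#' @param abundance_noise_cv Coefficient of variation of multiplicative
#'   abundance noise.
#' @param rt_noise_sd Per-observation RT noise (minutes).
#' @param mass_noise_ppm Per-observation mass jitter (ppm, sd).
#' @return An object of class `tdp_truth`: list with `proteoforms`,
#'   `runs`, `params`, `seed`.
#' @export
generate_truth <- function(n_proteoforms = 200,
                           n_samples = c(cortex = 5, hypothalamus = 4),
                           seed = 1,
                           mass_range = c(3500, 30000),
                           min_mass_sep_da = 3,
                           rt_range = c(10, 120),
                           abundance_meanlog = log(1e7),
                           abundance_sdlog = 1,
                           frac_regulated = 0.25,
                           effect_log2fc = 1,
                           cvs = c(-30L, -40L, -50L),
                           frac_unknown_shift = 0.3,
                           frac_named_ptm = 0.2,
                           p_toppic = 0.70,
                           p_tdportal = 0.68,
                           rt_slope_sd = 0.02,
                           rt_intercept_sd = 1,
                           ppm_offset_sd = 3,
                           dropout = 0.1,
                           deisotoping_rate = 0.05,
                           abundance_noise_cv = 0.2,
                           rt_noise_sd = 0.05,
                           mass_noise_ppm = 1) {
  params <- as.list(environment())
  truth <- withr::with_seed(seed, {
    if (n_proteoforms == 0) {
      proteoforms <- tibble::tibble(
        truth_id = character(), accession = character(), gene = character(),
        proteoform = character(), mono_mass = double(), true_rt = double(),
        base_abundance = double(), log2fc = double(),
        has_unknown_shift = logical(), seen_toppic = logical(),
        seen_tdportal = logical())
      cv_w <- matrix(numeric(0), 0, length(cvs))
    } else {
      # log-uniform masses with a minimum spacing (rejection sampling)
      masses <- numeric(0)
      while (length(masses) < n_proteoforms) {
        cand <- exp(stats::runif(n_proteoforms, log(mass_range[1]),
                                 log(mass_range[2])))
        masses <- c(masses, cand)
        masses <- masses[order(masses)]
        keep <- c(TRUE, diff(masses) >= min_mass_sep_da)
        masses <- masses[keep]
      }
      masses <- sort(sample(masses, n_proteoforms))
      kind <- sample(c("unknown", "named", "none"), n_proteoforms,
                     replace = TRUE,
                     prob = c(frac_unknown_shift, frac_named_ptm,
                              1 - frac_unknown_shift - frac_named_ptm))
      # a small share of named PTMs lacks a confident site
      unloc <- kind == "named" & stats::runif(n_proteoforms) < 0.25
      kind[unloc] <- "named_unlocalized"
      shifts <- stats::runif(n_proteoforms, -100, 500)
      pf <- vapply(seq_len(n_proteoforms), function(i) {
        make_proteoform_string(random_sequence(12L), kind[i], shifts[i])
      }, character(1))
      reg <- stats::runif(n_proteoforms) < frac_regulated
      fc <- ifelse(reg, sample(c(-1, 1), n_proteoforms, replace = TRUE) *
                     effect_log2fc, 0)
      # CV usage profile per proteoform (Dirichlet-like weights)
      g <- matrix(stats::rgamma(n_proteoforms * length(cvs), shape = 2),
                  ncol = length(cvs))
      cv_w <- g / rowSums(g)
      proteoforms <- tibble::tibble(
        truth_id = sprintf("pf%04d", seq_len(n_proteoforms)),
        accession = sprintf("P%05d", seq_len(n_proteoforms)),
        gene = sprintf("Gene%04d", seq_len(n_proteoforms)),
        proteoform = pf,
        mono_mass = masses,
        true_rt = stats::runif(n_proteoforms, rt_range[1], rt_range[2]),
        base_abundance = stats::rlnorm(n_proteoforms, abundance_meanlog,
                                       abundance_sdlog),
        log2fc = fc,
        has_unknown_shift = kind == "unknown",
        seen_toppic = stats::runif(n_proteoforms) < p_toppic,
        seen_tdportal = stats::runif(n_proteoforms) < p_tdportal
      )
    }
    colnames(cv_w) <- paste0("w_cv", abs(cvs))
    proteoforms <- dplyr::bind_cols(proteoforms, tibble::as_tibble(cv_w))
    regions <- rep(names(n_samples), n_samples)
    runs <- tibble::tibble(
      run_id = sprintf("Sample_%s_%02d", substr(regions, 1, 1),
                       unlist(lapply(n_samples, seq_len))),
      region = regions,
      rt_slope = stats::rnorm(length(regions), 1, rt_slope_sd),
      rt_intercept = stats::rnorm(length(regions), 0, rt_intercept_sd),
      ppm_offset = stats::rnorm(length(regions), 0, ppm_offset_sd)
    )
    list(proteoforms = proteoforms, runs = runs)
  })
  out <- list(proteoforms = truth$proteoforms, runs = truth$runs,
              params = params, seed = seed, cvs = cvs)
  class(out) <- "tdp_truth"
  out
}

#' @export
print.tdp_truth <- function(x, ...) {
  cat("<tdp_truth>", nrow(x$proteoforms), "proteoforms,",
      nrow(x$runs), "runs (", paste(unique(x$runs$region), collapse = " vs "),
      "), seed", x$seed, "\n")
  invisible(x)
}

#' Simulate engine and feature tables from a ground truth
#'
#' Produces internal-format tibbles: TopPIC-style PrSMs, TDPortal-style
#' proteoform records and per-run/per-CV MS1 features.  Features carry
#' warped RTs (the run's affine drift applied), per-run ppm mass offsets,
#' deisotoping shifts of one isotope spacing at the configured rate,
#' multiplicative log-normal abundance noise and dropout.  Each tibble
#' keeps a hidden `truth_id` column for evaluation; the on-disk writers
#' ignore it.
#'
#' @param truth A `tdp_truth` from [generate_truth()].
#' @return A list with `toppic_prsms`, `tdportal_prsms`, `features`
#'   (tibbles) and `truth`.
#' @export
simulate_tables <- function(truth) {
  p <- truth$params
  cvs <- truth$cvs
  pf <- truth$proteoforms
  runs <- truth$runs
  noise_sdlog <- sqrt(log(1 + p$abundance_noise_cv^2))
  withr::with_seed(truth$seed + 1L, {
    feat <- list(); tp <- list(); td <- list()
    scan_counter <- 0L
    for (r in seq_len(nrow(runs))) {
      run <- runs[r, ]
      eff <- if (run$region == names(p$n_samples)[1])
        2^(pf$log2fc / 2) else 2^(-pf$log2fc / 2)
      detected <- stats::runif(nrow(pf)) >= p$dropout
      warp_fun <- function(t) run$rt_slope * t + run$rt_intercept
      mass_fac <- 1 + run$ppm_offset * 1e-6
      for (i in which(detected)) {
        total_ab <- pf$base_abundance[i] * eff[i] *
          stats::rlnorm(1, 0, noise_sdlog)
        w <- as.numeric(pf[i, paste0("w_cv", abs(cvs))])
        for (ci in seq_along(cvs)) {
          jit <- if (p$mass_noise_ppm > 0)
            1 + stats::rnorm(1, 0, p$mass_noise_ppm) * 1e-6 else 1
          m <- pf$mono_mass[i] * mass_fac * jit
          if (p$deisotoping_rate > 0 &&
              stats::runif(1) < p$deisotoping_rate) {
            m <- m + sample(c(-1, 1), 1) * ISOTOPE_SPACING_DA
            deiso <- TRUE
          } else deiso <- FALSE
          rt <- warp_fun(pf$true_rt[i]) +
            (if (p$rt_noise_sd > 0) stats::rnorm(1, 0, p$rt_noise_sd) else 0)
          feat[[length(feat) + 1]] <- tibble::tibble(
            run_id = run$run_id, cv = cvs[ci], mono_mass = m,
            rt_apex = rt, rt_start = rt - 0.5, rt_end = rt + 0.5,
            abundance = total_ab * w[ci],
            charge_min = 5L, charge_max = 15L,
            truth_id = pf$truth_id[i], deiso_shifted = deiso
          )
        }
        if (pf$seen_toppic[i]) {
          n_prsm <- 1L + stats::rpois(1, 1)
          cv_draw <- sample(cvs, n_prsm, replace = TRUE, prob = w)
          for (k in seq_len(n_prsm)) {
            scan_counter <- scan_counter + 1L
            jit <- if (p$mass_noise_ppm > 0)
              1 + stats::rnorm(1, 0, p$mass_noise_ppm) * 1e-6 else 1
            rtj <- if (p$rt_noise_sd > 0) stats::rnorm(1, 0, 2 * p$rt_noise_sd) else 0
            tp[[length(tp) + 1]] <- tibble::tibble(
              engine = "toppic", run_id = run$run_id, cv = cv_draw[k],
              scan = as.character(scan_counter),
              rt_min = warp_fun(pf$true_rt[i]) + rtj,
              precursor_mass = pf$mono_mass[i] * mass_fac * jit,
              adjusted_mass = pf$mono_mass[i] * mass_fac,
              charge = sample(5:15, 1),
              evalue = 10^stats::runif(1, -15, -2),
              qvalue = stats::runif(1, 0, 0.009),
              accession = pf$accession[i], gene = pf$gene[i],
              first_residue = 2L, last_residue = 13L,
              proteoform = pf$proteoform[i],
              intensity = total_ab * stats::runif(1, 0.1, 1),
              truth_id = pf$truth_id[i]
            )
          }
        }
        if (pf$seen_tdportal[i]) {
          # this engine reports the theoretical (database) proteoform
          # mass, which carries no per-run instrument error
          rtj <- if (p$rt_noise_sd > 0) stats::rnorm(1, 0, 2 * p$rt_noise_sd) else 0
          td[[length(td) + 1]] <- tibble::tibble(
            engine = "tdportal", run_id = run$run_id,
            cv = sample(cvs, 1, prob = w), scan = NA_character_,
            rt_min = warp_fun(pf$true_rt[i]) + rtj,
            precursor_mass = pf$mono_mass[i],
            adjusted_mass = NA_real_, charge = NA_integer_,
            evalue = 10^stats::runif(1, -15, -2),
            qvalue = stats::runif(1, 0, 0.009),
            accession = pf$accession[i], gene = pf$gene[i],
            first_residue = 2L, last_residue = 13L,
            proteoform = pf$proteoform[i], intensity = NA_real_,
            truth_id = pf$truth_id[i]
          )
        }
      }
    }
    complete_prsms <- function(x) {
      if (!length(x)) {
        return(tibble::tibble(engine = character(), run_id = character(),
                              cv = integer(), scan = character(),
                              rt_min = double(), precursor_mass = double(),
                              adjusted_mass = double(), charge = integer(),
                              evalue = double(), qvalue = double(),
                              accession = character(), gene = character(),
                              first_residue = integer(),
                              last_residue = integer(),
                              proteoform = character(), intensity = double(),
                              modifications = list(),
                              has_unknown_shift = logical(),
                              truth_id = character()))
      }
      out <- dplyr::bind_rows(x)
      out$modifications <- parse_proteoform_mods(out$proteoform)
      out$has_unknown_shift <- has_unknown_mass_shift(out$modifications)
      dplyr::relocate(out, "modifications", "has_unknown_shift",
                      .before = "truth_id")
    }
    features <- if (length(feat)) dplyr::bind_rows(feat) else
      tibble::tibble(run_id = character(), cv = integer(),
                     mono_mass = double(), rt_apex = double(),
                     rt_start = double(), rt_end = double(),
                     abundance = double(), charge_min = integer(),
                     charge_max = integer(), truth_id = character(),
                     deiso_shifted = logical())
    list(toppic_prsms = complete_prsms(tp), tdportal_prsms = complete_prsms(td),
         features = features, truth = truth)
  })
}

#' Simulate an averaged MALDI peak list from a ground truth
#'
#' Peaks are placed at the predicted m/z (monoisotopic or envelope apex)
#' of the `top_k` most abundant proteoforms at charges 1 and 2, with
#' intensities proportional to abundance, plus uniformly placed noise
#' peaks kept away from any true peak.
#'
#' @param truth A `tdp_truth`.
#' @param top_k Number of most-abundant proteoforms that produce peaks.
#' @param mode `"monoisotopic"` or `"apex"` peak positions.
#' @param charges Charge states producing peaks.
#' @param n_noise Number of noise peaks.
#' @param mz_range m/z acquisition window.
#' @return A list with `peaks` (tibble `mz`, `intensity`) and `truth_peaks`
#'   (the annotation and charge behind each true peak).
#' @export
simulate_maldi <- function(truth, top_k = 20, mode = c("monoisotopic", "apex"),
                           charges = 1:2, n_noise = 10,
                           mz_range = c(3500, 20000)) {
  mode <- match.arg(mode)
  pf <- truth$proteoforms
  withr::with_seed(truth$seed + 2L, {
    top <- pf[order(-pf$base_abundance), ][seq_len(min(top_k, nrow(pf))), ]
    rows <- list()
    for (i in seq_len(nrow(top))) {
      k <- if (mode == "apex") apex_offset_isotopes(top$mono_mass[i]) else 0L
      for (z in charges) {
        mz <- mz_from_mass(top$mono_mass[i] + k * ISOTOPE_SPACING_DA, z)
        if (mz >= mz_range[1] && mz <= mz_range[2]) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            mz = mz, intensity = top$base_abundance[i] / z,
            annotation = top$proteoform[i], charge = z,
            truth_id = top$truth_id[i])
        }
      }
    }
    truth_peaks <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(mz = double(), intensity = double(),
                     annotation = character(), charge = integer(),
                     truth_id = character())
    noise <- tibble::tibble(
      mz = stats::runif(n_noise, mz_range[1], mz_range[2]),
      intensity = stats::runif(n_noise, 0,
                               max(truth_peaks$intensity, 1) * 0.05))
    if (nrow(truth_peaks)) {
      # keep noise well away (>200 ppm) from every true peak
      far <- vapply(noise$mz, function(m) {
        all(abs(ppm_error(m, truth_peaks$mz)) > 200)
      }, logical(1))
      noise <- noise[far, ]
    }
    peaks <- dplyr::arrange(
      dplyr::bind_rows(truth_peaks[, c("mz", "intensity")], noise), .data$mz)
    list(peaks = peaks, truth_peaks = truth_peaks)
  })
}

#' Write a simulated data set in the on-disk dialects
#'
#' Creates `toppic.tsv` and `tdportal.tsv` (run and CV encoded in the
#' file-name column), one `features/<run>_CV<k>.tsv` per run and CV, and
#' `truth.json` for evaluation.
#'
#' @param sim Output of [simulate_tables()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of file paths, shaped like a pipeline
#'   config's input section.
#' @export
write_synthetic_tables <- function(sim, dir) {
  dir.create(file.path(dir, "features"), recursive = TRUE,
             showWarnings = FALSE)
  toppic_path <- file.path(dir, "toppic.tsv")
  td_path <- file.path(dir, "tdportal.tsv")
  write_toppic_table(sim$toppic_prsms, toppic_path)
  write_tdportal_table(sim$tdportal_prsms, td_path)
  fpaths <- character(0)
  f <- sim$features
  for (run in unique(f$run_id)) {
    for (cv in unique(f$cv[f$run_id == run])) {
      path <- file.path(dir, "features",
                        paste0(run, "_CV", abs(cv), ".tsv"))
      write_promex_table(f[f$run_id == run & f$cv == cv, ], path)
      fpaths <- c(fpaths, path)
    }
  }
  truth_json <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    proteoforms = sim$truth$proteoforms,
    runs = sim$truth$runs,
    seed = sim$truth$seed
  ), truth_json, digits = NA)
  invisible(list(toppic = toppic_path, tdportal = td_path,
                 features = fpaths, truth = truth_json))
}
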
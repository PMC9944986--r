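test_that("reference run is the one with most PrSMs, ties lexicographic", {
  prsms <- dplyr::bind_rows(
    make_prsms(run_id = "A", mass = rep(5000, 10), rt = 1:10),
    make_prsms(run_id = "B", mass = rep(5000, 7), rt = 1:7))
  expect_equal(select_reference_run(prsms), "A")
  tie <- dplyr::bind_rows(
    make_prsms(run_id = "B", mass = rep(5000, 5), rt = 1:5),
    make_prsms(run_id = "A", mass = rep(5000, 5), rt = 1:5))
  expect_equal(select_reference_run(tie), "A")

  # 9-run random instance vs brute-force argmax
  set.seed(11)
  counts <- sample(5:60, 9)
  runs <- paste0("run", 1:9)
  prsms9 <- dplyr::bind_rows(lapply(1:9, function(i) {
    make_prsms(run_id = runs[i], mass = rep(6000, counts[i]),
               rt = seq_len(counts[i]))
  }))
  expect_equal(select_reference_run(prsms9), runs[which.max(counts)])
})

test_that("anchors come from the intersection of shared proteoforms", {
  a <- make_prsms(run_id = "A", mass = c(5000, 6000), rt = c(10, 20),
                  accession = c("P1", "P2"),
                  proteoform = c("M.AAA.A", "M.CCC.A"))
  b <- make_prsms(run_id = "B", mass = c(7000, 8000), rt = c(30, 40),
                  accession = c("P3", "P4"),
                  proteoform = c("M.DDD.A", "M.EEE.A"))
  expect_warning(anch <- build_anchors(a, b), "anchor")
  expect_equal(nrow(anch), 0)

  expect_warning(self <- build_anchors(a, a), "anchor")
  expect_equal(nrow(self), 2)
  expect_equal(self$rt_ref, self$rt_target)

  # synthetic overlap of 50 shared proteoforms
  masses <- seq(5000, 14800, by = 200)
  pfs <- sprintf("M.PF%02d.A", seq_along(masses))
  ref <- make_prsms(run_id = "R", mass = masses, rt = seq_along(masses),
                    accession = sprintf("P%02d", seq_along(masses)),
                    proteoform = pfs)
  tgt <- make_prsms(run_id = "T", mass = masses, rt = seq_along(masses) + 1,
                    accession = sprintf("P%02d", seq_along(masses)),
                    proteoform = pfs)
  anch50 <- build_anchors(ref, tgt)
  expect_equal(nrow(anch50), 50)
})

test_that("apex PrSM per proteoform prefers intensity, then E-value", {
  run <- make_prsms(run_id = "A", mass = rep(5000, 3), rt = c(10, 11, 12),
                    evalue = c(1e-3, 1e-9, 1e-6),
                    intensity = c(NA, 100, 500))
  expect_warning(anch <- build_anchors(run, run), "anchor")
  expect_equal(anch$rt_ref, 12)  # the most intense PrSM is the apex
  run2 <- make_prsms(run_id = "A", mass = rep(5000, 3), rt = c(10, 11, 12),
                     evalue = c(1e-3, 1e-9, 1e-6))
  expect_warning(anch2 <- build_anchors(run2, run2), "anchor")
  expect_equal(anch2$rt_ref, 11)  # no intensities: best E-value wins
})

test_that("LOESS warp recovers identity, affine, and smooth nonlinear drifts", {
  # anchors exactly on the identity line
  t0 <- seq(10, 110, length.out = 50)
  w_id <- fit_rt_warp(tibble::tibble(rt_ref = t0, rt_target = t0))
  expect_lt(max(abs(warp_rt(w_id, t0) - t0)), 1e-6)

  # affine drift: rt_target = 1.05 rt_ref + 2, noise sd 0.05 min
  set.seed(101)
  rt_ref <- stats::runif(100, 10, 120)
  rt_target <- 1.05 * rt_ref + 2 + stats::rnorm(100, 0, 0.05)
  w_aff <- fit_rt_warp(tibble::tibble(rt_ref = rt_ref, rt_target = rt_target))
  expect_lt(median(abs(warp_rt(w_aff, rt_target) - rt_ref)), 0.1)

  # sinusoidal drift, amplitude 1 min over 120 min, 200 anchors
  rt_ref2 <- stats::runif(200, 0, 120)
  rt_target2 <- rt_ref2 + sin(rt_ref2 / 120 * 2 * pi) +
    stats::rnorm(200, 0, 0.05)
  w_sin <- fit_rt_warp(tibble::tibble(rt_ref = rt_ref2, rt_target = rt_target2))
  expect_lt(median(abs(warp_rt(w_sin, rt_target2) - rt_ref2)), 0.2)
})

test_that("degenerate or scarce anchors fall back to the identity warp", {
  few <- tibble::tibble(rt_ref = c(10, 20), rt_target = c(10, 20))
  expect_s3_class(fit_rt_warp(few), "rt_warp")
  expect_true(fit_rt_warp(few)$identity)
  same_rt <- tibble::tibble(rt_ref = stats::runif(20, 10, 100),
                            rt_target = rep(50, 20))
  expect_warning(w <- fit_rt_warp(same_rt), "degenerate")
  expect_true(w$identity)
})

test_that("applying a warp changes only RT fields and conserves records", {
  f <- make_features(mass = c(5000, 6000), rt = c(10, 20))
  shifted <- fit_rt_warp(tibble::tibble(rt_ref = seq(5, 100, length.out = 40),
                                        rt_target = seq(5, 100, length.out = 40) + 2))
  out <- apply_rt_warp(f, shifted)
  expect_equal(nrow(out), nrow(f))
  expect_equal(out$rt_apex, f$rt_apex - 2, tolerance = 1e-6)
  expect_equal(out$mono_mass, f$mono_mass)
  expect_equal(out$abundance, f$abundance)
  # identity warp after a warp changes nothing further
  expect_equal(apply_rt_warp(out, identity_warp()), out)
})

test_that("ppm offset estimation is exact, accurate under noise, and robust", {
  same <- tibble::tibble(mass_ref = c(5000, 10000), mass_target = c(5000, 10000))
  expect_equal(estimate_ppm_offset(same), 0)

  set.seed(102)
  m <- stats::runif(100, 4000, 25000)
  inj <- tibble::tibble(mass_ref = m,
                        mass_target = m * (1 + 8e-6) *
                          (1 + stats::rnorm(100, 0, 1) * 1e-6))
  expect_lt(abs(estimate_ppm_offset(inj) - 8), 0.5)

  # one wild outlier among 20 anchors barely moves the median
  m20 <- stats::runif(20, 5000, 20000)
  wild <- tibble::tibble(mass_ref = m20, mass_target = m20)
  wild$mass_target[1] <- wild$mass_ref[1] * 1.001  # +1000 ppm
  expect_lt(abs(estimate_ppm_offset(wild)), 1)
})

test_that("mass recalibration arithmetic and inverse composition", {
  r <- make_prsms(mass = 10000, rt = 10)
  out <- recalibrate_masses(r, 15)
  expect_equal(out$precursor_mass, 9999.85)
  expect_equal(recalibrate_masses(r, 0)$precursor_mass, 10000)
  # recalibrating back with the opposite offset is the identity to 1e-9
  back <- recalibrate_masses(out, -15)
  expect_equal(back$precursor_mass / r$precursor_mass, 1,
               tolerance = 1e-9)
})

test_that("aligning a multi-run set to itself leaves RTs and masses unchanged", {
  set.seed(103)
  masses <- seq(5000, 12000, by = 250)
  pfs <- sprintf("M.PF%02d.A", seq_along(masses))
  one_run <- function(id) {
    make_prsms(run_id = id, mass = masses,
               rt = seq(10, 100, length.out = length(masses)),
               accession = sprintf("P%02d", seq_along(masses)),
               proteoform = pfs)
  }
  prsms <- dplyr::bind_rows(one_run("A"), one_run("B"))
  cal <- calibrate_runs(prsms)
  expect_equal(cal$prsms$rt_min, prsms$rt_min, tolerance = 1e-6)
  expect_equal(cal$prsms$precursor_mass, prsms$precursor_mass,
               tolerance = 1e-9)
  expect_equal(cal$models$ppm_offset, 0)
})
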
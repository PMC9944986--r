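test_that("ppm error is the signed relative difference in parts per million", {
  expect_equal(ppm_error(1000, 1000), 0)
  expect_equal(ppm_error(10000.15, 10000.00), 15.0)
  expect_equal(ppm_error(4999.925, 5000.000), -15.0)
})

test_that("chained mass grouping follows the 1 Da / 15 ppm predecessor rule", {
  # chaining: consecutive 6 ppm gaps stay in one group
  expect_equal(assign_mass_groups(c(5000.000, 5000.030, 5000.060)),
               c(1L, 1L, 1L))
  # 0.090 Da = 18 ppm at 5 kDa: ppm rule splits
  expect_equal(assign_mass_groups(c(5000.000, 5000.090)), c(1L, 2L))
  # 1.2 Da at 50 kDa is only 24 ppm but breaks the 1 Da rule
  expect_equal(assign_mass_groups(c(50000.0, 50001.2)), c(1L, 2L))
  expect_equal(assign_mass_groups(numeric(0)), integer(0))
  expect_error(assign_mass_groups(c(2, 1)), "sorted")
})

test_that("chained RT grouping uses an inclusive 4 min gap", {
  expect_equal(assign_rt_groups(c(10.0, 13.9, 18.0)), c(1L, 1L, 2L))
  expect_equal(assign_rt_groups(c(0, 4, 8, 12)), rep(1L, 4))  # gaps exactly 4
  expect_equal(assign_rt_groups(numeric(0)), integer(0))
})

test_that("chained grouping matches a brute-force scan oracle", {
  set.seed(301)
  for (i in 1:200) {
    n <- sample(1:100, 1)
    masses <- sort(stats::runif(n, 5000, 5005))
    got <- assign_mass_groups(masses)
    want <- oracle_chain_groups(masses, function(prev, cur) {
      gap <- cur - prev
      gap > 1.0 || gap > 15e-6 * prev
    })
    expect_identical(got, want)
    rts <- sort(stats::runif(n, 0, 120))
    expect_identical(assign_rt_groups(rts),
                     oracle_chain_groups(rts, function(p, c) c - p > 4))
  }
})

test_that("cross-run alignment fills one row per feature correspondence", {
  f <- dplyr::bind_rows(
    make_features(run_id = "A", mass = c(5000, 6000, 7000),
                  rt = c(10, 20, 30), abundance = 1:3),
    make_features(run_id = "B", mass = c(5000, 6000, 7000),
                  rt = c(10, 20, 30), abundance = 4:6))
  al <- align_features_across_runs(f)
  expect_equal(nrow(al), 3)
  expect_equal(sum(is.na(al[, c("ab_A", "ab_B")])), 0)

  # run B missing one feature -> exactly one NA cell
  f2 <- dplyr::bind_rows(
    make_features(run_id = "A", mass = c(5000, 6000, 7000),
                  rt = c(10, 20, 30), abundance = 1:3),
    make_features(run_id = "B", mass = c(5000, 7000),
                  rt = c(10, 30), abundance = 4:5))
  al2 <- align_features_across_runs(f2)
  expect_equal(sum(is.na(al2[, c("ab_A", "ab_B")])), 1)
  expect_true(is.na(al2$ab_B[al2$mono_mass == 6000]))
})

test_that("alignment recovers known correspondences under dropout", {
  set.seed(302)
  mass <- sort(exp(stats::runif(120, log(4000), log(25000))))
  mass <- mass[c(TRUE, diff(mass) > 5)]
  n <- length(mass)
  rt <- stats::runif(n, 10, 120)
  mk <- function(run) {
    keep <- stats::runif(n) > 0.1   # 10% dropout
    tibble::tibble(run_id = run, cv = -40L,
                   mono_mass = mass[keep] * (1 + stats::rnorm(sum(keep), 0, 1) * 1e-6),
                   rt_apex = rt[keep] + stats::rnorm(sum(keep), 0, 0.1),
                   rt_start = 0, rt_end = 200,
                   abundance = which(keep),  # abundance encodes the truth id
                   charge_min = 5L, charge_max = 10L)
  }
  f <- dplyr::bind_rows(mk("A"), mk("B"), mk("C"))
  al <- align_features_across_runs(f)
  ab <- as.matrix(al[, c("ab_A", "ab_B", "ab_C")])
  # a row is correct when all its cells carry the same true feature id
  consistent <- apply(ab, 1, function(r) length(unique(r[!is.na(r)])) == 1)
  expect_gte(mean(consistent), 0.98)
  # every input feature occupies exactly one cell
  expect_equal(sum(!is.na(ab)), nrow(f))
})

test_that("feature groups summarize count, max mass, mean RT and medians", {
  one <- align_features_across_runs(
    make_features(run_id = "A", mass = 5000, rt = 10, abundance = 7))
  fg1 <- build_feature_groups(one)
  expect_equal(nrow(fg1$groups), 1)
  expect_equal(fg1$groups$n_features, 1)
  expect_equal(fg1$groups$consensus_mass, 5000)
  expect_equal(fg1$groups$ab_A, 7)

  # abundance is reorganized, never altered: totals are conserved
  set.seed(303)
  f <- dplyr::bind_rows(lapply(c("A", "B", "C"), function(run) {
    make_features(run_id = run, mass = stats::runif(40, 4000, 20000),
                  rt = stats::runif(40, 10, 110),
                  abundance = stats::runif(40, 1e5, 1e7))
  }))
  al <- build_feature_groups(align_features_across_runs(f))
  ab_cols <- grep("^ab_", names(al$members), value = TRUE)
  expect_equal(sum(as.matrix(al$members[, ab_cols]), na.rm = TRUE),
               sum(f$abundance))
  # every aligned feature row belongs to exactly one group
  expect_equal(sum(table(al$members$group_id)), nrow(al$members))
  expect_setequal(al$members$group_id, al$groups$group_id)
})

test_that("collapsing keeps one lowest-E-value record per engine key", {
  td <- make_prsms(engine = "tdportal", mass = c(8000.001, 8000.002),
                   rt = c(30, 31), accession = "P1",
                   evalue = c(1e-3, 1e-8))
  ids <- collapse_ids(NULL, td)
  expect_equal(nrow(ids), 1)
  expect_equal(ids$evalue, 1e-8)
  expect_equal(ids$source, "tdportal")

  pf <- cluster_prsms(make_prsms(mass = rep(5000, 3), rt = c(10, 10, 10)))
  ids2 <- collapse_ids(summarize_pfcs(pf), NULL)
  expect_equal(nrow(ids2), 1)
  expect_equal(ids2$key, "pfc_1")

  expect_equal(nrow(collapse_ids(NULL, NULL)), 0)
})

test_that("ID-to-group matching tolerates deisotoping shifts, preferring 0 then |k|", {
  groups <- tibble::tibble(group_id = c("g1", "g2"),
                           consensus_mass = c(11001.002, 11003.000),
                           mean_rt = c(50, 50))
  id <- tibble::tibble(source = "toppic", key = "k", accession = "P",
                       annotation = "x", mass = 11000.000, rt = 49,
                       evalue = 1e-9, has_unknown_shift = FALSE,
                       is_noise = FALSE)
  cand <- match_ids_to_groups(id, groups)
  expect_equal(cand$group_id, "g1")       # 11003 is ~90 ppm off even shifted
  expect_equal(cand$shift, 1)             # one isotope spacing up
  expect_lt(abs(cand$ppm), 1)

  same <- tibble::tibble(group_id = "g", consensus_mass = 11000.000,
                         mean_rt = 49.5)
  expect_equal(match_ids_to_groups(id, same)$shift, 0)

  # RT gate: a perfect mass match 5 min away is rejected
  far_rt <- tibble::tibble(group_id = "g", consensus_mass = 11000.000,
                           mean_rt = 54.5)
  expect_equal(nrow(match_ids_to_groups(id, far_rt)), 0)
})

test_that("conflict resolution follows the stated priority order exhaustively", {
  # all 8 combinations of (unknown shift, noise cluster, better E-value)
  combos <- expand.grid(unknown = c(FALSE, TRUE), noise = c(FALSE, TRUE),
                        good_e = c(FALSE, TRUE))
  base <- function(unknown, noise, good_e, key) {
    tibble::tibble(group_id = "g", id_index = 1L, shift = 0L, ppm = 0,
                   delta_rt = 0, source = "toppic", key = key,
                   accession = "P", annotation = key,
                   evalue = if (good_e) 1e-12 else 1e-4,
                   has_unknown_shift = unknown, is_noise = noise)
  }
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    base(combos$unknown[i], combos$noise[i], combos$good_e[i],
         sprintf("c%d", i))
  })
  # pairwise: for every pair, the winner must be the one that is better on
  # the highest-priority differing attribute
  for (i in seq_along(rows)) {
    for (j in seq_along(rows)) {
      if (i == j) next
      win <- resolve_conflicts(dplyr::bind_rows(rows[[i]], rows[[j]]))
      a <- combos[i, ]; b <- combos[j, ]
      want <- if (a$unknown != b$unknown) {
        if (!a$unknown) i else j
      } else if (a$noise != b$noise) {
        if (!a$noise) i else j
      } else if (a$good_e != b$good_e) {
        if (a$good_e) i else j
      } else i  # stable input order
      expect_equal(win$key, sprintf("c%d", want))
    }
  }

  # spec'd spot checks: clean beats a better-scored unknown-shift ID;
  # non-noise beats noise; then smaller E-value
  clean <- base(FALSE, FALSE, FALSE, "clean")
  shifty <- base(TRUE, FALSE, TRUE, "shifty")
  expect_equal(resolve_conflicts(dplyr::bind_rows(shifty, clean))$key, "clean")
  noise <- base(FALSE, TRUE, TRUE, "noise")
  expect_equal(resolve_conflicts(dplyr::bind_rows(noise, clean))$key, "clean")
  expect_equal(resolve_conflicts(dplyr::bind_rows(
    base(FALSE, FALSE, FALSE, "e4"), base(FALSE, FALSE, TRUE, "e12")))$key,
    "e12")
})

test_that("deisotoping-shifted features still receive their identification", {
  truth <- generate_truth(n_proteoforms = 120, seed = 21, rt_slope_sd = 0,
                          rt_intercept_sd = 0, ppm_offset_sd = 0,
                          dropout = 0, deisotoping_rate = 0.2,
                          p_toppic = 1, p_tdportal = 0)
  sim <- simulate_tables(truth)
  expect_gt(sum(sim$features$deiso_shifted), 0)
  al <- align_features_across_runs(sim$features)
  fg <- build_feature_groups(al)
  ids <- tibble::tibble(
    source = "toppic", key = truth$proteoforms$truth_id,
    accession = truth$proteoforms$accession,
    annotation = truth$proteoforms$proteoform,
    mass = truth$proteoforms$mono_mass, rt = truth$proteoforms$true_rt,
    evalue = 1e-10, has_unknown_shift = FALSE, is_noise = FALSE)
  cand <- match_ids_to_groups(ids, fg$groups)
  affected <- unique(sim$features$truth_id[sim$features$deiso_shifted])
  matched <- ids$key[unique(cand$id_index)]
  expect_gte(mean(affected %in% matched), 0.95)
  # shift annotations are used where the group consensus is off by one
  expect_true(any(cand$shift != 0))
})
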
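sample_groups_9 <- stats::setNames(rep(c("cortex", "hypothalamus"), c(5, 4)),
                                   c(paste0("c", 1:5), paste0("h", 1:4)))

toy_qm <- function(ab, stage = "raw") {
  quant_matrix(ab, tibble::tibble(row = seq_len(nrow(ab))),
               sample_groups_9[colnames(ab)], stage = stage)
}

test_that("min-samples filter drops under-observed proteoforms", {
  ab <- matrix(NA_real_, 5, 4, dimnames = list(NULL, c("c1", "c2", "h1", "h2")))
  ab[1, 1] <- 1                 # observed once -> dropped
  ab[2, c(1, 3)] <- 1           # observed twice -> kept
  ab[3, ] <- 1                  # fully observed -> kept
  ab[4, c(2, 3, 4)] <- 1        # kept
  # row 5 never observed -> dropped
  qm <- toy_qm(ab)
  expect_message(out <- filter_min_samples(qm, k = 2), "kept 3 of 5")
  expect_equal(nrow(out$abundance), 3)
  expect_equal(out$annotations$row, c(2L, 3L, 4L))
})

test_that("median normalization equalizes sample medians and preserves scale", {
  set.seed(401)
  ab <- matrix(stats::rlnorm(9 * 50, log(1e6), 1), 50, 9,
               dimnames = list(NULL, names(sample_groups_9)))
  ab[sample(length(ab), 60)] <- NA
  doubled <- ab
  doubled[, "c3"] <- doubled[, "c3"] * 2
  out <- normalize_median(toy_qm(doubled))
  med <- apply(out$abundance, 2, stats::median, na.rm = TRUE)
  expect_equal(unname(diff(range(med))), 0, tolerance = 1e-9)
  expect_equal(out$stage, "normalized")

  # already-equal medians pass through unchanged
  eq <- matrix(rep(c(1, 2, 3), 3), 3, 3,
               dimnames = list(NULL, c("c1", "c2", "h1")))
  out_eq <- normalize_median(toy_qm(eq))
  expect_equal(out_eq$abundance, eq, tolerance = 1e-12)
})

test_that("downshifted-normal imputation has the stated distribution and is seeded", {
  # one sample whose observed log2 values have mean exactly 20, sd exactly 2
  set.seed(402)
  obs <- as.numeric(scale(stats::rnorm(200))) * 2 + 20
  n_miss <- 1e4
  ab <- matrix(NA_real_, 200 + n_miss, 2,
               dimnames = list(NULL, c("c1", "c2")))
  ab[, 2] <- 20
  ab[seq_along(obs), 1] <- obs
  qm <- toy_qm(ab, stage = "log2")
  out <- impute_downshifted(qm, seed = 99)
  imputed <- out$abundance[-seq_along(obs), 1]
  # draws ~ Normal(20 - 1.8 * 2, (0.3 * 2)^2) = Normal(16.4, 0.6^2)
  expect_equal(mean(imputed), 16.4, tolerance = 0.02)
  expect_equal(stats::sd(imputed), 0.6, tolerance = 0.02)
  expect_false(anyNA(out$abundance))
  expect_equal(out$stage, "imputed")

  # determinism under the seed; identity when nothing is missing
  out2 <- impute_downshifted(qm, seed = 99)
  expect_identical(out$abundance, out2$abundance)
  full <- toy_qm(matrix(1:6, 2, 3, dimnames = list(NULL, c("c1", "c2", "h1"))),
                 stage = "log2")
  expect_equal(impute_downshifted(full, seed = 1)$abundance, full$abundance)

  # imputed values sit below the sample's observed median (99th percentile)
  expect_lt(stats::quantile(imputed, 0.99), stats::median(obs))
})

test_that("unpaired Student t matches the closed form and behaves under the null", {
  ab <- rbind(c(1, 2, 3, 2, 3, 4), c(5, 6, 7, 5, 6, 7))
  colnames(ab) <- c("c1", "c2", "c3", "h1", "h2", "h3")
  sg <- stats::setNames(rep(c("cortex", "hypothalamus"), each = 3),
                        colnames(ab))
  qm <- quant_matrix(ab, tibble::tibble(row = 1:2), sg, stage = "log2")
  tt <- ttest_unpaired(qm, "cortex", "hypothalamus")
  # A = (1,2,3), B = (2,3,4): pooled t = -1.2247, df = 4, p = 0.2878
  expect_equal(tt$t[1], -1.224745, tolerance = 1e-6)
  expect_equal(tt$df[1], 4)
  expect_equal(tt$p_value[1], 0.2878641, tolerance = 1e-6)
  expect_equal(tt$log2fc[1], -1)
  # identical groups: t = 0, p = 1
  expect_equal(tt$t[2], 0)
  expect_equal(tt$p_value[2], 1)

  # type-I error under the null is nominal
  set.seed(403)
  ab0 <- matrix(stats::rnorm(2000 * 9, 20, 2), 2000, 9,
                dimnames = list(NULL, names(sample_groups_9)))
  tt0 <- ttest_unpaired(toy_qm(ab0, stage = "log2"),
                        "cortex", "hypothalamus")
  expect_gte(mean(tt0$p_value < 0.05), 0.04)
  expect_lte(mean(tt0$p_value < 0.05), 0.06)
})

test_that("two-fold effects are recovered with correct sign through the stack", {
  set.seed(404)
  n <- 300
  sdlog <- sqrt(log(1 + 0.2^2))   # lognormal noise, CV 20%
  base <- stats::rlnorm(n, log(1e7), 1)
  fc <- sample(c(-1, 1), n, replace = TRUE)
  ab <- cbind(
    sapply(1:5, function(i) base * 2^(fc / 2) * stats::rlnorm(n, 0, sdlog)),
    sapply(1:4, function(i) base * 2^(-fc / 2) * stats::rlnorm(n, 0, sdlog)))
  colnames(ab) <- names(sample_groups_9)
  qm <- impute_downshifted(log2_transform(normalize_median(toy_qm(ab))),
                           seed = 5)
  tt <- ttest_unpaired(qm, "cortex", "hypothalamus")
  expect_lt(abs(median(abs(tt$log2fc)) - 1), 0.25)
  expect_gte(mean(sign(tt$log2fc) == fc), 0.95)
})

test_that("stage transitions are one-way", {
  ab <- matrix(1:6, 2, 3, dimnames = list(NULL, c("c1", "c2", "h1")))
  qm <- toy_qm(ab)
  norm <- normalize_median(qm)
  expect_error(normalize_median(norm), "stage")
  lg <- log2_transform(norm)
  expect_error(log2_transform(lg), "stage")
  expect_error(impute_downshifted(qm, seed = 1), "stage")
})

test_that("PCA separates groups and reports non-increasing variance", {
  set.seed(405)
  n <- 150
  eff <- sample(c(-1, 1), n, TRUE) * 2
  ab <- cbind(
    sapply(1:5, function(i) 20 + eff / 2 + stats::rnorm(n, 0, 0.5)),
    sapply(1:4, function(i) 20 - eff / 2 + stats::rnorm(n, 0, 0.5)))
  colnames(ab) <- names(sample_groups_9)
  qm <- toy_qm(ab, stage = "log2")
  pca <- run_pca(qm)
  expect_true(all(diff(pca$var_explained) <= 1e-12))
  sc <- pca$scores
  sil <- vapply(seq_len(nrow(sc)), function(i) {
    own <- sc$group == sc$group[i]
    a <- mean(abs(sc$PC1[i] - sc$PC1[own & seq_len(nrow(sc)) != i]))
    b <- mean(abs(sc$PC1[i] - sc$PC1[!own]))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)

  # duplicated samples land on identical scores
  ab2 <- ab
  ab2[, "c2"] <- ab2[, "c1"]
  pca2 <- run_pca(toy_qm(ab2, stage = "log2"))
  s1 <- unlist(pca2$scores[pca2$scores$sample == "c1", c("PC1", "PC2")])
  s2 <- unlist(pca2$scores[pca2$scores$sample == "c2", c("PC1", "PC2")])
  expect_equal(s1, s2, ignore_attr = TRUE, tolerance = 1e-9)

  # pairwise-complete PCA handles missing values without imputation
  ab3 <- ab
  ab3[sample(length(ab3), 100)] <- NA
  pca3 <- run_pca(toy_qm(ab3, stage = "log2"), use = "pairwise")
  expect_equal(nrow(pca3$scores), 9)
  sc3 <- pca3$scores
  m_c <- mean(sc3$PC1[sc3$group == "cortex"])
  m_h <- mean(sc3$PC1[sc3$group == "hypothalamus"])
  expect_gt(abs(m_c - m_h), 0)
})
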
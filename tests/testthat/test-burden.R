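mk_bins <- function(depth, width = 1000) {
  n <- length(depth)
  tibble::tibble(chrom = "chrS",
                 start = as.integer(seq(1, by = width, length.out = n)),
                 end = as.integer(seq(width, by = width, length.out = n)),
                 depth = depth)
}

test_that("sensitivity is the per-stratum germline recovery fraction", {
  withr::with_seed(1, {
    bins <- mk_bins(rpois(200, 30))
    truth <- tibble::tibble(chrom = "chrS", pos = sort(sample(2e5, 400)))
  })
  s_all <- estimate_sensitivity(truth, truth, bins)
  expect_true(all(s_all$sensitivity == 1))

  rec_half <- truth[seq(1, 400, by = 2), ]
  s_half <- estimate_sensitivity(rec_half, truth, bins)
  expect_true(all(abs(s_half$sensitivity - 0.5) < 0.15))
  expect_equal(sum(s_half$n_recovered) / sum(s_half$n_truth), 0.5,
               tolerance = 0.02)
})

test_that("depth-dependent dropout is recovered within binomial error", {
  withr::with_seed(7, {
    bins <- mk_bins(rpois(500, 30))
    truth <- tibble::tibble(chrom = "chrS", pos = sort(sample(5e5, 3000)))
    # logistic dropout in depth
    o <- IRanges::findOverlaps(IRanges::IRanges(truth$pos, truth$pos),
                               IRanges::IRanges(bins$start, bins$end),
                               select = "first")
    p_rec <- stats::plogis((bins$depth[o] - 28) / 3)
    rec <- truth[stats::runif(3000) < p_rec, ]
  })
  prof <- estimate_sensitivity(rec, truth, bins, n_strata = 4)
  mid_depth <- (prof$depth_lo + prof$depth_hi) / 2
  expected <- stats::plogis((mid_depth - 28) / 3)
  se <- sqrt(expected * (1 - expected) / prof$n_truth)
  expect_true(all(abs(prof$sensitivity - expected) < 4 * se + 0.03))
  # monotone increasing with depth for a monotone dropout curve
  expect_true(all(diff(prof$sensitivity) > -0.1))
})

test_that("burden scales linearly with calls and inversely with sensitivity", {
  prof <- structure(
    tibble::tibble(stratum = 1L, depth_lo = 20, depth_hi = 40,
                   n_truth = 100L, n_recovered = 100L, sensitivity = 1,
                   length_bp = 1e9),
    method = "standard", class = c("sensitivity_profile", "tbl_df", "tbl",
                                   "data.frame"))
  expect_equal(genome_burden(100, prof)$burden_per_gb, 100)
  expect_equal(genome_burden(200, prof)$burden_per_gb, 200)
  prof$sensitivity <- 0.5
  expect_equal(genome_burden(100, prof)$burden_per_gb, 200)
  # per-cell conversion constant
  expect_equal(genome_burden(100, prof)$burden_per_cell, 200 * 5.845)
})

test_that("standard and refined burden agree without zero-depth regions", {
  withr::with_seed(2, {
    bins <- mk_bins(rpois(300, 30))
    bins$depth <- pmax(bins$depth, 1)
    truth <- tibble::tibble(chrom = "chrS", pos = sort(sample(3e5, 500)))
  })
  s_std <- estimate_sensitivity(truth, truth, bins, method = "standard")
  s_ref <- estimate_sensitivity(truth, truth, bins, method = "refined")
  b_std <- genome_burden(50, s_std)
  b_ref <- genome_burden(50, s_ref)
  expect_equal(b_std$burden_per_gb, b_ref$burden_per_gb)
})

test_that("zero-depth refinement rescues cells the standard method loses", {
  withr::with_seed(3, {
    depth <- rpois(400, 30)
    calls_pos <- sort(sample(4e5, 200))
    truth <- tibble::tibble(chrom = "chrS", pos = sort(sample(4e5, 800)))
  })
  # sibling cell: full coverage
  bins_ok <- mk_bins(depth)
  s_ok <- estimate_sensitivity(truth, truth, bins_ok, method = "standard")
  calls <- tibble::tibble(chrom = "chrS", pos = calls_pos)
  b_ok <- genome_burden(calls, s_ok, depth_profile = bins_ok)

  # same cell truth, but 35% of the genome in a contiguous zero-depth block
  depth_zero <- depth
  depth_zero[100:239] <- 0L
  bins_z <- mk_bins(depth_zero)
  s_std <- estimate_sensitivity(truth, truth, bins_z, method = "standard")
  expect_equal(nrow(s_std), 0)
  expect_error(genome_burden(calls, s_std, depth_profile = bins_z),
               "refined")

  s_refined <- estimate_sensitivity(truth, truth, bins_z, method = "refined")
  b_ref <- genome_burden(calls, s_refined, depth_profile = bins_z)
  expect_true(is.finite(b_ref$burden_per_gb))
  expect_lt(abs(b_ref$burden_per_gb - b_ok$burden_per_gb) /
              b_ok$burden_per_gb, 0.1)
})

test_that("noiseless data are interpolated exactly by model 1", {
  d <- cohort_design(n_control_donors = 4, n_ihd_donors = 0,
                     cells_per_donor = 3, beta0 = 10, beta1 = 5,
                     sigma_u = 0, sigma_e = 0, seed = 1)
  cells <- simulate_burden(d)
  cells$burden_per_gb <- cells$true_burden_per_gb
  fit <- suppressWarnings(fit_burden_model(cells, model = 1))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "(Intercept)"], 10, tolerance = 1e-6)
  expect_equal(td$estimate[td$term == "age"], 5, tolerance = 1e-6)
})

test_that("balanced two-donor fits equal the closed-form GLS oracle", {
  withr::with_seed(11, {
    data <- tibble::tibble(
      donor_id = rep(c("A", "B"), each = 6),
      age = rep(c(20, 60), each = 6),
      burden_per_gb = 100 + 7 * age + rep(rnorm(2, 0, 40), each = 6) +
        rnorm(12, 0, 60))
  })
  fit <- fit_burden_model(data, model = 1)
  g <- glance(fit)
  X <- cbind(1, data$age)
  Z <- stats::model.matrix(~ 0 + donor_id, data)
  V <- g$sigma^2 * diag(12) + g$sigma_u^2 * Z %*% t(Z)
  beta_gls <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*%
                      data$burden_per_gb)
  expect_equal(unname(tidy(fit)$estimate), as.vector(beta_gls),
               tolerance = 1e-6)
})

test_that("zero between-donor variance reproduces OLS exactly", {
  # donors drawn from the same line: sigma_u estimated at the boundary,
  # fallback yields the ordinary least-squares fit
  withr::with_seed(5, {
    data <- tibble::tibble(
      donor_id = rep(sprintf("d%d", 1:6), each = 3),
      age = rep(c(10, 25, 40, 55, 70, 80), each = 3),
      burden_per_gb = 50 + 8 * age + rnorm(18, 0, 30))
  })
  fit <- suppressWarnings(fit_burden_model(data, model = 1))
  ols <- lm(burden_per_gb ~ age, data)
  if (fit$fallback || isTRUE(fit$singular)) {
    expect_equal(unname(tidy(fit)$estimate), unname(coef(ols)),
                 tolerance = 1e-8)
  } else {
    # non-singular fit: ML estimates still match OLS closely here
    expect_equal(unname(tidy(fit)$estimate), unname(coef(ols)),
                 tolerance = 1e-3)
  }
  # explicit model 3 always equals OLS
  f3 <- fit_burden_model(data, model = 3)
  expect_equal(unname(tidy(f3)$estimate), unname(coef(ols)),
               tolerance = 1e-10)
})

test_that("the aging-rate estimator is unbiased with honest CI coverage", {
  true_b1 <- 7.90
  res <- vapply(1:200, function(s) {
    d <- cohort_design(n_control_donors = 10, n_ihd_donors = 0,
                       cells_per_donor = 3, beta0 = 50, beta1 = true_b1,
                       sigma_u = 30, sigma_e = 60, seed = 5000 + s)
    cells <- simulate_burden(d, truncate = FALSE)
    cells$burden_per_gb <- cells$true_burden_per_gb
    fit <- suppressWarnings(suppressMessages(fit_burden_model(cells, 1)))
    td <- tidy(fit)
    i <- which(td$term == "age")
    ci_lo <- td$estimate[i] - stats::qt(0.975, td$df[i]) * td$std.error[i]
    ci_hi <- td$estimate[i] + stats::qt(0.975, td$df[i]) * td$std.error[i]
    c(td$estimate[i], ci_lo <= true_b1 && true_b1 <= ci_hi)
  }, numeric(2))
  mc_se <- sd(res[1, ]) / sqrt(200)
  expect_lt(abs(mean(res[1, ]) - true_b1), 2 * mc_se + 1e-9)
  expect_gte(mean(res[2, ]), 0.92)
  expect_lte(mean(res[2, ]), 0.98)
})

test_that("covariate adjustment behaves as a variance decomposition", {
  d <- cohort_design(seed = 21)
  cells <- simulate_burden(d)
  cells$burden_per_gb <- cells$true_burden_per_gb
  withr::with_seed(22, {
    noise <- rnorm(nrow(cells), 0, 80)
    cells$artifact <- noise
    cells$burden_noisy <- cells$burden_per_gb + noise
  })
  f_plain <- suppressWarnings(fit_burden_model(cells, 2,
                                               response = "burden_noisy"))
  f_adj <- suppressWarnings(adjust_covariate(cells, "artifact", 2,
                                             response = "burden_noisy"))
  expect_lt(glance(f_adj)$sigma, glance(f_plain)$sigma)

  # orthogonal covariate leaves the condition effect essentially unchanged
  t_plain <- tidy(f_plain); t_adj <- tidy(f_adj)
  bI_p <- t_plain$estimate[t_plain$term == "conditionIHD"]
  bI_a <- t_adj$estimate[t_adj$term == "conditionIHD"]
  expect_lt(abs(bI_a - bI_p), 3 * t_plain$std.error[t_plain$term == "conditionIHD"])

  # a depth-artifact confound: adjustment moves beta_I toward the truth
  withr::with_seed(23, {
    cells2 <- simulate_burden(cohort_design(seed = 23), truncate = FALSE)
    art <- ifelse(cells2$condition == "IHD", 1, 0) + rnorm(nrow(cells2), 0, 0.5)
    cells2$mapd_like <- art
    cells2$burden_per_gb <- cells2$true_burden_per_gb + 400 * art
  })
  f_raw <- suppressWarnings(fit_burden_model(cells2, 2))
  f_cov <- suppressWarnings(adjust_covariate(cells2, "mapd_like", 2))
  e_raw <- tidy(f_raw)$estimate[tidy(f_raw)$term == "conditionIHD"]
  e_cov <- tidy(f_cov)$estimate[tidy(f_cov)$term == "conditionIHD"]
  expect_lt(abs(e_cov - 686), abs(e_raw - 686))

  cells$flat <- 1
  expect_error(adjust_covariate(cells, "flat", 2), "constant")
  cells$dup_cond <- as.numeric(cells$condition == "IHD")
  expect_error(adjust_covariate(cells, "dup_cond", 2), "collinear")
})

test_that("model preconditions are enforced", {
  d <- cohort_design(n_control_donors = 3, n_ihd_donors = 0,
                     cells_per_donor = 2, seed = 1)
  cells <- simulate_burden(d)
  cells$burden_per_gb <- cells$true_burden_per_gb
  expect_error(fit_burden_model(cells, model = 2), "both conditions")
  expect_error(fit_burden_model(cells[1:2, ], model = 1), ">= 2 donors")
})
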
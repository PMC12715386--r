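test_that("expected_ratio follows the contribution model", {
  expect_equal(expected_ratio(1, 0), 7)
  expect_equal(expected_ratio(1, 1), 14)
  expect_equal(expected_ratio(3, 1), 28 / 3)
  expect_equal(expected_ratio(0, 4), Inf)
  expect_equal(expected_ratio(2, 2, rho = 5), 10)
  # mass-proportional variant replaces head count with mass fraction
  expect_equal(expected_ratio(1, 1, mode = "mass", male_mass = 5, total_mass = 20),
               7 * 4)
})

test_that("expected_ratio is strictly decreasing in the number of males", {
  for (f in 1:3) {
    vals <- vapply(1:5, function(m) expected_ratio(m, f), numeric(1))
    expect_true(all(diff(vals) < 0))
  }
  # all-male samples sit at the per-male ratio regardless of count
  expect_equal(expected_ratio(5, 0), expected_ratio(1, 0))
})

test_that("estimate_male_proportion inverts the expected-ratio model exactly", {
  expect_equal(estimate_male_proportion(1 / 7)$p_male, 1)
  expect_equal(estimate_male_proportion(0)$p_male, 0)
  expect_equal(estimate_male_proportion(1 / 14)$p_male, 0.5)
  for (m in 1:5) for (f in 0:5) {
    p <- estimate_male_proportion(1 / expected_ratio(m, f))$p_male
    expect_equal(p, m / (m + f), tolerance = 1e-12)
  }
  # raw value kept above 1, clamped value bounded
  big <- estimate_male_proportion(0.3)
  expect_gt(big$p_male_raw, 1)
  expect_equal(big$p_male, 1)
  # strictly increasing in the observed ratio
  ps <- estimate_male_proportion(seq(0, 0.13, by = 0.01))$p_male_raw
  expect_true(all(diff(ps) > 0))
})

test_that("expected_ratio_individuals pools known per-individual ratios", {
  inds <- data.frame(sex = c("M", "F"), rho_i = c(7, Inf), mass_g = c(6, 7))
  expect_equal(expected_ratio_individuals(inds), 14)
  # two males with different ratios: harmonic pooling of male contributions
  inds2 <- data.frame(sex = c("M", "M"), rho_i = c(4, 12), mass_g = c(6, 6))
  expect_equal(expected_ratio_individuals(inds2), 2 / (1 / 4 + 1 / 12))
  expect_equal(expected_ratio_individuals(data.frame(sex = "F", rho_i = Inf,
                                                     mass_g = 7)), Inf)
  # mass weighting
  inds3 <- data.frame(sex = c("M", "F"), rho_i = c(7, Inf), mass_g = c(5, 15))
  expect_equal(expected_ratio_individuals(inds3, mode = "mass"), 20 / (5 / 7))
})

test_that("mass_correct rescales ratios by the mass fraction", {
  r <- data.frame(common_to_male = 5, male_to_common = 0.2)
  out <- mass_correct(r, male_mass = 10, total_mass = 30)
  expect_equal(out$male_to_common, 0.2 * 10 / 30, tolerance = 1e-10)
  expect_true(out$mass_corrected)

  r2 <- data.frame(common_to_male = 14, male_to_common = 1 / 14)
  out2 <- mass_correct(r2, male_mass = 5, total_mass = 10)
  expect_equal(out2$common_to_male, 28)

  # all-male: identity
  out3 <- mass_correct(r, male_mass = 30, total_mass = 30)
  expect_equal(out3$common_to_male, 5)
  expect_equal(out3$male_to_common, 0.2)

  # male signal without male mass is inconsistent metadata
  expect_error(mass_correct(r, male_mass = 0, total_mass = 30), "inconsistent")
})

test_that("group labels parse the xM:yF convention", {
  out <- parse_group_label(c("3M:1F", "1M", "4F", "2M:2F"))
  expect_equal(out$n_males, c(3L, 1L, 0L, 2L))
  expect_equal(out$n_females, c(1L, 0L, 4L, 2L))
  expect_error(parse_group_label("three males"), "cannot parse")
})

test_that("calibrate recovers a noiseless linear relationship exactly", {
  # data exactly linear on the transformed (log10 + 1) scale
  p <- rep(c(0.25, 0.5, 0.75, 1), each = 3)
  r <- 10^(0.02 + 0.8 * log10(p + 1)) - 1
  fit <- suppressWarnings(calibrate(p, r, variant = "proportion"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$slope, 0.8, tolerance = 1e-9)
  expect_true(fit$slope_ci_low <= fit$slope && fit$slope <= fit$slope_ci_high)

  # expected variant on identical observed/expected: slope exactly one
  exp_r <- c(7, 9.33, 10.5, 14, 14, 21, 28)
  fit2 <- suppressWarnings(calibrate(exp_r, exp_r, variant = "expected"))
  expect_equal(fit2$slope, 1, tolerance = 1e-9)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-9)

  expect_error(calibrate(rep(0.5, 5), runif(5), variant = "proportion"),
               "degenerate")
})

test_that("the slope-equals-one test matches a direct t computation", {
  set.seed(88)
  x <- c(7, 9.33, 10.5, 14, 14, 21, 28)
  y <- x * exp(rnorm(7, 0, 0.25))
  fit <- calibrate(x, y, variant = "expected")
  lmfit <- lm(log10(y) ~ log10(x))
  se <- summary(lmfit)$coefficients[2, 2]
  t <- unname(coef(lmfit)[2] - 1) / se
  expect_equal(fit$slope_eq_one_p, unname(2 * pt(abs(t), 5, lower.tail = FALSE)),
               tolerance = 1e-10)
})

test_that("compare_groups runs the parametric branch when assumptions hold", {
  set.seed(12)
  g <- rep(c("1M:1F", "2M:1F", "1M:2F"), each = 8)
  y <- 10^(rnorm(24, mean = rep(c(1.15, 0.85, 1.3), each = 8), sd = 0.08))
  res <- compare_groups(y, g, mode = "auto")
  expect_equal(res$method, "anova_tukey")
  # omnibus agrees with a direct aov on log10 ratios
  an <- summary(aov(log10(y) ~ factor(g)))[[1]]
  expect_equal(res$statistic, an[1, "F value"], tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_true(all(c("comparison", "p_adj") %in% names(res$posthoc)))
})

test_that("compare_groups falls back to Kruskal-Wallis with Dunn-BH post hoc", {
  set.seed(13)
  g <- rep(c("A", "B", "C"), each = 7)
  y <- c(rexp(7, 1), rexp(7, 0.3), rexp(7, 0.1)) # heavily skewed
  res <- compare_groups(y, g, mode = "nonparametric", log_transform = FALSE)
  expect_equal(res$method, "kruskal_dunn_bh")
  kw <- kruskal.test(y ~ factor(g))
  expect_equal(res$statistic, unname(kw$statistic), tolerance = 1e-10)
  expect_equal(nrow(res$posthoc), 3)
  expect_true(all(res$posthoc$p_adj >= res$posthoc$p_unadj - 1e-12))
})

test_that("two-group Dunn z agrees with the Kruskal-Wallis statistic", {
  set.seed(14)
  y <- runif(16)
  g <- rep(c("A", "B"), each = 8)
  res <- compare_groups(y, g, mode = "nonparametric", log_transform = FALSE)
  expect_equal(res$posthoc$z^2, unname(kruskal.test(y ~ factor(g))$statistic),
               tolerance = 1e-10)
})

test_that("identical values across groups give a null omnibus statistic", {
  y <- rep(5, 12)
  g <- rep(c("A", "B"), each = 6)
  res <- compare_groups(y, g, mode = "nonparametric", log_transform = FALSE)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(compare_groups(rep(1, 3), c("A", "A", "A")), "two groups")
})

test_that("accuracy_vs_expected detects shifts and accepts exact agreement", {
  # exact agreement: statistic at the null centre
  res <- accuracy_vs_expected(rep(14, 5), rep("1M:1F", 5), c("1M:1F" = 14))
  expect_equal(res$p_value, 1)

  # a group shifted threefold with n = 9 is significant (exact signed-rank)
  set.seed(15)
  obs <- 14 * 3 * exp(rnorm(9, 0, 0.05))
  res2 <- accuracy_vs_expected(obs, rep("g", 9), c(g = 14))
  expect_lt(res2$p_value, 0.05)
  expect_equal(res2$statistic, 45) # all ranks positive

  # small groups are skipped with a warning
  expect_warning(
    out <- accuracy_vs_expected(c(14, 15), rep("tiny", 2), c(tiny = 14)),
    "fewer than 3")
  expect_null(out)
})

test_that("male-proportion estimates recover the truth on simulated eDNA samples", {
  cfg <- sim_config()
  comps <- list(c(1, 3), c(2, 2), c(3, 1)) # p = 0.25, 0.5, 0.75
  set.seed(2024)
  for (cmp in comps) {
    p_true <- cmp[1] / sum(cmp)
    est <- replicate(200, {
      # a group of 3 replicate tanks, averaged as a field survey would
      mean(replicate(3, {
        inds <- simulate_individuals(cmp[1], cmp[2], cfg)
        conc <- simulate_sample(inds, "edna", cfg)
        estimate_male_proportion(conc[["male"]] / conc[["common"]])$p_male
      }))
    })
    expect_lt(abs(mean(est) - p_true), 0.08)
  }
})

test_that("estimator spread shrinks as the number of males grows", {
  cfg <- sim_config()
  set.seed(2025)
  spread <- function(m, f) {
    r <- replicate(200, {
      inds <- simulate_individuals(m, f, cfg)
      conc <- simulate_sample(inds, "mock", cfg)
      log10(conc[["common"]] / conc[["male"]] / expected_ratio(m, f))
    })
    var(r)
  }
  expect_gt(spread(1, 1) / spread(3, 1), 1)
})
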
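test_that("simulate_individuals reproduces the copy-ratio distribution", {
  cfg <- sim_config()
  inds <- simulate_individuals(1000, 0, cfg, seed = 42)
  expect_true(all(inds$sex == "M"))
  expect_lt(abs(mean(inds$rho_i) - 7) / 7, 0.05)
  expect_true(abs(rsd(inds$rho_i) - 38) < 8) # clipping trims the tails a little
  expect_true(all(inds$rho_i >= 3 & inds$rho_i <= 14))

  fem <- simulate_individuals(0, 4, cfg, seed = 1)
  expect_true(all(fem$sex == "F"))
  expect_true(all(!is.finite(fem$rho_i)))
  expect_equal(simulate_sample(fem, "mock", cfg)[["male"]], 0)
})

test_that("simulation is deterministic under a fixed seed and leaves the RNG alone", {
  cfg <- sim_config()
  a <- simulate_individuals(5, 5, cfg, seed = 7)
  b <- simulate_individuals(5, 5, cfg, seed = 7)
  expect_identical(a, b)

  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(simulate_individuals(3, 3, cfg, seed = 99)); x2 <- runif(1)
  expect_identical(x1, x2)

  e1 <- simulate_experiment(seed = 11)
  e2 <- simulate_experiment(seed = 11)
  expect_identical(e1, e2)
})

test_that("simulate_sample composes contributions per the mixing model", {
  cfg <- sim_config(mock_c0 = 100, rho_rsd_pct = 0, rho_clip = NULL)
  inds <- data.frame(id = c("m", "f"), sex = c("M", "F"), mass_g = c(6, 7),
                     rho_i = c(7, Inf), shed_mult = c(1, 1))
  conc <- simulate_sample(inds, "mock", cfg)
  expect_equal(conc[["common"]], 200)
  expect_equal(conc[["male"]], 100 / 7)
  expect_equal(conc[["common"]] / conc[["male"]], 14)

  # eDNA: contribution proportional to mass when b = 1 and noise is off
  cfg2 <- sim_config(shed_cv = 0, shed_rate_per_g = 5)
  inds2 <- data.frame(id = c("m", "f"), sex = c("M", "F"), mass_g = c(10, 5),
                      rho_i = c(7, Inf), shed_mult = c(1, 1))
  conc2 <- simulate_sample(inds2, "edna", cfg2)
  expect_equal(conc2[["common"]], 5 * 15)
  expect_equal(conc2[["male"]], 5 * 10 / 7)
})

test_that("simulate_droplets yields consistent counts and a calibrated estimator", {
  cfg <- sim_config(false_pos_rate = 0)
  # zero concentration, zero false positives: never a positive droplet
  z <- simulate_droplets(c(common = 0, male = 0), n_wells = 5, cfg = cfg, seed = 3)
  expect_true(all(z$positives == 0))

  # estimator consistency: mean of per-well estimates within 2% at lambda ~ 0.1
  truth <- 0.1 / 8.5e-4 * 22 / 4 # conc whose per-droplet mean is 0.1
  w <- simulate_droplets(c(common = truth, male = 0), n_wells = 400,
                         template_volume = 4, cfg = cfg, seed = 4)
  com <- w[w$target == "common", ]
  est <- mapply(function(k, n) concentration(k, n, template_volume = 4)$conc_start,
                com$positives, com$accepted)
  expect_lt(abs(mean(est) - truth) / truth, 0.02)
})

test_that("cross-reactive droplets stay below the conservative HEX threshold", {
  cfg <- sim_config(false_pos_rate = 0.05) # inflated so some appear in one well
  out <- simulate_droplets(c(common = 700, male = 0), n_wells = 2,
                           template_volume = 4, cfg = cfg, seed = 5,
                           amplitudes = TRUE)
  male_counts <- out$counts[out$counts$target == "male", ]
  expect_gt(sum(male_counts$positives), 0) # cross-reactivity did fire
  cls <- classify_droplets(out$reads)
  expect_true(all(cls$positives[cls$target == "male"] == 0))
})

test_that("dilution series scales truth by the dilution factor", {
  cfg <- sim_config(false_pos_rate = 0)
  truth <- c(common = 686, male = 98)
  ser <- simulate_dilution_series(truth, replicates = 6, cfg = cfg, seed = 6)
  # 10% agreement is claimed only where lambda stays above ~1e-3
  for (f in c(1, 4)) {
    m <- merge_wells(ser[ser$dilution_factor == f & ser$target == "male", ])
    expect_lt(abs(m$conc_start - truth[["male"]] / f) / (truth[["male"]] / f), 0.1)
  }
  # deeper levels remain unbiased but noisier: still within 50%
  for (f in c(16, 64)) {
    m <- merge_wells(ser[ser$dilution_factor == f & ser$target == "male", ])
    expect_lt(abs(m$conc_start - truth[["male"]] / f) / (truth[["male"]] / f), 0.5)
  }
  # an all-female extract yields all-zero male wells at every level
  fem <- simulate_dilution_series(c(common = 700, male = 0), cfg = cfg, seed = 7)
  expect_true(all(fem$positives[fem$target == "male"] == 0))
})

test_that("the experiment layout matches the mock design arithmetic", {
  ex <- simulate_experiment(seed = 21)
  mock_ids <- ex$metadata$sample_id[ex$metadata$sample_type == "mock"]
  expect_equal(length(mock_ids), 7 * 3) # 7 groups x 3 series
  wells <- ex$droplets[ex$droplets$sample_id %in% mock_ids, ]
  # 3 technical replicates per sample per target
  expect_equal(nrow(wells[wells$target == "male", ]), 63)
  expect_equal(nrow(wells[wells$target == "common", ]), 63)
  # controls present: all-female and NTC per series
  expect_equal(sum(ex$metadata$sample_type == "female_control"), 3)
  expect_equal(sum(ex$metadata$sample_type == "ntc"), 3)
  # contamination off: NTC wells are empty
  ntc <- ex$droplets[grepl("^NTC", ex$droplets$sample_id), ]
  expect_true(all(ntc$positives == 0))
})

test_that("a shared low-ratio male depresses the groups it enters", {
  ex <- simulate_experiment(seed = 22, shared_male_rho = 3)
  tr <- merge(ex$truth, ex$metadata, by = "sample_id")
  tr <- tr[tr$sample_type == "mock", ]
  shared_groups <- c("1M:1F", "2M:2F", "1M:2F", "1M:3F")
  dev <- sapply(split(tr, tr$group %in% shared_groups), function(d) {
    exp_pop <- mapply(expected_ratio, d$n_males, d$n_females)
    mean(log(d$expected_cm / exp_pop))
  })
  # groups carrying the rho = 3 male sit systematically below the
  # population-average expectation; the others straddle it
  expect_lt(dev[["TRUE"]], dev[["FALSE"]])
  expect_lt(dev[["TRUE"]], 0)
})
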
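# synthetic_data: genotypes, phenotypes, volumes, truth record.

test_that("sim_config validates its stated world", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(allele_freq_ranges = list(c(0, 0.5))),
               "frequency", class = "prsvbm_validation_error")
  expect_error(sim_config(allele_freq_ranges = list(c(0.9, 0.2))),
               "frequency", class = "prsvbm_validation_error")
  expect_error(sim_config(planted_voxels = matrix(c(25, 1, 1), 1),
                          volume_shape = c(10, 10, 10)),
               "planted", class = "prsvbm_validation_error")
  expect_error(sim_config(odds_ratio_range = c(-1, 2)),
               class = "prsvbm_validation_error")
})

test_that("hard calls and degenerate frequencies behave as stated", {
  cfg <- sim_config(n_subjects = 50, n_populations = 1, dosage_noise_sd = 0,
                    allele_freq_ranges = list(c(0.3, 0.7)), seed = 71)
  g <- simulate_genotypes(cfg)
  expect_true(all(unclass(g$dosages) %in% c(0, 1, 2)))
  # near-zero frequency: column essentially monomorphic at 0
  cfg0 <- sim_config(n_subjects = 80, n_populations = 1, dosage_noise_sd = 0,
                     allele_freq_ranges = list(c(1e-9, 2e-9)), seed = 72)
  g0 <- simulate_genotypes(cfg0)
  expect_true(all(unclass(g0$dosages) == 0))
})

test_that("population means match the binomial expectation 2f", {
  cfg <- sim_config(n_subjects = 200, n_populations = 2,
                    allele_freq_ranges = list(c(0.1, 0.2), c(0.8, 0.9)),
                    dosage_noise_sd = 0, seed = 73)
  g <- simulate_genotypes(cfg)
  pop <- g$truth$population_labels
  f <- g$truth$allele_freqs
  for (k in 1:2) {
    n_k <- sum(pop == k)
    mu <- colMeans(unclass(g$dosages)[pop == k, ])
    se <- sqrt(2 * f[k, ] * (1 - f[k, ]) / n_k)
    expect_true(all(abs(mu - 2 * f[k, ]) <= 3 * se))
  }
  # the two populations differ in mean dosage
  expect_gt(mean(unclass(g$dosages)[pop == 2, ]) -
            mean(unclass(g$dosages)[pop == 1, ]), 1)
})

test_that("truth scores equal compute_prs on the emitted data, exactly", {
  cfg <- sim_config(n_subjects = 60, seed = 74)
  g <- suppressMessages(simulate_genotypes(cfg))
  sc <- compute_prs(g$dosages, g$weights)
  expect_identical(unname(g$truth$true_scores), sc$score)
  expect_identical(unname(g$truth$true_weights), g$weights$weight)
})

test_that("simulators are bitwise-deterministic under a fixed seed", {
  cfg <- sim_config(n_subjects = 40, volume_shape = c(6, 6, 6), seed = 75,
                    beta_voxel = 0.3)
  a <- suppressMessages(simulate_genotypes(cfg))
  b <- suppressMessages(simulate_genotypes(cfg))
  expect_identical(a, b)
  expect_identical(simulate_phenotypes(a$dosages, a$truth, cfg),
                   simulate_phenotypes(b$dosages, b$truth, cfg))
  expect_identical(simulate_volumes(a$truth$true_scores, cfg),
                   simulate_volumes(b$truth$true_scores, cfg))
})

test_that("phenotypes carry the planted linear effect", {
  # null: correlation with score within +-3/sqrt(n) of 0
  cfg0 <- sim_config(n_subjects = 400, outcomes = "y", beta_prs = 0, seed = 76)
  g0 <- suppressMessages(simulate_genotypes(cfg0))
  ph0 <- simulate_phenotypes(g0$dosages, g0$truth, cfg0)
  expect_lt(abs(cor(ph0$y, g0$truth$true_scores)), 3 / sqrt(400))
  # planted 0.5 with unit outcome variance recovers 0.5 +- 0.1
  cfg1 <- sim_config(n_subjects = 1000, outcomes = "y", beta_prs = 0.5,
                     sex_effect = 0, age_effect = 0,
                     noise_sd = sqrt(1 - 0.5^2), seed = 77)
  g1 <- suppressMessages(simulate_genotypes(cfg1))
  ph1 <- simulate_phenotypes(g1$dosages, g1$truth, cfg1)
  b <- coef(lm(scale(ph1$y) ~ scale(g1$truth$true_scores)))[2]
  expect_lt(abs(b - 0.5), 0.1)
})

test_that("missingness is injected at the stated rate", {
  cfg <- sim_config(outcomes = c("y1", "y2"), missing_rate = c(0.05, 0),
                    seed = 78)
  g <- suppressMessages(simulate_genotypes(cfg))
  ph <- simulate_phenotypes(g$dosages, g$truth, cfg)
  n_obs <- sum(!is.na(ph$y1))
  # binomial(1558, .95): ~1480 +- 3 sd
  expect_lt(abs(n_obs - 1558 * 0.95), 3 * sqrt(1558 * 0.05 * 0.95))
  expect_identical(sum(is.na(ph$y2)), 0L)
  # demographic margins of the stated world
  expect_true(all(ph$age >= 18 & ph$age <= 27))
  expect_true(all(ph$sex %in% 0:1))
})

test_that("volumes plant a point effect after smoothing", {
  # no smoothing, no noise: planted voxel is exactly baseline + z(score)
  cfg <- sim_config(n_subjects = 10, volume_shape = c(5, 5, 5),
                    smoothing_fwhm_voxels = 0, volume_noise_sd = 0,
                    beta_voxel = 1, planted_voxels = matrix(c(3, 3, 3), 1),
                    seed = 79)
  g <- suppressMessages(simulate_genotypes(cfg))
  st <- simulate_volumes(g$truth$true_scores, cfg)
  z <- as.vector(scale(g$truth$true_scores))
  expect_equal(st$data[, 3, 3, 3], 1 + z, tolerance = 1e-12)
  expect_equal(st$data[, 2, 3, 3], rep(1, 10), tolerance = 1e-12)
  expect_equal(st$affine, diag(c(3, 3, 3, 1)))
})

test_that("gaussian smoothing uses sigma = FWHM / 2.3548 and conserves mass", {
  fwhm <- 3
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  expect_equal(2 * sqrt(2 * log(2)), 2.3548, tolerance = 1e-4)
  # impulse response deep in the volume interior matches the separable
  # kernel, and mass is conserved away from the renormalized edges
  shape <- c(31, 31, 31)
  vol <- array(0, shape); vol[16, 16, 16] <- 1
  sm <- prsvbm:::gaussian_smooth_3d(vol, fwhm)
  half <- ceiling(4 * sigma)
  k <- dnorm(seq(-half, half), sd = sigma); k <- k / sum(k)
  k0 <- k[half + 1]
  expect_equal(sm[16, 16, 16], k0^3, tolerance = 1e-10)
  expect_equal(sm[17, 16, 16], k[half + 2] * k0^2, tolerance = 1e-10)
  expect_equal(sum(sm), 1, tolerance = 1e-10)      # interior: mass conserved
  # constant volumes stay constant (edge renormalization)
  expect_equal(prsvbm:::gaussian_smooth_3d(array(2, c(6, 6, 6)), fwhm),
               array(2, c(6, 6, 6)), tolerance = 1e-12)
})

test_that("null volumes show nominal voxelwise correlation calibration", {
  cfg <- sim_config(n_subjects = 40, volume_shape = c(6, 6, 6),
                    smoothing_fwhm_voxels = 0, beta_voxel = 0, seed = 80)
  g <- suppressMessages(simulate_genotypes(cfg))
  st <- simulate_volumes(g$truth$true_scores, cfg)
  z <- as.vector(scale(g$truth$true_scores))
  Y <- matrix(st$data, nrow = 40)
  r <- as.vector(cor(z, Y))
  crit <- qt(0.975, 38) / sqrt(38 + qt(0.975, 38)^2)
  frac <- mean(abs(r) > crit)
  expect_gt(frac, 0.01); expect_lt(frac, 0.10)
})

test_that("write_simulation emits the plain-text interface round-trippably", {
  cfg <- sim_config(n_subjects = 15, volume_shape = c(4, 4, 4),
                    outcomes = c("y1", "y2"), seed = 81)
  sim <- suppressMessages(simulate_genotypes(cfg))
  sim$phenotypes <- simulate_phenotypes(sim$dosages, sim$truth, cfg)
  sim$volumes <- simulate_volumes(sim$truth$true_scores, cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  wt <- suppressMessages(load_weights(paths["weights"]))
  expect_equal(wt$weight, sim$weights$weight, tolerance = 1e-10)
  d <- suppressMessages(load_dosages(paths["dosages"], wt))
  expect_equal(unclass(d), unclass(sim$dosages), tolerance = 1e-10,
               ignore_attr = TRUE)
  nii <- read_nifti(paths["volumes"])
  expect_equal(aperm(nii$data, c(4, 1, 2, 3)), sim$volumes$data,
               tolerance = 1e-5)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(unname(truth$true_scores),
               unname(sim$truth$true_scores), tolerance = 1e-10)
})
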
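# vbm_mapper: mask, voxelwise GLM, max-T FWE, clusters, extraction.

test_that("build_mask keeps voxels above threshold in every subject", {
  st <- toy_stack(n = 8, shape = c(4, 4, 4), seed = 51)
  expect_identical(build_mask(st)$n_voxels, 64L)     # all intensities ~1
  st$data[3, 2, 2, 2] <- 0                           # one subject at 0
  m <- build_mask(st)
  expect_false(m$data[2, 2, 2])
  expect_identical(m$n_voxels, 63L)
  # brute-force oracle: per-voxel minimum over subjects
  mins <- apply(st$data, c(2, 3, 4), min)
  expect_identical(m$data, mins > 0.05)
  st$data[] <- 0
  expect_error(build_mask(st), "empty", class = "prsvbm_validation_error")
})

test_that("voxelwise_glm equals a per-voxel lm loop", {
  n <- 20
  td <- toy_design(n = n, seed = 52)
  st <- toy_stack(n = n, shape = c(5, 5, 5), seed = 53)
  mask <- build_mask(st)
  tm <- voxelwise_glm(st, td$design, mask)
  X <- td$design$X
  for (v in list(c(1, 1, 1), c(3, 4, 2), c(5, 5, 5))) {
    y <- st$data[, v[1], v[2], v[3]]
    t_lm <- summary(lm(y ~ X - 1))$coefficients["Xscore", "t value"]
    expect_equal(tm[v[1], v[2], v[3]], t_lm, tolerance = 1e-8)
  }
  # exact linear voxel dominates the map
  st2 <- st
  st2$data[, 2, 2, 2] <- 1 + 0.5 * X[, "score"]
  tm2 <- voxelwise_glm(st2, td$design, build_mask(st2))
  expect_identical(which.max(abs(tm2)), 2L + (2L - 1L) * 5L + (2L - 1L) * 25L)
  # zero-variance voxel gets t = 0
  st3 <- st
  st3$data[, 1, 1, 1] <- 1
  tm3 <- voxelwise_glm(st3, td$design, build_mask(st3))
  expect_identical(tm3[1, 1, 1], 0)
})

test_that("t-map is invariant to a common subject reordering", {
  n <- 15
  td <- toy_design(n = n, seed = 54)
  st <- toy_stack(n = n, shape = c(4, 3, 3), seed = 55)
  mask <- build_mask(st)
  tm <- voxelwise_glm(st, td$design, mask)
  set.seed(56); ord <- sample(n)
  st_p <- volume_stack(st$data[ord, , , , drop = FALSE], st$affine,
                       st$subject_ids[ord])
  ph_p <- td$ph[ord, ]; sc_p <- td$scores[ord, ]
  tm_p <- voxelwise_glm(st_p, build_design(ph_p, sc_p), mask)
  expect_equal(tm_p, tm, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("maxT_fwe on a one-voxel mask equals the one-sided permutation p", {
  n <- 30
  td <- toy_design(n = n, seed = 57)
  st <- toy_stack(n = n, shape = c(3, 3, 3), seed = 58,
                  effect_voxel = c(2, 2, 2), beta = 0.4,
                  score = td$design$X[, "score"])
  mask1 <- structure(list(data = array(FALSE, c(3, 3, 3)), n_voxels = 1L),
                     class = "vbm_mask")
  mask1$data[2, 2, 2] <- TRUE
  sm <- maxT_fwe(st, td$design, mask1, B = 300, seed = 59)
  pp <- permutation_pvalue(td$design, st$data[, 2, 2, 2], B = 300, seed = 59,
                           alternative = "greater")
  expect_identical(sm$p_fwe_map[2, 2, 2], pp$p_perm)
  expect_equal(sm$t_map[2, 2, 2], pp$t_obs, tolerance = 1e-10)
})

test_that("maxT_fwe respects direction, floor and the B = 1 degenerate case", {
  n <- 25
  td <- toy_design(n = n, seed = 60)
  st <- toy_stack(n = n, shape = c(4, 4, 4), seed = 61,
                  effect_voxel = c(3, 3, 3), beta = 1, base = 4,
                  score = td$design$X[, "score"])
  mask <- build_mask(st)
  smp <- maxT_fwe(st, td$design, mask, B = 200, seed = 62)
  expect_identical(smp$p_fwe_map[3, 3, 3], 1 / 200)   # strong planted effect
  expect_true(smp$significant[3, 3, 3])
  expect_length(smp$max_t_distribution, 200)
  # p_fwe never below the single-voxel permutation p (correction is
  # conservative relative to an uncorrected test at the same voxel)
  pp <- permutation_pvalue(td$design, st$data[, 3, 3, 3], B = 200, seed = 62,
                           alternative = "greater")
  expect_gte(smp$p_fwe_map[3, 3, 3], pp$p_perm)
  # negative direction does not flag the positive effect
  smn <- maxT_fwe(st, td$design, mask, B = 200, seed = 62,
                  direction = "negative")
  expect_false(smn$significant[3, 3, 3])
  # B = 1: p is 1 or 1/1 everywhere, defined
  sm1 <- maxT_fwe(st, td$design, mask, B = 1, seed = 63)
  expect_true(all(sm1$p_fwe_map == 1))
})

test_that("p_fwe is nonincreasing in t within a map", {
  n <- 20
  td <- toy_design(n = n, seed = 64)
  st <- toy_stack(n = n, shape = c(4, 4, 3), seed = 65)
  mask <- build_mask(st)
  sm <- maxT_fwe(st, td$design, mask, B = 100, seed = 66)
  tv <- sm$t_map[mask$data]; pv <- sm$p_fwe_map[mask$data]
  ord <- order(tv)
  expect_true(all(diff(pv[ord]) <= 1e-12))
})

test_that("cluster_extent labels components per connectivity semantics", {
  shape <- c(6, 6, 6)
  tm <- array(0, shape)
  df <- 20
  thr <- qt(0.001, df, lower.tail = FALSE)
  # L-shaped face-adjacent triple -> one cluster of size 3
  tm[2, 2, 2] <- thr + 1; tm[3, 2, 2] <- thr + 2; tm[3, 3, 2] <- thr + 0.5
  mask <- full_mask(shape)
  rep18 <- cluster_extent(tm, mask, df = df)
  expect_identical(nrow(rep18), 1L)
  expect_identical(rep18$size_voxels, 3L)
  expect_identical(c(rep18$peak_i, rep18$peak_j, rep18$peak_k), c(3L, 2L, 2L))
  # corner-sharing pair: one cluster at 26-connectivity, two at 6
  tm2 <- array(0, shape)
  tm2[1, 1, 1] <- thr + 1; tm2[2, 2, 2] <- thr + 1
  expect_identical(nrow(cluster_extent(tm2, mask, df = df, connectivity = 26)), 1L)
  expect_identical(nrow(cluster_extent(tm2, mask, df = df, connectivity = 6)), 2L)
  # edge-sharing pair: joined at 18, separate at 6
  tm3 <- array(0, shape)
  tm3[1, 1, 1] <- thr + 1; tm3[2, 2, 1] <- thr + 1
  expect_identical(nrow(cluster_extent(tm3, mask, df = df, connectivity = 18)), 1L)
  expect_identical(nrow(cluster_extent(tm3, mask, df = df, connectivity = 6)), 2L)
  # empty report allowed
  expect_identical(nrow(cluster_extent(array(0, shape), mask, df = df)), 0L)
})

test_that("peak world coordinates follow the affine", {
  shape <- c(5, 5, 5)
  tm <- array(0, shape); tm[4, 2, 5] <- 10
  aff <- diag(c(1.5, 1.5, 1.5, 1)); aff[1:3, 4] <- c(-3, -3, -3)
  rep <- cluster_extent(tm, full_mask(shape), df = 30, affine = aff)
  # world = affine %*% (0-based index, 1)
  expect_equal(c(rep$peak_x, rep$peak_y, rep$peak_z),
               as.vector(aff %*% c(3, 1, 4, 1))[1:3])
})

test_that("extract_cluster_values averages the selected voxels", {
  st <- toy_stack(n = 6, shape = c(3, 3, 3), seed = 67)
  # single voxel: exactly those intensities
  sel <- array(FALSE, c(3, 3, 3)); sel[2, 1, 3] <- TRUE
  expect_equal(unname(extract_cluster_values(st, sel)), st$data[, 2, 1, 3])
  # uniform volume: constant vector
  st2 <- st; for (s in 1:6) st2$data[s, , , ] <- s
  sel2 <- array(FALSE, c(3, 3, 3)); sel2[c(1, 5, 20)] <- TRUE
  expect_equal(unname(extract_cluster_values(st2, sel2)), as.numeric(1:6))
  # brute-force mean oracle on an index-matrix voxel set
  vox <- rbind(c(1, 1, 1), c(3, 2, 1), c(2, 3, 3))
  got <- extract_cluster_values(st, vox)
  oracle <- sapply(1:6, function(s) mean(st$data[s, , , ][vox]))
  expect_equal(unname(got), oracle, tolerance = 1e-12)
  expect_error(extract_cluster_values(st, array(FALSE, c(3, 3, 3))),
               "empty", class = "prsvbm_validation_error")
})

test_that("write_stat_map emits readable volumes and the max-T TSV", {
  n <- 12
  td <- toy_design(n = n, seed = 68)
  st <- toy_stack(n = n, shape = c(3, 3, 3), seed = 69)
  sm <- maxT_fwe(st, td$design, build_mask(st), B = 50, seed = 70)
  dir <- withr::local_tempdir()
  paths <- write_stat_map(sm, file.path(dir, "out"), affine = st$affine)
  tm <- read_nifti(paths[1])
  expect_equal(tm$data, sm$t_map, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(tm$affine, st$affine, tolerance = 1e-6)
  mt <- read.table(paths[3], header = TRUE, sep = "\t")
  expect_equal(mt$max_t, sm$max_t_distribution, tolerance = 1e-6)
})
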
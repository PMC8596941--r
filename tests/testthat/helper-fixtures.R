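# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

toy_weights <- function(m = 4, or = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(or)) or <- round(runif(m, 1.05, 1.25), 3)
  weight_table(data.frame(
    id = sprintf("rs%03d", seq_len(m)),
    chr = "1", pos = seq_len(m) * 1000L,
    effect_allele = rep(c("A", "C", "G", "T"), length.out = m),
    other_allele = rep(c("G", "T", "A", "C"), length.out = m),
    OR = or, stringsAsFactors = FALSE))
}

toy_dosages <- function(n = 10, weights = toy_weights(), seed = 2) {
  set.seed(seed)
  m <- nrow(weights)
  dosage_matrix(matrix(round(runif(n * m, 0, 2), 3), n, m),
                sprintf("S%03d", seq_len(n)), weights$id)
}

# Minimal design with sex, age and a score column; returns the pieces a
# test usually needs.
toy_design <- function(n = 40, seed = 3, beta = 0, noise_sd = 1) {
  set.seed(seed)
  ph <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                   sex = rbinom(n, 1, 0.5), age = runif(n, 18, 27),
                   stringsAsFactors = FALSE)
  sc <- data.frame(subject_id = ph$subject_id, score = rnorm(n),
                   stringsAsFactors = FALSE)
  y <- beta * sc$score + 0.2 * ph$sex + rnorm(n, 0, noise_sd)
  list(design = build_design(ph, sc), ph = ph, scores = sc, y = y)
}

# Small volume stack with optional linear score effect at one voxel.
toy_stack <- function(n = 20, shape = c(5, 5, 5), seed = 4,
                      effect_voxel = NULL, beta = 0, score = NULL,
                      base = 1) {
  set.seed(seed)
  dat <- array(base + rnorm(n * prod(shape), 0, 0.2), c(n, shape))
  if (!is.null(effect_voxel)) {
    z <- as.vector(scale(score))
    dat[cbind(seq_len(n), matrix(rep(effect_voxel, each = n), n))] <-
      dat[cbind(seq_len(n), matrix(rep(effect_voxel, each = n), n))] + beta * z
  }
  volume_stack(dat, affine = diag(c(3, 3, 3, 1)),
               subject_ids = sprintf("S%03d", seq_len(n)))
}

full_mask <- function(shape) {
  structure(list(data = array(TRUE, shape), n_voxels = prod(shape)),
            class = "vbm_mask")
}

# Independent exhaustive Freedman-Lane oracle: enumerates every
# permutation and refits the full model with lm() each time.
exhaustive_perm_oracle <- function(X, score_col, y) {
  n <- nrow(X)
  Z <- X[, setdiff(colnames(X), score_col), drop = FALSE]
  red <- lm.fit(Z, y)
  f <- red$fitted.values; r <- red$residuals
  tstat <- function(yy) {
    fit <- lm(yy ~ X - 1)
    summary(fit)$coefficients[paste0("X", score_col), "t value"]
  }
  t_obs <- tstat(y)
  perms <- prsvbm:::enumerate_permutations(n)
  tstar <- apply(perms, 2, function(p) tstat(f + r[p]))
  eps <- 1e-8 * (1 + abs(t_obs))    # same tie slack as the implementation
  max(sum(abs(tstar) >= abs(t_obs) - eps) / ncol(perms), 1 / ncol(perms))
}
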
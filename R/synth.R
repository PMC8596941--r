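## Synthetic genotypes, phenotypes and volumes with planted effects.
##
## The generator states a small world with the statistical structure the
## analysis assumes: discrete subpopulations with distinct allele
## frequencies (so the genetic PCs have something to find), outcomes
## that are linear in the standardized score plus sex/age effects and
## Gaussian noise, and smoothed noise volumes with a point effect of the
## score planted at known voxels. A ground-truth record accompanies
## every dataset so recovery can be tested.

#' Names of the simulated outcome battery
#'
#' Fourteen outcomes mirroring a cognitive/mood battery: a fluid
#' intelligence test, a mass intelligence test, digit span, four
#' divergent-thinking scores plus their total, four speeded
#' color-word-interference scores, a depression inventory, and a total
#' mood disturbance score.
#' @return character vector of length 14.
#' @export
default_outcomes <- function() {
  c("rapm", "tbit_total", "digit_span", "sa_total", "sa_fluency",
    "sa_flexibility", "sa_originality", "sa_elaboration", "word_color",
    "color_word", "reverse_stroop", "stroop", "bdi", "poms_tmd")
}

#' Simulation configuration
#'
#' Defaults state the emulated study: 1,558 subjects (899 male, 659
#' female), 24 risk loci with odds ratios in `[1.05, 1.25]`, age uniform
#' on `[18, 27]`, two subpopulations whose per-variant allele
#' frequencies are drawn independently from `[0.1, 0.9]` (strong but
#' direction-random differentiation), 14 null outcomes, and 20x20x20 volumes
#' at 3 mm voxels smoothed at 8 mm FWHM (8/3 voxels).
#'
#' @param n_subjects number of subjects.
#' @param n_variants number of risk loci.
#' @param n_populations number of discrete subpopulations (>= 1).
#' @param allele_freq_ranges list of per-population `c(lo, hi)` allele
#'   frequency intervals in (0, 1); recycled to `n_populations`.
#' @param odds_ratio_range `c(lo, hi)` interval for simulated ORs.
#' @param dosage_noise_sd sd of the truncated Gaussian blur applied to
#'   hard allele counts (imputation-uncertainty model); 0 gives hard
#'   calls in {0, 1, 2}.
#' @param male_fraction fraction of subjects coded sex = 1.
#' @param age_range uniform age interval in years.
#' @param outcomes outcome names.
#' @param beta_prs standardized score effect per outcome (recycled).
#' @param sex_effect,age_effect covariate effects on every outcome (the
#'   age effect applies to z-scored age).
#' @param noise_sd residual sd of each outcome.
#' @param missing_rate per-outcome completely-at-random missingness
#'   probability (recycled).
#' @param volume_shape 3D integer triple.
#' @param voxel_size_mm physical voxel size.
#' @param smoothing_fwhm_voxels Gaussian smoothing FWHM in voxels
#'   (sigma = FWHM / (2 sqrt(2 ln 2)) = FWHM / 2.3548).
#' @param planted_voxels integer matrix (rows = 1-based voxel triples)
#'   where the score effect is added; defaults to the volume center.
#' @param beta_voxel intensity added per SD of score at planted voxels.
#' @param volume_baseline offset keeping in-brain intensities above the
#'   mask threshold.
#' @param volume_noise_sd sd of the pre-smoothing voxel noise.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 1558,
                       n_variants = 24,
                       n_populations = 2,
                       allele_freq_ranges = list(c(0.1, 0.9), c(0.1, 0.9)),
                       odds_ratio_range = c(1.05, 1.25),
                       dosage_noise_sd = 0.05,
                       male_fraction = 899 / 1558,
                       age_range = c(18, 27),
                       outcomes = default_outcomes(),
                       beta_prs = 0,
                       sex_effect = 0.2,
                       age_effect = 0.05,
                       noise_sd = 1,
                       missing_rate = 0,
                       volume_shape = c(20, 20, 20),
                       voxel_size_mm = c(3, 3, 3),
                       smoothing_fwhm_voxels = 8 / 3,
                       planted_voxels = NULL,
                       beta_voxel = 0,
                       volume_baseline = 1,
                       volume_noise_sd = 1,
                       seed = 1) {
  if (is.null(planted_voxels))
    planted_voxels <- matrix(ceiling(as.integer(volume_shape) / 2), 1)
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_variants = as.integer(n_variants),
              n_populations = as.integer(n_populations),
              allele_freq_ranges = rep(allele_freq_ranges,
                                       length.out = n_populations),
              odds_ratio_range = odds_ratio_range,
              dosage_noise_sd = dosage_noise_sd,
              male_fraction = male_fraction,
              age_range = age_range,
              outcomes = outcomes,
              beta_prs = rep(beta_prs, length.out = length(outcomes)),
              sex_effect = sex_effect, age_effect = age_effect,
              noise_sd = noise_sd,
              missing_rate = rep(missing_rate, length.out = length(outcomes)),
              volume_shape = as.integer(volume_shape),
              voxel_size_mm = voxel_size_mm,
              smoothing_fwhm_voxels = smoothing_fwhm_voxels,
              planted_voxels = matrix(as.integer(planted_voxels),
                                      ncol = 3,
                                      dimnames = NULL),
              beta_voxel = beta_voxel,
              volume_baseline = volume_baseline,
              volume_noise_sd = volume_noise_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_subjects < 2 || cfg$n_variants < 1 || cfg$n_populations < 1)
    stop_validation("n_subjects, n_variants and n_populations must be positive")
  for (r in cfg$allele_freq_ranges) {
    if (length(r) != 2 || r[1] <= 0 || r[2] >= 1 || r[1] > r[2])
      stop_validation("allele frequency ranges must lie within (0, 1)")
  }
  if (any(cfg$odds_ratio_range <= 0))
    stop_validation("odds ratios must be positive")
  if (any(cfg$volume_shape < 1))
    stop_validation("volume_shape must be positive")
  if (cfg$smoothing_fwhm_voxels < 0 || cfg$noise_sd <= 0 ||
      cfg$volume_noise_sd < 0)
    stop_validation("noise and smoothing parameters must be nonnegative (noise_sd > 0)")
  pv <- cfg$planted_voxels
  if (nrow(pv) && (any(pv < 1) || any(sweep(pv, 2, cfg$volume_shape, ">"))))
    stop_validation("planted voxels fall outside volume_shape")
  invisible(cfg)
}

#' Simulate genotype dosages, a weight table and the truth record
#'
#' Subjects are split as evenly as possible across populations; each
#' population draws per-variant allele frequencies uniformly from its
#' own interval. Hard genotypes are binomial(2, f) effect-allele counts;
#' with `dosage_noise_sd > 0` they are blurred by truncated Gaussian
#' noise and clipped to `[0, 2]`, emulating imputation uncertainty.
#' Odds ratios are drawn uniformly from `odds_ratio_range`. The emitted
#' `truth$true_scores` are computed by [compute_prs()] on the emitted
#' dosages, so downstream scoring can be checked exactly.
#'
#' @param cfg a [sim_config()].
#' @return list: `dosages` ([dosage_matrix()]), `weights`
#'   ([weight_table()]), `truth` (list: `true_weights`, `true_scores`,
#'   `population_labels`, `allele_freqs`, `planted_voxels`, `beta_prs`).
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_subjects; m <- cfg$n_variants
  pop <- rep(seq_len(cfg$n_populations), length.out = n)
  freqs <- t(vapply(seq_len(cfg$n_populations), function(k) {
    r <- cfg$allele_freq_ranges[[k]]
    stats::runif(m, r[1], r[2])
  }, numeric(m)))                          # populations x variants
  if (cfg$n_populations == 1) dim(freqs) <- c(1, m)
  counts <- matrix(stats::rbinom(n * m, 2, freqs[pop, ]), n, m)
  dos <- counts
  if (cfg$dosage_noise_sd > 0)
    dos <- pmin(pmax(counts + stats::rnorm(n * m, 0, cfg$dosage_noise_sd), 0), 2)
  subject_ids <- sprintf("S%04d", seq_len(n))
  variant_ids <- sprintf("rs%05d", seq_len(m))
  alleles <- c("A", "C", "G", "T")
  eff <- sample(alleles, m, replace = TRUE)
  oth <- vapply(eff, function(a) sample(setdiff(alleles, a), 1), "")
  wt <- weight_table(data.frame(
    id = variant_ids, chr = as.character(sample(1:22, m, replace = TRUE)),
    pos = sort(sample.int(5e7, m)), effect_allele = eff, other_allele = oth,
    OR = stats::runif(m, cfg$odds_ratio_range[1], cfg$odds_ratio_range[2]),
    stringsAsFactors = FALSE))
  dmat <- dosage_matrix(dos, subject_ids, variant_ids)
  prs <- compute_prs(dmat, wt)
  truth <- list(true_weights = stats::setNames(wt$weight, wt$id),
                true_scores = stats::setNames(prs$score, prs$subject_id),
                population_labels = stats::setNames(pop, subject_ids),
                allele_freqs = freqs,
                planted_voxels = cfg$planted_voxels,
                beta_prs = stats::setNames(cfg$beta_prs, cfg$outcomes))
  list(dosages = dmat, weights = wt, truth = truth)
}

#' Simulate a phenotype table with planted score effects
#'
#' Each outcome is `beta_prs * z(score) + sex_effect * sex +
#' age_effect * z(age) + N(0, noise_sd)`. Sex is Bernoulli
#' (`male_fraction`), age uniform on `age_range`. Missing values are
#' injected completely at random per outcome at `missing_rate`.
#'
#' @param dosages a [dosage_matrix()] (provides subject ids/count).
#' @param truth truth record from [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @return data.frame: `subject_id`, `sex`, `age`, one column per
#'   outcome.
#' @export
simulate_phenotypes <- function(dosages, truth, cfg) {
  n <- nrow(dosages)
  if (length(truth$true_scores) != n)
    stop_validation("truth record does not match dosage matrix dimensions")
  set.seed(cfg$seed + 1L)
  sex <- stats::rbinom(n, 1, cfg$male_fraction)
  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  z <- function(x) as.vector(scale(x))
  zs <- z(truth$true_scores)
  ph <- data.frame(subject_id = rownames(dosages), sex = sex, age = age,
                   stringsAsFactors = FALSE)
  for (k in seq_along(cfg$outcomes)) {
    y <- cfg$beta_prs[k] * zs + cfg$sex_effect * sex +
      cfg$age_effect * z(age) + stats::rnorm(n, 0, cfg$noise_sd)
    if (cfg$missing_rate[k] > 0)
      y[stats::runif(n) < cfg$missing_rate[k]] <- NA
    ph[[cfg$outcomes[k]]] <- y
  }
  ph
}

## Separable Gaussian smoothing of a 3D array; kernel truncated at 4 sigma,
## renormalized at the edges (so a constant array stays constant).
gaussian_smooth_3d <- function(vol, fwhm_voxels) {
  if (fwhm_voxels <= 0) return(vol)
  sigma <- fwhm_voxels / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = d[axis])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wsum <- numeric(n)
    for (j in seq_along(k)) {
      off <- j - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
      wsum[ok] <- wsum[ok] + k[j]
    }
    out <- out / wsum
    dim(out) <- d[perm]
    aperm(out, order(perm))
  }
  for (ax in 1:3) vol <- smooth_axis(vol, ax)
  vol
}

#' Simulate subject volumes with a planted score effect
#'
#' Each subject's volume is `baseline + smooth(N(0, volume_noise_sd))`
#' with Gaussian smoothing at `smoothing_fwhm_voxels`; then each planted
#' voxel receives `beta_voxel * z(score)` (added after smoothing, a
#' point effect). The baseline keeps all intensities above the default
#' mask threshold with overwhelming probability.
#'
#' @param scores per-subject numeric scores (named or aligned).
#' @param cfg a [sim_config()].
#' @return a [volume_stack()] with the affine implied by
#'   `voxel_size_mm`.
#' @export
simulate_volumes <- function(scores, cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 2L)
  n <- length(scores)
  shp <- cfg$volume_shape
  zs <- if (stats::sd(scores) > 0) as.vector(scale(scores)) else numeric(n)
  data <- array(0, c(n, shp))
  pv <- cfg$planted_voxels
  for (s in seq_len(n)) {
    vol <- cfg$volume_baseline +
      gaussian_smooth_3d(array(stats::rnorm(prod(shp), 0, cfg$volume_noise_sd), shp),
                         cfg$smoothing_fwhm_voxels)
    if (nrow(pv) && cfg$beta_voxel != 0)
      vol[pv] <- vol[pv] + cfg$beta_voxel * zs[s]
    data[s, , , ] <- vol
  }
  affine <- diag(c(cfg$voxel_size_mm, 1))
  volume_stack(data, affine = affine,
               subject_ids = if (!is.null(names(scores))) names(scores)
                             else sprintf("S%04d", seq_len(n)))
}

#' Write a simulated dataset to disk
#'
#' Emits the plain-text external interface: dosage TSV, weight TSV,
#' phenotype TSV, one 4D NIfTI of subject volumes, and a truth JSON.
#'
#' @param sim list with `dosages`, `weights`, `truth` (from
#'   [simulate_genotypes()]), plus optional `phenotypes` and `volumes`.
#' @param dir output directory (created if needed).
#' @return invisible named character vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(dosages = file.path(dir, "dosages.tsv"),
             weights = file.path(dir, "weights.tsv"),
             truth = file.path(dir, "truth.json"))
  dos <- data.frame(subject_id = rownames(sim$dosages),
                    unclass(sim$dosages), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(dos, paths["dosages"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(sim$weights)[
      c("id", "chr", "pos", "effect_allele", "other_allele", "OR")],
    paths["weights"], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$allele_freqs <- as.data.frame(truth$allele_freqs)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  if (!is.null(sim$phenotypes)) {
    paths["phenotypes"] <- file.path(dir, "phenotypes.tsv")
    utils::write.table(sim$phenotypes, paths["phenotypes"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sim$volumes)) {
    paths["volumes"] <- file.path(dir, "volumes.nii")
    # NIfTI stores x,y,z,subject; the stack holds subject first
    write_nifti(aperm(sim$volumes$data, c(2, 3, 4, 1)), paths["volumes"],
                affine = sim$volumes$affine)
  }
  invisible(paths)
}
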
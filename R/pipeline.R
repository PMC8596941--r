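## End-to-end orchestration: simulate -> score -> PCs -> association
## table -> voxelwise maps -> post hoc correlations, from a config file.

#' Pipeline configuration
#'
#' Defaults mirror the conventional analysis constants: 6 genetic PCs,
#' 5,000 permutations for both behavioral and imaging inference, FDR
#' level 0.05, mask threshold 0.05, cluster-forming p 0.001.
#'
#' @param weights,dosages,phenotypes,volumes input paths; leave `NULL`
#'   and supply `simulate` to generate inputs instead.
#' @param simulate optional [sim_config()] block.
#' @param K_pcs number of genetic principal components.
#' @param B_behavior,B_imaging permutation counts.
#' @param q_fdr FDR level.
#' @param mask_threshold intensity mask cutoff.
#' @param cluster_p cluster-forming uncorrected p.
#' @param scheme permutation scheme.
#' @param outcomes outcome columns to test (default: all phenotype
#'   columns other than `subject_id`, `sex`, `age`).
#' @param run_vbm run the voxelwise stage when volumes are available.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(weights = NULL, dosages = NULL, phenotypes = NULL,
                            volumes = NULL, simulate = NULL, K_pcs = 6,
                            B_behavior = 5000, B_imaging = 5000,
                            q_fdr = 0.05, mask_threshold = 0.05,
                            cluster_p = 0.001, scheme = "freedman_lane",
                            outcomes = NULL, run_vbm = TRUE,
                            seed = 1, out_dir = "prsvbm_out") {
  stopifnot(K_pcs >= 0, B_behavior >= 1, B_imaging >= 1,
            q_fdr > 0, q_fdr < 1, cluster_p > 0, cluster_p < 1)
  if (is.null(simulate) && (is.null(weights) || is.null(dosages) || is.null(phenotypes)))
    stop_validation("either a simulate block or weights+dosages+phenotypes paths are required")
  structure(list(weights = weights, dosages = dosages,
                 phenotypes = phenotypes, volumes = volumes,
                 simulate = simulate, K_pcs = K_pcs,
                 B_behavior = B_behavior, B_imaging = B_imaging,
                 q_fdr = q_fdr, mask_threshold = mask_threshold,
                 cluster_p = cluster_p, scheme = scheme,
                 outcomes = outcomes, run_vbm = isTRUE(run_vbm),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys matching the arguments of [pipeline_config()]; a `simulate`
#' mapping is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    if (!is.null(y$simulate$planted_voxels))
      y$simulate$planted_voxels <- matrix(unlist(y$simulate$planted_voxels),
                                          ncol = 3, byrow = TRUE)
    if (!is.null(y$simulate$allele_freq_ranges))
      y$simulate$allele_freq_ranges <- lapply(y$simulate$allele_freq_ranges, unlist)
    y$simulate <- do.call(sim_config, y$simulate)
  }
  do.call(pipeline_config, y)
}

#' Run the full pipeline
#'
#' Stages: (1) load or simulate inputs; (2) polygenic scores; (3)
#' genetic PCs; (4) per-outcome association table with permutation and
#' two-stage-FDR p-values; (5) when volumes are present, voxelwise
#' regression with max-T FWE correction in both directions plus
#' cluster-extent reports; (6) post hoc sex-stratified correlations
#' among score, significant outcomes and cluster values. Every stage's
#' outputs and all parameters/seeds land under `out_dir`, with a
#' `manifest.json` making the run reproducible.
#'
#' @param config a [pipeline_config()].
#' @return invisible list of in-memory results (`scores`, `pcs`,
#'   `association`, `stat_maps`, `clusters`, `posthoc`, `manifest`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  ## stage 1: inputs
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      g <- simulate_genotypes(config$simulate)
      g$phenotypes <- simulate_phenotypes(g$dosages, g$truth, config$simulate)
      g$volumes <- simulate_volumes(g$truth$true_scores, config$simulate)
      g
    })
    write_simulation(sim, file.path(config$out_dir, "inputs"))
    weights <- sim$weights; dosages <- sim$dosages
    phenotypes <- sim$phenotypes; volumes <- sim$volumes
  } else {
    weights <- stage("load_weights", load_weights(config$weights))
    fmt <- if (grepl("\\.vcf(\\.gz)?$", config$dosages)) "vcf" else "tsv"
    dosages <- stage("load_dosages", load_dosages(config$dosages, weights, fmt))
    phenotypes <- stage("load_phenotypes",
      utils::read.table(config$phenotypes, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE))
    volumes <- NULL
    if (!is.null(config$volumes)) {
      nii <- stage("load_volumes", read_nifti(config$volumes))
      volumes <- volume_stack(aperm(nii$data, c(4, 1, 2, 3)),
                              affine = nii$affine,
                              subject_ids = phenotypes$subject_id)
    }
  }
  note("inputs: %d subjects, %d variants", nrow(dosages), ncol(dosages))

  ## stage 2: scores
  scores <- stage("score", compute_prs(dosages, weights))
  utils::write.table(scores, file.path(config$out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 3: PCs
  pcs <- stage("pca", top_pcs(dosages, K = config$K_pcs))
  write_pcs(pcs, file.path(config$out_dir, "pcs.tsv"))
  note("pca: %d components over %d variants", ncol(pcs$components),
       pcs$n_variants_used)

  ## stage 4: association table
  outcomes <- config$outcomes
  if (is.null(outcomes))
    outcomes <- setdiff(names(phenotypes), c("subject_id", "sex", "age"))
  assoc <- stage("assoc",
    run_association_table(phenotypes, scores, pcs, outcomes,
                          B = config$B_behavior, seed = config$seed,
                          scheme = config$scheme, q = config$q_fdr))
  write_association_table(assoc, file.path(config$out_dir, "association.tsv"))
  note("assoc: %d outcomes, n range %d-%d", nrow(assoc), min(assoc$n), max(assoc$n))

  ## stage 5: voxelwise maps
  stat_maps <- NULL; clusters <- NULL; posthoc <- NULL
  design <- build_design(phenotypes, scores, pcs)
  if (!is.null(volumes) && config$run_vbm) {
    mask <- stage("vbm", build_mask(volumes, config$mask_threshold))
    note("vbm: %d voxels in mask", mask$n_voxels)
    stat_maps <- lapply(c(positive = "positive", negative = "negative"),
      function(dir) stage("vbm",
        maxT_fwe(volumes, design, mask, B = config$B_imaging,
                 seed = config$seed, direction = dir)))
    clusters <- lapply(stat_maps, function(sm) {
      tm <- if (sm$direction == "positive") sm$t_map else -sm$t_map
      cluster_extent(tm, mask, df = sm$df, p_uncorrected = config$cluster_p,
                     affine = volumes$affine)
    })
    for (dir in names(stat_maps)) {
      write_stat_map(stat_maps[[dir]],
                     file.path(config$out_dir, paste0("vbm_", dir)),
                     affine = volumes$affine)
      utils::write.table(clusters[[dir]],
                         file.path(config$out_dir, paste0("clusters_", dir, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      note("vbm %s: %d significant voxel(s), %d cluster(s) at p<%g",
           dir, sum(stat_maps[[dir]]$significant), nrow(clusters[[dir]]),
           config$cluster_p)
    }

    ## stage 6: post hoc sex-stratified correlations
    posthoc <- stage("posthoc", {
      vars <- data.frame(score = scores$score[match(phenotypes$subject_id,
                                                    scores$subject_id)])
      for (o in outcomes[seq_len(min(3, length(outcomes)))])
        vars[[o]] <- phenotypes[[o]]
      for (dir in names(stat_maps)) {
        sig <- stat_maps[[dir]]$significant
        if (any(sig))
          vars[[paste0("cluster_", dir)]] <-
            extract_cluster_values(volumes, sig)
      }
      posthoc_correlations(vars, phenotypes$sex)
    })
    utils::write.table(posthoc$table,
                       file.path(config$out_dir, "posthoc_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = TRUE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("prsvbm")),
    r_version = R.version.string,
    seed = config$seed,
    parameters = config[c("K_pcs", "B_behavior", "B_imaging", "q_fdr",
                          "mask_threshold", "cluster_p", "scheme")],
    outcomes = outcomes,
    log = log_lines)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(scores = scores, pcs = pcs, association = assoc,
                 stat_maps = stat_maps, clusters = clusters,
                 posthoc = posthoc, manifest = manifest))
}

#' Sex-stratified Pearson correlation table
#'
#' Pearson r and two-sided p for every variable pair, computed
#' separately within each sex stratum, arranged as one square character
#' table: male (sex = 1) correlations above the diagonal, female below,
#' `-` on the diagonal. Cells of a stratum with fewer than 3 complete
#' pairs are flagged `NA`.
#'
#' @param vars data.frame of numeric variables (columns are table rows/
#'   columns).
#' @param sex 0/1 vector aligned with `vars` rows.
#' @return list: `table` (character matrix "r, p"), `male`, `female`
#'   (numeric r matrices with p attributes).
#' @export
posthoc_correlations <- function(vars, sex) {
  stopifnot(nrow(vars) == length(sex))
  nm <- names(vars)
  k <- length(nm)
  strata <- list(female = sex == 0, male = sex == 1)
  res <- lapply(strata, function(keep) {
    v <- vars[keep, , drop = FALSE]
    r <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
    p <- r
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j) next
      ok <- stats::complete.cases(v[[i]], v[[j]])
      if (sum(ok) < 3) next
      ct <- stats::cor.test(v[[i]][ok], v[[j]][ok])
      r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
    }
    attr(r, "p") <- p
    r
  })
  tab <- matrix("-", k, k, dimnames = list(nm, nm))
  cell <- function(r, p) {
    if (is.na(r)) "NA" else sprintf("%.3f, %.3g", r, p)
  }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    src <- if (j > i) res$male else res$female   # upper = male, lower = female
    tab[i, j] <- cell(src[i, j], attr(src, "p")[i, j])
  }
  list(table = tab, male = res$male, female = res$female)
}
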
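## Whole-brain voxelwise regression with max-statistic permutation FWE
## correction, mask construction, and cluster-extent reporting.

#' Construct a volume stack
#'
#' @param data subjects x X x Y x Z numeric array.
#' @param affine 4x4 voxel-to-world transform (0-based voxel indices).
#' @param subject_ids character vector, one per volume.
#' @return object of class `volume_stack`.
#' @export
volume_stack <- function(data, affine = diag(4), subject_ids = NULL) {
  if (length(dim(data)) != 4) stop_validation("volume stack must be a 4D array")
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(dim(data)[1]))
  if (length(subject_ids) != dim(data)[1])
    stop_validation("subject_ids length does not match number of volumes")
  if (!all(is.finite(data))) stop_validation("volume stack contains non-finite values")
  structure(list(data = data, affine = affine,
                 subject_ids = as.character(subject_ids),
                 voxel_size_mm = sqrt(colSums(affine[1:3, 1:3]^2))),
            class = "volume_stack")
}

#' Analysis mask: voxels above threshold in every subject
#'
#' A voxel enters the analysis iff every subject's intensity there
#' exceeds `threshold` (an intensity-inclusion mask, the usual
#' proportional threshold on tissue-probability-scaled volumes).
#'
#' @param stack a [volume_stack()].
#' @param threshold intensity cutoff (default 0.05).
#' @return list of class `vbm_mask`: `data` (logical X x Y x Z),
#'   `n_voxels`.
#' @export
build_mask <- function(stack, threshold = 0.05) {
  mins <- apply(stack$data, c(2, 3, 4), min)
  m <- mins > threshold
  if (!any(m)) stop_validation("mask is empty: no voxel exceeds %.3g in all subjects", threshold)
  structure(list(data = m, n_voxels = sum(m)), class = "vbm_mask")
}

## subjects x masked-voxels matrix view of a stack.
masked_matrix <- function(stack, mask) {
  n <- dim(stack$data)[1]
  Y <- matrix(stack$data, nrow = n)      # subjects x all voxels, column-major
  Y[, as.vector(mask$data), drop = FALSE]
}

#' Voxelwise GLM t-map for the score coefficient
#'
#' Fits, at every masked voxel, the same multiple regression as the
#' behavioral analysis (intensity on intercept, covariates and score)
#' and returns the t statistic of the score coefficient. Voxels with
#' zero residual variance get t = 0. The vectorized path is the same
#' code used for single outcomes, so it matches per-voxel scalar
#' regression identically.
#'
#' @param stack a [volume_stack()].
#' @param design a `prs_design` aligned with the stack's subjects.
#' @param mask a [vbm_mask()].
#' @return X x Y x Z numeric t-map, 0 outside the mask, with attribute
#'   `df` (residual degrees of freedom).
#' @export
voxelwise_glm <- function(stack, design, mask) {
  pc <- vbm_pieces(stack, design)
  Y <- masked_matrix(stack, mask)
  st <- score_t_stats(Y, pc$QZ, pc$s_tilde, pc$df)
  t_map <- array(0, dim(mask$data))
  t_map[mask$data] <- st$t
  attr(t_map, "df") <- pc$df
  t_map
}

## Validate stack/design alignment and precompute the reduced-model
## pieces. Volumes must be complete (no NA), so no casewise deletion.
vbm_pieces <- function(stack, design) {
  X <- design$X
  if (nrow(X) != dim(stack$data)[1])
    stop_validation("design has %d rows but stack has %d volumes",
                    nrow(X), dim(stack$data)[1])
  if (!identical(rownames(X), stack$subject_ids))
    stop_validation("subject order differs between design and volume stack")
  if (anyNA(X)) stop_validation("design contains missing values")
  p <- ncol(X)
  if (qr(X)$rank < p) stop_validation("rank-deficient imaging design")
  s <- X[, design$score_col]
  Z <- X[, setdiff(colnames(X), design$score_col), drop = FALSE]
  QZ <- reduced_basis(Z)
  list(QZ = QZ, s_tilde = as.vector(residualize(cbind(s), QZ)),
       df = nrow(X) - p)
}

#' Max-T permutation family-wise error correction
#'
#' Freedman-Lane permutation on the score column, exactly as in
#' [permutation_pvalue()] but recording, per permutation, the map-wide
#' maximum signed t over the mask in the requested direction. The
#' per-voxel FWE-corrected p is
#' `p_fwe(v) = max(#{b : max_t*_b >= t_obs(v)} / B, 1/B)` for the
#' positive direction (negated t for the negative direction). The
#' permutation schedule is shared across voxels, as max-T requires, and
#' is reproducible from `(n, B, seed)`.
#'
#' @param stack a [volume_stack()].
#' @param design a `prs_design`.
#' @param mask a [vbm_mask()].
#' @param B number of permutations (default 5000).
#' @param seed integer seed.
#' @param direction `"positive"` (score increases intensity) or
#'   `"negative"`.
#' @param alpha significance level for the reported significant set.
#' @param strict reject when `p_fwe < alpha` (default); `FALSE` uses
#'   `<=`.
#' @return list of class `stat_map`: `t_map`, `p_fwe_map` (1 outside the
#'   mask), `max_t_distribution` (length B), `significant` (logical
#'   array), `df`, `direction`.
#' @export
maxT_fwe <- function(stack, design, mask, B = 5000, seed = 1,
                     direction = c("positive", "negative"),
                     alpha = 0.05, strict = TRUE) {
  direction <- match.arg(direction)
  pc <- vbm_pieces(stack, design)
  Y <- masked_matrix(stack, mask)
  sgn <- if (direction == "positive") 1 else -1
  t_obs <- sgn * score_t_stats(Y, pc$QZ, pc$s_tilde, pc$df)$t
  perms <- make_permutations(nrow(Y), B, seed)
  R <- residualize(Y, pc$QZ)
  css <- colSums(R^2)
  ss <- sum(pc$s_tilde^2)
  max_t <- numeric(B)
  for (b in seq_len(B)) {
    Rp <- R[perms[, b], , drop = FALSE]
    num <- as.vector(crossprod(pc$s_tilde, Rp))
    rz <- colSums(crossprod(pc$QZ, Rp)^2)
    cssb <- pmax(css - rz, 0)
    rss <- pmax(cssb - num^2 / ss, 0)
    max_t[b] <- max(sgn * t_from_parts(num, cssb, rss, ss, pc$df))
  }
  p_fwe <- pmax(vapply(t_obs, function(t0)
    sum(max_t >= t0 - perm_tie_eps(t0)), 0) / B, 1 / B)
  t_map <- array(0, dim(mask$data)); t_map[mask$data] <- sgn * t_obs
  p_map <- array(1, dim(mask$data)); p_map[mask$data] <- p_fwe
  sig <- array(FALSE, dim(mask$data))
  sig[mask$data] <- if (strict) p_fwe < alpha else p_fwe <= alpha
  structure(list(t_map = t_map, p_fwe_map = p_map,
                 max_t_distribution = max_t, significant = sig,
                 df = pc$df, direction = direction),
            class = "stat_map")
}

connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6, 18, 26))
    stop_validation("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = d == 1, "18" = d >= 1 & d <= 2, "26" = d >= 1)
  g[keep, , drop = FALSE]
}

#' Cluster-extent report at an uncorrected threshold
#'
#' Thresholds the t-map at the Student quantile whose upper-tail
#' probability equals `p_uncorrected` (at the model's residual df) and
#' labels connected components of suprathreshold in-mask voxels.
#'
#' @param t_map t-map from [voxelwise_glm()] or a `stat_map` (its
#'   positive-direction t is used); must carry a `df` attribute unless
#'   `df` is given.
#' @param mask a [vbm_mask()].
#' @param df residual degrees of freedom (defaults to `attr(t_map, "df")`).
#' @param p_uncorrected voxel threshold (default 0.001, one-sided).
#' @param connectivity 6 (faces), 18 (faces+edges, default) or 26.
#' @param affine optional 4x4 matrix for peak world coordinates.
#' @return data.frame, one row per cluster: `cluster`, `size_voxels`,
#'   `peak_t`, `peak_i/j/k` (1-based voxel index), `peak_x/y/z` (mm,
#'   when affine given), sorted by decreasing size. Zero rows when no
#'   voxel survives.
#' @export
cluster_extent <- function(t_map, mask, df = NULL, p_uncorrected = 0.001,
                           connectivity = 18, affine = NULL) {
  if (inherits(t_map, "stat_map")) {
    if (is.null(df)) df <- t_map$df
    t_map <- t_map$t_map
  }
  if (is.null(df)) df <- attr(t_map, "df")
  if (is.null(df)) stop_validation("df not supplied and not carried by t_map")
  thr <- stats::qt(p_uncorrected, df = df, lower.tail = FALSE)
  supra <- (t_map > thr) & mask$data
  labs <- label_components(supra, connectivity)
  ncl <- max(labs)
  if (ncl == 0)
    return(data.frame(cluster = integer(0), size_voxels = integer(0),
                      peak_t = numeric(0), peak_i = integer(0),
                      peak_j = integer(0), peak_k = integer(0)))
  rows <- lapply(seq_len(ncl), function(cl) {
    idx <- which(labs == cl, arr.ind = TRUE)
    tv <- t_map[labs == cl]
    pk <- idx[which.max(tv), ]
    data.frame(cluster = cl, size_voxels = nrow(idx), peak_t = max(tv),
               peak_i = pk[1], peak_j = pk[2], peak_k = pk[3])
  })
  rep <- do.call(rbind, rows)
  rep <- rep[order(-rep$size_voxels), , drop = FALSE]
  rep$cluster <- seq_len(nrow(rep))
  if (!is.null(affine)) {
    # world = affine %*% (0-based voxel index, 1)
    vox <- t(cbind(rep$peak_i - 1, rep$peak_j - 1, rep$peak_k - 1, 1))
    world <- t(affine %*% vox)
    rep$peak_x <- world[, 1]; rep$peak_y <- world[, 2]; rep$peak_z <- world[, 3]
  }
  rownames(rep) <- NULL
  rep
}

## Connected-component labeling of a logical 3D array (flood fill).
label_components <- function(supra, connectivity = 18) {
  offs <- connectivity_offsets(connectivity)
  dims <- dim(supra)
  labs <- array(0L, dims)
  cur <- 0L
  todo <- which(supra)
  for (start in todo) {
    if (labs[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labs[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]; queue <- queue[-length(queue)]
      iv <- arrayInd(v, dims)
      nb <- sweep(offs, 2, as.integer(iv), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * dims[1] + (nb[, 3] - 1L) * dims[1] * dims[2]
      lin <- lin[supra[lin] & labs[lin] == 0L]
      labs[lin] <- cur
      queue <- c(queue, lin)
    }
  }
  labs
}

#' Per-subject mean intensity over a voxel set
#'
#' Used for post hoc analyses of significant clusters: each subject's
#' mean intensity over the cluster's voxels.
#'
#' @param stack a [volume_stack()].
#' @param voxels logical X x Y x Z array, or an n x 3 matrix of 1-based
#'   voxel indices.
#' @return named numeric vector, one value per subject.
#' @export
extract_cluster_values <- function(stack, voxels) {
  dims <- dim(stack$data)[2:4]
  if (is.matrix(voxels) && !is.logical(voxels)) {
    sel <- array(FALSE, dims)
    sel[voxels] <- TRUE
  } else {
    sel <- voxels
  }
  if (!any(sel)) stop_validation("empty voxel set")
  Y <- matrix(stack$data, nrow = dim(stack$data)[1])[, as.vector(sel), drop = FALSE]
  stats::setNames(rowMeans(Y), stack$subject_ids)
}

#' Write a stat map's volumes and sidecars to disk
#'
#' @param sm a `stat_map` from [maxT_fwe()].
#' @param prefix output path prefix; writes `<prefix>_tmap.nii`,
#'   `<prefix>_pfwe.nii`, `<prefix>_maxt.tsv`.
#' @param affine 4x4 affine for the NIfTI headers.
#' @return invisible character vector of paths written.
#' @export
write_stat_map <- function(sm, prefix, affine = diag(4)) {
  paths <- c(paste0(prefix, "_tmap.nii"), paste0(prefix, "_pfwe.nii"),
             paste0(prefix, "_maxt.tsv"))
  write_nifti(sm$t_map, paths[1], affine = affine)
  write_nifti(sm$p_fwe_map, paths[2], affine = affine)
  utils::write.table(data.frame(perm = seq_along(sm$max_t_distribution),
                                max_t = sm$max_t_distribution),
                     paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
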
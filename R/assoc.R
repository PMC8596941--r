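## Behavioral association inference: OLS, Freedman-Lane permutation
## p-values, and two-stage sharpened FDR across outcomes.

#' Build a regression design matrix
#'
#' Assembles intercept, sex, age, the genetic principal components and
#' the polygenic score into a named design, aligned on subject id. The
#' score column is the coefficient of interest in all downstream tests.
#'
#' @param phenotypes data.frame with `subject_id`, `sex`, `age` columns.
#' @param scores data.frame `subject_id`, `score` (output of
#'   [compute_prs()]).
#' @param pcs optional `pc_result` from [top_pcs()]; its components are
#'   added as `PC1..PCK` covariates.
#' @return object of class `prs_design`: list with `X` (numeric matrix,
#'   first column intercept), `score_col = "score"`, `subject_ids`.
#' @export
build_design <- function(phenotypes, scores, pcs = NULL) {
  ids <- as.character(phenotypes$subject_id)
  m <- match(ids, as.character(scores$subject_id))
  if (anyNA(m)) stop_validation("%d subject(s) missing from score table", sum(is.na(m)))
  X <- cbind(intercept = 1, sex = as.numeric(phenotypes$sex),
             age = as.numeric(phenotypes$age))
  if (!is.null(pcs) && ncol(pcs$components) > 0) {
    mp <- match(ids, pcs$subject_ids)
    if (anyNA(mp)) stop_validation("%d subject(s) missing from PC table", sum(is.na(mp)))
    X <- cbind(X, pcs$components[mp, , drop = FALSE])
  }
  X <- cbind(X, score = scores$score[m])
  rownames(X) <- ids
  structure(list(X = X, score_col = "score", subject_ids = ids),
            class = "prs_design")
}

## Split a prs_design into full matrix X, reduced matrix Z (covariates
## only) and the score column s, after casewise deletion against y.
## Returns NULL-checked pieces plus the kept row index.
design_pieces <- function(design, y) {
  X <- design$X
  sc <- design$score_col
  if (!sc %in% colnames(X)) stop_validation("design has no '%s' column", sc)
  ok <- stats::complete.cases(X) & is.finite(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop_validation("too few complete cases (%d) for %d coefficients", n, p)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop_validation("rank-deficient design; collinear column(s): %s",
                    paste(bad, collapse = ", "))
  }
  s <- X[, sc]
  Z <- X[, setdiff(colnames(X), sc), drop = FALSE]
  QZ <- reduced_basis(Z)
  s_tilde <- as.vector(residualize(cbind(s), QZ))
  list(X = X, Z = Z, QZ = QZ, s = s, s_tilde = s_tilde, y = y,
       n = n, p = p, df = n - p, kept = which(ok))
}

#' Multiple regression of one outcome on the design
#'
#' Ordinary least squares with casewise deletion. The t value for the
#' score coefficient uses n - p residual degrees of freedom. The
#' standardized coefficient is the score coefficient after z-scoring the
#' outcome and every non-intercept predictor (so it is the expected
#' outcome change in SD units per SD of score, holding covariates fixed).
#'
#' @param design a `prs_design` from [build_design()].
#' @param outcome numeric vector aligned with the design rows.
#' @return list: `beta_std`, `t_value`, `n`, `df`, `residuals`,
#'   `fitted`, `kept` (row indices used).
#' @export
fit_regression <- function(design, outcome) {
  pc <- design_pieces(design, outcome)
  st <- score_t_stats(cbind(pc$y), pc$QZ, pc$s_tilde, pc$df)
  sd_s <- stats::sd(pc$s); sd_y <- stats::sd(pc$y)
  if (sd_y == 0) stop_validation("outcome is constant after casewise deletion")
  beta_std <- st$beta * sd_s / sd_y
  fit <- stats::lm.fit(pc$X, pc$y)
  list(beta_std = beta_std, t_value = st$t, n = pc$n, df = pc$df,
       residuals = fit$residuals, fitted = fit$fitted.values, kept = pc$kept)
}

#' Permutation p-value for the score coefficient
#'
#' Two-sided by default: `p = max(#{b : |t*_b| >= |t_obs|} / B, 1/B)`.
#' The default Freedman-Lane scheme permutes the residuals of the
#' covariates-only fit and adds back its fitted values before refitting
#' the full model, so the covariate structure is preserved under the
#' null; `"raw_y"` permutes the outcome directly. With `exact = TRUE`
#' (n <= 8) all n! permutations are enumerated instead of sampled and
#' the denominator is n!.
#'
#' @param design a `prs_design`.
#' @param outcome numeric outcome vector.
#' @param B number of permutations (default 5000).
#' @param seed integer seed for the permutation schedule.
#' @param scheme `"freedman_lane"` or `"raw_y"`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact enumerate all permutations (small n only).
#' @return list: `p_perm`, `t_obs`, `B` (permutations used), `max_t`
#'   (the permuted t values).
#' @export
permutation_pvalue <- function(design, outcome, B = 5000, seed = 1,
                               scheme = c("freedman_lane", "raw_y"),
                               alternative = c("two.sided", "greater", "less"),
                               exact = FALSE) {
  scheme <- match.arg(scheme)
  alternative <- match.arg(alternative)
  pc <- design_pieces(design, outcome)
  if (stats::sd(pc$y) == 0) stop_validation("outcome is constant after casewise deletion")
  t_obs <- score_t_stats(cbind(pc$y), pc$QZ, pc$s_tilde, pc$df)$t
  perms <- if (exact) enumerate_permutations(pc$n) else make_permutations(pc$n, B, seed)
  B_eff <- ncol(perms)
  R <- if (scheme == "freedman_lane") residualize(cbind(pc$y), pc$QZ) else cbind(pc$y)
  tstar <- as.vector(perm_score_t(R, pc$QZ, pc$s_tilde, pc$df, perms))
  eps <- perm_tie_eps(t_obs)
  count <- switch(alternative,
                  two.sided = sum(abs(tstar) >= abs(t_obs) - eps),
                  greater   = sum(tstar >= t_obs - eps),
                  less      = sum(tstar <= t_obs + eps))
  list(p_perm = max(count / B_eff, 1 / B_eff), t_obs = t_obs, B = B_eff,
       t_star = tstar)
}

#' Two-stage sharpened FDR adjustment (Benjamini-Krieger-Yekutieli)
#'
#' Stage 1 runs Benjamini-Hochberg at level `q' = q / (1 + q)` and
#' counts `r1` rejections; the estimated number of true nulls is
#' `m0 = max(m - r1, 1)`. The adjusted p-values are the standard BH
#' step-up adjusted p-values sharpened by the null-fraction estimate:
#' `p_adj = min(1, BH(p) * (m0 / m) * (1 + q))`, returned in input
#' order. With no stage-1 rejections this reduces to BH inflated by
#' (1+q) and capped at 1.
#'
#' @param pvalues p-values in (0, 1].
#' @param q target FDR level (default 0.05).
#' @return numeric vector of adjusted p-values, same order as input.
#' @export
bky_adjust <- function(pvalues, q = 0.05) {
  p <- as.numeric(pvalues)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_validation("p-values must lie in (0, 1]")
  if (q <= 0 || q >= 1) stop_validation("q must lie in (0, 1)")
  m <- length(p)
  q1 <- q / (1 + q)
  ord <- order(p)
  ps <- p[ord]
  r1 <- max(c(0L, which(ps <= seq_len(m) * q1 / m)))
  m0 <- max(m - r1, 1L)
  bh <- rev(cummin(rev(m * ps / seq_len(m))))      # BH step-up adjusted p
  adj_sorted <- pmin(1, bh * (m0 / m) * (1 + q))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

#' Per-outcome association table with permutation and FDR p-values
#'
#' For each requested outcome: casewise deletion of missing values (the
#' analyzed n is recorded per outcome), OLS fit, Freedman-Lane
#' permutation p-value for the score coefficient, then two-stage
#' sharpened FDR adjustment across the full outcome set.
#'
#' @param phenotypes data.frame with `subject_id`, `sex`, `age` and one
#'   column per outcome.
#' @param scores output of [compute_prs()].
#' @param pcs optional `pc_result`.
#' @param outcomes character vector of phenotype column names to test.
#' @param B permutations per outcome.
#' @param seed integer seed.
#' @param scheme permutation scheme, see [permutation_pvalue()].
#' @param q FDR level.
#' @return data.frame: `outcome`, `n`, `beta_std`, `t`, `p_perm`,
#'   `p_fdr`, with attributes `B`, `seed`, `scheme`, `q`.
#' @export
run_association_table <- function(phenotypes, scores, pcs = NULL, outcomes,
                                  B = 5000, seed = 1,
                                  scheme = "freedman_lane", q = 0.05) {
  unknown <- setdiff(outcomes, names(phenotypes))
  if (length(unknown))
    stop_validation("unknown outcome(s): %s", paste(unknown, collapse = ", "))
  design <- build_design(phenotypes, scores, pcs)
  rows <- lapply(seq_along(outcomes), function(k) {
    y <- as.numeric(phenotypes[[outcomes[k]]])
    fit <- fit_regression(design, y)
    # per-outcome seed offset keeps outcomes independent but reproducible
    pp <- permutation_pvalue(design, y, B = B, seed = seed + k - 1,
                             scheme = scheme)
    data.frame(outcome = outcomes[k], n = fit$n, beta_std = fit$beta_std,
               t = fit$t_value, p_perm = pp$p_perm, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_fdr <- bky_adjust(tab$p_perm, q = q)
  attr(tab, "B") <- B; attr(tab, "seed") <- seed
  attr(tab, "scheme") <- scheme; attr(tab, "q") <- q
  tab
}

#' Write an association table to TSV
#'
#' @param tab output of [run_association_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(tab, path) {
  out <- tab
  names(out) <- c("outcome", "n", "beta_std", "t", "p_uncorrected", "p_fdr")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
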
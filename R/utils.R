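## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Report-style rounding: `0.0385` at 3 digits becomes `0.039`, unlike
#' [base::round()]'s round-half-to-even. Used wherever adjusted p-values
#' are displayed at table precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 3) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("prsvbm_validation_error", "error")))
}

#' Permutation schedule
#'
#' Draws `B` random permutations of `1:n` under a fixed seed. Both the
#' behavioral permutation test and the imaging max-T correction consume
#' this schedule, so a shared `(n, B, seed)` triple yields identical
#' permutations in both (required for their exact-agreement invariant).
#'
#' @param n number of subjects.
#' @param B number of permutations.
#' @param seed integer seed.
#' @return an `n x B` integer matrix; column `b` is the b-th permutation.
#' @export
make_permutations <- function(n, B, seed) {
  stopifnot(n >= 1, B >= 1)
  set.seed(as.integer(seed))
  vapply(seq_len(B), function(b) sample.int(n), integer(n))
}

## All n! permutations of 1:n as an n x n! matrix (n <= 8).
enumerate_permutations <- function(n) {
  stopifnot(n >= 1, n <= 8)
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- enumerate_permutations(n - 1L)
  cols <- vector("list", n)
  for (k in seq_len(n)) {
    # insert n at position k of every (n-1)-permutation
    top <- if (k > 1L) sub[seq_len(k - 1L), , drop = FALSE] else NULL
    bot <- if (k <= n - 1L) sub[k:(n - 1L), , drop = FALSE] else NULL
    cols[[k]] <- rbind(top, matrix(n, 1, ncol(sub)), bot)
  }
  do.call(cbind, cols)
}

## Tie tolerance for permutation counting: the identity permutation (and
## symmetry-paired permutations at small n) reproduce the observed t up
## to floating-point reassociation; counting with this slack keeps the
## empirical p equal to the exact enumeration p.
perm_tie_eps <- function(t_obs) 1e-8 * (1 + abs(t_obs))

## Orthonormal basis (thin Q) of the column space of Z.
reduced_basis <- function(Z) {
  qr.Q(qr(Z))
}

## Residualize columns of Y against the span of QZ: (I - QZ QZ') Y.
residualize <- function(Y, QZ) {
  Y - QZ %*% crossprod(QZ, Y)
}

#' Score-coefficient t statistics for many outcomes at once
#'
#' For the partitioned model `y = Z g + s b + e`, the t statistic of `b`
#' can be written with the covariate-residualized score
#' `s~ = (I - H_Z) s`:
#' `t = (s~'y / s~'s~) / sqrt(RSS / df / s~'s~)` with
#' `RSS = ||(I-H_Z) y||^2 - (s~'y)^2 / s~'s~` and `df = n - ncol(Z) - 1`.
#' Vectorized over the columns of `Y`; this is the single code path used
#' for observed statistics, behavioral permutations, and the voxelwise
#' map, so vectorized and scalar fits agree by construction (and are
#' cross-checked against per-column [stats::lm()] in the tests).
#'
#' Columns with (near-)zero residual variance get t = 0.
#'
#' @param Y n x V matrix of outcomes (V voxels or permuted copies).
#' @param QZ orthonormal basis of the reduced (covariates-only) design.
#' @param s_tilde covariate-residualized score column.
#' @param df residual degrees of freedom of the full model.
#' @return list with `t` (length V), `beta` (length V), `rss` (length V).
#' @keywords internal
score_t_stats <- function(Y, QZ, s_tilde, df) {
  ss <- sum(s_tilde^2)
  if (ss < 1e-12) stop_validation("score column has zero variance after covariate residualization")
  E <- residualize(Y, QZ)
  num <- as.vector(crossprod(s_tilde, Y))   # s~ is orthogonal to span(Z)
  css <- colSums(E^2)
  beta <- num / ss
  rss <- pmax(css - num^2 / ss, 0)
  list(t = t_from_parts(num, css, rss, ss, df), beta = beta, rss = rss)
}

## Shared t computation with explicit degenerate handling:
## - css ~ 0: outcome fully explained by the covariates alone (or
##   constant) -> no score information, t = 0;
## - rss ~ 0 with css > 0: the score explains the outcome exactly ->
##   |t| is reported as a huge finite sentinel rather than Inf.
t_from_parts <- function(num, css, rss, ss, df) {
  beta <- num / ss
  se2 <- rss / df / ss
  tval <- ifelse(se2 > 0, beta / sqrt(se2), 0)
  flat <- css <= 1e-20
  exact <- !flat & rss <= 1e-12 * css
  tval[flat] <- 0
  tval[exact] <- sign(beta[exact]) * 1e15
  tval
}

## Fast per-permutation score t for the max-T / permutation-p loops.
##
## Freedman-Lane: Y*_b = (H_Z + P_b (I - H_Z)) Y, and the full-model t for
## the score column depends on Y*_b only through s~'Y*_b = s~'(P_b R) and
## ||(I-H_Z) Y*_b||^2 = ||(I-H_Z) P_b R||^2, with R = (I-H_Z) Y. Column
## sums of squares of P_b R equal those of R, so only the k x V product
## QZ'(P_b R) is recomputed per permutation: O(n V k) per iteration.
##
## Returns a B x V matrix of permuted t values.
perm_score_t <- function(R, QZ, s_tilde, df, perms) {
  ss <- sum(s_tilde^2)
  css <- colSums(R^2)                       # invariant under row permutation
  B <- ncol(perms)
  V <- ncol(R)
  if (V == 1L) {
    # single outcome: treat the B permuted copies as columns of one matrix
    Rp <- matrix(R[perms], nrow(R), B)
    num <- as.vector(crossprod(s_tilde, Rp))
    rz <- colSums(crossprod(QZ, Rp)^2)
    cssb <- pmax(css - rz, 0)
    rss <- pmax(cssb - num^2 / ss, 0)
    return(cbind(t_from_parts(num, cssb, rss, ss, df)))
  }
  out <- matrix(0, B, V)
  for (b in seq_len(B)) {
    Rp <- R[perms[, b], , drop = FALSE]
    num <- as.vector(crossprod(s_tilde, Rp))
    rz <- colSums(crossprod(QZ, Rp)^2)
    cssb <- pmax(css - rz, 0)
    rss <- pmax(cssb - num^2 / ss, 0)
    out[b, ] <- t_from_parts(num, cssb, rss, ss, df)
  }
  out
}
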
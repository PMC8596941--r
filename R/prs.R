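## Polygenic risk scoring from log-odds-ratio weights and allele dosages.

#' Construct and validate a variant weight table
#'
#' A weight table holds one row per risk locus: variant id, chromosome,
#' 1-based position, effect and other allele, and the source-GWAS odds
#' ratio. The per-variant weight is the natural log of the odds ratio;
#' the score for a subject is the dosage-weighted sum of these weights.
#' "Effect allele" means the allele the GWAS odds ratio refers to, not
#' the genome-assembly reference base.
#'
#' @param df data.frame with columns `id`, `chr`, `pos`, `effect_allele`,
#'   `other_allele`, `OR`.
#' @return a `weight_table`: the input with a `weight = log(OR)` column.
#' @export
weight_table <- function(df) {
  required <- c("id", "chr", "pos", "effect_allele", "other_allele", "OR")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_validation("weight table missing columns: %s", paste(missing, collapse = ", "))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop_validation("duplicate variant ids in weight table: %s",
                    paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  df$OR <- as.numeric(df$OR)
  if (any(!is.finite(df$OR)) || any(df$OR <= 0))
    stop_validation("odds ratios must be finite and > 0")
  bad <- !(df$effect_allele %in% c("A", "C", "G", "T")) |
         !(df$other_allele %in% c("A", "C", "G", "T"))
  if (any(bad))
    stop_validation("non-ACGT allele for variant(s): %s",
                    paste(df$id[bad], collapse = ", "))
  df$weight <- log(df$OR)
  structure(df, class = c("weight_table", "data.frame"))
}

#' Load a variant weight table from TSV
#'
#' @param path TSV with header columns `id`, `chr`, `pos`, `effect_allele`,
#'   `other_allele`, `OR`.
#' @return a [weight_table()].
#' @export
load_weights <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  df$pos <- as.integer(df$pos)
  wt <- weight_table(df)
  message(sprintf("loaded %d variant weights from %s", nrow(wt), path))
  wt
}

#' Construct and validate a dosage matrix
#'
#' Dosages are expected counts of the effect allele in `[0, 2]` under
#' imputation uncertainty (2 = homozygous for the effect allele). Missing
#' dosages are allowed as `NA`.
#'
#' @param values numeric subjects x variants matrix.
#' @param subject_ids,variant_ids row/column identifiers.
#' @return a `dosage_matrix` (numeric matrix with dimnames and class).
#' @export
dosage_matrix <- function(values, subject_ids, variant_ids) {
  values <- as.matrix(values)
  if (length(subject_ids) != nrow(values) || length(variant_ids) != ncol(values))
    stop_validation("id lengths do not match matrix dimensions")
  if (anyDuplicated(subject_ids)) stop_validation("duplicate subject ids")
  if (anyDuplicated(variant_ids)) stop_validation("duplicate variant ids")
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop_validation("dosages outside [0, 2] (range %.3f..%.3f)", rng[1], rng[2])
  dimnames(values) <- list(as.character(subject_ids), as.character(variant_ids))
  structure(values, class = c("dosage_matrix", "matrix", "array"))
}

#' Load subject x variant dosages from TSV or VCF
#'
#' The returned matrix is restricted to variants present in `weights`,
#' in weight-table order; weight-table variants absent from the file are
#' reported and dropped from scoring.
#'
#' For VCF input the FORMAT field `DS` (ALT dosage) or `GP` (genotype
#' probabilities, ordered hom-REF / het / hom-ALT) is used. Dosage is
#' re-oriented to the weight table's effect allele: when the VCF ALT is
#' the effect allele the DS value is taken as is; when the REF is the
#' effect allele the dosage is `2 - DS`. GP triples are converted to an
#' ALT dosage as `0*P(hom-REF) + 1*P(het) + 2*P(hom-ALT)` first. A
#' variant whose effect allele matches neither REF nor ALT is a
#' strand/allele error.
#'
#' @param path file path.
#' @param weights a [weight_table()].
#' @param format `"tsv"` (first column `subject_id`, remaining columns
#'   named by variant id) or `"vcf"`.
#' @return a [dosage_matrix()].
#' @export
load_dosages <- function(path, weights, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    subj <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    colnames(mat) <- names(df)[-1]
  } else {
    parsed <- read_vcf_dosages(path, weights)
    subj <- parsed$subject_ids
    mat <- parsed$values
  }
  keep <- intersect(weights$id, colnames(mat))
  dropped <- setdiff(weights$id, keep)
  if (length(dropped))
    message(sprintf("%d weight-table variant(s) absent from %s and dropped from scoring: %s",
                    length(dropped), path, paste(dropped, collapse = ", ")))
  if (!length(keep)) stop_validation("no weight-table variants found in %s", path)
  dosage_matrix(mat[, keep, drop = FALSE], subj, keep)
}

## VCF branch of load_dosages(); requires VariantAnnotation.
read_vcf_dosages <- function(path, weights) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF dosages requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  ids <- rownames(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  gen <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(gen)) {
    ds <- gen$DS                               # variants x subjects
    storage.mode(ds) <- "double"
  } else if ("GP" %in% names(gen)) {
    gp <- gen$GP                               # variants x subjects x 3 (or list-array)
    if (is.list(gp)) {
      ds <- apply(gp, c(1, 2), function(p) sum(unlist(p) * c(0, 1, 2)))
    } else {
      ds <- gp[, , 2, drop = FALSE][, , 1] + 2 * gp[, , 3, drop = FALSE][, , 1]
      dim(ds) <- dim(gp)[1:2]
      dimnames(ds) <- dimnames(gp)[1:2]
    }
  } else {
    stop_validation("VCF %s has neither DS nor GP FORMAT fields", path)
  }
  keep <- ids %in% weights$id
  ds <- ds[keep, , drop = FALSE]; ids <- ids[keep]
  ref <- ref[keep]; alt <- alt[keep]
  eff <- weights$effect_allele[match(ids, weights$id)]
  oth <- weights$other_allele[match(ids, weights$id)]
  flip <- eff == ref & oth == alt
  asis <- eff == alt & oth == ref
  bad <- !(flip | asis)
  if (any(bad))
    stop_validation("effect allele matches neither REF nor ALT for: %s",
                    paste(ids[bad], collapse = ", "))
  ds[flip, ] <- 2 - ds[flip, , drop = FALSE]
  list(subject_ids = colnames(ds), values = t(ds))
}

#' Compute polygenic risk scores
#'
#' `score[s] = sum_i w_i * P[s, i]` over the weight-table variants present
#' in the dosage matrix, summed in weight-table order; `w_i = ln(OR_i)`
#' and `P[s, i]` is subject s's effect-allele dosage. A subject with
#' missing dosages is scored over the observed variants without
#' rescaling, and the per-subject missing count is reported.
#'
#' @param dosages a [dosage_matrix()] whose variants are a subset of
#'   `weights$id`.
#' @param weights a [weight_table()].
#' @return data.frame `subject_id`, `score`, `n_missing`.
#' @export
compute_prs <- function(dosages, weights) {
  vids <- colnames(dosages)
  extra <- setdiff(vids, weights$id)
  if (length(extra))
    stop_validation("dosage variants not in weight table: %s", paste(extra, collapse = ", "))
  ord <- weights$id[weights$id %in% vids]
  if (!length(ord)) stop_validation("no variants shared between dosages and weights")
  w <- weights$weight[match(ord, weights$id)]
  P <- unclass(dosages)[, ord, drop = FALSE]
  n_missing <- rowSums(is.na(P))
  P0 <- P
  P0[is.na(P0)] <- 0
  score <- as.vector(P0 %*% w)
  data.frame(subject_id = rownames(P), score = score,
             n_missing = as.integer(n_missing),
             stringsAsFactors = FALSE, row.names = NULL)
}
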
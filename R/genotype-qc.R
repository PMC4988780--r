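# Variant-level QC: missingness, MAF, Hardy-Weinberg exact test, and
# covariate-adjusted genotype principal components.

#' Per-variant summary statistics
#'
#' @param g a `genotype_matrix`.
#' @return data frame with one row per variant: `variant_id`, genotype counts
#'   `n0`/`n1`/`n2` over non-missing subjects, `n_obs`, `missing_rate`,
#'   alt-allele frequency `alt_freq`, and `maf` (folded at 0.5; `NA` when all
#'   dosages are missing).
#' @export
variant_stats <- function(g) {
  d <- g$dosage
  n <- nrow(d)
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  n_obs <- n0 + n1 + n2
  missing_rate <- 1 - n_obs / n
  alt_freq <- ifelse(n_obs > 0, (n1 + 2 * n2) / (2 * n_obs), NA_real_)
  maf <- pmin(alt_freq, 1 - alt_freq)
  data.frame(variant_id = g$variants$variant_id,
             n0 = n0, n1 = n1, n2 = n2, n_obs = n_obs,
             missing_rate = missing_rate, alt_freq = alt_freq, maf = maf,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test on the heterozygote count given the allele totals:
#' the p-value is the sum of probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (two-sided, no mid-p). Monomorphic tables return 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (homozygous ref, het, homozygous alt).
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("total genotype count must be >= 1")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1.0)
  # P(het = h | nA, na) on the log scale; h runs over counts with h ≡ nA (mod 2)
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  logp <- lgamma(n + 1) - lgamma((nA - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((na - hs) / 2 + 1) + hs * log(2) +
    lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  logp <- logp - max(logp)
  pr <- exp(logp); pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Filter variants on missingness, MAF, and Hardy-Weinberg equilibrium
#'
#' Kept variants satisfy `missing_rate <= missing_max`, `maf >= maf_min`, and
#' `hwe_p >= hwe_alpha`. A removed variant is attributed to the first filter
#' it fails in the order missingness, MAF, HWE (removal is the union, so the
#' kept set does not depend on the order). Variants with all dosages missing
#' fail the missingness filter.
#'
#' @param g a `genotype_matrix`.
#' @param missing_max,maf_min,hwe_alpha thresholds, each in (0, 1); defaults
#'   0.05, 0.01 and 0.001.
#' @return list with `genotypes` (filtered `genotype_matrix`) and `report`
#'   (a `qc_report`: counts plus the per-variant table).
#' @export
filter_variants <- function(g, missing_max = 0.05, maf_min = 0.01,
                            hwe_alpha = 0.001) {
  stopifnot(missing_max > 0, missing_max <= 1, maf_min >= 0, maf_min < 1,
            hwe_alpha >= 0, hwe_alpha < 1)
  st <- variant_stats(g)
  hwe_p <- vapply(seq_len(nrow(st)), function(i) {
    if (st$n_obs[i] == 0) return(NA_real_)
    hwe_exact_p(st$n0[i], st$n1[i], st$n2[i])
  }, numeric(1))
  fail_miss <- st$missing_rate > missing_max | st$n_obs == 0
  fail_maf <- !fail_miss & (is.na(st$maf) | st$maf < maf_min)
  fail_hwe <- !fail_miss & !fail_maf & (!is.na(hwe_p) & hwe_p < hwe_alpha)
  kept <- !(fail_miss | fail_maf | fail_hwe)
  per_variant <- cbind(st, hwe_p = hwe_p, kept = kept)
  report <- structure(list(
    n_input_variants = nrow(st),
    n_removed_missing = sum(fail_miss),
    n_removed_maf = sum(fail_maf),
    n_removed_hwe = sum(fail_hwe),
    per_variant = per_variant
  ), class = "qc_report")
  if (!any(kept)) warning("no variants survive QC filters")
  gk <- genotype_matrix(g$dosage[, kept, drop = FALSE],
                        {
                          vi <- g$variants[kept, , drop = FALSE]
                          class(vi) <- c("variant_info", "data.frame")
                          rownames(vi) <- NULL
                          vi
                        },
                        g$subjects)
  list(genotypes = gk, report = report)
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  kept <- x$n_input_variants - x$n_removed_missing - x$n_removed_maf -
    x$n_removed_hwe
  cat("<qc_report> ", x$n_input_variants, " variants: ",
      x$n_removed_missing, " removed (missingness), ",
      x$n_removed_maf, " (MAF), ", x$n_removed_hwe, " (HWE); ",
      kept, " kept\n", sep = "")
  invisible(x)
}

#' Build the covariate design matrix for a cohort
#'
#' Intercept; site as one-hot indicators with the alphabetically first level
#' as reference (omitted entirely when only one level is present); then sex,
#' age, bmi, pack_years, current_smoker, optionally the seven cell counts.
#'
#' @param covariates covariate data frame (see [read_cohort()]).
#' @param cell_counts include CBC columns (`neutrophil`, `lymphocyte`,
#'   `monocyte`, `eosinophil`, `basophil`, `red_blood_cells`, `platelet`)?
#' @return numeric design matrix with named columns, first is `(Intercept)`.
#' @export
covariate_design <- function(covariates, cell_counts = FALSE) {
  site <- factor(as.character(covariates$site),
                 levels = sort(unique(as.character(covariates$site))))
  base_cols <- c("sex", "age", "bmi", "pack_years", "current_smoker")
  X <- as.matrix(covariates[, base_cols, drop = FALSE])
  mode(X) <- "numeric"
  if (nlevels(site) > 1) {
    S <- stats::model.matrix(~site)[, -1, drop = FALSE]
    X <- cbind(S, X)
  }
  if (cell_counts) {
    cbc <- c("neutrophil", "lymphocyte", "monocyte", "eosinophil",
             "basophil", "red_blood_cells", "platelet")
    miss <- setdiff(cbc, names(covariates))
    if (length(miss) > 0)
      stop("cell-count covariates missing: ", paste(miss, collapse = ", "))
    C <- as.matrix(covariates[, cbc, drop = FALSE])
    mode(C) <- "numeric"
    X <- cbind(X, C)
  }
  cbind(`(Intercept)` = 1, X)
}

#' Covariate-adjusted genotype principal components
#'
#' Each variant's dosage vector is standardized (mean 0, unit variance,
#' missing values set to the mean), residualized on the covariate design,
#' and the subjects-by-variants residual matrix is decomposed by SVD. Scores
#' are the left singular vectors scaled by their singular values; the sign of
#' each component is fixed so that its largest-magnitude variant loading is
#' positive.
#'
#' @param g a QC-filtered `genotype_matrix`.
#' @param design covariate design matrix from [covariate_design()], or `NULL`
#'   for intercept-only (plain PCA of standardized dosages).
#' @param k number of components, `1 <= k <= min(n_subjects, n_variants)`.
#' @return list of class `genotype_pcs`: `scores` (n x k, zero-mean columns),
#'   `eigenvalues` (all `min(n,p)` eigenvalues, for a scree decision), `k`.
#' @export
genotype_pcs <- function(g, design = NULL, k = 1) {
  d <- g$dosage
  n <- nrow(d); p <- ncol(d)
  if (k < 1 || k > min(n, p)) stop("k must be in [1, min(n_subjects, n_variants)]")
  Z <- apply(d, 2, function(col) {
    mu <- mean(col, na.rm = TRUE)
    s <- stats::sd(col, na.rm = TRUE)
    col[is.na(col)] <- mu
    if (is.na(s) || s == 0) rep(0, length(col)) else (col - mu) / s
  })
  if (is.null(design)) design <- matrix(1, n, 1)
  qrX <- qr(design)
  R <- Z - qr.fitted(qrX, Z)
  sv <- svd(R, nu = k, nv = k)
  eigenvalues <- sv$d^2 / (n - 1)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- g$subjects
  structure(list(scores = scores, eigenvalues = eigenvalues, k = k),
            class = "genotype_pcs")
}
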
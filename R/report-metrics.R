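# Variance-explained decompositions, nested-model R-squared comparisons for
# phenotypes, and the cell-count sensitivity (concordance) analysis.

.r2 <- function(y, X) {
  fit <- stats::lm.fit(as.matrix(X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Hierarchical variance decomposition of a biomarker
#'
#' Sequential R-squared with clinical covariates entered first, then the top
#' independent pQTL SNP, then the second: `r2_clinical = R2(y ~ C)`,
#' `r2_snp1 = R2(y ~ C + g1) - r2_clinical`,
#' `r2_snp2 = R2(y ~ C + g1 + g2) - previous`, and
#' `r2_residual = 1 - total`. The increments are order-dependent by design.
#'
#' @param y transformed analyte values (tobit-mode analytes should pass
#'   conditional-expectation-filled values; the result is then approximate
#'   and flagged).
#' @param design clinical covariate design (with intercept).
#' @param g1 dosage of the top independent signal.
#' @param g2 optional dosage of the second independent signal.
#' @param approximate flag recorded for filled tobit analytes.
#' @return list of class `variance_decomposition`: `r2_clinical`, `r2_snp1`,
#'   `r2_snp2`, `r2_residual`, `approximate`.
#' @export
variance_decomposition <- function(y, design, g1, g2 = NULL,
                                   approximate = FALSE) {
  ok <- !is.na(y) & stats::complete.cases(design) & !is.na(g1)
  if (!is.null(g2)) ok <- ok & !is.na(g2)
  y <- y[ok]; X <- as.matrix(design)[ok, , drop = FALSE]
  g1 <- g1[ok]; if (!is.null(g2)) g2 <- g2[ok]
  r2_c <- .r2(y, X)
  r2_1 <- .r2(y, cbind(X, g1)) - r2_c
  r2_2 <- if (is.null(g2)) 0 else .r2(y, cbind(X, g1, g2)) - r2_c - r2_1
  structure(list(r2_clinical = r2_c, r2_snp1 = r2_1, r2_snp2 = r2_2,
                 r2_residual = 1 - r2_c - r2_1 - r2_2,
                 approximate = approximate),
            class = "variance_decomposition")
}

#' Nested-model R-squared comparison for a phenotype
#'
#' Three nested fits: covariates only, plus the biomarker, plus the pQTL
#' SNP. For a continuous phenotype the values are ordinary R-squared and
#' non-decreasing by construction; for a binary phenotype McFadden
#' pseudo-R-squared is reported with `pseudo = TRUE`.
#'
#' @param D phenotype vector.
#' @param design covariate design.
#' @param B biomarker values (filled, transformed scale).
#' @param g SNP dosage.
#' @param binary is `D` binary?
#' @return list: `r2_covariates`, `r2_plus_biomarker`,
#'   `r2_plus_biomarker_and_snp`, `pseudo`.
#' @export
phenotype_r2_comparison <- function(D, design, B, g, binary = FALSE) {
  ok <- !is.na(D) & stats::complete.cases(design) & !is.na(B) & !is.na(g)
  D <- D[ok]; X <- as.matrix(design)[ok, , drop = FALSE]
  B <- B[ok]; g <- g[ok]
  if (!binary) {
    out <- c(.r2(D, X), .r2(D, cbind(X, B)), .r2(D, cbind(X, B, g)))
  } else {
    mcfadden <- function(Xm) {
      f <- suppressWarnings(stats::glm.fit(Xm, D, family = stats::binomial()))
      p0 <- mean(D)
      ll0 <- sum(D * log(p0) + (1 - D) * log(1 - p0))
      1 - (-f$deviance / 2) / ll0
    }
    out <- c(mcfadden(X), mcfadden(cbind(X, B)), mcfadden(cbind(X, B, g)))
  }
  list(r2_covariates = out[1], r2_plus_biomarker = out[2],
       r2_plus_biomarker_and_snp = out[3], pseudo = binary)
}

#' Concordance of association p-values with and without cell-count covariates
#'
#' Pearson correlation of -log10 p between a base scan and a CBC-adjusted
#' scan over identical (variant, analyte) pairs, reported for all pairs and
#' for the significant subset; the raw-p correlation is reported alongside
#' (it is dominated by the uniform bulk, hence secondary).
#'
#' @param scan_base,scan_cbc association data frames over identical pairs.
#' @param significance_threshold p-value level (applied to the base scan)
#'   defining the significant subset.
#' @return list of class `sensitivity_report`: `cor_all`, `cor_significant`,
#'   `cor_raw_p`, `n_pairs`, `n_significant`, `pairs` (per-pair table).
#' @export
cellcount_sensitivity <- function(scan_base, scan_cbc,
                                  significance_threshold = 8e-10) {
  kb <- paste(scan_base$variant_id, scan_base$analyte, sep = "\r")
  kc <- paste(scan_cbc$variant_id, scan_cbc$analyte, sep = "\r")
  if (!setequal(kb, kc) || anyDuplicated(kb) || anyDuplicated(kc)) {
    diff <- c(setdiff(kb, kc), setdiff(kc, kb))
    stop("scans cover different (variant, analyte) pairs; e.g. ",
         paste(utils::head(gsub("\r", "/", diff), 3), collapse = ", "))
  }
  sc <- scan_cbc[match(kb, kc), ]
  ok <- !is.na(scan_base$p) & !is.na(sc$p)
  lp_b <- -log10(scan_base$p[ok]); lp_c <- -log10(sc$p[ok])
  sig <- scan_base$p[ok] < significance_threshold
  cor_sig <- if (sum(sig) >= 3) stats::cor(lp_b[sig], lp_c[sig]) else NA_real_
  pairs <- data.frame(variant_id = scan_base$variant_id[ok],
                      analyte = scan_base$analyte[ok],
                      p_base = scan_base$p[ok], p_cbc = sc$p[ok],
                      significant = sig, stringsAsFactors = FALSE)
  structure(list(cor_all = stats::cor(lp_b, lp_c), cor_significant = cor_sig,
                 cor_raw_p = stats::cor(scan_base$p[ok], sc$p[ok]),
                 n_pairs = sum(ok), n_significant = sum(sig), pairs = pairs),
            class = "sensitivity_report")
}
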
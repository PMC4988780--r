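# Conditional-independence classification of (SNP, biomarker, phenotype)
# trios. Under the Mendelian-randomization premise that genotype causes
# molecular/phenotypic change (never the reverse), each candidate causal
# graph implies a distinct pattern of (conditional) dependence among the
# trio, testable through slopes in a small battery of regressions:
#   M1: D ~ g + C          -> b1 (SNP-disease, marginal)
#   M2: D ~ g + B + C      -> b3 (SNP-disease | biomarker), b2 (biomarker-
#                             disease | SNP)
#   M3: B ~ g + D + C      -> b5 (SNP-biomarker | disease)
# Testing the biomarker-disease slope with D as response (b2) or with B as
# response is equivalent - both probe dependence of B and D given g - so
# only b2 enters the battery.

#' Fit the trio regression battery in one cohort
#'
#' @param g variant dosage vector.
#' @param biomarker a `prepared_analyte` for the biomarker (linear or tobit
#'   mode). When tobit-mode, its censored values are replaced by their
#'   conditional expectation before use as a covariate in M1/M2, and M3 is
#'   fit by tobit regression.
#' @param D phenotype vector (continuous, or 0/1 when `d_binary`).
#' @param design covariate design for disease models (M1/M2); may include
#'   the cohort's biomarker PC1.
#' @param design_biomarker covariate design for the biomarker-response model
#'   M3; defaults to `design`. Pass a design without the biomarker PC1 here
#'   to avoid conditioning a response on a function of itself.
#' @param d_binary is the phenotype binary (logistic M1/M2)?
#' @return data frame with rows `t_SD`, `t_SD_given_B`, `t_BD_given_S`,
#'   `t_SB_given_D`: columns `beta`, `se`, `p`, `n`, `converged`.
#' @export
fit_trio_regressions <- function(g, biomarker, D, design,
                                 design_biomarker = design,
                                 d_binary = FALSE) {
  if (stats::var(g, na.rm = TRUE) == 0) stop("variant has zero variance in sample")
  B <- if (biomarker$mode == "tobit") {
    conditional_expectation_fill(biomarker, design_biomarker)
  } else biomarker$y
  fit_disease <- function(y, X) {
    if (d_binary) logistic_fit(y, X) else ols_fit(y, X)
  }
  res <- list()
  f1 <- fit_disease(D, cbind(design, dosage = g))
  res$t_SD <- c(.wald_row(f1, "dosage"), n = f1$n_used, converged = f1$converged)
  f2 <- fit_disease(D, cbind(design, biomarker = B, dosage = g))
  res$t_SD_given_B <- c(.wald_row(f2, "dosage"), n = f2$n_used,
                        converged = f2$converged)
  res$t_BD_given_S <- c(.wald_row(f2, "biomarker"), n = f2$n_used,
                        converged = f2$converged)
  X3 <- cbind(design_biomarker, phenotype = D, dosage = g)
  f3 <- if (biomarker$mode == "tobit") {
    suppressWarnings(tobit_fit(biomarker$y, X3, biomarker$c,
                               biomarker$censored_mask))
  } else ols_fit(biomarker$y, X3)
  res$t_SB_given_D <- c(.wald_row(f3, "dosage"), n = f3$n_used,
                        converged = f3$converged)
  do.call(rbind, lapply(names(res), function(nm) {
    r <- res[[nm]]
    data.frame(test = nm, beta = r$beta, se = r$se, p = r$p, n = r$n,
               converged = as.logical(r$converged), stringsAsFactors = FALSE)
  }))
}

#' Meta-combine per-cohort trio test batteries
#'
#' Each test's per-cohort (beta, p) pair passes through [signed_z()] and
#' [stouffer_meta()]. When one cohort's battery is `NULL` the other cohort's
#' p-values are used directly and the battery is flagged single-cohort.
#'
#' @param tests1,tests2 data frames from [fit_trio_regressions()].
#' @param n1,n2 cohort sizes.
#' @param method meta statistic, see [stouffer_meta()].
#' @return list of class `trio_battery`: named meta p-values `t_SD`,
#'   `t_SD_given_B`, `t_BD_given_S`, `t_SB_given_D`; `per_cohort` (both
#'   input tables); `single_cohort` flag.
#' @export
meta_combine_tests <- function(tests1, tests2, n1, n2, method = "weighted") {
  tests <- c("t_SD", "t_SD_given_B", "t_BD_given_S", "t_SB_given_D")
  single <- is.null(tests1) || is.null(tests2)
  if (single) {
    warning("one cohort missing; using single-cohort p-values")
    tt <- if (is.null(tests1)) tests2 else tests1
    mp <- stats::setNames(tt$p[match(tests, tt$test)], tests)
  } else {
    mp <- vapply(tests, function(nm) {
      r1 <- tests1[tests1$test == nm, ]; r2 <- tests2[tests2$test == nm, ]
      stouffer_meta(signed_z(r1$p, r1$beta), n1,
                    signed_z(r2$p, r2$beta), n2, method = method)$meta_p
    }, numeric(1))
  }
  structure(list(meta_p = mp, per_cohort = list(tests1, tests2),
                 single_cohort = single),
            class = "trio_battery")
}

#' Classify a trio battery into a causal model category
#'
#' With `S(x)` meaning meta-p(x) < `alpha` (dependence) and `!S(x)` read as
#' conditional independence, the decision table formalizing the
#' d-separation signatures of the five graphs is:
#' \describe{
#'   \item{causal (g -> B -> D)}{S(t_SD), !S(t_SD_given_B), S(t_BD_given_S),
#'     S(t_SB_given_D): the SNP-disease association vanishes given the
#'     mediating biomarker.}
#'   \item{reactive (g -> D -> B)}{S(t_SD), S(t_SD_given_B),
#'     S(t_BD_given_S), !S(t_SB_given_D): the SNP-biomarker association
#'     vanishes given disease.}
#'   \item{independent (B <- g -> D)}{S(t_SD), S(t_SD_given_B),
#'     !S(t_BD_given_S), S(t_SB_given_D): biomarker and disease are
#'     independent given the SNP.}
#'   \item{collide (g -> B <- D)}{!S(t_SD), S(t_SD_given_B),
#'     S(t_BD_given_S), S(t_SB_given_D): SNP and disease are marginally
#'     independent but dependent given the biomarker.}
#'   \item{complete}{all four dependencies present.}
#'   \item{other}{any remaining pattern.}
#' }
#' Accepting the null as evidence of conditional independence is inherent
#' to the procedure; the battery p-values are always retained so margins
#' can be judged.
#'
#' @param battery a `trio_battery` (or named vector of the four meta
#'   p-values).
#' @param alpha dependence level, default 0.01.
#' @return one of `"causal"`, `"reactive"`, `"independent"`, `"collide"`,
#'   `"complete"`, `"other"`.
#' @export
classify_trio <- function(battery, alpha = 0.01) {
  mp <- if (inherits(battery, "trio_battery")) battery$meta_p else battery
  need <- c("t_SD", "t_SD_given_B", "t_BD_given_S", "t_SB_given_D")
  if (!all(need %in% names(mp))) stop("battery must contain the four tests")
  S <- mp[need] < alpha
  names(S) <- need
  if (S["t_SD"] && !S["t_SD_given_B"] && S["t_BD_given_S"] && S["t_SB_given_D"])
    return("causal")
  if (S["t_SD"] && S["t_SD_given_B"] && S["t_BD_given_S"] && !S["t_SB_given_D"])
    return("reactive")
  if (S["t_SD"] && S["t_SD_given_B"] && !S["t_BD_given_S"] && S["t_SB_given_D"])
    return("independent")
  if (!S["t_SD"] && S["t_SD_given_B"] && S["t_BD_given_S"] && S["t_SB_given_D"])
    return("collide")
  if (all(S)) return("complete")
  "other"
}

#' Classify a set of trios across two cohorts
#'
#' Convenience driver: for each (variant, analyte, phenotype) trio, fits the
#' regression battery in both cohorts, meta-combines, and classifies.
#'
#' @param trios data frame with columns `variant_id`, `analyte_id`,
#'   `phenotype` (a column of the phenotype tables), `binary` (logical).
#' @param cohort1,cohort2 lists with `bundle` (a `cohort_bundle`),
#'   `prepared` (named list of `prepared_analyte`), `design`, and optional
#'   `design_biomarker`.
#' @param alpha dependence level for [classify_trio()].
#' @param method meta statistic.
#' @return data frame: trio columns, the four meta p-values, per-cohort
#'   slope-sign concordance for t_SD, and `category`.
#' @export
classify_trios <- function(trios, cohort1, cohort2, alpha = 0.01,
                           method = "weighted") {
  one <- function(i) {
    tr <- trios[i, ]
    per_cohort <- lapply(list(cohort1, cohort2), function(co) {
      g <- co$bundle$genotypes$dosage[, tr$variant_id]
      D <- co$bundle$phenotypes[[tr$phenotype]]
      db <- if (is.null(co$design_biomarker)) co$design else co$design_biomarker
      tryCatch(
        fit_trio_regressions(g, co$prepared[[tr$analyte_id]], D, co$design,
                             design_biomarker = db, d_binary = isTRUE(tr$binary)),
        error = function(e) NULL)
    })
    if (is.null(per_cohort[[1]]) && is.null(per_cohort[[2]])) {
      return(data.frame(tr, t_SD = NA, t_SD_given_B = NA, t_BD_given_S = NA,
                        t_SB_given_D = NA, sign_concordant = NA,
                        category = "unclassifiable", stringsAsFactors = FALSE))
    }
    bat <- suppressWarnings(
      meta_combine_tests(per_cohort[[1]], per_cohort[[2]],
                         cohort1$bundle$n, cohort2$bundle$n, method = method))
    conc <- if (!bat$single_cohort) {
      b1 <- per_cohort[[1]]$beta[per_cohort[[1]]$test == "t_SD"]
      b2 <- per_cohort[[2]]$beta[per_cohort[[2]]$test == "t_SD"]
      sign(b1) == sign(b2)
    } else NA
    data.frame(tr, t_SD = bat$meta_p["t_SD"],
               t_SD_given_B = bat$meta_p["t_SD_given_B"],
               t_BD_given_S = bat$meta_p["t_BD_given_S"],
               t_SB_given_D = bat$meta_p["t_SB_given_D"],
               sign_concordant = conc,
               category = classify_trio(bat, alpha = alpha),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(trios)), one))
  rownames(out) <- NULL
  out
}
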
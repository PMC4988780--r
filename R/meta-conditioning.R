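# Two-cohort meta-analysis by the sample-size-weighted signed-Z statistic
# Z = (n1*z1 + n2*z2) / (n1 + n2), significance and replication calls,
# recursive conditioning for independent signals, and local/distant
# classification of pQTLs against the analyte's encoding gene.

#' Signed z-score from a two-sided p-value and effect direction
#'
#' `z = sign(beta) * |qnorm(p/2)|`. For extremely small p-values supply the
#' natural-log p via `log_p = TRUE`; the quantile is then evaluated in log
#' space so `|z|` stays finite and accurate far below the smallest
#' representable double.
#'
#' @param p two-sided p-value in (0, 1] (or its natural log).
#' @param beta effect estimate whose sign orients the z-score.
#' @param log_p is `p` given as `log(p)`?
#' @return signed z (vectorized).
#' @export
signed_z <- function(p, beta, log_p = FALSE) {
  if (!log_p && any(p <= 0 | p > 1)) stop("p must be in (0, 1]")
  if (log_p && any(p > 0)) stop("log p must be <= 0")
  lp <- if (log_p) p else log(p)
  z <- abs(stats::qnorm(lp - log(2), log.p = TRUE))
  sign(beta) * z
}

#' Sample-size-weighted signed-Z meta-analysis of two cohorts
#'
#' Combines per-cohort signed z-scores as
#' \deqn{Z = (n_1 z_1 + n_2 z_2) / (n_1 + n_2)} with meta p-value
#' \eqn{2\Phi(-|Z|)}. Note the arithmetic-mean denominator: this weighted
#' statistic is conservative relative to the classical Stouffer form
#' \eqn{(\sqrt{n_1} z_1 + \sqrt{n_2} z_2)/\sqrt{n_1+n_2}}, which is
#' available via `method = "classical"`.
#'
#' @param z1,z2 signed z-scores from [signed_z()].
#' @param n1,n2 cohort sample sizes (>= 1).
#' @param method `"weighted"` (the arithmetic-mean form, default) or
#'   `"classical"`.
#' @return list with `Z`, `meta_p`, and `log10_meta_p` (finite even when
#'   `meta_p` underflows).
#' @export
stouffer_meta <- function(z1, n1, z2, n2, method = c("weighted", "classical")) {
  method <- match.arg(method)
  stopifnot(n1 >= 1, n2 >= 1)
  Z <- switch(method,
              weighted = (n1 * z1 + n2 * z2) / (n1 + n2),
              classical = (sqrt(n1) * z1 + sqrt(n2) * z2) / sqrt(n1 + n2))
  lp <- stats::pnorm(-abs(Z), log.p = TRUE) + log(2)
  list(Z = Z, meta_p = pmin(1, 2 * stats::pnorm(-abs(Z))),
       log10_meta_p = pmin(0, lp / log(10)))
}

#' Meta-combine two per-cohort association scans
#'
#' Joins two scan tables (from [scan_analyte()] or
#' [read_association_table()]) on (variant, analyte) and applies
#' [signed_z()] and [stouffer_meta()]. Rows flagged non-converged in either
#' cohort are excluded with a message.
#'
#' @param res1,res2 per-cohort association data frames.
#' @param n1,n2 cohort sample sizes used as meta weights.
#' @param method meta statistic, see [stouffer_meta()].
#' @return data frame: `variant_id`, `analyte`, per-cohort `beta`/`p`/`n`/`z`,
#'   `Z`, `meta_p`, `log10_meta_p`.
#' @export
meta_scan <- function(res1, res2, n1, n2, method = "weighted") {
  key1 <- paste(res1$variant_id, res1$analyte, sep = "\r")
  key2 <- paste(res2$variant_id, res2$analyte, sep = "\r")
  m <- match(key1, key2)
  ok <- !is.na(m)
  r1 <- res1[ok, , drop = FALSE]
  r2 <- res2[m[ok], , drop = FALSE]
  if ("converged" %in% names(r1) && "converged" %in% names(r2)) {
    conv <- r1$converged & r2$converged
    if (any(!conv)) message(sum(!conv), " association(s) dropped (non-converged fit)")
    r1 <- r1[conv, , drop = FALSE]; r2 <- r2[conv, , drop = FALSE]
  }
  z1 <- signed_z(r1$p, r1$beta)
  z2 <- signed_z(r2$p, r2$beta)
  mt <- stouffer_meta(z1, n1, z2, n2, method = method)
  data.frame(variant_id = r1$variant_id, analyte = r1$analyte,
             beta1 = r1$beta, p1 = r1$p, n1 = n1, z1 = z1,
             beta2 = r2$beta, p2 = r2$p, n2 = n2, z2 = z2,
             Z = mt$Z, meta_p = mt$meta_p, log10_meta_p = mt$log10_meta_p,
             stringsAsFactors = FALSE)
}

#' Flag genome-wide-significant meta associations
#'
#' Significance is the strict inequality `meta_p < threshold`. The default
#' threshold 8e-10 is the Bonferroni-style genome-wide level for a scan of
#' several hundred thousand variants against on the order of 90 analytes;
#' [bonferroni_threshold()] computes `0.05 / (n_variants * n_analytes)` for
#' the user's own panel.
#'
#' @param meta_p numeric vector of meta p-values.
#' @param threshold significance level in (0, 1).
#' @return logical vector.
#' @export
call_significant <- function(meta_p, threshold = 8e-10) {
  stopifnot(threshold > 0, threshold < 1)
  !is.na(meta_p) & meta_p < threshold
}

#' @rdname call_significant
#' @param n_variants,n_analytes dimensions of the scan.
#' @export
bonferroni_threshold <- function(n_variants, n_analytes) {
  0.05 / (n_variants * n_analytes)
}

#' Cross-cohort replication by significance and direction
#'
#' Each association significant in the discovery cohort at
#' `discovery_threshold` is replicated when its p-value in the other cohort
#' is below `0.05 / m` (`m` = number of discovery-significant associations)
#' AND the effect directions agree. Associations absent from the replication
#' scan are unreplicated and flagged missing.
#'
#' @param results_A discovery-cohort association data frame.
#' @param results_B replication-cohort association data frame.
#' @param discovery_threshold significance level defining discoveries.
#' @return list: `table` (discovery rows with `p_B`, `beta_B`, `replicated`,
#'   `missing_in_B`), `m_discovery`, `replication_threshold`, `n_replicated`.
#' @export
replication_check <- function(results_A, results_B, discovery_threshold = 8e-10) {
  disc <- results_A[!is.na(results_A$p) & results_A$p < discovery_threshold, ,
                    drop = FALSE]
  m <- nrow(disc)
  thr <- if (m > 0) 0.05 / m else NA_real_
  keyA <- paste(disc$variant_id, disc$analyte, sep = "\r")
  keyB <- paste(results_B$variant_id, results_B$analyte, sep = "\r")
  idx <- match(keyA, keyB)
  p_B <- results_B$p[idx]
  beta_B <- results_B$beta[idx]
  missing_in_B <- is.na(idx)
  replicated <- !missing_in_B & !is.na(p_B) & p_B < thr &
    sign(disc$beta) == sign(beta_B)
  tab <- cbind(disc,
               data.frame(p_B = p_B, beta_B = beta_B,
                          replicated = replicated, missing_in_B = missing_in_B))
  list(table = tab, m_discovery = m, replication_threshold = thr,
       n_replicated = sum(replicated))
}

#' Classify a pQTL as local (cis) or distant (trans)
#'
#' Local: same chromosome as the analyte's encoding gene and within 1 Mb of
#' the gene interval (distance 0 inside the interval). Unknown gene locus
#' yields `"unknown"`.
#'
#' @param variant one-row `variant_info` (or list with `chromosome`,
#'   `position`).
#' @param analyte one-row `analyte_meta` (or list with `gene_chromosome`,
#'   `gene_start`, `gene_end`).
#' @param window basepair window, default 1e6.
#' @return `"local"`, `"distant"`, or `"unknown"`.
#' @export
classify_local_distant <- function(variant, analyte, window = 1e6) {
  gc <- analyte$gene_chromosome
  if (is.na(gc) || is.na(analyte$gene_start) || is.na(analyte$gene_end))
    return("unknown")
  if (as.character(variant$chromosome) != as.character(gc)) return("distant")
  pos <- variant$position
  d <- max(0, analyte$gene_start - pos, pos - analyte$gene_end)
  if (d <= window) "local" else "distant"
}

# conditional meta p for one candidate given selected dosages, per cohort
.conditional_assoc <- function(prepared, g, design, selected_ids, candidate_id) {
  sel <- g$dosage[, selected_ids, drop = FALSE]
  dj <- g$dosage[, candidate_id]
  y <- prepared$y
  ok <- !is.na(y) & stats::complete.cases(design) & !is.na(dj) &
    stats::complete.cases(sel)
  if (stats::var(dj[ok]) == 0) return(NULL)
  if (length(selected_ids) > 0) {
    # proxy guard: skip candidates collinear with an already-selected variant
    r2 <- suppressWarnings(stats::cor(dj[ok], sel[ok, , drop = FALSE]))^2
    if (any(r2 > 0.99, na.rm = TRUE)) return(NULL)
  }
  Xj <- cbind(design[ok, , drop = FALSE], sel[ok, , drop = FALSE],
              dosage = dj[ok])
  fit <- if (prepared$mode == "tobit") {
    tryCatch(suppressWarnings(
      tobit_fit(y[ok], Xj, prepared$c, prepared$censored_mask[ok])),
      error = function(e) NULL)
  } else {
    tryCatch(ols_fit(y[ok], Xj), error = function(e) NULL)
  }
  if (is.null(fit) || !isTRUE(fit$converged) ||
      !"dosage" %in% names(fit$coefficients)) return(NULL)
  .wald_row(fit, "dosage")
}

#' Recursive conditioning for independent association signals
#'
#' Forward selection over a candidate set (variants with marginal meta
#' p-value below the candidate threshold, conventionally 1e-8): the top
#' marginal meta hit is selected first; then, repeatedly, every remaining
#' candidate is refit per cohort with all previously selected variants'
#' dosages added to the covariate design, the candidate's conditional
#' p-values are meta-combined, and the smallest conditional meta p is
#' compared against the Bonferroni level `0.05 / T` (`T` = remaining
#' candidates; `K - 1` in the first round). Selection stops when the
#' smallest conditional meta p fails that level. Candidates collinear with a
#' selected variant (dosage r-squared > 0.99) are skipped.
#'
#' @param analyte_id analyte being dissected.
#' @param candidate_ids variant identifiers of the candidate pool (K >= 1).
#' @param cohort1,cohort2 lists with elements `prepared` (the analyte's
#'   `prepared_analyte`), `genotypes`, `design`, `n`.
#' @param marginal_meta optional meta data frame from [meta_scan()] used to
#'   pick the top SNP; recomputed from single-variant scans when `NULL`.
#' @param alpha numerator of the Bonferroni level, default 0.05.
#' @param method meta statistic, see [stouffer_meta()].
#' @return list of class `independent_signals`: `analyte_id`, `selected`
#'   (data frame `variant_id`, `cond_meta_p`, `order`), `K`, `stop_reason`.
#' @export
recursive_conditioning <- function(analyte_id, candidate_ids, cohort1, cohort2,
                                   marginal_meta = NULL, alpha = 0.05,
                                   method = "weighted") {
  K <- length(candidate_ids)
  if (K < 1) stop("candidate pool is empty")
  if (is.null(marginal_meta)) {
    sub <- function(co) {
      gi <- match(candidate_ids, co$genotypes$variants$variant_id)
      vi <- co$genotypes$variants[gi, , drop = FALSE]
      class(vi) <- c("variant_info", "data.frame"); rownames(vi) <- NULL
      gm <- genotype_matrix(co$genotypes$dosage[, gi, drop = FALSE], vi,
                            co$genotypes$subjects)
      scan_analyte(co$prepared, gm, co$design)
    }
    marginal_meta <- meta_scan(sub(cohort1), sub(cohort2),
                               cohort1$n, cohort2$n, method = method)
  }
  mm <- marginal_meta[marginal_meta$variant_id %in% candidate_ids &
                        marginal_meta$analyte == analyte_id, , drop = FALSE]
  if (nrow(mm) == 0) stop("no marginal meta results for candidate pool")
  ord <- order(mm$meta_p, -abs(mm$Z), mm$variant_id)
  top <- mm$variant_id[ord[1]]
  selected <- data.frame(variant_id = top, cond_meta_p = mm$meta_p[ord[1]],
                         order = 1L, stringsAsFactors = FALSE)
  remaining <- setdiff(candidate_ids, top)
  stop_reason <- if (length(remaining) == 0) "candidate pool exhausted" else ""
  while (length(remaining) > 0) {
    Tn <- length(remaining)
    thr <- alpha / Tn
    rows <- lapply(remaining, function(v) {
      w1 <- .conditional_assoc(cohort1$prepared, cohort1$genotypes,
                               cohort1$design, selected$variant_id, v)
      w2 <- .conditional_assoc(cohort2$prepared, cohort2$genotypes,
                               cohort2$design, selected$variant_id, v)
      if (is.null(w1) || is.null(w2)) return(NULL)
      mt <- stouffer_meta(signed_z(w1$p, w1$beta), cohort1$n,
                          signed_z(w2$p, w2$beta), cohort2$n, method = method)
      data.frame(variant_id = v, meta_p = mt$meta_p, Z = mt$Z,
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows) || nrow(rows) == 0) {
      stop_reason <- "all remaining candidates collinear or unfit"
      break
    }
    ro <- order(rows$meta_p, -abs(rows$Z), rows$variant_id)
    best <- rows[ro[1], ]
    if (best$meta_p < thr) {
      selected <- rbind(selected,
                        data.frame(variant_id = best$variant_id,
                                   cond_meta_p = best$meta_p,
                                   order = nrow(selected) + 1L,
                                   stringsAsFactors = FALSE))
      remaining <- setdiff(remaining, best$variant_id)
      if (length(remaining) == 0) stop_reason <- "candidate pool exhausted"
    } else {
      stop_reason <- sprintf("min conditional meta p %.3g >= %.3g (0.05/T, T=%d)",
                             best$meta_p, thr, Tn)
      break
    }
  }
  structure(list(analyte_id = analyte_id, selected = selected, K = K,
                 stop_reason = stop_reason),
            class = "independent_signals")
}
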
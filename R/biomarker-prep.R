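# LLOQ-aware biomarker preprocessing. Pipeline order is fixed: impute
# half-LLOQ -> inverse normal transform -> truncation value for the tobit
# likelihood. Values recorded below the LLOQ stay flagged through the
# transform via the censored mask; their (tied) transformed values matter
# only for initialization, never for the censored likelihood itself.

#' Triage an analyte by its censored fraction
#'
#' Analytes with more than 90% of measurements below the LLOQ are dropped
#' from analysis; below 10% they are analysed by ordinary linear regression;
#' between 10% and 90% (inclusive at both boundaries) by censored (tobit)
#' regression.
#'
#' @param pct_below_lloq fraction of measurements below the LLOQ, in [0, 1].
#' @return `"drop"`, `"linear"`, or `"tobit"`.
#' @export
triage_analyte <- function(pct_below_lloq) {
  stopifnot(pct_below_lloq >= 0, pct_below_lloq <= 1)
  if (pct_below_lloq > 0.90) "drop"
  else if (pct_below_lloq < 0.10) "linear"
  else "tobit"
}

#' Impute measurements below the LLOQ as half the LLOQ
#'
#' @param raw numeric vector of raw measurements.
#' @param below_lloq_mask logical vector, `TRUE` where the recorded value was
#'   below the LLOQ.
#' @param lloq positive limit of quantification.
#' @return `raw` with masked entries replaced by `lloq / 2`.
#' @export
impute_half_lloq <- function(raw, below_lloq_mask, lloq) {
  if (lloq <= 0) stop("lloq must be > 0")
  raw[which(below_lloq_mask)] <- lloq / 2
  raw
}

#' Rank-based inverse normal transformation
#'
#' Maps values to standard-normal quantiles via
#' `qnorm((rank - 0.5) / m)` over the `m` non-missing values, with average
#' ranks for ties (so tied inputs - in particular all half-LLOQ imputed
#' values - map to identical outputs). Missing values stay missing.
#'
#' @param values numeric vector with at least 2 non-missing entries.
#' @return transformed vector, same length and missingness as `values`.
#' @export
inverse_normal_transform <- function(values) {
  obs <- !is.na(values)
  m <- sum(obs)
  if (m < 2) stop("inverse normal transform needs >= 2 non-missing values")
  if (length(unique(values[obs])) == 1) {
    warning("all values identical; transform maps everything to 0")
    values[obs] <- 0
    return(values)
  }
  r <- rank(values[obs], ties.method = "average")
  values[obs] <- stats::qnorm((r - 0.5) / m)
  values
}

#' Tobit truncation value on the transformed scale
#'
#' The truncation value is the minimum transformed value among non-censored
#' observations minus a small constant (1e-10), so every censored
#' observation lies strictly below it.
#'
#' @param transformed transformed values.
#' @param censored_mask logical, `TRUE` for below-LLOQ entries.
#' @return scalar truncation value `c`.
#' @export
truncation_value <- function(transformed, censored_mask) {
  keep <- !censored_mask & !is.na(transformed)
  if (!any(keep))
    stop("all observations censored; analyte should have been dropped at triage")
  min(transformed[keep]) - 1e-10
}

#' Prepare one analyte for association analysis
#'
#' Runs the fixed preprocessing pipeline: triage on the below-LLOQ fraction,
#' half-LLOQ imputation, inverse normal transformation, and (for tobit-mode
#' analytes) the truncation value.
#'
#' @param raw raw measurements (assay units, `NA` = missing).
#' @param below_lloq logical mask of below-LLOQ entries.
#' @param lloq the analyte's LLOQ.
#' @param analyte_id identifier carried through to results.
#' @return A list of class `prepared_analyte`: `analyte_id`, `mode`
#'   (`"linear"`/`"tobit"`/`"drop"`), `y` (transformed values; `NULL` when
#'   dropped), `censored_mask`, `c` (truncation value, tobit only),
#'   `pct_below_lloq`.
#' @export
prepare_analyte <- function(raw, below_lloq, lloq, analyte_id = "analyte") {
  obs <- !is.na(raw)
  if (!any(obs)) stop("analyte ", analyte_id, " has no observed values")
  pct <- sum(below_lloq[obs]) / sum(obs)
  mode <- triage_analyte(pct)
  out <- list(analyte_id = analyte_id, mode = mode, y = NULL,
              censored_mask = below_lloq, c = NULL, pct_below_lloq = pct)
  if (mode != "drop") {
    y <- inverse_normal_transform(impute_half_lloq(raw, below_lloq, lloq))
    out$y <- y
    if (mode == "tobit") out$c <- truncation_value(y, below_lloq)
  }
  structure(out, class = "prepared_analyte")
}

#' Mean of a normal distribution truncated above
#'
#' E[Y | Y < c] for Y ~ N(mu, sigma^2): `mu - sigma * phi(a) / Phi(a)` with
#' `a = (c - mu) / sigma`. When `Phi(a)` underflows, the asymptotic
#' first-order form `c + sigma / a` is used with a warning.
#'
#' @param mu,sigma mean and SD of the untruncated normal (`sigma > 0`).
#' @param cc upper truncation point.
#' @return the truncated mean (vectorized over `mu`).
#' @export
truncated_normal_mean <- function(mu, sigma, cc) {
  stopifnot(sigma > 0)
  a <- (cc - mu) / sigma
  lphi <- stats::dnorm(a, log = TRUE)
  lPhi <- stats::pnorm(a, log.p = TRUE)
  out <- mu - sigma * exp(lphi - lPhi)
  under <- !is.finite(lPhi) | lPhi < -700
  if (any(under)) {
    warning("truncated-normal mean: CDF underflow; using asymptotic form")
    out[under] <- cc + sigma / a[under]
  }
  out
}

#' Fill censored biomarker values by their conditional expectation
#'
#' For use of a tobit-mode biomarker as a covariate: censored entries are
#' replaced by the conditional expectation of the latent value given that it
#' lies below the truncation value `c`, under a tobit fit of the transformed
#' biomarker on a covariate design.
#'
#' @param prepared a tobit-mode `prepared_analyte`.
#' @param X covariate design matrix (with intercept).
#' @param fit optional pre-computed [tobit_fit()] of `prepared$y` on `X`;
#'   fitted internally when `NULL`.
#' @return numeric vector: censored entries filled, others unchanged.
#' @export
conditional_expectation_fill <- function(prepared, X, fit = NULL) {
  if (prepared$mode != "tobit")
    stop("conditional-expectation fill applies to tobit-mode analytes")
  y <- prepared$y
  cen <- prepared$censored_mask & !is.na(y)
  if (is.null(fit))
    fit <- tobit_fit(y, X, prepared$c, prepared$censored_mask)
  mu <- as.vector(X[cen, , drop = FALSE] %*% fit$coefficients)
  y[cen] <- truncated_normal_mean(mu, fit$sigma, prepared$c)
  y
}

#' First principal component of the biomarker panel as a candidate covariate
#'
#' PCA (centered, unit-scaled) over subjects of the transformed analyte
#' matrix, restricted to analytes surviving triage; tobit-mode analytes
#' contribute conditional-expectation-filled values. PC1 is screened for
#' association against every covariate design column by univariate
#' regression; under `policy = "auto"` it is included only when no covariate
#' associates with it at Bonferroni level `0.05 / n_terms`.
#'
#' @param prepared_list list of `prepared_analyte` objects (modes linear or
#'   tobit; dropped analytes are ignored). At least 2 usable analytes.
#' @param design covariate design matrix from [covariate_design()].
#' @param policy `"auto"` (screen), `"always"`, or `"never"`.
#' @return list of class `biomarker_pc`: `scores` (zero-mean PC1 per
#'   subject), `include_flag`, `screen_p` (named per-covariate p-values).
#' @export
biomarker_pc1 <- function(prepared_list, design, policy = c("auto", "always", "never")) {
  policy <- match.arg(policy)
  usable <- Filter(function(p) p$mode %in% c("linear", "tobit"), prepared_list)
  if (length(usable) < 2)
    stop("biomarker PC1 needs >= 2 analytes in linear or tobit mode")
  cols <- lapply(usable, function(p) {
    if (p$mode == "tobit") conditional_expectation_fill(p, design) else p$y
  })
  Y <- do.call(cbind, cols)
  # complete rows only; PCA is not missing-tolerant
  keep <- stats::complete.cases(Y)
  Ys <- scale(Y[keep, , drop = FALSE])
  sv <- svd(Ys, nu = 1, nv = 1)
  pc1 <- rep(NA_real_, nrow(Y))
  s1 <- sv$u[, 1] * sv$d[1]
  v <- sv$v[, 1]
  if (v[which.max(abs(v))] < 0) s1 <- -s1
  pc1[keep] <- s1
  terms <- setdiff(colnames(design), "(Intercept)")
  screen_p <- vapply(terms, function(nm) {
    x <- design[keep, nm]
    if (stats::var(x) == 0) return(1.0)
    f <- stats::lm.fit(cbind(1, x), s1)
    rss <- sum(f$residuals^2)
    sig2 <- rss / (length(s1) - 2)
    xc <- x - mean(x)
    se <- sqrt(sig2 / sum(xc^2))
    b <- f$coefficients[2]
    2 * stats::pnorm(-abs(b / se))
  }, numeric(1))
  include <- switch(policy,
                    auto = all(screen_p >= 0.05 / max(1, length(terms))),
                    always = TRUE,
                    never = FALSE)
  structure(list(scores = pc1, include_flag = include, screen_p = screen_p),
            class = "biomarker_pc")
}
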
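# Per-cohort association engines. The genotype dosage term is always the
# last design column; Wald p-values are 2*pnorm(-|beta/se|) throughout so
# per-cohort p-values feed the signed-Z meta-analysis coherently.

.drop_aliased <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("dropping ", ncol(X) - qrX$rank, " aliased design column(s): ",
            paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)], collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

#' Ordinary least squares fit with Wald standard errors
#'
#' @param y numeric response.
#' @param X design matrix including intercept; collinear columns are dropped
#'   with a warning.
#' @return list of class `regression_fit`: `coefficients`, `se`, `sigma`
#'   (residual SD, divisor `n - p`), `loglik`, `n_used`, `converged`,
#'   `model = "ols"`.
#' @export
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  keep <- !is.na(y) & stats::complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  X <- .drop_aliased(X)
  n <- length(y); p <- ncol(X)
  if (n <= p) stop("ols_fit: n <= number of design columns")
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(X)
  sig_mle <- sqrt(rss / n)
  ll <- if (rss > 0) sum(stats::dnorm(fit$residuals, 0, sig_mle, log = TRUE)) else Inf
  structure(list(coefficients = fit$coefficients, se = se,
                 sigma = sqrt(sigma2), loglik = ll, n_used = n,
                 converged = TRUE, model = "ols"),
            class = "regression_fit")
}

# negative log-likelihood and gradient of the left-censored gaussian model,
# parametrized (beta, log sigma)
.tobit_nll <- function(theta, y, X, cc, cen) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]; s <- exp(theta[p + 1])
  mu <- as.vector(X %*% beta)
  r <- (y[!cen] - mu[!cen]) / s
  a <- (cc - mu[cen]) / s
  -(sum(stats::dnorm(r, log = TRUE) - log(s)) +
      sum(stats::pnorm(a, log.p = TRUE)))
}

.tobit_grad <- function(theta, y, X, cc, cen) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]; s <- exp(theta[p + 1])
  mu <- as.vector(X %*% beta)
  r <- (y[!cen] - mu[!cen]) / s
  a <- (cc - mu[cen]) / s
  lam <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))
  g_beta <- -crossprod(X[!cen, , drop = FALSE], r / s) +
    crossprod(X[cen, , drop = FALSE], lam / s)
  g_ls <- -sum(r^2 - 1) + sum(lam * a)
  c(as.vector(g_beta), g_ls)
}

#' Left-censored (tobit) maximum-likelihood regression
#'
#' Maximizes the censored-gaussian log-likelihood
#' \deqn{\ell(\beta,\sigma)=\sum_{unc}\left[\log\phi\!\left(\frac{y_i-x_i\beta}{\sigma}\right)-\log\sigma\right]+\sum_{cens}\log\Phi\!\left(\frac{c-x_i\beta}{\sigma}\right)}
#' by BFGS in \eqn{(\beta, \log\sigma)} with analytic gradient, initialized
#' from OLS on the observed values. Standard errors come from the inverse
#' observed information at the optimum; convergence requires gradient norm
#' below 1e-6 (max-norm) within 200 iterations.
#'
#' @param y transformed response; censored entries carry their (tied)
#'   transformed value, which only seeds the initialization.
#' @param X design matrix with intercept.
#' @param cc truncation value, below the minimum uncensored `y`.
#' @param censored_mask logical, `TRUE` for below-LLOQ observations.
#' @return a `regression_fit` (`model = "tobit"`; `sigma` is the MLE scale).
#'   Non-convergence or scale collapse is flagged via `converged = FALSE`.
#' @export
tobit_fit <- function(y, X, cc, censored_mask) {
  X <- as.matrix(X)
  keep <- !is.na(y) & stats::complete.cases(X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  cen <- censored_mask[keep]
  if (!any(!cen)) stop("tobit_fit: no uncensored observations")
  if (any(!cen) && cc >= min(y[!cen]))
    stop("truncation value must lie below the minimum uncensored response")
  X <- .drop_aliased(X)
  p <- ncol(X)
  init <- stats::lm.fit(X, y)
  s0 <- max(stats::sd(init$residuals), 1e-3)
  theta0 <- c(init$coefficients, log(s0))
  opt <- stats::optim(theta0, .tobit_nll, .tobit_grad, y = y, X = X, cc = cc,
                      cen = cen, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-14))
  theta <- opt$par
  grad <- .tobit_grad(theta, y, X, cc, cen)
  # Newton polish: BFGS stops on function improvement; a few full Newton
  # steps drive the gradient to machine-level zero near the optimum
  for (it in 1:5) {
    if (max(abs(grad)) < 1e-8) break
    H <- stats::optimHess(theta, .tobit_nll, .tobit_grad, y = y, X = X,
                          cc = cc, cen = cen)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    cand <- theta - step
    if (.tobit_nll(cand, y, X, cc, cen) <= opt$value + 1e-8) {
      theta <- cand
      grad <- .tobit_grad(theta, y, X, cc, cen)
    } else break
  }
  sigma <- unname(exp(theta[p + 1]))
  converged <- max(abs(grad)) < 1e-6 && sigma > 1e-8
  H <- stats::optimHess(theta, .tobit_nll, .tobit_grad, y = y, X = X,
                        cc = cc, cen = cen)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, p + 1, p + 1))
  se <- sqrt(pmax(diag(V)[seq_len(p)], 0))
  coefs <- theta[seq_len(p)]
  names(coefs) <- names(se) <- colnames(X)
  if (!converged) warning("tobit fit did not converge (gradient norm ",
                          format(max(abs(grad))), ")")
  structure(list(coefficients = coefs, se = se, sigma = sigma,
                 loglik = -opt$value, n_used = length(y),
                 converged = converged, model = "tobit"),
            class = "regression_fit")
}

#' Logistic regression fit with Wald standard errors
#'
#' Fisher-scoring MLE via `glm.fit`; perfect separation is flagged through
#' the `converged` field (diverging coefficients or failed IRLS).
#'
#' @param y01 binary response in \{0, 1\}, both classes present.
#' @param X design matrix with intercept.
#' @return a `regression_fit` (`model = "logistic"`, `sigma = NA`).
#' @export
logistic_fit <- function(y01, X) {
  X <- as.matrix(X)
  keep <- !is.na(y01) & stats::complete.cases(X)
  y01 <- y01[keep]; X <- X[keep, , drop = FALSE]
  if (!all(y01 %in% c(0, 1))) stop("logistic_fit: response must be 0/1")
  if (length(unique(y01)) < 2) stop("logistic_fit: one response class absent")
  X <- .drop_aliased(X)
  fit <- suppressWarnings(stats::glm.fit(X, y01, family = stats::binomial()))
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  V <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(diag(V))
  names(se) <- colnames(X)
  separated <- !fit$converged || any(abs(fit$coefficients) > 15) ||
    fit$boundary
  if (separated) warning("logistic fit flagged (possible separation)")
  structure(list(coefficients = fit$coefficients, se = se, sigma = NA_real_,
                 loglik = -fit$deviance / 2, n_used = length(y01),
                 converged = !separated, model = "logistic"),
            class = "regression_fit")
}

.wald_row <- function(fit, term) {
  b <- unname(fit$coefficients[term]); s <- unname(fit$se[term])
  z <- b / s
  list(beta = b, se = s, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Genome-wide association scan of one analyte
#'
#' Regresses the prepared (transformed) analyte on each variant's dosage in
#' turn, with the cohort covariate design, using the analyte's triage mode
#' (OLS or tobit). Complete cases are taken per variant on the dosage. For
#' linear-mode analytes with no missing dosages a residualization fast path
#' (Frisch-Waugh) gives numerically identical slopes and Wald z.
#' In-sample monomorphic variants yield `beta = 0, p = 1` and are flagged.
#'
#' @param prepared a `prepared_analyte` (mode linear or tobit).
#' @param g a `genotype_matrix` (QC-filtered).
#' @param design covariate design matrix: intercept, genotype PCs, optional
#'   biomarker PC1, site indicators, clinical covariates.
#' @param cohort cohort label carried into results.
#' @return data frame, one row per variant: `variant_id`, `chr`, `pos`,
#'   `analyte`, `cohort`, `model`, `n`, `beta`, `se`, `z`, `p`, `converged`.
#' @export
scan_analyte <- function(prepared, g, design, cohort = "cohort") {
  if (prepared$mode == "drop")
    stop("analyte ", prepared$analyte_id, " was triaged to drop")
  y <- prepared$y
  D <- g$dosage
  nv <- ncol(D)
  out <- data.frame(variant_id = g$variants$variant_id,
                    chr = g$variants$chromosome, pos = g$variants$position,
                    analyte = prepared$analyte_id, cohort = cohort,
                    model = prepared$mode, n = NA_integer_,
                    beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                    converged = TRUE, stringsAsFactors = FALSE)
  base_ok <- !is.na(y) & stats::complete.cases(design)

  if (prepared$mode == "linear" && !anyNA(D[base_ok, , drop = FALSE])) {
    # fast path: residualize response and dosages on the covariate design once
    idx <- which(base_ok)
    n <- length(idx)
    Xc <- design[idx, , drop = FALSE]
    qrX <- qr(Xc)
    pX <- qrX$rank
    yr <- qr.resid(qrX, y[idx])
    Dr <- qr.resid(qrX, D[idx, , drop = FALSE])
    dd <- colSums(Dr^2)
    mono <- dd < 1e-12
    dy <- colSums(Dr * yr)
    beta <- ifelse(mono, 0, dy / dd)
    rss <- sum(yr^2) - beta^2 * dd
    df <- n - pX - 1
    se <- sqrt(pmax(rss, 0) / df / dd)
    z <- beta / se
    out$n <- n
    out$beta <- beta
    out$se <- se
    out$z <- z
    out$p <- 2 * stats::pnorm(-abs(z))
    out$beta[mono] <- 0; out$se[mono] <- NA; out$z[mono] <- NA
    out$p[mono] <- 1; out$converged[mono] <- FALSE
    return(out)
  }

  for (j in seq_len(nv)) {
    dj <- D[, j]
    ok <- base_ok & !is.na(dj)
    nj <- sum(ok)
    out$n[j] <- nj
    if (nj < ncol(design) + 2 || stats::var(dj[ok]) == 0) {
      out$beta[j] <- 0; out$p[j] <- 1; out$converged[j] <- FALSE
      next
    }
    Xj <- cbind(design[ok, , drop = FALSE], dosage = dj[ok])
    fit <- if (prepared$mode == "tobit") {
      tryCatch(suppressWarnings(
        tobit_fit(y[ok], Xj, prepared$c, prepared$censored_mask[ok])),
        error = function(e) NULL)
    } else {
      tryCatch(ols_fit(y[ok], Xj), error = function(e) NULL)
    }
    if (is.null(fit) || !"dosage" %in% names(fit$coefficients)) {
      out$converged[j] <- FALSE; out$beta[j] <- 0; out$p[j] <- 1
      next
    }
    w <- .wald_row(fit, "dosage")
    out$beta[j] <- w$beta; out$se[j] <- w$se; out$z[j] <- w$z; out$p[j] <- w$p
    out$converged[j] <- fit$converged
  }
  out
}
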
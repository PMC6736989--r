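# Negative-binomial GLM with log link, known dispersion, fitted by IRLS.
# Shared by the differential-expression tests and the unwanted-variation
# residual step. alpha parameterizes variance = mu + alpha * mu^2; alpha = 0
# is the Poisson limit.

nb_irls <- function(y, X, offset = rep(0, length(y)), alpha = 0,
                    max_iter = 50L, tol = 1e-8) {
  n <- length(y)
  p <- ncol(X)
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  beta <- rep(0, p)
  dev_old <- Inf
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    w <- mu / (1 + alpha * mu)
    z <- eta - offset + (y - mu) / mu
    XtW <- t(X * w)
    XtWX <- XtW %*% X
    fit <- tryCatch(solve(XtWX, XtW %*% z), error = function(e) NULL)
    if (is.null(fit)) break
    beta <- drop(fit)
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    dev <- nb_deviance(y, mu, alpha)
    if (is.finite(dev) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  se <- rep(NA_real_, p)
  if (!is.null(XtWX)) {
    w <- mu / (1 + alpha * mu)
    XtWX <- t(X * w) %*% X
    cv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }
  list(beta = beta, se = se, mu = mu, converged = converged,
       deviance = dev_old, loglik = nb_loglik(y, mu, alpha))
}

nb_deviance <- function(y, mu, alpha) {
  if (alpha <= 0) {
    t1 <- ifelse(y > 0, y * log(y / mu), 0)
    return(2 * sum(t1 - (y - mu)))
  }
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- (y + 1 / alpha) * log((1 + alpha * y) / (1 + alpha * mu))
  2 * sum(t1 - t2)
}

nb_loglik <- function(y, mu, alpha) {
  if (alpha <= 0) sum(stats::dpois(y, lambda = mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

# signed square-root deviance residuals of an NB fit
nb_deviance_residuals <- function(y, mu, alpha) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  if (alpha <= 0) d <- 2 * (t1 - (y - mu))
  else d <- 2 * (t1 - (y + 1 / alpha) * log((1 + alpha * y) / (1 + alpha * mu)))
  sign(y - mu) * sqrt(pmax(d, 0))
}

# group design matrix: intercept + one indicator per non-reference group,
# plus optional numeric covariates (columns of `covariates`)
group_design <- function(group, covariates = NULL) {
  group <- factor(group)
  if (nlevels(group) < 2) {
    X <- matrix(1, length(group), 1, dimnames = list(NULL, "Intercept"))
  } else {
    X <- stats::model.matrix(~group)
    colnames(X) <- sub("^group", "", colnames(X))
    colnames(X)[1] <- "Intercept"
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("W", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  X
}
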
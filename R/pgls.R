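# Phylogenetic generalized least squares (PGLS) with Pagel's lambda.
#
# Residual covariance is the Brownian-motion shared-branch-length matrix
# of the species tree with off-diagonals scaled by lambda in [0, 1]
# (lambda = 0: star-like independence; lambda = 1: full Brownian
# covariance). Lambda is estimated by maximising the profile
# log-likelihood; the regression coefficients are the closed-form GLS
# estimates at the fitted lambda.

#' Brownian covariance matrix with Pagel's lambda transform
#'
#' Entry (i, j) is the shared root-to-tip branch length of tips i and j;
#' off-diagonals are multiplied by `lambda`, diagonals (root-to-tip
#' depths) are unchanged.
#'
#' @param tree An `ape::phylo` with non-negative branch lengths.
#' @param lambda Pagel's lambda in \[0, 1\].
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
brownian_vcv <- function(tree, lambda = 1) {
  stopifnot(inherits(tree, "phylo"), lambda >= 0, lambda <= 1)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    abort("Tree must have non-negative branch lengths.")
  V <- ape::vcv(tree)
  d <- diag(V)
  V <- V * lambda
  diag(V) <- d
  V
}

pgls_loglik <- function(lambda, X, y, tree, V1) {
  V <- V1 * lambda
  diag(V) <- diag(V1)
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  # whiten: solve L z = v with L = t(ch)
  Xw <- backsolve(ch, X, transpose = TRUE)
  yw <- backsolve(ch, y, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  logdet <- 2 * sum(log(diag(ch)))
  -n / 2 * log(2 * pi) - n / 2 * log(sigma2) - logdet / 2 - n / 2
}

#' Fit a phylogenetic generalized least squares regression
#'
#' Fits `y ~ x` with residual covariance [brownian_vcv()] at Pagel's
#' lambda; `lambda = NULL` (default) profiles it by maximum likelihood
#' over \[0, 1\] (Brent search, tolerance 1e-6). Reports the slope with a
#' two-sided t-test and an adjusted R-squared computed from residual and
#' total sums of squares in the whitened space.
#'
#' @param data A data frame with one row per taxon.
#' @param x,y Column names (strings) of predictor and response.
#' @param tree An `ape::phylo`; tip labels must match `data[[taxon_col]]`.
#' @param taxon_col Column holding taxon names (default `"taxon"`).
#' @param lambda Fix lambda instead of estimating it.
#' @return An object of class `"pgls_fit"` with elements `slope`,
#'   `intercept`, `lambda`, `adj_r2`, `p_value`, `slope_se`, `df`,
#'   `loglik`, `n`.
#' @examples
#' tr <- ape::rcoal(16)
#' traits <- simulate_brownian_traits(tr, 2, 1, 0.5, seed = 1)
#' pgls_fit(traits, x = "x", y = "y", tree = tr)
#' @export
pgls_fit <- function(data, x, y, tree, taxon_col = "taxon", lambda = NULL) {
  data <- as_tibble(data)
  stopifnot(inherits(tree, "phylo"))
  data <- data[stats::complete.cases(data[, c(x, y)]), , drop = FALSE]
  if (nrow(data) < 4) abort("PGLS needs at least 4 complete-case taxa.")
  taxa <- data[[taxon_col]] %||% abort("`taxon_col` not found in data.")
  if (!setequal(taxa, tree$tip.label))
    abort("Taxa in data and tree tip labels must match one-to-one.")
  V1 <- ape::vcv(tree)[taxa, taxa]
  xv <- data[[x]]
  yv <- data[[y]]
  X <- cbind(`(Intercept)` = 1, slope = xv)
  n <- length(yv)

  if (is.null(lambda)) {
    opt <- optimize(function(l) pgls_loglik(l, X, yv, tree, V1),
                    interval = c(0, 1), maximum = TRUE, tol = 1e-6)
    # guard the boundary: optimize() never evaluates the endpoints
    cand <- c(opt$maximum, 0, 1)
    ll <- c(opt$objective,
            pgls_loglik(0, X, yv, tree, V1), pgls_loglik(1, X, yv, tree, V1))
    lambda_hat <- cand[which.max(ll)]
  } else {
    stopifnot(lambda >= 0, lambda <= 1)
    lambda_hat <- lambda
  }

  V <- V1 * lambda_hat
  diag(V) <- diag(V1)
  ch <- chol(V)
  Xw <- backsolve(ch, X, transpose = TRUE)
  yw <- backsolve(ch, yv, transpose = TRUE)
  fit <- stats::lm.fit(Xw, yw)
  beta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  p <- ncol(X)
  sigma2 <- rss / (n - p)
  XtX_inv <- chol2inv(chol(crossprod(Xw)))
  se <- sqrt(diag(XtX_inv) * sigma2)
  tstat <- beta / se
  pval <- 2 * pt(abs(tstat), df = n - p, lower.tail = FALSE)
  # R^2 against the GLS intercept-only model, in the whitened space
  w1 <- backsolve(ch, rep(1, n), transpose = TRUE)
  null_fit <- stats::lm.fit(cbind(w1), yw)
  tss <- sum(null_fit$residuals^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)
  structure(list(slope = unname(beta[2]), intercept = unname(beta[1]),
                 lambda = lambda_hat, adj_r2 = adj_r2,
                 p_value = unname(pval[2]), slope_se = unname(se[2]),
                 df = n - p,
                 loglik = pgls_loglik(lambda_hat, X, yv, tree, V1),
                 n = n, x = x, y = y),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS: %s ~ %s (n = %d)\n", x$y, x$x, x$n))
  cat(sprintf("  slope %.4f (se %.4f, p = %.3g), intercept %.4f\n",
              x$slope, x$slope_se, x$p_value, x$intercept))
  cat(sprintf("  lambda %.3f, adjusted R^2 %.3f\n", x$lambda, x$adj_r2))
  invisible(x)
}

#' Tidy a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient.
#' @export
tidy.pgls_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", x$x),
         estimate = c(x$intercept, x$slope),
         std.error = c(NA_real_, x$slope_se),
         p.value = c(NA_real_, x$p_value))
}

#' One-row summary of a PGLS fit
#'
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @return A tibble with `lambda`, `adj.r.squared`, `p.value`, `logLik`,
#'   `nobs`.
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble(lambda = x$lambda, adj.r.squared = x$adj_r2,
         p.value = x$p_value, logLik = x$loglik, nobs = x$n)
}
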
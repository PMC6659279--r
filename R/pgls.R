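# Phylogenetic generalized least squares with Pagel's lambda.
#
# The model is y = X beta + e,  e ~ MVN(0, sigma2 * V(lambda)), where V is
# the Brownian covariance of the tree and V(lambda) multiplies its
# off-diagonal by lambda in [0, 1]. beta and sigma2 are profiled out
# analytically (ML); lambda is maximised by bounded scalar search. All
# linear algebra goes through one Cholesky factorisation of V — no explicit
# matrix inverse is ever formed.

#' Generalized least squares fit with a fixed covariance matrix
#'
#' Fits `y = X beta + e`, `e ~ MVN(0, sigma2 * V)` by maximum likelihood.
#' The fit is computed in the whitened space `L^-1 y`, `L^-1 X` with
#' `V = L L'` (Cholesky), so no explicit inverse of `V` is formed.
#' `sigma2` is the ML profile estimate `r' V^-1 r / n`; standard errors
#' carry the usual `n/(n - p)` small-sample variance adjustment and
#' confidence intervals use the t distribution with `n - p` degrees of
#' freedom.
#'
#' @param y Numeric response vector, optionally named by taxon. When both
#'   `y` and `V` carry names, `V` is re-ordered to match `y`.
#' @param X Design matrix (including the intercept column), rows ordered
#'   as `y`.
#' @param V Positive-definite covariance matrix (up to the scalar
#'   `sigma2`), e.g. a lambda-transformed output of [vcv_from_tree()].
#' @param lambda Value recorded in the fit (`NA` when `V` was supplied
#'   directly); purely informational here — use [fit_lambda_ml()] to
#'   estimate it.
#' @param level Confidence level for the per-coefficient intervals.
#' @param extra_params Number of variance-structure parameters counted in
#'   `k` beyond the `p` coefficients: 1 for `sigma2` alone (default), 2
#'   when lambda was also estimated.
#'
#' @return An object of class `"pgls_fit"`: list with `beta`, `se`,
#'   `ci_low`, `ci_high`, `significant`, `vcov`, `lambda`, `sigma2`
#'   (ML), `logLik`, `k`, `n`, `p`, `aicc`, `rss` (whitened residual sum
#'   of squares), `fitted`, `residuals`, `level`.
#' @export
gls_fit <- function(y, X, V, lambda = NA_real_, level = 0.95,
                    extra_params = 1L) {
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n) {
    stop("dimensions of y, X and V disagree", call. = FALSE)
  }
  if (!is.null(names(y)) && !is.null(rownames(V))) {
    if (!setequal(names(y), rownames(V))) {
      stop("taxa of y and V differ", call. = FALSE)
    }
    V <- V[names(y), names(y)]
  }
  if (n <= p) {
    stop(sprintf("degenerate fit: n = %d observations for p = %d coefficients",
                 n, p), call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  U <- tryCatch(chol(V), error = function(e) {
    stop("covariance matrix is not positive definite", call. = FALSE)
  })
  # whitening: with V = U'U, z = U^-T y satisfies z'z = y' V^-1 y
  yw <- backsolve(U, y, transpose = TRUE)
  Xw <- backsolve(U, X, transpose = TRUE)
  fit <- lm.fit(Xw, yw)
  beta <- fit$coefficients
  rw <- fit$residuals
  rss <- sum(rw^2)
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(U)))
  if (sigma2 <= 0) {
    stop("residuals are exactly zero: sigma2 = 0, likelihood unbounded",
         call. = FALSE)
  }
  lnL <- -n / 2 * log(2 * pi * sigma2) - logdetV / 2 - n / 2
  XtViX_inv <- chol2inv(qr.R(qr(Xw)))
  vcov_beta <- sigma2 * n / (n - p) * XtViX_inv
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov_beta))
  tq <- stats::qt(1 - (1 - level) / 2, df = n - p)
  ci_low <- beta - tq * se
  ci_high <- beta + tq * se
  k <- p + as.integer(extra_params)
  structure(list(
    beta = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    ci_low = stats::setNames(ci_low, colnames(X)),
    ci_high = stats::setNames(ci_high, colnames(X)),
    significant = stats::setNames(ci_low > 0 | ci_high < 0, colnames(X)),
    vcov = vcov_beta,
    lambda = lambda,
    sigma2 = sigma2,
    logLik = lnL,
    k = k, n = n, p = p,
    aicc = if (n - k - 1 > 0) aicc(lnL, k, n) else NA_real_,
    rss = rss,
    fitted = as.vector(X %*% beta),
    residuals = as.vector(y - X %*% beta),
    level = level
  ), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("<pgls_fit> n = %d, p = %d, lambda = %s, sigma2 = %.4g, lnL = %.3f, AICc = %.3f\n",
              x$n, x$p,
              if (is.na(x$lambda)) "fixed V" else sprintf("%.3f", x$lambda),
              x$sigma2, x$logLik, x$aicc))
  tab <- data.frame(estimate = x$beta, se = x$se,
                    ci_low = x$ci_low, ci_high = x$ci_high,
                    significant = x$significant)
  print(round(tab[1:4], 4))
  invisible(x)
}

# profile log-likelihood of lambda given the base Brownian covariance
.lambda_profile <- function(y, X, V0) {
  function(lam) gls_fit(y, X, apply_lambda(V0, lam), lambda = lam)$logLik
}

#' PGLS with maximum-likelihood Pagel's lambda
#'
#' Maximises the profile log-likelihood over `lambda` in `[0, 1]`: an
#' 11-point coarse grid brackets the optimum, Brent's method
#' ([stats::optimize()], tolerance `1e-6`) refines it within the bracketing
#' window, and both endpoints are checked explicitly. The returned fit's
#' parameter count is `k = p + 2` (`sigma2` and `lambda`).
#'
#' @param y Named numeric response vector (names = taxa).
#' @param X Design matrix, rows ordered as `y`.
#' @param tree An [ape::phylo] whose tips match `names(y)` (any order).
#' @param V0 Alternatively, the Brownian covariance matrix itself.
#' @param tol Convergence tolerance for the scalar search.
#' @param level Confidence level for coefficient intervals.
#' @return A `"pgls_fit"` (see [gls_fit()]) with `lambda` set to the ML
#'   estimate.
#' @export
fit_lambda_ml <- function(y, X, tree = NULL, V0 = NULL, tol = 1e-6,
                          level = 0.95) {
  if (is.null(V0)) {
    if (is.null(tree)) stop("supply a tree or a covariance matrix", call. = FALSE)
    V0 <- vcv_from_tree(tree)
  }
  if (!is.null(names(y)) && !is.null(rownames(V0))) {
    if (!setequal(names(y), rownames(V0))) {
      stop("taxa of y and the tree/covariance differ", call. = FALSE)
    }
    V0 <- V0[names(y), names(y)]
  }
  f <- .lambda_profile(y, X, V0)
  grid <- seq(0, 1, by = 0.1)
  gvals <- vapply(grid, f, numeric(1L))
  if (any(!is.finite(gvals))) {
    stop("lambda profile likelihood non-finite; optimisation trace: ",
         paste(sprintf("f(%.1f)=%g", grid, gvals), collapse = ", "),
         call. = FALSE)
  }
  ibest <- which.max(gvals)
  lo <- grid[max(1L, ibest - 1L)]
  hi <- grid[min(length(grid), ibest + 1L)]
  opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, grid[ibest], 0, 1)
  cvals <- c(opt$objective, gvals[ibest], gvals[1L], gvals[length(grid)])
  lam_hat <- cand[which.max(cvals)]
  gls_fit(y, X, apply_lambda(V0, lam_hat), lambda = lam_hat, level = level,
          extra_params = 2L)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param lnL Maximised log-likelihood.
#' @param k Number of estimated parameters (coefficients + variance
#'   parameters).
#' @param n Number of observations.
#' @return Numeric scalar.
#' @examples
#' aicc(-10, 3, 10)  # 30
#' @export
aicc <- function(lnL, k, n) {
  if (n - k - 1 <= 0) {
    stop(sprintf("AICc undefined: n = %d <= k + 1 = %d", n, k + 1),
         call. = FALSE)
  }
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank a set of fitted models by AICc
#'
#' Computes `delta_aicc = AICc - min(AICc)`, Akaike weights
#' `exp(-delta/2) / sum(exp(-delta/2))`, and the full pairwise
#' evidence-ratio matrix `w_a / w_b`. Ties in the ranking break by fewer
#' parameters, then model name, for deterministic output.
#'
#' @param fits Named list of `"pgls_fit"` objects (or a named list of
#'   lists with elements `aicc`, `k`, `n` — the aggregated fits of
#'   [multi_tree_pgls()] qualify). All fits must share `n`.
#' @return An object of class `"model_comparison"`: list with `table`
#'   (data.frame: model, aicc, delta_aicc, weight, lambda, r, k, sorted by
#'   delta) and `evidence_ratios` (matrix).
#' @export
compare_models <- function(fits) {
  if (!length(fits) || is.null(names(fits)) || any(!nzchar(names(fits)))) {
    stop("fits must be a non-empty named list", call. = FALSE)
  }
  get0n <- function(f, field) if (!is.null(f[[field]])) f[[field]] else NA_real_
  n_set <- unique(vapply(fits, function(f) as.numeric(f$n), numeric(1L)))
  if (length(n_set) != 1L) {
    stop("all models must be fitted to the same observations (n differs)",
         call. = FALSE)
  }
  tab <- data.frame(
    model = names(fits),
    aicc = vapply(fits, function(f) as.numeric(f$aicc), numeric(1L)),
    k = vapply(fits, function(f) as.numeric(f$k), numeric(1L)),
    lambda = vapply(fits, function(f) as.numeric(get0n(f, "lambda")), numeric(1L)),
    r = vapply(fits, function(f) as.numeric(get0n(f, "r")), numeric(1L)),
    stringsAsFactors = FALSE
  )
  tab$delta_aicc <- tab$aicc - min(tab$aicc)
  w <- exp(-tab$delta_aicc / 2)
  tab$weight <- w / sum(w)
  ord <- order(tab$delta_aicc, tab$k, tab$model)
  tab <- tab[ord, c("model", "aicc", "delta_aicc", "weight", "lambda", "r", "k")]
  rownames(tab) <- NULL
  er <- outer(tab$weight, tab$weight, "/")
  dimnames(er) <- list(tab$model, tab$model)
  structure(list(table = tab, evidence_ratios = er, n = n_set),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %d models, n = %g\n", nrow(x$table), x$n))
  tab <- x$table
  tab[2:6] <- lapply(tab[2:6], round, 3)
  print(tab)
  invisible(x)
}

#' Evidence ratio of one model over another
#'
#' Ratio of Akaike weights, `exp((delta_b - delta_a) / 2)`.
#'
#' @param comparison A `"model_comparison"`.
#' @param a,b Model names.
#' @return Numeric scalar: how many times more likely `a` is than `b`.
#' @export
evidence_ratio <- function(comparison, a, b) {
  stopifnot(inherits(comparison, "model_comparison"))
  er <- comparison$evidence_ratios
  if (!a %in% rownames(er) || !b %in% rownames(er)) {
    stop("unknown model name", call. = FALSE)
  }
  er[a, b]
}

#' Per-coefficient confidence intervals
#'
#' `beta_hat +/- t_{1-alpha/2, n-p} * se`; a coefficient is flagged
#' significant when its interval excludes 0.
#'
#' @param fit A `"pgls_fit"`.
#' @param level Confidence level (default 0.95).
#' @return data.frame with columns `term`, `estimate`, `se`, `low`,
#'   `high`, `significant`.
#' @export
confidence_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "pgls_fit"))
  df <- fit$n - fit$p
  if (df <= 0) stop("no residual degrees of freedom", call. = FALSE)
  tq <- stats::qt(1 - (1 - level) / 2, df = df)
  low <- fit$beta - tq * fit$se
  high <- fit$beta + tq * fit$se
  data.frame(term = names(fit$beta), estimate = unname(fit$beta),
             se = unname(fit$se), low = unname(low), high = unname(high),
             significant = unname(low > 0 | high < 0),
             stringsAsFactors = FALSE)
}

#' Effect size r of a model against the intercept-only null
#'
#' `r = sqrt(1 - RSS_model / RSS_null)`, each residual sum of squares
#' taken in the whitened space of that fit's own `V(lambda_hat)`. `r^2` is
#' the share of (phylogenetically whitened) variance explained.
#'
#' @param fit,null_fit `"pgls_fit"` objects on the same data; `null_fit`
#'   is intercept-only with the same lambda handling.
#' @return Numeric scalar in `[0, 1]`.
#' @export
effect_size <- function(fit, null_fit) {
  stopifnot(inherits(fit, "pgls_fit"), inherits(null_fit, "pgls_fit"))
  if (fit$n != null_fit$n) stop("fits are on different data", call. = FALSE)
  if (null_fit$rss <= 0) stop("null model has zero residual sum of squares",
                              call. = FALSE)
  ratio <- fit$rss / null_fit$rss
  sqrt(max(0, 1 - ratio))
}

#' PGLS aggregated across random polytomy resolutions
#'
#' Resolves the tree's polytomies [resolve_polytomies()] once per
#' iteration under per-iteration seeds derived from the master seed, fits
#' the lambda-ML PGLS on each resolution, and reports the per-iteration
#' table together with across-iteration mean and median summaries of AICc,
#' lambda, the coefficients and their intervals. Fully reproducible from
#' the master seed. Single-iteration failures are recorded and excluded; if
#' more than 1% of iterations fail the whole call errors.
#'
#' @param y Named response vector (names = taxa in the tree).
#' @param X Design matrix, rows ordered as `y`.
#' @param tree [ape::phylo], binary or polytomous.
#' @param n_iter Number of random resolutions (the study design used
#'   1000).
#' @param seed Master seed.
#' @param level Confidence level.
#' @return Object of class `"multi_pgls"`: list with `aggregate` (lists
#'   `mean` and `median`, each with `aicc`, `lambda`, `sigma2`, `logLik`,
#'   `beta`, `se`, `ci_low`, `ci_high`), `iterations` (data.frame),
#'   `fits` (list of per-iteration `"pgls_fit"`), `n`, `k`, `aicc`
#'   (mean, the headline ranking value), `lambda`, `failed` (integer
#'   iteration ids).
#' @export
multi_tree_pgls <- function(y, X, tree, n_iter = 1000L, seed = 1L,
                            level = 0.95) {
  stopifnot(n_iter >= 1L)
  seeds <- derive_seeds(seed, n_iter)
  binary <- is_binary_rooted(tree)
  fits <- vector("list", n_iter)
  failed <- integer(0L)
  base_fit <- NULL
  for (i in seq_len(n_iter)) {
    if (binary && !is.null(base_fit)) {
      fits[[i]] <- base_fit  # no polytomies: every resolution is the tree
      next
    }
    res <- tryCatch({
      tr <- resolve_polytomies(tree, seeds[i])
      fit_lambda_ml(y, X, tree = tr, level = level)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, i)
      fits[i] <- list(NULL)
    } else {
      fits[[i]] <- res
      if (binary) base_fit <- res
    }
  }
  if (length(failed) > max(1, 0.01 * n_iter)) {
    stop(sprintf("%d of %d iterations failed (> 1%%); first error at iteration %d",
                 length(failed), n_iter, failed[1L]), call. = FALSE)
  }
  ok <- fits[!vapply(fits, is.null, logical(1L))]
  iter_tab <- do.call(rbind, lapply(which(!vapply(fits, is.null, logical(1L))),
                                    function(i) {
    f <- fits[[i]]
    cbind(data.frame(iteration = i, seed = seeds[i], aicc = f$aicc,
                     lambda = f$lambda, sigma2 = f$sigma2, logLik = f$logLik),
          as.data.frame(as.list(stats::setNames(f$beta, paste0("beta_", names(f$beta))))),
          as.data.frame(as.list(stats::setNames(f$ci_low, paste0("lo_", names(f$beta))))),
          as.data.frame(as.list(stats::setNames(f$ci_high, paste0("hi_", names(f$beta))))))
  }))
  agg <- function(fun) {
    list(
      aicc = fun(vapply(ok, `[[`, numeric(1L), "aicc")),
      lambda = fun(vapply(ok, `[[`, numeric(1L), "lambda")),
      sigma2 = fun(vapply(ok, `[[`, numeric(1L), "sigma2")),
      logLik = fun(vapply(ok, `[[`, numeric(1L), "logLik")),
      beta = apply(do.call(rbind, lapply(ok, `[[`, "beta")), 2L, fun),
      se = apply(do.call(rbind, lapply(ok, `[[`, "se")), 2L, fun),
      ci_low = apply(do.call(rbind, lapply(ok, `[[`, "ci_low")), 2L, fun),
      ci_high = apply(do.call(rbind, lapply(ok, `[[`, "ci_high")), 2L, fun)
    )
  }
  mean_agg <- agg(mean)
  structure(list(
    aggregate = list(mean = mean_agg, median = agg(stats::median)),
    iterations = iter_tab,
    fits = fits,
    n = ok[[1L]]$n,
    k = ok[[1L]]$k,
    aicc = mean_agg$aicc,
    lambda = mean_agg$lambda,
    beta = mean_agg$beta,
    ci_low = mean_agg$ci_low,
    ci_high = mean_agg$ci_high,
    failed = failed,
    n_iter = n_iter,
    seed = seed
  ), class = "multi_pgls")
}

#' @export
print.multi_pgls <- function(x, ...) {
  cat(sprintf("<multi_pgls> %d iterations (%d failed), n = %d\n",
              x$n_iter, length(x$failed), x$n))
  cat(sprintf("  mean AICc = %.3f, mean lambda = %.3f\n", x$aicc, x$lambda))
  print(round(rbind(beta = x$beta, ci_low = x$ci_low, ci_high = x$ci_high), 4))
  invisible(x)
}
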
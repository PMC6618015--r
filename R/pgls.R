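# Phylogenetic generalized least squares with Pagel's lambda.

#' Brownian phylogenetic covariance with Pagel's lambda
#'
#' `V_ij` is the shared root-to-tip path length of tips i and j, scaled
#' by `lambda` off the diagonal; diagonal entries are unscaled tip
#' depths (the Pagel transform).
#'
#' @param tree An `ape` phylo tree with unique tips and positive branch
#'   lengths.
#' @param lambda Scalar in `[0, 1]`.
#' @return Species x species covariance matrix, tips as dimnames.
#' @export
brownian_covariance <- function(tree, lambda = 1) {
  if (anyDuplicated(tree$tip.label)) stop_invalid("duplicate tip labels")
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0)) {
    stop_invalid("tree must have positive branch lengths")
  }
  if (lambda < 0 || lambda > 1) stop_invalid("`lambda` must lie in [0, 1]")
  v <- ape::vcv.phylo(tree)
  d <- diag(v)
  v <- v * lambda
  diag(v) <- d
  v
}

pgls_loglik <- function(y, X, V) {
  n <- length(y)
  L <- t(chol(V))
  yw <- forwardsolve(L, y)
  Xw <- forwardsolve(L, X)
  qr_ <- qr(Xw)
  beta <- qr.coef(qr_, yw)
  resid <- yw - Xw %*% beta
  rss <- sum(resid^2)
  sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(L))) + n)
  list(beta = beta, rss = rss, sigma2 = sigma2, loglik = ll,
       yw = yw, Xw = Xw)
}

#' Phylogenetic generalized least squares under Pagel's lambda
#'
#' GLS fit `beta = (X' V^-1 X)^-1 X' V^-1 y` with
#' `V = brownian_covariance(tree, lambda)`. `lambda` is either fixed or
#' profiled by maximum likelihood over `[0, 1]` (golden-section/Brent
#' search, tolerance 1e-6). The slope p-value is a t-test with `n - 2`
#' degrees of freedom; `r_squared` is computed in the V-whitened space
#' against the GLS intercept-only fit.
#'
#' @param data Tibble with a `species` column matching the tree's tips.
#' @param y,x Column names (strings) of response and predictor.
#' @param tree `ape` phylo tree.
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @return Object of class `pgls_fit` with `coefficients` tibble
#'   (intercept and slope with SE, t, p), `lambda`, `loglik`,
#'   `r_squared`, `sigma2`, `n`, and the model frame.
#' @export
pgls_fit <- function(data, y, x, tree, lambda = "ML") {
  data <- as_tibble(data)
  if (!all(c("species", y, x) %in% names(data))) {
    stop_invalid("`data` must carry columns species, y and x")
  }
  if (!setequal(data$species, tree$tip.label)) {
    stop_invalid("species must match the tree's tip set")
  }
  n <- nrow(data)
  if (n < 3) stop_invalid("PGLS needs at least 3 species")
  ord <- match(tree$tip.label, data$species)
  yy <- data[[y]][ord]
  xx <- data[[x]][ord]
  if (any(!is.finite(yy)) || any(!is.finite(xx))) {
    stop_invalid("response and predictor must be finite")
  }
  X <- cbind(`(Intercept)` = 1, slope = xx)
  fit_lambda <- function(l) pgls_loglik(yy, X, brownian_covariance(tree, l))
  if (identical(lambda, "ML")) {
    opt <- optimize(function(l) fit_lambda(l)$loglik, c(0, 1),
                    maximum = TRUE, tol = 1e-6)
    lam <- opt$maximum
    # the interior optimum can lose to a boundary; check both ends
    cand <- c(0, lam, 1)
    lls <- vapply(cand, function(l) fit_lambda(l)$loglik, numeric(1))
    lam <- cand[which.max(lls)]
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop_invalid("`lambda` must be 'ML' or a value in [0, 1]")
    }
    lam <- lambda
  }
  f <- fit_lambda(lam)
  df_resid <- n - 2
  sigma2_hat <- f$rss / df_resid
  xtx_inv <- chol2inv(qr.R(qr(f$Xw)))
  se <- sqrt(diag(xtx_inv) * sigma2_hat)
  est <- as.numeric(f$beta)
  tval <- est / se
  pval <- 2 * pt(abs(tval), df_resid, lower.tail = FALSE)
  # whitened-space r^2 against the GLS intercept-only fit
  w0 <- forwardsolve(t(chol(brownian_covariance(tree, lam))),
                     rep(1, n))
  b0 <- sum(w0 * f$yw) / sum(w0^2)
  tss <- sum((f$yw - w0 * b0)^2)
  r2 <- if (tss > 0) 1 - f$rss / tss else NA_real_
  structure(
    list(
      coefficients = tibble(term = c("(Intercept)", x), estimate = est,
                            std_error = se, statistic = tval,
                            p_value = pval),
      lambda = lam, loglik = f$loglik, r_squared = r2,
      sigma2 = f$sigma2, n = n, response = y, predictor = x,
      data = tibble(species = tree$tip.label, y = yy, x = xx)
    ),
    class = "pgls_fit"
  )
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("<pgls_fit> ", x$response, " ~ ", x$predictor, " | n = ", x$n,
      " | lambda = ", signif(x$lambda, 4),
      " | r^2 = ", signif(x$r_squared, 3), "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.pgls_fit <- function(x, ...) x$coefficients

#' @export
glance.pgls_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, lambda = x$lambda, loglik = x$loglik,
         sigma2 = x$sigma2, n = x$n,
         p_value = x$coefficients$p_value[2])
}

#' @export
autoplot.pgls_fit <- function(object, ...) {
  cf <- object$coefficients$estimate
  ggplot(object$data, aes(x = .data$x, y = .data$y)) +
    geom_abline(intercept = cf[1], slope = cf[2], linetype = 2,
                colour = "grey40") +
    geom_point(size = 2) +
    labs(x = object$predictor, y = object$response,
         subtitle = sprintf("lambda = %.3f, r^2 = %.3f, p = %.3g",
                            object$lambda, object$r_squared,
                            object$coefficients$p_value[2])) +
    theme_minimal()
}
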
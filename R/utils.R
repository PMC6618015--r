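# Internal helpers shared across modules.

#' Derive a stage-specific RNG seed from a single global seed
#'
#' All stochastic stages draw their seed from one global integer so that a
#' whole simulated study is reproducible bit-for-bit while stages remain
#' independently re-runnable. The derived seed always fits in a 32-bit
#' signed integer.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"genotypes"`).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "genotypes")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 65536L
  as.integer((abs(as.integer(seed)) %% 1000003L) * 2011L + h)
}

stop_invalid <- function(msg) {
  abort(msg, class = "sexconflictr_invalid")
}

# ceil(n/2) rule used by "half or more" / "fewer than half" filters
half_of <- function(n) ceiling(n / 2)

# log-sum-exp safe normalization of a nonnegative vector to sum 1
normalize_sum1 <- function(x) {
  s <- sum(x)
  if (s <= 0) stop_invalid("cannot normalize a vector with nonpositive sum")
  x / s
}

# Vectorized golden-section maximization over [0, 1], one bracket per row.
# f(p) must accept a vector p (one value per problem) and return the
# objective per problem. Tolerance on the bracket width.
golden_max <- function(f, n, tol = 1e-6) {
  a <- rep(0, n)
  b <- rep(1, n)
  gr <- (sqrt(5) - 1) / 2
  repeat {
    x1 <- b - gr * (b - a)
    x2 <- a + gr * (b - a)
    f1 <- f(x1)
    f2 <- f(x2)
    up <- f2 >= f1
    a <- ifelse(up, x1, a)
    b <- ifelse(up, b, x2)
    if (max(b - a) < tol) break
  }
  (a + b) / 2
}
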
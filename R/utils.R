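# Internal numerical helpers shared across modules.

#' @importFrom withr local_seed
.withSeed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = env)
  invisible(NULL)
}

#' Derive a reproducible stream of sub-seeds from a master seed
#'
#' Every stochastic stage of the benchmark takes an explicit seed; the
#' orchestrator draws one sub-seed per stage from this stream so that a single
#' master seed reproduces a whole run.
#'
#' @param masterSeed integer master seed.
#' @param n number of sub-seeds to draw.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
seedStream <- function(masterSeed, n) {
  .withSeed(as.integer(masterSeed))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

.geoMean <- function(x) exp(mean(log(x)))

# Column-wise ranks with midranks for ties (samples in rows).
.rankCols <- function(X) {
  if (is.null(dim(X))) return(rank(X))
  apply(X, 2L, rank)
}

# Two-sided p-value for a correlation coefficient via the t approximation
# (the convention stats::cor.test falls back to in the presence of ties).
.corP <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n > 2
  tt <- abs(r[ok]) * sqrt((n - 2) / pmax(1 - r[ok]^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  pmin(p, 1)
}

# Spearman correlations of the columns of X against the columns of Y
# (or all column pairs of X when Y is NULL), with t-approximation p-values.
.spearman <- function(X, Y = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  rx <- .rankCols(X)
  if (is.null(Y)) {
    r <- suppressWarnings(stats::cor(rx))
  } else {
    Y <- as.matrix(Y)
    stopifnot(nrow(Y) == n)
    r <- suppressWarnings(stats::cor(rx, .rankCols(Y)))
  }
  list(rho = r, p = array(.corP(r, n), dim = dim(r), dimnames = dimnames(r)))
}

# Vectorized Kruskal-Wallis test of every column of X across groups g.
# Equivalent to stats::kruskal.test per column (ties handled through the
# empirical rank variance); returns the H statistic and chi-square p-value.
.kruskalCols <- function(X, g) {
  X <- as.matrix(X)
  g <- as.factor(g)
  n <- nrow(X)
  R <- .rankCols(X)
  M <- stats::model.matrix(~ g - 1)
  ng <- colSums(M)
  gm <- crossprod(M, R) / ng                 # group mean ranks (G x m)
  rbar <- (n + 1) / 2
  ssb <- colSums(ng * (gm - rbar)^2)
  sst <- colSums((R - rbar)^2)
  H <- ifelse(sst > 0, (n - 1) * ssb / sst, NA_real_)
  list(statistic = H,
       p = stats::pchisq(H, df = nlevels(g) - 1, lower.tail = FALSE))
}

# type-7 quantile, the single convention used for every quantile in the package
.q7 <- function(x, p) stats::quantile(x, probs = p, type = 7, names = FALSE)

.checkCountMatrix <- function(x, what = "counts") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix")
  if (any(!is.finite(x)) || any(x < 0))
    stop(what, " must be finite and nonnegative")
  invisible(x)
}
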
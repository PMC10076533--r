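# Internal helpers shared across modules.

#' Sample from a geometric distribution truncated to {0, ..., m-1}
#'
#' P(d = k) is proportional to (1-p)^k for k in 0..m-1.  p = 0 degenerates
#' to the discrete uniform on 0..m-1; p = 1 is the point mass at 0.
#' Used by the drug-signature simulator to pull signature genes toward one
#' end of the rank list with strength monotone in the compound's activity.
#'
#' @noRd
rtruncgeom <- function(n, p, m) {
  stopifnot(p >= 0, p <= 1, m >= 1)
  u <- stats::runif(n)
  if (p <= 0) return(floor(u * m))
  if (p >= 1) return(rep(0L, n))
  q <- 1 - p
  # inverse CDF of the truncated geometric
  d <- floor(log(1 - u * (1 - q^m)) / log(q))
  pmin(pmax(d, 0), m - 1)
}

#' Derive a stage seed from the master seed
#'
#' Fixed documented derivation so pipeline stages can be rerun in
#' isolation reproducibly; kept below 2^31 - 1.
#'
#' @noRd
stage_seed <- function(seed, stage) {
  offsets <- c(
    reports = 101L, expression = 211L, drugsig = 307L, ic50 = 401L,
    mgps = 503L, demo = 601L
  )
  off <- offsets[[stage]]
  (as.integer(seed) * 1009L + off) %% 2147483647L
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Computes rho as the product-moment correlation of average ranks and a
#' two-sided p-value from the t distribution with n - 2 degrees of
#' freedom.  Deterministic; ties handled by average ranks.
#'
#' @param x,y Paired numeric vectors (finite, length >= 3).
#' @return A list with elements `rho`, `p` and `n`.
#' @examples
#' spearman_cor(1:10, (1:10)^2)$rho  # 1
#' @export
spearman_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("spearman_cor() needs at least 3 complete pairs, got ", n)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("spearman_cor(): zero variance; rho is undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

# Vectorised Spearman of each column of X against y.  Zero-variance
# columns get rho = NA, p = 1 (they can never be selected downstream).
spearman_cols <- function(X, y) {
  n <- length(y)
  R <- apply(X, 2, rank)
  ry <- rank(y)
  sds <- apply(R, 2, stats::sd)
  rho <- suppressWarnings(as.vector(stats::cor(R, ry)))
  rho[sds == 0] <- NA_real_
  p <- rep(1, length(rho))
  ok <- !is.na(rho) & abs(rho) < 1
  tt <- rho[ok] * sqrt((n - 2) / (1 - rho[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[!is.na(rho) & abs(rho) >= 1] <- 0
  list(rho = rho, p = p)
}

# Deterministic TSV writers/readers used by every stage.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
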
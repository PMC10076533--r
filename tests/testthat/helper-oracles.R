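# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Brute-force KS-type enrichment score: evaluate the two max-expressions
# directly from the definition.
oracle_es <- function(positions, N) {
  V <- sort(positions)
  s <- length(V)
  a_terms <- b_terms <- numeric(s)
  for (j in seq_len(s)) {
    a_terms[j] <- j / s - V[j] / N
    b_terms[j] <- V[j] / N - (j - 1) / s
  }
  a <- max(a_terms)
  b <- max(b_terms)
  if (a >= b) a else -b
}

# Independently coded ROR and Wald CI.
oracle_ror <- function(a, b, c, d) {
  or <- a / b / (c / d)
  se <- sqrt(sum(1 / c(a, b, c, d)))
  c(ror = or, lci = or * exp(-1.96 * se), uci = or * exp(1.96 * se))
}

# Numerical gamma quantile by bisection on the CDF (independent of qgamma).
oracle_gamma_quantile <- function(p, shape, rate) {
  f <- function(x) stats::pgamma(x, shape = shape, rate = rate) - p
  lo <- 0
  hi <- shape / rate + 1
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# Posterior mean of ln(lambda) under a gamma-mixture posterior by
# numerical integration of the density.
oracle_post_mean_log <- function(q, s1, r1, s2, r2) {
  # integrate each component over its own extreme-quantile window so the
  # quadrature always sees the density peak
  comp <- function(s, r) {
    stats::integrate(function(x) log(x) * stats::dgamma(x, s, r),
                     lower = stats::qgamma(1e-13, s, r),
                     upper = stats::qgamma(1 - 1e-13, s, r),
                     rel.tol = 1e-11, subdivisions = 1000L)$value
  }
  q * comp(s1, r1) + (1 - q) * comp(s2, r2)
}

# Tiny three-report FAERS-style fixture used by the preprocessing tests.
make_report_fixture <- function() {
  demo <- data.frame(
    PRIMARYID = c(101L, 201L, 301L), CASEID = c(10L, 20L, 30L),
    EVENT_DT = c(20190101L, 20190202L, 20190303L))
  drug <- data.frame(
    PRIMARYID = c(101L, 201L, 301L), CASEID = c(10L, 20L, 30L),
    ROLE_COD = "PS",
    DRUGNAME = c("ASPIRIN", "IBUPROFEN", "NAPROXEN"))
  reac <- data.frame(
    PRIMARYID = c(101L, 201L, 301L), CASEID = c(10L, 20L, 30L),
    PT = c("Psoriasis", "Headache", "Psoriasis"))
  read_reports(demo, drug, reac)
}

# Small signature + exactly reversing / concordant rank profiles.
make_signature <- function(up, down) {
  list(up_genes = up, down_genes = down)
}
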
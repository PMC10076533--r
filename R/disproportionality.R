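# Disproportionality statistics on drug-event 2x2 tables: reporting odds
# ratio (ROR) with Wald CI, Bayesian information component (IC) with
# gamma-posterior credible bounds, and inverse-signal flagging.

#' Reporting odds ratio with 95% Wald confidence interval
#'
#' ROR = (a d)/(b c); CI = exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)).
#' Any zero cell makes the ROR undefined (NA) unless the Haldane-Anscombe
#' +0.5 correction is enabled.
#'
#' @param a,b,c,d Vectors of cell counts (drug&event, drug&other, other
#'   drug&event, neither).
#' @param haldane Add 0.5 to every cell before computing (default FALSE).
#' @return Data frame: ror, ror_lci, ror_uci (NA where undefined).
#' @export
compute_ror <- function(a, b, c, d, haldane = FALSE) {
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- lci <- uci <- rep(NA_real_, length(a))
  ror[ok] <- (a[ok] * d[ok]) / (b[ok] * c[ok])
  se <- sqrt(1 / a[ok] + 1 / b[ok] + 1 / c[ok] + 1 / d[ok])
  lci[ok] <- exp(log(ror[ok]) - 1.96 * se)
  uci[ok] <- exp(log(ror[ok]) + 1.96 * se)
  data.frame(ror = ror, ror_lci = lci, ror_uci = uci)
}

#' Information component with 95% credible interval
#'
#' IC = log2((a + 0.5)/(E + 0.5)) where E is the expected count under
#' independence.  Credible bounds are log2 of the 2.5th/97.5th percentiles
#' of the gamma posterior with shape a + 0.5 and rate E + 0.5 (whose mean
#' is the regularised observed/expected ratio).
#'
#' @param a Observed counts.
#' @param E Expected counts under independence (> 0; E = 0 gives NA).
#' @return Data frame: ic, ic025, ic975.
#' @export
compute_ic <- function(a, E) {
  ok <- is.finite(E) & E > 0 & is.finite(a) & a >= 0
  ic <- lo <- hi <- rep(NA_real_, length(a))
  sh <- a[ok] + 0.5
  rt <- E[ok] + 0.5
  ic[ok] <- log2(sh / rt)
  lo[ok] <- log2(stats::qgamma(0.025, shape = sh, rate = rt))
  hi[ok] <- log2(stats::qgamma(0.975, shape = sh, rate = rt))
  data.frame(ic = ic, ic025 = lo, ic975 = hi)
}

#' Flag inverse signals on a computed statistics table
#'
#' Strict-threshold rules: inverse_ror iff ror_uci < 1; inverse_ic iff
#' ic975 < 0; inverse_ebgm iff ebgm95 < 1.  Undefined statistics are never
#' flagged.
#'
#' @param results Data frame carrying whichever of ror_uci, ic975, ebgm95
#'   were computed.
#' @return `results` with logical columns inverse_ror / inverse_ic /
#'   inverse_ebgm added for available methods; attribute `signal_counts`
#'   holds the per-method flag totals.
#' @export
flag_signals <- function(results) {
  counts <- c()
  if ("ror_uci" %in% names(results)) {
    results$inverse_ror <- !is.na(results$ror_uci) & results$ror_uci < 1
    counts["ror"] <- sum(results$inverse_ror)
  }
  if ("ic975" %in% names(results)) {
    results$inverse_ic <- !is.na(results$ic975) & results$ic975 < 0
    counts["ic"] <- sum(results$inverse_ic)
  }
  if ("ebgm95" %in% names(results)) {
    results$inverse_ebgm <- !is.na(results$ebgm95) & results$ebgm95 < 1
    counts["ebgm"] <- sum(results$inverse_ebgm)
  }
  attr(results, "signal_counts") <- counts
  results
}

#' Full disproportionality analysis of a contingency table
#'
#' Computes ROR, IC and EBGM (with a freshly fitted gamma-mixture prior
#' unless one is supplied) for every drug-event cell and flags inverse
#' signals.
#'
#' @param cells A `contingency` data frame from [build_contingency()].
#' @param methods Subset of c("ror", "ic", "ebgm").
#' @param prior Optional pre-fitted [fit_mgps()] prior (refitted otherwise).
#' @param seed Seed for the prior fit's multi-start optimisation.
#' @return Signal table: one row per (drug, event) with statistics,
#'   interval bounds and inverse flags.
#' @export
disproportionality <- function(cells, methods = c("ror", "ic", "ebgm"),
                               prior = NULL, seed = 1L) {
  stopifnot(all(c("drug", "event", "a", "b", "c", "d", "expected")
                %in% names(cells)))
  methods <- match.arg(methods, c("ror", "ic", "ebgm"), several.ok = TRUE)
  out <- cells[c("drug", "event", "a", "expected")]
  if ("ror" %in% methods)
    out <- cbind(out, compute_ror(cells$a, cells$b, cells$c, cells$d))
  if ("ic" %in% methods)
    out <- cbind(out, compute_ic(cells$a, cells$expected))
  if ("ebgm" %in% methods) {
    if (is.null(prior))
      prior <- fit_mgps(cells$a, cells$expected, seed = seed)
    out <- cbind(out, compute_ebgm(cells$a, cells$expected, prior))
    attr(out, "prior") <- prior
  }
  flag_signals(out)
}
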
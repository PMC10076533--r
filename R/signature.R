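# Disease signature: per-study moderated t-tests combined by fixed-effect
# meta-analysis, with asymmetric fold-change / adjusted-p DEG thresholds.

#' Collapse probe-level rows to one row per gene by maximum IQR
#'
#' When several probes map to a gene, the probe with the largest
#' interquartile range across samples is kept; ties go to the
#' lexicographically smallest probe id.  Unmapped probes are dropped (count
#' attached as attribute `n_unmapped`).
#'
#' @param mat Probe x sample numeric matrix with probe ids as rownames.
#' @param probe_gene_map Data frame (probe, gene).
#' @return Gene x sample matrix.
#' @export
collapse_probes <- function(mat, probe_gene_map) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (is.null(probe_gene_map) || nrow(probe_gene_map) == 0)
    stop("empty probe-gene map")
  names(probe_gene_map)[1:2] <- c("probe", "gene")
  gene <- probe_gene_map$gene[match(rownames(mat), probe_gene_map$probe)]
  unmapped <- is.na(gene)
  m <- mat[!unmapped, , drop = FALSE]
  gene <- gene[!unmapped]
  iqr <- apply(m, 1, stats::IQR)
  ord <- order(gene, -iqr, rownames(m))
  m <- m[ord, , drop = FALSE]
  gene <- gene[ord]
  keep <- !duplicated(gene)
  out <- m[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  attr(out, "n_unmapped") <- sum(unmapped)
  out
}

#' Normalise an expression matrix onto the log2 scale
#'
#' If values look linear-scale (max > 50), applies log2(x + 1); then
#' median-centres each sample.
#'
#' @param mat Gene x sample matrix.
#' @return Normalised matrix.
#' @export
normalize_expression <- function(mat) {
  if (max(mat, na.rm = TRUE) > 50) mat <- log2(mat + 1)
  sweep(mat, 2, apply(mat, 2, stats::median), "-")
}

# Moment-matching estimate of the variance-prior parameters (d0, s0^2)
# under the scaled inverse-chi-square model s^2_g ~ s0^2 F(dg, d0):
#   E s^2 = s0^2 d0/(d0-2),  Var s^2 = s0^4 2 d0^2 (dg+d0-2)/(dg (d0-2)^2 (d0-4))
# Solved for d0 from the squared coefficient of variation of the gene
# variances; d0 = Inf (full moderation) when the observed dispersion does
# not exceed the chi-square sampling floor.
estimate_var_prior <- function(s2, dg) {
  m1 <- mean(s2)
  v <- stats::var(s2)
  if (!is.finite(v) || m1 <= 0) return(list(d0 = Inf, s02 = m1))
  r <- v / m1^2
  denom <- dg * r - 2
  if (denom <= 0) return(list(d0 = Inf, s02 = m1))
  d0 <- (4 * dg * r + 2 * dg - 4) / denom
  if (!is.finite(d0) || d0 <= 4.01) d0 <- 4.01  # moment formula's validity edge
  s02 <- m1 * (d0 - 2) / d0
  list(d0 = d0, s02 = s02)
}

#' Per-gene moderated t-test for one study
#'
#' Two-sample comparison (case vs control) with empirical-Bayes variance
#' shrinkage: the posterior variance is
#' (d0 s0^2 + dg s^2_g)/(d0 + dg) with (d0, s0^2) estimated from the
#' gene-wise variance distribution by moment matching; the t statistic uses
#' the posterior SD with d0 + dg degrees of freedom.  Also returns Hedges'
#' g (bias-corrected standardized mean difference) with its standard error,
#' and the log2 fold change (case minus control mean, data assumed log2).
#'
#' @param mat Gene x sample matrix (log2 scale).
#' @param labels Character/factor vector over samples, values "case" and
#'   "control", >= 2 samples each.
#' @param d0 Override the prior degrees of freedom (0 = no moderation,
#'   i.e. ordinary pooled-variance t; Inf = complete shrinkage to s0^2).
#' @return Data frame: gene, effect (Hedges' g), se, log2fc, t, df, p;
#'   attributes `d0`, `s02`.
#' @export
moderated_t <- function(mat, labels, d0 = NULL) {
  labels <- as.character(labels)
  stopifnot(ncol(mat) == length(labels),
            all(labels %in% c("case", "control")))
  i1 <- labels == "case"; i2 <- labels == "control"
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per arm")
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  v1 <- apply(mat[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(mat[, i2, drop = FALSE], 1, stats::var)
  dg <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dg
  if (all(s2 == 0)) stop("zero variance in every gene")

  if (is.null(d0)) {
    if (nrow(mat) < 2) {
      warning("single-gene matrix: falling back to no moderation (d0 = 0)")
      pri <- list(d0 = 0, s02 = mean(s2))
    } else {
      pri <- estimate_var_prior(s2, dg)
    }
  } else {
    pri <- list(d0 = d0, s02 = if (nrow(mat) >= 2 && is.finite(d0) && d0 > 0)
      estimate_var_prior(s2, dg)$s02 else mean(s2))
  }
  s2_post <- if (is.infinite(pri$d0)) rep(pri$s02, length(s2)) else
    (pri$d0 * pri$s02 + dg * s2) / (pri$d0 + dg)
  df_post <- pri$d0 + dg
  se_diff <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se_diff
  tt[se_diff == 0] <- 0
  p <- 2 * stats::pt(-abs(tt), df = df_post)
  p[se_diff == 0] <- 1

  # Hedges' g on the unmoderated pooled SD
  sp <- sqrt(s2)
  J <- 1 - 3 / (4 * dg - 1)
  g <- ifelse(sp > 0, J * (m1 - m2) / sp, 0)
  se_g <- sqrt((1 / n1 + 1 / n2) + g^2 / (2 * (n1 + n2)))

  out <- data.frame(gene = rownames(mat), effect = g, se = se_g,
                    log2fc = m1 - m2, t = tt, df = df_post, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "d0") <- pri$d0
  attr(out, "s02") <- pri$s02
  out
}

#' Fixed-effect meta-analysis across studies
#'
#' Combines per-study effects by inverse-variance weighting (w = 1/se^2):
#' combined effect = sum(w theta)/sum(w), se = sqrt(1/sum(w)), p from the
#' combined z (default) and additionally by Fisher's method; log2 fold
#' changes combined with the same weights.  Benjamini-Hochberg adjustment
#' over all genes, applied once.
#'
#' @param per_study List of [moderated_t()] result data frames.
#' @param min_studies Minimum number of studies a gene must appear in
#'   (default: all of them).
#' @return Data frame of class `gene_meta`: gene, effect, se, z, p,
#'   p_fisher, p_adj, log2fc, n_studies.
#' @export
combine_fixed_effect <- function(per_study, min_studies = NULL) {
  stopifnot(is.list(per_study), length(per_study) >= 1)
  k <- length(per_study)
  if (is.null(min_studies)) min_studies <- k
  all_genes <- sort(unique(unlist(lapply(per_study, `[[`, "gene"))))
  G <- length(all_genes)
  eff <- se <- fc <- pp <- matrix(NA_real_, G, k)
  for (j in seq_len(k)) {
    m <- match(per_study[[j]]$gene, all_genes)
    eff[m, j] <- per_study[[j]]$effect
    se[m, j] <- per_study[[j]]$se
    fc[m, j] <- per_study[[j]]$log2fc
    pp[m, j] <- per_study[[j]]$p
  }
  n_st <- rowSums(!is.na(eff))
  keep <- n_st >= min_studies
  if (!any(keep)) stop("no gene present in >= ", min_studies, " studies")
  w <- 1 / se^2
  sw <- rowSums(w, na.rm = TRUE)
  effc <- rowSums(w * eff, na.rm = TRUE) / sw
  fcc <- rowSums(w * fc, na.rm = TRUE) / sw
  sec <- sqrt(1 / sw)
  z <- effc / sec
  p_z <- 2 * stats::pnorm(-abs(z))
  # Fisher's combination of the per-study two-sided p-values
  x2 <- rowSums(-2 * log(pmax(pp, 1e-300)), na.rm = TRUE)
  p_fisher <- stats::pchisq(x2, df = 2 * n_st, lower.tail = FALSE)

  out <- data.frame(gene = all_genes, effect = effc, se = sec, z = z,
                    p = p_z, p_fisher = p_fisher, log2fc = fcc,
                    n_studies = n_st, stringsAsFactors = FALSE)[keep, ]
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("gene_meta", "data.frame")
  out
}

#' Select differentially expressed genes into a disease signature
#'
#' Asymmetric thresholds: up = {p_adj < alpha and log2fc > up_fc}, down =
#' {p_adj < alpha and log2fc < down_fc}; a stricter "core" signature at
#' +/- core_fc is also emitted.
#'
#' @param meta A `gene_meta` table from [combine_fixed_effect()].
#' @param alpha Adjusted-p threshold (default 0.001).
#' @param up_fc Up log2 fold-change cut (> 0; default 1.5).
#' @param down_fc Down log2 fold-change cut (< 0; default -2.0).
#' @param core_fc Absolute cut for the core signature (default 2.5).
#' @return Object of class `disease_signature`: up_genes, down_genes,
#'   core_up, core_down, table (the thresholded rows).
#' @export
select_degs <- function(meta, alpha = 0.001, up_fc = 1.5, down_fc = -2.0,
                        core_fc = 2.5) {
  if (up_fc <= 0) stop("up_fc must be > 0")
  if (down_fc >= 0) stop("down_fc must be < 0")
  sig <- meta$p_adj < alpha
  up <- meta$gene[sig & meta$log2fc > up_fc]
  down <- meta$gene[sig & meta$log2fc < down_fc]
  structure(list(
    up_genes = up, down_genes = down,
    core_up = meta$gene[sig & meta$log2fc > core_fc],
    core_down = meta$gene[sig & meta$log2fc < -core_fc],
    alpha = alpha, up_fc = up_fc, down_fc = down_fc, core_fc = core_fc,
    table = meta[meta$gene %in% c(up, down), , drop = FALSE]),
    class = "disease_signature")
}

#' @export
print.disease_signature <- function(x, ...) {
  cat("Disease signature:", length(x$up_genes), "up /",
      length(x$down_genes), "down genes",
      sprintf("(adj p < %g, log2FC > %g or < %g)\n",
              x$alpha, x$up_fc, x$down_fc))
  cat("Core signature (|log2FC| >", x$core_fc, "):",
      length(x$core_up), "up /", length(x$core_down), "down\n")
  invisible(x)
}

#' Build a disease signature from per-study expression data
#'
#' Convenience wrapper: normalise each study, run the moderated t-test,
#' combine by fixed-effect meta-analysis and threshold.
#'
#' @param studies Named list; each element a list with `matrix` (genes x
#'   samples) and `labels` ("case"/"control").
#' @param normalize Apply [normalize_expression()] per study (default TRUE).
#' @param ... Passed to [select_degs()].
#' @return A `disease_signature`; the full meta table is in `$meta`.
#' @export
meta_signature <- function(studies, normalize = TRUE, ...) {
  per_study <- lapply(studies, function(s) {
    m <- if (normalize) normalize_expression(s$matrix) else s$matrix
    moderated_t(m, s$labels)
  })
  meta <- combine_fixed_effect(per_study)
  sig <- select_degs(meta, ...)
  sig$meta <- meta
  sig
}
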
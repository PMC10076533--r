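# Integration: correlate summarized reverse scores with inverse-signal
# activities, call reversal genes by leave-one-compound-out
# cross-validation, and validate against IC50 potency.

#' Correlate sRGES with inverse-signal activity values
#'
#' One Spearman correlation per available activity column (ror_uci, ic975,
#' ebgm95) against srges, pairwise-complete.  Lower activity values mean a
#' stronger inverse signal and lower srges means stronger reversal, so a
#' working pipeline yields positive correlations.
#'
#' @param activity Data frame with `srges` and any of `ror_uci`, `ic975`,
#'   `ebgm95` per compound.
#' @return Data frame: method, rho, p, n (skipped methods omitted with a
#'   warning).
#' @export
correlate_signals <- function(activity) {
  stopifnot("srges" %in% names(activity))
  methods <- intersect(c("ror_uci", "ic975", "ebgm95"), names(activity))
  rows <- list()
  for (m in methods) {
    ok <- is.finite(activity$srges) & is.finite(activity[[m]])
    if (sum(ok) < 3) {
      warning("fewer than 3 complete pairs for ", m, "; skipped")
      next
    }
    r <- spearman_cor(activity$srges[ok], activity[[m]][ok])
    rows[[m]] <- data.frame(method = m, rho = r$rho, p = r$p, n = r$n,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pick each compound's representative profile for gene-rank analyses
#'
#' Prefers the exact reference condition; otherwise the profile nearest to
#' it by (|log10 dose - 1|, |time - 24|) lexicographically.
#'
#' @param profiles Long profile table (compound_id, cell_line, dose_um,
#'   time_h, gene, rank).
#' @param ref_dose,ref_time Reference condition.
#' @return Compounds x genes integer rank matrix.
#' @export
representative_ranks <- function(profiles, ref_dose = 10, ref_time = 24) {
  key <- unique(profiles[c("compound_id", "cell_line", "dose_um", "time_h")])
  d_dose <- abs(log10(key$dose_um) - log10(ref_dose))
  d_time <- abs(key$time_h - ref_time)
  pick <- do.call(rbind, lapply(split(seq_len(nrow(key)), key$compound_id),
    function(i) {
      i[order(d_dose[i], d_time[i], key$cell_line[i])][1]
    }))
  sel <- key[pick, , drop = FALSE]
  genes <- sort(unique(profiles$gene))
  M <- matrix(NA_integer_, nrow(sel), length(genes),
              dimnames = list(sel$compound_id, genes))
  for (r in seq_len(nrow(sel))) {
    p <- profiles[profiles$compound_id == sel$compound_id[r] &
                    profiles$cell_line == sel$cell_line[r] &
                    profiles$dose_um == sel$dose_um[r] &
                    profiles$time_h == sel$time_h[r], , drop = FALSE]
    M[r, p$gene] <- p$rank
  }
  M[order(rownames(M)), , drop = FALSE]
}

#' Call reversal genes by leave-one-compound-out cross-validation
#'
#' In each trial one compound is excluded; for every gene the Spearman
#' correlation between its rank across the remaining compounds and their
#' activity is computed with a two-sided p, and p-values are BH-adjusted
#' across genes within the trial.  A gene is selected iff its adjusted p is
#' below `fdr_threshold` in every trial (an intersection over trials; set
#' `min_trial_fraction` < 1 to relax).
#'
#' @param rank_mat Compounds x genes rank matrix (one representative
#'   profile per compound, e.g. [representative_ranks()]).
#' @param activity Numeric activity per compound (same order as rows);
#'   e.g. the ROR upper confidence bound.
#' @param fdr_threshold FDR cut within each trial (default 0.25).
#' @param min_trial_fraction Fraction of trials a gene must pass
#'   (default 1 = all trials).
#' @return List of class `reversal_genes`: `calls` (gene, rho_min,
#'   rho_max, max_p_adj, n_pass, selected), `selected` (gene names),
#'   `norm_ranks` (genes x compounds normalised rank matrix, compounds
#'   ordered by increasing activity).
#' @export
loocv_reversal_genes <- function(rank_mat, activity, fdr_threshold = 0.25,
                                 min_trial_fraction = 1) {
  n <- nrow(rank_mat)
  if (n < 4) stop("need at least 4 compounds for leave-one-out trials")
  stopifnot(length(activity) == n)
  if (stats::var(activity) == 0) stop("constant activity vector")
  G <- ncol(rank_mat)
  pass <- matrix(FALSE, n, G)
  rho_all <- matrix(NA_real_, n, G)
  padj_all <- matrix(NA_real_, n, G)
  for (k in seq_len(n)) {
    sc <- spearman_cols(rank_mat[-k, , drop = FALSE], activity[-k])
    padj <- stats::p.adjust(sc$p, method = "BH")
    pass[k, ] <- !is.na(sc$rho) & padj < fdr_threshold
    rho_all[k, ] <- sc$rho
    padj_all[k, ] <- padj
  }
  n_pass <- colSums(pass)
  selected <- n_pass >= ceiling(min_trial_fraction * n)
  calls <- data.frame(
    gene = colnames(rank_mat),
    rho_min = apply(rho_all, 2, min),
    rho_max = apply(rho_all, 2, max),
    max_p_adj = apply(padj_all, 2, max),
    n_pass = n_pass,
    selected = selected,
    stringsAsFactors = FALSE)
  ord <- order(activity, rownames(rank_mat))
  norm_ranks <- t(rank_mat[ord, , drop = FALSE]) / G
  structure(list(calls = calls, selected = calls$gene[selected],
                 norm_ranks = norm_ranks,
                 fdr_threshold = fdr_threshold, n_trials = n),
            class = "reversal_genes")
}

#' @export
print.reversal_genes <- function(x, ...) {
  cat("Leave-one-compound-out reversal-gene calls (", x$n_trials,
      " trials, FDR < ", x$fdr_threshold, " in all trials)\n", sep = "")
  if (length(x$selected) == 0) cat("  none selected\n")
  else cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Summarise IC50 assay rows per compound
#'
#' @param ic50 Data frame: inchikey, ic50_nm (assay rows, nM).
#' @param key_chars Number of leading InChIKey characters used as the join
#'   key (default 14, the connectivity block; 27 = full key).
#' @return Data frame: key, ic50_median, ic50_min, ic50_max, n_assays.
#' @export
summarize_ic50 <- function(ic50, key_chars = 14) {
  stopifnot(all(c("inchikey", "ic50_nm") %in% names(ic50)))
  key <- substr(ic50$inchikey, 1, key_chars)
  agg <- lapply(split(ic50$ic50_nm, key), function(v) {
    data.frame(ic50_median = stats::median(v), ic50_min = min(v),
               ic50_max = max(v), n_assays = length(v))
  })
  out <- cbind(data.frame(key = names(agg), stringsAsFactors = FALSE),
               do.call(rbind, agg))
  rownames(out) <- NULL
  out
}

#' Validate summarized reverse scores against IC50 potency
#'
#' Joins compounds to IC50 assay rows by InChIKey (first `key_chars`
#' characters), summarises multiple assays per compound as median, minimum
#' and maximum, and reports the Spearman correlation of srges with each
#' summary.
#'
#' @param compounds Data frame: inchikey, srges (one row per compound).
#' @param ic50 Data frame: inchikey, ic50_nm.
#' @param key_chars Join-key length (default 14; see [summarize_ic50()]).
#' @return List: `correlations` (stat, rho, p, n), `joined` (per-compound
#'   table), `n_unmatched`.
#' @export
ic50_validate <- function(compounds, ic50, key_chars = 14) {
  stopifnot(all(c("inchikey", "srges") %in% names(compounds)))
  summ <- summarize_ic50(ic50, key_chars)
  ckey <- substr(compounds$inchikey, 1, key_chars)
  m <- match(ckey, summ$key)
  if (all(is.na(m)))
    stop("no shared InChIKeys between compounds and the IC50 table; ",
         "sample compound keys: ",
         paste(utils::head(unique(ckey), 5), collapse = ", "),
         " | sample IC50 keys: ",
         paste(utils::head(summ$key, 5), collapse = ", "))
  joined <- cbind(compounds, summ[m, c("ic50_median", "ic50_min",
                                       "ic50_max", "n_assays")])
  n_unmatched <- sum(is.na(m))
  ok <- !is.na(m)
  rows <- lapply(c("ic50_median", "ic50_min", "ic50_max"), function(stat) {
    r <- spearman_cor(joined$srges[ok], joined[[stat]][ok])
    data.frame(stat = stat, rho = r$rho, p = r$p, n = r$n,
               stringsAsFactors = FALSE)
  })
  correlations <- do.call(rbind, rows)
  rownames(joined) <- NULL
  list(correlations = correlations, joined = joined,
       n_unmatched = n_unmatched)
}
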
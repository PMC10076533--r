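# Reverse gene-expression scoring: KS-type enrichment of the disease up-
# and down-gene sets in each compound's ranked signature, the RGES, and
# per-compound summarisation anchored at the 10 uM / 24 h reference.

#' KS-type enrichment score of a gene set in a ranked list
#'
#' With V(1) < ... < V(s) the sorted rank positions of the set in a list of
#' length N, a = max_j (j/s - V(j)/N) and b = max_j (V(j)/N - (j-1)/s);
#' es = a if a >= b, else -b.  Positive when the set sits near the top
#' (rank 1) of the list.
#'
#' @param positions Integer rank positions of the set's genes (subset of
#'   1..N, nonempty, no duplicates).
#' @param N Length of the ranked list.
#' @return Enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(positions, N) {
  s <- length(positions)
  if (s == 0) stop("empty gene set")
  if (any(positions < 1 | positions > N)) stop("positions outside 1..N")
  if (anyDuplicated(positions)) stop("duplicate rank positions")
  V <- sort(positions)
  j <- seq_len(s)
  a <- max(j / s - V / N)
  b <- max(V / N - (j - 1) / s)
  if (a >= b) a else -b
}

#' Reverse gene-expression score of one compound profile
#'
#' es_up and es_down are the enrichment scores of the disease up- and
#' down-gene sets in the compound's ranked signature (rank 1 = most
#' up-regulated by the compound).  When the two scores have opposite signs,
#' rges = es_up - es_down; when they agree in sign the profile is not a
#' reversal and rges = 0.  A fully reversing profile (disease up-genes at
#' the bottom, down-genes at the top) minimises the score; rges < 0
#' indicates reversal.
#'
#' @param ranks Named integer vector: gene -> rank (a permutation of
#'   1..N over the profile's gene universe).
#' @param signature A [disease_signature] (or list with `up_genes` and
#'   `down_genes`).
#' @return List: es_up, es_down, rges, n_up, n_down.
#' @export
rges <- function(ranks, signature) {
  N <- length(ranks)
  up <- intersect(signature$up_genes, names(ranks))
  down <- intersect(signature$down_genes, names(ranks))
  if (length(up) == 0 || length(down) == 0)
    stop("signature has empty intersection with the profile universe ",
         "in the up or down direction")
  if (length(up) < length(signature$up_genes) ||
      length(down) < length(signature$down_genes))
    warning("signature only partially covered by the profile universe; ",
            "subsetting")
  es_up <- enrichment_score(unname(ranks[up]), N)
  es_down <- enrichment_score(unname(ranks[down]), N)
  r <- if (sign(es_up) != sign(es_down)) es_up - es_down else 0
  list(es_up = es_up, es_down = es_down, rges = r,
       n_up = length(up), n_down = length(down))
}

#' Score every profile of a long-format signature table
#'
#' @param profiles Long data frame: compound_id, inchikey, cell_line,
#'   dose_um, time_h, gene, rank (or a numeric `value` column, converted to
#'   ranks with average-rank ties then stable gene-id ordering; rank 1 =
#'   most up-regulated).
#' @param signature A [disease_signature].
#' @return Data frame: one row per profile with es_up, es_down, rges.
#' @export
score_profiles <- function(profiles, signature) {
  need <- c("compound_id", "inchikey", "cell_line", "dose_um", "time_h", "gene")
  stopifnot(all(need %in% names(profiles)))
  key <- interaction(profiles$compound_id, profiles$cell_line,
                     profiles$dose_um, profiles$time_h, drop = TRUE)
  out <- lapply(split(profiles, key), function(p) {
    if ("rank" %in% names(p)) {
      rk <- p$rank
    } else {
      # higher value = more up-regulated -> rank 1; ties broken by gene id
      rk <- order(order(-p$value, p$gene))
    }
    names(rk) <- p$gene
    r <- rges(rk, signature)
    data.frame(compound_id = p$compound_id[1], inchikey = p$inchikey[1],
               cell_line = p$cell_line[1], dose_um = p$dose_um[1],
               time_h = p$time_h[1], es_up = r$es_up, es_down = r$es_down,
               rges = r$rges, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$compound_id, out$cell_line, out$dose_um, out$time_h), ,
      drop = FALSE]
}

#' Summarise profile-level RGES to one sRGES per compound
#'
#' Conditions are split into dose classes (< 10 vs >= 10 uM) and time
#' classes (< 24 vs >= 24 h); the (>= 10 uM, >= 24 h) class contains the
#' 10 uM / 24 h reference condition.  For each non-reference class a global
#' offset is estimated as the mean RGES difference between that class and
#' the reference class across compounds profiled in both; profile scores
#' are corrected by their class offset and averaged per compound with
#' weight 1 for reference-class profiles and `w0` otherwise.
#'
#' @param scored Output of [score_profiles()].
#' @param w0 Weight of non-reference profiles (default 0.5).
#' @param ref_dose,ref_time Reference condition (defaults 10 uM, 24 h).
#' @return Data frame: compound_id, inchikey, srges, n_profiles;
#'   attribute `offsets` holds the per-class corrections.
#' @export
summarize_rges <- function(scored, w0 = 0.5, ref_dose = 10, ref_time = 24) {
  stopifnot(nrow(scored) >= 1, w0 > 0)
  cls <- paste0(ifelse(scored$dose_um >= ref_dose, "hiD", "loD"), "_",
                ifelse(scored$time_h >= ref_time, "hiT", "loT"))
  ref_cls <- "hiD_hiT"
  offsets <- c(hiD_hiT = 0)
  for (k in setdiff(unique(cls), ref_cls)) {
    diffs <- c()
    for (cp in unique(scored$compound_id)) {
      in_k <- cls == k & scored$compound_id == cp
      in_ref <- cls == ref_cls & scored$compound_id == cp
      if (any(in_k) && any(in_ref))
        diffs <- c(diffs, mean(scored$rges[in_k]) - mean(scored$rges[in_ref]))
    }
    if (length(diffs) == 0) {
      warning("no compound pairs class ", k, " against the reference class; ",
              "offset set to 0")
      offsets[k] <- 0
    } else {
      offsets[k] <- mean(diffs)
    }
  }
  corrected <- scored$rges - offsets[cls]
  wt <- ifelse(cls == ref_cls, 1, w0)
  agg <- lapply(split(seq_len(nrow(scored)), scored$compound_id), function(i) {
    data.frame(compound_id = scored$compound_id[i[1]],
               inchikey = scored$inchikey[i[1]],
               srges = stats::weighted.mean(corrected[i], wt[i]),
               n_profiles = length(i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  attr(out, "offsets") <- offsets
  out[order(out$srges), , drop = FALSE]
}
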
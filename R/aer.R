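# Adverse-event report preprocessing: parsing the quarterly ASCII dialect,
# case-version deduplication, suspect-drug / event filters, drug-event
# contingency tables, PT -> ICD-10 mapping, and target-event selection.

#' Read adverse-event report tables
#'
#' Parses the `$`-delimited DEMO/DRUG/REAC tables.  One case report per
#' PRIMARYID; malformed rows (empty DRUGNAME or PT, unparseable ids) are
#' skipped and counted.
#'
#' @param demo,drug,reac File paths, or data frames already in memory.
#' @param sep Field delimiter (default `"$"`).
#' @return A list of class `aer_reports` with data frames `demo`
#'   (PRIMARYID, CASEID, EVENT_DT), `drug` (+ ROLE_COD, DRUGNAME), `reac`
#'   (+ PT), and attribute `n_skipped`.
#' @export
read_reports <- function(demo, drug, reac, sep = "$") {
  load1 <- function(x, required) {
    if (is.character(x)) {
      if (!file.exists(x)) stop("file not found: ", x)
      x <- utils::read.delim(x, sep = sep, stringsAsFactors = FALSE,
                             check.names = FALSE)
    }
    miss <- setdiff(required, names(x))
    if (length(miss))
      stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
    if (nrow(x) == 0) warning("empty table (columns: ",
                              paste(required, collapse = ","), ")")
    x
  }
  demo <- load1(demo, c("PRIMARYID", "CASEID", "EVENT_DT"))
  drug <- load1(drug, c("PRIMARYID", "CASEID", "ROLE_COD", "DRUGNAME"))
  reac <- load1(reac, c("PRIMARYID", "CASEID", "PT"))

  skipped <- 0L
  bad_drug <- is.na(drug$DRUGNAME) | trimws(drug$DRUGNAME) == ""
  skipped <- skipped + sum(bad_drug)
  drug <- drug[!bad_drug, , drop = FALSE]
  bad_reac <- is.na(reac$PT) | trimws(reac$PT) == ""
  skipped <- skipped + sum(bad_reac)
  reac <- reac[!bad_reac, , drop = FALSE]
  bad_demo <- is.na(demo$PRIMARYID) | is.na(demo$CASEID)
  skipped <- skipped + sum(bad_demo)
  demo <- demo[!bad_demo, , drop = FALSE]
  if (anyDuplicated(demo$PRIMARYID))
    stop("PRIMARYID must be unique within a file set")

  structure(list(demo = demo, drug = drug, reac = reac),
            n_skipped = skipped, class = "aer_reports")
}

#' @export
print.aer_reports <- function(x, ...) {
  cat("Adverse-event reports:", nrow(x$demo), "report versions,",
      length(unique(x$demo$CASEID)), "cases,",
      nrow(x$drug), "drug rows,", nrow(x$reac), "event rows\n")
  invisible(x)
}

#' Deduplicate case reports
#'
#' Keeps exactly one report version per case: the one maximising
#' (EVENT_DT, PRIMARYID) lexicographically — the most recent case version,
#' ties broken by the larger version identifier.  Output is sorted by
#' CASEID.  Idempotent.
#'
#' @param reports An `aer_reports` object.
#' @return The deduplicated `aer_reports`.
#' @export
deduplicate_reports <- function(reports) {
  stopifnot(inherits(reports, "aer_reports"))
  d <- reports$demo
  ord <- order(d$CASEID, -xtfrm(d$EVENT_DT), -xtfrm(d$PRIMARYID))
  d <- d[ord, , drop = FALSE]
  d <- d[!duplicated(d$CASEID), , drop = FALSE]
  d <- d[order(d$CASEID), , drop = FALSE]
  keep <- d$PRIMARYID
  out <- list(demo = d,
              drug = reports$drug[reports$drug$PRIMARYID %in% keep, , drop = FALSE],
              reac = reports$reac[reports$reac$PRIMARYID %in% keep, , drop = FALSE])
  structure(out, n_skipped = attr(reports, "n_skipped"),
            class = "aer_reports")
}

#' Normalise a drug name
#'
#' Uppercase, trim, collapse internal whitespace, strip trailing dosage
#' tokens such as "10 MG" or "0.5 ML".  No ingredient resolution.
#'
#' @param x Character vector of raw drug names.
#' @return Normalised character vector.
#' @export
normalize_drug_name <- function(x) {
  x <- toupper(trimws(x))
  x <- gsub("[[:space:]]+", " ", x)
  gsub(" [0-9.]+ ?(MG|MCG|G|ML|%)( .*)?$", "", x)
}

# Combination-drug rule: a separator among / \ + or " AND " between two
# alphanumeric ingredient tokens (alphanumeric so names like "B12" count).
is_combination_drug <- function(x) {
  grepl("[[:alnum:]] ?[/\\\\+] ?[[:alnum:]]", x) |
    grepl("[[:alnum:]] AND [[:alnum:]]", x)
}

#' Filter reports to primary-suspect, single-ingredient, informative events
#'
#' Applies the three standard pharmacovigilance filters: keep only
#' primary-suspect drug rows; drop event terms in the exclusion list
#' (default "Drug ineffective", "Medication error"; case-insensitive;
#' reports whose every PT is excluded are dropped); drop combination-drug
#' names (two or more active ingredients in one dosage form).  Removal
#' counts per filter are attached as attribute `removed`.
#'
#' @param reports An `aer_reports` object (deduplicated).
#' @param excluded_pts Character vector of PT terms to drop.
#' @param combo_list Optional curated character vector of additional
#'   multi-ingredient drug names.
#' @return Filtered `aer_reports` with normalised DRUGNAME.
#' @export
filter_reports <- function(reports,
                           excluded_pts = c("Drug ineffective",
                                            "Medication error"),
                           combo_list = character()) {
  stopifnot(inherits(reports, "aer_reports"))
  drug <- reports$drug
  reac <- reports$reac

  n0 <- nrow(drug)
  drug <- drug[drug$ROLE_COD == "PS", , drop = FALSE]
  removed_role <- n0 - nrow(drug)

  drug$DRUGNAME <- normalize_drug_name(drug$DRUGNAME)
  combo <- is_combination_drug(drug$DRUGNAME) |
    drug$DRUGNAME %in% toupper(combo_list)
  removed_combo <- sum(combo)
  drug <- drug[!combo, , drop = FALSE]

  excl <- tolower(reac$PT) %in% tolower(excluded_pts)
  removed_pt <- sum(excl)
  reac <- reac[!excl, , drop = FALSE]

  # a report survives only if it still has a suspect drug and an event
  keep <- intersect(drug$PRIMARYID, reac$PRIMARYID)
  demo <- reports$demo[reports$demo$PRIMARYID %in% keep, , drop = FALSE]
  drug <- drug[drug$PRIMARYID %in% keep, , drop = FALSE]
  reac <- reac[reac$PRIMARYID %in% keep, , drop = FALSE]

  structure(list(demo = demo, drug = drug, reac = reac),
            n_skipped = attr(reports, "n_skipped"),
            removed = c(role = removed_role, combination = removed_combo,
                        excluded_pt = removed_pt),
            class = "aer_reports")
}

#' Extract unique (report, drug, event) pair triplets
#'
#' The counting unit for contingency tables: each report contributes at
#' most one count per (drug, event) pair.
#'
#' @param reports A filtered `aer_reports` object.
#' @return Data frame: report, drug, event.
#' @export
report_pairs <- function(reports) {
  stopifnot(inherits(reports, "aer_reports"))
  m <- merge(reports$drug[c("PRIMARYID", "DRUGNAME")],
             reports$reac[c("PRIMARYID", "PT")], by = "PRIMARYID")
  out <- unique(data.frame(report = m$PRIMARYID, drug = m$DRUGNAME,
                           event = m$PT, stringsAsFactors = FALSE))
  out[order(out$report, out$drug, out$event), , drop = FALSE]
}

#' Build 2x2 contingency cells for every (drug, event) pair
#'
#' For each pair: a = reports with the drug and the event, b = with the
#' drug but another event, c = other drugs with the event, d = the rest;
#' E = (a+b)(a+c)/n is the expected count under independence.  Cells with
#' a = 0 are retained (needed by the Bayesian statistics).
#'
#' @param pairs Data frame with columns `drug` and `event` (one row per
#'   unique report-drug-event triplet, e.g. from [report_pairs()]).
#' @return Data frame of class `contingency`: drug, event, a, b, c, d, n,
#'   expected.
#' @export
build_contingency <- function(pairs) {
  stopifnot(all(c("drug", "event") %in% names(pairs)))
  n <- nrow(pairs)
  if (n == 0) stop("no drug-event pairs: cannot build contingency tables")
  tab <- table(factor(pairs$drug), factor(pairs$event))
  a <- as.vector(tab)
  n_drug <- rep(rowSums(tab), ncol(tab))
  n_event <- rep(colSums(tab), each = nrow(tab))
  b <- n_drug - a
  cc <- n_event - a
  d <- n - a - b - cc
  out <- data.frame(
    drug = rep(rownames(tab), ncol(tab)),
    event = rep(colnames(tab), each = nrow(tab)),
    a = a, b = b, c = cc, d = d, n = n,
    expected = n_drug * n_event / n,
    stringsAsFactors = FALSE)
  class(out) <- c("contingency", "data.frame")
  out
}

#' Map event terms to ICD-10 codes
#'
#' @param events Character vector of PT terms.
#' @param mapping Two-column data frame (pt, icd10) or a TSV path.
#' @param excluded_chapters ICD-10 chapters flagged as excluded
#'   (default A, B, R: infectious diseases and symptoms/signs).
#' @return Data frame: event, icd10, chapter, mapped, excluded; attribute
#'   `coverage` is the mapped fraction.
#' @export
map_events_to_icd10 <- function(events, mapping,
                                excluded_chapters = c("A", "B", "R")) {
  if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping))
    mapping <- read_tsv(mapping)
  stopifnot(ncol(mapping) >= 2)
  names(mapping)[1:2] <- c("pt", "icd10")
  dup <- mapping$pt[duplicated(mapping$pt)]
  conflict <- unique(dup[vapply(dup, function(p) {
    length(unique(mapping$icd10[mapping$pt == p])) > 1
  }, logical(1))])
  if (length(conflict))
    stop("conflicting ICD-10 mappings for PT(s): ",
         paste(conflict, collapse = ", "))
  mapping <- mapping[!duplicated(mapping$pt), , drop = FALSE]
  events <- unique(events)
  code <- mapping$icd10[match(tolower(events), tolower(mapping$pt))]
  chapter <- toupper(substr(code, 1, 1))
  out <- data.frame(event = events, icd10 = code, chapter = chapter,
                    mapped = !is.na(code),
                    excluded = !is.na(code) & chapter %in% excluded_chapters,
                    stringsAsFactors = FALSE)
  attr(out, "coverage") <- mean(out$mapped)
  out
}

#' Rank candidate target events by their number of inversely-signalled drugs
#'
#' For each mapped, non-excluded event (optionally grouping related PTs
#' under one label), counts the distinct drugs carrying an inverse flag and
#' returns events sorted by that count (descending, ties alphabetical).
#'
#' @param signals A signal table (see [flag_signals()]) with columns
#'   `drug`, `event` and the requested inverse flag.
#' @param mapped Output of [map_events_to_icd10()].
#' @param groups Optional named list: group label -> character vector of PT
#'   synonyms counted together.
#' @param method Which inverse flag to count: "ror", "ic" or "ebgm".
#' @return Data frame: event, n_inverse_drugs, sorted.
#' @export
select_target_event <- function(signals, mapped, groups = NULL,
                                method = c("ror", "ic", "ebgm")) {
  method <- match.arg(method)
  flag <- paste0("inverse_", method)
  stopifnot(flag %in% names(signals))
  ok_events <- mapped$event[mapped$mapped & !mapped$excluded]
  s <- signals[signals$event %in% ok_events & signals[[flag]] %in% TRUE, ,
               drop = FALSE]
  if (nrow(s) == 0) {
    warning("no inversely-flagged pairs among mapped events")
    return(data.frame(event = character(), n_inverse_drugs = integer()))
  }
  lab <- s$event
  if (!is.null(groups)) {
    for (g in names(groups)) lab[lab %in% groups[[g]]] <- g
  }
  cnt <- tapply(s$drug, lab, function(d) length(unique(d)))
  out <- data.frame(event = names(cnt), n_inverse_drugs = as.integer(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_inverse_drugs, out$event), , drop = FALSE]
  rownames(out) <- NULL
  out
}
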
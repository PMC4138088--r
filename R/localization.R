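# Localization-evidence integration.
#
# Candidates are annotated -- never filtered -- with a chloroplast-support
# verdict combining (a) a consensus targeting-prediction score (the Bayesian
# consensus over many predictors, supplied as input, with >=10 taken as a
# reliable chloroplast prediction), or for the rice dialect a single
# predictor's chloroplast call, and (b) experimental support flags from two
# curated sources (proteomics/GFP evidence and a large-scale chloroplast
# study). The consensus score itself is never recomputed here.

EVIDENCE_DIALECTS <- c("consensus", "single_predictor")
VERDICT_LEVELS <- c("unsupported", "consensus_only", "experimental_only",
                    "strong")

#' Load a localization-evidence table
#'
#' TSV with columns `locus`, `dialect` (`consensus` or `single_predictor`),
#' `cp_score`, `mt_score`, `sec_score`, `suba` (`yes`/`none`), `suba_method`
#' (e.g. `"MS/MS"`, `"MS/MS and GFP"`, empty when `suba` is `none`), `c2010`
#' (`yes`/`no`) and `targetp_cp` (`true`/`false`, meaningful for the
#' `single_predictor` dialect).
#'
#' @param path Path to the TSV file.
#' @return Data frame of class `coat_evidence`.
#' @export
load_evidence_table <- function(path) {
  tab <- read_tsv_strict(path, required = c("locus", "dialect", "cp_score",
                                            "mt_score", "sec_score", "suba",
                                            "suba_method", "c2010",
                                            "targetp_cp"))
  as_evidence_table(tab, source = path)
}

as_evidence_table <- function(tab, source = "<data>") {
  if (anyDuplicated(tab$locus)) {
    stop(source, ": duplicate evidence record(s) for locus: ",
         paste(unique(tab$locus[duplicated(tab$locus)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(tab$dialect), EVIDENCE_DIALECTS)
  if (length(bad) > 0L) {
    stop(source, ": unknown evidence dialect(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (col in c("cp_score", "mt_score", "sec_score")) {
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  consensus <- tab$dialect == "consensus"
  if (any(consensus & (is.na(tab$cp_score) | is.na(tab$mt_score) |
                       is.na(tab$sec_score)))) {
    stop(source, ": consensus-dialect records require numeric cp/mt/sec scores",
         call. = FALSE)
  }
  if (any(!is.na(tab$cp_score) & tab$cp_score < 0)) {
    stop(source, ": negative consensus score", call. = FALSE)
  }
  tab$suba <- tolower(tab$suba)
  if (!all(tab$suba %in% c("yes", "none", "no"))) {
    stop(source, ": suba must be yes/none", call. = FALSE)
  }
  tab$suba[tab$suba == "no"] <- "none"
  tab$c2010 <- tolower(tab$c2010)
  if (!all(tab$c2010 %in% c("yes", "no"))) {
    stop(source, ": c2010 must be yes/no", call. = FALSE)
  }
  tab$targetp_cp <- tolower(tab$targetp_cp) %in% c("true", "yes", "1")
  if (any(!consensus & !nzchar(tab$dialect))) {
    stop(source, ": missing dialect", call. = FALSE)
  }
  rownames(tab) <- NULL
  class(tab) <- c("coat_evidence", setdiff(class(tab), "coat_evidence"))
  tab
}

#' Is chloroplast localization supported by the consensus score?
#'
#' The stated rule for the consensus dialect: a chloroplast consensus score of
#' at least 10 (inclusive) counts as a reliable, strong prediction.
#'
#' @param ev One evidence record (single-row `coat_evidence` slice or list
#'   with fields `dialect` and `cp_score`).
#' @param threshold Score threshold, default 10.
#' @return Logical.
#' @export
consensus_supported <- function(ev, threshold = 10) {
  ev <- as_evidence_record(ev)
  if (!identical(ev$dialect, "consensus")) {
    stop("consensus_supported() applies to the consensus dialect only ",
         "(got '", ev$dialect, "')", call. = FALSE)
  }
  ev$cp_score >= threshold
}

as_evidence_record <- function(ev) {
  if (is.data.frame(ev)) {
    stopifnot(nrow(ev) == 1L)
    ev <- as.list(ev)
    if (is.list(ev$dialect)) ev <- lapply(ev, `[[`, 1L)
  }
  ev
}

#' Integrate one evidence record into a support verdict
#'
#' The four-way verdict lattice formalizes how the three corroborating
#' sources combine (the sources annotate; no source vetoes another):
#' \describe{
#'   \item{strong}{prediction support (consensus score >= threshold, or the
#'     single predictor's chloroplast call) *and* experimental support (either
#'     flag).}
#'   \item{experimental_only}{experimental support without prediction
#'     support.}
#'   \item{consensus_only}{prediction support without experimental support.}
#'   \item{unsupported}{neither.}
#' }
#' Mitochondrial and secretory scores are carried for reporting but do not
#' enter the verdict.
#'
#' @param ev One evidence record.
#' @param threshold Consensus-score threshold, default 10.
#' @return List of class `support_verdict` with `locus`, `level` and
#'   `reasons` (character vector naming every contributing source).
#' @export
integrate_evidence <- function(ev, threshold = 10) {
  ev <- as_evidence_record(ev)
  if (is.null(ev$locus) || is.na(ev$locus) || !nzchar(ev$locus)) {
    stop("evidence record lacks a locus id", call. = FALSE)
  }
  reasons <- character(0)
  predicted <- FALSE
  if (identical(ev$dialect, "consensus")) {
    if (ev$cp_score >= threshold) {
      predicted <- TRUE
      reasons <- c(reasons,
                   sprintf("consensus score %.1f >= %g", ev$cp_score,
                           threshold))
    }
  } else if (identical(ev$dialect, "single_predictor")) {
    if (isTRUE(ev$targetp_cp)) {
      predicted <- TRUE
      reasons <- c(reasons, "single-predictor chloroplast call")
    }
  } else {
    stop("unknown evidence dialect: ", ev$dialect, call. = FALSE)
  }
  experimental <- FALSE
  if (identical(ev$suba, "yes")) {
    experimental <- TRUE
    method <- if (!is.null(ev$suba_method) && nzchar(ev$suba_method))
      paste0(" (", ev$suba_method, ")") else ""
    reasons <- c(reasons, paste0("experimental localization", method))
  }
  if (identical(ev$c2010, "yes")) {
    experimental <- TRUE
    reasons <- c(reasons, "large-scale chloroplast study")
  }
  level <- if (predicted && experimental) "strong"
           else if (experimental) "experimental_only"
           else if (predicted) "consensus_only"
           else "unsupported"
  structure(list(locus = ev$locus, level = level, reasons = reasons),
            class = "support_verdict")
}

#' Join screen hits with localization evidence
#'
#' Every hit locus receives a verdict; loci lacking an evidence record are
#' mapped to `unsupported` with reason `"no record"`. Evidence for loci
#' outside the hit set is ignored (counted in the `ignored` attribute so
#' silent data loss is visible).
#'
#' @param result A `screen_result`.
#' @param evidence A `coat_evidence` table.
#' @param threshold Consensus-score threshold, default 10.
#' @return Named list locus -> `support_verdict`, with attribute `ignored`
#'   giving the ignored evidence loci.
#' @export
join_evidence <- function(result, evidence, threshold = 10) {
  stopifnot(inherits(result, "screen_result"))
  loci <- sort(unique(c(result$single_subunit_loci,
                        result$multi_subunit_loci)))
  if (anyDuplicated(evidence$locus)) {
    stop("duplicate evidence record(s) for locus: ",
         paste(unique(evidence$locus[duplicated(evidence$locus)]),
               collapse = ", "), call. = FALSE)
  }
  verdicts <- vector("list", length(loci))
  names(verdicts) <- loci
  for (locus in loci) {
    i <- match(locus, evidence$locus)
    verdicts[[locus]] <- if (is.na(i)) {
      structure(list(locus = locus, level = "unsupported",
                     reasons = "no record"), class = "support_verdict")
    } else {
      integrate_evidence(evidence[i, , drop = FALSE], threshold = threshold)
    }
  }
  ignored <- setdiff(evidence$locus, loci)
  if (length(ignored) > 0L) {
    message(length(ignored), " evidence record(s) for non-candidate loci ",
            "ignored")
  }
  attr(verdicts, "ignored") <- sort(ignored)
  verdicts
}
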
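# End-to-end pipeline and report writers.
#
# run_screen() ties the stages together in the workflow order: build the
# signature catalog from query proteins, screen the annotated proteome,
# join localization evidence, classify candidates and subunits, summarize.
# Reports are byte-stable given identical inputs; the timestamp is isolated
# inside the provenance block.

#' Run the full screening pipeline
#'
#' @param queries A `coat_queries` table or a path to a query TSV.
#' @param proteome A `coat_proteome` table or a path to a proteome TSV.
#' @param evidence A `coat_evidence` table or a path to an evidence TSV
#'   (optional: without it every candidate is `unsupported`).
#' @param vesicle_keywords Keywords marking a vesicle-transport role.
#' @param consensus_threshold Consensus-score threshold (default 10).
#' @param notes Free-text notes carried into the provenance block.
#' @return Object of class `coat_report`: list with `catalog`, `result`,
#'   `verdicts`, `locus_colors`, `identity_colors`, `summary`
#'   (`summary_counts`) and `provenance`.
#' @examples
#' fx <- load_fixture("arabidopsis")
#' rep <- run_screen(fx$queries, fx$proteome, fx$evidence)
#' rep$summary
#' @export
run_screen <- function(queries, proteome, evidence = NULL,
                       vesicle_keywords = DEFAULT_VESICLE_KEYWORDS,
                       consensus_threshold = 10, notes = character(0)) {
  stopifnot(consensus_threshold > 0)
  inputs <- list()
  if (is.character(queries)) {
    inputs$queries <- queries
    queries <- load_query_table(queries)
  }
  if (is.character(proteome)) {
    inputs$proteome <- proteome
    proteome <- load_proteome_table(proteome)
  }
  if (is.character(evidence)) {
    inputs$evidence <- evidence
    evidence <- load_evidence_table(evidence)
  }
  catalog <- build_catalog(queries)
  n_warn <- 0L
  result <- withCallingHandlers(
    screen_proteome(proteome, catalog),
    warning = function(w) {
      n_warn <<- n_warn + 1L
      invokeRestart("muffleWarning")
    })
  if (is.null(evidence)) {
    evidence <- as_evidence_table(
      data.frame(locus = character(0), dialect = character(0),
                 cp_score = character(0), mt_score = character(0),
                 sec_score = character(0), suba = character(0),
                 suba_method = character(0), c2010 = character(0),
                 targetp_cp = character(0), stringsAsFactors = FALSE))
  }
  verdicts <- suppressMessages(
    join_evidence(result, evidence, threshold = consensus_threshold))
  locus_colors <- classify_all_loci(proteome, result, verdicts,
                                    vesicle_keywords)
  identity_colors <- vapply(names(result$by_identity), function(id) {
    classify_identity(id, result, locus_colors)$color
  }, "")
  summary <- summarize_screen(result, locus_colors)

  checksums <- if (length(inputs) > 0L)
    vapply(inputs, function(p) unname(tools::md5sum(p)), "") else character(0)
  provenance <- list(
    tool = "coatscreen",
    version = as.character(utils::packageVersion("coatscreen")),
    consensus_threshold = consensus_threshold,
    vesicle_keywords = vesicle_keywords,
    input_md5 = as.list(checksums),
    warnings = n_warn,
    ignored_evidence = attr(verdicts, "ignored"),
    unknown_accessions = result$unknown_accessions,
    notes = notes,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  structure(list(catalog = catalog, result = result, verdicts = verdicts,
                 locus_colors = locus_colors,
                 identity_colors = identity_colors,
                 summary = summary, provenance = provenance),
            class = "coat_report")
}

#' @export
print.coat_report <- function(x, ...) {
  cat("<coat_report>\n")
  print(x$summary)
  reds <- names(x$identity_colors)[x$identity_colors == "red"]
  cat("subunits with no candidate (red): ", length(reds), "\n", sep = "")
  invisible(x)
}

#' Write a report to disk
#'
#' Writes `candidates.tsv` (locus, system, complex, subunit, witness
#' signature, multi flag, verdict level, color), `identities.tsv`
#' (subject, color, rationale) and `report.json` (summary + provenance +
#' tables). Tables are byte-stable across runs on identical inputs; the
#' timestamp lives only in the provenance block.
#'
#' @param report A `coat_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "coat_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hits <- report$result$hits
  cand <- data.frame(
    locus = hits$locus, system = hits$system, complex = hits$complex,
    subunit = hits$subunit, witness_signature = hits$witness_domains,
    multi_flag = ifelse(hits$multi, "multi", "single"),
    verdict = vapply(hits$locus, function(l) report$verdicts[[l]]$level, ""),
    color = unname(report$locus_colors[hits$locus]),
    stringsAsFactors = FALSE)
  write_tsv(cand, file.path(dir, "candidates.tsv"))

  ident <- data.frame(
    subject = names(report$identity_colors),
    color = unname(report$identity_colors),
    candidates = vapply(names(report$identity_colors), function(id)
      length(report$result$by_identity[[id]]), integer(1)),
    stringsAsFactors = FALSE)
  ident <- ident[order(ident$subject), , drop = FALSE]
  write_tsv(ident, file.path(dir, "identities.tsv"))

  json <- list(
    summary = list(
      total_candidates = report$summary$total_candidates,
      single_subunit = report$summary$single_subunit,
      multi_subunit = report$summary$multi_subunit,
      green = report$summary$green,
      per_identity = as.list(report$summary$per_identity)),
    identity_colors = as.list(report$identity_colors),
    locus_colors = as.list(report$locus_colors),
    provenance = report$provenance)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Reload a written report summary
#'
#' Round trip: `read_report_summary(write_report(x, d))` reproduces
#' `x$summary` exactly.
#'
#' @param dir Directory written by [write_report()].
#' @return A `summary_counts` object.
#' @export
read_report_summary <- function(dir) {
  json <- jsonlite::read_json(file.path(dir, "report.json"))
  s <- json$summary
  structure(list(
    total_candidates = as.integer(s$total_candidates),
    single_subunit = as.integer(s$single_subunit),
    multi_subunit = as.integer(s$multi_subunit),
    green = as.integer(s$green),
    per_identity = vapply(s$per_identity, as.integer, integer(1))),
    class = "summary_counts")
}

# ---- command-line interface ------------------------------------------------

cli_args <- function(args, flags) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3L)
    if (!key %in% flags) stop("unknown flag: --", key, call. = FALSE)
    if (i == length(args)) stop("flag --", key, " needs a value", call. = FALSE)
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands:
#' \describe{
#'   \item{screen}{`--queries Q.tsv --proteome P.tsv [--evidence E.tsv]
#'     [--threshold 10] [--keywords "vesicle transport,endocytosis"]
#'     --out DIR` -- full pipeline, writes `candidates.tsv`,
#'     `identities.tsv`, `report.json`.}
#'   \item{scan}{`--patterns PAT.tsv --fasta SEQ.fa --out annot.tsv` --
#'     PROSITE pattern scan producing a proteome-annotation TSV mergeable
#'     into `screen` input.}
#'   \item{simulate}{`--seed N --out DIR [--background N] [--single N]
#'     [--multi N]` -- writes a generated instance plus its ground truth.}
#'   \item{fixtures}{`--name arabidopsis|rice --out DIR` -- materialize a
#'     packaged fixture to disk.}
#' }
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Exit status, invisibly (0 on success).
#' @export
coatscreen_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: coatscreen <screen|scan|simulate|fixtures> [--flags]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  status <- tryCatch({
    switch(cmd,
      screen = cmd_screen(rest),
      scan = cmd_scan(rest),
      simulate = cmd_simulate(rest),
      fixtures = cmd_fixtures(rest),
      stop("unknown subcommand: ", cmd, call. = FALSE))
    0L
  }, error = function(e) {
    message("coatscreen ", cmd, ": ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cmd_screen <- function(args) {
  opt <- cli_args(args, c("queries", "proteome", "evidence", "out",
                          "threshold", "keywords"))
  if (is.null(opt$queries) || is.null(opt$proteome) || is.null(opt$out)) {
    stop("screen requires --queries, --proteome and --out", call. = FALSE)
  }
  keywords <- if (is.null(opt$keywords)) DEFAULT_VESICLE_KEYWORDS
              else trimws(strsplit(opt$keywords, ",")[[1]])
  rep <- run_screen(opt$queries, opt$proteome, opt$evidence,
                    vesicle_keywords = keywords,
                    consensus_threshold = as.numeric(opt$threshold %||% 10))
  write_report(rep, opt$out)
  message("screen: ", rep$summary$total_candidates, " candidate loci (",
          rep$summary$single_subunit, " single, ",
          rep$summary$multi_subunit, " multi, green ",
          rep$summary$green, ") -> ", opt$out)
  invisible(rep)
}

cmd_scan <- function(args) {
  opt <- cli_args(args, c("patterns", "fasta", "out"))
  if (is.null(opt$patterns) || is.null(opt$fasta) || is.null(opt$out)) {
    stop("scan requires --patterns, --fasta and --out", call. = FALSE)
  }
  patterns <- read_pattern_table(opt$patterns)
  annot <- annotate_proteome(patterns, opt$fasta)
  ids <- names(annot) %||% character(0)
  tab <- data.frame(
    locus = ids,
    name = ids,
    domains = vapply(annot, render_domain_set, ""),
    role_text = rep("", length(ids)),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$locus), , drop = FALSE]
  write_tsv(tab, opt$out)
  message("scan: ", nrow(tab), " annotated sequence(s) -> ", opt$out)
  invisible(tab)
}

cmd_simulate <- function(args) {
  opt <- cli_args(args, c("seed", "out", "background", "single", "multi",
                          "queries"))
  if (is.null(opt$seed) || is.null(opt$out)) {
    stop("simulate requires --seed and --out", call. = FALSE)
  }
  queries <- if (is.null(opt$queries))
    load_fixture("arabidopsis")$queries else load_query_table(opt$queries)
  catalog <- build_catalog(queries)
  cfg <- generator_config(
    n_background = as.integer(opt$background %||% 50L),
    n_planted_single = as.integer(opt$single %||% 8L),
    n_planted_multi = as.integer(opt$multi %||% 3L),
    seed = as.integer(opt$seed))
  inst <- generate_screen_instance(cfg, catalog)
  dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
  prot <- inst$proteome
  prot_tab <- data.frame(locus = prot$locus, name = prot$name,
                         domains = vapply(prot$domains, render_domain_set, ""),
                         role_text = prot$role_text, stringsAsFactors = FALSE)
  write_tsv(prot_tab, file.path(opt$out, "proteome.tsv"))
  ev <- inst$evidence
  ev_tab <- data.frame(locus = ev$locus, dialect = ev$dialect,
                       cp_score = sprintf("%.1f", ev$cp_score),
                       mt_score = sprintf("%.1f", ev$mt_score),
                       sec_score = sprintf("%.1f", ev$sec_score),
                       suba = ev$suba, suba_method = ev$suba_method,
                       c2010 = ev$c2010,
                       targetp_cp = tolower(ev$targetp_cp),
                       stringsAsFactors = FALSE)
  write_tsv(ev_tab, file.path(opt$out, "evidence.tsv"))
  jsonlite::write_json(inst$truth, file.path(opt$out, "ground_truth.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  message("simulate: ", nrow(prot_tab), " loci -> ", opt$out)
  invisible(inst)
}

cmd_fixtures <- function(args) {
  opt <- cli_args(args, c("name", "out"))
  if (is.null(opt$name) || is.null(opt$out)) {
    stop("fixtures requires --name and --out", call. = FALSE)
  }
  dir <- system.file("extdata", "fixtures", package = "coatscreen",
                     mustWork = TRUE)
  dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
  files <- list.files(dir, pattern = paste0("^", opt$name, "_"),
                      full.names = TRUE)
  if (length(files) == 0L) stop("unknown fixture: ", opt$name, call. = FALSE)
  file.copy(files, opt$out, overwrite = TRUE)
  message("fixtures: ", length(files), " file(s) -> ", opt$out)
  invisible(files)
}
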
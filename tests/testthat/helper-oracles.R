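# Test helpers: independent oracles and in-code fixture builders.
# The oracles deliberately re-derive expectations by different means than the
# implementation (regex translation for the pattern scanner, exhaustive
# subset checks for the screen).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# ---- tabular fixture builders (exercise the public file interfaces) --------

write_queries_tsv <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  header <- "protein_id\torganism\tsystem\tcomplex\tsubunit\tdomains"
  writeLines(c(header, rows), path, useBytes = TRUE)
  path
}

write_proteome_tsv <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  header <- "locus\tname\tdomains\trole_text"
  writeLines(c(header, rows), path, useBytes = TRUE)
  path
}

write_evidence_tsv <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  header <- paste("locus", "dialect", "cp_score", "mt_score", "sec_score",
                  "suba", "suba_method", "c2010", "targetp_cp", sep = "\t")
  writeLines(c(header, rows), path, useBytes = TRUE)
  path
}

evidence_row <- function(locus, cp = 0, suba = "none", c2010 = "no",
                         dialect = "consensus", targetp = "false",
                         method = ifelse(suba == "yes", "MS/MS", "")) {
  paste(locus, dialect, cp, 0, 0, suba, method, c2010, targetp, sep = "\t")
}

# ---- regex translation oracle for the PROSITE scanner ----------------------

pattern_to_regex <- function(pattern) {
  parts <- vapply(pattern$elements, function(el) {
    base <- switch(el$kind,
      any = "[A-Z]",
      exact = el$residues,
      class = paste0("[", paste(el$residues, collapse = ""), "]"),
      negated_class = paste0("[", paste(setdiff(AA20, el$residues),
                                        collapse = ""), "]"))
    if (el$min == 1L && el$max == 1L) base
    else sprintf("(?:%s){%d,%d}", base, el$min, el$max)
  }, "")
  paste0(paste(parts, collapse = ""),
         if (pattern$anchored_end) "$" else "")
}

# Match-start positions according to the regex translation: anchored matching
# of the translated pattern at every candidate start.
oracle_match_starts <- function(pattern, sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) return(integer(0))
  rx <- paste0("^(?:", pattern_to_regex(pattern), ")")
  starts <- if (pattern$anchored_start) 1L else seq_len(n)
  hits <- vapply(starts, function(s) {
    regexpr(rx, substring(sequence, s), perl = TRUE) == 1L
  }, logical(1))
  starts[hits]
}

# ---- brute-force screening oracle ------------------------------------------

# Hit set recomputed from first principles: for every locus x identity, scan
# all signatures of that identity for a subset relation.
sort_named <- function(l) {
  if (length(l) == 0L) return(setNames(list(), character(0)))
  lapply(l[order(names(l))], sort)
}

oracle_screen <- function(proteome, catalog) {
  sig <- catalog$signatures
  out <- setNames(list(), character(0))
  for (i in seq_len(nrow(proteome))) {
    locus <- proteome$locus[i]
    dom <- proteome$domains[[i]]
    ids <- character(0)
    for (j in seq_len(nrow(sig))) {
      if (all(sig$required[[j]] %in% dom)) ids <- c(ids, sig$identity[j])
    }
    if (length(ids) > 0L) out[[locus]] <- sort(unique(ids))
  }
  out
}

# Random (catalog, proteome) pair over a small accession universe; some
# proteome domains fall outside the catalog on purpose.
random_screen_case <- function(n_loci = 20L, n_sig = 6L, universe_size = 12L) {
  universe <- sprintf("PF0%04d", seq_len(universe_size))
  systems <- c("CCV", "COPI", "GTPase")
  qrows <- vapply(seq_len(n_sig), function(j) {
    dom <- sample(universe, sample.int(3L, 1L))
    paste(sprintf("Q%02d", j), "yeast", sample(systems, 1L),
          sprintf("CPX%d", sample.int(3L, 1L)),
          sprintf("su%d", sample.int(4L, 1L)),
          paste(dom, collapse = ";"), sep = "\t")
  }, "")
  extra <- sprintf("PF8%04d", 1:3)
  prows <- vapply(seq_len(n_loci), function(i) {
    k <- sample.int(8L, 1L) - 1L
    dom <- sample(c(universe, extra), k)
    paste(sprintf("L%03d", i), "x", paste(dom, collapse = ";"), "role",
          sep = "\t")
  }, "")
  queries <- load_query_table(write_queries_tsv(qrows))
  proteome <- load_proteome_table(write_proteome_tsv(prows))
  list(catalog = build_catalog(queries), proteome = proteome)
}

# A minimal two-signature catalog used across unit tests.
tiny_catalog <- function() {
  build_catalog(load_query_table(write_queries_tsv(c(
    "HC_Y\tyeast\tCCV\ttriskelion\theavy chain\tPF01394;PS50236",
    "LC_Y\tyeast\tCCV\ttriskelion\tlight chain\tPF01086",
    "B1_Y\tyeast\tCCV\tAP1\tbeta1\tPF01602",
    "B2_Y\tyeast\tCCV\tAP2\tbeta2\tPF01602"
  ))))
}

fixture_ab <- function() load_fixture("arabidopsis")

run_fixture_screen <- function(name = "arabidopsis") {
  fx <- load_fixture(name)
  suppressWarnings(run_screen(fx$queries, fx$proteome, fx$evidence))
}
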
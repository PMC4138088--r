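# PROSITE pattern parsing and scanning.
#
# Only pattern-type entries (PS0xxxx) are regular-expression-like motifs that
# can be evaluated against a raw sequence; profile entries (PS5xxxx) and Pfam
# families are position-weight/HMM models and must arrive as precomputed
# annotations. Registering a pattern string under a non-pattern accession is
# therefore an error, not a silent downgrade.

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
# Ambiguity/rare codes tolerated in sequences; they satisfy only the
# wildcard element, never an exact/class element (conservative: an ambiguous
# residue cannot invent a hit).
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "O")

#' Parse a PROSITE pattern
#'
#' Accepts the standard PROSITE pattern grammar: elements separated by `-`;
#' `x` for any residue; `[ABC]` for a residue class; `{ABC}` for a negated
#' class; `(n)` or `(n,m)` repeat counts; a leading `<` anchoring the match to
#' the sequence start and a trailing `>` anchoring it to the end; an optional
#' trailing `.`.
#'
#' @param text Pattern string, e.g. `"C-x(2)-C."`.
#' @param accession The pattern-type (`PS0xxxx`) accession the pattern defines.
#' @return An object of class `prosite_pattern` with fields `accession`,
#'   `elements` (list of elements with `kind` in
#'   `exact`/`any`/`class`/`negated_class`, `residues`, `min`, `max`),
#'   `anchored_start`, `anchored_end`.
#' @examples
#' p <- parse_prosite_pattern("C-x(2)-C.", "PS00190")
#' scan_sequence(p, "ACHHCA", "demo")
#' @export
parse_prosite_pattern <- function(text, accession) {
  stopifnot(is.character(text), length(text) == 1L)
  if (accession_kind(accession) != "pattern") {
    stop("accession ", accession, " is not a PROSITE pattern (PS0xxxx); ",
         "profile/family assignments must be supplied as annotations",
         call. = FALSE)
  }
  raw <- gsub("[[:space:]]", "", text)
  raw <- sub("\\.$", "", raw)
  anchored_start <- startsWith(raw, "<")
  if (anchored_start) raw <- substring(raw, 2L)
  anchored_end <- endsWith(raw, ">")
  if (anchored_end) raw <- substring(raw, 1L, nchar(raw) - 1L)
  if (!nzchar(raw)) stop("empty pattern: ", text, call. = FALSE)
  tokens <- strsplit(raw, "-", fixed = TRUE)[[1]]
  if (any(!nzchar(tokens))) {
    stop("empty element in pattern: ", text, call. = FALSE)
  }
  elements <- vector("list", length(tokens))
  for (i in seq_along(tokens)) {
    elements[[i]] <- parse_pattern_element(tokens[i], i)
  }
  structure(list(accession = accession, elements = elements,
                 anchored_start = anchored_start, anchored_end = anchored_end),
            class = "prosite_pattern")
}

parse_pattern_element <- function(token, index) {
  err <- function(...) {
    stop("pattern element ", index, " ('", token, "'): ", ..., call. = FALSE)
  }
  m <- regmatches(token, regexec("^(.*?)\\((\\d+)(?:,(\\d+))?\\)$", token))[[1]]
  if (length(m) > 0L) {
    base <- m[2]
    min_rep <- as.integer(m[3])
    max_rep <- if (nzchar(m[4])) as.integer(m[4]) else min_rep
    if (max_rep < min_rep) err("repeat range (", min_rep, ",", max_rep,
                               ") has max < min")
  } else {
    if (grepl("[()]", token)) err("malformed repeat specification")
    base <- token
    min_rep <- 1L
    max_rep <- 1L
  }
  if (!nzchar(base)) err("missing residue specification before repeat")
  if (base == "x") {
    return(list(kind = "any", residues = character(0),
                min = min_rep, max = max_rep))
  }
  if (startsWith(base, "[") || startsWith(base, "{")) {
    open <- substring(base, 1L, 1L)
    close <- if (open == "[") "]" else "}"
    if (!endsWith(base, close) || nchar(base) < 3L) {
      err("unbalanced brackets")
    }
    inner <- substring(base, 2L, nchar(base) - 1L)
    if (grepl("[][{}]", inner)) err("unbalanced brackets")
    residues <- strsplit(inner, "")[[1]]
    bad <- setdiff(residues, AA_STANDARD)
    if (length(bad) > 0L) err("unknown residue letter(s): ",
                              paste(bad, collapse = ", "))
    return(list(kind = if (open == "[") "class" else "negated_class",
                residues = sort(unique(residues)),
                min = min_rep, max = max_rep))
  }
  if (nchar(base) == 1L && base %in% AA_STANDARD) {
    return(list(kind = "exact", residues = base, min = min_rep, max = max_rep))
  }
  err("unknown residue letter: ", base)
}

#' Render a parsed pattern back to PROSITE syntax
#'
#' `parse_prosite_pattern(render_prosite_pattern(p), p$accession)` is
#' grammar-equivalent to `p` (repeat `(1,1)` is omitted, `(n,n)` collapses to
#' `(n)`).
#'
#' @param pattern A `prosite_pattern`.
#' @return A single pattern string ending in `.`.
#' @export
render_prosite_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  toks <- vapply(pattern$elements, function(el) {
    base <- switch(el$kind,
      any = "x",
      exact = el$residues,
      class = paste0("[", paste(el$residues, collapse = ""), "]"),
      negated_class = paste0("{", paste(el$residues, collapse = ""), "}"))
    rep <- if (el$min == 1L && el$max == 1L) ""
           else if (el$min == el$max) paste0("(", el$min, ")")
           else paste0("(", el$min, ",", el$max, ")")
    paste0(base, rep)
  }, "")
  paste0(if (pattern$anchored_start) "<" else "",
         paste(toks, collapse = "-"),
         if (pattern$anchored_end) ">" else "", ".")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("<prosite_pattern ", x$accession, "> ",
      render_prosite_pattern(x), "\n", sep = "")
  invisible(x)
}

# Does a single sequence character satisfy one element? Ambiguous letters
# (X and friends) satisfy only the wildcard.
element_accepts <- function(el, ch) {
  switch(el$kind,
    any = TRUE,
    exact = ch == el$residues,
    class = ch %in% el$residues,
    negated_class = (ch %in% AA_STANDARD) && !(ch %in% el$residues))
}

#' Scan a protein sequence with a PROSITE pattern
#'
#' Reports matches at every feasible start position (overlapping matches
#' included). Per start position exactly one span is reported: the greedy
#' (leftmost-longest) expansion of the repeat counts. Coordinates are 1-based
#' and inclusive, following ScanProsite convention.
#'
#' @param pattern A `prosite_pattern`.
#' @param sequence Amino-acid string over the 20 standard letters plus `X`;
#'   case-insensitive.
#' @param sequence_id Identifier copied into the result.
#' @return Data frame with columns `sequence_id`, `start`, `end`, sorted by
#'   `start`. An empty sequence yields zero rows.
#' @export
scan_sequence <- function(pattern, sequence, sequence_id = "seq") {
  stopifnot(inherits(pattern, "prosite_pattern"),
            is.character(sequence), length(sequence) == 1L)
  empty <- data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (!nzchar(sequence)) return(empty)
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), c(AA_STANDARD, AA_AMBIGUOUS))
  if (length(bad) > 0L) {
    stop("sequence ", sequence_id, " contains invalid letter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- length(chars)
  elements <- pattern$elements
  n_el <- length(elements)
  need_end <- pattern$anchored_end

  # Greedy backtracking: element ei tries its maximal repeat count first and
  # yields the end position (0-length match at position p returns p-1).
  match_here <- function(pos, ei) {
    if (ei > n_el) {
      if (need_end && pos != n + 1L) return(-1L)
      return(pos - 1L)
    }
    el <- elements[[ei]]
    # longest feasible consecutive run of this element from pos
    run <- 0L
    while (run < el$max && pos + run <= n &&
           element_accepts(el, chars[pos + run])) {
      run <- run + 1L
    }
    if (run < el$min) return(-1L)
    for (k in seq(from = run, to = el$min, by = -1L)) {
      res <- match_here(pos + k, ei + 1L)
      if (res >= 0L) return(res)
    }
    -1L
  }

  starts <- if (pattern$anchored_start) 1L else seq_len(n)
  hits_start <- integer(0)
  hits_end <- integer(0)
  for (s in starts) {
    e <- match_here(s, 1L)
    if (e >= 0L) {
      hits_start <- c(hits_start, s)
      hits_end <- c(hits_end, e)
    }
  }
  if (length(hits_start) == 0L) return(empty)
  data.frame(sequence_id = sequence_id, start = hits_start, end = hits_end,
             stringsAsFactors = FALSE)
}

#' Read a pattern definitions table
#'
#' TSV with columns `accession` and `pattern_text`; every accession must be
#' pattern-type (PS0xxxx).
#'
#' @param path Path to the TSV file.
#' @return Named list of `prosite_pattern` objects keyed by accession.
#' @export
read_pattern_table <- function(path) {
  tab <- read_tsv_strict(path, required = c("accession", "pattern_text"))
  if (anyDuplicated(tab$accession)) {
    stop(path, ": duplicate pattern accession(s): ",
         paste(unique(tab$accession[duplicated(tab$accession)]),
               collapse = ", "), call. = FALSE)
  }
  pats <- Map(parse_prosite_pattern, tab$pattern_text, tab$accession)
  names(pats) <- tab$accession
  pats
}

#' Annotate a proteome by pattern scanning
#'
#' Assigns a pattern accession to a protein iff the pattern has at least one
#' match span in its sequence. The result is sparse -- proteins with no match
#' are absent from the map -- and mergeable with externally supplied
#' profile/family annotations.
#'
#' @param patterns List of `prosite_pattern` objects (e.g. from
#'   [read_pattern_table()]).
#' @param fasta Either a path to a FASTA file or a named character vector of
#'   sequences. Sequence ids must be unique; a duplicate id is an error.
#' @return Named list mapping protein id to a sorted character vector of
#'   matched accessions.
#' @export
annotate_proteome <- function(patterns, fasta) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && is.null(names(fasta))) {
    read_fasta_simple(fasta)
  } else {
    fasta
  }
  if (length(seqs) > 0L && (is.null(names(seqs)) || any(!nzchar(names(seqs))))) {
    stop("sequences must be named", call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate FASTA id(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (id in names(seqs)) {
    acc <- character(0)
    for (p in patterns) {
      if (nrow(scan_sequence(p, seqs[[id]], id)) > 0L) {
        acc <- c(acc, p$accession)
      }
    }
    if (length(acc) > 0L) out[[id]] <- sort(unique(acc))
  }
  out
}
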
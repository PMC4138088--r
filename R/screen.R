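#' Load a proteome annotation table
#'
#' TSV with columns `locus`, `name`, `domains` (`;`-separated accessions,
#' possibly empty) and `role_text` (free-text role phrases from the source
#' annotation). Locus ids must be unique.
#'
#' @param path Path to the TSV file.
#' @return Data frame of class `coat_proteome` with list-column `domains`.
#' @export
load_proteome_table <- function(path) {
  tab <- read_tsv_strict(path, required = c("locus", "name", "domains",
                                            "role_text"))
  as_proteome_table(tab, source = path)
}

as_proteome_table <- function(tab, source = "<data>") {
  if (anyDuplicated(tab$locus)) {
    stop(source, ": duplicate locus id(s): ",
         paste(unique(tab$locus[duplicated(tab$locus)]), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(tab)
  domains <- vector("list", max(n, 0L))
  for (i in seq_len(n)) {
    d <- tryCatch(parse_domain_set(tab$domains[i]), error = function(e) e)
    if (inherits(d, "error")) {
      stop(source, ", row ", i, " (", tab$locus[i], "): ",
           conditionMessage(d), call. = FALSE)
    }
    domains[[i]] <- d
  }
  out <- tab[, setdiff(names(tab), "domains"), drop = FALSE]
  out$domains <- domains
  rownames(out) <- NULL
  class(out) <- c("coat_proteome", class(out))
  out
}

#' Screen a proteome against a signature catalog
#'
#' A locus hits a subunit identity iff at least one signature of that identity
#' has its required domain set contained in the locus's domain set (superset
#' containment, not equality: a candidate may carry extra domains, e.g. the
#' rice clathrin heavy chains carry an additional decarboxylase site yet still
#' match the heavy-chain signature). Each (locus, identity) pair is reported
#' once, witnessed by the matching signature with the smallest required set
#' (ties broken by source id).
#'
#' Loci hitting two or more distinct identities form the "commonly occurring
#' domain" (multi-subunit) partition; the remainder are single-subunit
#' candidates.
#'
#' @param proteome A `coat_proteome` data frame.
#' @param catalog A `signature_catalog`.
#' @param warn_unknown Warn (once, with a count) about proteome accessions
#'   absent from the catalog. They are ignored either way.
#' @return An object of class `screen_result`: list with
#'   \describe{
#'     \item{hits}{data frame `locus`, `system`, `complex`, `subunit`,
#'       `identity`, `witness_source`, `witness_domains`, `multi`, ordered by
#'       locus then identity.}
#'     \item{by_identity}{named list identity -> sorted locus vector (empty
#'       character vector for identities with no candidates).}
#'     \item{partition}{`multi_subunit_loci` and `single_subunit_loci`
#'       partition the hit loci.}
#'     \item{unknown_accessions}{proteome accessions not present in any
#'       signature.}
#'   }
#' @export
screen_proteome <- function(proteome, catalog, warn_unknown = TRUE) {
  stopifnot(inherits(proteome, "coat_proteome"),
            inherits(catalog, "signature_catalog"))
  if (nrow(catalog$signatures) == 0L) {
    stop("signature catalog is empty", call. = FALSE)
  }
  sig <- catalog$signatures
  sig_size <- lengths(sig$required)

  prot_acc <- unique(unlist(proteome$domains, use.names = FALSE))
  unknown <- setdiff(prot_acc, names(catalog$domain_index))
  if (warn_unknown && length(unknown) > 0L) {
    warning(length(unknown), " proteome accession(s) not in any signature ",
            "were ignored (e.g. ", paste(utils::head(sort(unknown), 3L),
                                         collapse = ", "), ")",
            call. = FALSE)
  }

  rows <- list()
  for (i in seq_len(nrow(proteome))) {
    locus <- proteome$locus[i]
    dom <- proteome$domains[[i]]
    if (length(dom) == 0L) next
    ok <- vapply(sig$required, function(req) all(req %in% dom), logical(1))
    if (!any(ok)) next
    idx <- which(ok)
    # one witness per identity: smallest required set, then source id
    ord <- idx[order(sig_size[idx], sig$source[idx])]
    ord <- ord[!duplicated(sig$identity[ord])]
    rows[[length(rows) + 1L]] <- data.frame(
      locus = locus,
      system = sig$system[ord],
      complex = sig$complex[ord],
      subunit = sig$subunit[ord],
      identity = sig$identity[ord],
      witness_source = sig$source[ord],
      witness_domains = vapply(sig$required[ord], render_domain_set, ""),
      stringsAsFactors = FALSE
    )
  }
  hits <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(locus = character(0), system = character(0),
               complex = character(0), subunit = character(0),
               identity = character(0), witness_source = character(0),
               witness_domains = character(0), stringsAsFactors = FALSE)
  hits <- hits[order(hits$locus, hits$identity), , drop = FALSE]
  rownames(hits) <- NULL

  n_ident <- vapply(split(hits$identity, hits$locus),
                    function(x) length(unique(x)), integer(1))
  multi <- sort(names(n_ident)[n_ident >= 2L])
  single <- sort(setdiff(unique(hits$locus), multi))
  hits$multi <- hits$locus %in% multi

  by_identity <- lapply(catalog$identities, function(id) {
    sort(unique(hits$locus[hits$identity == id]))
  })
  names(by_identity) <- catalog$identities

  structure(
    list(hits = hits, by_identity = by_identity,
         multi_subunit_loci = multi, single_subunit_loci = single,
         unknown_accessions = sort(unknown)),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n")
  cat("  candidate loci: ", length(x$single_subunit_loci) +
        length(x$multi_subunit_loci),
      " (single ", length(x$single_subunit_loci),
      ", multi ", length(x$multi_subunit_loci), ")\n", sep = "")
  cat("  identities with >=1 candidate: ",
      sum(lengths(x$by_identity) > 0L), "/", length(x$by_identity),
      "\n", sep = "")
  invisible(x)
}

#' Count candidates for one subunit identity
#'
#' @param result A `screen_result`.
#' @param identity Identity key `"system/complex/subunit"` or a character
#'   vector `c(system, complex, subunit)`.
#' @param exclude_multi Drop loci that also hit other identities (the
#'   "commonly occurring domain" candidates), counting only subunit-specific
#'   candidates.
#' @return Integer count; an identity absent from the catalog yields 0 with a
#'   warning.
#' @export
count_candidates <- function(result, identity, exclude_multi = FALSE) {
  stopifnot(inherits(result, "screen_result"))
  key <- identity_key(identity)
  if (!key %in% names(result$by_identity)) {
    warning("identity not in catalog: ", key, call. = FALSE)
    return(0L)
  }
  loci <- result$by_identity[[key]]
  if (exclude_multi) loci <- setdiff(loci, result$multi_subunit_loci)
  length(loci)
}

identity_key <- function(identity) {
  if (length(identity) == 3L) {
    identity <- render_identity(identity[1], identity[2],
                                canonical_subunit(identity[3]))
  }
  parts <- strsplit(identity, "/", fixed = TRUE)[[1]]
  if (length(parts) == 3L) {
    identity <- render_identity(parts[1], parts[2], canonical_subunit(parts[3]))
  }
  identity
}

#' Compare a candidate's domain architecture with a reference set
#'
#' Used to articulate why a hit may still be a poor homolog: e.g. the
#' magnesium-chelatase subunit ChlD matches the F-COPI zeta signature through
#' its VWFA profile but lacks the clathrin adaptor small-chain domain carried
#' by genuine zeta subunits.
#'
#' @param candidate A single-row `coat_proteome` slice, or a character vector
#'   of accessions.
#' @param reference Character vector of reference accessions.
#' @return List with `missing` (reference domains the candidate lacks) and
#'   `extra` (candidate domains outside the reference), both sorted.
#' @export
compare_signatures <- function(candidate, reference) {
  dom <- if (is.character(candidate)) candidate
         else if (inherits(candidate, "coat_proteome") && nrow(candidate) == 1L)
           candidate$domains[[1]]
         else stop("candidate must be accessions or a one-row proteome slice",
                   call. = FALSE)
  list(missing = sort(setdiff(reference, dom)),
       extra = sort(setdiff(dom, reference)))
}
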
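#' Load a query-protein table
#'
#' Reads a UTF-8 TSV of query vesicle-coat proteins, one row per protein, with
#' columns `protein_id`, `organism`, `system`, `complex`, `subunit` and
#' `domains` (a `;`-separated list of PROSITE/Pfam accessions). Each query
#' protein later contributes exactly one subunit signature -- its full domain
#' set -- to the catalog built by [build_catalog()].
#'
#' Rows with a malformed accession or an empty domain set are rejected with an
#' error locating the row. Fully duplicated rows are collapsed. Additional
#' columns (e.g. an `inferred` provenance flag) are carried through untouched.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `coat_queries` with columns `protein_id`,
#'   `organism`, `system`, `complex`, `subunit` (canonical Unicode form) and a
#'   list-column `domains` of sorted accession character vectors.
#' @seealso [build_catalog()], [load_fixture()]
#' @export
load_query_table <- function(path) {
  tab <- read_tsv_strict(path, required = c("protein_id", "organism", "system",
                                            "complex", "subunit", "domains"))
  as_query_table(tab, source = path)
}

# Shared validation path for file input and in-memory data frames.
as_query_table <- function(tab, source = "<data>") {
  n <- nrow(tab)
  if (n == 0L) {
    out <- data.frame(protein_id = character(0), organism = character(0),
                      system = character(0), complex = character(0),
                      subunit = character(0), stringsAsFactors = FALSE)
    out$domains <- list()
    class(out) <- c("coat_queries", class(out))
    return(out)
  }
  validate_organism(tab$organism)
  validate_system(tab$system)
  tab$subunit <- canonical_subunit(tab$subunit)
  domains <- vector("list", n)
  for (i in seq_len(n)) {
    d <- tryCatch(parse_domain_set(tab$domains[i]), error = function(e) e)
    if (inherits(d, "error")) {
      stop(source, ", row ", i, " (", tab$protein_id[i], "): ",
           conditionMessage(d), call. = FALSE)
    }
    if (length(d) == 0L) {
      stop(source, ", row ", i, " (", tab$protein_id[i],
           "): empty domain set", call. = FALSE)
    }
    domains[[i]] <- d
  }
  key <- paste(tab$protein_id, tab$organism, tab$system, tab$complex,
               tab$subunit, vapply(domains, render_domain_set, ""), sep = "\r")
  keep <- !duplicated(key)
  out <- tab[keep, setdiff(names(tab), "domains"), drop = FALSE]
  out$domains <- domains[keep]
  rownames(out) <- NULL
  class(out) <- c("coat_queries", class(out))
  out
}

#' Build a signature catalog from query proteins
#'
#' Derives one subunit signature per query protein: the signature's required
#' domain set is the protein's full domain set, and its identity is the
#' (system, complex, subunit) triple the protein annotates. Two query proteins
#' with the same identity but different domain sets (e.g. a yeast and an
#' Arabidopsis ortholog) yield two distinct signatures under that identity;
#' exact duplicates of an (identity, required-set) pair are collapsed, keeping
#' the lexicographically first source id.
#'
#' @param queries A `coat_queries` data frame from [load_query_table()].
#' @return An object of class `signature_catalog`: a list with
#'   \describe{
#'     \item{signatures}{data frame with columns `system`, `complex`,
#'       `subunit`, `identity` (rendered `system/complex/subunit` key),
#'       `source` (query protein id), `organism`, and list-column `required`.}
#'     \item{domain_index}{named list mapping each accession to the sorted set
#'       of identity keys whose signatures contain it (the exact inversion of
#'       `signatures`).}
#'     \item{identities}{sorted unique identity keys.}
#'   }
#' @export
build_catalog <- function(queries) {
  stopifnot(inherits(queries, "coat_queries"))
  sig <- data.frame(
    system   = queries$system,
    complex  = queries$complex,
    subunit  = queries$subunit,
    identity = render_identity(queries$system, queries$complex, queries$subunit),
    source   = queries$protein_id,
    organism = queries$organism,
    stringsAsFactors = FALSE
  )
  sig$required <- queries$domains
  # collapse duplicate (identity, required) pairs, keep first source by id
  ord <- order(sig$identity,
               vapply(sig$required, render_domain_set, ""),
               sig$source)
  sig <- sig[ord, , drop = FALSE]
  key <- paste(sig$identity, vapply(sig$required, render_domain_set, ""),
               sep = "\r")
  sig <- sig[!duplicated(key), , drop = FALSE]
  rownames(sig) <- NULL

  domain_index <- list()
  for (i in seq_len(nrow(sig))) {
    for (a in sig$required[[i]]) {
      domain_index[[a]] <- c(domain_index[[a]], sig$identity[i])
    }
  }
  domain_index <- lapply(domain_index, function(x) sort(unique(x)))
  if (length(domain_index) > 0L) {
    domain_index <- domain_index[order(names(domain_index))]
  } else {
    domain_index <- stats::setNames(list(), character(0))
  }

  structure(
    list(signatures = sig,
         domain_index = domain_index,
         identities = sort(unique(sig$identity))),
    class = "signature_catalog"
  )
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat("<signature_catalog>\n")
  cat("  signatures: ", nrow(x$signatures), " (",
      length(x$identities), " subunit identities)\n", sep = "")
  cat("  domains indexed: ", length(x$domain_index), "\n", sep = "")
  shared <- shared_domain_report(x)
  cat("  shared domains (>=2 identities): ", length(shared), "\n", sep = "")
  invisible(x)
}

#' Report domains shared by several subunit identities
#'
#' A "commonly occurring" domain is one that appears in the signatures of two
#' or more distinct subunit identities (e.g. the Adaptin N-terminal region,
#' PF01602, identifies the large subunits of several AP complexes as well as
#' the F-COPI coatomer gamma subunit). A proteome protein carrying only such
#' domains cannot be assigned to a single subunit.
#'
#' @param catalog A `signature_catalog`.
#' @return Named list mapping each shared accession to the sorted character
#'   vector of identity keys (always of length >= 2).
#' @export
shared_domain_report <- function(catalog) {
  stopifnot(inherits(catalog, "signature_catalog"))
  Filter(function(ids) length(ids) >= 2L, catalog$domain_index)
}
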
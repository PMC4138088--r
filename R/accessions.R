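#' Domain accessions
#'
#' Domain identifiers are PROSITE (`PS#####`) or Pfam (`PF#####`) accessions.
#' The accession prefix determines the entry *kind*:
#' \describe{
#'   \item{pattern}{`PS0xxxx` -- a PROSITE pattern, a regular-expression-like
#'     motif that can be scanned directly against a protein sequence
#'     (see [parse_prosite_pattern()]).}
#'   \item{profile}{`PS5xxxx` -- a PROSITE profile (position-weight model).
#'     Profiles are not scannable by this package; their assignments must be
#'     supplied in the proteome annotation table.}
#'   \item{family}{`PF#####` -- a Pfam family/domain, likewise supplied as an
#'     external annotation.}
#' }
#'
#' @param accession Character vector of accessions.
#' @return `accession_kind()` returns a character vector with values
#'   `"pattern"`, `"profile"` or `"family"`; `is_valid_accession()` a logical
#'   vector.
#' @examples
#' accession_kind(c("PS00435", "PS51072", "PF01602"))
#' @export
accession_kind <- function(accession) {
  stopifnot(is.character(accession))
  bad <- !is_valid_accession(accession)
  if (any(bad)) {
    stop("malformed domain accession(s): ",
         paste(unique(accession[bad]), collapse = ", "), call. = FALSE)
  }
  kind <- character(length(accession))
  kind[startsWith(accession, "PF")] <- "family"
  kind[startsWith(accession, "PS5")] <- "profile"
  kind[startsWith(accession, "PS") & !startsWith(accession, "PS5")] <- "pattern"
  kind
}

#' @rdname accession_kind
#' @export
is_valid_accession <- function(accession) {
  grepl("^(PS[0-9]{5}|PF[0-9]{5})$", accession)
}

# Split a `;`-separated accession field into a sorted unique character set.
# Validation errors name the offending accession so a caller can locate the
# bad row.
parse_domain_set <- function(field) {
  acc <- unlist(strsplit(field, ";", fixed = TRUE), use.names = FALSE)
  acc <- trimws(acc)
  acc <- acc[nzchar(acc)]
  if (length(acc) == 0L) return(character(0))
  bad <- acc[!is_valid_accession(acc)]
  if (length(bad) > 0L) {
    stop("malformed domain accession(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  sort(unique(acc))
}

render_domain_set <- function(domains) paste(domains, collapse = ";")

# ---- subunit identities ----------------------------------------------------

VALID_SYSTEMS <- c("CCV", "COPI", "GTPase")
VALID_ORGANISMS <- c("arabidopsis", "yeast", "mouse", "human", "rice")

# ASCII aliases accepted on input for Greek subunit names. Stored form is
# always the Unicode (NFC) rendering on the left.
SUBUNIT_ALIASES <- c(
  "γ"        = "gamma",
  "α"        = "alpha",
  "δ"        = "delta",
  "ε"        = "epsilon",
  "ζ"        = "zeta",
  "β′"  = "beta-prime",
  "β1"       = "beta1",
  "β2"       = "beta2",
  "β3"       = "beta3",
  "β4"       = "beta4",
  "μ1"       = "mu1",
  "μ2"       = "mu2",
  "μ3"       = "mu3",
  "μ4"       = "mu4",
  "μ5"       = "mu5",
  "σ1"       = "sigma1",
  "σ2"       = "sigma2",
  "σ3"       = "sigma3",
  "σ4"       = "sigma4",
  "σ5"       = "sigma5"
)

#' Canonicalize a subunit name
#'
#' Subunit names containing Greek letters are stored in Unicode and compared
#' in NFC normal form. ASCII aliases (e.g. `"beta-prime"` for `"β′"`,
#' `"mu2"` for `"μ2"`) are accepted on input and mapped to the Unicode
#' form.
#'
#' @param subunit Character vector of subunit names.
#' @return Character vector of canonical (NFC Unicode) subunit names.
#' @export
canonical_subunit <- function(subunit) {
  x <- stringi::stri_trans_nfc(enc2utf8(as.character(subunit)))
  idx <- match(x, unname(SUBUNIT_ALIASES))
  hit <- !is.na(idx)
  x[hit] <- names(SUBUNIT_ALIASES)[idx[hit]]
  x
}

# Stable rendering of a (system, complex, subunit) triple, used as the unique
# key of a subunit identity and for deterministic report ordering.
render_identity <- function(system, complex, subunit) {
  paste(system, complex, subunit, sep = "/")
}

validate_system <- function(system) {
  bad <- setdiff(unique(system), VALID_SYSTEMS)
  if (length(bad) > 0L) {
    stop("unknown vesicle system(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(VALID_SYSTEMS, collapse = ", "),
         call. = FALSE)
  }
  invisible(system)
}

validate_organism <- function(organism) {
  bad <- setdiff(unique(organism), VALID_ORGANISMS)
  if (length(bad) > 0L) {
    stop("unknown organism(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(VALID_ORGANISMS, collapse = ", "),
         call. = FALSE)
  }
  invisible(organism)
}
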
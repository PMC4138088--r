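# Traffic-light classification of candidates and subunits.
#
# green  -- a single-subunit candidate whose annotated role already relates to
#           vesicle transport and whose chloroplast location has some support;
# yellow -- every other candidate (commonly occurring domains, a role
#           unrelated to vesicle transport, an unknown role, or no
#           localization support);
# red    -- a subunit identity for which no candidate was detected at all.
# Green/yellow apply to candidate loci, red only to identities.

DEFAULT_VESICLE_KEYWORDS <- c("vesicle transport", "endocytosis")

#' Classify one candidate locus
#'
#' A locus is green iff all three conditions hold: its role text matches at
#' least one vesicle keyword (substring, case-insensitive), it is a
#' single-subunit candidate, and its localization verdict is not
#' `unsupported`. Otherwise it is yellow, with a rationale naming every rule
#' that fired (the rules are not ranked).
#'
#' @param record One-row `coat_proteome` slice (or list with `locus`,
#'   `role_text`).
#' @param multi Is the locus a multi-subunit ("commonly occurring domain")
#'   candidate?
#' @param verdict A `support_verdict` for the locus.
#' @param vesicle_keywords Character vector of role keywords.
#' @return List of class `category_verdict`: `subject`, `color`
#'   (`green`/`yellow`), `rationale`.
#' @export
classify_locus <- function(record, multi, verdict,
                           vesicle_keywords = DEFAULT_VESICLE_KEYWORDS) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  role <- record$role_text %||% ""
  if (is.na(role)) role <- ""
  has_role <- nzchar(trimws(role)) && !identical(tolower(trimws(role)),
                                                 "unknown")
  vesicle_role <- has_role && any(vapply(vesicle_keywords, function(k) {
    grepl(k, role, ignore.case = TRUE, fixed = FALSE)
  }, logical(1)))
  supported <- !identical(verdict$level, "unsupported")

  if (vesicle_role && !multi && supported) {
    return(structure(list(subject = record$locus, color = "green",
                          rationale = "vesicle-transport role, single subunit, localization supported"),
                     class = "category_verdict"))
  }
  why <- c(
    if (multi) "commonly occurring domains (multiple subunits)",
    if (!has_role) "unknown role",
    if (has_role && !vesicle_role) "role unrelated to vesicle transport",
    if (!supported) "no chloroplast localization support"
  )
  structure(list(subject = record$locus, color = "yellow",
                 rationale = paste(why, collapse = "; ")),
            class = "category_verdict")
}

#' Classify one subunit identity
#'
#' Red iff the identity has no candidate locus at all; otherwise the best
#' color (green beats yellow) among its candidates' classifications.
#'
#' @param identity Identity key or `c(system, complex, subunit)`.
#' @param result A `screen_result`.
#' @param locus_colors Named character vector locus -> `"green"`/`"yellow"`
#'   (e.g. derived from [classify_locus()] over all hit loci).
#' @return List of class `category_verdict`.
#' @export
classify_identity <- function(identity, result, locus_colors = NULL) {
  stopifnot(inherits(result, "screen_result"))
  key <- identity_key(identity)
  if (!key %in% names(result$by_identity)) {
    stop("identity not in catalog: ", key, call. = FALSE)
  }
  loci <- result$by_identity[[key]]
  if (length(loci) == 0L) {
    return(structure(list(subject = key, color = "red",
                          rationale = "no proteins with the signature domains detected"),
                     class = "category_verdict"))
  }
  colors <- if (is.null(locus_colors)) rep("yellow", length(loci))
            else locus_colors[loci]
  color <- if (any(colors == "green", na.rm = TRUE)) "green" else "yellow"
  structure(list(subject = key, color = color,
                 rationale = paste0(length(loci), " candidate(s); best color ",
                                    color)),
            class = "category_verdict")
}

#' @export
print.category_verdict <- function(x, ...) {
  cat("<", x$color, "> ", x$subject, " -- ", x$rationale, "\n", sep = "")
  invisible(x)
}

#' Summarize a screen into headline counts
#'
#' @param result A `screen_result`.
#' @param locus_colors Named character vector locus -> color covering all hit
#'   loci (see [classify_locus()]).
#' @return List of class `summary_counts`: `total_candidates`,
#'   `single_subunit`, `multi_subunit`, `green`, and `per_identity` (named
#'   integer vector, multi-subunit candidates included).
#' @export
summarize_screen <- function(result, locus_colors = NULL) {
  stopifnot(inherits(result, "screen_result"))
  single <- length(result$single_subunit_loci)
  multi <- length(result$multi_subunit_loci)
  green <- if (is.null(locus_colors)) 0L else sum(locus_colors == "green")
  per_identity <- vapply(result$by_identity, length, integer(1))
  structure(list(total_candidates = single + multi,
                 single_subunit = single,
                 multi_subunit = multi,
                 green = as.integer(green),
                 per_identity = per_identity),
            class = "summary_counts")
}

#' @export
print.summary_counts <- function(x, ...) {
  cat("candidate loci: ", x$total_candidates,
      " (single-subunit ", x$single_subunit,
      ", multi-subunit ", x$multi_subunit,
      "; green ", x$green, ")\n", sep = "")
  invisible(x)
}

# Convenience: classify every hit locus of a screen result.
# Returns a named character vector locus -> color.
classify_all_loci <- function(proteome, result, verdicts,
                              vesicle_keywords = DEFAULT_VESICLE_KEYWORDS) {
  loci <- sort(unique(c(result$single_subunit_loci,
                        result$multi_subunit_loci)))
  colors <- character(length(loci))
  names(colors) <- loci
  for (locus in loci) {
    i <- match(locus, proteome$locus)
    rec <- if (is.na(i)) list(locus = locus, role_text = "")
           else proteome[i, , drop = FALSE]
    colors[locus] <- classify_locus(
      rec, multi = locus %in% result$multi_subunit_loci,
      verdict = verdicts[[locus]],
      vesicle_keywords = vesicle_keywords)$color
  }
  colors
}
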
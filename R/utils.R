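# Internal I/O helpers. All tabular interchange is UTF-8 TSV with a header
# row; reading is strict about required columns so format errors surface at
# the file boundary, not deep in the pipeline.

read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "", fileEncoding = "UTF-8",
                           colClasses = "character")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop(path, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

write_tsv <- function(tab, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(tab), collapse = "\t"),
               if (nrow(tab) > 0L)
                 do.call(paste, c(lapply(tab, as.character), sep = "\t"))),
             con, useBytes = TRUE)
  invisible(path)
}

# Minimal FASTA reader used when Biostrings is not wanted at run time; the
# scan entry points accept either a file path or a named character vector.
read_fasta_simple <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(setNames(character(0), character(0)))
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop(path, ": not FASTA (first line lacks '>')", call. = FALSE)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, "", 1L)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), "")
  out <- character(length(ids))
  names(out) <- ids
  out[as.integer(names(seqs))] <- unname(seqs)
  names(out) <- ids
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
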
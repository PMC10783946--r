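#' Feature-barcode whitelists
#'
#' A feature whitelist is the ordered set of designed barcode sequences being
#' assayed (one per antibody, hashtag oligo, sgRNA, ...). It is the single
#' input to mismatch-map construction, to the QC report and to the error
#' simulation. Quantification additionally requires all barcodes to share one
#' length, because read scanning uses a window of exactly that length.
#'
#' @name whitelist
NULL

#' Construct a feature whitelist
#'
#' Validates ids and sequences and returns a `fb_whitelist` object. Feature
#' ids must be non-empty, whitespace-free and pairwise distinct; sequences
#' must be uppercase A/C/G/T and pairwise distinct.
#'
#' @param feature_id character vector of feature labels.
#' @param sequence character vector of DNA barcode sequences, same length.
#' @return an object of class `fb_whitelist`: a data frame with columns
#'   `feature_id` and `sequence`, plus attribute `uniform_length`.
#' @examples
#' wl <- feature_whitelist(c("F1", "F2"), c("ACGT", "TGCA"))
#' @export
feature_whitelist <- function(feature_id, sequence) {
  feature_id <- as.character(feature_id)
  sequence <- as.character(sequence)
  if (length(feature_id) != length(sequence)) {
    stop("feature_id and sequence must have equal length", call. = FALSE)
  }
  if (length(feature_id) == 0L) {
    stop("whitelist is empty", call. = FALSE)
  }
  bad_id <- !nzchar(feature_id) | grepl("[[:space:]]", feature_id)
  if (any(bad_id)) {
    stop(sprintf("invalid feature id(s) (empty or containing whitespace): %s",
                 paste(sQuote(feature_id[bad_id]), collapse = ", ")),
         call. = FALSE)
  }
  stop_invalid_dna(sequence, what = "barcode sequence")
  dup_id <- unique(feature_id[duplicated(feature_id)])
  if (length(dup_id) > 0L) {
    stop(sprintf("duplicate feature id(s): %s",
                 paste(sQuote(dup_id), collapse = ", ")), call. = FALSE)
  }
  dup_seq <- unique(sequence[duplicated(sequence)])
  if (length(dup_seq) > 0L) {
    offenders <- feature_id[sequence %in% dup_seq]
    stop(sprintf("duplicate barcode sequence(s) %s shared by: %s",
                 paste(sQuote(dup_seq), collapse = ", "),
                 paste(sQuote(offenders), collapse = ", ")), call. = FALSE)
  }
  wl <- data.frame(feature_id = feature_id, sequence = sequence,
                   stringsAsFactors = FALSE)
  attr(wl, "uniform_length") <- length(unique(nchar(sequence))) == 1L
  class(wl) <- c("fb_whitelist", "data.frame")
  wl
}

#' Read a feature-barcode whitelist from TSV or FASTA
#'
#' The TSV dialect is two tab-separated columns, `feature_id` then
#' `sequence`, with no header by default (`header = TRUE` skips line 1).
#' FASTA records use the record id as the feature id. File order is
#' preserved.
#'
#' @param path file path.
#' @param format `"tsv"` or `"fasta"`; default guesses from the extension
#'   (`.fa`, `.fasta` -> fasta, otherwise tsv).
#' @param header for TSV only: skip the first line.
#' @return an `fb_whitelist`.
#' @export
read_whitelist <- function(path, format = c("auto", "tsv", "fasta"),
                           header = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("whitelist file not found: %s", path), call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta)(\\.gz)?$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    recs <- Biostrings::readBStringSet(path, format = "fasta")
    ids <- sub("[[:space:]].*$", "", names(recs))
    seqs <- as.character(recs)
    bad <- which(!is_valid_dna(seqs))
    if (length(bad) > 0L) {
      stop(sprintf(
        "invalid character in sequence of record %s (only A/C/G/T allowed)",
        paste(sQuote(ids[bad]), collapse = ", ")), call. = FALSE)
    }
    return(feature_whitelist(ids, seqs))
  }
  lines <- readLines(path)
  if (header && length(lines) > 0L) lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("whitelist file is empty", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2L)) {
    stop(sprintf("TSV whitelist needs >= 2 tab-separated columns; line %d has %d",
                 which(nfield < 2L)[1L] + if (header) 1L else 0L,
                 min(nfield)), call. = FALSE)
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  seqs <- vapply(parts, `[[`, character(1), 2L)
  bad <- which(!is_valid_dna(seqs))
  if (length(bad) > 0L) {
    stop(sprintf("invalid character in barcode sequence at line %d: %s",
                 bad[1L] + if (header) 1L else 0L, sQuote(seqs[bad[1L]])),
         call. = FALSE)
  }
  feature_whitelist(ids, seqs)
}

#' Read a cell-barcode on-list
#'
#' Plain text, one cell barcode per line (the 10x-style "onlist" dialect).
#'
#' @param path file path (plain or gzipped).
#' @return character vector of barcodes.
#' @export
read_onlist <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("on-list file not found: %s", path), call. = FALSE)
  }
  x <- readLines(path)
  x <- x[nzchar(x)]
  if (length(x) == 0L) stop("on-list file is empty", call. = FALSE)
  stop_invalid_dna(x, what = "on-list barcode")
  if (anyDuplicated(x)) x <- unique(x)
  x
}

#' @export
print.fb_whitelist <- function(x, ...) {
  lens <- sort(unique(nchar(x$sequence)))
  cat(sprintf("Feature whitelist: %d barcodes, length%s %s%s\n",
              nrow(x), if (length(lens) > 1L) "s" else "",
              paste(lens, collapse = ", "),
              if (attr(x, "uniform_length")) " (uniform)" else ""))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

is_uniform_length <- function(whitelist) {
  isTRUE(attr(whitelist, "uniform_length"))
}

require_uniform <- function(whitelist) {
  if (!inherits(whitelist, "fb_whitelist")) {
    stop("expected an fb_whitelist (see feature_whitelist())", call. = FALSE)
  }
  if (!is_uniform_length(whitelist)) {
    stop("this operation requires all barcodes to have equal length",
         call. = FALSE)
  }
  invisible(whitelist)
}
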
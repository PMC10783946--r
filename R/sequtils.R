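#' Sequence utilities
#'
#' Small helpers shared across the package: Hamming distance, reverse
#' complement and DNA-alphabet validation. All sequences are plain uppercase
#' character strings over {A, C, G, T}; N and IUPAC ambiguity codes are
#' rejected everywhere a whitelist sequence is expected, because the
#' single-base mismatch expansion is defined over the 4-letter alphabet only.
#'
#' @name sequtils
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Test whether strings are valid DNA over {A,C,G,T}
#'
#' @param x character vector.
#' @return logical vector, TRUE where `x` is non-empty and contains only
#'   uppercase A/C/G/T.
#' @examples
#' is_valid_dna(c("ACGT", "acgt", "ACGN", ""))
#' @export
is_valid_dna <- function(x) {
  !is.na(x) & nzchar(x) & !grepl("[^ACGT]", x)
}

stop_invalid_dna <- function(x, what = "sequence") {
  bad <- which(!is_valid_dna(x))
  if (length(bad) > 0L) {
    stop(sprintf(
      "invalid %s (must be non-empty, uppercase A/C/G/T only): %s",
      what, paste(sQuote(x[bad[seq_len(min(5L, length(bad)))]]), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}

#' Hamming distance between two equal-length strings
#'
#' The number of positions at which two equal-length sequences differ. This
#' is the metric under which single-base mismatch error correction operates:
#' a barcode set with minimum pairwise Hamming distance d can unambiguously
#' correct floor((d-1)/2) substitutions.
#'
#' @param a,b character strings of equal length.
#' @return integer distance.
#' @examples
#' hamming("ACGT", "ACGA")  # 1
#' @export
hamming <- function(a, b) {
  if (length(a) != 1L || length(b) != 1L) {
    stop("hamming() expects single strings; see hamming_all() for vectors",
         call. = FALSE)
  }
  if (nchar(a) != nchar(b)) {
    stop(sprintf("hamming distance undefined for unequal lengths (%d vs %d)",
                 nchar(a), nchar(b)), call. = FALSE)
  }
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Hamming distance from one string to each element of a vector of
# equal-length strings. Internal workhorse for on-list correction, QC
# histograms and the brute-force test oracles.
hamming_all <- function(x, pool) {
  if (length(pool) == 0L) return(integer(0))
  n <- nchar(x)
  if (any(nchar(pool) != n)) {
    stop("hamming_all(): all sequences must share the query's length",
         call. = FALSE)
  }
  xi <- utf8ToInt(x)
  m <- matrix(utf8ToInt(paste(pool, collapse = "")), nrow = n)
  colSums(m != xi)
}

#' Reverse complement of a DNA sequence
#'
#' @param seq character vector of DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' revcomp("GATTACA")  # "TGTAATC"
#' @export
revcomp <- function(seq) {
  stop_invalid_dna(seq)
  comp <- chartr("ACGT", "TGCA", seq)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}
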
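#' Barcode-design quality control
#'
#' Clashing barcode designs — short barcodes, long shared subsequences,
#' small pairwise Hamming distances, long homopolymer runs, skewed
#' per-position nucleotide content — degrade error correction and can lose
#' or misassign reads. These metrics quantify each failure mode on a
#' whitelist before any sequencing is done.
#'
#' @name qc
NULL

#' Upper bounds on barcode-set size under a distance constraint
#'
#' How many length-L DNA barcodes can coexist with minimum pairwise
#' Hamming distance d? Two classical coding-theory bounds bracket the
#' answer:
#' \itemize{
#'   \item Singleton bound: `4^(L - d + 1)`;
#'   \item sphere-packing (Hamming) bound:
#'     `floor(4^L / sum_{i=0..t} choose(L, i) * 3^i)` with
#'     `t = floor((d - 1) / 2)`.
#' }
#' Both are computed in exact integer arithmetic (doubles are exact below
#' 2^53, so L is capped at 26).
#'
#' @param L barcode length in bases.
#' @param d required minimum pairwise Hamming distance, `1 <= d <= L`.
#' @param bound `"singleton"` or `"sphere_packing"`.
#' @return the bound as a numeric integer value.
#' @examples
#' diversity_bound(4, 3, "sphere_packing")  # floor(256 / 13) = 19
#' @export
diversity_bound <- function(L, d, bound = c("singleton", "sphere_packing")) {
  bound <- match.arg(bound)
  if (length(L) != 1L || length(d) != 1L || L < 1L || d < 1L || d > L) {
    stop("need 1 <= d <= L", call. = FALSE)
  }
  if (L > 26L) {
    stop("L > 26 would overflow exact integer arithmetic in doubles",
         call. = FALSE)
  }
  if (bound == "singleton") {
    return(4^(L - d + 1))
  }
  t <- floor((d - 1) / 2)
  sphere <- sum(choose(L, 0:t) * 3^(0:t))
  floor(4^L / sphere)
}

#' Group barcodes by shared length-k substrings
#'
#' Enumerates every contiguous length-k substring of every barcode and
#' reports the substrings shared by two or more distinct barcodes. A
#' barcode appearing in at least one shared group is "ambiguous" at that
#' k: reads covering the shared stretch cannot distinguish the barcodes.
#'
#' @param whitelist an `fb_whitelist`.
#' @param k substring length, `>= 1`.
#' @return list with `groups` (named list: substring -> character vector
#'   of feature ids, only groups of >= 2), `ambiguous_ids` (feature ids in
#'   any group) and `n_ambiguous`.
#' @export
shared_subsequence_groups <- function(whitelist, k) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  ids <- whitelist$feature_id
  seqs <- whitelist$sequence
  sub_id <- character(0)
  sub_seq <- character(0)
  for (i in seq_along(seqs)) {
    len <- nchar(seqs[i])
    if (len < k) next
    kmers <- unique(substring(seqs[i], 1:(len - k + 1L), k:len))
    sub_seq <- c(sub_seq, kmers)
    sub_id <- c(sub_id, rep(ids[i], length(kmers)))
  }
  if (length(sub_seq) == 0L) {
    return(list(groups = list(), ambiguous_ids = character(0),
                n_ambiguous = 0L))
  }
  groups <- split(sub_id, sub_seq)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  groups <- lapply(groups, sort)
  amb <- sort(unique(as.character(unlist(groups, use.names = FALSE))))
  list(groups = groups, ambiguous_ids = amb, n_ambiguous = length(amb))
}

#' Longest substring shared by two sequences
#'
#' The largest k at which two sequences have a common contiguous length-k
#' substring (0 if none, e.g. disjoint alphabets).
#'
#' @param a,b DNA strings.
#' @return integer length of the longest common substring.
#' @export
longest_shared_substring <- function(a, b) {
  for (k in min(nchar(a), nchar(b)):1) {
    ka <- unique(substring(a, 1:(nchar(a) - k + 1L), k:nchar(a)))
    kb <- unique(substring(b, 1:(nchar(b) - k + 1L), k:nchar(b)))
    if (any(ka %in% kb)) return(k)
  }
  0L
}

#' Pairwise Hamming-distance histograms
#'
#' Distances over all unordered pairs of equal-length barcodes, and the
#' same between each barcode and the reverse complement of every other
#' barcode. Unequal-length pairs are skipped and counted. Each barcode's
#' distance to its own reverse complement is reported separately.
#'
#' @param whitelist an `fb_whitelist` with >= 2 barcodes (fewer yields an
#'   empty histogram with a warning).
#' @return list with `histogram` (named integer: distance -> pair count),
#'   `min_distance`, `revcomp_histogram`, `revcomp_min_distance`,
#'   `self_revcomp_distance` (named by feature id) and `skipped_pairs`.
#' @export
hamming_histograms <- function(whitelist) {
  ids <- whitelist$feature_id
  seqs <- whitelist$sequence
  n <- length(seqs)
  if (n < 2L) {
    warning("fewer than 2 barcodes: pairwise histograms are empty",
            call. = FALSE)
    self_rc <- if (n == 1L)
      stats::setNames(hamming(seqs, revcomp(seqs)), ids) else
      stats::setNames(integer(0), character(0))
    return(list(histogram = integer(0), min_distance = NA_integer_,
                revcomp_histogram = integer(0),
                revcomp_min_distance = NA_integer_,
                self_revcomp_distance = self_rc, skipped_pairs = 0L))
  }
  rc <- revcomp(seqs)
  lens <- nchar(seqs)
  d <- integer(0); drc <- integer(0); skipped <- 0L
  for (i in seq_len(n - 1L)) {
    same <- which(lens[(i + 1L):n] == lens[i]) + i
    skipped <- skipped + (n - i) - length(same)
    if (length(same) > 0L) {
      d <- c(d, hamming_all(seqs[i], seqs[same]))
      drc <- c(drc, hamming_all(seqs[i], rc[same]))
    }
  }
  tab <- function(x) {
    if (length(x) == 0L) return(integer(0))
    t <- table(x)
    stats::setNames(as.integer(t), names(t))
  }
  list(histogram = tab(d),
       min_distance = if (length(d)) min(d) else NA_integer_,
       revcomp_histogram = tab(drc),
       revcomp_min_distance = if (length(drc)) min(drc) else NA_integer_,
       self_revcomp_distance = stats::setNames(
         vapply(seq_len(n), function(i) hamming(seqs[i], rc[i]), integer(1)),
         ids),
       skipped_pairs = skipped)
}

#' Homopolymer runs per barcode
#'
#' Maximal runs of a single repeated base of at least `min_len` bases. A
#' run of length 5 is reported once, as length 5 (maximality: never also
#' as its sub-runs).
#'
#' @param whitelist an `fb_whitelist`.
#' @param min_len minimum run length to report, `>= 2`.
#' @return list with `runs` (per feature id, a data frame of `base`,
#'   `length`) and `distribution` (named integer: run length -> total
#'   count across barcodes).
#' @export
homopolymer_runs <- function(whitelist, min_len = 2L) {
  if (min_len < 2L) stop("min_len must be >= 2", call. = FALSE)
  runs <- lapply(whitelist$sequence, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
    keep <- r$lengths >= min_len
    data.frame(base = r$values[keep], length = r$lengths[keep],
               stringsAsFactors = FALSE)
  })
  names(runs) <- whitelist$feature_id
  all_len <- unlist(lapply(runs, `[[`, "length"), use.names = FALSE)
  dist <- if (length(all_len) == 0L) integer(0) else {
    t <- table(all_len)
    stats::setNames(as.integer(t), names(t))
  }
  list(runs = runs, distribution = dist)
}

#' Per-position nucleotide content
#'
#' For each position p (0-based), the fraction of barcodes covering that
#' position (length > p) that carry each base there. Rows sum to 1.
#'
#' @param whitelist an `fb_whitelist`.
#' @return numeric matrix, positions x bases (A, C, G, T).
#' @export
position_content <- function(whitelist) {
  seqs <- whitelist$sequence
  maxlen <- max(nchar(seqs))
  out <- matrix(0, nrow = maxlen, ncol = 4L,
                dimnames = list(as.character(0:(maxlen - 1L)), DNA_BASES))
  for (p in seq_len(maxlen)) {
    covering <- seqs[nchar(seqs) >= p]
    b <- substr(covering, p, p)
    out[p, ] <- as.numeric(table(factor(b, levels = DNA_BASES))) /
      length(covering)
  }
  out
}

#' Full barcode-design QC report
#'
#' Bundles every metric into one JSON-serializable list and raises
#' warnings for the two design flaws that measurably lose reads: a
#' minimum pairwise Hamming distance of 2 or less (single-base variants
#' collide) and shared substrings of length L - 1 or longer (a read
#' covering the shared stretch is ambiguous).
#'
#' @param whitelist an `fb_whitelist`.
#' @param sub_len substring length for the shared-subsequence metric;
#'   default `max(L) - 1`.
#' @param homopolymer_min minimum homopolymer run length (default 3).
#' @return a list of class `fb_qc_report` with fields `n_barcodes`,
#'   `lengths`, `min_pairwise_hamming`, `hamming_histogram`,
#'   `revcomp_hamming_histogram`, `self_revcomp_distance`,
#'   `skipped_pairs`, `ambiguous_by_sublen`, `shared_groups`,
#'   `homopolymer_runs`, `homopolymer_distribution`, `position_content`,
#'   `diversity` and `warnings`.
#' @export
qc_report <- function(whitelist, sub_len = NULL, homopolymer_min = 3L) {
  L <- max(nchar(whitelist$sequence))
  if (is.null(sub_len)) sub_len <- max(1L, L - 1L)
  hh <- hamming_histograms(whitelist)
  hp <- homopolymer_runs(whitelist, min_len = homopolymer_min)

  # ambiguity profile across the whole range of substring lengths
  amb_profile <- vapply(seq_len(L), function(k) {
    shared_subsequence_groups(whitelist, k)$n_ambiguous
  }, integer(1))
  names(amb_profile) <- as.character(seq_len(L))
  shared <- shared_subsequence_groups(whitelist, sub_len)

  d <- hh$min_distance
  div <- if (!is.na(d) && d >= 1L && L <= 26L &&
             isTRUE(attr(whitelist, "uniform_length"))) {
    list(L = L, d = d,
         singleton = diversity_bound(L, d, "singleton"),
         sphere_packing = diversity_bound(L, d, "sphere_packing"))
  } else NULL

  warnings <- character(0)
  if (!is.na(d) && d <= 2L) {
    warnings <- c(warnings, sprintf(
      "minimum pairwise Hamming distance is %d (<= 2): single-base error correction will collide", d))
  }
  long_shared <- shared_subsequence_groups(whitelist, max(1L, L - 1L))
  if (long_shared$n_ambiguous > 0L) {
    warnings <- c(warnings, sprintf(
      "%d barcode(s) share a substring of length >= %d: %s",
      long_shared$n_ambiguous, max(1L, L - 1L),
      paste(long_shared$ambiguous_ids, collapse = ", ")))
  }

  pc <- position_content(whitelist)
  structure(
    list(n_barcodes = nrow(whitelist),
         lengths = sort(unique(nchar(whitelist$sequence))),
         min_pairwise_hamming = hh$min_distance,
         hamming_histogram = hh$histogram,
         revcomp_hamming_histogram = hh$revcomp_histogram,
         revcomp_min_distance = hh$revcomp_min_distance,
         self_revcomp_distance = hh$self_revcomp_distance,
         skipped_pairs = hh$skipped_pairs,
         sub_len = sub_len,
         ambiguous_by_sublen = amb_profile,
         shared_groups = shared$groups,
         shared_ambiguous_ids = shared$ambiguous_ids,
         homopolymer_min = homopolymer_min,
         homopolymer_runs = hp$runs,
         homopolymer_distribution = hp$distribution,
         position_content = pc,
         diversity = div,
         warnings = warnings),
    class = "fb_qc_report"
  )
}

#' @export
print.fb_qc_report <- function(x, ...) {
  cat(sprintf("Barcode QC: %d barcodes, length(s) %s\n", x$n_barcodes,
              paste(x$lengths, collapse = ", ")))
  cat(sprintf("  min pairwise Hamming distance: %s\n",
              x$min_pairwise_hamming))
  cat(sprintf("  barcodes sharing a %d-mer: %d\n", x$sub_len,
              length(x$shared_ambiguous_ids)))
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report an `fb_qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  out <- unclass(report)
  # named count vectors become JSON objects keyed by distance / run length
  for (f in c("hamming_histogram", "revcomp_hamming_histogram",
              "self_revcomp_distance", "ambiguous_by_sublen",
              "homopolymer_distribution")) {
    out[[f]] <- as.list(out[[f]])
  }
  out$homopolymer_runs <- lapply(out$homopolymer_runs, function(df) {
    list(base = df$base, length = df$length)
  })
  pc <- out$position_content
  out$position_content <- lapply(seq_len(nrow(pc)), function(i) {
    as.list(pc[i, ])
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
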
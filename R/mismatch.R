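#' Single-base mismatch maps
#'
#' The mismatch map expands every whitelist barcode into itself plus all
#' 3L single-base substitution variants, each labelled with its parent
#' feature. Looking a read window up in this map realizes 1-substitution
#' error correction: counts of a barcode's variants collapse onto the
#' parent. Collisions are pruned conservatively so that no sequence in the
#' map is claimed by more than one parent.
#'
#' @name mismatch
NULL

#' Enumerate all single-base substitution variants of a sequence
#'
#' Returns exactly 3L distinct sequences at Hamming distance 1 from the
#' input, in deterministic order: position-major (5' to 3'), then
#' alphabetical substitute base. The input itself is not included.
#'
#' @param sequence a DNA string.
#' @return character vector of length `3 * nchar(sequence)`, named
#'   `"{pos}.{base}"` with 0-based position and substitute base.
#' @examples
#' generate_mismatches("AA")
#' @export
generate_mismatches <- function(sequence) {
  if (length(sequence) != 1L) stop("one sequence at a time", call. = FALSE)
  stop_invalid_dna(sequence)
  L <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  out <- character(3L * L)
  labs <- character(3L * L)
  k <- 0L
  for (pos in seq_len(L)) {
    for (base in DNA_BASES[DNA_BASES != chars[pos]]) {
      k <- k + 1L
      v <- chars
      v[pos] <- base
      out[k] <- paste(v, collapse = "")
      labs[k] <- paste0(pos - 1L, ".", base)
    }
  }
  names(out) <- labs
  out
}

#' Build the mismatch map for a whitelist
#'
#' Expands each parent into its exact sequence plus all single-base
#' variants, then prunes collisions:
#' \itemize{
#'   \item an exact parent sequence always maps to its own parent (priority
#'     over any variant claim); a variant equal to another parent's exact
#'     sequence is removed from the generating parent's variant set and
#'     recorded in `cross_exact_hits`;
#'   \item a variant generated by two or more parents is removed entirely
#'     and recorded in `ambiguous_variants`.
#' }
#' A parent pair at Hamming distance <= 2 necessarily loses variants; a
#' warning is emitted when any such pair exists.
#'
#' @param whitelist an `fb_whitelist` with uniform barcode length.
#' @return an object of class `fb_mismatch_map` with fields:
#'   \describe{
#'     \item{seq}{character vector of all retained sequences (exact +
#'       variants), the lookup keys}
#'     \item{parent_id}{parallel vector of owning feature ids}
#'     \item{is_exact}{parallel logical, TRUE for exact parent sequences}
#'     \item{variant_label}{parallel `"{pos}.{base}"` labels, NA for exact}
#'     \item{ambiguous_variants}{variants removed because >= 2 parents
#'       generated them}
#'     \item{cross_exact_hits}{variants removed because they equal another
#'       parent's exact sequence}
#'     \item{retained_per_parent}{named integer, retained variants (not
#'       counting the exact sequence) per parent}
#'     \item{L}{barcode length; `n_parents`: number of parents}
#'   }
#' @examples
#' wl <- feature_whitelist(c("F1", "F2"), c("AAAA", "TTTT"))
#' mm <- build_mismatch_map(wl)
#' @export
build_mismatch_map <- function(whitelist) {
  require_uniform(whitelist)
  parents <- whitelist$feature_id
  pseqs <- whitelist$sequence
  L <- nchar(pseqs[1L])
  n <- length(parents)

  var_seq <- vector("list", n)
  for (i in seq_len(n)) var_seq[[i]] <- generate_mismatches(pseqs[i])
  all_var <- unlist(var_seq, use.names = FALSE)
  all_lab <- unlist(lapply(var_seq, names), use.names = FALSE)
  all_par <- rep(parents, each = 3L * L)

  # prune: variants hitting another parent's exact sequence
  cross <- all_var %in% pseqs
  # prune: variants generated by >= 2 distinct parents (a variant sequence
  # cannot be generated twice by the same parent)
  dup <- all_var %in% all_var[duplicated(all_var)]

  cross_exact_hits <- sort(unique(all_var[cross]))
  ambiguous_variants <- sort(unique(all_var[dup & !cross]))
  keep <- !cross & !dup

  seqs <- c(pseqs, all_var[keep])
  pids <- c(parents, all_par[keep])
  labs <- c(rep(NA_character_, n), all_lab[keep])
  exact <- c(rep(TRUE, n), rep(FALSE, sum(keep)))

  retained <- table(factor(all_par[keep], levels = parents))
  retained <- stats::setNames(as.integer(retained), parents)

  dmin <- if (n >= 2L) min_pairwise_hamming(pseqs) else Inf
  if (is.finite(dmin) && dmin <= 2L) {
    warning(sprintf(
      "minimum pairwise Hamming distance is %d (<= 2): some single-base variants collide and were removed; error correction will lose reads",
      dmin), call. = FALSE)
  }

  structure(
    list(seq = seqs, parent_id = pids, is_exact = exact,
         variant_label = labs,
         ambiguous_variants = ambiguous_variants,
         cross_exact_hits = cross_exact_hits,
         retained_per_parent = retained,
         L = L, n_parents = n,
         parent_order = parents, parent_seq = stats::setNames(pseqs, parents)),
    class = "fb_mismatch_map"
  )
}

# minimum pairwise Hamming distance among equal-length sequences
min_pairwise_hamming <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) return(Inf)
  dmin <- Inf
  for (i in seq_len(n - 1L)) {
    d <- hamming_all(seqs[i], seqs[(i + 1L):n])
    dmin <- min(dmin, min(d))
    if (dmin == 0L) break
  }
  dmin
}

#' @export
print.fb_mismatch_map <- function(x, ...) {
  cat(sprintf(
    "Mismatch map: %d parents (L = %d), %d entries (%d exact + %d variants)\n",
    x$n_parents, x$L, length(x$seq), sum(x$is_exact), sum(!x$is_exact)))
  if (length(x$ambiguous_variants) > 0L || length(x$cross_exact_hits) > 0L) {
    cat(sprintf("  removed: %d multi-parent variants, %d cross-exact hits\n",
                length(x$ambiguous_variants), length(x$cross_exact_hits)))
  }
  invisible(x)
}

# variant-sequence -> parent lookup; returns parent ids (NA where absent)
lookup_parents <- function(map, queries) {
  idx <- match(queries, map$seq)
  list(parent = map$parent_id[idx], exact = map$is_exact[idx], idx = idx)
}

#' Write a mismatch map as a mismatched FASTA file
#'
#' One record per retained map entry. Headers are `>{parent_id}` for exact
#' parent sequences and `>{parent_id}-{pos}.{base}` for the variant
#' substituting `{base}` at 0-based `{pos}`. Records are ordered by parent
#' (whitelist order), exact sequence first, then variants position-major /
#' alphabetical. Sequences are written on a single line.
#'
#' @param map an `fb_mismatch_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mismatch_fasta <- function(map, path) {
  if (!inherits(map, "fb_mismatch_map")) {
    stop("expected an fb_mismatch_map", call. = FALSE)
  }
  if (length(map$seq) == 0L) {
    stop("refusing to write an empty FASTA (mismatch map has no entries)",
         call. = FALSE)
  }
  ord <- order(match(map$parent_id, map$parent_order), !map$is_exact,
               seq_along(map$seq))
  hdr <- ifelse(map$is_exact[ord], map$parent_id[ord],
                paste0(map$parent_id[ord], "-", map$variant_label[ord]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", hdr, "\n", map$seq[ord]), con, sep = "\n")
  invisible(path)
}

#' Read a mismatched FASTA back into sequence/parent pairs
#'
#' Parses the header grammar of [write_mismatch_fasta()]. Used for
#' round-trip checks and for feeding externally generated mismatch FASTAs
#' into the scanner.
#'
#' @param path FASTA path.
#' @return data frame with columns `seq`, `parent_id`, `is_exact`,
#'   `variant_label`.
#' @export
read_mismatch_fasta <- function(path) {
  recs <- Biostrings::readDNAStringSet(path, format = "fasta")
  hdr <- sub("[[:space:]].*$", "", names(recs))
  m <- regmatches(hdr, regexec("^(.*)-([0-9]+\\.[ACGT])$", hdr))
  has_lab <- lengths(m) == 3L
  parent <- hdr
  parent[has_lab] <- vapply(m[has_lab], `[[`, character(1), 2L)
  lab <- rep(NA_character_, length(hdr))
  lab[has_lab] <- vapply(m[has_lab], `[[`, character(1), 3L)
  data.frame(seq = as.character(recs), parent_id = parent,
             is_exact = !has_lab, variant_label = lab,
             stringsAsFactors = FALSE)
}
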
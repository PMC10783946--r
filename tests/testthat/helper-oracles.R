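# Brute-force oracles, independent of the package internals. Everything
# here recomputes assignments from first principles (explicit Hamming
# distances over all windows / all sequences) so the fast-path code in the
# package can be checked against it.

BASES <- c("A", "C", "G", "T")

ham <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# all 4^L DNA strings of length L
all_seqs <- function(L) {
  g <- do.call(expand.grid,
               c(rep(list(BASES), L), list(stringsAsFactors = FALSE)))
  do.call(paste0, g)
}

rand_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n),
         function(i) paste(sample(BASES, len[i], replace = TRUE),
                           collapse = ""),
         character(1))
}

# a random whitelist of n distinct sequences of length L, optionally with a
# minimum pairwise Hamming distance enforced by rejection
rand_whitelist <- function(n, L, min_dist = 1L, max_tries = 10000L) {
  seqs <- character(0)
  for (i in seq_len(max_tries)) {
    cand <- rand_dna(1L, L)
    if (length(seqs) == 0L ||
        min(vapply(seqs, ham, integer(1), cand)) >= min_dist) {
      seqs <- c(seqs, cand)
      if (length(seqs) == n) break
    }
  }
  if (length(seqs) < n) stop("rand_whitelist: rejection failed")
  feature_whitelist(paste0("P", seq_len(n)), seqs)
}

# Membership rule, from first principles: a length-L sequence maps to parent
# i iff it IS parent i's exact sequence, or it is within Hamming distance 1
# of parent i and of no other parent (and is no parent's exact sequence).
# Returns parent index or NA.
oracle_assign <- function(s, pseqs) {
  exact <- which(pseqs == s)
  if (length(exact) >= 1L) return(exact[1L])
  d <- vapply(pseqs, ham, integer(1), s)
  w <- which(d <= 1L)
  if (length(w) == 1L) w else NA_integer_
}

# Vectorized oracle_assign over many query sequences
oracle_assign_all <- function(queries, pseqs) {
  L <- nchar(pseqs[1L])
  qm <- matrix(utf8ToInt(paste(queries, collapse = "")), nrow = L)
  dmat <- vapply(pseqs, function(p) colSums(qm != utf8ToInt(p)),
                 numeric(length(queries)))
  dmat <- matrix(dmat, nrow = length(queries))
  out <- rep(NA_integer_, length(queries))
  n_close <- rowSums(dmat <= 1L)
  uniq <- which(n_close == 1L)
  out[uniq] <- apply(dmat[uniq, , drop = FALSE] <= 1L, 1L, which)
  exact <- which(rowSums(dmat == 0L) >= 1L)
  out[exact] <- apply(dmat[exact, , drop = FALSE] == 0L, 1L, which)
  out
}

# Window-scan classification from first principles: every window of the
# read is assigned by oracle_assign; one distinct parent -> that parent,
# two or more -> "ambiguous", none -> "unassigned".
oracle_scan <- function(read, pseqs) {
  L <- nchar(pseqs[1L])
  n <- nchar(read)
  if (is.na(read) || n < L) return(list(status = "unassigned"))
  hits <- integer(0)
  for (j in 0:(n - L)) {
    w <- substr(read, j + 1L, j + L)
    if (grepl("[^ACGT]", w)) next
    a <- oracle_assign(w, pseqs)
    if (!is.na(a)) hits <- c(hits, a)
  }
  u <- unique(hits)
  if (length(u) == 0L) list(status = "unassigned")
  else if (length(u) > 1L) list(status = "ambiguous")
  else list(status = "assigned", parent = u)
}

# Greedy code construction: walk all length-L strings in lexicographic
# order, keep each that is at distance >= d from everything kept so far.
# Any bound on code size must dominate the size this achieves.
greedy_code_size <- function(L, d) {
  kept <- character(0)
  for (s in sort(all_seqs(L))) {
    if (length(kept) == 0L ||
        min(vapply(kept, ham, integer(1), s)) >= d) {
      kept <- c(kept, s)
    }
  }
  length(kept)
}

# Longest common substring by dynamic programming (independent of the
# package's substring-enumeration implementation)
lcs_length_dp <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  prev <- integer(length(cb))
  best <- 0L
  for (i in seq_along(ca)) {
    cur <- integer(length(cb))
    for (j in seq_along(cb)) {
      if (ca[i] == cb[j]) {
        cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

# Path to a bundled synthetic barcode set
extdata <- function(name) {
  system.file("extdata", name, package = "fbquant", mustWork = TRUE)
}
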
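#' Substitution-error simulation
#'
#' How many barcode reads survive error correction at a given per-base
#' substitution rate? Each simulated read draws a parent barcode
#' uniformly, mutates each base independently with probability p (uniform
#' over the three alternative bases) and looks the mutated sequence up in
#' the collision-pruned mismatch map (whole-sequence lookup). The read is
#' "correct" if it maps back to its parent, "misassigned" if it maps to a
#' different parent, and "lost" if it maps nowhere (the mutated sequence
#' is outside every retained distance-0/1 neighborhood, or fell on a
#' pruned ambiguous variant).
#'
#' For a single barcode of length L the closed form is
#' `P(correct) = (1 - p)^L + L * p * (1 - p)^(L - 1)` (zero or exactly one
#' substitution), which the simulation converges to.
#'
#' @name sim
NULL

mutate_seqs <- function(seqs, p) {
  # independent per-base substitution, uniform over the 3 other bases
  n <- length(seqs)
  if (n == 0L || p <= 0) return(seqs)
  L <- nchar(seqs[1L])
  m <- matrix(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]],
              nrow = L)
  hit <- which(matrix(stats::runif(n * L) < p, nrow = L))
  if (length(hit) > 0L) {
    # pick uniformly among the 3 bases differing from the current one
    cur <- m[hit]
    pick <- sample.int(3L, length(hit), replace = TRUE)
    alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                  nrow = 3L, dimnames = list(NULL, DNA_BASES))
    m[hit] <- alt[cbind(pick, match(cur, DNA_BASES))]
  }
  apply(m, 2L, paste, collapse = "")
}

#' Simulate barcode assignment under substitution errors
#'
#' @param whitelist an `fb_whitelist` with uniform length, or a prebuilt
#'   `fb_mismatch_map`.
#' @param p per-base substitution probability, in `[0, 1]`.
#' @param n_reads number of simulated reads.
#' @param seed integer seed; the result is deterministic given the seed.
#' @param weights optional per-parent sampling weights (default uniform).
#' @return an object of class `fb_sim_result`: a list with `error_rate`,
#'   `n_reads`, `seed`, `fraction_correct`, `fraction_lost` (unassigned +
#'   ambiguous), `fraction_misassigned`, and `per_parent` (a data frame
#'   with the same fractions per true parent).
#' @examples
#' wl <- feature_whitelist(c("F1", "F2"), c("ACGTACGT", "TTGGCCAA"))
#' simulate_assignment(wl, p = 0.01, n_reads = 1000, seed = 1)
#' @export
simulate_assignment <- function(whitelist, p, n_reads, seed = 1L,
                                weights = NULL) {
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single value in [0, 1]", call. = FALSE)
  }
  if (n_reads < 1L) stop("n_reads must be >= 1", call. = FALSE)
  map <- if (inherits(whitelist, "fb_mismatch_map")) whitelist
         else build_mismatch_map(whitelist)
  parents <- map$parent_order
  pseqs <- unname(map$parent_seq[parents])
  if (!is.null(weights) && length(weights) != length(parents)) {
    stop("weights must have one entry per parent", call. = FALSE)
  }

  set.seed(as.integer(seed))
  truth_idx <- sample.int(length(parents), n_reads, replace = TRUE,
                          prob = weights)
  reads <- mutate_seqs(pseqs[truth_idx], p)
  called <- lookup_parents(map, reads)$parent

  correct <- !is.na(called) & called == parents[truth_idx]
  misassigned <- !is.na(called) & called != parents[truth_idx]
  lost <- is.na(called)

  per_parent <- do.call(rbind, lapply(seq_along(parents), function(i) {
    sel <- truth_idx == i
    nn <- sum(sel)
    data.frame(
      parent_id = parents[i], n_reads = nn,
      fraction_correct = if (nn) sum(correct[sel]) / nn else NA_real_,
      fraction_lost = if (nn) sum(lost[sel]) / nn else NA_real_,
      fraction_misassigned = if (nn) sum(misassigned[sel]) / nn else NA_real_,
      stringsAsFactors = FALSE)
  }))

  structure(
    list(error_rate = p, n_reads = as.integer(n_reads),
         seed = as.integer(seed),
         fraction_correct = sum(correct) / n_reads,
         fraction_lost = sum(lost) / n_reads,
         fraction_misassigned = sum(misassigned) / n_reads,
         per_parent = per_parent),
    class = "fb_sim_result"
  )
}

#' @export
print.fb_sim_result <- function(x, ...) {
  cat(sprintf(
    "Error simulation: p = %g, n = %d | correct %.4f, lost %.4f, misassigned %.4f\n",
    x$error_rate, x$n_reads, x$fraction_correct, x$fraction_lost,
    x$fraction_misassigned))
  invisible(x)
}

#' Sweep simulation over several error rates
#'
#' One [simulate_assignment()] run per rate; the seed for rate index i is
#' `seed + i - 1`, so sweeps are reproducible and each rate independent.
#'
#' @param whitelist an `fb_whitelist` or `fb_mismatch_map`.
#' @param p_values non-empty numeric vector of error rates.
#' @param n_reads reads per rate.
#' @param seed master seed.
#' @return list of `fb_sim_result`, one per rate, plus a `summary`
#'   attribute: a data frame of rate vs the three fractions.
#' @export
sweep_error_rates <- function(whitelist, p_values, n_reads, seed = 1L) {
  if (length(p_values) == 0L) stop("p_values is empty", call. = FALSE)
  map <- if (inherits(whitelist, "fb_mismatch_map")) whitelist
         else build_mismatch_map(whitelist)
  out <- lapply(seq_along(p_values), function(i) {
    simulate_assignment(map, p_values[i], n_reads,
                        seed = as.integer(seed) + i - 1L)
  })
  attr(out, "summary") <- data.frame(
    error_rate = p_values,
    fraction_correct = vapply(out, `[[`, numeric(1), "fraction_correct"),
    fraction_lost = vapply(out, `[[`, numeric(1), "fraction_lost"),
    fraction_misassigned = vapply(out, `[[`, numeric(1),
                                  "fraction_misassigned"))
  out
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = len)
  apply(m, 2L, paste, collapse = "")
}

#' Specify a synthetic paired-FASTQ fixture
#'
#' Describes a synthetic experiment: fixed-layout R1 (cell barcode then
#' UMI, optionally padded), R2 carrying the tag at a fixed or uniformly
#' random offset inside random filler sequence, substitution errors at a
#' per-base rate inside the tag region, and PCR duplicates (each molecule
#' emitted `pcr_copies` times with the same cell/UMI/tag).
#'
#' @param whitelist an `fb_whitelist` with uniform length.
#' @param n_cells number of distinct cells; cell barcodes are drawn at
#'   random with pairwise Hamming distance >= 2 enforced by rejection.
#' @param cb_len,umi_len cell-barcode and UMI lengths in bases.
#' @param reads_per_pair reads generated for every (cell, feature) pair.
#' @param r2_len total R2 length; filler is random sequence.
#' @param tag_offset `"uniform"` for a uniformly random admissible offset
#'   per read, or a single fixed 0-based offset.
#' @param error_rate per-base substitution rate applied to the tag region.
#' @param pcr_copies copies of each read pair (PCR duplication).
#' @param seed integer seed.
#' @return a list of class `fb_fixture_spec`.
#' @export
fixture_spec <- function(whitelist, n_cells = 2L, cb_len = 16L,
                         umi_len = 10L, reads_per_pair = 5L,
                         r2_len = NULL, tag_offset = "uniform",
                         error_rate = 0, pcr_copies = 1L, seed = 1L) {
  require_uniform(whitelist)
  L <- nchar(whitelist$sequence[1L])
  if (is.null(r2_len)) r2_len <- L + 10L
  if (r2_len < L) stop("r2_len must be >= tag length", call. = FALSE)
  if (!identical(tag_offset, "uniform")) {
    tag_offset <- as.integer(tag_offset)
    if (tag_offset < 0L || tag_offset + L > r2_len) {
      stop("fixed tag_offset does not fit in r2_len", call. = FALSE)
    }
  }
  if (error_rate < 0 || error_rate > 1) {
    stop("error_rate must be in [0, 1]", call. = FALSE)
  }
  if (n_cells < 1L || reads_per_pair < 1L || pcr_copies < 1L) {
    stop("counts must be positive", call. = FALSE)
  }
  structure(
    list(whitelist = whitelist, n_cells = as.integer(n_cells),
         cb_len = as.integer(cb_len), umi_len = as.integer(umi_len),
         reads_per_pair = as.integer(reads_per_pair),
         r2_len = as.integer(r2_len), tag_offset = tag_offset,
         error_rate = error_rate, pcr_copies = as.integer(pcr_copies),
         seed = as.integer(seed)),
    class = "fb_fixture_spec"
  )
}

write_fastq <- function(ids, seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

#' Generate a synthetic paired-FASTQ fixture
#'
#' Writes `R1.fastq.gz`, `R2.fastq.gz` and `truth.tsv` (read id, cell,
#' UMI, true feature, tag offset, number of injected substitutions) into
#' `out_dir`. Byte-identical output for identical spec + seed.
#'
#' @param spec an `fb_fixture_spec`.
#' @param out_dir output directory (created if needed).
#' @param gzip write gzipped FASTQ (default TRUE).
#' @return list with `r1`, `r2`, `truth` file paths, the `truth` data
#'   frame, the implied `layout` and the cell barcodes used.
#' @export
generate_fixture <- function(spec, out_dir, gzip = TRUE) {
  stopifnot(inherits(spec, "fb_fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  wl <- spec$whitelist
  L <- nchar(wl$sequence[1L])

  # cell barcodes: rejection sampling to pairwise Hamming distance >= 2
  cells <- character(0)
  attempts <- 0L
  while (length(cells) < spec$n_cells) {
    attempts <- attempts + 1L
    if (attempts > 1000L * spec$n_cells) {
      stop("could not draw cell barcodes at pairwise distance >= 2",
           call. = FALSE)
    }
    cand <- random_dna(1L, spec$cb_len)
    if (length(cells) == 0L || min(hamming_all(cand, cells)) >= 2L) {
      cells <- c(cells, cand)
    }
  }

  grid <- expand.grid(cell = cells, feature = seq_len(nrow(wl)),
                      rep = seq_len(spec$reads_per_pair),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_mol <- nrow(grid)
  umis <- random_dna(n_mol, spec$umi_len)
  tags <- wl$sequence[grid$feature]
  mutated <- mutate_seqs(tags, spec$error_rate)
  n_sub <- vapply(seq_len(n_mol),
                  function(i) hamming(tags[i], mutated[i]), integer(1))
  offs <- if (identical(spec$tag_offset, "uniform")) {
    sample.int(spec$r2_len - L + 1L, n_mol, replace = TRUE) - 1L
  } else rep(spec$tag_offset, n_mol)
  filler <- random_dna(n_mol, spec$r2_len)
  r2 <- paste0(substr(filler, 1L, offs),
               mutated,
               substr(filler, offs + L + 1L, spec$r2_len))
  r1 <- paste0(grid$cell, umis)

  # PCR duplicates: repeat whole molecules
  rep_idx <- rep(seq_len(n_mol), each = spec$pcr_copies)
  ids <- sprintf("read%06d", seq_along(rep_idx))
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  r1_path <- file.path(out_dir, paste0("R1", ext))
  r2_path <- file.path(out_dir, paste0("R2", ext))
  write_fastq(ids, r1[rep_idx], r1_path)
  write_fastq(ids, r2[rep_idx], r2_path)

  truth <- data.frame(read_id = ids,
                      cell = grid$cell[rep_idx],
                      umi = umis[rep_idx],
                      feature_id = wl$feature_id[grid$feature[rep_idx]],
                      tag_offset = offs[rep_idx],
                      n_substitutions = n_sub[rep_idx],
                      stringsAsFactors = FALSE)
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  layout <- read_layout(cb_span = c(0L, spec$cb_len),
                        umi_span = c(spec$cb_len, spec$cb_len + spec$umi_len))
  list(r1 = r1_path, r2 = r2_path, truth = truth_path,
       truth_table = truth, layout = layout, cells = cells)
}
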
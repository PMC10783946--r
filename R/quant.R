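#' Tag-read quantification
#'
#' The quantification pipeline turns paired FASTQ reads into a sparse
#' cells x features matrix of UMI counts. Per read pair: the cell barcode
#' and UMI are extracted from read 1 at fixed spans; the tag read is
#' (optionally) anchor- and fixed-trimmed; every length-L window of the
#' trimmed tag read is looked up in the mismatch map, so the tag is found
#' regardless of its offset and despite a single substitution error; the
#' cell barcode is corrected against an on-list; duplicate (cell, UMI,
#' feature) triples collapse to one molecule.
#'
#' All intervals are 0-based half-open.
#'
#' @name quant
NULL

#' Describe where cell barcode, UMI and tag live in a read pair
#'
#' @param cb_span integer length-2, 0-based half-open interval of the cell
#'   barcode in read 1.
#' @param umi_span integer length-2, 0-based half-open interval of the UMI
#'   in read 1; must not overlap `cb_span`.
#' @param tag_read which mate carries the tag (1 or 2; default 2).
#' @param trim5,trim3 fixed number of bases removed from the 5'/3' end of
#'   the tag read (after anchor trimming).
#' @param anchor optional DNA string; its first exact occurrence in the tag
#'   read is located and only the flank named by `anchor_keep` is kept.
#'   Reads without the anchor are discarded.
#' @param anchor_keep `"after"` or `"before"`: which flank of the anchor to
#'   keep.
#' @param scan_offset `NULL` to scan every window offset (the default), or
#'   a single 0-based offset to scan only the window starting there.
#' @param revcomp also scan the reverse complement of the tag read.
#' @return an object of class `fb_layout`.
#' @examples
#' read_layout(cb_span = c(0, 16), umi_span = c(16, 26))
#' @export
read_layout <- function(cb_span, umi_span, tag_read = 2L,
                        trim5 = 0L, trim3 = 0L,
                        anchor = NULL, anchor_keep = c("after", "before"),
                        scan_offset = NULL, revcomp = FALSE) {
  anchor_keep <- match.arg(anchor_keep)
  chk_span <- function(s, what) {
    if (length(s) != 2L || any(s < 0L) || s[2L] <= s[1L]) {
      stop(sprintf("%s must be a 0-based half-open interval [start, end) with end > start >= 0",
                   what), call. = FALSE)
    }
    as.integer(s)
  }
  cb_span <- chk_span(cb_span, "cb_span")
  umi_span <- chk_span(umi_span, "umi_span")
  if (max(cb_span[1L], umi_span[1L]) < min(cb_span[2L], umi_span[2L])) {
    stop("cb_span and umi_span overlap", call. = FALSE)
  }
  if (!tag_read %in% c(1L, 2L)) stop("tag_read must be 1 or 2", call. = FALSE)
  if (trim5 < 0L || trim3 < 0L) stop("trim5/trim3 must be >= 0", call. = FALSE)
  if (!is.null(anchor)) stop_invalid_dna(anchor, what = "anchor")
  if (!is.null(scan_offset) && (length(scan_offset) != 1L || scan_offset < 0L)) {
    stop("scan_offset must be a single 0-based offset", call. = FALSE)
  }
  structure(
    list(cb_span = cb_span, umi_span = umi_span, tag_read = as.integer(tag_read),
         trim5 = as.integer(trim5), trim3 = as.integer(trim3),
         anchor = anchor, anchor_keep = anchor_keep,
         scan_offset = if (is.null(scan_offset)) NULL else as.integer(scan_offset),
         revcomp = isTRUE(revcomp)),
    class = "fb_layout"
  )
}

#' Trim a tag read according to a layout
#'
#' Anchor trimming happens first: the first exact occurrence of the anchor
#' is located and the flank named by `anchor_keep` is kept; a read without
#' the anchor is discarded (`NA`). Fixed `trim5`/`trim3` bases are then
#' removed. A read left with no sequence is discarded.
#'
#' @param seq character vector of tag-read sequences.
#' @param layout an `fb_layout`.
#' @return character vector; `NA` marks discarded reads.
#' @export
trim_tag_read <- function(seq, layout) {
  out <- seq
  if (!is.null(layout$anchor)) {
    pos <- regexpr(layout$anchor, out, fixed = TRUE)
    found <- !is.na(pos) & pos > 0L
    alen <- nchar(layout$anchor)
    out[!found] <- NA_character_
    if (layout$anchor_keep == "after") {
      out[found] <- substr(out[found], pos[found] + alen, nchar(out[found]))
    } else {
      out[found] <- substr(out[found], 1L, pos[found] - 1L)
    }
  }
  ok <- !is.na(out)
  len <- nchar(out[ok])
  keep <- len > layout$trim5 + layout$trim3
  res <- rep(NA_character_, sum(ok))
  res[keep] <- substr(out[ok][keep], layout$trim5 + 1L,
                      len[keep] - layout$trim3)
  out[ok] <- res
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

#' Extract cell barcode and UMI from read 1
#'
#' Reads shorter than the spans require, and reads whose cell barcode
#' contains N, are discarded. UMIs may contain N (they still deduplicate
#' as literal strings).
#'
#' @param read1_seq character vector of read-1 sequences.
#' @param layout an `fb_layout`.
#' @return data frame with columns `cell`, `umi`; `NA` rows mark discards.
#' @export
extract_cell_umi <- function(read1_seq, layout) {
  need <- max(layout$cb_span[2L], layout$umi_span[2L])
  cell <- rep(NA_character_, length(read1_seq))
  umi <- rep(NA_character_, length(read1_seq))
  ok <- nchar(read1_seq) >= need
  cell[ok] <- substr(read1_seq[ok], layout$cb_span[1L] + 1L, layout$cb_span[2L])
  umi[ok] <- substr(read1_seq[ok], layout$umi_span[1L] + 1L, layout$umi_span[2L])
  bad_cell <- ok & grepl("N", cell, fixed = TRUE)
  cell[bad_cell] <- NA_character_
  umi[bad_cell] <- NA_character_
  data.frame(cell = cell, umi = umi, stringsAsFactors = FALSE)
}

#' Correct cell barcodes against an on-list
#'
#' An exact on-list member maps to itself; otherwise, if exactly one
#' on-list member lies at Hamming distance 1, the barcode is corrected to
#' that member; otherwise the barcode is discarded (`NA`). With a `NULL`
#' on-list the identity is applied.
#'
#' @param cell character vector of cell barcodes.
#' @param onlist character vector of valid barcodes, or `NULL`.
#' @return character vector of corrected barcodes, `NA` for discards.
#' @export
correct_cell_barcode <- function(cell, onlist = NULL) {
  if (is.null(onlist)) return(cell)
  if (length(onlist) == 0L) stop("on-list is empty", call. = FALSE)
  out <- ifelse(cell %in% onlist, cell, NA_character_)
  todo <- unique(cell[is.na(out) & !is.na(cell)])
  if (length(todo) > 0L) {
    fix <- vapply(todo, function(cb) {
      if (!is_valid_dna(cb) || nchar(cb) != nchar(onlist[1L])) {
        return(NA_character_)
      }
      hits <- onlist[match(generate_mismatches(cb), onlist, nomatch = 0L)]
      if (length(hits) == 1L) hits else NA_character_
    }, character(1))
    idx <- match(cell, todo)
    repl <- !is.na(idx)
    out[repl] <- fix[idx[repl]]
  }
  out
}

# reverse complement tolerant of N (reads, not whitelist sequences)
rc_lenient <- function(seq) {
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Scan a trimmed tag read against a mismatch map
#'
#' Every length-L window of the read (and of its reverse complement when
#' `revcomp`) is looked up in the map. Windows containing non-ACGT
#' characters never match. If the windows hit exactly one distinct parent,
#' the read is assigned to it; hits on two or more parents make the read
#' ambiguous; no hit leaves it unassigned. Within an assigned read the
#' reported window is the leftmost one, with exact-sequence windows
#' preferred over variant windows and forward strand preferred over
#' reverse; `n_mismatches` is 0 if any hit window equals the parent
#' sequence, else 1.
#'
#' @param trimmed_seq a single trimmed tag-read sequence.
#' @param map an `fb_mismatch_map`.
#' @param revcomp also scan the reverse complement.
#' @param offset `NULL` to scan all offsets, or a single 0-based offset.
#' @return a list with `status` (`"assigned"`, `"ambiguous"` or
#'   `"unassigned"`) and, when assigned, `parent_id`, `offset`,
#'   `n_mismatches` and `strand` (`"forward"`/`"reverse"`).
#' @examples
#' mm <- build_mismatch_map(feature_whitelist("F1", "ACGT"))
#' scan_read("TTACGTTT", mm)
#' @export
scan_read <- function(trimmed_seq, map, revcomp = FALSE, offset = NULL) {
  res <- scan_reads_bulk(trimmed_seq, map, revcomp = revcomp,
                         fixed_offset = offset)
  if (res$status[1L] != "assigned") return(list(status = res$status[1L]))
  list(status = "assigned", parent_id = res$parent_id[1L],
       offset = res$offset[1L], n_mismatches = res$n_mismatches[1L],
       strand = res$strand[1L])
}

# Vectorized window scan over many reads. Returns a data frame with one row
# per read: status, parent_id, offset, n_mismatches, strand.
scan_reads_bulk <- function(seqs, map, revcomp = FALSE, fixed_offset = NULL) {
  n <- length(seqs)
  status <- rep("unassigned", n)
  parent <- rep(NA_character_, n)
  offs <- rep(NA_integer_, n)
  nmm <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  L <- map$L
  live <- which(!is.na(seqs) & nchar(seqs) >= L)
  if (length(live) > 0L) {
    hit_read <- integer(0); hit_off <- integer(0)
    hit_par <- character(0); hit_ex <- logical(0); hit_rev <- logical(0)
    collect <- function(sq, idx, rev) {
      lens <- nchar(sq)
      for (len in unique(lens)) {
        grp <- which(lens == len)
        offsets <- if (is.null(fixed_offset)) 0:(len - L) else {
          if (fixed_offset + L > len) integer(0) else fixed_offset
        }
        for (j in offsets) {
          w <- substr(sq[grp], j + 1L, j + L)
          mi <- match(w, map$seq)
          got <- which(!is.na(mi))
          if (length(got) > 0L) {
            hit_read <<- c(hit_read, idx[grp[got]])
            hit_off <<- c(hit_off, rep(j, length(got)))
            hit_par <<- c(hit_par, map$parent_id[mi[got]])
            hit_ex <<- c(hit_ex, map$is_exact[mi[got]])
            hit_rev <<- c(hit_rev, rep(rev, length(got)))
          }
        }
      }
    }
    collect(seqs[live], live, FALSE)
    if (revcomp) collect(rc_lenient(seqs[live]), live, TRUE)
    if (length(hit_read) > 0L) {
      npar <- vapply(split(hit_par, hit_read),
                     function(p) length(unique(p)), integer(1))
      rid <- as.integer(names(npar))
      status[rid[npar >= 2L]] <- "ambiguous"
      amb <- rid[npar >= 2L]
      keep <- !(hit_read %in% amb)
      if (any(keep)) {
        # exact preferred, then forward strand, then leftmost window
        ord <- order(hit_read[keep], !hit_ex[keep], hit_rev[keep],
                     hit_off[keep])
        kr <- hit_read[keep][ord]
        first <- !duplicated(kr)
        sel <- which(keep)[ord][first]
        rsel <- hit_read[sel]
        status[rsel] <- "assigned"
        parent[rsel] <- hit_par[sel]
        offs[rsel] <- hit_off[sel]
        nmm[rsel] <- ifelse(hit_ex[sel], 0L, 1L)
        strand[rsel] <- ifelse(hit_rev[sel], "reverse", "forward")
      }
    }
  }
  data.frame(status = status, parent_id = parent, offset = offs,
             n_mismatches = nmm, strand = strand, stringsAsFactors = FALSE)
}

#' Collapse duplicate molecules
#'
#' Identical (cell, UMI, feature) triples collapse to one record. A
#' (cell, UMI) pair observed with two or more distinct features is dropped
#' entirely: such molecules cannot be attributed to a single feature.
#' Output order is deterministic (sorted by cell, UMI, feature).
#'
#' @param records data frame with columns `cell`, `umi`, `parent_id`.
#' @return deduplicated data frame.
#' @export
deduplicate <- function(records) {
  stopifnot(all(c("cell", "umi", "parent_id") %in% names(records)))
  if (nrow(records) == 0L) return(records[order(records$cell), , drop = FALSE])
  uniq <- unique(records[, c("cell", "umi", "parent_id")])
  key <- paste(uniq$cell, uniq$umi, sep = "\r")
  conflicted <- key %in% key[duplicated(key)]
  uniq <- uniq[!conflicted, , drop = FALSE]
  uniq <- uniq[order(uniq$cell, uniq$umi, uniq$parent_id), , drop = FALSE]
  rownames(uniq) <- NULL
  uniq
}

read_fastq_seqs <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Quantify a feature-barcode experiment
#'
#' Runs the full pipeline on paired FASTQ files: cell barcode / UMI
#' extraction, on-list correction, tag-read trimming, window scanning
#' against the mismatch map, UMI deduplication, and sparse matrix
#' assembly. Cell rows are sorted lexicographically; feature columns
#' follow whitelist order.
#'
#' @param fastq_r1,fastq_r2 paths to the paired FASTQ files (plain or
#'   gzipped); record order must be synchronized.
#' @param whitelist an `fb_whitelist` with uniform length, or a
#'   prebuilt `fb_mismatch_map`.
#' @param layout an `fb_layout`.
#' @param onlist optional character vector of valid cell barcodes (or a
#'   file path; see [read_onlist()]).
#' @return an object of class `fb_count_matrix`: a list with `counts`
#'   (sparse dgCMatrix, cells x features), `cells`, `features`, and
#'   `stats` — a named list of the run counters (`pairs_read`,
#'   `discarded_by_layout`, `discarded_by_onlist`, `unassigned`,
#'   `ambiguous`, `assigned`, `umis_after_dedup`).
#' @export
quantify <- function(fastq_r1, fastq_r2, whitelist, layout, onlist = NULL) {
  map <- if (inherits(whitelist, "fb_mismatch_map")) whitelist
         else build_mismatch_map(whitelist)
  if (map$n_parents == 0L) stop("empty whitelist", call. = FALSE)
  if (is.character(onlist) && length(onlist) == 1L && file.exists(onlist)) {
    onlist <- read_onlist(onlist)
  }
  r1 <- read_fastq_seqs(fastq_r1)
  r2 <- read_fastq_seqs(fastq_r2)
  if (length(r1) != length(r2)) {
    stop(sprintf("R1/R2 record counts differ: %s has %d, %s has %d",
                 fastq_r1, length(r1), fastq_r2, length(r2)), call. = FALSE)
  }
  n <- length(r1)
  tag_seq <- if (layout$tag_read == 2L) r2 else r1

  cu <- extract_cell_umi(r1, layout)
  trimmed <- trim_tag_read(tag_seq, layout)
  layout_ok <- !is.na(cu$cell) & !is.na(trimmed)
  discarded_layout <- sum(!layout_ok)

  corrected <- cu$cell
  if (!is.null(onlist)) {
    corrected[layout_ok] <- correct_cell_barcode(cu$cell[layout_ok], onlist)
  }
  onlist_ok <- layout_ok & !is.na(corrected)
  discarded_onlist <- sum(layout_ok & is.na(corrected))

  idx <- which(onlist_ok)
  scan <- scan_reads_bulk(trimmed[idx], map, revcomp = layout$revcomp,
                          fixed_offset = layout$scan_offset)
  n_unassigned <- sum(scan$status == "unassigned")
  n_ambiguous <- sum(scan$status == "ambiguous")
  assigned <- scan$status == "assigned"
  n_assigned <- sum(assigned)

  records <- data.frame(cell = corrected[idx][assigned],
                        umi = cu$umi[idx][assigned],
                        parent_id = scan$parent_id[assigned],
                        stringsAsFactors = FALSE)
  dedup <- deduplicate(records)

  features <- map$parent_order
  cells <- sort(unique(dedup$cell))
  counts <- Matrix::sparseMatrix(
    i = match(dedup$cell, cells),
    j = match(dedup$parent_id, features),
    x = rep(1L, nrow(dedup)),
    dims = c(length(cells), length(features)),
    dimnames = list(cells, features)
  )
  structure(
    list(counts = methods::as(counts, "CsparseMatrix"),
         cells = cells, features = features,
         stats = list(pairs_read = n,
                      discarded_by_layout = discarded_layout,
                      discarded_by_onlist = discarded_onlist,
                      unassigned = n_unassigned,
                      ambiguous = n_ambiguous,
                      assigned = n_assigned,
                      umis_after_dedup = nrow(dedup))),
    class = "fb_count_matrix"
  )
}

#' @export
print.fb_count_matrix <- function(x, ...) {
  s <- x$stats
  cat(sprintf("Count matrix: %d cells x %d features, %d UMIs\n",
              length(x$cells), length(x$features), sum(x$counts)))
  cat(sprintf("  pairs: %d | layout-discard: %d | onlist-discard: %d | unassigned: %d | ambiguous: %d | assigned: %d\n",
              s$pairs_read, s$discarded_by_layout, s$discarded_by_onlist,
              s$unassigned, s$ambiguous, s$assigned))
  invisible(x)
}

#' Write a count matrix to a MatrixMarket directory
#'
#' Writes `matrix.mtx` (coordinate integer, 1-based indices),
#' `barcodes.txt` (one cell per line, row order), `features.txt` (one
#' feature id per line, column order) and, when run statistics are
#' attached, `run_info.json`.
#'
#' @param matrix an `fb_count_matrix`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_matrix <- function(matrix, out_dir) {
  if (!inherits(matrix, "fb_count_matrix")) {
    stop("expected an fb_count_matrix", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(matrix$counts, "TsparseMatrix")
  ord <- order(m@j, m@i)
  lines <- c(
    "%%MatrixMarket matrix coordinate integer general",
    sprintf("%d %d %d", nrow(m), ncol(m), length(m@x)),
    sprintf("%d %d %d", m@i[ord] + 1L, m@j[ord] + 1L, as.integer(m@x[ord]))
  )
  writeLines(lines, file.path(out_dir, "matrix.mtx"))
  writeLines(matrix$cells, file.path(out_dir, "barcodes.txt"))
  writeLines(matrix$features, file.path(out_dir, "features.txt"))
  if (!is.null(matrix$stats)) {
    jsonlite::write_json(matrix$stats, file.path(out_dir, "run_info.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out_dir)
}

#' Read a count matrix written by [write_matrix()]
#'
#' @param out_dir directory containing `matrix.mtx`, `barcodes.txt`,
#'   `features.txt`.
#' @return an `fb_count_matrix` (without run statistics unless
#'   `run_info.json` is present).
#' @export
read_matrix <- function(out_dir) {
  m <- Matrix::readMM(file.path(out_dir, "matrix.mtx"))
  cells <- readLines(file.path(out_dir, "barcodes.txt"))
  feats <- readLines(file.path(out_dir, "features.txt"))
  counts <- methods::as(m, "CsparseMatrix")
  dimnames(counts) <- list(cells, feats)
  stats <- NULL
  info <- file.path(out_dir, "run_info.json")
  if (file.exists(info)) stats <- jsonlite::read_json(info)
  structure(list(counts = counts, cells = cells, features = feats,
                 stats = stats),
            class = "fb_count_matrix")
}
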
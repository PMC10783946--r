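layout44 <- read_layout(cb_span = c(0, 9), umi_span = c(9, 13),
                        trim5 = 4, trim3 = 4)

test_that("tag-read trimming applies anchor first, then fixed trims", {
  expect_equal(trim_tag_read("AAAACGTACGTTTT", layout44), "CGTACG")
  anch <- read_layout(cb_span = c(0, 9), umi_span = c(9, 13),
                      anchor = "TAGCAT", anchor_keep = "after")
  expect_equal(trim_tag_read("GGGGTAGCATACGT", anch), "ACGT")
  expect_true(is.na(trim_tag_read("GGGGTTTTTTACGT", anch)))  # anchor absent
  before <- read_layout(cb_span = c(0, 9), umi_span = c(9, 13),
                        anchor = "TAGCAT", anchor_keep = "before")
  expect_equal(trim_tag_read("GGGGTAGCATACGT", before), "GGGG")
  # trim5 + trim3 >= remaining length discards the read
  expect_true(is.na(trim_tag_read("AAACCTTT", layout44)))
})

test_that("scan_read classifies windows per the mismatch-map rules", {
  mm1 <- build_mismatch_map(feature_whitelist("F1", "ACGT"))
  hit <- scan_read("TTACGTTT", mm1)
  expect_equal(hit[c("status", "parent_id", "offset", "n_mismatches")],
               list(status = "assigned", parent_id = "F1", offset = 2L,
                    n_mismatches = 0L))
  hit1 <- scan_read("TTACCTTT", mm1)
  expect_equal(hit1$n_mismatches, 1L)
  expect_equal(hit1$offset, 2L)

  mm2 <- build_mismatch_map(feature_whitelist(c("F1", "F2"),
                                              c("AAAA", "TTTT")))
  expect_equal(scan_read("AAAATTTT", mm2)$status, "ambiguous")
  expect_equal(scan_read("GCG", mm2)$status, "unassigned")    # too short
  expect_equal(scan_read("GGCGCGCC", mm2)$status, "unassigned")
  # windows containing N never match, but clean windows of the read still do
  expect_equal(scan_read("NAAAAG", mm2)$parent_id, "F1")
  # exact window preferred over an earlier variant window of the same parent
  both <- scan_read("AAATAAAA", mm2)
  expect_equal(both$n_mismatches, 0L)
  expect_equal(both$offset, 4L)
})

test_that("reverse-complement scanning finds tags on the opposite strand", {
  mm <- build_mismatch_map(feature_whitelist("F1", "ACGTAAGG"))
  read <- paste0("GG", revcomp("ACGTAAGG"), "CC")
  expect_equal(scan_read(read, mm)$status, "unassigned")
  hit <- scan_read(read, mm, revcomp = TRUE)
  expect_equal(hit$parent_id, "F1")
  expect_equal(hit$strand, "reverse")
})

test_that("cell barcode and UMI extraction enforces span and N rules", {
  lay <- read_layout(cb_span = c(0, 9), umi_span = c(9, 13))
  got <- extract_cell_umi("AAACCCGGGTTTNNNN", lay)
  expect_equal(got$cell, "AAACCCGGG")
  expect_equal(got$umi, "TTTN")                    # UMI may contain N
  lay16 <- read_layout(cb_span = c(0, 16), umi_span = c(16, 20))
  expect_true(is.na(extract_cell_umi("ACGTACGT", lay16)$cell))  # too short
  expect_true(is.na(extract_cell_umi("AANACCGGGTTTAAAA", lay)$cell))
})

test_that("on-list correction rescues unique distance-1 barcodes only", {
  onlist <- c("AAAA", "CCCC", "GGGG")
  expect_equal(correct_cell_barcode("AAAA", onlist), "AAAA")
  expect_equal(correct_cell_barcode("AAAT", onlist), "AAAA")
  # distance 1 from two members -> discard
  onlist2 <- c("AAAA", "AACC")
  expect_true(is.na(correct_cell_barcode("AACA", onlist2)))
  expect_true(is.na(correct_cell_barcode("TTTT", onlist)))
  expect_equal(correct_cell_barcode("TTTT", NULL), "TTTT")
})

test_that("deduplication collapses triples and drops UMI conflicts", {
  rec <- data.frame(cell = c("c1", "c1", "c1", "c1"),
                    umi = c("u1", "u1", "u1", "u2"),
                    parent_id = c("F1", "F1", "F2", "F1"),
                    stringsAsFactors = FALSE)
  out <- deduplicate(rec)
  # (c1,u1) seen with F1 and F2 -> dropped entirely; (c1,u2,F1) kept
  expect_equal(nrow(out), 1L)
  expect_equal(out$umi, "u2")
  same <- data.frame(cell = "c1", umi = "u1", parent_id = "F1")
  expect_equal(nrow(deduplicate(rbind(same, same))), 1L)
})

test_that("quantify recovers the truth matrix on a clean fixture", {
  wl <- feature_whitelist(paste0("T", 1:2), c("ACGTACGT", "TTGGCCAA"))
  spec <- fixture_spec(wl, n_cells = 2L, reads_per_pair = 25L,
                       error_rate = 0, seed = 101L)
  fx <- generate_fixture(spec, withr::local_tempdir())
  q <- quantify(fx$r1, fx$r2, wl, fx$layout)
  expect_equal(q$stats$assigned, 100L)
  expect_equal(sum(q$counts), 100)               # no duplicate UMIs drawn
  truth <- fx$truth_table
  expect_setequal(q$cells, unique(truth$cell))
  for (cell in q$cells) {
    for (f in wl$feature_id) {
      expect_equal(
        q$counts[cell, f],
        length(unique(truth$umi[truth$cell == cell & truth$feature_id == f])))
    }
  }
})

test_that("PCR duplicates do not change the matrix (dedup idempotence)", {
  wl <- feature_whitelist(paste0("T", 1:2), c("ACGTACGT", "TTGGCCAA"))
  base <- fixture_spec(wl, n_cells = 2L, reads_per_pair = 10L,
                       error_rate = 0, seed = 33L)
  dup <- fixture_spec(wl, n_cells = 2L, reads_per_pair = 10L,
                      error_rate = 0, pcr_copies = 3L, seed = 33L)
  fx1 <- generate_fixture(base, withr::local_tempdir())
  q1 <- quantify(fx1$r1, fx1$r2, wl, fx1$layout)
  fx2 <- generate_fixture(dup, withr::local_tempdir())
  q2 <- quantify(fx2$r1, fx2$r2, wl, fx2$layout)
  expect_equal(q2$stats$pairs_read, 3L * q1$stats$pairs_read)
  expect_equal(as.matrix(q2$counts), as.matrix(q1$counts))
})

test_that("a tag with two substitutions is unassigned", {
  wl <- feature_whitelist("T1", "ACGTACGT")
  mm <- build_mismatch_map(wl)
  mutated <- "ACCTACGA"                            # distance 2 from the tag
  expect_equal(ham(mutated, "ACGTACGT"), 2L)
  expect_equal(scan_read(paste0("GG", mutated, "TT"), mm)$status,
               "unassigned")
})

test_that("read counts are conserved and read order does not matter", {
  wl <- feature_whitelist(paste0("T", 1:3),
                          c("ACGTACGT", "TTGGCCAA", "GAGAGATC"))
  spec <- fixture_spec(wl, n_cells = 3L, reads_per_pair = 7L,
                       error_rate = 0.05, seed = 55L)
  fx <- generate_fixture(spec, withr::local_tempdir())
  q <- quantify(fx$r1, fx$r2, wl, fx$layout)
  s <- q$stats
  expect_equal(s$assigned + s$unassigned + s$ambiguous +
                 s$discarded_by_layout + s$discarded_by_onlist,
               s$pairs_read)
  expect_lte(sum(q$counts), s$assigned)

  # shuffle the paired records and re-quantify
  shuffle_fastq <- function(path, perm, out) {
    lines <- readLines(path)
    recs <- matrix(lines, nrow = 4L)
    writeLines(as.vector(recs[, perm]), out)
  }
  set.seed(9)
  perm <- sample(s$pairs_read)
  tmp <- withr::local_tempdir()
  shuffle_fastq(fx$r1, perm, file.path(tmp, "R1.fastq"))
  shuffle_fastq(fx$r2, perm, file.path(tmp, "R2.fastq"))
  q2 <- quantify(file.path(tmp, "R1.fastq"), file.path(tmp, "R2.fastq"),
                 wl, fx$layout)
  expect_equal(as.matrix(q2$counts), as.matrix(q$counts))
  expect_equal(q2$stats, q$stats)
})

test_that("quantify validates its inputs", {
  wl <- feature_whitelist("T1", "ACGTACGT")
  spec <- fixture_spec(wl, n_cells = 1L, reads_per_pair = 3L, seed = 2L)
  fx <- generate_fixture(spec, tmp <- withr::local_tempdir())
  short <- file.path(tmp, "short.fastq")
  writeLines(c("@r1", "ACGTACGTACGTACGTACGTACGTAC", "+",
               strrep("I", 26)), short)
  expect_error(quantify(fx$r1, short, wl, fx$layout), "record counts differ")
})

test_that("MatrixMarket output matches the format and round-trips", {
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(1, 3),
                            dims = c(2, 2),
                            dimnames = list(c("c1", "c2"), c("F1", "F2")))
  cm <- structure(list(counts = methods::as(m, "CsparseMatrix"),
                       cells = c("c1", "c2"), features = c("F1", "F2"),
                       stats = NULL),
                  class = "fb_count_matrix")
  out <- withr::local_tempdir()
  write_matrix(cm, out)
  lines <- readLines(file.path(out, "matrix.mtx"))
  expect_equal(lines[1], "%%MatrixMarket matrix coordinate integer general")
  expect_equal(lines[2], "2 2 2")
  expect_setequal(lines[3:4], c("1 1 1", "2 2 3"))
  expect_equal(readLines(file.path(out, "barcodes.txt")), c("c1", "c2"))
  back <- read_matrix(out)
  expect_equal(as.matrix(back$counts), as.matrix(cm$counts))

  # empty matrix: still a valid MTX with zero entries
  e <- structure(list(counts = Matrix::sparseMatrix(i = integer(0),
                                                    j = integer(0),
                                                    x = numeric(0),
                                                    dims = c(0, 2)),
                      cells = character(0), features = c("F1", "F2"),
                      stats = NULL),
                 class = "fb_count_matrix")
  out2 <- withr::local_tempdir()
  write_matrix(e, out2)
  expect_equal(readLines(file.path(out2, "matrix.mtx"))[2], "0 2 0")
  expect_equal(dim(read_matrix(out2)$counts), c(0L, 2L))
})
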
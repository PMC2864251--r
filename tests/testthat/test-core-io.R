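test_that("aligned_reads enforces its invariants", {
  expect_error(aligned_reads("r1", "chr1", 100, 120, "+", "ACGT"),
               "indels unsupported")
  expect_error(aligned_reads("r1", "chr1", 100, 104, "+", "ACGT",
                             mismatches = list(data.frame(offset = 7,
                                                          ref = "A",
                                                          read = "G"))),
               "out of read bounds")
  expect_error(aligned_reads("r1", "chr1", 100, 104, "+", "ACGT",
                             mismatches = list(data.frame(offset = 1,
                                                          ref = "C",
                                                          read = "C"))),
               "ref == read")
  expect_error(aligned_reads("r1", "chr1", 100, 104, "*", "ACGT"),
               "strand")
})

test_that("5' end is start on plus and end-1 on minus strand", {
  r <- aligned_reads(c("p", "m"), "chr1", c(100, 100), c(122, 122),
                     c("+", "-"))
  expect_identical(five_prime(r), c(100L, 121L))
})

test_that("SAM writing and reading round-trips reads with mismatches", {
  mm_plus <- data.frame(offset = 8L, ref = "A", read = "G")
  mm_minus <- data.frame(offset = 3L, ref = "A", read = "G")
  r <- aligned_reads(
    read_id = c("r1", "r2", "r3"), chrom = "chr1",
    start = c(10L, 40L, 70L), end = c(32L, 62L, 92L),
    strand = c("+", "-", "+"),
    sequence = c("ACGTACGTGCGTACGTACGTAC", "TTGGACGTACGTACGTACGTAC",
                 "ACGTACGTACGTACGTACGTAC"),
    copies = c(1L, 5L, 1L),
    mismatches = list(mm_plus, mm_minus, NULL))
  path <- tempfile(fileext = ".sam")
  write_sam(r, path, chrom_lengths = c(chr1 = 1000L))
  back <- read_alignments(path, sample = NA_character_)
  back <- back[match(r$read_id, back$read_id), ]
  expect_identical(back$read_id, r$read_id)
  expect_identical(back$start, r$start)
  expect_identical(back$end, r$end)
  expect_identical(back$strand, r$strand)
  expect_identical(back$sequence, r$sequence)
  expect_identical(back$copies, r$copies)
  expect_identical(back$mismatches[[1]], mm_plus)
  expect_identical(back$mismatches[[2]], mm_minus)
  expect_identical(nrow(back$mismatches[[3]]), 0L)
})

test_that("MD tag decoding recovers the substitution offset and bases", {
  # 22M read starting at pos 101 with MD 8A13: reference has A at read
  # offset 8 where the read shows G
  sam <- c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000",
           paste("q1", 0, "chr1", 101, 255, "22M", "*", 0, 0,
                 "ACGTACGTGACGTACGTACGTA", "*", "NM:i:1", "MD:Z:8A13",
                 sep = "\t"),
           paste("q2", 0, "chr1", 201, 255, "22M", "*", 0, 0,
                 "ACGTACGTACGTACGTACGTAC", "*", "NM:i:0", "MD:Z:22",
                 sep = "\t"))
  path <- tempfile(fileext = ".sam")
  writeLines(sam, path)
  r <- read_alignments(path)
  r <- r[match(c("q1", "q2"), r$read_id), ]
  expect_identical(r$mismatches[[1]],
                   data.frame(offset = 8L, ref = "A", read = "G"))
  expect_identical(nrow(r$mismatches[[2]]), 0L)
  expect_identical(r$start[1], 100L)
})

test_that("indel-containing SAM records are rejected with a message", {
  sam <- c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000",
           paste("q1", 0, "chr1", 101, 255, "10M1I11M", "*", 0, 0,
                 "ACGTACGTACGTACGTACGTAC", "*", sep = "\t"),
           paste("q2", 0, "chr1", 201, 255, "22M", "*", 0, 0,
                 "ACGTACGTACGTACGTACGTAC", "*", sep = "\t"))
  path <- tempfile(fileext = ".sam")
  writeLines(sam, path)
  expect_message(r <- read_alignments(path), "1 read\\(s\\) with indel")
  expect_identical(r$read_id, "q2")
})

test_that("BED input converts coordinates and minus-strand 5' ends", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t122\tr1_x7\t0\t-",
               "chr1\t300\t322\tr2\t0\t+"), path)
  r <- read_alignments(path)
  expect_identical(r$start, c(100L, 300L))
  expect_identical(five_prime(r), c(121L, 300L))
  expect_identical(r$copies, c(7L, 1L))
  expect_identical(r$read_id, c("r1", "r2"))
})

test_that("GFF3 annotation reading converts coordinates and parents", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tmiRNA_primary_transcript\t101\t180\t.\t+\t.\tID=mir-x",
               "chr1\t.\tmiRNA\t111\t132\t.\t+\t.\tID=mir-x-5p;Parent=mir-x"),
             path)
  ann <- read_annotation(path)
  pre <- ann[ann$class == "pre_mirna", ]
  expect_identical(c(pre$start, pre$end), c(100L, 180L))
  arm <- ann[ann$class == "mirna_arm", ]
  expect_identical(arm$parent, "mir-x")
})

test_that("annotation invariants reject duplicates and orphans", {
  expect_error(
    annotation_set("chr1", c(0, 10), c(50, 40), "+",
                   c("pre_mirna", "pre_mirna"), c("a", "a")),
    "duplicate")
  expect_error(
    annotation_set("chr1", 0, 50, "+", "mirna_arm", "a-5p", parent = "ghost"),
    "unresolvable parent")
  expect_error(annotation_set("chr1", 10, 10, "+", "gene", "g"),
               "start < end")
})

test_that("annotation GFF3 write/read round-trips", {
  ann <- toy_annotation()
  path <- tempfile(fileext = ".gff3")
  write_annotation(ann, path)
  back <- read_annotation(path)
  back <- back[match(ann$name, back$name), ]
  rownames(back) <- NULL
  expect_equal(as.data.frame(back), as.data.frame(ann))
})

test_that("count matrix TSV round-trips raw and normalized states", {
  sim <- simulate_counts(11, n_mirnas = 20)
  path <- tempfile(fileext = ".tsv")
  write_count_matrix(sim$counts, path)
  back <- read_count_matrix(path)
  expect_equal(unclass(back), unclass(sim$counts), ignore_attr = TRUE)
  expect_identical(sample_info(back), sample_info(sim$counts))
  norm <- ocm_normalize(sim$counts)
  write_count_matrix(norm, path)
  nback <- read_count_matrix(path)
  expect_equal(unclass(nback), unclass(norm), ignore_attr = TRUE)
  expect_equal(ocm_values(nback), ocm_values(norm))
  expect_identical(attr(nback, "removed_rows"), attr(norm, "removed_rows"))
})
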
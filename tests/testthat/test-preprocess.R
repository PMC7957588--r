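adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("cleaning removes each filler class for exactly one reason and conserves counts", {
  inserts <- c(short = "ACGTACGTACGTACGTA",              # 17 nt
               polya = "AAAAAAAAAAAAAAAAAAAA",           # 20 nt poly-A
               ok = "ACGTTGCACTGATCGATCGAT",             # 21 nt clean
               long = strrep("ACGT", 8))                 # 32 nt
  reads <- paste0(inserts, adapter)
  quals <- strrep("I", nchar(reads))
  lowq <- "ACGTTGCACTGATCGATCGAT"
  reads <- c(reads, paste0(lowq, adapter), adapter)
  q5 <- strrep("I", nchar(reads[5])); substr(q5, 3, 3) <- "#"
  quals <- c(quals, q5, strrep("I", nchar(adapter)))

  cl <- clean_reads(reads = reads, qualities = quals, adapter = adapter)
  expect_identical(cl$reads, unname(inserts["ok"]))
  expect_identical(unname(cl$stats$discarded[c("too_short", "poly_a",
                                               "too_long", "low_quality",
                                               "adapter_only")]),
                   rep(1L, 5))
  expect_identical(cl$stats$raw_reads,
                   cl$stats$clean_reads + sum(cl$stats$discarded))
})

test_that("cleaning is idempotent on already-clean reads", {
  set.seed(5)
  reads <- paste0(vapply(1:50, function(i) random_seq(21), ""), adapter)
  cl <- clean_reads(reads = reads, adapter = adapter)
  cl2 <- clean_reads(reads = cl$reads, adapter = adapter)
  expect_identical(cl2$reads, cl$reads)
  expect_identical(sum(cl2$stats$discarded), 0L)
})

test_that("collapsing sums per-library counts over exact sequences", {
  tags <- collapse_tags(list(A = c("ACGTACGTACGTACGTAA", "ACGTACGTACGTACGTAA",
                                   "ACGTACGTACGTACGTAA"),
                             B = c("ACGTACGTACGTACGTAA", "TTTTGGGGCCCCAAAATT")))
  expect_identical(nrow(tags), 2L)
  shared <- tags[tags$sequence == "ACGTACGTACGTACGTAA", ]
  expect_identical(c(shared$A, shared$B), c(3L, 1L))
  expect_identical(sum(tags$A), 3L)
  empty <- collapse_tags(list(A = character(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("annotation follows the fixed priority order and is a partition", {
  genome <- c(chr1 = paste0(random_seq(100), "ACGGACTGATTGCACGGCTAAT",
                            random_seq(100)))
  tag_in_sno_and_repeat <- substr(genome[["chr1"]], 101, 122)
  tags <- collapse_tags(list(
    L1 = c(tag_in_sno_and_repeat, "TTACGGCATGCATTACGGCAT", random_seq(21))))
  hits <- map_tags(tags$sequence, genome)
  refs <- list(rRNA = character(0), scRNA = character(0),
               snoRNA = paste0("GGG", tag_in_sno_and_repeat, "CCC"),
               snRNA = character(0),
               tRNA = paste0("AA", "TTACGGCATGCATTACGGCAT", "GG"),
               repeats = data.frame(chrom = "chr1", start = 90, end = 140))
  ann <- annotate_tags(tags, refs, hits)
  expect_identical(ann$annotation[ann$sequence == tag_in_sno_and_repeat],
                   "snoRNA") # snoRNA outranks repeat
  expect_identical(ann$annotation[ann$sequence == "TTACGGCATGCATTACGGCAT"],
                   "tRNA")
  expect_true(all(table(ann$annotation) >= 0))
  expect_false(anyNA(ann$annotation))
  expect_error(annotate_tags(tags, refs[-3], hits), "snoRNA")
})

test_that("tags map to both strands with all hits recorded", {
  core <- "ACGGACTGATTGCACGGCTAAT"
  genome <- c(chr1 = paste0(random_seq(50), core, random_seq(30), core,
                            random_seq(40)))
  tags <- c(core, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(core))), random_seq(22))
  hits <- map_tags(tags, genome)
  expect_identical(sum(hits$tag == 1 & hits$strand == "+"), 2L)
  expect_identical(sum(hits$tag == 2 & hits$strand == "-"), 2L)
  expect_identical(sum(hits$tag == 3), 0L)
  expect_identical(hits$start[hits$tag == 1],
                   hits$start[hits$tag == 2]) # same loci, opposite strand
})

test_that("length statistics reproduce designed 24/21-nt ratios", {
  mk <- function(n21, n24) {
    tags <- collapse_tags(list(L = c(rep("ACGTACGTACGTACGTACGTA", n21),
                                     rep("ACGTACGTACGTACGTACGTACGT", n24))))
    length_stats(tags)
  }
  expect_equal(mk(100, 59)$ratio_24_21, 0.59)
  expect_equal(mk(100, 99)$ratio_24_21, 0.99)
  expect_equal(mk(10, 10)$ratio_24_21, 1.0)
  onlyl24 <- mk(0, 5)
  expect_true(is.na(onlyl24$ratio_24_21)) # undefined, not an error
})
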
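test_that("excision emits strand-aware windows containing the tag", {
  genome <- c(chr1 = paste(rep("ACGT", 250), collapse = ""))
  w <- excise_precursor(genome, "chr1", 500, 520, "+")
  expect_identical(nrow(w), 3L)
  expect_true(all(substr(w$sequence, w$tag_start, w$tag_end) ==
                    substr(genome[["chr1"]], 500, 520)))
  expect_true(all(nchar(w$sequence) >= 60 & nchar(w$sequence) <= 400))

  # near the contig edge, windows are clipped but still emitted if >= 60 nt
  we <- excise_precursor(genome, "chr1", 10, 30, "+")
  expect_true(nrow(we) >= 1)
  expect_true(all(w$start >= 1))

  # minus-strand windows are reverse-complemented
  wm <- excise_precursor(genome, "chr1", 500, 520, "-")
  tag_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(genome[["chr1"]], 500, 520))))
  expect_true(all(substr(wm$sequence, wm$tag_start, wm$tag_end) == tag_rc))
})

test_that("a clean 19-pair duplex with 2-nt overhangs passes every criterion", {
  hp <- flat_hairpin()
  ev <- evaluate_hairpin(hp$sequence, hp$reads, structure = hp$structure,
                         mfe = -45)
  expect_true(ev$pass)
  expect_identical(ev$matched_pairs, 19L)
  expect_identical(c(ev$overhang_5p, ev$overhang_3p), c(2L, 2L))
  expect_identical(length(ev$bulges), 0L)
  # stated arithmetic: length 100, MFE -45, GC 0.5
  expect_equal(ev$mfe_per_nt, -0.45)
  expect_equal(ev$mfei, 0.90)
  expect_true(ev$verdicts[["mfe"]] && ev$verdicts[["mfei"]])
})

test_that("MFEI strictly decreases with GC at fixed structure and energy", {
  hp <- flat_hairpin()
  gc_levels <- c(0.3, 0.4, 0.5, 0.6, 0.7)
  mfei <- vapply(gc_levels, function(gc) {
    seqn <- paste(c(rep("G", round(100 * gc)), rep("A", 100 - round(100 * gc))),
                  collapse = "")
    evaluate_hairpin(seqn, hp$reads, structure = hp$structure,
                     mfe = -45)$mfei
  }, 0)
  expect_true(all(diff(mfei) < 0))
})

test_that("a 3-nt overhang at one duplex end fails criterion 2 only", {
  hp <- flat_hairpin()
  reads <- hp$reads
  reads$start[2] <- reads$start[2] + 1L # 3p read shifted: overhang becomes 3
  reads$end[2] <- reads$end[2] + 1L
  ev <- evaluate_hairpin(hp$sequence, reads, structure = hp$structure,
                         mfe = -45)
  expect_false(ev$verdicts[["c2"]])
  expect_identical(ev$overhang_3p, 3L)
  expect_true(all(ev$verdicts[c("c1", "c3", "c4", "c5")]))
})

test_that("reads outside the precursor raise an error", {
  hp <- flat_hairpin()
  bad <- hp$reads
  bad$end[2] <- 150L
  expect_error(evaluate_hairpin(hp$sequence, bad, structure = hp$structure,
                                mfe = -45), "outside")
})

test_that("each designed violation flips exactly its criterion", {
  set.seed(71)
  compliant <- c(c1 = TRUE, c2 = TRUE, c3 = TRUE, c4 = TRUE, c5 = TRUE,
                 mfe = TRUE, mfei = TRUE)
  flips <- list(`1` = "c1", `2` = "c2", `3` = "c3", `4` = "c4",
                `5` = c("c5", "mfe", "mfei"), mfe = c("c5", "mfe"),
                mfei = c("c5", "mfei"))
  for (viol in names(flips)) {
    ok <- FALSE
    for (try in 1:25) {
      d <- heatmiR:::design_hairpin(viol)
      sc <- d$scaffold
      reads <- data.frame(start = c(sc$read5[1], sc$read3[1]),
                          end = c(sc$read5[2], sc$read3[2]),
                          max_count = d$counts)
      ev <- evaluate_hairpin(sc$precursor, reads)
      expected <- compliant
      expected[flips[[viol]]] <- FALSE
      if (is.na(ev$reason) && identical(ev$verdicts, expected)) {
        ok <- TRUE
        break
      }
    }
    expect_true(ok, label = paste("violation class", viol, "realized"))
    expect_false(ev$pass)
  }
})

test_that("a duplex with exactly 16 matched pairs fails strict criterion 1", {
  set.seed(72)
  for (try in 1:50) {
    d <- heatmiR:::design_hairpin("1")
    sc <- d$scaffold
    reads <- data.frame(start = c(sc$read5[1], sc$read3[1]),
                        end = c(sc$read5[2], sc$read3[2]),
                        max_count = d$counts)
    ev <- evaluate_hairpin(sc$precursor, reads)
    if (is.na(ev$reason) && ev$matched_pairs == 16L) break
  }
  expect_identical(ev$matched_pairs, 16L)
  expect_false(ev$verdicts[["c1"]]) # "exceeding 16" is strict
})

test_that("two 1-nt asymmetric bulges fail criterion 3", {
  set.seed(73)
  for (try in 1:50) {
    d <- heatmiR:::design_hairpin("3")
    sc <- d$scaffold
    reads <- data.frame(start = c(sc$read5[1], sc$read3[1]),
                        end = c(sc$read5[2], sc$read3[2]),
                        max_count = d$counts)
    ev <- evaluate_hairpin(sc$precursor, reads)
    if (is.na(ev$reason) && length(ev$bulges) == 2L) break
  }
  expect_true(all(ev$bulges == 1L))
  expect_false(ev$verdicts[["c3"]])
})

test_that("stem-loop trimming recovers the planted hairpin from a padded window", {
  set.seed(74)
  d <- heatmiR:::design_hairpin("none")
  sc <- d$scaffold
  window <- paste0(strrep("A", 50), sc$precursor, strrep("A", 50))
  f <- fold_rna(window)
  tr <- trim_to_stemloop(f$structure, 50 + sc$read5[1], 50 + sc$read5[2])
  expect_false(is.null(tr))
  expect_gte(tr[1], 40)
  expect_lte(tr[2], nchar(window) - 40)
  # the trimmed region still contains both arm reads
  expect_lte(tr[1], 50 + sc$read5[1])
  expect_gte(tr[2], 50 + sc$read3[2])
})
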
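test_that("genome generation is seed-deterministic and truth-closed", {
  g1 <- generate_genome(n_compliant_hairpins = 1L, decoy_criteria = "4",
                        n_new_members = 0L, n_known = 2L,
                        genome_length = 8000L, seed = 61L)
  g2 <- generate_genome(n_compliant_hairpins = 1L, decoy_criteria = "4",
                        n_new_members = 0L, n_known = 2L,
                        genome_length = 8000L, seed = 61L)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth$planted_hairpins, g2$truth$planted_hairpins)

  # every planted feature is reachable from the generated sequence
  hp <- g1$truth$planted_hairpins
  for (i in seq_len(nrow(hp))) {
    expect_identical(substr(g1$genome[[hp$chrom[i]]], hp$start[i], hp$end[i]),
                     hp$precursor[i])
    expect_true(grepl(hp$mature_5p[i], hp$precursor[i], fixed = TRUE))
  }
  for (s in g1$truth$planted_mirnas$sequence[
         g1$truth$planted_mirnas$class == "known"]) {
    expect_true(grepl(s, g1$genome[["chr1"]], fixed = TRUE))
  }
  expect_identical(table(hp$violated)[["4"]], 1L)
})

test_that("an impossible placement fails with an explicit error", {
  expect_error(generate_genome(n_compliant_hairpins = 5L,
                               genome_length = 3000L, seed = 1L),
               "too small")
})

test_that("the expression design realizes all nine types with designed counts", {
  g <- generate_genome(n_compliant_hairpins = 1L, decoy_criteria = character(0),
                       n_new_members = 0L, n_known = 9L,
                       genome_length = 10000L, seed = 62L)
  truth <- design_expression(g$truth)
  d <- truth$expression_design
  known <- d[grepl("^gma-", d$id), ]
  expect_setequal(known$pattern_type,
                  c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX"))
  t2 <- known[known$pattern_type == "II", ]
  expect_identical(t2$NF1NT, 0L)  # expressed only under HT (on/off)
  expect_gt(t2$NF1HT, 0L)
  expect_true(t2$on_off)
  t9 <- known[known$pattern_type == "IX", ]
  expect_true(all(t9[, c("NF1NT", "NF1HT", "YF1NT", "YF1HT")] == 200L))
})

test_that("library generation is deterministic and echoes the design", {
  g <- generate_genome(n_compliant_hairpins = 0L, decoy_criteria = character(0),
                       n_new_members = 0L, n_known = 1L,
                       genome_length = 6000L, seed = 63L)
  truth <- design_expression(g$truth)
  t1 <- generate_libraries(truth, g$genome, depth_per_library = 3000L,
                           noise_rate = 0, seed = 9L)
  t2 <- generate_libraries(truth, g$genome, depth_per_library = 3000L,
                           noise_rate = 0, seed = 9L)
  expect_identical(t1$libraries_reads, t2$libraries_reads)
  # single designed miRNA: every read starting with it is identical, and the
  # multinomial with one category returns the designed total exactly
  mature <- truth$expression_design$sequence[1L]
  for (lib in truth$libraries$library) {
    reads <- t1$libraries_reads[[lib]]$sequences
    n_mir <- sum(startsWith(reads, mature))
    expect_identical(n_mir, truth$expression_design[[lib]][1L])
    expect_identical(length(reads), 3000L)
  }
})

test_that("depth warnings flag designs that cannot reach significance", {
  g <- generate_genome(n_compliant_hairpins = 0L, decoy_criteria = character(0),
                       n_new_members = 0L, n_known = 2L,
                       genome_length = 6000L, seed = 64L)
  truth <- design_expression(g$truth)
  libs <- truth$libraries$library
  truth$expression_design[, libs] <-
    truth$expression_design[, libs] %/% 100L # tiny counts: p cannot reach 0.05
  warned <- generate_libraries(truth, g$genome, depth_per_library = 3000L,
                               seed = 9L)
  expect_gt(length(warned$warnings), 0L)
})

test_that("transcripts embed planted sites at their recorded windows", {
  g <- generate_genome(n_compliant_hairpins = 1L, decoy_criteria = character(0),
                       n_new_members = 0L, n_known = 9L,
                       genome_length = 10000L, seed = 65L)
  truth <- design_expression(g$truth)
  truth <- generate_transcripts_and_degs(truth, n_transcripts = 15L,
                                         seed = 66L)
  sites <- truth$planted_target_sites
  d <- truth$expression_design
  for (i in which(sites$kind == "edge")) {
    m <- d$sequence[d$id == sites$mirna_id[i]]
    window <- substr(truth$transcripts[[sites$transcript_id[i]]],
                     sites$start[i], sites$start[i] + nchar(m) - 1L)
    expect_identical(window, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(m))))
  }
  # DEG design rows echo into the table, including anti-correlated partners
  expect_true(all(truth$expected_edges$gene_id %in% truth$deg_design$gene_id))
  lfc <- truth$deg_design$log2fc[match(truth$expected_edges$gene_id,
                                       truth$deg_design$gene_id)]
  expect_true(all(abs(lfc) > log2(1.5)))
  # every rule has a decoy site violating it
  viol <- sites[grepl("^violates_", sites$kind), ]
  expect_setequal(viol$kind, paste0("violates_r", 1:6))
  for (i in seq_len(nrow(viol))) {
    rule <- sub("violates_", "", viol$kind[i])
    expect_false(viol[[rule]][i])
  }
})
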
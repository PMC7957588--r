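mk_tags <- function(seqs, counts = rep(10L, length(seqs))) {
  tags <- collapse_tags(list(L1 = rep(seqs, counts)))
  tags
}

test_that("known matching tolerates terminal shifts but not internal mismatches", {
  mature <- "TGGAAGCTGTGAAGCTGACCT"
  catalog <- data.frame(id = c("gma-miR001", "gma-miR002"),
                        family = c("miR001", "miR002"),
                        species = "Glycine max",
                        sequence = c(mature, "ACCCGTTTACGGGACTGACTA"),
                        stringsAsFactors = FALSE)
  internal <- mature
  substr(internal, 10, 10) <- "A"
  tags <- mk_tags(c(mature,                        # identical
                    substr(mature, 1, 20),         # missing last nt
                    substr(mature, 3, 21),         # 2-nt 5' trim
                    paste0("AC", mature),          # 2-nt 5' extension
                    substr(mature, 4, 21),         # 3-nt trim: too far
                    internal))                     # internal substitution
  res <- match_known(tags, catalog)
  hit_tags <- tags$sequence[match(res$assignments$tag_id, tags$tag_id)]
  expect_setequal(hit_tags, c(mature, substr(mature, 1, 20),
                              substr(mature, 3, 21), paste0("AC", mature)))
  rec <- res$records[res$records$mirna_id == "gma-miR001", ]
  expect_identical(rec$class, "known")
  expect_identical(rec$n_tags, 4L)
  expect_equal(rec$L1, 40) # counts of all assigned tags are summed
})

test_that("a tag matching two catalog entries is assigned to both and flagged", {
  mature <- "TGGAAGCTGTGAAGCTGACCT"
  catalog <- data.frame(id = c("a", "b"), family = c("fa", "fb"),
                        species = "x",
                        sequence = c(mature, substr(mature, 2, 21)),
                        stringsAsFactors = FALSE)
  res <- match_known(mk_tags(mature), catalog)
  expect_identical(sort(unique(res$assignments$mirna_id)), c("a", "b"))
  expect_true(all(res$records$ambiguous))
})

test_that("new members require homology and a validated hairpin", {
  gen <- generate_genome(n_compliant_hairpins = 0L, decoy_criteria = "1",
                         n_new_members = 1L, n_known = 1L,
                         genome_length = 8000L, seed = 31L)
  truth <- gen$truth
  hp <- truth$planted_hairpins
  nm <- hp[hp$class == "new_member", ]
  decoy <- hp[hp$class == "decoy", ]
  tags <- mk_tags(c(nm$mature_5p, nm$mature_3p, decoy$mature_5p,
                    decoy$mature_3p), counts = c(50L, 30L, 50L, 30L))
  hits <- map_tags(tags$sequence, gen$genome)
  foreign <- truth$foreign_catalog
  res <- match_new_member(tags, foreign, gen$genome, hits)
  expect_identical(sort(res$records$arm), c("3p", "5p"))
  expect_true(all(res$records$class == "new_member"))
  expect_identical(unique(res$records$family), foreign$family[1])
  expect_setequal(
    tags$sequence[match(res$assignments$tag_id, tags$tag_id)],
    c(nm$mature_5p, nm$mature_3p))

  # three mismatches from the best foreign match: rejected by threshold
  far <- strsplit(nm$mature_5p, "")[[1]]
  for (p in c(2, 8, 15)) far[p] <- setdiff(c("A", "C", "G", "T"), far[p])[1]
  tags3 <- mk_tags(paste(far, collapse = ""))
  expect_identical(nrow(match_new_member(tags3, foreign, gen$genome,
                                         map_tags(tags3$sequence, gen$genome))$records),
                   NULL)

  # homologous to the decoy arm: the locus fails a criterion, so rejected
  foreign2 <- data.frame(id = "xx-miR1", family = "miR1", species = "x",
                         sequence = decoy$mature_5p, stringsAsFactors = FALSE)
  res2 <- match_new_member(tags, foreign2, gen$genome, hits)
  expect_null(res2$records)
  expect_true("no_valid_hairpin" %in% res2$rejected$reason)
})

test_that("novel calling recovers planted loci, both arms, and rejects decoys", {
  gen <- generate_genome(n_compliant_hairpins = 2L,
                         decoy_criteria = c("2", "mfei"),
                         n_new_members = 0L, n_known = 1L,
                         genome_length = 12000L, seed = 32L)
  hp <- gen$truth$planted_hairpins
  seqs <- c(hp$mature_5p, hp$mature_3p)
  counts <- rep(c(50L, 30L), each = nrow(hp))
  tags <- mk_tags(seqs, counts)
  hits <- map_tags(tags$sequence, gen$genome)
  res <- call_novel(tags, gen$genome, hits)
  compliant <- hp[hp$violated == "none", ]
  expect_setequal(res$records$mature_sequence,
                  c(compliant$mature_5p, compliant$mature_3p))
  expect_identical(sum(res$records$arm == "5p"), 2L)
  expect_identical(nrow(res$hairpins), 2L)
  expect_true(all(res$hairpins$verdict))
})

test_that("novel matures within two mismatches share a family", {
  s1 <- "TGGAAGCTGTGAAGCTGACCT"
  s2 <- s1; substr(s2, 7, 7) <- "A"          # 1 mismatch from s1
  s3 <- "ACCCGTTTACGGGACTGACTA"              # unrelated
  fam <- heatmiR:::cluster_families(c(s1, s2, s3))
  expect_identical(fam[1], fam[2])
  expect_false(fam[1] == fam[3])
})

test_that("candidate tags end in exactly one class (partition)", {
  run <- tiny_run()
  res <- run$res
  known_tags <- unique(res$known$assignments$tag_id)
  nm_tags <- unique(res$new_member$assignments$tag_id)
  novel_tags <- unique(res$novel$assignments$tag_id)
  expect_length(intersect(known_tags, nm_tags), 0L)
  expect_length(intersect(known_tags, novel_tags), 0L)
  expect_length(intersect(nm_tags, novel_tags), 0L)
})
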
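rc <- function(x) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(x)))

test_that("pair states classify Watson-Crick, wobble and mismatch positions", {
  m <- "TGGAAGCTGTGAAGCTGACCT"
  expect_true(all(pair_states(m, rc(m)) == "match"))

  # G opposite T at one position: GU wobble worth half a mismatch
  site <- rc(m)
  p <- 2L # miRNA position 2 is a G in m
  expect_identical(substr(m, p, p), "G")
  substr(site, nchar(m) + 1L - p, nchar(m) + 1L - p) <- "T"
  st <- pair_states(m, site)
  expect_identical(unname(st[p]), "GU")
  expect_equal(apply_rules(st)$total_score, 0.5)

  # A opposite A is a plain mismatch
  m2 <- paste0("A", substr(m, 2, 21))
  site2 <- rc(m2)
  substr(site2, 21, 21) <- "A"
  st2 <- pair_states(m2, site2)
  expect_identical(unname(st2[1]), "mismatch")
  expect_equal(apply_rules(st2)$total_score, 1)

  expect_error(pair_states(m, substr(rc(m), 1, 20)), "equal length")
})

test_that("rules r1-r5 implement the stated thresholds", {
  L <- 21L
  st <- rep("match", L)
  v <- apply_rules(st)
  expect_true(v$r1 && v$r2 && v$r3 && v$r4 && v$r5)

  gu10 <- st; gu10[10] <- "GU" # wobble at a seed-cleavage position
  expect_false(apply_rules(gu10)$r4)
  expect_true(apply_rules(gu10, gu_strict = FALSE)$r4)

  run3 <- st; run3[15:17] <- "mismatch"
  expect_false(apply_rules(run3)$r2)

  heavy <- st; heavy[c(13, 15, 17)] <- "mismatch"; heavy[c(19, 21, 2)] <- "GU"
  expect_equal(apply_rules(heavy)$total_score, 4.5)
  expect_false(apply_rules(heavy)$r1)

  adj <- st; adj[5:6] <- c("GU", "mismatch")
  expect_false(apply_rules(adj)$r3)

  seedheavy <- st; seedheavy[c(2, 4, 6)] <- "mismatch"
  expect_false(apply_rules(seedheavy)$r5) # 3 > 2.5 in positions 1-12
  expect_true(apply_rules(seedheavy)$r1)
})

test_that("duplex ratio rule is inclusive at the threshold", {
  m <- "TGGAAGCTGTGAAGCTGACCT"
  r <- mfe_ratio(m, rc(m))
  expect_equal(r$ratio, 1.0)
  expect_true(r$r6)
  v <- duplex_ratio_verdict(-0.75 * 18.4, -18.4)
  expect_equal(v$ratio, 0.75)
  expect_true(v$pass) # exactly 75% passes
  expect_false(duplex_ratio_verdict(-13.7, -18.4)$pass)
})

test_that("scanner agrees exactly with the brute-force oracle", {
  set.seed(21)
  for (i in 1:60) {
    m <- random_seq(21)
    tx <- random_seq(400)
    if (i %% 2 == 0) { # plant a mutated near-site to exercise the boundary
      site <- mutate_seq(rc(m), sample(0:6, 1))
      pos <- sample(300, 1)
      substr(tx, pos, pos + 20) <- site
    }
    got <- scan_targets(c(mir = m), c(tx = tx), check_mfe = FALSE)
    expect_identical(got$start, oracle_scan(m, tx),
                     label = paste("pair", i))
  }
})

test_that("planted perfect sites are reported once at the planted window", {
  set.seed(22)
  m <- random_seq(21)
  tx <- random_seq(500)
  substr(tx, 137, 157) <- rc(m)
  hit <- scan_targets(c(mir = m), c(tx = tx))
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$start, 137L)
  expect_identical(hit$end, 157L)
  expect_true(hit$best)
  expect_equal(hit$mfe_ratio, 1.0)
  # a transcript shorter than the miRNA yields no windows, not an error
  expect_identical(nrow(scan_targets(c(mir = m), c(short = "ACGTACG"))), 0L)
  # an empty miRNA set yields an empty table
  expect_identical(nrow(scan_targets(character(0), c(tx = tx))), 0L)
})

test_that("adding a mismatch never rescues r1 and never raises the MFE ratio", {
  set.seed(23)
  m <- random_seq(21)
  site <- rc(m)
  prev_ratio <- 1.0
  prev_score <- 0
  for (k in 1:6) {
    pos <- 3L + 3L * k # spread mutations
    b <- substr(m, pos, pos)
    substr(site, 22L - pos, 22L - pos) <- b # same base: guaranteed non-pair
    st <- pair_states(m, site)
    v <- apply_rules(st)
    expect_gt(v$total_score, prev_score)
    if (prev_score > 4) expect_false(v$r1)
    ratio <- mfe_ratio(m, site)$ratio
    expect_lte(ratio, prev_ratio + 0.02)
    prev_ratio <- ratio
    prev_score <- v$total_score
  }
})
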
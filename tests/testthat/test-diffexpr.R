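test_that("TPM follows the stated formula and normalization identity", {
  counts <- matrix(c(50, 0, 999950, 10, 20, 999970), ncol = 2,
                   dimnames = list(c("a", "b", "rest"), c("L1", "L2")))
  totals <- c(L1 = 1e6, L2 = 1e6)
  m <- tpm(counts, totals)
  expect_equal(m["a", "L1"], 50)
  expect_equal(m["b", "L1"], 0)
  expect_equal(unname(colSums(m)), c(1e6, 1e6))
  expect_error(tpm(counts, c(L1 = 0, L2 = 1e6)), "positive")
})

test_that("the exact tag-count test is symmetric and calibrated under the null", {
  set.seed(41)
  n <- 2000L
  p <- rexp(n); p <- p / sum(p)
  x <- stats::rmultinom(1, 1e6, p)[, 1]
  y <- stats::rmultinom(1, 1.1e6, p)[, 1]
  pv <- ac_test(x, y, 1e6, 1.1e6)
  pv_sw <- ac_test(y, x, 1.1e6, 1e6)
  expect_equal(pv, pv_sw)
  rej <- mean(pv < 0.05)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(rej - 0.05), 3 * se)
  # clearly different proportions are detected
  expect_lt(ac_test(50, 400, 1e5, 1e5), 1e-10)
})

test_that("DEM calls apply both thresholds, with inclusive fold change", {
  counts <- matrix(c(100, 100, 0,   50,
                     400, 150, 30, 100),
                   ncol = 2, dimnames = list(c("m1", "m2", "m3", "m4"),
                                             c("NT", "HT")))
  totals <- c(NT = 1e5, HT = 1e5)
  dem <- call_dem(counts, totals, c("NT", "HT"))
  expect_true(dem$significant[dem$mirna_id == "m1"])   # FC 4
  expect_false(dem$significant[dem$mirna_id == "m2"])  # FC 1.5 < 2
  m3 <- dem[dem$mirna_id == "m3", ]
  expect_true(m3$significant && m3$on_off)             # expressed only in HT
  expect_identical(m3$direction, "up")
  m4 <- dem[dem$mirna_id == "m4", ]                    # FC exactly 2
  expect_equal(m4$fold_change, 2)
  expect_true(m4$significant)                          # >= is inclusive
})

test_that("swapping the contrast inverts fold changes and keeps significance", {
  set.seed(42)
  counts <- matrix(rpois(60, 80), ncol = 2,
                   dimnames = list(sprintf("m%02d", 1:30), c("A", "B")))
  counts[1:5, 2] <- counts[1:5, 1] * 5L
  totals <- c(A = 5e5, B = 6e5)
  d1 <- call_dem(counts, totals, c("A", "B"))
  d2 <- call_dem(counts, totals, c("B", "A"))
  expect_equal(d1$fold_change, 1 / d2$fold_change)
  expect_equal(d1$p_value, d2$p_value)
  expect_identical(d1$significant, d2$significant)
})

test_that("the nine-type grid is total and anchored on I, IV and IX", {
  resp <- c("up", "down", "unchanged")
  combos <- expand.grid(tolerant = resp, sensitive = resp,
                        stringsAsFactors = FALSE)
  mk_dem <- function(dirs) {
    data.frame(mirna_id = sprintf("m%d", seq_along(dirs)), direction = dirs,
               on_off = FALSE, stringsAsFactors = FALSE)
  }
  ty <- classify_type(mk_dem(combos$tolerant), mk_dem(combos$sensitive))
  expect_identical(sort(ty$pattern_type),
                   sort(c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                          "IX")))
  expect_identical(ty$pattern_type[combos$tolerant == "up" &
                                     combos$sensitive == "up"], "I")
  expect_identical(ty$pattern_type[combos$tolerant == "down" &
                                     combos$sensitive == "down"], "IV")
  expect_identical(ty$pattern_type[combos$tolerant == "unchanged" &
                                     combos$sensitive == "unchanged"], "IX")
  expect_error(classify_type(mk_dem("up"), NULL), "both genotype contrasts")
})

test_that("relative expression by 2^-ddCt matches hand arithmetic", {
  mk <- function(gt, ct_, gc, cc) {
    data.frame(sample = rep(c("test", "calibrator"), each = 2),
               gene = rep(c("target", "control"), 2),
               ct = c(gt, ct_, gc, cc))
  }
  expect_equal(ddct(mk(20, 20, 20, 20))$rq, 1.0)  # ddCt = 0
  expect_equal(ddct(mk(19, 20, 20, 20))$rq, 2.0)  # ddCt = -1
  expect_equal(ddct(mk(24, 20, 26, 20))$rq, 4.0)  # worked example
  expect_error(ddct(mk(24, 20, 26, 20)[-2, ]), "missing well")
  # replicate dispersion is propagated
  tbl <- rbind(mk(24, 20, 26, 20), mk(24.4, 20, 26, 20))
  d <- ddct(tbl)
  expect_gt(d$sd_ddct, 0)
  expect_true(d$rq_low < d$rq && d$rq < d$rq_high)
})
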
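# Rule-based miRNA target prediction on ungapped duplexes.
#
# A candidate site is a transcript window of the miRNA's length, compared
# antiparallel: miRNA position 1 (5' end) pairs the window's 3'-most base.
# Positions are indexed 1..L from the miRNA 5' end. Six rules are applied:
#   r1  total mismatch score <= 4 (G-U wobble counts 0.5)
#   r2  no more than 2 adjacent non-matches anywhere
#   r3  no adjacent non-matches within positions 2-12
#   r4  positions 10 and 11 both Watson-Crick matched
#   r5  mismatch score over positions 1-12 <= 2.5
#   r6  |duplex MFE| >= 75% of |MFE against the perfect complement|
# With the default strict G-U handling, a wobble counts as a non-match for
# the adjacency rules r2-r4 while contributing only 0.5 to the r1/r5 scores.

# 4x4 lookup: rows miRNA base, cols target base (A,C,G,T); 0 match, 1 GU
# wobble (miRNA G vs target T, or miRNA T vs target G), 2 mismatch.
PAIR_TABLE <- matrix(c(
  # target: A  C  G  T      miRNA:
            2, 2, 2, 0,   # A
            2, 2, 0, 2,   # C
            2, 0, 2, 1,   # G
            0, 2, 1, 2),  # T
  nrow = 4L, byrow = TRUE)

#' Per-position pairing states of a miRNA/target duplex
#'
#' @param mirna miRNA sequence, 5'->3' (DNA or RNA alphabet).
#' @param site  target site of the same length, transcript 5'->3'; position
#'   `i` of the miRNA is compared with position `L + 1 - i` of the site.
#' @return character vector of length L over `{"match", "GU", "mismatch"}`,
#'   indexed from the miRNA 5' end.
#' @export
pair_states <- function(mirna, site) {
  if (nchar(mirna) != nchar(site)) {
    stop("miRNA and site must have equal length (",
         nchar(mirna), " vs ", nchar(site), ")")
  }
  m <- seq_to_int(rna2dna(toupper(mirna)))
  s <- rev(seq_to_int(rna2dna(toupper(site))))
  if (any(m == 0L) || any(s == 0L)) stop("non-ACGT/U base in input")
  c("match", "GU", "mismatch")[PAIR_TABLE[cbind(m, s)] + 1L]
}

#' Apply the position-indexed complementarity rules r1-r5
#'
#' @param states pairing states from [pair_states()].
#' @param max_score,seed_max_score,max_adjacent r1/r5/r2 thresholds.
#' @param gu_strict if `TRUE` (default) a G-U wobble counts as a non-match
#'   for the adjacency/position rules r2-r4; it always contributes 0.5 to
#'   the r1/r5 scores.
#' @return named list: `total_score`, `score_1_12`, `max_adjacent_run`, and
#'   logical verdicts `r1`..`r5`.
#' @export
apply_rules <- function(states, max_score = 4, seed_max_score = 2.5,
                        max_adjacent = 2L, gu_strict = TRUE) {
  L <- length(states)
  stopifnot(L >= 13L)
  w <- c(match = 0, GU = 0.5, mismatch = 1)[states]
  nm <- if (gu_strict) states != "match" else states == "mismatch"
  total <- sum(w)
  seed_score <- sum(w[1:12])
  runs <- rle(nm)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  adj_2_12 <- any(nm[2:11] & nm[3:12])
  list(total_score = total,
       score_1_12 = seed_score,
       max_adjacent_run = as.integer(max_run),
       r1 = total <= max_score,
       r2 = max_run <= max_adjacent,
       r3 = !adj_2_12,
       r4 = !nm[10] && !nm[11],
       r5 = seed_score <= seed_max_score)
}

#' Rule-6 verdict from duplex and perfect-complement MFEs
#'
#' The rule passes when the magnitude of the miRNA/site duplex MFE is at
#' least `min_ratio` of the magnitude of the miRNA bound to its perfect
#' complement; the comparison is inclusive, so a ratio of exactly
#' `min_ratio` passes.
#'
#' @param duplex,perfect MFE values in kcal/mol (both non-positive).
#' @param min_ratio inclusive threshold.
#' @return list `ratio`, `pass` (vectorized).
#' @export
duplex_ratio_verdict <- function(duplex, perfect, min_ratio = 0.75) {
  ratio <- ifelse(abs(perfect) > 0, abs(duplex) / abs(perfect), 0)
  list(ratio = ratio, pass = ratio >= min_ratio)
}

#' Duplex minimum-free-energy ratio rule (r6)
#'
#' Ratio of the miRNA/site duplex MFE magnitude to the MFE magnitude of the
#' miRNA hybridized to its perfect complement; the rule passes when the
#' ratio is at least `min_ratio` (inclusive).
#'
#' @param mirna,site equal-length sequences, both 5'->3'.
#' @param min_ratio inclusive pass threshold.
#' @return list `duplex_mfe`, `perfect_mfe`, `ratio`, `r6`.
#' @export
mfe_ratio <- function(mirna, site, min_ratio = 0.75) {
  d <- duplex_mfe(mirna, site)
  p <- duplex_mfe(mirna, revcomp(mirna))
  v <- duplex_ratio_verdict(d, p, min_ratio)
  list(duplex_mfe = d, perfect_mfe = p, ratio = v$ratio, r6 = v$pass)
}

# vectorized rule evaluation of every window of one transcript against one
# miRNA; returns the indices of windows passing r1-r5 plus their scores.
scan_one <- function(mir_int, tr_int, max_score, seed_max_score,
                     max_adjacent, gu_strict) {
  L <- length(mir_int)
  W <- length(tr_int) - L + 1L
  if (W < 1L) return(NULL)
  idx <- outer(seq_len(W) - 1L, seq_len(L), "+")
  siteM <- matrix(tr_int[idx], nrow = W)
  # column j of siteM is site position j (5'->3'); miRNA position for that
  # column is L + 1 - j, so compare against the reversed miRNA and then
  # reorder columns to miRNA-position indexing.
  mirM <- matrix(rev(mir_int), nrow = W, ncol = L, byrow = TRUE)
  S <- matrix(PAIR_TABLE[mirM + (siteM - 1L) * 4L], nrow = W)[, L:1, drop = FALSE]
  gu <- S == 1L
  mm <- S == 2L
  nm <- if (gu_strict) S != 0L else mm
  total <- rowSums(mm) + 0.5 * rowSums(gu)
  seed <- rowSums(mm[, 1:12, drop = FALSE]) + 0.5 * rowSums(gu[, 1:12, drop = FALSE])
  run3 <- rep(FALSE, W)
  for (i in seq_len(L - max_adjacent)) {
    blk <- nm[, i:(i + max_adjacent), drop = FALSE]
    run3 <- run3 | rowSums(blk) == max_adjacent + 1L
  }
  adj <- rep(FALSE, W)
  for (i in 2:11) adj <- adj | (nm[, i] & nm[, i + 1L])
  ok <- total <= max_score & !run3 & !adj & !nm[, 10L] & !nm[, 11L] &
    seed <= seed_max_score
  which_ok <- which(ok)
  if (!length(which_ok)) return(NULL)
  list(start = which_ok, total_score = total[which_ok],
       score_1_12 = seed[which_ok])
}

#' Scan transcripts for miRNA target sites
#'
#' Slides every miRNA along every transcript one nucleotide at a time,
#' applies rules r1-r5 to each window, and (optionally) rule r6 to the
#' survivors. Overlapping accepted windows are all reported; the
#' best-scoring site per (miRNA, transcript) is flagged.
#'
#' @param mirnas named character vector of mature miRNA sequences (5'->3').
#' @param transcripts named character vector of transcript sequences.
#' @param gu_strict see [apply_rules()].
#' @param check_mfe apply rule r6 with the duplex folding engine; when
#'   `FALSE`, r6 is reported as `NA` and not used for filtering.
#' @param min_mfe_ratio inclusive r6 threshold.
#' @return data.frame, one row per accepted site: `mirna_id`,
#'   `transcript_id`, `start`, `end` (1-based transcript coordinates),
#'   `total_score`, `score_1_12`, `mfe_ratio`, `best` and the aligned duplex
#'   strings (`mirna_5p3p`, `site_3p5p`, `pairing` with `|` match, `o` G-U,
#'   a space otherwise).
#' @export
scan_targets <- function(mirnas, transcripts, gu_strict = TRUE,
                         check_mfe = TRUE, min_mfe_ratio = 0.75,
                         max_score = 4, seed_max_score = 2.5,
                         max_adjacent = 2L) {
  empty <- data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      total_score = numeric(0), score_1_12 = numeric(0),
                      mfe_ratio = numeric(0), best = logical(0),
                      mirna_5p3p = character(0), site_3p5p = character(0),
                      pairing = character(0), stringsAsFactors = FALSE)
  if (!length(mirnas) || !length(transcripts)) return(empty)
  stopifnot(!is.null(names(mirnas)), !is.null(names(transcripts)))
  mir_ints <- lapply(rna2dna(toupper(mirnas)), seq_to_int)
  tr_ints <- lapply(rna2dna(toupper(transcripts)), seq_to_int)
  out <- list()
  for (mi in seq_along(mirnas)) {
    L <- length(mir_ints[[mi]])
    if (L < 13L) next
    for (ti in seq_along(transcripts)) {
      hit <- scan_one(mir_ints[[mi]], tr_ints[[ti]], max_score,
                      seed_max_score, max_adjacent, gu_strict)
      if (is.null(hit)) next
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = names(mirnas)[mi], transcript_id = names(transcripts)[ti],
        start = hit$start, end = hit$start + L - 1L,
        total_score = hit$total_score, score_1_12 = hit$score_1_12,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  sites <- do.call(rbind, out)
  site_seq <- substr(transcripts[sites$transcript_id], sites$start, sites$end)
  mir_seq <- unname(mirnas[sites$mirna_id])
  if (check_mfe) {
    d <- duplex_mfe(mir_seq, site_seq)
    p <- duplex_mfe(unname(mirnas), revcomp(unname(mirnas)))
    names(p) <- names(mirnas)
    v <- duplex_ratio_verdict(d, p[sites$mirna_id], min_mfe_ratio)
    sites$mfe_ratio <- unname(v$ratio)
    sites <- sites[unname(v$pass), , drop = FALSE]
    site_seq <- substr(transcripts[sites$transcript_id], sites$start, sites$end)
    mir_seq <- unname(mirnas[sites$mirna_id])
  } else {
    sites$mfe_ratio <- NA_real_
  }
  if (!nrow(sites)) return(empty)
  # alignment strings and best-per-(miRNA, transcript) flag
  aln <- vapply(seq_len(nrow(sites)), function(i) {
    st <- pair_states(mir_seq[i], site_seq[i])
    paste(c("|", "o", " ")[match(st, c("match", "GU", "mismatch"))],
          collapse = "")
  }, "")
  sites$best <- FALSE
  key <- paste(sites$mirna_id, sites$transcript_id)
  for (k in unique(key)) {
    rows <- which(key == k)
    sites$best[rows[which.min(sites$total_score[rows])]] <- TRUE
  }
  sites$mirna_5p3p <- mir_seq
  sites$site_3p5p <- vapply(site_seq, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, "", USE.NAMES = FALSE)
  sites$pairing <- aln
  rownames(sites) <- NULL
  sites
}
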
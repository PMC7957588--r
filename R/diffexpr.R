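# TPM normalization, differential expression for unreplicated tag counts,
# nine-type expression-pattern classification, and the 2^-ddCt qPCR utility.

#' Tags-per-million normalization
#'
#' `TPM = count / total clean tags of the library * 1e6`. Summed over all
#' clean tags of a library the TPM column therefore equals exactly 1e6;
#' summed over miRNAs only, it is at most 1e6.
#'
#' @param counts numeric matrix (rows features, columns libraries).
#' @param totals per-library total clean tag counts (named or in column
#'   order); all strictly positive.
#' @return matrix of TPM values, same shape as `counts`.
#' @export
tpm <- function(counts, totals) {
  counts <- as.matrix(counts)
  if (!is.null(names(totals)) && !is.null(colnames(counts))) {
    totals <- totals[colnames(counts)]
  }
  stopifnot(length(totals) == ncol(counts))
  if (any(totals <= 0)) stop("library totals must be positive")
  sweep(counts, 2L, totals, "/") * 1e6
}

#' Exact test for a difference between two unreplicated tag counts
#'
#' Audic-Claverie style exact test for tag counts `x` and `y` observed in
#' libraries of `nx` and `ny` total clean tags: conditional on `x`, `y`
#' follows a negative binomial with size `x + 1` and probability
#' `nx / (nx + ny)`, whose tails give the one-sided p-values; the two-sided
#' p-value doubles the smaller tail (capped at 1). The pair is oriented
#' canonically (conditioning on the library with the smaller observed
#' proportion) so the p-value is invariant under swapping the contrast.
#'
#' @param x,y integer tag counts (vectorized).
#' @param nx,ny library totals.
#' @return numeric vector of two-sided p-values.
#' @export
ac_test <- function(x, y, nx, ny) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  nx <- rep_len(nx, n); ny <- rep_len(ny, n)
  swap <- x / nx > y / ny | (x / nx == y / ny & nx < ny)
  x2 <- ifelse(swap, y, x); y2 <- ifelse(swap, x, y)
  nx2 <- ifelse(swap, ny, nx); ny2 <- ifelse(swap, nx, ny)
  prob <- nx2 / (nx2 + ny2)
  up <- stats::pnbinom(y2 - 1L, size = x2 + 1, prob = prob,
                       lower.tail = FALSE)
  lo <- stats::pnbinom(y2, size = x2 + 1, prob = prob)
  pmin(1, 2 * pmin(up, lo))
}

#' Call differentially expressed miRNAs between two libraries
#'
#' Fold change is the TPM ratio of library B over library A; when either
#' raw count is zero, `pseudocount` raw counts are added to both sides
#' before computing the ratio so on/off miRNAs remain representable. A
#' record is significant when `max(FC, 1/FC) >= fc_threshold` and the exact
#' test p-value is below `alpha`. No multiple-testing correction is applied
#' to the calls; a Benjamini-Hochberg column is emitted for information.
#'
#' @param counts matrix of raw counts (rows miRNAs, columns libraries,
#'   rownames = miRNA ids).
#' @param totals per-library total clean tags (named).
#' @param contrast length-2 character vector `c(A, B)` of library names;
#'   conventionally A = control (NT) and B = treatment (HT).
#' @param fc_threshold,alpha significance thresholds (fold change is
#'   compared inclusively, p strictly).
#' @param pseudocount raw pseudocount used when either count is zero.
#' @return data.frame: `mirna_id`, `count_a`, `count_b`, `tpm_a`, `tpm_b`,
#'   `fold_change` (B over A), `log2_fc`, `p_value`, `fdr`, `significant`,
#'   `direction` (`up`, `down`, `unchanged`), `on_off` flag.
#' @export
call_dem <- function(counts, totals, contrast, fc_threshold = 2,
                     alpha = 0.05, pseudocount = 1) {
  stopifnot(length(contrast) == 2L, all(contrast %in% colnames(counts)))
  a <- counts[, contrast[1L]]
  b <- counts[, contrast[2L]]
  na <- totals[[contrast[1L]]]
  nb <- totals[[contrast[2L]]]
  zero <- a == 0 | b == 0
  a_adj <- ifelse(zero, a + pseudocount, a)
  b_adj <- ifelse(zero, b + pseudocount, b)
  fc <- (b_adj / nb) / (a_adj / na)
  p <- ac_test(a, b, na, nb)
  sig <- pmax(fc, 1 / fc) >= fc_threshold & p < alpha
  data.frame(
    mirna_id = rownames(counts), count_a = a, count_b = b,
    tpm_a = a / na * 1e6, tpm_b = b / nb * 1e6,
    fold_change = fc, log2_fc = log2(fc), p_value = p,
    fdr = stats::p.adjust(p, method = "BH"),
    significant = sig,
    direction = ifelse(sig, ifelse(fc > 1, "up", "down"), "unchanged"),
    on_off = zero & sig,
    stringsAsFactors = FALSE, row.names = NULL)
}

PATTERN_GRID <- matrix(
  c("I",   "III", "II",   # tolerant induced
    "VI",  "IV",  "V",    # tolerant repressed
    "VII", "VIII", "IX"), # tolerant unchanged
  nrow = 3L, byrow = TRUE,
  dimnames = list(c("up", "down", "unchanged"),
                  c("up", "down", "unchanged")))

#' Classify miRNAs into the nine expression-pattern types
#'
#' Each miRNA's heat response in the tolerant and the sensitive genotype
#' (HT vs NT, from [call_dem()]: `up`, `down`, or `unchanged`) places it in
#' a 3x3 grid of pattern types I-IX. Induced in both genotypes is type I,
#' repressed in both type IV, unchanged in both (no heat response) type IX;
#' the placement of the remaining six cells is this package's convention
#' (see the methods vignette). On/off expression is reported as a flag, not
#' a separate type.
#'
#' @param dem_tolerant,dem_sensitive [call_dem()] tables for the HT-vs-NT
#'   contrast within each genotype, aligned on `mirna_id`.
#' @return data.frame `mirna_id`, `response_tolerant`, `response_sensitive`,
#'   `pattern_type`, `on_off`.
#' @export
classify_type <- function(dem_tolerant, dem_sensitive) {
  if (is.null(dem_tolerant) || is.null(dem_sensitive)) {
    stop("both genotype contrasts are required to classify pattern types")
  }
  m <- match(dem_tolerant$mirna_id, dem_sensitive$mirna_id)
  if (anyNA(m)) stop("contrasts cover different miRNA sets")
  rt <- dem_tolerant$direction
  rs <- dem_sensitive$direction[m]
  data.frame(
    mirna_id = dem_tolerant$mirna_id,
    response_tolerant = rt,
    response_sensitive = rs,
    pattern_type = PATTERN_GRID[cbind(rt, rs)],
    on_off = dem_tolerant$on_off | dem_sensitive$on_off[m],
    stringsAsFactors = FALSE)
}

#' Relative expression by the 2^-ddCt method
#'
#' Quantifies a target gene relative to an internal control, comparing a
#' test sample with a calibrator sample:
#' `2^-((Ct_gene,test - Ct_ctrl,test) - (Ct_gene,cal - Ct_ctrl,cal))`.
#' Replicates are averaged per well class and their standard deviations
#' propagated to the ddCt scale.
#'
#' @param ct data.frame with columns `sample` (`test` / `calibrator`),
#'   `gene` (`target` / `control`), and `ct` (one row per replicate).
#' @return list: `ddct`, `rq` (relative quantity `2^-ddct`), `rq_low`,
#'   `rq_high` (one propagated SD), `sd_ddct`.
#' @export
ddct <- function(ct) {
  stopifnot(all(c("sample", "gene", "ct") %in% colnames(ct)))
  if (any(!is.finite(ct$ct))) stop("non-finite Ct value")
  cell <- function(s, g) {
    v <- ct$ct[ct$sample == s & ct$gene == g]
    if (!length(v)) stop("missing well: sample=", s, " gene=", g)
    c(mean = mean(v), var = if (length(v) > 1L) stats::var(v) / length(v) else 0)
  }
  gt <- cell("test", "target"); ctl_t <- cell("test", "control")
  gc_ <- cell("calibrator", "target"); ctl_c <- cell("calibrator", "control")
  dd <- (gt["mean"] - ctl_t["mean"]) - (gc_["mean"] - ctl_c["mean"])
  sd_dd <- sqrt(gt["var"] + ctl_t["var"] + gc_["var"] + ctl_c["var"])
  list(ddct = unname(dd), rq = unname(2^-dd),
       rq_low = unname(2^-(dd + sd_dd)), rq_high = unname(2^-(dd - sd_dd)),
       sd_ddct = unname(sd_dd))
}
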
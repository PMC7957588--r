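# Precursor excision, stem-loop trimming and the five structural criteria
# for novel miRNA hairpins:
#   c1  > 16 matched pairs in the miR/miR* duplex and arm length difference
#       of at most 4 nt
#   c2  exactly 2-nt 3' overhangs at both duplex ends (the most abundant
#       read per arm defines the arm)
#   c3  at most one asymmetric bulge within the duplex, none larger than 2 nt
#   c4  the most abundant arm read reaches min_reads in at least one library
#   c5  MFE per nucleotide < -0.2 kcal/mol/nt and MFEI > 0.85, where
#       MFEI = |MFE/length * 100| / GC%  (equivalently |MFE/nt| / GC fraction)

#' Excise candidate precursor windows around a genomic tag hit
#'
#' Emits up to three windows around the mapped tag - 5'-heavy, 3'-heavy and
#' centered - clipped to the contig and restricted to 60-400 nt. Minus-strand
#' hits are reverse-complemented so the returned sequence is the transcribed
#' precursor 5'->3'.
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom,start,end,strand genomic location of the tag (1-based
#'   inclusive).
#' @param flank_max,flank_min long and short flank extents (nt).
#' @return data.frame: `sequence`, `chrom`, `start`, `end`, `strand`,
#'   `tag_start`, `tag_end` (1-based tag position within the window, already
#'   strand-adjusted), `layout`.
#' @export
excise_precursor <- function(genome, chrom, start, end, strand = "+",
                             flank_max = 250L, flank_min = 20L) {
  stopifnot(chrom %in% names(genome))
  chrom_seq <- genome[[chrom]]
  clen <- nchar(chrom_seq)
  mid <- as.integer((flank_max + flank_min) / 2)
  layouts <- list(`5p_heavy` = c(flank_max, flank_min),
                  `3p_heavy` = c(flank_min, flank_max),
                  centered  = c(mid, mid))
  # upstream/downstream are in transcript orientation
  rows <- lapply(names(layouts), function(nm) {
    fl <- layouts[[nm]]
    if (strand == "+") {
      ws <- max(1L, start - fl[1L]); we <- min(clen, end + fl[2L])
    } else {
      ws <- max(1L, start - fl[2L]); we <- min(clen, end + fl[1L])
    }
    len <- we - ws + 1L
    if (len < 60L) return(NULL)
    if (len > 400L) { # trim the longer flank symmetrically toward the tag
      excess <- len - 400L
      if (strand == "+") ws <- ws + excess else we <- we - excess
      len <- 400L
    }
    seqn <- substr(chrom_seq, ws, we)
    if (strand == "-") {
      seqn <- revcomp(seqn)
      ts <- we - end + 1L
    } else {
      ts <- start - ws + 1L
    }
    data.frame(sequence = seqn, chrom = chrom, start = ws, end = we,
               strand = strand, tag_start = ts,
               tag_end = ts + (end - start), layout = nm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), tag_start = integer(0),
                      tag_end = integer(0), layout = character(0),
                      stringsAsFactors = FALSE)
  }
  unique(out)
}

#' Trim a folded window to the stem-loop enclosing a tag
#'
#' Locates the hairpin loop the tag's pairing partners lead to and expands
#' outward to the outermost base pair that still encloses exactly that one
#' loop, discarding background sequence and neighboring structure. Returns
#' `NULL` when the tag is unpaired, spans several loops, or sits under a
#' multiloop.
#'
#' @param structure dot-bracket string of the folded window.
#' @param tag_start,tag_end 1-based tag position within the window.
#' @return integer vector `c(start, end)` of the stem-loop within the
#'   window, or `NULL`.
#' @export
trim_to_stemloop <- function(structure, tag_start, tag_end) {
  pmap <- pair_map(structure)
  tag_pos <- tag_start:tag_end
  paired <- tag_pos[!is.na(pmap[tag_pos])]
  if (!length(paired)) return(NULL)
  loops <- innermost_pairs(pmap)
  if (!nrow(loops)) return(NULL)
  i <- paired[1L]
  lo <- min(i, pmap[i]); hi <- max(i, pmap[i])
  inside <- loops[, "a"] >= lo & loops[, "b"] <= hi
  if (sum(inside) != 1L) return(NULL)
  a_star <- loops[inside, "a"]; b_star <- loops[inside, "b"]
  # enclosing pairs of the loop, outermost first
  enc <- which(!is.na(pmap) & seq_along(pmap) <= a_star & pmap >= b_star)
  if (!length(enc)) return(NULL)
  n_loops_in <- function(a, b) sum(loops[, "a"] >= a & loops[, "b"] <= b)
  for (a in sort(enc)) {
    b <- pmap[a]
    if (n_loops_in(a, b) == 1L) return(c(a, b))
  }
  NULL
}

# classify reads into arms given the innermost pair (loop) of a stem-loop
# structure; returns "5p", "3p", "loop" or "spanning"
read_arm <- function(start, end, loop_a, loop_b) {
  if (start <= loop_a && end >= loop_b) return("spanning")
  if (start <= loop_a) return("5p")
  if (end >= loop_b) return("3p")
  "loop"
}

#' Evaluate a candidate precursor against the five hairpin criteria
#'
#' @param precursor precursor sequence (5'->3', DNA or RNA alphabet).
#' @param reads data.frame of reads mapped within the precursor: `start`,
#'   `end` (1-based precursor coordinates) and `max_count` (the read's
#'   highest per-library count). The most abundant read per arm defines the
#'   miR/miR* duplex.
#' @param structure,mfe optional precomputed fold; computed with
#'   [fold_rna()] when absent.
#' @param min_pairs,max_size_diff,overhang,max_bulges,max_bulge_size,min_reads,max_mfe_nt,min_mfei
#'   criterion thresholds; defaults are the standard plant miRNA annotation
#'   values (matched pairs strictly greater than 16, arm size difference at
#'   most 4 nt, 2-nt 3' overhangs, at most one asymmetric bulge of at most
#'   2 nt, at least 10 reads in some library, MFE/nt below -0.2 kcal/mol/nt,
#'   MFEI above 0.85).
#' @return list: logical `verdicts` (`c1`..`c5`, `mfe`, `mfei`), `pass`,
#'   `reason` (when unevaluable), duplex statistics, `mfe`, `mfe_per_nt`,
#'   `mfei`, `gc`, `structure`, and the arm read rows (`arm5p`, `arm3p`).
#' @export
evaluate_hairpin <- function(precursor, reads, structure = NULL, mfe = NULL,
                             min_pairs = 16L, max_size_diff = 4L,
                             overhang = 2L, max_bulges = 1L,
                             max_bulge_size = 2L, min_reads = 10L,
                             max_mfe_nt = -0.2, min_mfei = 0.85) {
  n <- nchar(precursor)
  if (nrow(reads) && (any(reads$start < 1L) || any(reads$end > n))) {
    stop("read outside the precursor (precursor length ", n, ")")
  }
  if (is.null(structure) || is.null(mfe)) {
    f <- fold_rna(precursor)
    structure <- f$structure
    mfe <- f$mfe
  }
  fail <- function(reason) {
    v <- stats::setNames(rep(FALSE, 7L),
                         c("c1", "c2", "c3", "c4", "c5", "mfe", "mfei"))
    list(verdicts = v, pass = FALSE, reason = reason,
         matched_pairs = 0L, size_difference = NA_integer_,
         overhang_5p = NA_integer_, overhang_3p = NA_integer_,
         bulges = integer(0), mfe = mfe, mfe_per_nt = mfe / n,
         mfei = abs(mfe / n) / gc_fraction(precursor),
         gc = gc_fraction(precursor), structure = structure,
         arm5p = NULL, arm3p = NULL)
  }
  pmap <- pair_map(structure)
  loops <- innermost_pairs(pmap)
  if (nrow(loops) != 1L) return(fail("not_single_stemloop"))
  loop_a <- loops[1L, "a"]; loop_b <- loops[1L, "b"]
  if (!nrow(reads)) return(fail("no_reads"))
  arm <- vapply(seq_len(nrow(reads)),
                function(i) read_arm(reads$start[i], reads$end[i],
                                     loop_a, loop_b), "")
  pick <- function(which_arm) {
    rows <- which(arm == which_arm)
    if (!length(rows)) return(NULL)
    reads[rows[which.max(reads$max_count[rows])], , drop = FALSE]
  }
  r5 <- pick("5p"); r3 <- pick("3p")
  if (is.null(r5) || is.null(r3)) return(fail("missing_arm_read"))

  s5 <- r5$start; e5 <- r5$end; s3 <- r3$start; e3 <- r3$end
  in3p <- function(p) !is.na(p) & p >= s3 & p <= e3
  in5p <- function(p) !is.na(p) & p >= s5 & p <= e5
  p5 <- (s5:e5)[in3p(pmap[s5:e5])] # 5p positions paired into the 3p read
  matched <- length(p5)
  if (!matched) return(fail("no_duplex_pairs"))
  size_diff <- abs((e5 - s5) - (e3 - s3))

  # 3' overhangs: project the first paired position back to the read ends
  i0 <- p5[1L]
  ovh_3p <- e3 - (pmap[i0] + (i0 - s5))
  p3 <- (s3:e3)[in5p(pmap[s3:e3])]
  j0 <- p3[1L]
  ovh_5p <- e5 - (pmap[j0] + (j0 - s3))

  # asymmetric bulges between consecutive duplex pairs
  bulges <- integer(0)
  if (matched > 1L) {
    gap5 <- diff(p5) - 1L
    gap3 <- -(diff(pmap[p5])) - 1L
    asym <- abs(gap5 - gap3)
    bulges <- asym[asym > 0L]
  }

  gc <- gc_fraction(precursor)
  mfe_per_nt <- mfe / n
  mfei <- abs(mfe_per_nt) / gc

  v <- c(
    c1 = matched > min_pairs && size_diff <= max_size_diff,
    c2 = ovh_5p == overhang && ovh_3p == overhang,
    c3 = length(bulges) <= max_bulges && all(bulges <= max_bulge_size),
    c4 = max(r5$max_count, r3$max_count) >= min_reads,
    mfe = mfe_per_nt < max_mfe_nt,
    mfei = mfei > min_mfei)
  v <- c(v[1:4], c5 = unname(v["mfe"] && v["mfei"]), v[5:6])
  list(verdicts = v, pass = all(v[c("c1", "c2", "c3", "c4", "c5")]),
       reason = NA_character_,
       matched_pairs = matched, size_difference = size_diff,
       overhang_5p = as.integer(ovh_5p), overhang_3p = as.integer(ovh_3p),
       bulges = bulges, mfe = mfe, mfe_per_nt = mfe_per_nt, mfei = mfei,
       gc = gc, structure = structure, arm5p = r5, arm3p = r3)
}
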
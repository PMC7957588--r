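# Read cleaning, tag collapsing, annotation and length statistics for
# small RNA libraries.

DISCARD_REASONS <- c("low_quality", "adapter_only", "too_short", "too_long",
                     "poly_a")

ANNOTATION_CLASSES <- c("rRNA", "scRNA", "snoRNA", "snRNA", "tRNA",
                        "repeat", "mRNA_fragment", "candidate_sRNA")

#' Clean raw small RNA reads
#'
#' Applies, in a fixed order, the standard small RNA-seq cleaning steps:
#' quality filtering (any base below `min_quality` within the first
#' `quality_cycles` cycles discards the read), 3' adapter trimming (the read
#' is cut at the first exact occurrence of the adapter's leading 8-mer;
#' reads that start with adapter are dropped as adapter-only), a length
#' window of `[min_len, max_len]` nucleotides, and a poly-A filter (reads
#' whose trimmed insert is at least `polya_frac` adenosine are dropped).
#' Each read is either retained or discarded for exactly one reason, so raw
#' read counts are conserved.
#'
#' @param fastq path to a FASTQ file (Phred+33); alternatively supply
#'   `reads` (and optionally `qualities`) directly.
#' @param adapter 3' adapter sequence (DNA alphabet).
#' @param reads,qualities optional character vectors bypassing `fastq`;
#'   missing qualities are treated as maximal.
#' @param min_quality minimum Phred score tolerated in the leading cycles.
#' @param quality_cycles number of leading cycles the quality rule inspects.
#' @param min_len,max_len retained insert length window (nt), inclusive.
#' @param polya_frac adenosine fraction at or above which an insert is
#'   discarded as poly-A.
#' @return list with `reads` (clean trimmed inserts), and `stats`: raw and
#'   clean read counts plus per-reason discard counts.
#' @export
clean_reads <- function(fastq = NULL, adapter = "TGGAATTCTCGGGTGCCAAGG",
                        reads = NULL, qualities = NULL,
                        min_quality = 20L, quality_cycles = 25L,
                        min_len = 18L, max_len = 30L, polya_frac = 0.8) {
  if (is.null(reads)) {
    stopifnot(!is.null(fastq))
    parsed <- tryCatch(
      Biostrings::readDNAStringSet(fastq, format = "fastq",
                                   with.qualities = TRUE),
      error = function(e) stop("malformed FASTQ in ", fastq, ": ",
                               conditionMessage(e), call. = FALSE))
    reads <- as.character(parsed)
    qualities <- as.character(S4Vectors::mcols(parsed)$qualities)
  }
  n_raw <- length(reads)
  reason <- rep(NA_character_, n_raw)

  # 1. quality: any base < min_quality among the first quality_cycles cycles.
  if (!is.null(qualities) && n_raw) {
    bad_class <- sprintf("[\\x21-\\x%x]", 33L + min_quality - 1L)
    lowq <- grepl(bad_class, substr(qualities, 1L, quality_cycles),
                  perl = TRUE)
    reason[lowq] <- "low_quality"
  }

  # 2. adapter trimming at the first exact hit of the adapter's leading 8-mer
  seed <- substr(adapter, 1L, min(8L, nchar(adapter)))
  hit <- regexpr(seed, reads, fixed = TRUE)
  insert <- ifelse(hit > 0L, substr(reads, 1L, hit - 1L), reads)
  reason[is.na(reason) & hit == 1L] <- "adapter_only"

  len <- nchar(insert)
  reason[is.na(reason) & len < min_len] <- "too_short"
  reason[is.na(reason) & len > max_len] <- "too_long"

  a_frac <- ifelse(len > 0L,
                   (len - nchar(gsub("A", "", insert, fixed = TRUE))) / len, 1)
  reason[is.na(reason) & a_frac >= polya_frac] <- "poly_a"

  keep <- is.na(reason)
  discarded <- vapply(DISCARD_REASONS,
                      function(r) sum(reason == r, na.rm = TRUE), 0L)
  list(reads = insert[keep],
       stats = list(raw_reads = n_raw, clean_reads = sum(keep),
                    discarded = discarded))
}

#' Collapse clean reads into unique counted sequence tags
#'
#' @param reads_by_library named list of character vectors (clean inserts),
#'   one per library.
#' @return data.frame with `tag_id`, `sequence`, `length`, one count column
#'   per library and `total`. The library names are kept in the
#'   `"libraries"` attribute. Ordered by decreasing total count, then
#'   sequence, so output is deterministic.
#' @export
collapse_tags <- function(reads_by_library) {
  stopifnot(is.list(reads_by_library), !is.null(names(reads_by_library)))
  libs <- names(reads_by_library)
  all_seq <- unique(unlist(reads_by_library, use.names = FALSE))
  if (is.null(all_seq) || !length(all_seq)) {
    tags <- data.frame(tag_id = character(0), sequence = character(0),
                       length = integer(0), stringsAsFactors = FALSE)
    for (lib in libs) tags[[lib]] <- integer(0)
    tags$total <- integer(0)
    attr(tags, "libraries") <- libs
    return(tags)
  }
  counts <- vapply(reads_by_library, function(r) {
    tabulate(match(r, all_seq), nbins = length(all_seq))
  }, integer(length(all_seq)))
  counts <- matrix(counts, nrow = length(all_seq),
                   dimnames = list(NULL, libs))
  total <- rowSums(counts)
  ord <- order(-total, all_seq)
  tags <- data.frame(tag_id = sprintf("tag%05d", seq_along(all_seq)),
                     sequence = all_seq[ord],
                     length = nchar(all_seq[ord]),
                     stringsAsFactors = FALSE)
  tags <- cbind(tags, as.data.frame(counts[ord, , drop = FALSE]))
  tags$total <- total[ord]
  attr(tags, "libraries") <- libs
  tags
}

tag_libraries <- function(tags) {
  libs <- attr(tags, "libraries")
  if (is.null(libs)) {
    fixed <- c("tag_id", "sequence", "length", "total", "annotation")
    libs <- setdiff(colnames(tags), fixed)
  }
  libs
}

tag_counts <- function(tags) {
  libs <- tag_libraries(tags)
  as.matrix(tags[, libs, drop = FALSE])
}

#' Map tags to a genome by exact matching on both strands
#'
#' Exact matching through a per-width k-mer index of the genome; all hits
#' of multi-mapping tags are recorded.
#'
#' @param sequences character vector of unique tag sequences.
#' @param genome named character vector of chromosome sequences.
#' @return data.frame `tag` (index into `sequences`), `chrom`, `start`,
#'   `end` (1-based inclusive) and `strand`; one row per hit, all hits kept.
#' @export
map_tags <- function(sequences, genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  out <- list()
  widths <- sort(unique(nchar(sequences)))
  for (ci in seq_along(genome)) {
    chrom_seq <- genome[[ci]]
    n <- nchar(chrom_seq)
    for (w in widths) {
      if (w > n) next
      idx <- which(nchar(sequences) == w)
      kmer <- substring(chrom_seq, 1:(n - w + 1L), w:n)
      for (strand in c("+", "-")) {
        qry <- if (strand == "+") sequences[idx] else revcomp(sequences[idx])
        m <- match(kmer, qry)
        pos <- which(!is.na(m))
        if (!length(pos)) next
        out[[length(out) + 1L]] <- data.frame(
          tag = idx[m[pos]], chrom = names(genome)[ci],
          start = pos, end = pos + w - 1L, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(tag = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$tag, res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

match_tags_to_refs <- function(sequences, refs) {
  # TRUE where a tag (either strand) is an exact substring of any reference
  hit <- logical(length(sequences))
  if (!length(refs)) return(hit)
  widths <- sort(unique(nchar(sequences)))
  for (r in c(refs, revcomp(refs))) {
    n <- nchar(r)
    for (w in widths) {
      if (w > n) next
      idx <- which(!hit & nchar(sequences) == w)
      if (!length(idx)) next
      kmer <- unique(substring(r, 1:(n - w + 1L), w:n))
      hit[idx] <- sequences[idx] %in% kmer
    }
  }
  hit
}

overlaps_intervals <- function(hits, intervals) {
  if (!nrow(hits) || is.null(intervals) || !nrow(intervals)) {
    return(logical(nrow(hits)))
  }
  q <- GenomicRanges::GRanges(hits$chrom, IRanges::IRanges(hits$start, hits$end))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(intervals$start, intervals$end))
  IRanges::overlapsAny(q, s)
}

#' Annotate tags against non-coding RNA classes, repeats and gene models
#'
#' Each tag receives exactly one class, the first match in the fixed
#' priority order rRNA, scRNA, snoRNA, snRNA, tRNA, repeat, mRNA_fragment,
#' candidate_sRNA. Non-coding classes are matched by exact substring on
#' either strand; repeat and mRNA_fragment require a genome hit overlapping
#' the corresponding interval set. Only `candidate_sRNA` tags proceed to
#' miRNA identification (the pipeline matches known miRNAs beforehand so
#' catalog miRNAs overlapping gene models are not removed as degradation
#' fragments).
#'
#' @param tags tag table from [collapse_tags()].
#' @param refs list with character vectors `rRNA`, `scRNA`, `snoRNA`,
#'   `snRNA`, `tRNA` (all required, possibly empty), and optional interval
#'   data.frames `repeats` and `genes` (`chrom`, `start`, `end`).
#' @param hits optional precomputed genome hits from [map_tags()]; required
#'   for repeat/mRNA_fragment classes when intervals are supplied.
#' @return `tags` with an `annotation` column added.
#' @export
annotate_tags <- function(tags, refs, hits = NULL) {
  needed <- c("rRNA", "scRNA", "snoRNA", "snRNA", "tRNA")
  missing <- setdiff(needed, names(refs))
  if (length(missing)) {
    stop("missing reference class(es): ", paste(missing, collapse = ", "))
  }
  ann <- rep(NA_character_, nrow(tags))
  for (cls in needed) {
    m <- match_tags_to_refs(tags$sequence, refs[[cls]])
    ann[is.na(ann) & m] <- cls
  }
  if (!is.null(hits) && nrow(hits)) {
    for (cls in c("repeat", "mRNA_fragment")) {
      ivl <- if (cls == "repeat") refs$repeats else refs$genes
      if (is.null(ivl) || !nrow(ivl)) next
      ov <- overlaps_intervals(hits, ivl)
      tag_ov <- unique(hits$tag[ov])
      ann[seq_len(nrow(tags)) %in% tag_ov & is.na(ann)] <- cls
    }
  }
  ann[is.na(ann)] <- "candidate_sRNA"
  tags$annotation <- ann
  tags
}

#' Per-library length distribution and summary statistics
#'
#' Computes the count-weighted tag length histogram (18-30 nt), the ratio of
#' 24-nt to 21-nt tag abundance, and the fraction of clean reads with at
#' least one exact genome hit.
#'
#' @param tags tag table from [collapse_tags()].
#' @param clean_stats optional named list of per-library cleaning stats from
#'   [clean_reads()] (adds raw/clean read counts).
#' @param hits optional genome hits from [map_tags()] (adds
#'   `mapped_fraction`).
#' @param min_len,max_len histogram support.
#' @return data.frame, one row per library: `library`, `raw_reads`,
#'   `clean_reads`, `mapped_fraction`, `len18`..`len30`, `ratio_24_21`
#'   (`NA` when no 21-nt tags were observed).
#' @export
length_stats <- function(tags, clean_stats = NULL, hits = NULL,
                         min_len = 18L, max_len = 30L) {
  libs <- tag_libraries(tags)
  counts <- tag_counts(tags)
  lens <- min_len:max_len
  mapped <- if (!is.null(hits)) seq_len(nrow(tags)) %in% unique(hits$tag)
            else rep(NA, nrow(tags))
  rows <- lapply(libs, function(lib) {
    cnt <- counts[, lib]
    hist <- vapply(lens, function(L) sum(cnt[tags$length == L]), 0)
    names(hist) <- paste0("len", lens)
    ratio <- if (hist[["len21"]] > 0) hist[["len24"]] / hist[["len21"]]
             else NA_real_
    mf <- if (all(is.na(mapped))) NA_real_
          else if (sum(cnt) > 0) sum(cnt[mapped]) / sum(cnt) else NA_real_
    raw <- if (!is.null(clean_stats)) clean_stats[[lib]]$raw_reads else NA
    clean <- if (!is.null(clean_stats)) clean_stats[[lib]]$clean_reads
             else sum(cnt)
    cbind(data.frame(library = lib, raw_reads = raw, clean_reads = clean,
                     mapped_fraction = mf, stringsAsFactors = FALSE),
          as.data.frame(as.list(hist)),
          data.frame(ratio_24_21 = ratio))
  })
  do.call(rbind, rows)
}

#' Per-class annotation breakdown
#'
#' @param tags annotated tag table.
#' @return data.frame with one row per annotation class: unique tag count
#'   and total (count-weighted) abundance per library.
#' @export
annotation_breakdown <- function(tags) {
  stopifnot("annotation" %in% colnames(tags))
  libs <- tag_libraries(tags)
  counts <- tag_counts(tags)
  rows <- lapply(ANNOTATION_CLASSES, function(cls) {
    sel <- tags$annotation == cls
    tot <- colSums(counts[sel, , drop = FALSE])
    cbind(data.frame(class = cls, unique_tags = sum(sel),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(tot)))
  })
  do.call(rbind, rows)
}
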
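# Assignment of candidate tags to known miRNAs, new members of known
# families, and novel miRNAs.

#' Read a mature miRNA catalog from FASTA
#'
#' Headers follow the miRBase-like convention `id family species...`.
#'
#' @param path FASTA file of mature sequences.
#' @return data.frame `id`, `family`, `species`, `sequence` (DNA alphabet).
#' @export
read_mirna_catalog <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), "\\s+")
  data.frame(
    id = vapply(parts, `[`, "", 1L),
    family = vapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_, ""),
    species = vapply(parts, function(p) if (length(p) >= 3L) paste(p[-(1:2)], collapse = " ") else NA_character_, ""),
    sequence = rna2dna(as.character(x)),
    stringsAsFactors = FALSE)
}

#' Match tags to a focal-species mature miRNA catalog
#'
#' A tag is assigned to a catalog entry when it is identical to the mature
#' sequence, or identical after shifting the mature sequence by at most
#' `max_shift` nucleotides at either terminus (isomiR tolerance): either
#' sequence may be a substring of the other provided both terminal offsets
#' are within `max_shift`. Internal mismatches are never tolerated. Counts
#' of all tags assigned to an entry are summed per library; tags matching
#' several entries are assigned to all of them and flagged ambiguous.
#'
#' @param tags tag table from [collapse_tags()].
#' @param catalog catalog data.frame from [read_mirna_catalog()].
#' @param max_shift maximum terminal shift (nt).
#' @return list: `records` (one row per matched catalog entry: `mirna_id`,
#'   `family`, `class = "known"`, `mature_sequence`, per-library counts,
#'   `n_tags`, `ambiguous`), and `assignments` (`tag_id` x `mirna_id` map).
#' @export
match_known <- function(tags, catalog, max_shift = 2L) {
  stopifnot(nrow(catalog) > 0L)
  libs <- tag_libraries(tags)
  counts <- tag_counts(tags)
  assign_list <- list()
  for (k in seq_len(nrow(catalog))) {
    mature <- catalog$sequence[k]
    lm <- nchar(mature)
    # tag contains mature (tag longer), both offsets <= max_shift
    pos <- regexpr(mature, tags$sequence, fixed = TRUE)
    off_l <- pos - 1L
    off_r <- tags$length - (pos + lm - 1L)
    hit_long <- pos > 0L & off_l <= max_shift & off_r <= max_shift
    # tag is a trimmed variant of mature (tag equal or shorter)
    variants <- unique(unlist(lapply(0:max_shift, function(a) {
      vapply(0:max_shift, function(b) substr(mature, 1L + a, lm - b), "")
    })))
    variants <- variants[nchar(variants) > 0L]
    hit_short <- tags$sequence %in% variants
    hit <- which(hit_long | hit_short)
    if (length(hit)) {
      assign_list[[length(assign_list) + 1L]] <- data.frame(
        tag_id = tags$tag_id[hit], tag_row = hit,
        mirna_id = catalog$id[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(assign_list)) {
    return(list(records = NULL,
                assignments = data.frame(tag_id = character(0),
                                         mirna_id = character(0))))
  }
  assignments <- do.call(rbind, assign_list)
  dup_tags <- unique(assignments$tag_id[duplicated(assignments$tag_id)])
  recs <- lapply(split(assignments, assignments$mirna_id), function(a) {
    k <- match(a$mirna_id[1L], catalog$id)
    cnt <- colSums(counts[a$tag_row, , drop = FALSE])
    cbind(data.frame(mirna_id = catalog$id[k], family = catalog$family[k],
                     class = "known", arm = NA_character_,
                     mature_sequence = catalog$sequence[k],
                     n_tags = nrow(a),
                     ambiguous = any(a$tag_id %in% dup_tags),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(cnt)))
  })
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  attr(records, "libraries") <- libs
  list(records = records,
       assignments = assignments[, c("tag_id", "mirna_id")])
}

# vectorized minimum ungapped mismatch distance of every tag sequence to a
# catalog (length difference <= max_len_diff); returns the distance and the
# best-matching catalog row
catalog_min_dist <- function(sequences, catalog, max_len_diff = 2L) {
  n <- length(sequences)
  dist <- rep(Inf, n)
  entry <- rep(NA_integer_, n)
  lens <- nchar(sequences)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    mat <- matrix(unlist(strsplit(sequences[idx], "", fixed = TRUE)),
                  nrow = L)
    for (k in seq_len(nrow(catalog))) {
      fseq <- catalog$sequence[k]
      Fl <- nchar(fseq)
      if (abs(L - Fl) > max_len_diff) next
      if (L <= Fl) { # tag slides inside the catalog sequence
        for (off in 0:(Fl - L)) {
          pat <- strsplit(substr(fseq, off + 1L, off + L), "", fixed = TRUE)[[1L]]
          mm <- colSums(mat != pat)
          better <- mm < dist[idx]
          dist[idx][better] <- mm[better]
          entry[idx][better] <- k
        }
      } else { # catalog sequence slides inside the tag
        fv <- strsplit(fseq, "", fixed = TRUE)[[1L]]
        for (off in 0:(L - Fl)) {
          mm <- colSums(mat[(off + 1L):(off + Fl), , drop = FALSE] != fv)
          better <- mm < dist[idx]
          dist[idx][better] <- mm[better]
          entry[idx][better] <- k
        }
      }
    }
  }
  list(dist = dist, entry = entry)
}

# reads mapped inside a genomic window, in precursor coordinates
reads_in_window <- function(tags, hits, chrom, ws, we, strand) {
  sel <- hits$chrom == chrom & hits$strand == strand &
    hits$start >= ws & hits$end <= we
  h <- hits[sel, , drop = FALSE]
  if (!nrow(h)) {
    return(data.frame(tag_row = integer(0), start = integer(0),
                      end = integer(0), max_count = numeric(0)))
  }
  counts <- tag_counts(tags)
  if (strand == "+") {
    st <- h$start - ws + 1L; en <- h$end - ws + 1L
  } else {
    st <- we - h$end + 1L; en <- we - h$start + 1L
  }
  data.frame(tag_row = h$tag, start = st, end = en,
             max_count = apply(counts[h$tag, , drop = FALSE], 1L, max))
}

# Excise windows around an anchor hit, trim each to its stem-loop, refold,
# and evaluate; returns the lowest-MFE passing hairpin (or NULL). With
# `all = TRUE`, returns every evaluated trimmed candidate instead.
validate_locus <- function(genome, anchor, tags, hits, min_reads = 10L,
                           all = FALSE, ...) {
  win <- excise_precursor(genome, anchor$chrom, anchor$start, anchor$end,
                          anchor$strand)
  if (!nrow(win)) return(NULL)
  folded <- fold_rna(win$sequence)
  cand <- list()
  for (i in seq_len(nrow(win))) {
    tr <- trim_to_stemloop(folded$structure[i], win$tag_start[i],
                           win$tag_end[i])
    if (is.null(tr)) next
    if (tr[2L] - tr[1L] + 1L < 60L) next
    if (win$strand[i] == "+") {
      ps <- win$start[i] + tr[1L] - 1L; pe <- win$start[i] + tr[2L] - 1L
    } else {
      pe <- win$end[i] - tr[1L] + 1L; ps <- win$end[i] - tr[2L] + 1L
    }
    cand[[paste(ps, pe)]] <- c(ps, pe)
  }
  if (!length(cand)) return(if (all) list() else NULL)
  best <- NULL
  evals <- list()
  for (co in cand) {
    ps <- co[1L]; pe <- co[2L]
    pseq <- substr(genome[[anchor$chrom]], ps, pe)
    if (anchor$strand == "-") pseq <- revcomp(pseq)
    reads <- reads_in_window(tags, hits, anchor$chrom, ps, pe, anchor$strand)
    ev <- evaluate_hairpin(pseq, reads, min_reads = min_reads, ...)
    ev$locus <- data.frame(chrom = anchor$chrom, start = ps, end = pe,
                           strand = anchor$strand, stringsAsFactors = FALSE)
    ev$precursor <- pseq
    ev$reads <- reads
    evals[[length(evals) + 1L]] <- ev
    if (ev$pass && (is.null(best) || ev$mfe < best$mfe)) best <- ev
  }
  if (all) evals else best
}

hairpin_records <- function(hp, tags, class, family, id_prefix) {
  libs <- tag_libraries(tags)
  rows <- list()
  for (arm in c("5p", "3p")) {
    r <- if (arm == "5p") hp$arm5p else hp$arm3p
    if (is.null(r)) next
    trow <- r$tag_row[1L]
    cnt <- tag_counts(tags)[trow, , drop = TRUE]
    rows[[arm]] <- cbind(
      data.frame(mirna_id = paste0(id_prefix, "-", arm), family = family,
                 class = class, arm = arm,
                 mature_sequence = tags$sequence[trow],
                 chrom = hp$locus$chrom, start = hp$locus$start,
                 end = hp$locus$end, strand = hp$locus$strand,
                 precursor = hp$precursor, structure = hp$structure,
                 mfe = hp$mfe, mfe_per_nt = hp$mfe_per_nt, mfei = hp$mfei,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(cnt)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "libraries") <- libs
  out
}

#' Identify new members of known miRNA families by cross-species homology
#'
#' A tag qualifies when it aligns, ungapped and with at most `max_mismatch`
#' substitutions (length difference at most 2 nt), to a mature miRNA of
#' another species, and at least one of its genomic loci folds into a
#' hairpin passing all structural criteria with the tag as an arm read.
#' Both arms are reported when both carry tags. The family label is
#' inherited from the matched foreign entry.
#'
#' @param tags candidate tag table (known-miRNA tags already removed).
#' @param foreign_catalog other-species catalog from [read_mirna_catalog()].
#' @param genome named character vector of chromosomes.
#' @param hits genome hits from [map_tags()] for `tags`.
#' @param max_mismatch homology threshold.
#' @param min_reads criterion-4 threshold, passed to [evaluate_hairpin()].
#' @param ... further thresholds for [evaluate_hairpin()].
#' @return list `records` (MiRNA records as in [match_known()], plus
#'   precursor columns), `assignments`, and `rejected` (tag and reason).
#' @export
match_new_member <- function(tags, foreign_catalog, genome, hits,
                             max_mismatch = 2L, min_reads = 10L, ...) {
  records <- NULL
  assignments <- data.frame(tag_id = character(0), mirna_id = character(0))
  rejected <- data.frame(tag_id = character(0), reason = character(0))
  done_loci <- character(0)
  hom <- catalog_min_dist(tags$sequence, foreign_catalog)
  for (ti in which(hom$dist <= max_mismatch)) {
    k <- hom$entry[ti]
    th <- hits[hits$tag == ti, , drop = FALSE]
    if (!nrow(th)) {
      rejected <- rbind(rejected, data.frame(tag_id = tags$tag_id[ti],
                                             reason = "no_genomic_hit"))
      next
    }
    hp <- NULL
    for (hi in seq_len(nrow(th))) {
      hp <- validate_locus(genome, th[hi, ], tags, hits,
                           min_reads = min_reads, ...)
      if (!is.null(hp)) break
    }
    if (is.null(hp)) {
      rejected <- rbind(rejected, data.frame(tag_id = tags$tag_id[ti],
                                             reason = "no_valid_hairpin"))
      next
    }
    # the homologous tag must itself be a mature arm read
    arms <- c(hp$arm5p$tag_row, hp$arm3p$tag_row)
    if (!(ti %in% arms)) {
      rejected <- rbind(rejected, data.frame(tag_id = tags$tag_id[ti],
                                             reason = "not_mature_arm"))
      next
    }
    locus_key <- paste(hp$locus$chrom, hp$locus$start, hp$locus$end,
                       hp$locus$strand)
    if (locus_key %in% done_loci) next
    done_loci <- c(done_loci, locus_key)
    fam <- foreign_catalog$family[k]
    rec <- hairpin_records(hp, tags, "new_member", fam,
                           paste0("N-", fam))
    records <- rbind(records, rec)
    arm_rows <- c(hp$arm5p$tag_row, hp$arm3p$tag_row)
    assignments <- rbind(assignments, data.frame(
      tag_id = tags$tag_id[arm_rows], mirna_id = rec$mirna_id))
  }
  if (!is.null(records)) attr(records, "libraries") <- tag_libraries(tags)
  list(records = records, assignments = assignments, rejected = rejected)
}

# single-linkage clustering of mature sequences at <= max_mismatch
cluster_families <- function(sequences, max_mismatch = 2L) {
  n <- length(sequences)
  fam <- seq_len(n)
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (sliding_mismatch(sequences[i], sequences[j]) <= max_mismatch) {
          old <- fam[j]
          fam[fam == old] <- fam[i]
        }
      }
    }
  }
  match(fam, unique(fam))
}

#' Identify novel miRNAs from unassigned candidate tags
#'
#' Clusters genomic hits of candidate tags into loci, excises and folds
#' candidate precursor windows around each locus anchor (the most abundant
#' tag), trims to the enclosing stem-loop, and keeps the lowest-MFE window
#' passing all five hairpin criteria. Overlapping accepted loci are merged
#' (lowest MFE wins). Both arms are reported when both carry reads. Novel
#' families are formed by single-linkage clustering of mature sequences at
#' a 2-mismatch radius.
#'
#' @param tags candidate tag table (tags already assigned as known or
#'   new_member must be excluded by the caller).
#' @param genome named character vector of chromosomes.
#' @param hits genome hits from [map_tags()] for `tags`.
#' @param min_reads criterion-4 threshold.
#' @param cluster_gap maximum genomic gap (nt) joining hits into one locus.
#' @param ... further thresholds for [evaluate_hairpin()].
#' @return list `records` (novel MiRNA records with family labels
#'   `novel-fam-XX`), `hairpins` (per-locus report with criterion verdicts),
#'   `assignments`.
#' @export
call_novel <- function(tags, genome, hits, min_reads = 10L,
                       cluster_gap = 200L, ...) {
  counts <- tag_counts(tags)
  maxc <- apply(counts, 1L, max)
  h <- hits[order(hits$chrom, hits$strand, hits$start), , drop = FALSE]
  accepted <- list()
  reports <- list()
  for (key in unique(paste(h$chrom, h$strand))) {
    sub <- h[paste(h$chrom, h$strand) == key, , drop = FALSE]
    cl <- cumsum(c(1L, as.integer(sub$start[-1L] >
                                    cummax(sub$end)[-nrow(sub)] + cluster_gap)))
    for (ci in unique(cl)) {
      cs <- sub[cl == ci, , drop = FALSE]
      anchor <- cs[which.max(maxc[cs$tag]), , drop = FALSE]
      hp <- validate_locus(genome, anchor, tags, hits,
                           min_reads = min_reads, ...)
      if (is.null(hp)) next
      accepted[[length(accepted) + 1L]] <- hp
    }
  }
  if (!length(accepted)) {
    return(list(records = NULL, hairpins = NULL,
                assignments = data.frame(tag_id = character(0),
                                         mirna_id = character(0))))
  }
  # merge overlapping accepted loci: keep the lowest-MFE representative
  loci <- do.call(rbind, lapply(accepted, `[[`, "locus"))
  keep <- rep(TRUE, length(accepted))
  ord <- order(vapply(accepted, `[[`, 0, "mfe"))
  for (i in seq_along(ord)) {
    if (!keep[ord[i]]) next
    for (j in ord[-seq_len(i)]) {
      if (!keep[j]) next
      same <- loci$chrom[ord[i]] == loci$chrom[j] &&
        loci$strand[ord[i]] == loci$strand[j] &&
        loci$start[ord[i]] <= loci$end[j] && loci$end[ord[i]] >= loci$start[j]
      if (same) keep[j] <- FALSE
    }
  }
  accepted <- accepted[keep]
  matures <- vapply(accepted, function(hp) {
    tags$sequence[hp$arm5p$tag_row[1L]] # 5p mature labels the locus family
  }, "")
  fam <- cluster_families(matures)
  records <- NULL
  assignments <- NULL
  for (i in seq_along(accepted)) {
    rec <- hairpin_records(accepted[[i]], tags, "novel",
                           sprintf("novel-fam-%02d", fam[i]),
                           sprintf("novel-miR%03d", i))
    records <- rbind(records, rec)
    arm_rows <- c(accepted[[i]]$arm5p$tag_row, accepted[[i]]$arm3p$tag_row)
    assignments <- rbind(assignments, data.frame(
      tag_id = tags$tag_id[arm_rows], mirna_id = rec$mirna_id))
    v <- accepted[[i]]$verdicts
    reports[[i]] <- cbind(accepted[[i]]$locus, data.frame(
      id = sprintf("novel-miR%03d", i),
      mfe = accepted[[i]]$mfe, mfe_per_nt = accepted[[i]]$mfe_per_nt,
      mfei = accepted[[i]]$mfei, t(as.data.frame(v)),
      verdict = accepted[[i]]$pass, stringsAsFactors = FALSE))
  }
  attr(records, "libraries") <- tag_libraries(tags)
  hairpins <- do.call(rbind, reports)
  rownames(hairpins) <- NULL
  list(records = records, hairpins = hairpins, assignments = assignments)
}
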
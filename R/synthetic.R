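# Synthetic input generator with machine-readable planted truth.
#
# Hairpin loci are built by explicit reverse-complement arm design: the 3p
# star is the reverse complement of the mature's first 19 nt, giving a
# 19-pair duplex with 2-nt 3' overhangs at both ends once the star's two
# extra 3' bases and the mature's two loop-proximal bases are accounted for.
# A paired flank stem encloses the duplex so stem-loop trimming retains both
# arm reads. Every locus is then verified in genomic context with the same
# excision + folding + criterion code the caller uses, and redrawn on
# disagreement, so folding-engine idiosyncrasies cannot silently break the
# planted truth. Decoy loci violate exactly one criterion each.

SYNTH_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"
SYNTH_LIBRARIES <- data.frame(
  library = c("NF1NT", "NF1HT", "YF1NT", "YF1HT"),
  genotype = c("tolerant", "tolerant", "sensitive", "sensitive"),
  condition = c("NT", "HT", "NT", "HT"),
  stringsAsFactors = FALSE)

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

# bases that can pair (Watson-Crick or G-U wobble) with b
pairing_partners <- function(b) {
  switch(b, A = "T", C = "G", G = c("C", "T"), T = c("A", "G"))
}

draw_seq <- function(n, gc, forbid_seed = NULL, max_a = 0.75) {
  for (i in 1:200) {
    s <- random_dna(n, gc)
    if (!is.null(forbid_seed) && grepl(forbid_seed, s, fixed = TRUE)) next
    a_frac <- (n - nchar(gsub("A", "", s, fixed = TRUE))) / n
    if (a_frac >= max_a) next
    return(s)
  }
  stop("could not draw a sequence with the requested composition")
}

# Assemble a precursor from designed parts. star_mismatch: positions of the
# 19-nt star complement turned into same-base non-pairs; star_insert:
# positions after which an unpairable base is inserted (asymmetric bulges).
make_scaffold <- function(mature, loop, flank, star_mismatch = integer(0),
                          star_insert = integer(0)) {
  m19 <- substr(mature, 1L, 19L)
  star <- strsplit(revcomp(m19), "", fixed = TRUE)[[1L]]
  for (j in star_mismatch) {
    star[j] <- substr(mature, 20L - j, 20L - j) # same base: no WC, no wobble
  }
  if (length(star_insert)) {
    for (j in sort(star_insert, decreasing = TRUE)) {
      near <- unique(unlist(lapply(c(19L - j, 20L - j, 21L - j), function(p) {
        if (p >= 1L && p <= 21L) pairing_partners(substr(mature, p, p))
      })))
      ins <- setdiff(BASES, near)[1L]
      star <- append(star, ins, after = j)
    }
  }
  # 3' extension of the star: two bases unable to pair with the flank bases
  # they would meet, forming the 2-nt 3' overhang below the duplex
  f_last <- substr(flank, nchar(flank), nchar(flank))
  ext <- setdiff(BASES, c(pairing_partners(f_last), "A"))[1:2]
  star <- paste(c(star, ext[c(1L, 1L)]), collapse = "")
  precursor <- paste0(flank, mature, loop, star, revcomp(flank))
  m_start <- nchar(flank) + 1L
  s_start <- nchar(flank) + nchar(mature) + nchar(loop) + 1L
  list(precursor = precursor,
       mature_5p = mature,
       mature_3p = star,
       read5 = c(m_start, m_start + nchar(mature) - 1L),
       read3 = c(s_start, s_start + nchar(star) - 1L))
}

# One hairpin design per violation class. Returns the scaffold plus the
# expected per-criterion verdicts and the read counts used for verification.
design_hairpin <- function(violated = "none") {
  counts <- c(100, 60)
  expected <- c(c1 = TRUE, c2 = TRUE, c3 = TRUE, c4 = TRUE,
                mfe = TRUE, mfei = TRUE)
  if (violated %in% c("none", "2", "4")) {
    sc <- make_scaffold(draw_seq(21L, 0.6, substr(SYNTH_ADAPTER, 1, 8)),
                        loop = draw_seq(9L, 0.2), flank = draw_seq(14L, 0.65))
    if (violated == "2") { # shift the planted 3p read one base into the loop
      sc$read3 <- sc$read3 - 1L
      sc$mature_3p <- substr(sc$precursor, sc$read3[1L], sc$read3[2L])
      expected["c2"] <- FALSE
    }
    if (violated == "4") {
      counts <- c(3, 2)
      expected["c4"] <- FALSE
    }
  } else if (violated == "1") { # 3 same-base non-pairs: 16 duplex pairs
    sc <- make_scaffold(draw_seq(21L, 0.6, substr(SYNTH_ADAPTER, 1, 8)),
                        loop = draw_seq(9L, 0.2), flank = draw_seq(20L, 0.7),
                        star_mismatch = c(5L, 9L, 13L))
    expected["c1"] <- FALSE
  } else if (violated == "3") { # two 1-nt asymmetric bulges
    sc <- make_scaffold(draw_seq(21L, 0.6, substr(SYNTH_ADAPTER, 1, 8)),
                        loop = draw_seq(9L, 0.2), flank = draw_seq(16L, 0.7),
                        star_insert = c(6L, 13L))
    expected["c3"] <- FALSE
  } else if (violated %in% c("5", "mfe", "mfei")) {
    # weak or compositionally skewed stems with a long loop diluting the
    # per-nucleotide energy; loop C content steers GC (C alone cannot pair C/A)
    if (violated == "mfe") { # weak fold but GC so low that MFEI stays high
      mature <- draw_seq(21L, 0.04)
      loop <- paste(sample(c("A", "C"), 60L, TRUE, prob = c(0.85, 0.15)),
                    collapse = "")
      flank <- draw_seq(10L, 0.05)
      expected[c("mfe")] <- FALSE
    } else if (violated == "5") { # weak fold and moderate GC: both fail
      mature <- draw_seq(21L, 0.04)
      loop <- paste(sample(c("A", "C"), 60L, TRUE, prob = c(0.45, 0.55)),
                    collapse = "")
      flank <- draw_seq(10L, 0.05)
      expected[c("mfe", "mfei")] <- FALSE
    } else { # strong GC-rich fold whose GC outruns the energy: MFEI low
      mature <- draw_seq(21L, 0.55)
      loop <- paste(sample(c("A", "C"), 60L, TRUE, prob = c(0.25, 0.75)),
                    collapse = "")
      flank <- draw_seq(12L, 0.6)
      expected["mfei"] <- FALSE
    }
    sc <- make_scaffold(mature, loop = loop, flank = flank)
  } else {
    stop("unknown violation class: ", violated)
  }
  expected <- c(expected[1:4],
                c5 = unname(expected["mfe"] && expected["mfei"]),
                expected[5:6])
  list(scaffold = sc, expected = expected, counts = counts,
       violated = violated)
}

# draw hairpin designs until the folding engine reproduces the intended
# verdict profile (construction is by reverse-complement design, but the
# realized structure is never assumed: the same fold + criterion code the
# caller uses must agree, guarding against folding-engine disagreement)
design_hairpin_verified <- function(violated = "none", max_tries = 40L) {
  for (i in seq_len(max_tries)) {
    d <- design_hairpin(violated)
    sc <- d$scaffold
    reads <- data.frame(start = c(sc$read5[1L], sc$read3[1L]),
                        end = c(sc$read5[2L], sc$read3[2L]),
                        max_count = d$counts)
    ev <- evaluate_hairpin(sc$precursor, reads)
    if (is.na(ev$reason) &&
        identical(unname(ev$verdicts), unname(d$expected))) {
      d$evaluation <- ev
      return(d)
    }
  }
  stop("could not realize a hairpin for violation class '", violated,
       "' in ", max_tries, " draws")
}

# verify one placed locus by running the caller's own excision, trimming,
# folding and evaluation at its genomic position
verify_locus_in_context <- function(genome, chrom, pos5, design, strand = "+") {
  sc <- design$scaffold
  tag_start <- pos5 + sc$read5[1L] - 1L
  tag_end <- pos5 + sc$read5[2L] - 1L
  tags <- data.frame(tag_id = c("t5", "t3"),
                     sequence = c(sc$mature_5p, sc$mature_3p),
                     length = nchar(c(sc$mature_5p, sc$mature_3p)),
                     L1 = design$counts, total = design$counts,
                     stringsAsFactors = FALSE)
  attr(tags, "libraries") <- "L1"
  hits <- data.frame(
    tag = c(1L, 2L), chrom = chrom,
    start = c(tag_start, pos5 + sc$read3[1L] - 1L),
    end = c(tag_end, pos5 + sc$read3[2L] - 1L),
    strand = strand, stringsAsFactors = FALSE)
  anchor <- hits[1L, ]
  evals <- validate_locus(genome, anchor, tags, hits, all = TRUE)
  if (!length(evals)) return(FALSE)
  passing <- Filter(function(e) e$pass, evals)
  exp_pass <- all(design$expected[c("c1", "c2", "c3", "c4", "c5")])
  if (exp_pass) {
    if (!length(passing)) return(FALSE)
    best <- passing[[which.min(vapply(passing, `[[`, 0, "mfe"))]]
    m5 <- tags$sequence[best$arm5p$tag_row[1L]]
    m3 <- tags$sequence[best$arm3p$tag_row[1L]]
    return(m5 == sc$mature_5p && m3 == sc$mature_3p)
  }
  if (length(passing)) return(FALSE) # a decoy must never pass
  # at least one candidate must reproduce the designed verdict profile
  any(vapply(evals, function(e) {
    is.na(e$reason) && identical(unname(e$verdicts),
                                 unname(design$expected))
  }, TRUE))
}

#' Generate a synthetic genome with planted hairpin loci
#'
#' Plants `n_compliant_hairpins` novel-miRNA stem-loops passing all five
#' criteria, one decoy per entry of `decoy_criteria` violating exactly that
#' criterion, `n_new_members` compliant loci whose mature arm is homologous
#' to a foreign catalog entry, and `n_known` embedded known-miRNA matures,
#' separated by random background. Each hairpin locus is verified in genomic
#' context by the same excision/folding/criterion code the identification
#' stage uses, and redrawn on disagreement.
#'
#' @param n_compliant_hairpins number of compliant novel loci.
#' @param decoy_criteria character vector over
#'   `{"1","2","3","4","5","mfe","mfei"}`; one decoy is planted per entry
#'   (`"5"` violates both energy thresholds, `"mfe"`/`"mfei"` exactly one).
#' @param n_new_members compliant loci destined for the new-member class.
#' @param n_known number of known matures embedded (and catalogued).
#' @param genome_length background genome size (nt).
#' @param gc_content background GC fraction, in (0, 1).
#' @param seed integer seed; identical seeds give identical output.
#' @param max_tries redraw budget per locus before failing.
#' @return list `genome` (named character), `features` (annotation
#'   intervals), and `truth` (planted hairpins, matures, catalogs, refs).
#' @export
generate_genome <- function(n_compliant_hairpins = 5L,
                            decoy_criteria = c("1", "2", "3", "4", "5",
                                               "mfe", "mfei"),
                            n_new_members = 2L, n_known = 9L,
                            genome_length = 50000L, gc_content = 0.45,
                            seed = 1L, max_tries = 40L) {
  stopifnot(gc_content > 0, gc_content < 1)
  with_seed(seed, {
    specs <- c(rep(list("none"), n_compliant_hairpins),
               as.list(decoy_criteria),
               rep(list("new_member"), n_new_members))
    classes <- c(rep("novel", n_compliant_hairpins),
                 rep("decoy", length(decoy_criteria)),
                 rep("new_member", n_new_members))
    n_loci <- length(specs) + n_known + 4L # +4 annotation segments
    slot <- as.integer(genome_length / (n_loci + 1L))
    if (slot < 450L) {
      stop("genome_length ", genome_length, " too small to place ", n_loci,
           " loci without overlap")
    }
    background <- random_dna(genome_length, gc_content)
    genome <- c(chr1 = background)
    known_matures <- vapply(seq_len(n_known), function(i) {
      draw_seq(21L, 0.5, substr(SYNTH_ADAPTER, 1, 8))
    }, "")

    hairpins <- NULL
    mirnas <- NULL
    place_at <- function(g, pos, s) {
      paste0(substr(g, 1L, pos - 1L), s, substr(g, pos + nchar(s), nchar(g)))
    }
    for (i in seq_along(specs)) {
      viol <- if (specs[[i]] == "new_member") "none" else specs[[i]]
      pos <- slot * i
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        d <- design_hairpin(viol)
        cand <- place_at(genome[["chr1"]], pos, d$scaffold$precursor)
        g2 <- c(chr1 = cand)
        if (verify_locus_in_context(g2, "chr1", pos, d)) {
          genome <- g2
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("placement failure: could not realize locus ", i,
             " (class ", classes[i], ", violated criterion ", viol,
             ") after ", max_tries, " tries")
      }
      sc <- d$scaffold
      id <- sprintf("locus%02d", i)
      hairpins <- rbind(hairpins, data.frame(
        locus_id = id, class = classes[i],
        violated = if (classes[i] == "decoy") specs[[i]] else "none",
        chrom = "chr1", start = pos,
        end = pos + nchar(sc$precursor) - 1L, strand = "+",
        precursor = sc$precursor,
        mature_5p = sc$mature_5p, mature_3p = sc$mature_3p,
        count_5p = d$counts[1L], count_3p = d$counts[2L],
        stringsAsFactors = FALSE))
      if (classes[i] != "decoy") {
        mirnas <- rbind(mirnas, data.frame(
          id = paste0(id, c("-5p", "-3p")), locus_id = id,
          sequence = c(sc$mature_5p, sc$mature_3p), arm = c("5p", "3p"),
          class = classes[i], stringsAsFactors = FALSE))
      }
    }
    # embed known matures and record decoy arm reads as expression rows
    for (k in seq_len(n_known)) {
      pos <- slot * (length(specs) + k)
      genome[["chr1"]] <- place_at(genome[["chr1"]], pos, known_matures[k])
      mirnas <- rbind(mirnas, data.frame(
        id = sprintf("gma-miR%03d", k), locus_id = NA_character_,
        sequence = known_matures[k], arm = NA_character_, class = "known",
        stringsAsFactors = FALSE))
    }
    # annotation segments: repeat x2, gene/exon x2 (sources of removable tags)
    seg_pos <- slot * (length(specs) + n_known + 1:4)
    features <- data.frame(
      type = c("repeat_region", "repeat_region", "gene", "gene"),
      chrom = "chr1", start = seg_pos, end = seg_pos + 399L,
      stringsAsFactors = FALSE)
    # foreign catalog: new-member matures with two substitutions
    nm <- mirnas[mirnas$class == "new_member" & mirnas$arm == "5p", ]
    foreign <- NULL
    if (nrow(nm)) {
      foreign <- data.frame(
        id = sprintf("ath-miR9%02d", seq_len(nrow(nm))),
        family = sprintf("miR9%02d", seq_len(nrow(nm))),
        species = "Arabidopsis thaliana",
        sequence = vapply(nm$sequence, function(s) {
          v <- strsplit(s, "", fixed = TRUE)[[1L]]
          for (p in c(4L, 11L)) v[p] <- setdiff(BASES, v[p])[1L]
          paste(v, collapse = "")
        }, "", USE.NAMES = FALSE),
        stringsAsFactors = FALSE)
    }
    focal <- data.frame(
      id = sprintf("gma-miR%03d", seq_len(n_known)),
      family = sprintf("miR%03d", seq_len(n_known)),
      species = "Glycine max",
      sequence = known_matures, stringsAsFactors = FALSE)
    refs <- list(
      rRNA = vapply(1:2, function(i) random_dna(600L, 0.5), ""),
      scRNA = vapply(1:2, function(i) random_dna(120L, 0.5), ""),
      snoRNA = vapply(1:2, function(i) random_dna(100L, 0.5), ""),
      snRNA = vapply(1:2, function(i) random_dna(150L, 0.5), ""),
      tRNA = vapply(1:3, function(i) random_dna(75L, 0.5), ""))
    truth <- list(seed = seed, adapter = SYNTH_ADAPTER,
                  libraries = SYNTH_LIBRARIES,
                  planted_hairpins = hairpins, planted_mirnas = mirnas,
                  focal_catalog = focal, foreign_catalog = foreign,
                  refs = refs, features = features)
    list(genome = genome, features = features, truth = truth)
  })
}

# designed per-library counts implementing the nine pattern types:
# response profiles per genotype (NT, HT)
RESPONSE_COUNTS <- list(up = c(40L, 400L), down = c(400L, 40L),
                        unchanged = c(200L, 200L),
                        on = c(0L, 300L), off = c(300L, 0L))

PATTERN_RESPONSES <- data.frame(
  pattern = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX"),
  tolerant = c("up", "up", "up", "down", "down", "down",
               "unchanged", "unchanged", "unchanged"),
  sensitive = c("up", "unchanged", "down", "down", "unchanged", "up",
                "up", "down", "unchanged"),
  stringsAsFactors = FALSE)

#' Design per-library expression for every planted miRNA
#'
#' Assigns each planted miRNA designed counts in the four libraries so that
#' all nine expression-pattern types are realized among the known miRNAs
#' (one per type, with the type II representative expressed only under HT
#' in the tolerant genotype), novel and new-member matures cycle through
#' heat-responsive patterns, star arms are expressed at a constant low
#' level (type IX), and decoy arm reads are expressed at the level their
#' violation class requires.
#'
#' @param truth truth list from [generate_genome()].
#' @return the truth list with an `expression_design` data.frame added:
#'   per-row designed counts for the four libraries, the intended
#'   `pattern_type` and an `on_off` flag.
#' @export
design_expression <- function(truth) {
  mir <- truth$planted_mirnas
  libs <- truth$libraries$library
  rows <- list()
  add <- function(id, sequence, tol, sen, pattern, on_off = FALSE) {
    cnt <- c(RESPONSE_COUNTS[[tol]], RESPONSE_COUNTS[[sen]])
    names(cnt) <- libs
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(id = id, sequence = sequence, pattern_type = pattern,
                 on_off = on_off, stringsAsFactors = FALSE),
      as.data.frame(as.list(cnt)))
  }
  known <- mir[mir$class == "known", ]
  for (i in seq_len(nrow(known))) {
    p <- PATTERN_RESPONSES[1L + (i - 1L) %% 9L, ]
    tol <- p$tolerant; on_off <- FALSE
    if (p$pattern == "II") { tol <- "on"; on_off <- TRUE }
    add(known$id[i], known$sequence[i], tol, p$sensitive, p$pattern, on_off)
  }
  resp_cycle <- PATTERN_RESPONSES[c(1, 2, 3, 4, 8), ]
  nonknown <- mir[mir$class != "known", ]
  matures <- nonknown[nonknown$arm == "5p", ]
  for (i in seq_len(nrow(matures))) {
    p <- resp_cycle[1L + (i - 1L) %% nrow(resp_cycle), ]
    add(matures$id[i], matures$sequence[i], p$tolerant, p$sensitive,
        p$pattern)
  }
  stars <- nonknown[nonknown$arm == "3p", ]
  for (i in seq_len(nrow(stars))) {
    add(stars$id[i], stars$sequence[i], "unchanged", "unchanged", "IX")
  }
  design <- do.call(rbind, rows)
  # star arms constant at 60; decoy arms at the counts their class requires
  design[design$id %in% stars$id, libs] <- 60L
  hp <- truth$planted_hairpins
  for (i in which(hp$class == "decoy")) {
    for (arm in c("5p", "3p")) {
      cnt <- if (arm == "5p") hp$count_5p[i] else hp$count_3p[i]
      design <- rbind(design, cbind(
        data.frame(id = paste0(hp$locus_id[i], "-", arm),
                   sequence = hp[[paste0("mature_", arm)]][i],
                   pattern_type = NA_character_, on_off = FALSE,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(stats::setNames(rep(cnt, 4L), libs)))))
    }
  }
  truth$expression_design <- design
  truth
}

synth_quality <- function(seqs) strrep("I", nchar(seqs))

with_adapter <- function(inserts, adapter, read_len = 40L) {
  substr(paste0(inserts, adapter), 1L, read_len)
}

random_fragments <- function(pool, n, min_len = 18L, max_len = 28L) {
  if (!n) return(character(0))
  src <- sample(pool, n, replace = TRUE)
  len <- sample(min_len:max_len, n, replace = TRUE)
  start <- vapply(nchar(src) - len, function(m) sample.int(max(m, 1L), 1L), 0L)
  substr(src, start, start + len - 1L)
}

#' Generate the four small RNA FASTQ libraries
#'
#' Samples miRNA reads multinomially from the expression design and adds
#' filler classes exercising every preprocessing filter: poly-A reads,
#' sub-18-nt inserts, low-quality reads and adapter-only reads (together
#' `noise_rate` of the library), plus non-coding RNA fragments, repeat and
#' gene-body fragments, and unmappable random background. All inserts carry
#' the 3' adapter and are written as 40-nt reads.
#'
#' @param truth truth list from [design_expression()].
#' @param genome named character vector from [generate_genome()].
#' @param depth_per_library total raw reads per library.
#' @param noise_rate fraction of reads in the four discarded filler classes.
#' @param seed integer seed.
#' @return the truth list with `libraries_reads`: per library, `sequences`
#'   and `qualities` (Phred+33), plus `designed_totals` and any depth
#'   warnings under `warnings`.
#' @export
generate_libraries <- function(truth, genome, depth_per_library = 100000L,
                               noise_rate = 0.12, seed = 1L) {
  stopifnot(!is.null(truth$expression_design))
  design <- truth$expression_design
  libs <- truth$libraries$library
  adapter <- truth$adapter
  # composition of the clean, non-miRNA remainder
  frac <- c(rRNA = 0.20, scRNA = 0.02, snoRNA = 0.02, snRNA = 0.02,
            tRNA = 0.05, repeat_frag = 0.03, mrna_frag = 0.05)
  seg <- truth$features
  rep_pool <- apply(seg[seg$type == "repeat_region", ], 1L, function(r) {
    substr(genome[[r[["chrom"]]]], as.integer(r[["start"]]),
           as.integer(r[["end"]]))
  })
  gene_pool <- apply(seg[seg$type == "gene", ], 1L, function(r) {
    substr(genome[[r[["chrom"]]]], as.integer(r[["start"]]),
           as.integer(r[["end"]]))
  })
  out <- list()
  with_seed(seed, {
    for (lib in libs) {
      d_counts <- design[[lib]]
      n_mir <- sum(d_counts)
      if (n_mir > 0L) {
        mir_counts <- as.vector(stats::rmultinom(1L, n_mir,
                                                 d_counts / n_mir))
      } else mir_counts <- integer(nrow(design))
      mir_reads <- rep(design$sequence, mir_counts)
      n_noise <- round(depth_per_library * noise_rate / 4L)
      n_class <- round(depth_per_library * frac)
      n_bg <- depth_per_library - length(mir_reads) - 4L * n_noise -
        sum(n_class)
      if (n_bg < 0L) stop("depth_per_library too small for the design")
      inserts <- c(
        mir_reads,
        random_fragments(truth$refs$rRNA, n_class[["rRNA"]]),
        random_fragments(truth$refs$scRNA, n_class[["scRNA"]]),
        random_fragments(truth$refs$snoRNA, n_class[["snoRNA"]]),
        random_fragments(truth$refs$snRNA, n_class[["snRNA"]]),
        random_fragments(truth$refs$tRNA, n_class[["tRNA"]]),
        random_fragments(rep_pool, n_class[["repeat_frag"]]),
        random_fragments(gene_pool, n_class[["mrna_frag"]]),
        vapply(seq_len(max(n_bg, 0L)),
               function(i) random_dna(sample(18:30, 1L), 0.45), ""),
        strrep("A", 20L + seq_len(n_noise) %% 6L),        # poly-A
        vapply(seq_len(n_noise),
               function(i) random_dna(sample(8:16, 1L), 0.45), ""), # short
        vapply(seq_len(n_noise),
               function(i) random_dna(21L, 0.45), ""))    # low-quality
      reads <- c(with_adapter(inserts, adapter),
                 rep(substr(adapter, 1L, 40L), n_noise))  # adapter-only
      quals <- synth_quality(reads)
      lowq_idx <- length(inserts) - n_noise + seq_len(n_noise)
      q <- quals[lowq_idx]
      substr(q, 10L, 10L) <- "#"
      quals[lowq_idx] <- q
      ord <- sample.int(length(reads))
      out[[lib]] <- list(sequences = reads[ord], qualities = quals[ord])
    }
  })
  truth$libraries_reads <- out
  truth$designed_totals <- stats::setNames(
    rep(depth_per_library, length(libs)), libs)
  # warn when a designed response cannot reach significance at this depth
  warn <- character(0)
  for (i in seq_len(nrow(design))) {
    pat <- design$pattern_type[i]
    if (is.na(pat) || pat == "IX") next
    for (g in c("tolerant", "sensitive")) {
      ls <- truth$libraries$library[truth$libraries$genotype == g]
      a <- design[[ls[1L]]][i]; b <- design[[ls[2L]]][i]
      if (a == b) next
      p <- ac_test(a, b, depth_per_library, depth_per_library)
      fc <- max((b + 1) / (a + 1), (a + 1) / (b + 1))
      if (p >= 0.05 || fc < 2) {
        warn <- c(warn, paste0(design$id[i], ": designed ", g,
                               " contrast not significant at this depth"))
      }
    }
  }
  truth$warnings <- warn
  truth
}

# ---- transcripts, target sites and the DEG table ----

mismatch_site <- function(mature, positions, gu = integer(0)) {
  # perfect complement, then disrupt at the given miRNA positions;
  # site index for miRNA position p is L + 1 - p (site written 5'->3')
  site <- strsplit(revcomp(mature), "", fixed = TRUE)[[1L]]
  L <- nchar(mature)
  for (p in positions) {
    b <- substr(mature, p, p)
    site[L + 1L - p] <- b # same base: neither Watson-Crick nor wobble
  }
  for (p in gu) { # G-U wobble: put U opposite G, or G opposite U
    b <- substr(mature, p, p)
    stopifnot(b %in% c("G", "T"))
    site[L + 1L - p] <- if (b == "G") "T" else "G"
  }
  paste(site, collapse = "")
}

#' Generate transcripts with planted target sites and the DEG table
#'
#' Embeds, for selected planted miRNAs, target sites that pass all six
#' rules (perfect complements), plus one site per rule violating exactly
#' that rule, and writes a gene-level differential-expression table with
#' anti-correlated, concordant and below-cutoff partners so the
#' negative-regulation join is fully exercised. One transcript carries
#' sites for two different miRNAs.
#'
#' @param truth truth list from [design_expression()].
#' @param n_transcripts number of transcripts (>= number of planted sites).
#' @param transcript_length transcript length (nt).
#' @param seed integer seed.
#' @return truth with `transcripts` (named character),
#'   `planted_target_sites` (including intended rule verdicts),
#'   `deg_design` and `expected_edges` added.
#' @export
generate_transcripts_and_degs <- function(truth, n_transcripts = 50L,
                                          transcript_length = 500L,
                                          seed = 1L) {
  design <- truth$expression_design
  stopifnot(n_transcripts >= 15L, transcript_length >= 250L)
  with_seed(seed, {
    genes <- sprintf("Gene%04d", seq_len(n_transcripts))
    tx <- vapply(genes, function(g) random_dna(transcript_length, 0.45), "")
    names(tx) <- paste0(genes, ".1")
    known <- design[grepl("^gma-", design$id), ]
    sites <- NULL
    deg <- NULL
    edges <- NULL
    plant <- function(tx, gene_i, mirna_row, site_seq, pos, kind, verdicts) {
      tid <- paste0(genes[gene_i], ".1")
      if (nchar(site_seq) + pos - 1L > nchar(tx[[tid]])) {
        stop("transcript ", tid, " shorter than the planted site window")
      }
      substr(tx[[tid]], pos, pos + nchar(site_seq) - 1L) <- site_seq
      sites <<- rbind(sites, cbind(
        data.frame(mirna_id = mirna_row$id, transcript_id = tid,
                   gene_id = genes[gene_i], start = pos, kind = kind,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(verdicts))))
      tx
    }
    all_pass <- stats::setNames(as.list(rep(TRUE, 6L)), paste0("r", 1:6))
    # anti-correlated targets for the first four heat-responsive known DEMs:
    # miRNA direction per genotype comes from the designed pattern
    responsive <- known[!known$pattern_type %in% "IX", ][1:4, ]
    gi <- 1L
    for (i in seq_len(nrow(responsive))) {
      m <- responsive[i, ]
      pr <- PATTERN_RESPONSES[PATTERN_RESPONSES$pattern == m$pattern_type, ]
      # gene moves opposite to the tolerant-genotype response when present,
      # else opposite to the sensitive response
      mdir <- if (pr$tolerant != "unchanged") pr$tolerant else pr$sensitive
      gdir <- if (mdir == "up") -1 else 1
      lfc <- gdir * 1.2
      tx <- plant(tx, gi, m, revcomp(m$sequence), 100L, "edge", all_pass)
      deg <- rbind(deg, data.frame(gene_id = genes[gi], log2fc = lfc,
                                   direction = ifelse(lfc > 0, "up", "down"),
                                   stringsAsFactors = FALSE))
      for (g in c("tolerant", "sensitive")) {
        r <- if (g == "tolerant") pr$tolerant else pr$sensitive
        if (r != "unchanged" && r != ifelse(lfc > 0, "up", "down")) {
          edges <- rbind(edges, data.frame(
            mirna_id = m$id, gene_id = genes[gi], contrast = g,
            stringsAsFactors = FALSE))
        }
      }
      gi <- gi + 1L
    }
    # one gene targeted by two DEMs simultaneously
    two <- known[known$pattern_type %in% c("I"), ][1L, ]
    two2 <- known[known$pattern_type %in% c("III"), ][1L, ]
    tx <- plant(tx, gi, two, revcomp(two$sequence), 80L, "edge", all_pass)
    tx <- plant(tx, gi, two2, revcomp(two2$sequence), 200L, "edge", all_pass)
    deg <- rbind(deg, data.frame(gene_id = genes[gi], log2fc = -1.5,
                                 direction = "down", stringsAsFactors = FALSE))
    edges <- rbind(edges,
                   data.frame(mirna_id = two$id, gene_id = genes[gi],
                              contrast = c("tolerant", "sensitive")),
                   data.frame(mirna_id = two2$id, gene_id = genes[gi],
                              contrast = "tolerant"))
    gi <- gi + 1L
    # concordant pair (no edge) and below-cutoff pair (no edge)
    conc <- known[known$pattern_type == "I", ][1L, ]
    tx <- plant(tx, gi, conc, revcomp(conc$sequence), 150L, "concordant",
                all_pass)
    deg <- rbind(deg, data.frame(gene_id = genes[gi], log2fc = 1.4,
                                 direction = "up", stringsAsFactors = FALSE))
    gi <- gi + 1L
    weak <- known[known$pattern_type == "IV", ][1L, ]
    tx <- plant(tx, gi, weak, revcomp(weak$sequence), 150L, "below_cutoff",
                all_pass)
    deg <- rbind(deg, data.frame(gene_id = genes[gi], log2fc = 0.4,
                                 direction = "up", stringsAsFactors = FALSE))
    gi <- gi + 1L
    # one decoy site per target rule, violating exactly that rule (r6 decoys
    # are verified against the duplex engine and retried across mismatch
    # placements)
    rule_mods <- list(
      r1 = list(pos = c(13L, 15L, 17L, 19L, 21L), gu = integer(0)),
      r2 = list(pos = c(14L, 15L, 16L), gu = integer(0)),
      r3 = list(pos = c(5L, 6L), gu = integer(0)),
      r4 = list(pos = 10L, gu = integer(0)),
      r5 = list(pos = c(2L, 4L, 6L), gu = integer(0)))
    host <- known[known$pattern_type == "I", ][1L, ]
    for (rn in names(rule_mods)) {
      site <- mismatch_site(host$sequence, rule_mods[[rn]]$pos)
      st <- pair_states(host$sequence, site)
      v <- apply_rules(st)
      r6v <- mfe_ratio(host$sequence, site)$r6
      verd <- stats::setNames(as.list(c(v$r1, v$r2, v$r3, v$r4, v$r5, r6v)),
                              paste0("r", 1:6))
      tx <- plant(tx, gi, host, site, 120L, paste0("violates_", rn), verd)
      gi <- gi + 1L
    }
    # r6 decoy: passes r1-r5 but loses too much duplex energy
    r6_done <- FALSE
    for (posset in list(c(13L, 15L, 17L), c(13L, 15L, 17L, 19L),
                        c(14L, 16L, 18L, 20L))) {
      site <- mismatch_site(host$sequence, posset)
      st <- pair_states(host$sequence, site)
      v <- apply_rules(st)
      if (!(v$r1 && v$r2 && v$r3 && v$r4 && v$r5)) next
      r6 <- mfe_ratio(host$sequence, site)
      if (!r6$r6) {
        verd <- stats::setNames(as.list(c(rep(TRUE, 5L), FALSE)),
                                paste0("r", 1:6))
        tx <- plant(tx, gi, host, site, 120L, "violates_r6", verd)
        gi <- gi + 1L
        r6_done <- TRUE
        break
      }
    }
    if (!r6_done) {
      truth$warnings <- c(truth$warnings,
                          "no r6-only decoy site could be constructed")
    }
    # background DEGs with negligible fold changes
    extra <- setdiff(genes, deg$gene_id)
    deg <- rbind(deg, data.frame(
      gene_id = extra, log2fc = round(stats::rnorm(length(extra), 0, 0.2), 3),
      direction = "none", stringsAsFactors = FALSE))
    deg$direction <- ifelse(abs(deg$log2fc) < log2(1.5), "none",
                            ifelse(deg$log2fc > 0, "up", "down"))
    truth$transcripts <- tx
    truth$planted_target_sites <- sites
    truth$deg_design <- deg[order(deg$gene_id), ]
    truth$expected_edges <- edges
    truth
  })
}
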
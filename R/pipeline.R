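# Pipeline configuration, fixture assembly and end-to-end orchestration.
# Stage outputs are flat TSV/FASTA files in a run directory; a YAML config
# and a JSON manifest (engine identity, seed, config hash, record counts)
# accompany every run.

write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

write_fastq <- function(sequences, qualities, path,
                        ids = sprintf("read%07d", seq_along(sequences))) {
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qualities))
  invisible(path)
}

write_gff3 <- function(features, path) {
  gr <- GenomicRanges::GRanges(
    features$chrom, IRanges::IRanges(features$start, features$end),
    strand = if (!is.null(features$strand)) features$strand else "*",
    type = features$type,
    ID = if (!is.null(features$ID)) features$ID
         else sprintf("feat%03d", seq_len(nrow(features))))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

read_gff3_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             type = as.character(gr$type), stringsAsFactors = FALSE)
}

write_catalog_fasta <- function(catalog, path) {
  x <- Biostrings::DNAStringSet(catalog$sequence)
  names(x) <- paste(catalog$id, catalog$family, catalog$species)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Assemble a pipeline configuration
#'
#' All thresholds default to the values the analysis is anchored on: tag
#' length window 18-30 nt, miRNA fold-change cutoff 2 at alpha 0.05, hairpin
#' MFE/nt below -0.2 kcal/mol/nt and MFEI above 0.85, target-score cutoffs
#' 4 and 2.5 with strict G-U handling, duplex-MFE ratio 0.75, DEG-side
#' cutoff 1.5-fold, criterion-4 read threshold 10, pseudocount 1.
#'
#' @param genome,annotation,transcripts,deg_table,focal_catalog,foreign_catalog
#'   input file paths (FASTA / GFF3 / TSV).
#' @param fastq named character vector of FASTQ paths (names = library ids).
#' @param ncrna named list of FASTA paths for classes rRNA, scRNA, snoRNA,
#'   snRNA, tRNA.
#' @param libraries data.frame `library`, `genotype`
#'   (`tolerant`/`sensitive`), `condition` (`NT`/`HT`).
#' @param adapter 3' adapter sequence.
#' @param seed integer seed recorded in the manifest.
#' @param ... threshold overrides (see defaults in the returned object).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genome, fastq, annotation = NULL,
                            transcripts = NULL, deg_table = NULL,
                            focal_catalog = NULL, foreign_catalog = NULL,
                            ncrna = list(), libraries = SYNTH_LIBRARIES,
                            adapter = SYNTH_ADAPTER, seed = 1L, ...) {
  cfg <- list(
    genome = genome, fastq = fastq, annotation = annotation,
    transcripts = transcripts, deg_table = deg_table,
    focal_catalog = focal_catalog, foreign_catalog = foreign_catalog,
    ncrna = ncrna, libraries = libraries, adapter = adapter, seed = seed,
    min_len = 18L, max_len = 30L, min_quality = 20L, quality_cycles = 25L,
    polya_frac = 0.8,
    fc_threshold = 2, alpha = 0.05, pseudocount = 1,
    max_mfe_nt = -0.2, min_mfei = 0.85, min_reads = 10L,
    max_score = 4, seed_max_score = 2.5, min_mfe_ratio = 0.75,
    gu_strict = TRUE, deg_fc_cutoff = 1.5,
    known_max_shift = 2L, homolog_max_mismatch = 2L,
    folding_engine = folding_engine())
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  paths <- c(genome = cfg$genome, cfg$fastq, annotation = cfg$annotation,
             transcripts = cfg$transcripts, deg_table = cfg$deg_table,
             focal = cfg$focal_catalog, foreign = cfg$foreign_catalog,
             unlist(cfg$ncrna))
  missing <- paths[!is.na(paths) & !file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ",
         paste(names(missing), "=", missing, collapse = ", "))
  }
  stopifnot(all(cfg$libraries$library %in% names(cfg$fastq)))
  invisible(cfg)
}

#' Run the full pipeline
#'
#' Executes preprocessing, miRNA identification, TPM/DEM/pattern typing,
#' target prediction and network integration, writing each stage's tables
#' to `out_dir` together with the serialized configuration and a run
#' manifest. Reruns with identical config and inputs produce byte-identical
#' result tables.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @return invisibly, a list with all stage results: `tags`, `stats`,
#'   `records` (miRNA records), `expression` (counts + TPM), `dems`,
#'   `types`, `sites`, `network`, `hairpins`, `clean_stats`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_counts <- list()

  # ---- preprocess ----
  genome <- as.character(Biostrings::readDNAStringSet(cfg$genome))
  names(genome) <- sub("\\s.*", "", names(genome))
  clean <- list()
  for (lib in cfg$libraries$library) {
    cl <- clean_reads(cfg$fastq[[lib]], adapter = cfg$adapter,
                      min_quality = cfg$min_quality,
                      quality_cycles = cfg$quality_cycles,
                      min_len = cfg$min_len, max_len = cfg$max_len,
                      polya_frac = cfg$polya_frac)
    clean[[lib]] <- cl
    log_counts[[paste0("raw_", lib)]] <- cl$stats$raw_reads
    log_counts[[paste0("clean_", lib)]] <- cl$stats$clean_reads
  }
  tags <- collapse_tags(lapply(clean, `[[`, "reads"))
  hits <- map_tags(tags$sequence, genome)
  refs <- lapply(cfg$ncrna, function(p) as.character(Biostrings::readDNAStringSet(p)))
  if (!is.null(cfg$annotation)) {
    ivl <- read_gff3_intervals(cfg$annotation)
    refs$repeats <- ivl[ivl$type == "repeat_region", , drop = FALSE]
    refs$genes <- ivl[ivl$type %in% c("gene", "exon"), , drop = FALSE]
  }
  tags <- annotate_tags(tags, refs, hits)
  clean_stats <- lapply(clean, `[[`, "stats")
  stats_tbl <- length_stats(tags, clean_stats, hits,
                            cfg$min_len, cfg$max_len)
  totals <- stats::setNames(stats_tbl$clean_reads, stats_tbl$library)
  log_counts$unique_tags <- nrow(tags)

  # ---- identify ----
  focal <- read_mirna_catalog(cfg$focal_catalog)
  known <- match_known(tags, focal, max_shift = cfg$known_max_shift)
  assigned <- unique(known$assignments$tag_id)
  cand <- tags$annotation == "candidate_sRNA" & !(tags$tag_id %in% assigned)
  cand_tags <- tags[cand, , drop = FALSE]
  attr(cand_tags, "libraries") <- tag_libraries(tags)
  cand_rows <- which(cand)
  cand_hits <- hits[hits$tag %in% cand_rows, , drop = FALSE]
  cand_hits$tag <- match(cand_hits$tag, cand_rows)
  newm <- list(records = NULL,
               assignments = data.frame(tag_id = character(0),
                                        mirna_id = character(0)))
  if (!is.null(cfg$foreign_catalog)) {
    foreign <- read_mirna_catalog(cfg$foreign_catalog)
    newm <- match_new_member(cand_tags, foreign, genome, cand_hits,
                             max_mismatch = cfg$homolog_max_mismatch,
                             min_reads = cfg$min_reads,
                             max_mfe_nt = cfg$max_mfe_nt,
                             min_mfei = cfg$min_mfei)
  }
  left <- !(cand_tags$tag_id %in% newm$assignments$tag_id)
  left_tags <- cand_tags[left, , drop = FALSE]
  attr(left_tags, "libraries") <- tag_libraries(tags)
  left_rows <- which(left)
  left_hits <- cand_hits[cand_hits$tag %in% left_rows, , drop = FALSE]
  left_hits$tag <- match(left_hits$tag, left_rows)
  novel <- call_novel(left_tags, genome, left_hits,
                      min_reads = cfg$min_reads,
                      max_mfe_nt = cfg$max_mfe_nt, min_mfei = cfg$min_mfei)
  libs <- cfg$libraries$library
  rec_cols <- c("mirna_id", "family", "class", "arm", "mature_sequence", libs)
  records <- rbind(known$records[, rec_cols],
                   if (!is.null(newm$records)) newm$records[, rec_cols],
                   if (!is.null(novel$records)) novel$records[, rec_cols])
  rownames(records) <- NULL
  log_counts$known <- sum(records$class == "known")
  log_counts$new_member <- sum(records$class == "new_member")
  log_counts$novel <- sum(records$class == "novel")

  # ---- expression / DEM / pattern types ----
  counts <- as.matrix(records[, libs, drop = FALSE])
  rownames(counts) <- records$mirna_id
  tpm_mat <- tpm(counts, totals)
  expression <- cbind(records[, c("mirna_id", "class", "family")],
                      stats::setNames(as.data.frame(counts),
                                      paste0("count_", libs)),
                      stats::setNames(as.data.frame(tpm_mat),
                                      paste0("tpm_", libs)))
  dems <- list()
  for (g in unique(cfg$libraries$genotype)) {
    sel <- cfg$libraries[cfg$libraries$genotype == g, ]
    ctr <- c(sel$library[sel$condition == "NT"],
             sel$library[sel$condition == "HT"])
    dems[[g]] <- call_dem(counts, totals, ctr,
                          fc_threshold = cfg$fc_threshold,
                          alpha = cfg$alpha, pseudocount = cfg$pseudocount)
  }
  types <- classify_type(dems$tolerant, dems$sensitive)

  # ---- targets ----
  sites <- NULL
  network <- list(edges = NULL, families = NULL)
  if (!is.null(cfg$transcripts)) {
    transcripts <- as.character(Biostrings::readDNAStringSet(cfg$transcripts))
    names(transcripts) <- sub("\\s.*", "", names(transcripts))
    dem_ids <- unique(unlist(lapply(dems, function(d) {
      d$mirna_id[d$significant]
    })))
    mir_seqs <- stats::setNames(records$mature_sequence, records$mirna_id)
    mir_seqs <- mir_seqs[names(mir_seqs) %in% dem_ids]
    sites <- scan_targets(mir_seqs, transcripts, gu_strict = cfg$gu_strict,
                          check_mfe = TRUE,
                          min_mfe_ratio = cfg$min_mfe_ratio,
                          max_score = cfg$max_score,
                          seed_max_score = cfg$seed_max_score)
    log_counts$target_sites <- nrow(sites)
    if (!is.null(cfg$deg_table)) {
      deg <- read_tsv(cfg$deg_table)
      fams <- stats::setNames(records$family, records$mirna_id)
      network <- build_network(dems, sites, deg,
                               deg_fc_cutoff = cfg$deg_fc_cutoff,
                               families = fams)
      log_counts$edges <- nrow(network$edges)
    }
  }

  # ---- outputs ----
  out <- function(name) file.path(out_dir, name)
  write_tsv(stats_tbl, out("library_stats.tsv"))
  write_tsv(annotation_breakdown(tags), out("annotation_breakdown.tsv"))
  tag_fa <- stats::setNames(tags$sequence,
                            sprintf("%s_x%d", tags$tag_id, tags$total))
  write_fasta(tag_fa, out("tags.fa"))
  write_tsv(expression, out("expression.tsv"))
  for (g in names(dems)) write_tsv(dems[[g]], out(paste0("dem_", g, ".tsv")))
  write_tsv(types, out("pattern_types.tsv"))
  if (!is.null(novel$hairpins)) write_tsv(novel$hairpins,
                                          out("hairpin_report.tsv"))
  if (!is.null(novel$records)) {
    write_fasta(stats::setNames(novel$records$mature_sequence,
                                novel$records$mirna_id),
                out("mature_novel.fa"))
    prec <- novel$records[!duplicated(novel$records$precursor), ]
    write_fasta(stats::setNames(prec$precursor,
                                sub("-[35]p$", "", prec$mirna_id)),
                out("precursors_novel.fa"))
  }
  if (!is.null(sites)) write_tsv(sites, out("target_sites.tsv"))
  if (!is.null(network$edges)) {
    write_tsv(network$edges, out("edges.tsv"))
    el <- network$edges[, c("mirna_id", "gene_id")]
    utils::write.table(el, out("network_edgelist.txt"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  cfg_ser <- cfg
  class(cfg_ser) <- NULL
  cfg_ser$libraries <- as.data.frame(cfg_ser$libraries)
  yaml::write_yaml(cfg_ser, out("config.yaml"))
  manifest <- list(
    package = "heatmiR",
    version = as.character(utils::packageVersion("heatmiR")),
    folding_engine = cfg$folding_engine,
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(out("config.yaml"))),
    timestamp = format(Sys.time(), tz = "UTC"),
    record_counts = log_counts)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(tags = tags, stats = stats_tbl, clean_stats = clean_stats,
                 records = records, expression = expression,
                 totals = totals, counts = counts, dems = dems,
                 types = types, sites = sites, network = network,
                 hairpins = novel$hairpins, known = known, new_member = newm,
                 novel = novel))
}

#' Build a complete synthetic input bundle on disk
#'
#' Generates a genome with planted hairpins, the four FASTQ libraries,
#' reference catalogs and annotation, transcripts with planted target sites
#' and the DEG table, writes everything under `dir`, and returns a ready
#' [pipeline_config()] plus the ground truth.
#'
#' @param preset `"tiny"` (quick checks) or `"demo"` (the full synthetic
#'   study: about 50-kb genome, 20 hairpin loci, 4 x 100k reads, 50
#'   transcripts, all nine pattern types and all seven decoy classes).
#' @param dir output directory.
#' @param seed integer seed; the whole bundle is reproducible from it.
#' @return list `config` (a [pipeline_config()]), `truth`, `paths`.
#' @export
make_fixture <- function(preset = c("demo", "tiny"), dir = tempfile("fixture"),
                         seed = 1L) {
  preset <- match.arg(preset)
  p <- switch(preset,
    tiny = list(n_compliant = 2L, decoys = c("1", "mfe"), n_new = 1L,
                n_known = 9L, glen = 20000L, depth = 20000L, ntx = 15L),
    demo = list(n_compliant = 5L, decoys = c("1", "2", "3", "4", "5",
                                             "mfe", "mfei"),
                n_new = 2L, n_known = 9L, glen = 50000L, depth = 100000L,
                ntx = 50L))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(n_compliant_hairpins = p$n_compliant,
                         decoy_criteria = p$decoys,
                         n_new_members = p$n_new, n_known = p$n_known,
                         genome_length = p$glen, seed = seed)
  truth <- design_expression(gen$truth)
  truth <- generate_libraries(truth, gen$genome,
                              depth_per_library = p$depth, seed = seed + 1L)
  truth <- generate_transcripts_and_degs(truth, n_transcripts = p$ntx,
                                         seed = seed + 2L)
  paths <- list(genome = file.path(dir, "genome.fa"),
                annotation = file.path(dir, "annotation.gff3"),
                focal = file.path(dir, "mature_focal.fa"),
                foreign = file.path(dir, "mature_other_species.fa"),
                transcripts = file.path(dir, "transcripts.fa"),
                deg = file.path(dir, "deg_table.tsv"),
                truth = file.path(dir, "truth.json"))
  write_fasta(gen$genome, paths$genome)
  feats <- truth$features
  hp <- truth$planted_hairpins
  feats <- rbind(feats,
                 data.frame(type = "miRNA_primary_transcript",
                            chrom = hp$chrom, start = hp$start, end = hp$end,
                            stringsAsFactors = FALSE))
  write_gff3(feats, paths$annotation)
  write_catalog_fasta(truth$focal_catalog, paths$focal)
  if (!is.null(truth$foreign_catalog)) {
    write_catalog_fasta(truth$foreign_catalog, paths$foreign)
  } else paths$foreign <- NULL
  ncrna <- list()
  for (cls in names(truth$refs)) {
    fp <- file.path(dir, paste0("ref_", cls, ".fa"))
    write_fasta(stats::setNames(truth$refs[[cls]],
                                paste0(cls, seq_along(truth$refs[[cls]]))), fp)
    ncrna[[cls]] <- fp
  }
  fastq <- character(0)
  for (lib in truth$libraries$library) {
    fp <- file.path(dir, paste0(lib, ".fastq"))
    write_fastq(truth$libraries_reads[[lib]]$sequences,
                truth$libraries_reads[[lib]]$qualities, fp)
    fastq[[lib]] <- fp
  }
  write_fasta(truth$transcripts, paths$transcripts)
  write_tsv(truth$deg_design, paths$deg)
  truth_json <- truth[setdiff(names(truth), "libraries_reads")]
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  cfg <- pipeline_config(genome = paths$genome, fastq = fastq,
                         annotation = paths$annotation,
                         transcripts = paths$transcripts,
                         deg_table = paths$deg,
                         focal_catalog = paths$focal,
                         foreign_catalog = paths$foreign,
                         ncrna = ncrna, libraries = truth$libraries,
                         adapter = truth$adapter, seed = seed)
  list(config = cfg, truth = truth, paths = c(paths, list(fastq = fastq),
                                              ncrna = ncrna))
}
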
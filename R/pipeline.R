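#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline. The defaults encode
#' the reference procedure: 100-bp gap flanks, more than two agreeing
#' spanning reads to fill a gap, a 1% terminal exemption and 50-bp minimum
#' piece for zero-coverage splitting, the longest 15X of reads when a
#' genome size is known, >95% alignment rate and identity for containment
#' removal, and the 1.25-fold uniqueness margin for strict bridging.
#' Alignment-layer defaults (minimum overlap 200 bp, maximum overhang
#' 50 bp, per-stage identity floors) are this implementation's own.
#'
#' @param flank_len gap flank length (bp).
#' @param min_votes minimum count of the winning inter-flank substring.
#' @param flank_identity identity floor for the fallback flank match.
#' @param end_fraction terminal fraction exempt from splitting.
#' @param min_segment minimum split piece kept (bp).
#' @param depth_factor long-read coverage multiple retained.
#' @param rate_thresh,ident_thresh containment thresholds (strict `>`).
#' @param uniq_ratio strict-bridging best/second-best margin (> 1).
#' @param min_overlap minimum dovetail overlap (bp).
#' @param max_overhang maximum dovetail overhang (bp).
#' @param aln_min_identity_contig identity floor for contig-vs-contig
#'   alignments.
#' @param aln_min_identity_cpblr identity floor for alignments involving
#'   long reads.
#' @param min_aln_len minimum alignment block length reported (bp).
#' @param blast_task blastn task.
#' @param mode `"full"`, `"redundancy_only"` (stage 2 only, no joining) or
#'   `"no_split"` (skip coverage-based splitting).
#' @param max_iter cap on alternative easy-bridging iterations.
#' @param seed seed recorded in the run manifest.
#' @return a named list of class `patch_config`.
#' @export
patch_config <- function(flank_len = 100L, min_votes = 3L,
                         flank_identity = 0.9, end_fraction = 0.01,
                         min_segment = 50L, depth_factor = 15,
                         rate_thresh = 0.95, ident_thresh = 0.95,
                         uniq_ratio = 1.25, min_overlap = 200L,
                         max_overhang = 50L,
                         aln_min_identity_contig = 0.95,
                         aln_min_identity_cpblr = 0.90,
                         min_aln_len = 100L, blast_task = "megablast",
                         mode = c("full", "redundancy_only", "no_split"),
                         max_iter = 25L, seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(flank_len = as.integer(flank_len),
              min_votes = as.integer(min_votes),
              flank_identity = flank_identity,
              end_fraction = end_fraction,
              min_segment = as.integer(min_segment),
              depth_factor = depth_factor, rate_thresh = rate_thresh,
              ident_thresh = ident_thresh, uniq_ratio = uniq_ratio,
              min_overlap = as.integer(min_overlap),
              max_overhang = as.integer(max_overhang),
              aln_min_identity_contig = aln_min_identity_contig,
              aln_min_identity_cpblr = aln_min_identity_cpblr,
              min_aln_len = as.integer(min_aln_len),
              blast_task = blast_task, mode = mode,
              max_iter = as.integer(max_iter), seed = as.integer(seed))
  stopifnot(cfg$uniq_ratio > 1,
            cfg$rate_thresh > 0, cfg$rate_thresh <= 1,
            cfg$ident_thresh > 0, cfg$ident_thresh <= 1,
            cfg$flank_len >= 1, cfg$min_segment >= 0,
            cfg$min_overlap >= 1, cfg$max_overhang >= 0,
            cfg$end_fraction >= 0, cfg$end_fraction < 0.5)
  class(cfg) <- c("patch_config", "list")
  cfg
}

#' Run the three-stage pipeline in memory
#'
#' Executes assembly modification (gap-filling; zero-coverage splitting
#' when short reads are given), representative selection (after optionally
#' subsetting the reads to the longest 15X of the genome size) and
#' iterative connection. In `redundancy_only` mode, stage 2 runs with the
#' reads present as containment evidence but only the contig
#' representatives are emitted and no joining is attempted.
#'
#' @param contigs [seq_set] of draft contigs.
#' @param cpblrs [seq_set] of corrected long reads.
#' @param reads optional short reads ([seq_set] or file paths).
#' @param genome_size optional expected genome size (bp).
#' @param config a [patch_config()] list.
#' @return list with `records` (final assembly), `layout`, `stats`
#'   (before/after [assembly_stats()]), `gap_log`, `split_log`, `pieces`,
#'   `delineated`, `join_log`, `unused_cpblrs`, `max_repeat`,
#'   `stage2_input` (sources for layout tiles).
#' @export
patch_assembly <- function(contigs, cpblrs, reads = NULL,
                           genome_size = NULL, config = patch_config()) {
  before <- assembly_stats(contigs)
  mod <- modify_assembly(contigs, cpblrs, reads, config)
  pool_reads <- subset_cpblrs(cpblrs, genome_size, config$depth_factor)
  stage2_input <- ss_bind(mod$records, pool_reads)
  reps <- select_representatives(stage2_input,
                                 rate_thresh = config$rate_thresh,
                                 ident_thresh = config$ident_thresh,
                                 config = config)
  if (config$mode == "redundancy_only") {
    keep <- reps$representatives$origin == "contig"
    records <- as_seq_set(reps$representatives[keep, , drop = FALSE])
    layout <- lapply(seq_len(nrow(records)), function(i)
      data.frame(source_id = records$id[i], src_start = 0L,
                 src_end = records$length[i], strand = "+",
                 stringsAsFactors = FALSE))
    names(layout) <- records$id
    conn <- list(records = records, layout = layout,
                 join_log = empty_df(data.frame(
                   bridge_id = "", mode = "", outcome = "", l_id = "",
                   l_end = "", r_id = "", r_end = "", trim = 0L,
                   insert_len = 0L, new_id = "", stringsAsFactors = FALSE)),
                 unused_cpblrs = reps$representatives$id[!keep],
                 max_repeat = NA_integer_)
  } else {
    conn <- iterative_connect(reps, stage2_input, config)
  }
  list(records = conn$records, layout = conn$layout,
       stats = rbind(cbind(when = "before", before),
                     cbind(when = "after", assembly_stats(conn$records))),
       gap_log = mod$gap_log, split_log = mod$split_log,
       pieces = mod$pieces, delineated = reps$delineated,
       join_log = conn$join_log, unused_cpblrs = conn$unused_cpblrs,
       max_repeat = conn$max_repeat, stage2_input = stage2_input)
}

#' Run the pipeline on files
#'
#' File-facing driver: reads the draft assembly and long reads (FASTA or
#' FASTQ, optionally gzipped), runs [patch_assembly()] and writes the
#' output directory: `patched.fasta`, `layout.tsv` (component coordinates
#' per output sequence), `joins.tsv`, `delineated.tsv`, `stats.tsv`,
#' `gaps.tsv`, `splits.tsv` and `manifest.json` (configuration plus input
#' checksums, sufficient to reproduce the run byte-identically).
#'
#' @param assembly draft assembly path.
#' @param long_reads corrected long-read path.
#' @param reads,reads2 optional short-read FASTQ path(s).
#' @param genome_size optional expected genome size (bp).
#' @param config a [patch_config()] list.
#' @param outdir output directory (created if needed).
#' @return the [patch_assembly()] result, invisibly, with `outdir`
#'   attached.
#' @export
run_patch <- function(assembly, long_reads, reads = NULL, reads2 = NULL,
                      genome_size = NULL, config = patch_config(),
                      outdir = "patch_out") {
  contigs <- read_sequences(assembly, "contig")
  cpblrs <- read_sequences(long_reads, "cpblr")
  read_paths <- c(reads, reads2)
  res <- patch_assembly(contigs, cpblrs,
                        reads = if (length(read_paths)) read_paths else NULL,
                        genome_size = genome_size, config = config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_assembly(res$records, file.path(outdir, "patched.fasta"))
  layout_tab <- do.call(rbind, lapply(names(res$layout), function(id) {
    t <- res$layout[[id]]
    w <- t$src_end - t$src_start
    data.frame(object = id, obj_start = cumsum(c(0L, w))[seq_len(nrow(t))],
               obj_end = cumsum(w), component = t$source_id,
               comp_start = t$src_start, comp_end = t$src_end,
               strand = t$strand, stringsAsFactors = FALSE)
  }))
  utils::write.table(layout_tab, file.path(outdir, "layout.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$join_log, file.path(outdir, "joins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$delineated, file.path(outdir, "delineated.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$stats, file.path(outdir, "stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$gap_log, file.path(outdir, "gaps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$split_log, file.path(outdir, "splits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    config = unclass(config),
    inputs = list(
      assembly = list(path = assembly, md5 = tools::md5sum(assembly)[[1L]]),
      long_reads = list(path = long_reads,
                        md5 = tools::md5sum(long_reads)[[1L]]),
      reads = if (length(read_paths)) lapply(read_paths, function(p)
        list(path = p, md5 = tools::md5sum(p)[[1L]])),
      genome_size = genome_size),
    counters = list(
      gaps_filled = sum(res$gap_log$action == "filled"),
      splits = sum(res$split_log$event == "excised_zero_run"),
      removed_redundant = nrow(res$delineated),
      joins = sum(res$join_log$outcome == "applied"),
      unused_cpblrs = length(res$unused_cpblrs)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$outdir <- outdir
  invisible(res)
}
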
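# Synthetic assembly scenarios with known ground truth. The simulator
# emulates the data regime the pipeline is designed for: a microbial-scale
# genome with a handful of kb-scale repeat families, a draft assembly
# fragmented at the repeats (short-read assemblers cannot phase them), a
# ~15-20X pool of kb-scale corrected long reads with very low residual
# error, and uniform error-free short reads for coverage-based splitting.

#' Define a simulation scenario
#'
#' @param seed integer seed; all randomness derives from it.
#' @param genome_len genome length in bp.
#' @param repeat_specs data frame with columns `length`, `copies`,
#'   `identity` — one row per repeat family, copies placed at
#'   non-overlapping loci and mutated down to the target identity.
#' @param n_gap_specs data frame with columns `contig` (index into the
#'   fragmented draft) and `length` (bp masked to `N` mid-contig).
#' @param chimera_specs list of integer pairs: draft contig indices to
#'   concatenate into a chimeric contig, with a short junction spacer whose
#'   sequence exists nowhere in the genome (so real reads leave it at zero
#'   coverage).
#' @param chimera_spacer spacer length in bp (default 30).
#' @param cpblr_depth,cpblr_len_mean,cpblr_len_sd long-read fold-coverage
#'   and length distribution (normal, truncated at 500 bp and the genome
#'   length).
#' @param cpblr_error per-base substitution rate and, independently,
#'   single-base indel rate of the corrected reads (default 1e-4,
#'   i.e. 0.01%).
#' @param short_read_len,short_depth short-read length and fold-coverage;
#'   short reads are error-free by default.
#' @param short_error per-base substitution rate for short reads.
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(seed = 1L, genome_len = 200000L,
                         repeat_specs = data.frame(length = integer(),
                                                   copies = integer(),
                                                   identity = numeric()),
                         n_gap_specs = data.frame(contig = integer(),
                                                  length = integer()),
                         chimera_specs = list(), chimera_spacer = 30L,
                         cpblr_depth = 15, cpblr_len_mean = 8000,
                         cpblr_len_sd = 1500, cpblr_error = 1e-4,
                         short_read_len = 100L, short_depth = 20,
                         short_error = 0) {
  sc <- list(seed = as.integer(seed), genome_len = as.integer(genome_len),
             repeat_specs = repeat_specs, n_gap_specs = n_gap_specs,
             chimera_specs = chimera_specs,
             chimera_spacer = as.integer(chimera_spacer),
             cpblr_depth = cpblr_depth, cpblr_len_mean = cpblr_len_mean,
             cpblr_len_sd = cpblr_len_sd, cpblr_error = cpblr_error,
             short_read_len = as.integer(short_read_len),
             short_depth = short_depth, short_error = short_error)
  stopifnot(sc$cpblr_error >= 0, sc$cpblr_error <= 1,
            sc$short_error >= 0, sc$short_error <= 1,
            sc$cpblr_depth >= 0, sc$short_depth >= 0,
            all(sc$repeat_specs$length < sc$genome_len))
  class(sc) <- "sim_scenario"
  sc
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute bases at the given 1-based positions with a different base
mutate_subs <- function(seq, pos) {
  if (length(pos) == 0L) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Simulate a genome with planted repeat families
#'
#' The background is i.i.d. uniform ACGT; each repeat family is copied to
#' distinct non-overlapping loci (kept away from the genome ends) and each
#' copy mutated down to its target identity. Deterministic for a fixed
#' scenario seed.
#'
#' @param scenario a [sim_scenario()].
#' @return list with `genome` (string) and `truth` — a list carrying
#'   `repeats` (data frame `family, copy, start, end`, 0-based half-open).
#' @export
simulate_genome <- function(scenario) {
  set.seed(sub_seed(scenario$seed, 1L))
  genome <- random_dna(scenario$genome_len)
  rs <- scenario$repeat_specs
  placed <- IRanges::IRanges()
  rows <- list()
  margin <- 2000L
  for (f in seq_len(nrow(rs))) {
    unit <- random_dna(rs$length[f])
    for (cp in seq_len(rs$copies[f])) {
      ok <- FALSE
      for (try in 1:1000) {
        s <- sample.int(scenario$genome_len - rs$length[f] - 2L * margin,
                        1L) + margin
        cand <- IRanges::IRanges(start = s + 1L, end = s + rs$length[f])
        # keep loci apart so flanking anchors stay unique
        grown <- cand
        IRanges::start(grown) <- max(1L, IRanges::start(cand) - margin)
        IRanges::end(grown) <- min(scenario$genome_len,
                                   IRanges::end(cand) + margin)
        if (length(placed) == 0L ||
            !any(IRanges::overlapsAny(grown, placed))) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place repeat copies without overlap")
      placed <- c(placed, cand)
      n_mut <- round((1 - rs$identity[f]) * rs$length[f])
      copy_seq <- mutate_subs(unit, if (n_mut > 0L)
        sample.int(rs$length[f], n_mut) else integer(0))
      substr(genome, s + 1L, s + rs$length[f]) <- copy_seq
      rows[[length(rows) + 1L]] <- data.frame(family = f, copy = cp,
                                              start = s,
                                              end = s + rs$length[f])
    }
  }
  repeats <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = integer(), copy = integer(), start = integer(),
               end = integer())
  list(genome = genome, truth = list(repeats = repeats))
}

#' Fragment a genome into a draft assembly
#'
#' Cuts the genome at every repeat locus (repeat interiors are withheld,
#' emulating a short-read assembler unable to resolve them), then plants
#' N-gaps and forms chimeric contigs per the scenario. Contig placements —
#' 0-based half-open contig intervals mapped to genome intervals — are
#' recorded so downstream results can be checked against the truth.
#'
#' @param genome genome string from [simulate_genome()].
#' @param truth truth list from [simulate_genome()].
#' @param scenario a [sim_scenario()].
#' @return list with `contigs` (a [seq_set]), `truth` extended with
#'   `placements` (`contig_id, c_start, c_end, g_start, g_end, strand`) and
#'   `gaps` (`contig_id, start, end, truth_seq`).
#' @export
fragment_assembly <- function(genome, truth, scenario) {
  set.seed(sub_seed(scenario$seed, 2L))
  rep_iv <- truth$repeats
  cuts <- rep_iv[order(rep_iv$start), , drop = FALSE]
  bounds <- c(0L, as.vector(t(as.matrix(cuts[, c("start", "end")]))),
              nchar(genome))
  seg_start <- bounds[seq(1L, length(bounds), by = 2L)]
  seg_end <- bounds[seq(2L, length(bounds), by = 2L)]
  keep <- seg_end - seg_start >= 200L
  seg_start <- seg_start[keep]; seg_end <- seg_end[keep]
  ids <- sprintf("ctg%02d", seq_along(seg_start))
  seqs <- vapply(seq_along(seg_start), function(i)
    substr0(genome, seg_start[i], seg_end[i]), "")
  placements <- data.frame(contig_id = ids, c_start = 0L,
                           c_end = seg_end - seg_start,
                           g_start = seg_start, g_end = seg_end,
                           strand = "+", stringsAsFactors = FALSE)
  gaps <- data.frame(contig_id = character(), start = integer(),
                     end = integer(), truth_seq = character(),
                     stringsAsFactors = FALSE)
  gs <- scenario$n_gap_specs
  for (k in seq_len(nrow(gs))) {
    i <- gs$contig[k]
    glen <- gs$length[k]
    clen <- nchar(seqs[i])
    if (glen + 400L > clen) stop("gap does not fit in contig ", i)
    at <- (clen - glen) %/% 2L
    gaps <- rbind(gaps, data.frame(contig_id = ids[i], start = at,
                                   end = at + glen,
                                   truth_seq = substr0(seqs[i], at, at + glen),
                                   stringsAsFactors = FALSE))
    substr(seqs[i], at + 1L, at + glen) <- strrep("N", glen)
  }
  drop <- logical(length(ids))
  for (pair in scenario$chimera_specs) {
    i <- pair[1L]; j <- pair[2L]
    spacer <- random_dna(scenario$chimera_spacer)
    cid <- sprintf("chimera_%s_%s", ids[i], ids[j])
    len_i <- nchar(seqs[i])
    placements <- rbind(
      placements[!placements$contig_id %in% ids[c(i, j)], , drop = FALSE],
      data.frame(contig_id = cid, c_start = 0L, c_end = len_i,
                 g_start = seg_start[i], g_end = seg_end[i], strand = "+",
                 stringsAsFactors = FALSE),
      data.frame(contig_id = cid,
                 c_start = len_i + scenario$chimera_spacer,
                 c_end = len_i + scenario$chimera_spacer + nchar(seqs[j]),
                 g_start = seg_start[j], g_end = seg_end[j], strand = "+",
                 stringsAsFactors = FALSE))
    gaps$contig_id[gaps$contig_id %in% ids[c(i, j)]] <- cid
    seqs <- c(seqs, paste0(seqs[i], spacer, seqs[j]))
    ids <- c(ids, cid)
    drop <- c(drop, FALSE)
    drop[c(i, j)] <- TRUE
  }
  contigs <- seq_set(ids[!drop], seqs[!drop], "contig")
  truth$placements <- placements
  truth$gaps <- gaps
  list(contigs = contigs, truth = truth)
}

#' Simulate corrected long reads from a genome
#'
#' Read starts are uniform, lengths normal (truncated at 500 bp and the
#' genome length), strands uniform; substitutions and single-base indels
#' are planted independently at the scenario's residual error rate. The
#' read count is chosen to reach the requested fold-coverage.
#'
#' @param genome genome string.
#' @param scenario a [sim_scenario()].
#' @return list with `reads` (a [seq_set], origin `"cpblr"`) and
#'   `placements` (`read_id, g_start, g_end, strand`, pre-error
#'   coordinates).
#' @export
simulate_cpblrs <- function(genome, scenario) {
  set.seed(sub_seed(scenario$seed, 3L))
  glen <- nchar(genome)
  n <- round(scenario$cpblr_depth * glen / scenario$cpblr_len_mean)
  if (n == 0L) {
    return(list(reads = seq_set(origin = "cpblr"),
                placements = data.frame(read_id = character(),
                                        g_start = integer(),
                                        g_end = integer(),
                                        strand = character())))
  }
  lens <- pmin(pmax(round(stats::rnorm(n, scenario$cpblr_len_mean,
                                       scenario$cpblr_len_sd)), 500L), glen)
  starts <- vapply(lens, function(l) sample.int(glen - l + 1L, 1L) - 1L, 0L)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  ids <- sprintf("read%05d", seq_len(n))
  seqs <- character(n)
  for (i in seq_len(n)) {
    s <- substr0(genome, starts[i], starts[i] + lens[i])
    if (scenario$cpblr_error > 0) {
      s <- plant_errors(s, scenario$cpblr_error)
    }
    if (strands[i] == "-") s <- revcomp(s)
    seqs[i] <- s
  }
  list(reads = seq_set(ids, seqs, "cpblr"),
       placements = data.frame(read_id = ids, g_start = starts,
                               g_end = starts + lens, strand = strands,
                               stringsAsFactors = FALSE))
}

# substitutions, single-base insertions and deletions, each at rate e
plant_errors <- function(seq, e) {
  n <- nchar(seq)
  ns <- stats::rbinom(1L, n, e)
  seq <- mutate_subs(seq, if (ns > 0L) sample.int(n, ns) else integer(0))
  ni <- stats::rbinom(1L, n, e)
  nd <- stats::rbinom(1L, n, e)
  ch <- strsplit(seq, "")[[1L]]
  if (nd > 0L) ch <- ch[-sample.int(length(ch), nd)]
  if (ni > 0L) {
    at <- sort(sample.int(length(ch), ni))
    ins <- sample(c("A", "C", "G", "T"), ni, replace = TRUE)
    for (k in rev(seq_len(ni))) ch <- append(ch, ins[k], after = at[k])
  }
  paste(ch, collapse = "")
}

#' Simulate uniform short reads
#'
#' Error-free (by default) fixed-length single-end reads drawn uniformly
#' from the genome. Because reads come from the true genome only, any
#' engineered junction sequence in a chimeric contig is covered by no read
#' and shows up as a zero-coverage run.
#'
#' @param genome genome string (the true sequence, not the draft).
#' @param scenario a [sim_scenario()].
#' @param path optional FASTQ path to write.
#' @return a [seq_set] of reads (invisibly also written to `path` if
#'   given).
#' @export
simulate_short_reads <- function(genome, scenario, path = NULL) {
  set.seed(sub_seed(scenario$seed, 4L))
  glen <- nchar(genome)
  w <- scenario$short_read_len
  n <- round(scenario$short_depth * glen / w)
  if (n == 0L) {
    reads <- seq_set(origin = "cpblr")
  } else {
    starts <- sample.int(glen - w + 1L, n, replace = TRUE) - 1L
    strands <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i)
      substr0(genome, starts[i], starts[i] + w), "")
    if (scenario$short_error > 0) {
      nm <- stats::rbinom(n, w, scenario$short_error)
      idx <- which(nm > 0L)
      for (i in idx) seqs[i] <- mutate_subs(seqs[i], sample.int(w, nm[i]))
    }
    seqs[strands == "-"] <- revcomp(seqs[strands == "-"])
    reads <- seq_set(sprintf("sr%06d", seq_len(n)), seqs, "cpblr")
  }
  if (!is.null(path)) write_fastq(reads, path)
  invisible(reads)
}

#' Check an assembly against the true genome for misjoins
#'
#' Aligns each assembled sequence to the truth genome and searches for a
#' colinear chain of alignments — consistent strand, monotone coordinates,
#' bounded diagonal shift — covering essentially the whole sequence. A
#' sequence that no such chain covers contains a misjoin: two adjacent
#' stretches whose true genomic loci are not adjacent.
#'
#' @param records [seq_set] of assembled sequences.
#' @param genome truth genome string.
#' @param min_cover minimum fraction of a sequence a single colinear chain
#'   must cover for the sequence to count as clean (default 0.98).
#' @param max_shift maximum diagonal shift (bp) tolerated between chained
#'   alignments; junction trims and small indels stay well below it.
#' @param config a [patch_config()] list (alignment parameters).
#' @return data frame `id, length, chain_cover, clean`; zero misjoins means
#'   every `clean` is `TRUE`.
#' @export
check_misjoins <- function(records, genome, min_cover = 0.98,
                           max_shift = 2000L, config = patch_config()) {
  ref <- seq_set("genome_truth", genome, "contig")
  hits <- align(records, ref, min_len = 500L,
                min_identity = config$aln_min_identity_cpblr,
                task = config$blast_task)
  out <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    h <- hits[hits$qid == id, , drop = FALSE]
    cover <- if (nrow(h) == 0L) 0 else
      best_colinear_cover(h, max_shift) / records$length[i]
    data.frame(id = id, length = records$length[i], chain_cover = cover,
               clean = cover >= min_cover, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# heaviest colinear chain (query bp covered) over hits of one query
best_colinear_cover <- function(h, max_shift) {
  # diagonal: constant along a colinear alignment on either strand
  diag <- ifelse(h$strand == "+", h$sstart - h$qstart, h$sstart + h$qend)
  ord <- order(h$qstart, h$qend)
  h <- h[ord, , drop = FALSE]
  diag <- diag[ord]
  n <- nrow(h)
  score <- h$qend - h$qstart
  for (j in seq_len(n)) {
    for (i in seq_len(j - 1L)) {
      if (h$strand[i] != h$strand[j]) next
      if (abs(diag[j] - diag[i]) > max_shift) next
      if (h$qstart[j] < h$qstart[i]) next
      gain <- min(h$qend[j] - h$qstart[j],
                  h$qend[j] - h$qend[i])        # new query bp only
      if (gain <= 0L) next
      cand <- score[i] + gain
      if (cand > score[j]) score[j] <- cand
    }
  }
  max(score)
}
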
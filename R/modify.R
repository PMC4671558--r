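#' Locate N-gaps in a contig
#'
#' Any run of `N` characters inside a contig defines a gap. Each maximal
#' run is returned together with the `flank_len` bases immediately outside
#' it on both sides; gap-filling matches these flanks against long reads to
#' find reads that span the gap. Gaps whose available flank is shorter than
#' `flank_len`, or whose flank itself contains `N` (a neighbouring gap too
#' close by), are marked `short_flank` and skipped by [fill_gaps()].
#'
#' @param contig a one-row [seq_set] record.
#' @param flank_len flank length in bp (default 100).
#' @return data frame with columns `contig_id, start, end` (0-based
#'   half-open interval of the N-run), `left_flank, right_flank,
#'   short_flank`.
#' @export
find_gaps <- function(contig, flank_len = 100L) {
  proto <- data.frame(contig_id = "", start = 0L, end = 0L,
                      left_flank = "", right_flank = "",
                      short_flank = FALSE, stringsAsFactors = FALSE)
  m <- gregexpr("N+", contig$seq)[[1L]]
  if (m[1L] == -1L) return(empty_df(proto))
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  len <- contig$length
  out <- lapply(seq_along(start), function(i) {
    ls <- start[i] - flank_len
    re <- end[i] + flank_len
    short <- ls < 0L || re > len
    lf <- if (ls >= 0L) substr0(contig$seq, ls, start[i]) else ""
    rf <- if (re <= len) substr0(contig$seq, end[i], re) else ""
    if (!short && (grepl("N", lf, fixed = TRUE) ||
                   grepl("N", rf, fixed = TRUE))) short <- TRUE
    data.frame(contig_id = contig$id, start = start[i], end = end[i],
               left_flank = lf, right_flank = rf, short_flank = short,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fill N-gaps with the consensus of spanning long reads
#'
#' For each gap, long reads in which both gap flanks are found (on either
#' strand, the read being reverse-complemented as needed) with the right
#' flank downstream of the left are "spanning". The substring of each
#' spanning read between the two flanks is extracted and the substrings are
#' grouped by exact equality; the N-run is replaced by the most frequent
#' substring only if its count reaches `min_votes` and strictly exceeds the
#' runner-up. A winning empty substring closes the gap to a direct
#' junction. Ties or insufficient evidence leave the gap untouched. Gaps
#' are processed right-to-left so earlier coordinates stay valid.
#'
#' Flank matching tries an exact search first; when a flank has no exact
#' occurrence in a read, an alignment-based fallback accepts a unique match
#' of the full flank at `>= flank_identity` identity.
#'
#' @param contig a one-row [seq_set] record.
#' @param gaps gap table from [find_gaps()] on this contig.
#' @param cpblrs [seq_set] of corrected long reads.
#' @param min_votes minimum count of the winning substring (default 3,
#'   i.e. more than two occurrences).
#' @param flank_identity identity threshold for the fallback flank match.
#' @param fallback enable the alignment-based fallback (default `TRUE`).
#' @return list with `record` (the updated contig) and `log` (one row per
#'   gap: coordinates, outcome, vote counts, replacement length).
#' @export
fill_gaps <- function(contig, gaps, cpblrs, min_votes = 3L,
                      flank_identity = 0.9, fallback = TRUE) {
  log_proto <- data.frame(contig_id = "", start = 0L, end = 0L,
                          action = "", votes = 0L, runner_up = 0L,
                          spanning = 0L, replacement_len = NA_integer_,
                          stringsAsFactors = FALSE)
  if (nrow(gaps) == 0L) return(list(record = contig, log = empty_df(log_proto)))
  gaps <- gaps[order(-gaps$start), , drop = FALSE]  # right-to-left
  seqs <- c(cpblrs$seq, revcomp(cpblrs$seq))
  logs <- vector("list", nrow(gaps))
  for (g in seq_len(nrow(gaps))) {
    gap <- gaps[g, ]
    if (gap$short_flank) {
      logs[[g]] <- data.frame(contig_id = contig$id, start = gap$start,
                              end = gap$end, action = "skipped_short_flank",
                              votes = 0L, runner_up = 0L, spanning = 0L,
                              replacement_len = NA_integer_,
                              stringsAsFactors = FALSE)
      next
    }
    inter <- unlist(lapply(seqs, spanning_substring,
                           lf = gap$left_flank, rf = gap$right_flank,
                           min_ident = flank_identity, fallback = fallback))
    inter <- inter[!grepl("N", inter, fixed = TRUE)]
    action <- "unfilled"; votes <- 0L; runner <- 0L; rep_len <- NA_integer_
    if (length(inter) > 0L) {
      tab <- sort(table(inter), decreasing = TRUE)
      votes <- as.integer(tab[1L])
      runner <- if (length(tab) > 1L) as.integer(tab[2L]) else 0L
      if (votes >= min_votes && votes > runner) {
        winner <- names(tab)[1L]
        contig$seq <- paste0(substr0(contig$seq, 0L, gap$start), winner,
                             substr0(contig$seq, gap$end, contig$length))
        contig$length <- nchar(contig$seq)
        action <- "filled"
        rep_len <- nchar(winner)
      }
    }
    logs[[g]] <- data.frame(contig_id = contig$id, start = gap$start,
                            end = gap$end, action = action, votes = votes,
                            runner_up = runner, spanning = length(inter),
                            replacement_len = rep_len,
                            stringsAsFactors = FALSE)
  }
  list(record = contig, log = do.call(rbind, rev(logs)))
}

# locate both flanks in one read orientation; returns the inter-flank
# substring, or NULL if the read does not span the gap unambiguously
spanning_substring <- function(read, lf, rf, min_ident, fallback) {
  lpos <- flank_positions(read, lf, min_ident, fallback)
  if (length(lpos) != 1L) return(NULL)     # absent or ambiguous
  rpos <- flank_positions(read, rf, min_ident, fallback)
  if (length(rpos) != 1L) return(NULL)
  l_end <- lpos + nchar(lf)                # 0-based end of left flank
  if (rpos < l_end) return(NULL)           # right flank must be downstream
  substr0(read, l_end, rpos)
}

# 0-based start positions of a flank in a read: exact search, then an
# alignment fallback over the full flank length. The fallback only runs
# when a third of the flank matches the read exactly somewhere (a read
# carrying the flank with scattered errors still has long exact chunks),
# which keeps the quadratic alignment off reads that do not span the gap.
flank_positions <- function(read, flank, min_ident, fallback) {
  m <- gregexpr(flank, read, fixed = TRUE)[[1L]]
  if (m[1L] != -1L) return(as.integer(m) - 1L)
  if (!fallback) return(integer(0))
  k <- nchar(flank) %/% 3L
  anchors <- c(substr(flank, 1L, k), substr(flank, k + 1L, 2L * k),
               substr(flank, 2L * k + 1L, nchar(flank)))
  if (!any(vapply(anchors, grepl, TRUE, x = read, fixed = TRUE))) {
    return(integer(0))
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(flank), Biostrings::DNAString(read),
    type = "global-local")
  cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
  ident <- Biostrings::nmatch(pa) / cols
  if (ident < min_ident) return(integer(0))
  as.integer(Biostrings::start(Biostrings::subject(pa))) - 1L
}

#' Per-base short-read coverage of contigs
#'
#' Places each short read at every position where it matches a contig
#' exactly (either strand, full length). Reads matching several places
#' equally well contribute depth at all of them, which keeps repeat regions
#' non-zero. Paired-end files are consumed as two single-end streams.
#' Positions covered by no read get depth zero — in particular engineered
#' junctions of chimeric contigs, whose sequence exists in no real read.
#'
#' @param contigs [seq_set] of (gap-filled) contigs.
#' @param reads either a [seq_set] of reads or a character vector of one or
#'   two FASTQ/FASTA paths.
#' @return named list of integer depth vectors, one per contig, each as
#'   long as its contig.
#' @export
compute_coverage <- function(contigs, reads) {
  if (is.character(reads)) {
    reads <- do.call(ss_bind, lapply(reads, read_sequences, origin = "cpblr"))
  }
  depth <- lapply(stats::setNames(contigs$length, contigs$id),
                  function(n) integer(n))
  if (nrow(reads) == 0L) return(depth)
  widths <- unique(nchar(reads$seq))
  subj <- as_dna(contigs)
  for (w in widths) {
    sel <- reads$seq[nchar(reads$seq) == w]
    pats <- Biostrings::DNAStringSet(unique(c(sel, revcomp(sel))))
    counts <- table(c(sel, revcomp(sel)))[as.character(pats)]
    pd <- Biostrings::PDict(pats)
    for (ci in seq_len(nrow(contigs))) {
      mi <- Biostrings::matchPDict(pd, subj[[ci]])
      st <- Biostrings::startIndex(mi)
      id <- contigs$id[ci]
      for (p in seq_along(st)) {
        if (is.null(st[[p]])) next
        mult <- as.integer(counts[p])
        for (s in st[[p]]) {
          depth[[id]][s:(s + w - 1L)] <- depth[[id]][s:(s + w - 1L)] + mult
        }
      }
    }
  }
  depth
}

#' Split a contig at zero-coverage positions
#'
#' Maximal zero-depth runs are excised and the flanking pieces become
#' separate contigs (`<id>_p1`, `<id>_p2`, ...), except runs lying entirely
#' within the terminal windows of length `floor(end_fraction * length)`,
#' which are exempt (contig ends legitimately taper). Resulting pieces
#' shorter than `min_segment` are discarded and logged. A contig with no
#' interior zero run is returned unchanged under its original id.
#'
#' @param contig a one-row [seq_set] record.
#' @param depth integer depth vector, one entry per base.
#' @param end_fraction fraction of the contig length exempt at each end
#'   (default 0.01).
#' @param min_segment minimum piece length kept (default 50 bp).
#' @return list with `records` (a [seq_set] of kept pieces; possibly
#'   empty), `pieces` (data frame mapping piece ids to 0-based half-open
#'   source intervals in the input contig, including discarded ones) and
#'   `log` (one row per excised run / discarded piece).
#' @export
split_zero_coverage <- function(contig, depth, end_fraction = 0.01,
                                min_segment = 50L) {
  stopifnot(length(depth) == contig$length)
  log_proto <- data.frame(contig_id = "", event = "", start = 0L, end = 0L,
                          stringsAsFactors = FALSE)
  runs <- zero_runs(depth)
  win <- floor(end_fraction * contig$length)
  interior <- runs[!(runs$end <= win |
                     runs$start >= contig$length - win), , drop = FALSE]
  if (nrow(interior) == 0L) {
    pieces <- data.frame(piece_id = contig$id, src_start = 0L,
                         src_end = contig$length, kept = TRUE,
                         stringsAsFactors = FALSE)
    return(list(records = contig, pieces = pieces, log = empty_df(log_proto)))
  }
  bounds <- c(0L, as.vector(t(as.matrix(interior[, c("start", "end")]))),
              contig$length)
  logs <- lapply(seq_len(nrow(interior)), function(i) {
    data.frame(contig_id = contig$id, event = "excised_zero_run",
               start = interior$start[i], end = interior$end[i],
               stringsAsFactors = FALSE)
  })
  seg_start <- bounds[seq(1L, length(bounds), by = 2L)]
  seg_end <- bounds[seq(2L, length(bounds), by = 2L)]
  keep <- (seg_end - seg_start) >= min_segment & (seg_end - seg_start) > 0L
  pieces <- data.frame(piece_id = paste0(contig$id, "_p", seq_along(seg_start)),
                       src_start = seg_start, src_end = seg_end, kept = keep,
                       stringsAsFactors = FALSE)
  for (i in which(!keep)) {
    logs[[length(logs) + 1L]] <-
      data.frame(contig_id = contig$id, event = "discarded_short_piece",
                 start = seg_start[i], end = seg_end[i],
                 stringsAsFactors = FALSE)
  }
  kept <- pieces[pieces$kept, , drop = FALSE]
  records <- if (nrow(kept) == 0L) {
    empty_df(contig)
  } else {
    seq_set(kept$piece_id,
            vapply(seq_len(nrow(kept)), function(i)
              substr0(contig$seq, kept$src_start[i], kept$src_end[i]), ""),
            "contig")
  }
  list(records = as_seq_set(records), pieces = pieces,
       log = do.call(rbind, logs))
}

zero_runs <- function(depth) {
  r <- rle(depth == 0L)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  data.frame(start = start[r$values], end = end[r$values])
}

#' Run the full assembly-modification stage
#'
#' Gap-fills every contig with spanning long reads, then (when short reads
#' are supplied) computes coverage on the gap-filled contigs and splits
#' them at interior zero-coverage positions. Filling runs before coverage
#' so that real sequence, not `N` runs, is what reads are placed against.
#'
#' @param contigs [seq_set] of draft contigs.
#' @param cpblrs [seq_set] of corrected long reads.
#' @param reads optional short reads ([seq_set] or file paths); when absent
#'   the splitting step is skipped entirely.
#' @param config a [patch_config()] list.
#' @return list with `records` (modified contigs), `pieces` (piece-to-source
#'   intervals for split contigs), `gap_log`, `split_log`.
#' @export
modify_assembly <- function(contigs, cpblrs, reads = NULL,
                            config = patch_config()) {
  gap_logs <- list(); filled <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    ct <- as_seq_set(contigs[i, , drop = FALSE])
    gaps <- find_gaps(ct, config$flank_len)
    res <- fill_gaps(ct, gaps, cpblrs, min_votes = config$min_votes,
                     flank_identity = config$flank_identity)
    filled[[i]] <- res$record
    gap_logs[[i]] <- res$log
  }
  recs <- as_seq_set(do.call(rbind, filled))
  gap_log <- do.call(rbind, gap_logs)
  split_log <- empty_df(data.frame(contig_id = "", event = "", start = 0L,
                                   end = 0L, stringsAsFactors = FALSE))
  pieces <- data.frame(piece_id = recs$id, source_id = recs$id,
                       src_start = 0L, src_end = recs$length,
                       stringsAsFactors = FALSE)
  if (!is.null(reads) && config$mode != "no_split") {
    depth <- compute_coverage(recs, reads)
    out <- list(); pc <- list()
    for (i in seq_len(nrow(recs))) {
      ct <- as_seq_set(recs[i, , drop = FALSE])
      sp <- split_zero_coverage(ct, depth[[ct$id]],
                                end_fraction = config$end_fraction,
                                min_segment = config$min_segment)
      out[[i]] <- sp$records
      split_log <- rbind(split_log, sp$log)
      kept <- sp$pieces[sp$pieces$kept, , drop = FALSE]
      if (nrow(kept)) {
        pc[[i]] <- data.frame(piece_id = kept$piece_id, source_id = ct$id,
                              src_start = kept$src_start,
                              src_end = kept$src_end,
                              stringsAsFactors = FALSE)
      }
    }
    recs <- as_seq_set(do.call(rbind, out))
    pieces <- do.call(rbind, pc)
  }
  list(records = recs, pieces = pieces, gap_log = gap_log,
       split_log = split_log)
}
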
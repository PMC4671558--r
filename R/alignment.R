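#' Local alignment of two sequence sets
#'
#' Aligns every query against every subject with `blastn` and returns one
#' row per local alignment (HSP). Coordinates are 0-based half-open on the
#' forward strand of each sequence; `strand` gives the orientation of the
#' query relative to the subject. Identity is matches divided by alignment
#' columns (indels count as columns). The trivial full-length self-hit of a
#' sequence against itself is excluded; non-trivial self-hits (internal
#' repeats) are kept. Rows are ordered by `(qid, sid, qstart)`.
#'
#' @param queries,subjects [seq_set] collections; either may be empty, in
#'   which case an empty hit table is returned.
#' @param min_len minimum alignment block length (bp) to report.
#' @param min_identity minimum identity fraction in `[0, 1]`.
#' @param task blastn task; the default `"megablast"` suits the
#'   high-identity comparisons this pipeline performs.
#' @return data frame with columns `qid, sid, qstart, qend, sstart, send,
#'   strand, aln_len, identity`.
#' @export
align <- function(queries, subjects, min_len = 100L, min_identity = 0.9,
                  task = "megablast") {
  stopifnot(min_len >= 1L)
  if (nrow(queries) == 0L || nrow(subjects) == 0L) return(empty_hits())
  td <- tempfile("aln")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  qf <- file.path(td, "q.fa"); sf <- file.path(td, "s.fa")
  Biostrings::writeXStringSet(as_dna(queries), qf)
  Biostrings::writeXStringSet(as_dna(subjects), sf)
  db <- file.path(td, "db")
  rc <- system2("makeblastdb",
                c("-in", sf, "-dbtype", "nucl", "-out", db,
                  "-logfile", file.path(td, "mkdb.log")))
  if (rc != 0L) stop("makeblastdb failed")
  out <- file.path(td, "hits.tsv")
  rc <- system2("blastn",
                c("-query", qf, "-db", db, "-task", task,
                  "-dust", "no", "-soft_masking", "false",
                  "-evalue", "1e-6", "-max_target_seqs", "100000",
                  "-num_threads", "1",
                  "-outfmt",
                  shQuote("6 qseqid sseqid qstart qend sstart send pident length nident"),
                  "-out", out))
  if (rc != 0L) stop("blastn failed")
  parse_blast_tab(out, queries, subjects, min_len, min_identity)
}

empty_hits <- function() {
  data.frame(qid = character(), sid = character(),
             qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(),
             strand = character(), aln_len = integer(),
             identity = numeric(), stringsAsFactors = FALSE)
}

parse_blast_tab <- function(path, queries, subjects, min_len, min_identity) {
  if (!file.exists(path) || file.size(path) == 0L) return(empty_hits())
  h <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("qid", "sid", "qstart", "qend",
                                       "sstart", "send", "pident",
                                       "length", "nident"))
  minus <- h$sstart > h$send
  strand <- ifelse(minus, "-", "+")
  s_lo <- pmin(h$sstart, h$send) - 1L   # to 0-based half-open, fwd strand
  s_hi <- pmax(h$sstart, h$send)
  hits <- data.frame(qid = as.character(h$qid), sid = as.character(h$sid),
                     qstart = h$qstart - 1L, qend = h$qend,
                     sstart = s_lo, send = s_hi,
                     strand = strand, aln_len = h$length,
                     identity = h$nident / h$length,
                     stringsAsFactors = FALSE)
  qlen <- stats::setNames(queries$length, queries$id)
  slen <- stats::setNames(subjects$length, subjects$id)
  trivial <- hits$qid == hits$sid & hits$strand == "+" &
    hits$qstart == 0L & hits$qend == qlen[hits$qid] &
    hits$sstart == 0L & hits$send == slen[hits$sid]
  hits <- hits[!trivial & hits$aln_len >= min_len &
                 hits$identity >= min_identity, , drop = FALSE]
  hits <- hits[order(hits$qid, hits$sid, hits$qstart, hits$sstart,
                     -hits$aln_len), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Containment of one sequence within another
#'
#' Measures how much of `inner` is found in `outer`: the alignment rate is
#' the fraction of `inner` covered by the union of its aligned intervals,
#' and the identity is the alignment-length-weighted mean identity of those
#' alignments. Used by representative selection, where a sequence whose
#' major portion (rate and identity both above threshold) lies within a
#' representative is removed as redundant.
#'
#' @param inner,outer one-row [seq_set] records.
#' @param hits hit table from [align()]; only rows with `qid == inner$id`
#'   and `sid == outer$id` are used.
#' @return data frame with `inner_id, outer_id, alignment_rate, identity`.
#' @export
containment <- function(inner, outer, hits) {
  h <- hits[hits$qid == inner$id & hits$sid == outer$id, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(data.frame(inner_id = inner$id, outer_id = outer$id,
                      alignment_rate = 0, identity = 0,
                      stringsAsFactors = FALSE))
  }
  cov <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(start = h$qstart + 1L, end = h$qend))))
  data.frame(inner_id = inner$id, outer_id = outer$id,
             alignment_rate = cov / inner$length,
             identity = sum(h$identity * h$aln_len) / sum(h$aln_len),
             stringsAsFactors = FALSE)
}

#' Classify an alignment as a dovetail (end-to-end) overlap
#'
#' A proper dovetail joins a suffix of one sequence to a prefix of another
#' (after strand normalisation): the alignment must reach within
#' `max_overhang` of exactly one end of each sequence, the participating
#' ends must be strand-consistent, and the overlap must be at least
#' `min_overlap` long. Alignments internal to either sequence — including
#' containments, where one sequence lies within the other — return `NULL`.
#'
#' @param hit a one-row hit table (see [align()]); the query is sequence
#'   "a", the subject sequence "b".
#' @param a_len,b_len full lengths (bp) of the two sequences.
#' @param max_overhang maximum unaligned bp allowed beyond the alignment at
#'   a participating end.
#' @param min_overlap minimum overlap length (bp).
#' @return a one-row data frame (`a_id, b_id, a_end, b_end, overlap_len,
#'   identity, strand, a_overhang, b_overhang`) or `NULL`.
#' @export
classify_end_overlap <- function(hit, a_len, b_len, max_overhang = 50L,
                                 min_overlap = 200L) {
  if (hit$aln_len < min_overlap) return(NULL)
  a_head <- hit$qstart                 # unaligned bp before query interval
  a_tail <- a_len - hit$qend
  b_head <- hit$sstart
  b_tail <- b_len - hit$send
  a_at <- end_of(a_head, a_tail, max_overhang)
  b_at <- end_of(b_head, b_tail, max_overhang)
  if (is.null(a_at) || is.null(b_at)) return(NULL)
  ok <- if (hit$strand == "+") a_at != b_at else a_at == b_at
  if (!ok) return(NULL)
  data.frame(a_id = hit$qid, b_id = hit$sid, a_end = a_at, b_end = b_at,
             overlap_len = hit$aln_len, identity = hit$identity,
             strand = hit$strand,
             a_overhang = if (a_at == "head") a_head else a_tail,
             b_overhang = if (b_at == "head") b_head else b_tail,
             stringsAsFactors = FALSE)
}

# which single end (within max_overhang) does the alignment reach?
# both ends reachable => containment-shaped, not a dovetail
end_of <- function(head_over, tail_over, max_overhang) {
  h <- head_over <= max_overhang
  t <- tail_over <= max_overhang
  if (h && !t) "head" else if (t && !h) "tail" else NULL
}

# classify every hit in a table; returns the stacked EndOverlap rows
# augmented with the hit geometry (query = a) needed by bridging
classify_hits <- function(hits, lengths, max_overhang = 50L,
                          min_overlap = 200L) {
  out <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, , drop = FALSE]
    if (h$qid == h$sid) next
    ov <- classify_end_overlap(h, lengths[[h$qid]], lengths[[h$sid]],
                               max_overhang, min_overlap)
    if (!is.null(ov)) {
      ov$a_start <- h$qstart; ov$a_stop <- h$qend
      ov$b_start <- h$sstart; ov$b_stop <- h$send
      out[[i]] <- ov
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) {
    return(empty_df(data.frame(a_id = "", b_id = "", a_end = "", b_end = "",
                               overlap_len = 0L, identity = 0, strand = "",
                               a_overhang = 0L, b_overhang = 0L,
                               a_start = 0L, a_stop = 0L, b_start = 0L,
                               b_stop = 0L, stringsAsFactors = FALSE)))
  }
  do.call(rbind, out)
}

#' Dump a hit table as a tab-separated overlap table
#'
#' @param hits hit table from [align()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_overlap_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
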
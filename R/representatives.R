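#' Subset long reads to the longest 15X of the genome size
#'
#' When an expected genome size is known, only the longest reads whose
#' cumulative length first reaches `depth_factor` times that size are kept
#' (the read crossing the threshold is included); otherwise, or when the
#' reads fall short of the threshold, all reads are kept. Restricting the
#' pool to the longest reads keeps representative selection and bridging
#' focused on the reads most likely to span repeats.
#'
#' @param cpblrs [seq_set] of corrected long reads.
#' @param genome_size expected genome size in bp, or `NULL`.
#' @param depth_factor coverage multiple to retain (default 15).
#' @return a [seq_set] (sorted by descending length when subsetting).
#' @export
subset_cpblrs <- function(cpblrs, genome_size = NULL, depth_factor = 15) {
  if (is.null(genome_size)) return(cpblrs)
  if (genome_size <= 0) stop("genome_size must be positive")
  ord <- order(-cpblrs$length, cpblrs$id)
  x <- cpblrs[ord, , drop = FALSE]
  cum <- cumsum(as.numeric(x$length))
  thresh <- depth_factor * genome_size
  if (cum[length(cum)] < thresh) return(as_seq_set(x))
  k <- which(cum >= thresh)[1L]
  as_seq_set(x[seq_len(k), , drop = FALSE])
}

#' Greedy longest-first representative sequence selection
#'
#' Iteratively picks the longest remaining sequence as a representative and
#' removes every remaining sequence whose major portion is contained in it:
#' alignment rate and identity (see [containment()]) both strictly above
#' their thresholds. Removed ("delineated") sequences are recorded against
#' the representative that absorbed them, so bridging can later rescue them
#' as candidates. Ties in length are broken by id.
#'
#' @param sequences non-empty [seq_set] (contigs and long reads combined).
#' @param rate_thresh,ident_thresh containment thresholds (default 0.95;
#'   strict inequality).
#' @param hits optional precomputed all-vs-all hit table from [align()];
#'   computed internally when `NULL`.
#' @param config a [patch_config()] list (alignment parameters).
#' @return list with `representatives` (a [seq_set] in selection order) and
#'   `delineated` (data frame `removed_id, representative_id,
#'   alignment_rate, identity`).
#' @export
select_representatives <- function(sequences, rate_thresh = 0.95,
                                   ident_thresh = 0.95, hits = NULL,
                                   config = patch_config()) {
  stopifnot(nrow(sequences) > 0L)
  if (is.null(hits)) {
    hits <- align(sequences, sequences, min_len = config$min_aln_len,
                  min_identity = config$aln_min_identity_cpblr,
                  task = config$blast_task)
  }
  remaining <- sequences$id[order(-sequences$length, sequences$id)]
  reps <- character(0)
  delin <- list()
  while (length(remaining) > 0L) {
    rep_id <- remaining[1L]
    reps <- c(reps, rep_id)
    remaining <- remaining[-1L]
    if (length(remaining) == 0L) break
    h <- hits[hits$sid == rep_id & hits$qid %in% remaining, , drop = FALSE]
    removed <- character(0)
    for (cand in unique(h$qid)) {
      ct <- containment(ss_get(sequences, cand), ss_get(sequences, rep_id), h)
      if (ct$alignment_rate > rate_thresh && ct$identity > ident_thresh) {
        removed <- c(removed, cand)
        delin[[length(delin) + 1L]] <-
          data.frame(removed_id = cand, representative_id = rep_id,
                     alignment_rate = ct$alignment_rate,
                     identity = ct$identity, stringsAsFactors = FALSE)
      }
    }
    remaining <- setdiff(remaining, removed)
  }
  delineated <- if (length(delin)) {
    do.call(rbind, delin)
  } else {
    empty_df(data.frame(removed_id = "", representative_id = "",
                        alignment_rate = 0, identity = 0,
                        stringsAsFactors = FALSE))
  }
  list(representatives = ss_get(sequences, reps), delineated = delineated)
}
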
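# Stage 3 — iterative connection of representative sequences by long-read
# bridging: strict bridging (1.25-fold uniqueness margin), repeat-size
# estimation, easy bridging, delineated-sequence rescue and final
# end-to-end merging.

# directional view of an end-overlap table: one row per (sequence r, end of
# r, partner p, end of p), deduplicated to the best overlap per pair of
# ends, carrying the alignment intervals on both sequences
end_overlap_view <- function(ov, mirror = TRUE) {
  proto <- data.frame(rid = "", rend = "", pid = "", pend = "",
                      overlap_len = 0L, identity = 0, strand = "",
                      r_lo = 0L, r_hi = 0L, p_lo = 0L, p_hi = 0L,
                      stringsAsFactors = FALSE)
  if (nrow(ov) == 0L) return(empty_df(proto))
  a <- data.frame(rid = ov$a_id, rend = ov$a_end, pid = ov$b_id,
                  pend = ov$b_end, overlap_len = ov$overlap_len,
                  identity = ov$identity, strand = ov$strand,
                  r_lo = ov$a_start, r_hi = ov$a_stop,
                  p_lo = ov$b_start, p_hi = ov$b_stop,
                  stringsAsFactors = FALSE)
  v <- if (mirror) {
    b <- data.frame(rid = ov$b_id, rend = ov$b_end, pid = ov$a_id,
                    pend = ov$a_end, overlap_len = ov$overlap_len,
                    identity = ov$identity, strand = ov$strand,
                    r_lo = ov$b_start, r_hi = ov$b_stop,
                    p_lo = ov$a_start, p_hi = ov$a_stop,
                    stringsAsFactors = FALSE)
    rbind(a, b)
  } else a
  v <- v[order(v$rid, v$rend, v$pid, v$pend, -v$overlap_len, -v$identity), ,
         drop = FALSE]
  v <- v[!duplicated(v[, c("rid", "rend", "pid", "pend")]), , drop = FALSE]
  rownames(v) <- NULL
  v
}

# best end-overlap at one sequence end, or NULL when the best is not at
# least `ratio` times the second best (ambiguous end)
resolve_unique <- function(cands, ratio) {
  if (nrow(cands) == 0L) return(NULL)
  cands <- cands[order(-cands$overlap_len, -cands$identity, cands$pid,
                       cands$pend), , drop = FALSE]
  if (nrow(cands) >= 2L &&
      cands$overlap_len[1L] < ratio * cands$overlap_len[2L]) return(NULL)
  cands[1L, , drop = FALSE]
}

bridge_proto <- function() {
  empty_df(data.frame(bridge_id = "", mode = "", bridge_len = 0L,
                      l_id = "", l_end = "", l_ov = 0L,
                      r_id = "", r_end = "", r_ov = 0L,
                      insert = "", ins_lo = 0L, ins_hi = 0L, trim = 0L,
                      stringsAsFactors = FALSE))
}

make_bridge <- function(rid, rlen, rseq, mode, lh, rt) {
  b1e <- lh$r_hi                       # head-side alignment end on bridge
  b2s <- rt$r_lo                       # tail-side alignment start on bridge
  if (b1e <= b2s) {
    insert <- substr0(rseq, b1e, b2s); trim <- 0L
  } else {
    insert <- ""; trim <- b1e - b2s; b2s <- b1e
  }
  data.frame(bridge_id = rid, mode = mode, bridge_len = rlen,
             l_id = lh$pid, l_end = lh$pend, l_ov = lh$overlap_len,
             r_id = rt$pid, r_end = rt$pend, r_ov = rt$overlap_len,
             insert = insert, ins_lo = b1e, ins_hi = b2s, trim = trim,
             stringsAsFactors = FALSE)
}

#' Find strict bridges in a self-aligned pool
#'
#' A pool sequence qualifies as a strict bridge when each of its two ends
#' has a unique best end-to-end overlap — best overlap length at least
#' `uniq_ratio` (default 1.25) times the second best at that end — and the
#' two resolved targets are distinct, at least one of them a contig (or
#' connected sequence). Ends with no overlap disqualify the candidate;
#' ends with a single overlap are vacuously unique.
#'
#' @param pool an internal assembly pool (see [iterative_connect()]); a
#'   [seq_set] is also accepted.
#' @param config a [patch_config()] list.
#' @param overlaps optional precomputed end-overlap table (as produced by
#'   classifying an all-vs-all self-alignment); computed when `NULL`.
#' @return a bridge table, one row per emitted bridge, carrying the
#'   junction geometry (`insert`, `trim`) needed to apply it.
#' @export
find_strict_bridges <- function(pool, config = patch_config(),
                                overlaps = NULL) {
  records <- if (inherits(pool, "seq_set")) pool else pool$records
  if (is.null(overlaps)) {
    hits <- align(records, records, min_len = config$min_aln_len,
                  min_identity = config$aln_min_identity_cpblr,
                  task = config$blast_task)
    lens <- as.list(stats::setNames(records$length, records$id))
    overlaps <- classify_hits(hits, lens, config$max_overhang,
                              config$min_overlap)
  }
  v <- end_overlap_view(overlaps, mirror = TRUE)
  origin <- stats::setNames(records$origin, records$id)
  out <- list()
  for (rid in records$id) {
    he <- v[v$rid == rid & v$rend == "head", , drop = FALSE]
    te <- v[v$rid == rid & v$rend == "tail", , drop = FALSE]
    if (nrow(he) == 0L || nrow(te) == 0L) next
    lh <- resolve_unique(he, config$uniq_ratio)
    rt <- resolve_unique(te, config$uniq_ratio)
    if (is.null(lh) || is.null(rt)) next
    if (lh$pid == rt$pid) next                    # circular / same target
    if (origin[lh$pid] != "contig" && origin[rt$pid] != "contig") next
    ri <- match(rid, records$id)
    out[[length(out) + 1L]] <-
      make_bridge(rid, records$length[ri], records$seq[ri], "strict", lh, rt)
  }
  if (length(out) == 0L) return(bridge_proto())
  do.call(rbind, out)
}

#' Find easy bridges: long reads cleanly tying exactly two contigs
#'
#' A candidate read qualifies when (i) it is longer than the estimated
#' maximum repeat size and (ii) each of its ends has end-to-end overlaps to
#' exactly one contig, the two contigs being distinct — no additional
#' overlap partner is tolerated at either end. The length gate keeps
#' repeat-length reads, which could tie the wrong copies together, out of
#' the joining step.
#'
#' @param cpblr_pool [seq_set] of candidate bridging reads.
#' @param contig_pool [seq_set] of target contigs / connected sequences.
#' @param max_repeat repeat-size gate in bp (see [estimate_max_repeat()]).
#' @param config a [patch_config()] list.
#' @param overlaps optional precomputed end-overlap table (candidate reads
#'   as the "a" side).
#' @return a bridge table (`mode = "easy"`).
#' @export
find_easy_bridges <- function(cpblr_pool, contig_pool, max_repeat,
                              config = patch_config(), overlaps = NULL) {
  if (nrow(cpblr_pool) == 0L || nrow(contig_pool) == 0L) {
    return(bridge_proto())
  }
  if (is.null(overlaps)) {
    hits <- align(cpblr_pool, contig_pool, min_len = config$min_aln_len,
                  min_identity = config$aln_min_identity_cpblr,
                  task = config$blast_task)
    lens <- as.list(stats::setNames(c(cpblr_pool$length, contig_pool$length),
                                    c(cpblr_pool$id, contig_pool$id)))
    overlaps <- classify_hits(hits, lens, config$max_overhang,
                              config$min_overlap)
  }
  v <- end_overlap_view(overlaps, mirror = FALSE)
  out <- list()
  for (ri in seq_len(nrow(cpblr_pool))) {
    rid <- cpblr_pool$id[ri]
    if (cpblr_pool$length[ri] <= max_repeat) next
    he <- v[v$rid == rid & v$rend == "head", , drop = FALSE]
    te <- v[v$rid == rid & v$rend == "tail", , drop = FALSE]
    if (nrow(he) == 0L || nrow(te) == 0L) next
    if (length(unique(he$pid)) != 1L || length(unique(te$pid)) != 1L) next
    lh <- resolve_unique(he, 1)
    rt <- resolve_unique(te, 1)
    if (lh$pid == rt$pid) next
    out[[length(out) + 1L]] <-
      make_bridge(rid, cpblr_pool$length[ri], cpblr_pool$seq[ri], "easy",
                  lh, rt)
  }
  if (length(out) == 0L) return(bridge_proto())
  do.call(rbind, out)
}

#' Apply bridges to an assembly pool
#'
#' Bridges are processed in descending bridge length. A bridge is applied
#' only when both target ends are still free; applying it orients the two
#' target containers head-to-tail, fills the junction with the bridge's
#' inter-alignment substring (or, when the two target alignments overlap on
#' the bridge, trims the overlap from the shorter target), consumes the two
#' joined ends and retires the bridge sequence from the pool. Bridges whose
#' targets have meanwhile been consumed, or whose two targets already sit
#' in the same container (which would circularise it), are skipped and
#' logged.
#'
#' @param bridges a bridge table from [find_strict_bridges()] or
#'   [find_easy_bridges()].
#' @param pool an assembly pool.
#' @param config a [patch_config()] list.
#' @return list with `pool` (updated), `applied` (count) and `log` (one row
#'   per bridge with its outcome).
#' @export
apply_bridges <- function(bridges, pool, config = patch_config()) {
  log_proto <- data.frame(bridge_id = "", mode = "", outcome = "",
                          l_id = "", l_end = "", r_id = "", r_end = "",
                          trim = 0L, insert_len = 0L, new_id = "",
                          stringsAsFactors = FALSE)
  if (nrow(bridges) == 0L) {
    return(list(pool = pool, applied = 0L, log = empty_df(log_proto)))
  }
  bridges <- bridges[order(-bridges$bridge_len, bridges$bridge_id), ,
                     drop = FALSE]
  logs <- list(); applied <- 0L
  for (i in seq_len(nrow(bridges))) {
    b <- bridges[i, , drop = FALSE]
    outcome <- NULL; new_id <- ""
    if (b$bridge_id %in% pool$used ||
        (b$bridge_id %in% pool$ends$orig_id &&
         !b$bridge_id %in% pool$records$id)) {
      outcome <- "bridge_consumed"
    } else {
      L <- resolve_end(pool, b$l_id, b$l_end)
      R <- resolve_end(pool, b$r_id, b$r_end)
      if (is.null(L) || is.null(R) ||
          identical(L, "consumed") || identical(R, "consumed")) {
        outcome <- "end_consumed"
      } else if (L$container == R$container) {
        outcome <- "self_join_skipped"
      } else if (L$container == b$bridge_id || R$container == b$bridge_id) {
        outcome <- "bridge_is_target"
      } else {
        tile <- NULL
        if (nchar(b$insert) > 0L) {
          # a connected sequence acting as bridge contributes its own
          # layout slice, so every inserted base still traces to an input
          tile <- if (b$bridge_id %in% names(pool$layout)) {
            slice_tiles(pool$layout[[b$bridge_id]], b$ins_lo, b$ins_hi)
          } else {
            data.frame(source_id = b$bridge_id, src_start = b$ins_lo,
                       src_end = b$ins_hi, strand = "+",
                       stringsAsFactors = FALSE)
          }
        }
        np <- join_containers(pool, L$container, L$cend, R$container,
                              R$cend, insert_seq = b$insert,
                              insert_tile = tile,
                              trim1 = b$trim, trim2 = b$trim)
        if (is.null(np)) {
          outcome <- "trim_exceeds_target"
        } else {
          pool <- np
          new_id <- pool$new_id
          pool <- consume_bridge(pool, b$bridge_id)
          applied <- applied + 1L
          outcome <- "applied"
        }
      }
    }
    logs[[i]] <- data.frame(bridge_id = b$bridge_id, mode = b$mode,
                            outcome = outcome, l_id = b$l_id,
                            l_end = b$l_end, r_id = b$r_id,
                            r_end = b$r_end, trim = b$trim,
                            insert_len = nchar(b$insert), new_id = new_id,
                            stringsAsFactors = FALSE)
  }
  list(pool = pool, applied = applied, log = do.call(rbind, logs))
}

#' Estimate the maximum repeat size in a sequence pool
#'
#' Self-aligns the pool (all vs. all) and takes the longest alignment that
#' is neither a proper dovetail nor part of a containment relation at the
#' representative-selection thresholds; non-trivial self-hits (internal or
#' inverted duplications within one sequence) also count. This is the gate
#' easy bridging measures read lengths against: a read no longer than the
#' largest repeat cannot be trusted to tie the right copies together.
#'
#' @param records [seq_set] of pool sequences.
#' @param config a [patch_config()] list.
#' @param hits optional precomputed self-alignment hit table.
#' @return list with `max_repeat` (bp; 0 when no such alignment exists).
#' @export
estimate_max_repeat <- function(records, config = patch_config(),
                                hits = NULL) {
  stopifnot(nrow(records) >= 1L)
  if (is.null(hits)) {
    hits <- align(records, records, min_len = config$min_aln_len,
                  min_identity = config$aln_min_identity_cpblr,
                  task = config$blast_task)
  }
  if (nrow(hits) == 0L) return(list(max_repeat = 0L))
  lens <- as.list(stats::setNames(records$length, records$id))
  self <- hits$qid == hits$sid
  best <- if (any(self)) max(hits$aln_len[self]) else 0L
  inter <- hits[!self, , drop = FALSE]
  if (nrow(inter) > 0L) {
    # pair-level containment: the shorter sequence essentially inside the
    # longer disqualifies the pair (that is redundancy, not repeat)
    pairs <- unique(t(apply(inter[, c("qid", "sid")], 1L, sort)))
    contained <- character(0)
    for (k in seq_len(nrow(pairs))) {
      ii <- pairs[k, 1L]; oo <- pairs[k, 2L]
      if (lens[[ii]] > lens[[oo]]) { tmp <- ii; ii <- oo; oo <- tmp }
      ct <- containment(ss_get(records, ii), ss_get(records, oo), inter)
      if (ct$alignment_rate > config$rate_thresh &&
          ct$identity > config$ident_thresh) {
        contained <- c(contained, paste(pairs[k, 1L], pairs[k, 2L]))
      }
    }
    for (k in seq_len(nrow(inter))) {
      h <- inter[k, , drop = FALSE]
      key <- paste(sort(c(h$qid, h$sid)), collapse = " ")
      if (key %in% contained) next
      ov <- classify_end_overlap(h, lens[[h$qid]], lens[[h$sid]],
                                 config$max_overhang, config$min_overlap)
      if (!is.null(ov)) next
      best <- max(best, h$aln_len)
    }
  }
  list(max_repeat = as.integer(best))
}

#' Rescue delineated sequences as easy-bridging candidates
#'
#' Representative reads that failed to bridge are, before being discarded,
#' given a second chance through the sequences they delineated during
#' representative selection: each contained read is re-instated as an
#' easy-bridging candidate and passed through the same gates. A read with
#' ambiguous ends can delineate a shorter read whose ends are clean.
#'
#' @param unused_cpblrs ids of representative reads still unused.
#' @param delineated delineation map from [select_representatives()].
#' @param all_sequences [seq_set] holding every stage-2 input sequence.
#' @param contig_pool [seq_set] of target contigs / connected sequences.
#' @param max_repeat repeat-size gate in bp.
#' @param config a [patch_config()] list.
#' @param exclude ids never to re-instate (e.g. reads already used).
#' @return a bridge table (`mode = "easy"`).
#' @export
rescue_delineated <- function(unused_cpblrs, delineated, all_sequences,
                              contig_pool, max_repeat,
                              config = patch_config(),
                              exclude = character(0)) {
  ids <- delineated$removed_id[delineated$representative_id %in% unused_cpblrs]
  ids <- setdiff(ids, exclude)
  if (length(ids) == 0L) return(bridge_proto())
  cands <- ss_get(all_sequences, ids)
  cands <- as_seq_set(cands[cands$origin == "cpblr", , drop = FALSE])
  if (nrow(cands) == 0L) return(bridge_proto())
  find_easy_bridges(cands, contig_pool, max_repeat, config)
}

#' Merge sequences sharing a long unique dovetail
#'
#' After bridging, contigs and connected sequences that share a proper
#' end-to-end overlap longer than the maximum repeat size are connected
#' directly, the overlap being trimmed from the shorter sequence. Each end
#' must be the other's unique best partner (reciprocal best), which
#' prevents repeat-induced star merges; merges are applied greedily by
#' descending overlap length, ends being consumed on use.
#'
#' @param pool an assembly pool.
#' @param max_repeat repeat-size gate in bp.
#' @param config a [patch_config()] list.
#' @return list with `pool`, `applied`, `log`.
#' @export
merge_end_overlaps <- function(pool, max_repeat, config = patch_config()) {
  log_proto <- data.frame(bridge_id = "", mode = "", outcome = "",
                          l_id = "", l_end = "", r_id = "", r_end = "",
                          trim = 0L, insert_len = 0L, new_id = "",
                          stringsAsFactors = FALSE)
  recs <- as_seq_set(pool$records[pool$records$origin == "contig", ,
                                  drop = FALSE])
  if (nrow(recs) < 2L) {
    return(list(pool = pool, applied = 0L, log = empty_df(log_proto)))
  }
  hits <- align(recs, recs, min_len = config$min_aln_len,
                min_identity = config$aln_min_identity_contig,
                task = config$blast_task)
  lens <- as.list(stats::setNames(recs$length, recs$id))
  ov <- classify_hits(hits, lens, config$max_overhang, config$min_overlap)
  v <- end_overlap_view(ov, mirror = TRUE)
  v <- v[v$overlap_len > max_repeat, , drop = FALSE]
  if (nrow(v) == 0L) {
    return(list(pool = pool, applied = 0L, log = empty_df(log_proto)))
  }
  key <- function(id, end) paste(id, end)
  best <- list()
  for (id in recs$id) for (e in c("head", "tail")) {
    cand <- v[v$rid == id & v$rend == e, , drop = FALSE]
    r <- resolve_unique(cand, 1)
    if (!is.null(r)) best[[key(id, e)]] <- r
  }
  pairs <- list()
  for (k in names(best)) {
    r <- best[[k]]
    back <- best[[key(r$pid, r$pend)]]
    if (is.null(back)) next
    if (key(back$pid, back$pend) != k) next     # not reciprocal
    pk <- paste(sort(c(k, key(r$pid, r$pend))), collapse = "|")
    pairs[[pk]] <- r
  }
  if (length(pairs) == 0L) {
    return(list(pool = pool, applied = 0L, log = empty_df(log_proto)))
  }
  ord <- order(-vapply(pairs, function(p) p$overlap_len, 0L))
  logs <- list(); applied <- 0L
  consumed <- character(0)
  for (p in pairs[ord]) {
    k1 <- key(p$rid, p$rend); k2 <- key(p$pid, p$pend)
    outcome <- "applied"; new_id <- ""
    if (k1 %in% consumed || k2 %in% consumed ||
        !p$rid %in% pool$records$id || !p$pid %in% pool$records$id) {
      outcome <- "end_consumed"
    } else {
      np <- join_containers(pool, p$rid, p$rend, p$pid, p$pend,
                            trim1 = p$r_hi - p$r_lo,
                            trim2 = p$p_hi - p$p_lo)
      if (is.null(np)) {
        outcome <- "trim_exceeds_target"
      } else {
        pool <- np
        new_id <- pool$new_id
        applied <- applied + 1L
        consumed <- c(consumed, k1, k2)
      }
    }
    logs[[length(logs) + 1L]] <-
      data.frame(bridge_id = "", mode = "merge", outcome = outcome,
                 l_id = p$rid, l_end = p$rend, r_id = p$pid,
                 r_end = p$pend, trim = min(p$r_hi - p$r_lo,
                                            p$p_hi - p$p_lo),
                 insert_len = 0L, new_id = new_id, stringsAsFactors = FALSE)
  }
  list(pool = pool, applied = applied, log = do.call(rbind, logs))
}

#' Iteratively connect representative sequences
#'
#' The stage-3 driver. Strict bridging is run to a fixpoint (the overlap
#' graph being recomputed after every application round), then the maximum
#' repeat size is estimated on the surviving pool, easy bridging and
#' delineated-sequence rescue are run to a fixpoint, sequences sharing a
#' long unique dovetail are merged, and an alternative easy-bridging loop
#' repeats the repeat-estimation/easy/rescue cycle until an iteration makes
#' no change. Reads that never served as bridges are dropped from the
#' assembly (and logged): they are evidence, not assembly content.
#'
#' @param reps output of [select_representatives()].
#' @param all_sequences [seq_set] of every stage-2 input (used to resurrect
#'   delineated reads).
#' @param config a [patch_config()] list.
#' @return list with `records` (final contigs and connected sequences),
#'   `layout` (named list of layout tile tables), `join_log`,
#'   `unused_cpblrs` (ids dropped), `max_repeat`.
#' @export
iterative_connect <- function(reps, all_sequences, config = patch_config()) {
  pool <- pool_new(reps$representatives)
  logs <- list()
  note <- function(l) if (nrow(l)) logs[[length(logs) + 1L]] <<- l

  strict_round <- function(pool) {
    repeat {
      br <- find_strict_bridges(pool, config)
      if (nrow(br) == 0L) break
      res <- apply_bridges(br, pool, config)
      note(res$log)
      pool <- res$pool
      if (res$applied == 0L) break
    }
    pool
  }
  easy_round <- function(pool, max_repeat) {
    applied_any <- FALSE
    repeat {
      cands <- as_seq_set(pool$records[pool$records$origin == "cpblr", ,
                                       drop = FALSE])
      targets <- as_seq_set(pool$records[pool$records$origin == "contig", ,
                                         drop = FALSE])
      br <- find_easy_bridges(cands, targets, max_repeat, config)
      if (nrow(br) == 0L) break
      res <- apply_bridges(br, pool, config)
      note(res$log)
      pool <- res$pool
      if (res$applied == 0L) break
      applied_any <- TRUE
    }
    repeat {
      unused <- pool$records$id[pool$records$origin == "cpblr"]
      targets <- as_seq_set(pool$records[pool$records$origin == "contig", ,
                                         drop = FALSE])
      br <- rescue_delineated(unused, reps$delineated, all_sequences,
                              targets, max_repeat, config,
                              exclude = pool$used)
      if (nrow(br) == 0L) break
      res <- apply_bridges(br, pool, config)
      note(res$log)
      pool <- res$pool
      if (res$applied == 0L) break
      applied_any <- TRUE
    }
    list(pool = pool, applied = applied_any)
  }

  pool <- strict_round(pool)
  max_repeat <- estimate_max_repeat(pool$records, config)$max_repeat
  er <- easy_round(pool, max_repeat)
  pool <- er$pool
  mr <- merge_end_overlaps(pool, max_repeat, config)
  note(mr$log)
  pool <- mr$pool
  for (it in seq_len(config$max_iter)) {
    free_before <- pool_free_ends(pool)
    max_repeat <- estimate_max_repeat(pool$records, config)$max_repeat
    er <- easy_round(pool, max_repeat)
    pool <- er$pool
    if (!er$applied || pool_free_ends(pool) >= free_before) break
  }
  keep <- pool$records$origin == "contig"
  unused <- pool$records$id[!keep]
  patch_log(sprintf("dropping %d unused long reads from the assembly",
                    length(unused)))
  records <- as_seq_set(pool$records[keep, , drop = FALSE])
  join_log <- if (length(logs)) do.call(rbind, logs) else
    empty_df(data.frame(bridge_id = "", mode = "", outcome = "", l_id = "",
                        l_end = "", r_id = "", r_end = "", trim = 0L,
                        insert_len = 0L, new_id = "",
                        stringsAsFactors = FALSE))
  list(records = records, layout = pool$layout[records$id],
       join_log = join_log, unused_cpblrs = unused,
       max_repeat = max_repeat)
}
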
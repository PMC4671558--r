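# Assembly pool: the mutable state of the iterative-connection stage.
#
# A pool holds the current set of sequences (contigs, connected sequences
# and not-yet-used CPBLR representatives), a per-sequence layout tracing
# every base back to an input sequence, and an end table mapping each
# original sequence end (head/tail) to the container and container-end
# where it currently sits. Free ends are consumed as joins are applied,
# which is also the termination witness: every applied join strictly
# decreases the number of live ends.

pool_new <- function(records) {
  layout <- lapply(seq_len(nrow(records)), function(i) {
    data.frame(source_id = records$id[i], src_start = 0L,
               src_end = records$length[i], strand = "+",
               stringsAsFactors = FALSE)
  })
  names(layout) <- records$id
  ends <- data.frame(orig_id = rep(records$id, each = 2L),
                     orig_end = rep(c("head", "tail"), nrow(records)),
                     container = rep(records$id, each = 2L),
                     cend = rep(c("head", "tail"), nrow(records)),
                     live = TRUE, stringsAsFactors = FALSE)
  list(records = records, layout = layout, ends = ends,
       counter = 1L, used = character(0))
}

# two free ends per pool sequence; strictly decreases with every join
pool_free_ends <- function(pool) 2L * nrow(pool$records)

flip_tiles <- function(t) {
  t <- t[rev(seq_len(nrow(t))), , drop = FALSE]
  t$strand <- ifelse(t$strand == "+", "-", "+")
  rownames(t) <- NULL
  t
}

tile_widths <- function(t) t$src_end - t$src_start

trim_tiles_right <- function(t, n) {
  while (n > 0L && nrow(t) > 0L) {
    w <- t$src_end[nrow(t)] - t$src_start[nrow(t)]
    if (w > n) {
      if (t$strand[nrow(t)] == "+") t$src_end[nrow(t)] <- t$src_end[nrow(t)] - n
      else t$src_start[nrow(t)] <- t$src_start[nrow(t)] + n
      n <- 0L
    } else {
      t <- t[-nrow(t), , drop = FALSE]
      n <- n - w
    }
  }
  t
}

# sub-layout covering [lo, hi) of the built sequence
slice_tiles <- function(t, lo, hi) {
  total <- sum(tile_widths(t))
  trim_tiles_left(trim_tiles_right(t, total - hi), lo)
}

trim_tiles_left <- function(t, n) {
  while (n > 0L && nrow(t) > 0L) {
    w <- t$src_end[1L] - t$src_start[1L]
    if (w > n) {
      if (t$strand[1L] == "+") t$src_start[1L] <- t$src_start[1L] + n
      else t$src_end[1L] <- t$src_end[1L] - n
      n <- 0L
    } else {
      t <- t[-1L, , drop = FALSE]
      n <- n - w
    }
  }
  t
}

#' Rebuild a sequence from its layout tiles
#'
#' Concatenates layout tiles (applying strand) against a source [seq_set];
#' used to assert that every output base traces back to an input base.
#'
#' @param tiles layout data frame (`source_id, src_start, src_end, strand`).
#' @param sources [seq_set] containing every source sequence.
#' @return the rebuilt nucleotide string.
#' @export
rebuild_from_layout <- function(tiles, sources) {
  parts <- vapply(seq_len(nrow(tiles)), function(i) {
    s <- sources$seq[match(tiles$source_id[i], sources$id)]
    if (is.na(s)) stop("layout references unknown source: ", tiles$source_id[i])
    p <- substr0(s, tiles$src_start[i], tiles$src_end[i])
    if (tiles$strand[i] == "-") revcomp(p) else p
  }, "")
  paste(parts, collapse = "")
}

# look up where a sequence end currently lives; `id` may be an original
# pool member or a connected sequence (those get end rows of their own)
resolve_end <- function(pool, id, end) {
  i <- which(pool$ends$orig_id == id & pool$ends$orig_end == end)
  if (length(i) == 0L) return(NULL)          # not a pool member
  i <- i[pool$ends$live[i]]
  if (length(i) == 0L) return("consumed")
  list(container = pool$ends$container[i[1L]], cend = pool$ends$cend[i[1L]])
}

# join container c1 (at its end e1) to c2 (at e2) producing a new
# connected sequence; junction carries either an insert (sequence + layout
# tile taken from the bridging read) or a trim of the mutual overlap taken
# from the shorter container (trim1 bp off c1 / trim2 bp off c2)
join_containers <- function(pool, c1, e1, c2, e2,
                            insert_seq = "", insert_tile = NULL,
                            trim1 = 0L, trim2 = 0L) {
  i1 <- match(c1, pool$records$id); i2 <- match(c2, pool$records$id)
  s1 <- pool$records$seq[i1]; s2 <- pool$records$seq[i2]
  t1 <- pool$layout[[c1]]; t2 <- pool$layout[[c2]]
  if (e1 == "head") { s1 <- revcomp(s1); t1 <- flip_tiles(t1) }
  if (e2 == "tail") { s2 <- revcomp(s2); t2 <- flip_tiles(t2) }
  if (trim1 > 0L || trim2 > 0L) {
    if (nchar(s1) <= nchar(s2)) {
      if (trim1 >= nchar(s1)) return(NULL)   # overlap swallows the target
      s1 <- substr0(s1, 0L, nchar(s1) - trim1)
      t1 <- trim_tiles_right(t1, trim1)
    } else {
      if (trim2 >= nchar(s2)) return(NULL)
      s2 <- substr0(s2, trim2, nchar(s2))
      t2 <- trim_tiles_left(t2, trim2)
    }
  }
  new_id <- sprintf("conn_%06d", pool$counter)
  pool$counter <- pool$counter + 1L
  seq <- paste0(s1, insert_seq, s2)
  tiles <- rbind(t1, insert_tile, t2)
  rownames(tiles) <- NULL
  keep <- !pool$records$id %in% c(c1, c2)
  newrec <- data.frame(id = new_id, seq = seq, origin = "contig",
                       length = nchar(seq), stringsAsFactors = FALSE)
  pool$records <- as_seq_set(rbind(pool$records[keep, , drop = FALSE], newrec))
  pool$layout[[c1]] <- NULL; pool$layout[[c2]] <- NULL
  pool$layout[[new_id]] <- tiles
  e <- pool$ends
  k1 <- which(e$container == c1 & e$cend == e1 & e$live)
  o1 <- which(e$container == c1 & e$cend != e1 & e$live)
  k2 <- which(e$container == c2 & e$cend == e2 & e$live)
  o2 <- which(e$container == c2 & e$cend != e2 & e$live)
  e$live[c(k1, k2)] <- FALSE
  e$container[o1] <- new_id; e$cend[o1] <- "head"
  e$container[o2] <- new_id; e$cend[o2] <- "tail"
  # the connected sequence's own ends become addressable for later rounds
  e <- rbind(e, data.frame(orig_id = new_id, orig_end = c("head", "tail"),
                           container = new_id, cend = c("head", "tail"),
                           live = TRUE, stringsAsFactors = FALSE))
  pool$ends <- e
  pool$new_id <- new_id
  pool
}

# remove a sequence used as a bridge from the pool (it becomes evidence,
# not assembly content); no-op for external (rescued) candidates
consume_bridge <- function(pool, rid) {
  if (rid %in% pool$records$id) {
    pool$records <- as_seq_set(pool$records[pool$records$id != rid, ,
                                            drop = FALSE])
    pool$layout[[rid]] <- NULL
    pool$ends$live[pool$ends$container == rid] <- FALSE
  }
  pool$used <- c(pool$used, rid)
  pool
}
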
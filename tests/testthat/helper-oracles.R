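# shared fixtures and independent oracles

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at_rate <- function(seq, rate) {
  n <- nchar(seq)
  k <- round(rate * n)
  if (k == 0L) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  at <- sample.int(n, k)
  for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# exact local-alignment oracle (Smith-Waterman via Biostrings), independent
# of the package's aligner; returns the best local block's coordinates
dp_local_oracle <- function(q, s) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(s), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2),
    gapOpening = 3, gapExtension = 1)
  list(qstart = Biostrings::start(Biostrings::pattern(pa)) - 1L,
       qend = Biostrings::end(Biostrings::pattern(pa)),
       sstart = Biostrings::start(Biostrings::subject(pa)) - 1L,
       send = Biostrings::end(Biostrings::subject(pa)),
       score = Biostrings::score(pa))
}

# brute-force geometric dovetail classifier: checks the four end-distance
# conditions literally, independent of classify_end_overlap's logic
dovetail_oracle <- function(hit, a_len, b_len, mo, mov) {
  if (hit$aln_len < mov) return(NULL)
  a_h <- hit$qstart <= mo
  a_t <- (a_len - hit$qend) <= mo
  b_h <- hit$sstart <= mo
  b_t <- (b_len - hit$send) <= mo
  if (sum(a_h, a_t) != 1L || sum(b_h, b_t) != 1L) return(NULL)
  a_end <- if (a_h) "head" else "tail"
  b_end <- if (b_h) "head" else "tail"
  ok <- if (hit$strand == "+") a_end != b_end else a_end == b_end
  if (!ok) return(NULL)
  list(a_end = a_end, b_end = b_end)
}

random_hit <- function() {
  a_len <- sample(300:3000, 1L)
  b_len <- sample(300:3000, 1L)
  qs <- sample.int(a_len, 1L) - 1L
  qe <- sample(qs:a_len, 1L)
  if (qe == qs) qe <- qs + 1L
  w <- qe - qs
  ss <- sample.int(max(1L, b_len - w + 1L), 1L) - 1L
  se <- min(b_len, ss + w)
  data.frame(qid = "a", sid = "b", qstart = qs, qend = qe,
             sstart = ss, send = se,
             strand = sample(c("+", "-"), 1L),
             aln_len = w, identity = stats::runif(1L, 0.9, 1),
             stringsAsFactors = FALSE)
}

# build a constructed end-overlap table row for bridge-threshold tests
ov_row <- function(a_id, b_id, a_end, b_end, overlap_len, strand = "+",
                   a_lo = 0L, a_hi = overlap_len,
                   b_lo = 0L, b_hi = overlap_len, identity = 1) {
  data.frame(a_id = a_id, b_id = b_id, a_end = a_end, b_end = b_end,
             overlap_len = overlap_len, identity = identity,
             strand = strand, a_overhang = 0L, b_overhang = 0L,
             a_start = a_lo, a_stop = a_hi, b_start = b_lo, b_stop = b_hi,
             stringsAsFactors = FALSE)
}

# independent re-implementation of the greedy longest-first selection,
# driven directly by containment() on a shared hit table
greedy_oracle <- function(ss, hits, rt = 0.95, it = 0.95) {
  rem <- ss$id[order(-ss$length, ss$id)]
  reps <- character(0)
  delin <- data.frame(removed_id = character(), representative_id = character(),
                      stringsAsFactors = FALSE)
  while (length(rem)) {
    r <- rem[1L]; reps <- c(reps, r); rem <- rem[-1L]
    keep <- logical(length(rem))
    for (i in seq_along(rem)) {
      ct <- containment(ss[ss$id == rem[i], ], ss[ss$id == r, ], hits)
      if (ct$alignment_rate > rt && ct$identity > it) {
        delin <- rbind(delin, data.frame(removed_id = rem[i],
                                         representative_id = r,
                                         stringsAsFactors = FALSE))
      } else keep[i] <- TRUE
    }
    rem <- rem[keep]
  }
  list(reps = reps, delin = delin)
}

# the reference end-to-end scenario: 200-kb genome, three 4-kb repeat
# families x2 copies at 0.98 identity, a 300-bp N-gap, one chimeric join,
# 15X long reads (mean 8 kb, residual error 1e-4), 20X 100-bp short reads
acceptance_scenario <- function(seed = 1L) {
  sim_scenario(seed = seed, genome_len = 200000,
               repeat_specs = data.frame(length = rep(4000L, 3),
                                         copies = rep(2L, 3),
                                         identity = rep(0.98, 3)),
               n_gap_specs = data.frame(contig = 2L, length = 300L),
               chimera_specs = list(c(4L, 6L)),
               cpblr_depth = 15, cpblr_len_mean = 8000, cpblr_len_sd = 1500,
               cpblr_error = 1e-4, short_read_len = 100L, short_depth = 20)
}

# small end-to-end scenario used by several suites (kept small for speed)
small_scenario <- function(seed = 7L) {
  sim_scenario(seed = seed, genome_len = 60000,
               repeat_specs = data.frame(length = 3000, copies = 2,
                                         identity = 0.98),
               cpblr_depth = 12, cpblr_len_mean = 7000, cpblr_len_sd = 1000,
               cpblr_error = 1e-4, short_depth = 15)
}
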
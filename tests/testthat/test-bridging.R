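test_that("strict bridging enforces the 1.25-fold uniqueness margin", {
  set.seed(61)
  recs <- seq_set(c("b", "c1", "c2", "c3"),
                  c(rand_dna(3000), rand_dna(5000), rand_dna(5000),
                    rand_dna(5000)),
                  c("cpblr", "contig", "contig", "contig"))
  ov <- rbind(
    ov_row("b", "c1", "head", "tail", 1000L,
           a_lo = 0L, a_hi = 1000L, b_lo = 4000L, b_hi = 5000L),
    ov_row("b", "c3", "head", "tail", 700L,
           a_lo = 0L, a_hi = 700L, b_lo = 4300L, b_hi = 5000L),
    ov_row("b", "c2", "tail", "head", 900L,
           a_lo = 2100L, a_hi = 3000L, b_lo = 0L, b_hi = 900L))
  br <- find_strict_bridges(recs, overlaps = ov)   # 1000 >= 1.25 * 700
  expect_equal(nrow(br), 1L)
  expect_equal(br$mode, "strict")
  expect_equal(c(br$l_id, br$l_end), c("c1", "tail"))
  expect_equal(c(br$r_id, br$r_end), c("c2", "head"))
  expect_equal(br$insert, substr(recs$seq[1], 1001, 2100))
  expect_equal(br$trim, 0L)

  ov$overlap_len[2] <- 900L                        # 1000 < 1.25 * 900
  expect_equal(nrow(find_strict_bridges(recs, overlaps = ov)), 0L)

  # both resolved targets must not be reads
  recs2 <- recs; recs2$origin <- "cpblr"
  ov$overlap_len[2] <- 700L
  expect_equal(nrow(find_strict_bridges(recs2, overlaps = ov)), 0L)
})

test_that("easy bridging gates on read length and clean single partners", {
  set.seed(62)
  rds <- seq_set("b", rand_dna(3000), "cpblr")
  cts <- seq_set(c("c1", "c2", "c3"),
                 vapply(rep(5000, 3), rand_dna, ""), "contig")
  ov <- rbind(
    ov_row("b", "c1", "head", "tail", 800L,
           a_lo = 0L, a_hi = 800L, b_lo = 4200L, b_hi = 5000L),
    ov_row("b", "c2", "tail", "head", 600L,
           a_lo = 2400L, a_hi = 3000L, b_lo = 0L, b_hi = 600L))
  br <- find_easy_bridges(rds, cts, max_repeat = 2000L, overlaps = ov)
  expect_equal(nrow(br), 1L)
  expect_equal(br$mode, "easy")

  # read no longer than the repeat gate is rejected
  expect_equal(nrow(find_easy_bridges(rds, cts, 3000L, overlaps = ov)), 0L)

  # a second partner at one end disqualifies the read outright
  ov2 <- rbind(ov, ov_row("b", "c3", "head", "tail", 300L,
                          a_lo = 0L, a_hi = 300L,
                          b_lo = 4700L, b_hi = 5000L))
  expect_equal(nrow(find_easy_bridges(rds, cts, 2000L, overlaps = ov2)), 0L)

  # both ends reaching the same contig would circularise it
  ov3 <- ov; ov3$b_id[2] <- "c1"
  expect_equal(nrow(find_easy_bridges(rds, cts, 2000L, overlaps = ov3)), 0L)
})

test_that("a spanning read bridges two contigs into their true join", {
  set.seed(63)
  G <- rand_dna(22000)
  pool <- asmpatch:::pool_new(seq_set(
    c("c1", "c2", "r"),
    c(substr(G, 1, 10000), substr(G, 12001, 22000), substr(G, 9001, 13000)),
    c("contig", "contig", "cpblr")))
  br <- find_strict_bridges(pool)
  expect_equal(nrow(br), 1L)
  expect_equal(br$bridge_id, "r")
  res <- apply_bridges(br, pool)
  expect_equal(res$applied, 1L)
  expect_equal(res$log$outcome, "applied")
  expect_equal(nrow(res$pool$records), 1L)
  expect_equal(res$pool$records$length, 22000L)
  expect_equal(res$pool$records$seq, G)
  got <- rebuild_from_layout(res$pool$layout[[res$pool$records$id]],
                             seq_set(c("c1", "c2", "r"),
                                     c(substr(G, 1, 10000),
                                       substr(G, 12001, 22000),
                                       substr(G, 9001, 13000)), "cpblr"))
  expect_equal(got, G)
})

test_that("overlapping target alignments trim the junction instead", {
  set.seed(64)
  G <- rand_dna(19000)
  pool <- asmpatch:::pool_new(seq_set(
    c("c1", "c2", "r"),
    c(substr(G, 1, 10000), substr(G, 9001, 19000), substr(G, 8501, 10500)),
    c("contig", "contig", "cpblr")))
  br <- find_strict_bridges(pool)
  br <- br[br$bridge_id == "r", , drop = FALSE]
  expect_equal(nrow(br), 1L)
  expect_equal(br$insert, "")
  expect_gt(br$trim, 0L)
  res <- apply_bridges(br, pool)
  expect_equal(res$applied, 1L)
  final <- res$pool$records
  expect_equal(final$length[final$origin == "contig"], 19000L)
  expect_true(final$seq[final$origin == "contig"] %in% c(G, revcomp(G)))
})

test_that("apply_bridges runs longest-first and logs skipped outcomes", {
  set.seed(65)
  pool <- asmpatch:::pool_new(seq_set(c("A", "B", "C"),
                                      vapply(rep(4000, 3), rand_dna, ""),
                                      "contig"))
  mk <- function(id, len, l_id, r_id, l_end = "tail", r_end = "head") {
    data.frame(bridge_id = id, mode = "strict", bridge_len = len,
               l_id = l_id, l_end = l_end, l_ov = 500L,
               r_id = r_id, r_end = r_end, r_ov = 500L,
               insert = "ACGT", ins_lo = 0L, ins_hi = 4L, trim = 0L,
               stringsAsFactors = FALSE)
  }
  brs <- rbind(mk("b1", 5000L, "A", "B"),
               mk("b2", 3000L, "A", "C"),              # same A end: loses
               mk("b3", 1000L, "B", "A", "tail", "head"))  # now same container
  res <- apply_bridges(brs, pool)
  expect_equal(res$applied, 1L)
  lg <- res$log
  expect_equal(lg$outcome[lg$bridge_id == "b1"], "applied")
  expect_equal(lg$outcome[lg$bridge_id == "b2"], "end_consumed")
  expect_equal(lg$outcome[lg$bridge_id == "b3"], "self_join_skipped")
  conn <- res$pool$records[res$pool$records$id == lg$new_id[1], ]
  A <- rebuild_from_layout(res$pool$layout[["C"]], res$pool$records) # C intact
  expect_equal(conn$length, 8004L)
})

test_that("estimate_max_repeat counts repeats, not overlaps or redundancy", {
  set.seed(66)
  cfg <- patch_config()
  plain <- seq_set(c("x", "y"), c(rand_dna(10000), rand_dna(10000)), "contig")
  expect_equal(estimate_max_repeat(plain, cfg)$max_repeat, 0L)

  blk <- rand_dna(3000)
  shared <- seq_set(c("x", "y"),
                    c(paste0(rand_dna(3000), blk, rand_dna(4000)),
                      paste0(rand_dna(2000), blk, rand_dna(5000))), "contig")
  mr <- estimate_max_repeat(shared, cfg)$max_repeat
  expect_gte(mr, 2900L); expect_lte(mr, 3100L)

  # a proper dovetail is an assembly overlap, not a repeat
  G <- rand_dna(12000)
  dt <- seq_set(c("x", "y"),
                c(substr(G, 1, 7000), substr(G, 6001, 12000)), "contig")
  expect_equal(estimate_max_repeat(dt, cfg)$max_repeat, 0L)

  # full containment is redundancy, not a repeat
  ct <- seq_set(c("x", "y"), c(G, substr(G, 2001, 7000)), "contig")
  expect_equal(estimate_max_repeat(ct, cfg)$max_repeat, 0L)

  # inverted duplication within one sequence counts via the self-hit
  u <- rand_dna(2000)
  inv <- seq_set("s", paste0(rand_dna(3000), u, rand_dna(3000),
                             revcomp(u), rand_dna(3000)), "contig")
  mri <- estimate_max_repeat(inv, cfg)$max_repeat
  expect_gte(mri, 1900L); expect_lte(mri, 2100L)
})

test_that("rescue re-instates delineated reads of unused representatives", {
  set.seed(67)
  G <- rand_dna(12000)
  cts <- seq_set(c("c1", "c2"),
                 c(substr(G, 1, 5000), substr(G, 7001, 12000)), "contig")
  d <- substr(G, 4001, 8000)
  allseq <- seq_set(c("c1", "c2", "R", "d", "dc"),
                    c(cts$seq, rand_dna(6000), d, d),
                    c("contig", "contig", "cpblr", "cpblr", "contig"))
  delin <- data.frame(removed_id = c("d", "dc"),
                      representative_id = c("R", "R"),
                      alignment_rate = 1, identity = 1,
                      stringsAsFactors = FALSE)
  br <- rescue_delineated("R", delin, allseq, cts, max_repeat = 1000L)
  expect_equal(nrow(br), 1L)           # "dc" has contig origin: not rescued
  expect_equal(br$bridge_id, "d")
  expect_equal(br$insert, substr(G, 5001, 7000))

  expect_equal(nrow(rescue_delineated("R", delin, allseq, cts, 1000L,
                                      exclude = c("d", "dc"))), 0L)
  expect_equal(nrow(rescue_delineated("other", delin, allseq, cts, 1000L)),
               0L)
})

test_that("merging joins reciprocal-best long dovetails only", {
  set.seed(68)
  G <- rand_dna(12000)
  pool <- asmpatch:::pool_new(seq_set(
    c("c1", "c2"), c(substr(G, 1, 7000), substr(G, 4001, 12000)), "contig"))
  res <- merge_end_overlaps(pool, max_repeat = 1000L)
  expect_equal(res$applied, 1L)
  final <- res$pool$records
  expect_equal(final$length, 12000L)
  expect_true(final$seq %in% c(G, revcomp(G)))

  # the overlap must exceed max_repeat to be trusted
  pool2 <- asmpatch:::pool_new(seq_set(
    c("c1", "c2"), c(substr(G, 1, 7000), substr(G, 4001, 12000)), "contig"))
  expect_equal(merge_end_overlaps(pool2, max_repeat = 4000L)$applied, 0L)

  # non-reciprocal best: c2's head prefers c3's deeper overlap over c1's
  X <- rand_dna(3500)
  ss <- seq_set(c("c1", "c2", "c3"),
                c(paste0(rand_dna(4000), substr(X, 1, 2500)),
                  paste0(X, rand_dna(8000)),
                  paste0(rand_dna(6000), X)), "contig")
  res3 <- merge_end_overlaps(asmpatch:::pool_new(ss), max_repeat = 1000L)
  expect_equal(res3$applied, 1L)
  final3 <- res3$pool$records
  expect_equal(nrow(final3), 2L)
  expect_true("c1" %in% final3$id)      # c1 left alone
  expect_equal(max(final3$length), 6000L + 3500L + 8000L)
})

test_that("iterative_connect assembles three contigs and two reads into one", {
  set.seed(69)
  G <- rand_dna(24000)
  mk_all <- function(mid) {
    seq_set(c("c1", "c2", "c3", "r1", "r2"),
            c(substr(G, 1, 8000), mid, substr(G, 18001, 24000),
              substr(G, 7001, 11000), substr(G, 15001, 19000)),
            c("contig", "contig", "contig", "cpblr", "cpblr"))
  }
  allseq <- mk_all(substr(G, 10001, 16000))
  reps <- select_representatives(allseq)
  expect_equal(nrow(reps$representatives), 5L)
  out <- iterative_connect(reps, allseq)
  expect_equal(nrow(out$records), 1L)
  expect_equal(out$records$length, 24000L)
  expect_equal(out$records$seq, G)
  expect_equal(rebuild_from_layout(out$layout[[out$records$id]], allseq), G)
  expect_equal(length(out$unused_cpblrs), 0L)
  expect_true(all(out$join_log$outcome %in%
                    c("applied", "end_consumed", "self_join_skipped",
                      "bridge_consumed", "bridge_is_target")))

  # a flipped middle contig still yields the genome up to orientation
  allseq2 <- mk_all(revcomp(substr(G, 10001, 16000)))
  out2 <- iterative_connect(select_representatives(allseq2), allseq2)
  expect_equal(nrow(out2$records), 1L)
  expect_true(out2$records$seq %in% c(G, revcomp(G)))
  expect_equal(nchar(rebuild_from_layout(out2$layout[[out2$records$id]],
                                         allseq2)), 24000L)
})
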
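test_that("find_gaps locates maximal N-runs with flanks", {
  expect_equal(nrow(find_gaps(seq_set("c", "ACGTACGT", "contig"))), 0L)

  ct <- seq_set("c", "AAAANNNCCCC", "contig")
  g <- find_gaps(ct, flank_len = 4)
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$start, g$end), c(4L, 7L))
  expect_equal(g$left_flank, "AAAA")
  expect_equal(g$right_flank, "CCCC")
  expect_false(g$short_flank)

  # flank reaching the contig end, or containing N, is marked short
  g2 <- find_gaps(seq_set("c", "AANNNCCCCCCC", "contig"), flank_len = 4)
  expect_true(g2$short_flank)
  g3 <- find_gaps(seq_set("c", "AAAAANNGANNCCCCC", "contig"), flank_len = 4)
  expect_equal(nrow(g3), 2L)
  expect_true(all(g3$short_flank))   # gaps closer than one flank length
})

test_that("gap intervals equal a linear-scan oracle on random sequences", {
  set.seed(41)
  for (k in 1:100) {
    s <- strsplit(rand_dna(300), "")[[1L]]
    n_runs <- sample(0:4, 1)
    for (r in seq_len(n_runs)) {
      at <- sample(1:280, 1)
      s[at:min(300, at + sample(1:15, 1))] <- "N"
    }
    seqc <- paste(s, collapse = "")
    g <- find_gaps(seq_set("c", seqc, "contig"), flank_len = 10)
    # oracle: character scan for maximal runs
    isn <- s == "N"
    r <- rle(isn)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    want <- cbind(starts[r$values], ends[r$values])
    expect_equal(nrow(g), nrow(want))
    if (nrow(g)) {
      expect_equal(g$start, unname(want[, 1]))
      expect_equal(g$end, unname(want[, 2]))
    }
  }
})

make_gap_case <- function(n_agree, n_dissent, inter = "ATGCTA") {
  set.seed(42)
  left <- rand_dna(120); right <- rand_dna(120)
  truth <- paste0(left, inter, right)
  ct <- seq_set("c", paste0(left, strrep("N", 8), right), "contig")
  reads <- character(0)
  for (i in seq_len(n_agree)) {
    reads <- c(reads, paste0(rand_dna(30), left, inter, right, rand_dna(30)))
  }
  for (i in seq_len(n_dissent)) {
    reads <- c(reads, paste0(rand_dna(30), left, "GGGGGG", right, rand_dna(30)))
  }
  list(contig = ct, truth = truth,
       reads = seq_set(paste0("r", seq_along(reads)), reads, "cpblr"))
}

test_that("gaps fill only with more than two agreeing spanning reads", {
  cs <- make_gap_case(3, 1)
  gaps <- find_gaps(cs$contig)
  res <- fill_gaps(cs$contig, gaps, cs$reads)
  expect_equal(res$record$seq, cs$truth)
  expect_equal(res$log$action, "filled")
  expect_equal(res$log$votes, 3L)

  cs2 <- make_gap_case(2, 0)
  res2 <- fill_gaps(cs2$contig, find_gaps(cs2$contig), cs2$reads)
  expect_equal(res2$log$action, "unfilled")
  expect_equal(res2$record$seq, cs2$contig$seq)

  # a tie between two equally voted substrings has no unique maximum
  cs3 <- make_gap_case(3, 3)
  res3 <- fill_gaps(cs3$contig, find_gaps(cs3$contig), cs3$reads)
  expect_equal(res3$log$action, "unfilled")
})

test_that("reverse-complement reads span gaps and empty fills close gaps", {
  cs <- make_gap_case(3, 0)
  rcreads <- seq_set(cs$reads$id, revcomp(cs$reads$seq), "cpblr")
  res <- fill_gaps(cs$contig, find_gaps(cs$contig), rcreads)
  expect_equal(res$record$seq, cs$truth)

  cs0 <- make_gap_case(3, 0, inter = "")
  res0 <- fill_gaps(cs0$contig, find_gaps(cs0$contig), cs0$reads)
  expect_equal(res0$record$seq, cs0$truth)   # direct junction
  expect_equal(res0$log$replacement_len, 0L)
})

test_that("simulated gap fills recover the masked truth exactly", {
  set.seed(43)
  genome <- rand_dna(10000)
  truth300 <- substr(genome, 4001, 4300)
  masked <- genome
  substr(masked, 4001, 4300) <- strrep("N", 300)
  ct <- seq_set("c", masked, "contig")
  starts <- seq(2200, 4400, by = 220)
  reads <- seq_set(paste0("r", seq_along(starts)),
                   vapply(starts, function(s) substr(genome, s, s + 2999), ""),
                   "cpblr")
  res <- fill_gaps(ct, find_gaps(ct), reads)
  expect_equal(res$record$seq, genome)
  expect_true(grepl(truth300, res$record$seq, fixed = TRUE))
})

test_that("gap filling never increases the N count", {
  set.seed(44)
  for (k in 1:5) {
    s <- rand_dna(2000)
    at <- sample(500:1200, 1)
    substr(s, at, at + 49) <- strrep("N", 50)
    ct <- seq_set("c", s, "contig")
    reads <- seq_set(paste0("r", 1:3), vapply(1:3, function(i)
      rand_dna(1000), ""), "cpblr")
    res <- fill_gaps(ct, find_gaps(ct), reads)
    n_before <- lengths(regmatches(s, gregexpr("N", s)))
    n_after <- lengths(regmatches(res$record$seq,
                                  gregexpr("N", res$record$seq)))
    expect_lte(n_after, n_before)
  }
})

test_that("coverage counts all best placements of each read", {
  set.seed(49)
  ct <- seq_set("c", rand_dna(20), "contig")
  empty <- seq_set(character(), character(), "cpblr")
  cov0 <- compute_coverage(ct, empty)
  expect_equal(cov0$c, integer(20))

  rd <- seq_set("r1", substr(ct$seq, 6, 15), "cpblr")
  cov1 <- compute_coverage(ct, rd)
  expect_equal(cov1$c, c(rep(0L, 5), rep(1L, 10), rep(0L, 5)))

  # a read matching two contigs exactly contributes to both
  set.seed(45)
  shared <- rand_dna(40)
  cts <- seq_set(c("a", "b"),
                 c(paste0(rand_dna(30), shared), paste0(shared, rand_dna(30))),
                 "contig")
  rd2 <- seq_set("r", substr(shared, 11, 30), "cpblr")
  cov2 <- compute_coverage(cts, rd2)
  expect_equal(sum(cov2$a), 20L)
  expect_equal(sum(cov2$b), 20L)
})

test_that("uniform simulated coverage has the expected interior depth", {
  set.seed(46)
  genome <- rand_dna(20000)
  sc <- sim_scenario(seed = 5, genome_len = 20000, short_depth = 20,
                     short_read_len = 100)
  reads <- simulate_short_reads(genome, sc)
  cov <- compute_coverage(seq_set("g", genome, "contig"), reads)
  interior <- cov$g[1000:19000]
  expect_gt(mean(interior), 15)
  expect_lt(mean(interior), 25)
  # ends taper below interior depth
  expect_lt(mean(cov$g[1:20]), mean(interior))
})

test_that("splitting excises interior zero runs and honours the exemptions", {
  set.seed(47)
  ct <- seq_set("c", rand_dna(1000), "contig")
  pos <- rep(3L, 1000)
  out <- split_zero_coverage(ct, pos)
  expect_equal(out$records$id, "c")
  expect_equal(out$records$seq, ct$seq)

  # zero run inside the terminal 1% window is exempt
  d2 <- pos; d2[996:1000] <- 0L
  out2 <- split_zero_coverage(ct, d2)
  expect_equal(out2$records$seq, ct$seq)

  # interior zero run is excised; a 40-bp piece is discarded, 400-bp kept
  d3 <- pos; d3[401:430] <- 0L; d3[471:1000] <- 0L
  out3 <- split_zero_coverage(ct, d3)
  expect_equal(out3$records$length, 400L)
  expect_equal(out3$records$seq, substr(ct$seq, 1, 400))
  expect_true(any(out3$log$event == "discarded_short_piece"))

  # a 50-bp piece is kept (the cutoff is strictly below 50)
  d4 <- pos; d4[401:430] <- 0L; d4[481:1000] <- 0L
  out4 <- split_zero_coverage(ct, d4)
  expect_equal(sort(out4$records$length), c(50L, 400L))
})

test_that("split pieces plus excised runs reconstruct the contig", {
  set.seed(48)
  for (k in 1:20) {
    n <- sample(500:2000, 1)
    ct <- seq_set("c", rand_dna(n), "contig")
    d <- rep(2L, n)
    for (r in seq_len(sample(1:3, 1))) {
      at <- sample(seq_len(n - 60), 1)
      d[at:(at + sample(10:50, 1))] <- 0L
    }
    out <- split_zero_coverage(ct, d, min_segment = 1)
    rebuilt <- paste(vapply(seq_len(nrow(out$pieces)), function(i)
      substr(ct$seq, out$pieces$src_start[i] + 1, out$pieces$src_end[i]), ""),
      collapse = "")
    # pieces cover exactly the non-excised positions, in order
    keepmask <- d > 0L
    # the terminal exemption can keep zero runs inside pieces
    pieces_iv <- IRanges::IRanges(out$pieces$src_start + 1, out$pieces$src_end)
    expect_true(all(which(keepmask) %in%
                      unlist(lapply(seq_along(pieces_iv), function(i)
                        IRanges::start(pieces_iv[i]):IRanges::end(pieces_iv[i])))))
    expect_equal(sum(out$pieces$src_end - out$pieces$src_start),
                 nchar(rebuilt))
  }
})

test_that("chimeric contigs split at their engineered junction", {
  sc <- sim_scenario(seed = 9, genome_len = 40000,
                     repeat_specs = data.frame(length = 2500, copies = 2,
                                               identity = 1.0),
                     chimera_specs = list(c(1, 3)),
                     cpblr_depth = 0, short_depth = 15)
  g <- simulate_genome(sc)
  fr <- fragment_assembly(g$genome, g$truth, sc)
  chim <- fr$contigs$id[grepl("^chimera", fr$contigs$id)]
  expect_length(chim, 1L)
  reads <- simulate_short_reads(g$genome, sc)
  cov <- compute_coverage(fr$contigs, reads)
  ct <- fr$contigs[fr$contigs$id == chim, ]
  class(ct) <- class(fr$contigs)
  out <- split_zero_coverage(ct, cov[[chim]])
  expect_gte(nrow(out$records), 2L)
  expect_true(any(out$log$event == "excised_zero_run"))
})
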
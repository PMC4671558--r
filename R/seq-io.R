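#' Sequence record collections
#'
#' A `seq_set` is the package's basic container: a data frame with one row
#' per sequence and columns `id` (unique), `seq` (uppercase string over
#' `{A,C,G,T,N}`), `origin` (`"contig"` or `"cpblr"`) and `length` (bp).
#' Draft contigs and corrected PacBio long reads (CPBLRs) travel through the
#' pipeline in this form.
#'
#' @param id character vector of unique sequence identifiers.
#' @param seq character vector of nucleotide strings (same length as `id`).
#' @param origin `"contig"` or `"cpblr"`; recycled to the number of records.
#' @return an object of class `seq_set` (a data frame).
#' @examples
#' seq_set(c("a", "b"), c("ACGT", "GGGTTT"), "contig")
#' @export
seq_set <- function(id = character(), seq = character(), origin = "contig") {
  stopifnot(length(id) == length(seq))
  origin <- rep_len(as.character(origin), length(id))
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1L]
    stop("duplicate sequence id: ", dup)
  }
  bad <- !origin %in% c("contig", "cpblr")
  if (any(bad)) stop("origin must be 'contig' or 'cpblr'")
  x <- data.frame(id = as.character(id), seq = as.character(seq),
                  origin = origin, length = nchar(seq),
                  stringsAsFactors = FALSE)
  if (any(x$length == 0L)) stop("zero-length sequence: ", x$id[x$length == 0L][1L])
  class(x) <- c("seq_set", "data.frame")
  x
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set: %d sequences, %s bp total\n",
              nrow(x), format(sum(x$length), big.mark = ",")))
  if (nrow(x)) {
    show <- utils::head(x[, c("id", "origin", "length")], 10L)
    print.data.frame(show, row.names = FALSE)
    if (nrow(x) > 10L) cat("...\n")
  }
  invisible(x)
}

as_seq_set <- function(x) {
  class(x) <- c("seq_set", "data.frame")
  rownames(x) <- NULL
  x
}

ss_get <- function(set, ids) {
  i <- match(ids, set$id)
  if (anyNA(i)) stop("unknown sequence id: ", ids[is.na(i)][1L])
  as_seq_set(set[i, , drop = FALSE])
}

ss_bind <- function(...) {
  x <- do.call(rbind, lapply(list(...), as.data.frame))
  seq_set(x$id, x$seq, x$origin)
}

as_dna <- function(set) {
  Biostrings::DNAStringSet(stats::setNames(set$seq, set$id))
}

#' Read sequences from FASTA or FASTQ
#'
#' Reads a (optionally gzip-compressed) FASTA or FASTQ file, auto-detecting
#' the format from the first non-empty character. Sequences are uppercased,
#' `U` is mapped to `T`, and any residual non-`ACGTN` IUPAC character is
#' either masked to `N` (default) or rejected. Empty records are dropped
#' with a warning.
#'
#' @param path input file path.
#' @param origin origin tag to assign, `"contig"` or `"cpblr"`.
#' @param non_acgtn `"mask"` to convert other IUPAC codes to `N` (with a
#'   counted warning) or `"reject"` to fail.
#' @return a [seq_set].
#' @export
read_sequences <- function(path, origin = c("contig", "cpblr"),
                           non_acgtn = c("mask", "reject")) {
  origin <- match.arg(origin)
  non_acgtn <- match.arg(non_acgtn)
  if (!file.exists(path)) stop("cannot read sequence file: ", path)
  fmt <- sniff_format(path)
  x <- if (fmt == "fastq") {
    Biostrings::readBStringSet(path, format = "fastq")
  } else {
    Biostrings::readBStringSet(path, format = "fasta")
  }
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    d <- which(ids == ids[duplicated(ids)][1L])
    stop(sprintf("duplicate id '%s' in %s (records %d and %d)",
                 ids[d[1L]], path, d[1L], d[2L]))
  }
  seqs <- toupper(as.character(x))
  seqs <- chartr("U", "T", seqs)
  n_other <- sum(nchar(gsub("[ACGTN]", "", seqs)))
  if (n_other > 0L) {
    if (non_acgtn == "reject") {
      stop(n_other, " non-ACGTN characters in ", path)
    }
    warning(n_other, " non-ACGTN characters mapped to N in ", path)
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), "",
                   USE.NAMES = FALSE)
  }
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    warning(sum(empty), " empty records dropped from ", path)
    ids <- ids[!empty]; seqs <- seqs[!empty]
  }
  seq_set(ids, seqs, origin)
}

sniff_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1L)
    if (length(l) == 0L) stop("empty sequence file: ", path)
    if (nzchar(trimws(l))) break
  }
  c1 <- substr(trimws(l), 1L, 1L)
  if (c1 == ">") "fasta" else if (c1 == "@") "fastq"
  else stop("unrecognised sequence format in ", path)
}

#' Write an assembly as FASTA
#'
#' Writes records as 80-column-wrapped FASTA in a deterministic order:
#' descending length, ties broken by id.
#'
#' @param records a [seq_set]; must be non-empty.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(records, path) {
  if (nrow(records) == 0L) stop("refusing to write an empty assembly")
  ord <- order(-records$length, records$id)
  records <- records[ord, , drop = FALSE]
  Biostrings::writeXStringSet(as_dna(records), path, width = 80L)
  invisible(path)
}

#' Basic assembly statistics
#'
#' Contig count, total length, largest contig, N50 and the number of `N`
#' characters per 100 kbp — the usual columns of an assembly report.
#' N50 is the length `L` such that contigs of length `>= L` together cover
#' at least half of the total assembly length.
#'
#' @param records a [seq_set]; must be non-empty.
#' @return a one-row data frame with columns `n_contigs`, `total_length`,
#'   `largest`, `n50`, `n_per_100kbp`.
#' @export
assembly_stats <- function(records) {
  if (nrow(records) == 0L) stop("no records")
  len <- sort(records$length, decreasing = TRUE)
  total <- sum(len)
  n50 <- len[which(cumsum(len) >= total / 2)[1L]]
  n_count <- sum(vapply(records$seq,
                        function(s) sum(charToRaw(s) == charToRaw("N")),
                        0L, USE.NAMES = FALSE))
  data.frame(n_contigs = length(len), total_length = total,
             largest = len[1L], n50 = n50,
             n_per_100kbp = 1e5 * n_count / total)
}

write_fastq <- function(records, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(c(paste0("@", records$id[i]), records$seq[i], "+",
                 strrep("I", records$length[i])), con)
  }
  invisible(path)
}
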
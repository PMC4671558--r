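# internal helpers shared across stages

patch_log <- function(...) {
  if (isTRUE(getOption("asmpatch.verbose", FALSE))) message(...)
  invisible(NULL)
}

#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over the `{A,C,G,T,N}` alphabet.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substring with 0-based half-open coordinates
substr0 <- function(s, start, end) {
  if (end <= start) return("")
  substr(s, start + 1L, end)
}

# derive a component sub-seed from a scenario seed; keeps values < 2^31
sub_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k)
}

# empty data frame with given column names/prototypes
empty_df <- function(proto) proto[0L, , drop = FALSE]
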
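#' Reverse-complement nucleotide strings
#'
#' @param x Character vector of sequences over \{A,C,G,T,N\} (case kept upper).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## total length of the union of half-open intervals [start, end)
interval_union_length <- function(start, end) {
  if (!length(start)) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  tot <- 0; cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > cur_e) {
      tot <- tot + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    } else cur_e <- max(cur_e, end[i])
  }
  tot + (cur_e - cur_s)
}

## clamp intervals to [0, len) and drop empties
clip_intervals <- function(start, end, len) {
  s <- pmax(start, 0); e <- pmin(end, len)
  keep <- s < e
  list(start = s[keep], end = e[keep])
}
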
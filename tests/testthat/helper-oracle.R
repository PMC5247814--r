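# Independent brute-force oracle for direct-repeat scanning, built on
# regular expressions (character-class expansion of the degenerate pattern)
# and Biostrings' reverse complement. Used only to cross-check the
# implementation; shares no code with it.

oracle_rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# every (offset, spacer length, strand) triple matching
# [AG]G[GT]TCA (N)spacer [AG]G[GT]TCA, via lookahead regex on both strands
oracle_scan <- function(seq, spacers = 0:9, half = "[AG]G[GT]TCA") {
  seq <- toupper(seq)
  L <- nchar(seq)
  rows <- list()
  for (s in spacers) {
    re <- sprintf("(?=(%s[ACGT]{%d}%s))", half, s, half)
    w <- 12L + s
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") seq else oracle_rc(seq)
      m <- gregexpr(re, subject, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      st0 <- as.integer(m) - 1L
      if (strand == "+") {
        st <- st0; en <- st0 + w
      } else {
        en <- L - st0; st <- en - w
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = st, end = en, strand = strand, spacer_length = s,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), spacer_length = integer(0)))
  }
  h <- do.call(rbind, rows)
  h <- h[order(h$start, h$end, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

hit_key <- function(h) sort(paste(h$start, h$end, h$strand))

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
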
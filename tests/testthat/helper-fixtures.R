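# Fixtures are built in code; nothing binary ships with the package.

random_dna <- function(n, gc = 0.4, with_n = 0) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chars <- sample(names(p), n, replace = TRUE, prob = p)
  if (with_n > 0) {
    idx <- sample(n, ceiling(with_n * n))
    chars[idx] <- "N"
  }
  paste(chars, collapse = "")
}

write_fasta_text <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# Independent brute-force scanner: tests every (offset, strand) pair with
# the single-window matcher only.
oracle_scan <- function(sequence, consensus, max_mismatches, width) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") consensus else
      modulescout::reverse_complement(consensus)
    if (width > L) next
    for (s in 0:(L - width)) {
      win <- substr(sequence, s + 1, s + width)
      if (modulescout::iupac_matches(win, pat, max_mismatches)) {
        hits[[length(hits) + 1]] <- data.frame(
          start = s, end = s + width, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Exact binomial upper tail by direct summation (independent of pbinom).
oracle_binom_tail <- function(k, n, p0) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i),
             numeric(1)))
}

# Exact hypergeometric upper tail by enumerating subset compositions.
oracle_hyper_tail <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

toy_occurrence <- function(gene = "g1", motif = "PAC", start = 2L,
                           end = 8L, strand = "+", mism = 0L,
                           dist = 792L) {
  data.frame(gene_id = gene, motif = motif, start = start, end = end,
             strand = strand, mismatches = mism, dist_to_atg = dist,
             stringsAsFactors = FALSE)
}
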
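# Consensus scanning.  Every offset of every region is tested on the plus
# strand against the consensus and on the minus strand against its reverse
# complement; minus-strand hits are reported in plus-strand coordinates.

# Vector of mismatch counts for all windows of `chars` against `consensus`.
window_mismatches <- function(chars, consensus) {
  w <- nchar(consensus)
  n_off <- length(chars) - w + 1L
  if (n_off < 1L) return(integer(0))
  cc <- strsplit(consensus, "", fixed = TRUE)[[1]]
  mm <- integer(n_off)
  for (j in seq_len(w)) {
    allowed <- IUPAC_CODES[[cc[j]]]
    mm <- mm + !(chars[j:(j + n_off - 1L)] %in% allowed)
  }
  mm
}

#' Scan one upstream region for a motif on both strands
#'
#' @param sequence DNA string of the region (A,C,G,T,N; case-insensitive),
#'   oriented 5'->3' on the gene's strand.
#' @param motif One-row `motif_set` (see [motif_set()]), or the whole set
#'   plus `name`.
#' @param gene_id Gene id recorded in the output.
#' @param name Motif name when `motif` holds several models.
#' @return Occurrence data frame (possibly 0-row) sorted by `start`, with
#'   0-based end-exclusive coordinates, strand relative to the gene, and
#'   `dist_to_atg = nchar(sequence) - end`.
#' @examples
#' m <- motif_set(PAC = "GATGAG")
#' scan_region("TTGATGAGCC", m, gene_id = "g1")
#' @export
scan_region <- function(sequence, motif, gene_id = "gene", name = NULL) {
  if (!is.null(name)) motif <- motif_row(motif, name)
  stopifnot(nrow(motif) == 1L)
  seq_u <- toupper(sequence)
  chars <- strsplit(seq_u, "", fixed = TRUE)[[1]]
  L <- length(chars)
  w <- motif$width
  cons <- motif$consensus
  mmax <- motif$max_mismatches
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") cons else reverse_complement(cons)
    mm <- window_mismatches(chars, pat)
    idx <- which(mm <= mmax)
    if (length(idx) > 0L) {
      start <- idx - 1L
      hits[[strand]] <- data.frame(
        gene_id = gene_id, motif = motif$name,
        start = start, end = start + w, strand = strand,
        mismatches = mm[idx], dist_to_atg = L - (start + w),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits) == 0L) empty_occurrences() else
    do.call(rbind, unname(hits))
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a set of upstream regions for a set of motifs
#'
#' @param regions Named [Biostrings::DNAStringSet] or named character
#'   vector of upstream sequences.
#' @param motifs A `motif_set`.
#' @return Combined occurrence data frame over all genes and motifs.
#' @export
scan_regions <- function(regions, motifs) {
  chars <- region_chars(regions)
  out <- vector("list", length(chars) * nrow(motifs))
  k <- 0L
  for (g in names(chars)) {
    for (i in seq_len(nrow(motifs))) {
      k <- k + 1L
      out[[k]] <- scan_region(chars[[g]], motifs[i, , drop = FALSE],
                              gene_id = g)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
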
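# Synthetic promoter generator: i.i.d. background with a chosen GC content
# and planted motif-pair modules of known spacing, order, strand agreement
# and position, emitted together with a ground-truth occurrence and module
# table so every statistic in the package can be validated without any
# external data.

#' Specification of a synthetic planted-module dataset
#'
#' Defaults emulate the tight proximal same-strand regime reported for the
#' budding-yeast-like module (median spacing 12 bp, coverage 0.46,
#' same-strand preference, proximal positioning) on 200 genes of 800 bp
#' with genome-like GC content 0.38.
#'
#' @param n_genes Number of genes.
#' @param L Region length in bp.
#' @param gc_content Background GC fraction.
#' @param coverage Fraction of genes with a planted module; the planted
#'   gene count is `round(coverage * n_genes)`.
#' @param order Length-2 character vector of motif names, 5'->3'.
#' @param motifs `motif_set` holding the motifs named in `order`.  Default:
#'   PAC/PAC2 plus a synthetic A/T-rich RRPE stand-in, consensus
#'   `TGAAAAWTTT` (the real element has no fixed published consensus; the
#'   stand-in is deliberately non-palindromic so strand statistics are
#'   identifiable).
#' @param gap `list(type = "constant", value = g)` or
#'   `list(type = "geometric", mean = g)` (truncated to what fits).
#' @param position `"proximal"` (distance fraction ~ Beta(1, 4), i.e.
#'   concentrated toward the translation start) or `"uniform"`.
#' @param p_same_strand Probability the second motif lands on the first
#'   motif's strand.
#' @param mismatch_rate Per-base probability of writing a mismatching base
#'   into a planted site (0 means every planted site matches exactly).
#' @param seed RNG seed resolved at generation time.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(n_genes = 200L, L = 800L, gc_content = 0.38,
                       coverage = 0.46, order = c("RRPE", "PAC"),
                       motifs = default_motifs(rrpe = "TGAAAAWTTT"),
                       gap = list(type = "constant", value = 12L),
                       position = c("proximal", "uniform"),
                       p_same_strand = 0.9, mismatch_rate = 0,
                       seed = NULL) {
  position <- match.arg(position)
  stopifnot(n_genes >= 1L, L >= 1L, gc_content > 0, gc_content < 1,
            coverage >= 0, coverage <= 1, length(order) == 2L,
            p_same_strand >= 0, p_same_strand <= 1,
            mismatch_rate >= 0, mismatch_rate < 1)
  if (!all(order %in% motifs$name)) {
    stop("order names motifs absent from the motif set: ",
         paste(setdiff(order, motifs$name), collapse = ", "))
  }
  if (!gap$type %in% c("constant", "geometric")) {
    stop("gap$type must be 'constant' or 'geometric'")
  }
  spec <- list(n_genes = as.integer(n_genes), L = as.integer(L),
               gc_content = gc_content, coverage = coverage, order = order,
               motifs = motifs, gap = gap, position = position,
               p_same_strand = p_same_strand, mismatch_rate = mismatch_rate,
               seed = seed)
  class(spec) <- "plant_spec"
  spec
}

sample_background <- function(n, gc) {
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(base_p), n, replace = TRUE, prob = base_p)
}

# realize an IUPAC consensus into concrete bases, then inject mismatches
realize_site <- function(consensus, mismatch_rate) {
  cc <- strsplit(consensus, "", fixed = TRUE)[[1]]
  bases <- vapply(cc, function(ch) {
    allowed <- IUPAC_CODES[[ch]]
    if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }, character(1))
  mism <- 0L
  if (mismatch_rate > 0) {
    flip <- which(stats::runif(length(cc)) < mismatch_rate)
    for (j in flip) {
      outside <- setdiff(c("A", "C", "G", "T"), IUPAC_CODES[[cc[j]]])
      if (length(outside) == 0L) next       # N consensus: cannot mismatch
      bases[j] <- sample(outside, 1L)
      mism <- mism + 1L
    }
  }
  list(bases = unname(bases), mismatches = mism)
}

#' Generate synthetic upstream regions with planted modules
#'
#' Background bases are i.i.d. with the requested GC; planted sites
#' overwrite the background and never overlap each other.  The emitted
#' ground truth is consistent with the sequences: re-scanning finds every
#' planted site within its mismatch budget.
#'
#' @param spec A [plant_spec()].
#' @return List with `regions` (named [Biostrings::DNAStringSet]),
#'   `occurrences` (truth occurrence table), `modules` (truth module
#'   table) and `spec` (the spec with the resolved seed).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  if (is.null(spec$seed)) spec$seed <- sample.int(.Machine$integer.max, 1L)
  ma <- motif_row(spec$motifs, spec$order[1])
  mb <- motif_row(spec$motifs, spec$order[2])
  min_gap <- if (spec$gap$type == "constant") spec$gap$value else 0L
  if (ma$width + mb$width + min_gap > spec$L) {
    stop("infeasible spec: planted module (", ma$width + mb$width + min_gap,
         " bp) does not fit in L = ", spec$L)
  }
  n_plant <- round(spec$coverage * spec$n_genes)
  with_seed(spec$seed, {
    gene_ids <- sprintf("g%03d", seq_len(spec$n_genes))
    planted <- sort(sample(seq_len(spec$n_genes), n_plant))
    seqs <- character(spec$n_genes)
    occ_rows <- list(); mod_rows <- list()
    for (i in seq_len(spec$n_genes)) {
      chars <- sample_background(spec$L, spec$gc_content)
      if (i %in% planted) {
        g <- draw_gap(spec, spec$L - ma$width - mb$width)
        span <- ma$width + g + mb$width
        dist3 <- draw_distance(spec, spec$L - span)  # 3'-edge upstream dist
        s1 <- spec$L - dist3 - span
        strand1 <- sample(c("+", "-"), 1L)
        strand2 <- if (stats::runif(1) < spec$p_same_strand) strand1 else
          setdiff(c("+", "-"), strand1)
        occ <- plant_pair(chars, spec, ma, mb, s1, g, strand1, strand2,
                          gene_ids[i])
        chars <- occ$chars
        occ_rows[[length(occ_rows) + 1L]] <- occ$occ
        first <- occ$occ[1, ]; second <- occ$occ[2, ]
        mid <- spec$L - as.integer(round((first$start + second$end) / 2))
        mod_rows[[length(mod_rows) + 1L]] <- data.frame(
          gene_id = gene_ids[i],
          order = order_label(first$motif, second$motif),
          motif_first = first$motif, motif_second = second$motif,
          start_first = first$start, end_first = first$end,
          strand_first = first$strand,
          start_second = second$start, end_second = second$end,
          strand_second = second$strand,
          gap = g, same_strand = strand1 == strand2,
          midpoint_dist = mid, signed_position = -mid,
          stringsAsFactors = FALSE)
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    occurrences <- if (length(occ_rows) > 0L)
      do.call(rbind, occ_rows) else empty_occurrences()
    modules <- if (length(mod_rows) > 0L)
      do.call(rbind, mod_rows) else module_columns()
    rownames(occurrences) <- rownames(modules) <- NULL
    regions <- Biostrings::DNAStringSet(stats::setNames(seqs, gene_ids))
    list(regions = regions, occurrences = occurrences, modules = modules,
         spec = spec)
  })
}

draw_gap <- function(spec, max_feasible) {
  if (spec$gap$type == "constant") return(as.integer(spec$gap$value))
  g <- stats::rgeom(1, 1 / (spec$gap$mean + 1))
  min(g, max_feasible)                      # truncated at what fits
}

draw_distance <- function(spec, max_dist) {
  if (max_dist <= 0L) return(0L)
  frac <- if (spec$position == "proximal") stats::rbeta(1, 1, 4)
          else stats::runif(1)
  as.integer(round(frac * max_dist))
}

plant_pair <- function(chars, spec, ma, mb, s1, g, strand1, strand2,
                       gene_id) {
  L <- length(chars)
  write_site <- function(chars, motif, start, strand) {
    site <- realize_site(motif$consensus, spec$mismatch_rate)
    bases <- site$bases
    if (strand == "-") {
      bases <- strsplit(reverse_complement(paste(bases, collapse = "")),
                        "", fixed = TRUE)[[1]]
    }
    chars[(start + 1L):(start + motif$width)] <- bases
    list(chars = chars, mismatches = site$mismatches)
  }
  w1 <- write_site(chars, ma, s1, strand1)
  s2 <- s1 + ma$width + g
  w2 <- write_site(w1$chars, mb, s2, strand2)
  occ <- data.frame(
    gene_id = gene_id, motif = c(ma$name, mb$name),
    start = c(s1, s2), end = c(s1 + ma$width, s2 + mb$width),
    strand = c(strand1, strand2),
    mismatches = c(w1$mismatches, w2$mismatches),
    dist_to_atg = c(L - (s1 + ma$width), L - (s2 + mb$width)),
    stringsAsFactors = FALSE)
  list(chars = w2$chars, occ = occ)
}

#' Generate synthetic regions with independently, uniformly placed motifs
#'
#' No module structure is planted: each gene receives the requested number
#' of instances of each motif at positions drawn uniformly over all
#' non-overlapping arrangements with random strands — the same placement
#' null used by [sample_null_distances()].  Used for null calibration of
#' the spacing statistic.
#'
#' @param n_genes,L,gc_content Background dimensions as in [plant_spec()].
#' @param motifs `motif_set`.
#' @param counts Named integer vector: instances planted per gene for each
#'   motif name.
#' @param mismatch_rate Per-base mismatch probability for planted sites.
#' @param seed RNG seed.
#' @return List with `regions` and the truth `occurrences` table.
#' @export
generate_null_dataset <- function(n_genes = 200L, L = 800L,
                                  gc_content = 0.38,
                                  motifs = default_motifs(rrpe = "TGAAAAWTTT"),
                                  counts = c(RRPE = 2L, PAC = 2L),
                                  mismatch_rate = 0, seed = NULL) {
  stopifnot(all(names(counts) %in% motifs$name))
  widths <- vapply(names(counts), function(nm) motif_row(motifs, nm)$width,
                   integer(1))
  labels <- rep(names(counts), counts)
  site_widths <- rep(widths, counts)
  if (sum(site_widths) > L) stop("instances do not fit in L")
  spec_mm <- list(mismatch_rate = mismatch_rate)
  with_seed(seed, {
    gene_ids <- sprintf("g%03d", seq_len(n_genes))
    seqs <- character(n_genes)
    occ_rows <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      chars <- sample_background(L, gc_content)
      k <- length(labels)
      perm <- if (k > 1L) sample.int(k) else 1L
      starts <- place_nonoverlapping(L, site_widths[perm])
      rows <- vector("list", k)
      for (j in seq_len(k)) {
        m <- motif_row(motifs, labels[perm][j])
        strand <- sample(c("+", "-"), 1L)
        w <- plant_pair_site(chars, m, starts[j], strand, spec_mm)
        chars <- w$chars
        rows[[j]] <- data.frame(
          gene_id = gene_ids[i], motif = m$name,
          start = starts[j], end = starts[j] + m$width, strand = strand,
          mismatches = w$mismatches,
          dist_to_atg = L - (starts[j] + m$width),
          stringsAsFactors = FALSE)
      }
      occ_rows[[i]] <- do.call(rbind, rows)
      seqs[i] <- paste(chars, collapse = "")
    }
    occurrences <- do.call(rbind, occ_rows)
    rownames(occurrences) <- NULL
    list(regions = Biostrings::DNAStringSet(stats::setNames(seqs, gene_ids)),
         occurrences = occurrences)
  })
}

plant_pair_site <- function(chars, motif, start, strand, spec) {
  site <- realize_site(motif$consensus, spec$mismatch_rate)
  bases <- site$bases
  if (strand == "-") {
    bases <- strsplit(reverse_complement(paste(bases, collapse = "")),
                      "", fixed = TRUE)[[1]]
  }
  chars[(start + 1L):(start + motif$width)] <- bases
  list(chars = chars, mismatches = site$mismatches)
}
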
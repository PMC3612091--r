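# The five module-score components and the combined, normalized score.

#' Motif overrepresentation significance in bits
#'
#' `Sig = -log2 P(X >= k)` for `X ~ Binomial(n, p0)`, where `k` is the
#' observed number of motif matches in the gene set, `n` the total number
#' of scanned windows (both strands) and `p0` the background per-window
#' match probability.  Computed in log space, so values of hundreds of bits
#' (tail probabilities around 2^-240, i.e. ~5.7e-73) are exact.
#'
#' @param k Observed match count, `0 <= k <= n`.
#' @param n Total scanned windows.
#' @param p0 Background per-window match probability, in (0,1).
#' @return Significance in bits (>= 0; 0 when `k == 0`).
#' @export
sig_value <- function(k, n, p0) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(p0) == 1L)
  if (!(p0 > 0 && p0 < 1)) stop("p0 must be in (0, 1)")
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  if (k == 0) return(0)
  log_tail <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = TRUE)
  max(0, -log_tail / log(2))
}

#' Background per-window match probability for a motif
#'
#' Probability that one window of i.i.d. bases matches the consensus with
#' at most `max_mismatches` mismatches.  Base frequencies come from a
#' background region set when given (counted on both strands, so the model
#' is strand-symmetric), else must be supplied directly.
#'
#' @param motif One-row `motif_set`.
#' @param background Optional region set used to estimate base frequencies.
#' @param base_freqs Optional named vector of A/C/G/T frequencies
#'   (overrides `background`).
#' @return Match probability in (0,1).
#' @export
background_p0 <- function(motif, background = NULL, base_freqs = NULL) {
  stopifnot(nrow(motif) == 1L)
  if (is.null(base_freqs)) {
    if (is.null(background)) stop("supply background regions or base_freqs")
    base_freqs <- base_frequencies(background)
  }
  base_freqs <- base_freqs[c("A", "C", "G", "T")] / sum(base_freqs)
  cc <- strsplit(motif$consensus, "", fixed = TRUE)[[1]]
  q <- vapply(cc, function(ch) sum(base_freqs[IUPAC_CODES[[ch]]]), numeric(1))
  # P(#mismatches <= m) by convolution over positions
  dp <- 1
  for (qj in q) dp <- c(dp * qj, 0) + c(0, dp * (1 - qj))
  p0 <- sum(dp[seq_len(motif$max_mismatches + 1L)])
  min(max(p0, .Machine$double.xmin), 1 - 1e-12)
}

#' Strand-symmetric base frequencies of a region set
#' @param regions Region set (DNAStringSet or named character).
#' @return Named A/C/G/T frequency vector summing to 1.
#' @export
base_frequencies <- function(regions) {
  chars <- region_chars(regions)
  tab <- table(factor(unlist(strsplit(chars, "", fixed = TRUE), use.names = FALSE),
                      levels = c("A", "C", "G", "T")))
  counts <- as.numeric(tab)
  names(counts) <- c("A", "C", "G", "T")
  # count both strands: A pairs with T, C with G
  sym <- c(A = (counts["A"] + counts["T"]) / 2,
           C = (counts["C"] + counts["G"]) / 2,
           G = (counts["C"] + counts["G"]) / 2,
           T = (counts["A"] + counts["T"]) / 2)
  names(sym) <- c("A", "C", "G", "T")
  sym / sum(sym)
}

# windows scanned for a motif of width w over the regions, both strands
total_windows <- function(regions, width) {
  lens <- if (is.numeric(regions)) regions else region_lengths(regions)
  sum(pmax(0L, lens - width + 1L)) * 2L
}

#' Sig value of a motif over a gene set
#'
#' Counts the motif's occurrences in the occurrence table, the scanned
#' windows in the regions, and applies [sig_value()].
#'
#' @param occurrences Occurrence table for the gene set.
#' @param regions The gene set's upstream regions (or named length vector).
#' @param motif One-row `motif_set`.
#' @param p0 Background per-window probability; see [background_p0()].
#' @return Sig in bits.
#' @export
sig_for_motif <- function(occurrences, regions, motif, p0) {
  k <- sum(occurrences$motif == motif$name)
  n <- total_windows(regions, motif$width)
  sig_value(k, n, p0)
}

# Uniform non-overlapping placement of k intervals with the given widths
# (in left-to-right slot order) on [0, L): sample k distinct values from
# {0..L-W+k-1}, sort, and shift by preceding widths.  Uniform over all
# C(L-W+k, k) arrangements.
place_nonoverlapping <- function(L, widths) {
  k <- length(widths)
  W <- sum(widths)
  M <- L - W + k
  if (M < k) return(NULL)
  x <- sort.int(sample.int(M, k)) - 1L
  x - (seq_len(k) - 1L) + c(0L, cumsum(widths))[seq_len(k)]
}

#' Null inter-motif distances by shuffling occurrence placements
#'
#' For each replicate and gene, repositions the gene's observed numbers of
#' A and B instances uniformly at random (non-overlapping, uniform over
#' valid arrangements, random strand), re-pairs them exactly as
#' [pair_occurrences()] does, and pools all resulting gaps.
#'
#' @param region_len Named vector of region lengths.
#' @param counts_a,counts_b Named per-gene occurrence counts of motifs A
#'   and B (names matching `region_len`; missing genes mean 0).
#' @param width_a,width_b Motif widths in bp.
#' @param max_gap Maximum edge-to-edge gap.
#' @param R Number of replicates.
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @param same_motif Set `TRUE` when A and B are the same motif; each
#'   unordered pair is then counted once per arrangement.
#' @return Integer vector of pooled null gaps.
#' @export
sample_null_distances <- function(region_len, counts_a, counts_b,
                                  width_a, width_b, max_gap = 200L,
                                  R = 1000L, seed = NULL,
                                  same_motif = FALSE) {
  stopifnot(R >= 1L)
  genes <- names(region_len)
  ca <- ifelse(is.na(counts_a[genes]), 0L, counts_a[genes])
  cb <- if (same_motif) integer(length(genes)) else
    ifelse(is.na(counts_b[genes]), 0L, counts_b[genes])
  names(ca) <- names(cb) <- genes
  # genes that cannot yield a pair contribute nothing; skip them
  active <- if (same_motif) genes[ca >= 2L] else genes[ca >= 1L & cb >= 1L]
  with_seed(seed, {
    gaps <- vector("list", length(active))
    for (gi in seq_along(active)) {
      g <- active[gi]
      L <- region_len[[g]]
      a <- ca[[g]]; b <- cb[[g]]
      labels <- c(rep("A", a), rep("B", b))
      widths <- c(rep(width_a, a), rep(width_b, b))
      k <- length(labels)
      if (L - sum(widths) < 0L) {
        warning("gene ", g, " too short to place all instances; skipped")
        next
      }
      gg <- vector("list", R)
      for (r in seq_len(R)) {
        perm <- if (k > 1L) sample.int(k) else 1L
        starts <- place_nonoverlapping(L, widths[perm])
        if (is.null(starts)) {
          warning("gene ", g, " too short to place all instances; skipped")
          break
        }
        ends <- starts + widths[perm]
        lab <- labels[perm]
        gg[[r]] <- null_pair_gaps(starts, ends, lab, max_gap, same_motif)
      }
      gaps[[gi]] <- unlist(gg, use.names = FALSE)
    }
    unlist(gaps, use.names = FALSE)
  })
}

# gaps of all qualifying A/B pairs among placed instances (slot order is
# position order because placements do not overlap)
null_pair_gaps <- function(starts, ends, labels, max_gap, same_motif) {
  k <- length(starts)
  if (k < 2L) return(integer(0))
  res <- integer(0)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- if (same_motif) labels[i] == labels[j] else labels[i] != labels[j]
      if (!ok) next
      gap <- starts[j] - ends[i]
      if (gap >= 0L && gap <= max_gap) res <- c(res, gap)
    }
  }
  res
}

#' Area-between-curves spacing statistic
#'
#' Compares the actual inter-motif distance distribution to a shuffling
#' null: `ABC = (mean(null) - mean(actual)) / d_max`, which equals the
#' signed area between the two empirical CDFs over `[0, d_max]` divided by
#' `d_max`.  Positive values mean actual modules are tighter than chance;
#' the statistic is clamped to `[-1, +1]`.
#'
#' @param actual_gaps,null_gaps Non-empty numeric vectors of gaps in
#'   `[0, d_max]`.
#' @param d_max Maximum possible gap (defaults to the pairing `max_gap`).
#' @return ABC score in `[-1, 1]`.
#' @examples
#' abc_score(c(0, 0, 0), c(200, 200, 200), 200)   # +1
#' abc_score(c(10, 20), c(40, 60), 100)           # 0.35
#' @export
abc_score <- function(actual_gaps, null_gaps, d_max) {
  if (length(actual_gaps) == 0L || length(null_gaps) == 0L) {
    stop("actual_gaps and null_gaps must be non-empty")
  }
  stopifnot(d_max > 0)
  abc <- (mean(null_gaps) - mean(actual_gaps)) / d_max
  min(1, max(-1, abc))
}

#' Positional-bias statistic of module upstream positions
#'
#' One-sample Kolmogorov-Smirnov statistic of the module upstream
#' distances against Uniform(0, L):
#' `D = sup |F_empirical - F_uniform|`, in `[0, 1]`.  Ties are handled by
#' evaluating the empirical CDF at sample points and their left limits.
#'
#' @param positions Upstream distances (bp from the translation start) of
#'   the module midpoints, in `[0, L]`.
#' @param L Region length in bp.
#' @return KS statistic D.
#' @export
position_score <- function(positions, L) {
  n <- length(positions)
  if (n == 0L) stop("positions must be non-empty")
  stopifnot(all(positions >= 0), all(positions <= L))
  x <- sort(positions) / L
  i <- seq_len(n)
  max(pmax(i / n - x, x - (i - 1) / n))
}

#' Gene-set coverage of a module
#'
#' Fraction of genes in the starting gene set containing at least one
#' instance of the module; a gene with several instances counts once.
#'
#' @param genes_with_module Number of distinct genes with >= 1 instance.
#' @param genes_total Size of the gene set (> 0).
#' @return Coverage in `[0, 1]`.
#' @export
module_coverage <- function(genes_with_module, genes_total) {
  if (genes_total <= 0) stop("genes_total must be positive")
  stopifnot(genes_with_module >= 0, genes_with_module <= genes_total)
  genes_with_module / genes_total
}

#' Strand-orientation preference score
#'
#' `|2 f_same - 1|`: symmetric, so a consistent preference for same-strand
#' or for opposite-strand placement both score high, and no preference
#' (f_same = 0.5) scores 0.
#'
#' @param f_same Fraction of module instances with both motifs on the same
#'   strand, in `[0, 1]`.
#' @return Orientation score in `[0, 1]`.
#' @export
orientation_score <- function(f_same) {
  stopifnot(f_same >= 0, f_same <= 1)
  abs(2 * f_same - 1)
}

#' Component weights for the combined module score
#' @param sig,abc,position,coverage,orientation Non-negative weights
#'   (sum must be positive).
#' @return A named numeric vector of class `score_weights`.
#' @export
score_weights <- function(sig = 1, abc = 1, position = 1, coverage = 1,
                          orientation = 1) {
  w <- c(sig = sig, abc = abc, position = position, coverage = coverage,
         orientation = orientation)
  if (any(w < 0)) stop("weights must be non-negative")
  if (sum(w) <= 0) stop("at least one weight must be positive")
  class(w) <- "score_weights"
  w
}

#' Combine module attributes into the normalized module score
#'
#' Each component is mapped to `[0, 1]`:
#' `sig_norm = min(min(sig_first, sig_second) / sig_ref, 1)`,
#' `abc_norm = (abc + 1) / 2`; position, coverage and orientation scores
#' are already in `[0, 1]`.  The module score is the weighted mean, so it
#' is normalized to `[0, 1]` and invariant to uniform weight rescaling.
#'
#' @param attrs List or one-row data frame with fields `sig_first`,
#'   `sig_second`, `abc`, `position_score`, `coverage`,
#'   `orientation_f_same`.
#' @param weights A [score_weights()] vector.
#' @param sig_ref Sig saturation point in bits (default 240: values at or
#'   above a typical strong motif's significance saturate the component).
#' @return Module score in `[0, 1]`.
#' @export
combine_module_score <- function(attrs, weights = score_weights(),
                                 sig_ref = 240) {
  stopifnot(sig_ref > 0)
  if (sum(weights) <= 0) stop("all-zero weights")
  comp <- c(
    sig = min(min(attrs$sig_first, attrs$sig_second) / sig_ref, 1),
    abc = (attrs$abc + 1) / 2,
    position = attrs$position_score,
    coverage = attrs$coverage,
    orientation = orientation_score(attrs$orientation_f_same))
  sum(unclass(weights) * comp) / sum(weights)
}

#' Compute all module attributes and the module score for one module order
#'
#' Runs the full scoring path for one (gene set, module order): component
#' Sig values, ABC against a freshly sampled shuffling null, positional
#' KS statistic, coverage, orientation preference, and the combined score.
#'
#' @param regions Upstream regions of the gene set.
#' @param occurrences Occurrence table for the gene set (all motifs).
#' @param order Length-2 character vector, e.g. `c("RRPE", "PAC")`: only
#'   modules with this 5'->3' order are scored.
#' @param motifs `motif_set` containing both component motifs.
#' @param max_gap Pairing gap limit in bp.
#' @param d_max ABC normalization constant (default `max_gap`).
#' @param R Null replicates (default 1000).
#' @param seed Optional seed for the shuffling null.
#' @param background Optional genome-background region set for `p0`
#'   estimation; defaults to the gene set itself.
#' @param weights [score_weights()].
#' @param sig_ref Sig saturation (bits).
#' @return One-row data frame: `order`, `n_genes`, `n_occurrences`,
#'   `sig_first`, `sig_second`, `abc`, `position_score`, `coverage`,
#'   `orientation_f_same`, `median_gap`, `median_upstream_position`
#'   (signed, negative upstream), `module_score`.
#' @export
score_module <- function(regions, occurrences, order, motifs,
                         max_gap = 200L, d_max = max_gap, R = 1000L,
                         seed = NULL, background = NULL,
                         weights = score_weights(), sig_ref = 240) {
  stopifnot(length(order) == 2L)
  lens <- region_lengths(regions)
  label <- order_label(order[1], order[2])
  ma <- motif_row(motifs, order[1])
  mb <- motif_row(motifs, order[2])
  bg <- if (is.null(background)) regions else background
  p0a <- background_p0(ma, background = bg)
  p0b <- background_p0(mb, background = bg)
  sig_first <- sig_for_motif(occurrences, lens, ma, p0a)
  sig_second <- sig_for_motif(occurrences, lens, mb, p0b)

  modules <- pair_occurrences(occurrences, order[1], order[2], lens, max_gap)
  modules <- modules[modules$order == label, , drop = FALSE]
  n_genes <- length(lens)
  base <- data.frame(order = label, n_genes = n_genes,
                     n_occurrences = nrow(modules),
                     sig_first = sig_first, sig_second = sig_second,
                     stringsAsFactors = FALSE)
  if (nrow(modules) == 0L) {
    warning("no modules with order ", label, "; score undefined")
    return(cbind(base, data.frame(
      abc = NA_real_, position_score = NA_real_, coverage = 0,
      orientation_f_same = NA_real_, median_gap = NA_real_,
      median_upstream_position = NA_real_, module_score = NA_real_)))
  }
  same_motif <- identical(order[1], order[2])
  occ_a <- occurrences[occurrences$motif == order[1], , drop = FALSE]
  occ_b <- occurrences[occurrences$motif == order[2], , drop = FALSE]
  counts_a <- table_counts(occ_a$gene_id)
  counts_b <- table_counts(occ_b$gene_id)
  null_gaps <- sample_null_distances(lens, counts_a, counts_b,
                                     ma$width, mb$width, max_gap, R, seed,
                                     same_motif = same_motif)
  abc <- if (length(null_gaps) > 0L)
    abc_score(modules$gap, null_gaps, d_max) else NA_real_
  pos <- position_score(modules$midpoint_dist, max(lens))
  cov <- module_coverage(length(unique(modules$gene_id)), n_genes)
  f_same <- mean(modules$same_strand)
  attrs <- data.frame(
    abc = abc, position_score = pos, coverage = cov,
    orientation_f_same = f_same,
    median_gap = stats::median(modules$gap),
    median_upstream_position = stats::median(modules$signed_position))
  score <- if (is.na(abc)) NA_real_ else
    combine_module_score(cbind(base, attrs), weights, sig_ref)
  cbind(base, attrs, data.frame(module_score = score))
}

table_counts <- function(ids) {
  if (length(ids) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(ids)
  stats::setNames(as.integer(tab), names(tab))
}
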
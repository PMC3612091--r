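# Downstream procedures: positional quartiles, group aggregation,
# orientation-based gene partitioning with term enrichment, and the greedy
# extra-gene search.

#' Fraction of motif occurrences per upstream positional bin
#'
#' Partitions the upstream region into `n_bins` equal bins of
#' `dist_to_atg` (bin 1 proximal to the translation start, covering
#' distances `[0, L/n_bins)`) and returns the fraction of occurrences per
#' bin.  The occurrence position is the upstream distance of its 3' edge;
#' bins are half-open so boundary occurrences are counted once.
#'
#' @param occurrences Occurrence data frame with `dist_to_atg`, or a bare
#'   numeric vector of distances.
#' @param L Region length in bp (default 800).
#' @param n_bins Number of bins (default 4, the quartiles); must divide L.
#' @return Numeric vector of `n_bins` fractions summing to 1, named by bin
#'   interval.
#' @examples
#' quartile_fractions(c(50, 150, 250, 650))   # 0.50 0.25 0.00 0.25
#' @export
quartile_fractions <- function(occurrences, L = 800L, n_bins = 4L) {
  d <- if (is.data.frame(occurrences)) occurrences$dist_to_atg else occurrences
  if (length(d) == 0L) stop("no occurrences")
  if (L %% n_bins != 0L) stop("L must be divisible by n_bins")
  width <- L / n_bins
  if (any(d < 0) || any(d >= L)) stop("distances must lie in [0, L)")
  bin <- pmin(floor(d / width), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  fr <- counts / length(d)
  names(fr) <- paste0(seq(0L, by = width, length.out = n_bins), "-",
                      seq(width, by = width, length.out = n_bins))
  fr
}

#' Does the proximal bin hold the most occurrences?
#'
#' `TRUE` iff the first (most proximal) bin has the strict maximum
#' fraction; ties give `FALSE` with a warning.
#'
#' @param fractions Output of [quartile_fractions()].
#' @return Logical flag.
#' @export
proximal_majority_flag <- function(fractions) {
  if (fractions[1] > max(fractions[-1])) return(TRUE)
  if (fractions[1] == max(fractions[-1])) {
    warning("proximal bin ties with another bin; flag is FALSE")
  }
  FALSE
}

#' Aggregate module attributes over groups of gene sets
#'
#' Computes the arithmetic mean of every numeric attribute per
#' (group x module order) and appends display transforms: `abc_display =
#' abc + 1` (shifting the ABC range to `[0, 2]` for plotting pipelines
#' that cannot take negatives) and `upstream_display =
#' |median_upstream_position|` (how far upstream, as a positive number).
#'
#' @param members Data frame with a `gene_set` label column, an `order`
#'   column and numeric attribute columns (e.g. rows from
#'   [score_module()] plus a `gene_set` label).
#' @param grouping Named character vector mapping gene-set labels to group
#'   labels.
#' @return Data frame of group x order means plus the display columns.
#' @export
aggregate_group_attributes <- function(members, grouping) {
  stopifnot(is.data.frame(members), "gene_set" %in% names(members),
            "order" %in% names(members))
  unknown <- setdiff(unique(members$gene_set), names(grouping))
  if (length(unknown) > 0L) {
    stop("no group for gene set label(s): ", paste(unknown, collapse = ", "))
  }
  members$group <- unname(grouping[members$gene_set])
  num_cols <- setdiff(names(members)[vapply(members, is.numeric, logical(1))],
                      c("n_genes"))
  agg <- stats::aggregate(members[num_cols],
                          by = list(group = members$group,
                                    order = members$order),
                          FUN = mean)
  agg$n_members <- stats::aggregate(
    seq_len(nrow(members)), by = list(group = members$group,
                                      order = members$order),
    FUN = length)$x
  if ("abc" %in% names(agg)) agg$abc_display <- agg$abc + 1
  if ("median_upstream_position" %in% names(agg)) {
    agg$upstream_display <- abs(agg$median_upstream_position)
  }
  agg[order(agg$group, agg$order), , drop = FALSE]
}

#' Partition genes by exclusive module orientation
#'
#' Splits a gene universe into: genes whose modules are all in `order1`
#' (at least one), genes whose modules are all in `order2`, and excluded
#' genes (both orders, other orders, or no modules at all).
#'
#' @param modules Module data frame (see [pair_occurrences()]).
#' @param order1,order2 Distinct order labels, e.g. `"RRPE-PAC"`.
#' @param genes Optional character vector of the full gene universe;
#'   defaults to the genes present in `modules`.
#' @return List with elements `subset1`, `subset2`, `excluded` (character
#'   vectors of gene ids).
#' @export
partition_by_orientation <- function(modules, order1, order2, genes = NULL) {
  if (identical(order1, order2)) stop("order labels must be distinct")
  if (is.null(genes)) genes <- unique(modules$gene_id)
  orders_by_gene <- split(modules$order, modules$gene_id)
  only <- function(g, ord) {
    o <- orders_by_gene[[g]]
    !is.null(o) && all(o == ord)
  }
  s1 <- genes[vapply(genes, only, logical(1), ord = order1)]
  s2 <- genes[vapply(genes, only, logical(1), ord = order2)]
  list(subset1 = s1, subset2 = s2,
       excluded = setdiff(genes, c(s1, s2)))
}

#' Hypergeometric term enrichment of a gene subset
#'
#' For every annotation term, the exact upper tail
#' `p = P(X >= k)` with `X ~ Hypergeometric(N = |universe|, K = term genes
#' in universe, n = |subset|)`.  Terms with `p <= alpha` are flagged
#' enriched; results are sorted by p.
#'
#' @param subset Character vector of gene ids (must be within `universe`).
#' @param universe Character vector of all gene ids considered.
#' @param annotations Data frame with columns `gene_id`, `term` (see
#'   [read_annotations()]).
#' @param alpha Enrichment threshold on the raw p-value (default 1e-3).
#' @param adjust `"none"` (default; raw p against `alpha`) or `"BH"`
#'   (Benjamini-Hochberg adjusted p against `alpha`).
#' @return Data frame: `term`, `k` (term genes in subset), `K` (in
#'   universe), `n`, `N`, `p`, optionally `p_adj`, and `enriched`.
#' @export
hypergeometric_enrichment <- function(subset, universe, annotations,
                                      alpha = 1e-3,
                                      adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  subset <- unique(subset); universe <- unique(universe)
  outside <- setdiff(subset, universe)
  if (length(outside) > 0L) {
    stop("subset gene(s) absent from universe: ",
         paste(outside, collapse = ", "))
  }
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term")])
  N <- length(universe); n <- length(subset)
  terms <- unique(ann$term)
  if (length(terms) == 0L) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      enriched = logical()))
  }
  K <- vapply(terms, function(t) sum(ann$term == t), integer(1))
  k <- vapply(terms, function(t)
    sum(ann$gene_id[ann$term == t] %in% subset), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, k = k, K = K, n = n, N = N, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$enriched <- out$p_adj <= alpha
  } else {
    out$enriched <- out$p <= alpha
  }
  out[order(out$p, out$term), , drop = FALSE]
}

#' Greedy search for extra genes that improve a motif's Sig value
#'
#' Starting from a gene set, repeatedly adds the candidate gene whose
#' inclusion maximally increases the motif's Sig value (recomputed on the
#' enlarged set each step, with the background probability held fixed),
#' stopping when no candidate increases Sig or `max_added` is reached.
#' Candidates with zero occurrences of the motif are never added.
#'
#' @param set_regions Upstream regions of the starting gene set.
#' @param candidate_regions Upstream regions of candidate genes (disjoint
#'   from the set).
#' @param motif One-row `motif_set` (or a set plus `name`).
#' @param name Motif name when `motif` holds several models.
#' @param background Optional background region set for `p0`; defaults to
#'   set and candidates pooled.
#' @param p0 Optional explicit background probability (overrides
#'   `background`).
#' @param max_added Maximum number of genes to add.
#' @return Data frame of added genes in addition order: `gene_id`,
#'   `n_occurrences`, `sig_before`, `sig_after`.  Zero rows when nothing
#'   improves Sig or `max_added = 0`.
#' @export
extra_gene_search <- function(set_regions, candidate_regions, motif,
                              name = NULL, background = NULL, p0 = NULL,
                              max_added = 20L) {
  if (!is.null(name)) motif <- motif_row(motif, name)
  stopifnot(nrow(motif) == 1L)
  set_len <- region_lengths(set_regions)
  cand_len <- region_lengths(candidate_regions)
  clash <- intersect(names(set_len), names(cand_len))
  if (length(clash) > 0L) {
    stop("candidates overlap the gene set: ", paste(clash, collapse = ", "))
  }
  if (is.null(p0)) {
    bg <- if (is.null(background))
      c(region_chars(set_regions), region_chars(candidate_regions))
    else background
    p0 <- background_p0(motif, background = bg)
  }
  occ_set <- scan_regions(set_regions, motif)
  occ_cand <- scan_regions(candidate_regions, motif)
  cand_k <- table_counts(occ_cand$gene_id)
  k <- nrow(occ_set)
  n <- total_windows(set_len, motif$width)
  win_per_gene <- pmax(cand_len - motif$width + 1L, 0L) * 2L
  pool <- names(cand_len)[names(cand_len) %in% names(cand_k)]  # >=1 occurrence
  added <- list()
  sig_now <- sig_value(k, n, p0)
  while (length(added) < max_added && length(pool) > 0L) {
    sig_if <- vapply(pool, function(g)
      sig_value(k + cand_k[[g]], n + win_per_gene[[g]], p0), numeric(1))
    best <- which.max(sig_if)
    if (sig_if[best] <= sig_now) break
    g <- pool[best]
    added[[length(added) + 1L]] <- data.frame(
      gene_id = g, n_occurrences = cand_k[[g]],
      sig_before = sig_now, sig_after = sig_if[best],
      stringsAsFactors = FALSE)
    k <- k + cand_k[[g]]
    n <- n + win_per_gene[[g]]
    sig_now <- sig_if[best]
    pool <- pool[-best]
  }
  if (length(added) == 0L) {
    return(data.frame(gene_id = character(), n_occurrences = integer(),
                      sig_before = numeric(), sig_after = numeric()))
  }
  out <- do.call(rbind, added)
  rownames(out) <- NULL
  out
}
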
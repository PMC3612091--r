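# Module discovery: a module instance is an ordered (5'->3') pair of motif
# occurrences in one upstream region, separated edge-to-edge by
# 0 <= gap <= max_gap.  Overlapping occurrences (gap < 0) never form a
# module.  The module position is the upstream distance of the midpoint of
# the spanned interval, also reported as a negative signed coordinate.

#' Order label for a 5'->3' pair of occurrences
#'
#' The label reads in the direction of transcription toward the translation
#' start: the occurrence with the smaller start comes first.  Equal starts
#' are broken by lexicographic motif name (a message records the tie).
#'
#' @param motif_first,motif_second Motif names of the 5' and 3' occurrence.
#' @return `"<first>-<second>"`.
#' @export
order_label <- function(motif_first, motif_second) {
  paste0(motif_first, "-", motif_second)
}

module_columns <- function() {
  data.frame(gene_id = character(), order = character(),
             motif_first = character(), motif_second = character(),
             start_first = integer(), end_first = integer(),
             strand_first = character(),
             start_second = integer(), end_second = integer(),
             strand_second = character(),
             gap = integer(), same_strand = logical(),
             midpoint_dist = integer(), signed_position = integer(),
             stringsAsFactors = FALSE)
}

# Pair all combinations of rows of a and b (occurrences of one gene),
# returning the kept module rows.  When same_motif, unordered pairs are
# counted once (i < j over the same table).
pair_one_gene <- function(a, b, max_gap, L, same_motif) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) return(NULL)
  idx <- expand.grid(i = seq_len(na), j = seq_len(nb))
  if (same_motif) idx <- idx[idx$i < idx$j, , drop = FALSE]
  if (nrow(idx) == 0L) return(NULL)
  ai <- a[idx$i, , drop = FALSE]
  bj <- b[idx$j, , drop = FALSE]
  a_first <- ai$start < bj$start |
    (ai$start == bj$start & ai$motif <= bj$motif)
  if (any(ai$start == bj$start)) {
    message("tie at equal starts in gene ", a$gene_id[1],
            "; broken by motif name order")
  }
  first <- ai; second <- bj
  first[!a_first, ] <- bj[!a_first, , drop = FALSE]
  second[!a_first, ] <- ai[!a_first, , drop = FALSE]
  gap <- second$start - first$end
  keep <- gap >= 0L & gap <= max_gap
  if (!any(keep)) return(NULL)
  first <- first[keep, , drop = FALSE]
  second <- second[keep, , drop = FALSE]
  gap <- gap[keep]
  mid_dist <- L - as.integer(round((first$start + second$end) / 2))
  data.frame(
    gene_id = first$gene_id, order = order_label(first$motif, second$motif),
    motif_first = first$motif, motif_second = second$motif,
    start_first = first$start, end_first = first$end,
    strand_first = first$strand,
    start_second = second$start, end_second = second$end,
    strand_second = second$strand,
    gap = gap, same_strand = first$strand == second$strand,
    midpoint_dist = mid_dist, signed_position = -mid_dist,
    stringsAsFactors = FALSE)
}

#' Pair motif occurrences into module instances
#'
#' Forms every 5'->3' pair of one occurrence of motif A and one of motif B
#' in the same gene (either sequence order, so both "A-B" and "B-A" labels
#' can result) whose edge-to-edge gap lies in `[0, max_gap]`.  When
#' `motif_a == motif_b` each unordered pair is counted once.  All
#' qualifying pairs are retained; coverage de-duplicates per gene
#' downstream.
#'
#' @param occurrences Occurrence data frame (several genes/motifs allowed).
#' @param motif_a,motif_b Names of the two component motifs (may be equal).
#' @param region_len Named vector of region lengths, or a region set
#'   (used for the module midpoint position).
#' @param max_gap Maximum edge-to-edge gap in bp (default 200).
#' @return Module data frame with one row per instance: order label, both
#'   occurrences, `gap`, `same_strand`, `midpoint_dist` (upstream distance
#'   of the spanned interval's midpoint) and `signed_position`
#'   (`-midpoint_dist`).
#' @examples
#' occ <- rbind(
#'   data.frame(gene_id = "g1", motif = "RRPE", start = 10, end = 18,
#'              strand = "+", mismatches = 0, dist_to_atg = 782),
#'   data.frame(gene_id = "g1", motif = "PAC", start = 30, end = 36,
#'              strand = "+", mismatches = 0, dist_to_atg = 764))
#' pair_occurrences(occ, "RRPE", "PAC", c(g1 = 800))
#' @export
pair_occurrences <- function(occurrences, motif_a, motif_b, region_len,
                             max_gap = 200L) {
  if (max_gap < 0L) stop("max_gap must be non-negative")
  if (!is.numeric(region_len)) region_len <- region_lengths(region_len)
  same_motif <- identical(motif_a, motif_b)
  occ_a <- occurrences[occurrences$motif == motif_a, , drop = FALSE]
  occ_b <- occurrences[occurrences$motif == motif_b, , drop = FALSE]
  genes <- intersect(unique(occ_a$gene_id), unique(occ_b$gene_id))
  out <- lapply(genes, function(g) {
    L <- region_len[[g]]
    if (is.null(L) || is.na(L)) stop("no region length for gene ", g)
    pair_one_gene(occ_a[occ_a$gene_id == g, , drop = FALSE],
                  occ_b[occ_b$gene_id == g, , drop = FALSE],
                  max_gap, L, same_motif)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(module_columns())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Discover modules for one or more motif pairs
#'
#' Convenience wrapper over [pair_occurrences()] for a list of order pairs,
#' e.g. `list(c("RRPE", "PAC"))`; both sequence orders of each pair are
#' reported (distinguished by the `order` column).
#'
#' @param occurrences Occurrence data frame.
#' @param pairs List of length-2 character vectors of motif names.
#' @param regions Region set or named length vector.
#' @param max_gap Maximum edge-to-edge gap in bp.
#' @return Combined module data frame.
#' @export
discover_modules <- function(occurrences, pairs, regions, max_gap = 200L) {
  lens <- if (is.numeric(regions)) regions else region_lengths(regions)
  out <- lapply(pairs, function(p) {
    stopifnot(length(p) == 2L)
    pair_occurrences(occurrences, p[1], p[2], lens, max_gap)
  })
  res <- do.call(rbind, out)
  res <- unique(res)   # same unordered pair listed twice yields duplicates
  rownames(res) <- NULL
  res
}
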
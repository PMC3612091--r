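test_that("planted gene count follows the rounding rule exactly", {
  sp <- plant_spec(n_genes = 50, coverage = 0.4, seed = 5)
  ds <- generate_dataset(sp)
  expect_equal(length(unique(ds$modules$gene_id)), 20L)
  expect_equal(nrow(ds$modules), 20L)
  expect_equal(nrow(ds$occurrences), 40L)
  expect_length(ds$regions, 50L)
})

test_that("generation is deterministic given the seed", {
  sp <- plant_spec(n_genes = 20, seed = 123)
  a <- generate_dataset(sp)
  b <- generate_dataset(sp)
  expect_identical(as.character(a$regions), as.character(b$regions))
  expect_identical(a$occurrences, b$occurrences)
})

test_that("truth is consistent with sequences: re-scanning finds every planted site", {
  sp <- plant_spec(n_genes = 40, coverage = 0.5, seed = 77)
  ds <- generate_dataset(sp)
  occ <- scan_regions(ds$regions, sp$motifs)
  # containment: accidental background matches are legitimate extras, but
  # every truth row must be rediscovered exactly
  key <- function(x) paste(x$gene_id, x$motif, x$start, x$end, x$strand)
  expect_true(all(key(ds$occurrences) %in% key(occ)))
  # and every truth module is discovered by pairing
  mods <- pair_occurrences(occ, sp$order[1], sp$order[2], ds$regions, 200L)
  mkey <- function(m) paste(m$gene_id, m$order, m$start_first, m$start_second,
                            m$strand_first, m$strand_second)
  expect_true(all(mkey(ds$modules) %in% mkey(mods)))
  expect_true(all(ds$modules$gap == 12L))
})

test_that("mismatched planted sites stay within budget and are recoverable", {
  motifs <- motif_set(RRPE = list(consensus = "TGAAAAWTTT",
                                  max_mismatches = 1),
                      PAC = list(consensus = "GATGAG", max_mismatches = 1))
  sp <- plant_spec(n_genes = 30, coverage = 0.5, motifs = motifs,
                   mismatch_rate = 0.05, seed = 8)
  ds <- generate_dataset(sp)
  occ <- scan_regions(ds$regions, motifs)
  truth1 <- ds$occurrences[ds$occurrences$mismatches <= 1, ]
  key <- function(x) paste(x$gene_id, x$motif, x$start, x$end, x$strand)
  expect_true(all(key(truth1) %in% key(occ)))
})

test_that("background composition matches the requested GC closely", {
  sp <- plant_spec(n_genes = 500, L = 800, gc_content = 0.30, coverage = 0,
                   seed = 9)
  ds <- generate_dataset(sp)
  f <- base_frequencies(ds$regions)
  expect_equal(unname(f["C"] + f["G"]), 0.30, tolerance = 0.01)
})

test_that("infeasible specs error before emitting output", {
  expect_error(generate_dataset(
    plant_spec(n_genes = 5, L = 20,
               gap = list(type = "constant", value = 30), seed = 1)),
    "infeasible")
  expect_error(plant_spec(order = c("RRPE", "NOPE")), "absent")
  expect_error(plant_spec(gap = list(type = "exotic", value = 1)),
               "gap\\$type")
})

test_that("geometric gaps are truncated to what fits", {
  sp <- plant_spec(n_genes = 40, L = 60, coverage = 1,
                   gap = list(type = "geometric", mean = 100), seed = 44,
                   position = "uniform")
  ds <- generate_dataset(sp)
  span_max <- 60L
  expect_true(all(ds$modules$end_second <= span_max))
  expect_true(all(ds$modules$gap >= 0))
})

test_that("independent placement mode plants the requested counts uniformly", {
  nd <- generate_null_dataset(n_genes = 30, counts = c(RRPE = 2L, PAC = 2L),
                              seed = 6)
  expect_equal(nrow(nd$occurrences), 30L * 4L)
  occ <- scan_regions(nd$regions, default_motifs(rrpe = "TGAAAAWTTT"))
  key <- function(x) paste(x$gene_id, x$motif, x$start, x$end, x$strand)
  expect_true(all(key(nd$occurrences) %in% key(occ)))
})

test_that("planted spacing, coverage, strand and position parameters are recovered", {
  motifs <- default_motifs(rrpe = "TGAAAAWTTT")
  sp <- plant_spec(n_genes = 200, coverage = 0.46, p_same_strand = 0.9,
                   gap = list(type = "constant", value = 38), seed = 2024)
  ds <- generate_dataset(sp)
  occ <- scan_regions(ds$regions, motifs)
  mods <- pair_occurrences(occ, "RRPE", "PAC", ds$regions, 200L)
  mods <- mods[mods$order == "RRPE-PAC", ]
  expect_equal(median(mods$gap), 38)
  cov <- length(unique(mods$gene_id)) / 200
  expect_lt(abs(cov - 0.46), 0.03)
  # strand preference on truth-matched modules (accidental modules carry
  # no planted strand signal; containment rule documented in the vignette)
  mkey <- function(m) paste(m$gene_id, m$start_first, m$start_second)
  planted <- mods[mkey(mods) %in% mkey(ds$modules), ]
  expect_lt(abs(mean(planted$same_strand) - 0.9), 0.05)
  # proximal planting biases the position statistic; uniform does not
  expect_gt(position_score(mods$midpoint_dist, 800), 0.3)
  # positional calibration at full coverage: the KS bound is a statement
  # about placement, not coverage, and needs the full 200-module sample
  spu <- plant_spec(n_genes = 200, coverage = 1, position = "uniform",
                    gap = list(type = "constant", value = 12), seed = 2025)
  dsu <- generate_dataset(spu)
  occu <- scan_regions(dsu$regions, motifs)
  mu <- pair_occurrences(occu, "RRPE", "PAC", dsu$regions, 200L)
  mu <- mu[mu$order == "RRPE-PAC", ]
  expect_lt(position_score(mu$midpoint_dist, 800), 0.1)
})
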
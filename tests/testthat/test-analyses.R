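test_that("quartile fractions bin by upstream distance and sum to 1", {
  expect_equal(unname(quartile_fractions(c(50, 150, 250, 650))),
               c(0.5, 0.25, 0, 0.25))
  expect_equal(unname(quartile_fractions(rep(0, 7))), c(1, 0, 0, 0))
  # boundary occurrences land in exactly one half-open bin
  expect_equal(unname(quartile_fractions(c(200, 400, 600, 0))),
               c(0.25, 0.25, 0.25, 0.25))
  set.seed(12)
  for (i in 1:15) {
    d <- sample(0:799, sample(1:50, 1), replace = TRUE)
    expect_equal(sum(quartile_fractions(d)), 1, tolerance = 1e-12)
  }
  expect_error(quartile_fractions(numeric(0)), "no occurrences")
  expect_error(quartile_fractions(c(10), L = 801), "divisible")
})

test_that("proximal majority requires a strict maximum in bin 1", {
  expect_true(proximal_majority_flag(c(0.76, 0.11, 0.07, 0.06)))
  expect_false(proximal_majority_flag(c(0.1, 0.6, 0.2, 0.1)))
  expect_warning(f <- proximal_majority_flag(c(0.25, 0.25, 0.25, 0.25)),
                 "ties")
  expect_false(f)
})

test_that("group aggregation means attributes and applies display transforms", {
  members <- data.frame(
    gene_set = c("sp1", "sp2", "sp1", "sp2"),
    order = c("RRPE-PAC", "RRPE-PAC", "PAC-RRPE", "PAC-RRPE"),
    module_score = c(0.5, 0.6, 0.3, 0.4),
    abc = c(-0.2, -0.32, 0.1, 0.3),
    median_upstream_position = c(-100, -136, -200, -220),
    stringsAsFactors = FALSE)
  grouping <- c(sp1 = "groupA", sp2 = "groupA")
  agg <- aggregate_group_attributes(members, grouping)
  rp <- agg[agg$order == "RRPE-PAC", ]
  expect_equal(rp$module_score, 0.55)
  expect_equal(rp$abc, -0.26)
  expect_equal(rp$abc_display, 0.74)
  expect_equal(rp$median_upstream_position, -118)
  expect_equal(rp$upstream_display, 118)
  expect_equal(rp$n_members, 2L)
  expect_error(aggregate_group_attributes(members, c(sp1 = "groupA")),
               "no group.*sp2")
})

test_that("orientation partition applies the exclusivity rule", {
  mods <- data.frame(
    gene_id = c("a", "a", "b", "c", "c", "d"),
    order = c("RRPE-PAC", "RRPE-PAC", "PAC-RRPE", "RRPE-PAC", "PAC-RRPE",
              "PAC2-RRPE"),
    stringsAsFactors = FALSE)
  p <- partition_by_orientation(mods, "RRPE-PAC", "PAC-RRPE",
                                genes = c("a", "b", "c", "d", "e"))
  expect_equal(p$subset1, "a")
  expect_equal(p$subset2, "b")
  expect_setequal(p$excluded, c("c", "d", "e"))
  expect_length(intersect(p$subset1, p$subset2), 0L)
  # each subset gene carries >= 1 module
  expect_true(all(c(p$subset1, p$subset2) %in% mods$gene_id))
  expect_error(partition_by_orientation(mods, "X", "X"), "distinct")
})

test_that("hypergeometric enrichment is the exact tail", {
  universe <- sprintf("g%03d", 1:100)
  ann <- data.frame(gene_id = universe[1:10], term = "T")
  subset <- universe[1:5]
  res <- hypergeometric_enrichment(subset, universe, ann)
  expect_equal(res$p, choose(10, 5) * choose(90, 0) / choose(100, 5))
  expect_true(res$enriched)

  # term absent from the subset: p = 1
  res0 <- hypergeometric_enrichment(universe[90:95], universe, ann)
  expect_equal(res0$p, 1)
  expect_false(res0$enriched)

  # subset == universe: p = 1 for every term
  resU <- hypergeometric_enrichment(universe, universe, ann)
  expect_true(all(resU$p == 1))

  expect_error(hypergeometric_enrichment(c("zz"), universe, ann),
               "absent from universe")
})

test_that("hypergeometric tail agrees with enumeration for N <= 12", {
  set.seed(31)
  for (i in 1:20) {
    N <- sample(4:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    want <- oracle_hyper_tail(k, K, N, n)
    got <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(got, want, tolerance = 1e-9)
    # and through the user-facing function
    universe <- sprintf("u%02d", 1:N)
    ann <- data.frame(gene_id = universe[seq_len(K)], term = "T")
    subset <- c(universe[seq_len(k)],
                universe[setdiff(seq_len(N), seq_len(K))][seq_len(n - k)])
    if (length(subset) == n && !anyNA(subset)) {
      res <- hypergeometric_enrichment(subset, universe, ann)
      expect_equal(res$p, want, tolerance = 1e-9)
    }
  }
})

test_that("BH adjustment mode is available but off by default", {
  universe <- sprintf("g%02d", 1:40)
  ann <- rbind(data.frame(gene_id = universe[1:6], term = "A"),
               data.frame(gene_id = universe[c(1:3, 20:30)], term = "B"))
  res <- hypergeometric_enrichment(universe[1:6], universe, ann,
                                   adjust = "BH")
  expect_true("p_adj" %in% names(res))
  expect_true(all(res$p_adj >= res$p))
})

test_that("extra gene search is greedy on Sig and obeys its stop rules", {
  pac <- motif_set(PAC = "GATGAG")
  set.seed(63)
  mk_gene <- function(n_sites) {
    chars <- strsplit(random_dna(200, gc = 0.5), "")[[1]]
    if (n_sites > 0) {
      for (j in seq_len(n_sites)) {
        s <- 30 * j
        chars[(s + 1):(s + 6)] <- strsplit("GATGAG", "")[[1]]
      }
    }
    paste(chars, collapse = "")
  }
  set_regions <- setNames(vapply(c(2, 1, 2), mk_gene, character(1)),
                          paste0("s", 1:3))
  # "empty" is built motif-free by construction (AC repeat)
  cands <- setNames(c(mk_gene(3), mk_gene(1), strrep("AC", 100)),
                    c("rich", "poor", "empty"))
  res <- extra_gene_search(set_regions, cands, pac, p0 = 1e-4,
                           max_added = 10)
  expect_false("empty" %in% res$gene_id)
  expect_true(all(diff(c(res$sig_before[1], res$sig_after)) > 0))
  # first addition matches brute-force best single addition
  occ_set <- scan_regions(set_regions, pac)
  k <- nrow(occ_set)
  n <- sum(nchar(set_regions) - 5) * 2
  single <- vapply(names(cands), function(g) {
    kc <- nrow(scan_regions(cands[g], pac))
    sig_value(k + kc, n + (nchar(cands[g]) - 5) * 2, 1e-4)
  }, numeric(1))
  expect_equal(res$gene_id[1], names(which.max(single)))

  expect_equal(nrow(extra_gene_search(set_regions, cands, pac, p0 = 1e-4,
                                      max_added = 0)), 0L)
  expect_error(extra_gene_search(set_regions, set_regions, pac, p0 = 1e-4),
               "overlap")
})
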
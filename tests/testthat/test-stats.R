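test_that("sig_value matches the exact binomial summation oracle", {
  expect_equal(sig_value(0, 10, 0.1), 0)
  expect_error(sig_value(5, 10, 1.2), "p0")
  expect_error(sig_value(11, 10, 0.1), "k must")
  set.seed(11)
  for (i in 1:25) {
    n <- sample(1:30, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.01, 0.6)
    want <- -log2(oracle_binom_tail(k, n, p0))
    expect_equal(sig_value(k, n, p0), want, tolerance = 1e-9)
  }
  # monotone increasing in k at fixed n, p0
  sigs <- vapply(0:20, function(k) sig_value(k, 20, 0.2), numeric(1))
  expect_true(all(diff(sigs) > 0))
})

test_that("background_p0 equals exhaustive window enumeration", {
  # brute force over all 4^w windows of an i.i.d. model
  freqs <- c(A = 0.35, C = 0.15, G = 0.15, T = 0.35)
  for (def in list(list(cons = "GATG", mm = 0L),
                   list(cons = "RWT", mm = 1L))) {
    m <- motif_set(X = list(consensus = def$cons, max_mismatches = def$mm))
    w <- m$width
    grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), w))
    p_exact <- 0
    for (r in seq_len(nrow(grid))) {
      win <- paste(as.character(unlist(grid[r, ])), collapse = "")
      if (iupac_matches(win, def$cons, def$mm)) {
        p_exact <- p_exact + prod(freqs[as.character(unlist(grid[r, ]))])
      }
    }
    expect_equal(background_p0(m, base_freqs = freqs), p_exact,
                 tolerance = 1e-12)
  }
})

test_that("abc_score follows the mean-difference formula and its symmetries", {
  expect_equal(abc_score(c(10, 20), c(40, 60), 100), 0.35)
  x <- c(3, 9, 27, 41)
  expect_identical(abc_score(x, x, 50), 0)
  expect_equal(abc_score(x, rev(c(50, 40, 2, 8)), 50),
               -abc_score(c(50, 40, 2, 8), x, 50))
  expect_error(abc_score(numeric(0), c(1), 10), "non-empty")
})

test_that("position_score is the KS statistic against Uniform(0, L)", {
  expect_equal(position_score(rep(0, 5), 800), 1)
  for (n in c(4, 10, 25)) {
    q <- (seq_len(n) - 0.5) / n * 800
    expect_equal(position_score(q, 800), 1 / (2 * n))
  }
  # duplicating the sample leaves D unchanged
  set.seed(4)
  x <- runif(40, 0, 800)
  expect_equal(position_score(c(x, x), 800), position_score(x, 800))
  # large uniform samples give small D
  set.seed(9)
  d <- vapply(1:20, function(i) position_score(runif(1000, 0, 800), 800),
              numeric(1))
  expect_true(mean(d < 0.06) >= 0.95)
})

test_that("coverage and orientation scores follow their definitions", {
  expect_equal(module_coverage(46, 100), 0.46)
  expect_equal(module_coverage(0, 100), 0)
  expect_error(module_coverage(1, 0), "positive")
  expect_equal(orientation_score(1), 1)
  expect_equal(orientation_score(0.5), 0)
  expect_equal(orientation_score(0), 1)
})

test_that("combined score is a normalized monotone weighted mean", {
  maxed <- list(sig_first = 300, sig_second = 250, abc = 1,
                position_score = 1, coverage = 1, orientation_f_same = 1)
  mined <- list(sig_first = 0, sig_second = 0, abc = -1,
                position_score = 0, coverage = 0, orientation_f_same = 0.5)
  expect_equal(combine_module_score(maxed), 1)
  expect_equal(combine_module_score(mined), 0)
  one <- list(sig_first = 240, sig_second = 240, abc = -1,
              position_score = 0, coverage = 0, orientation_f_same = 0.5)
  expect_equal(combine_module_score(one), 0.2)
  zero_w <- stats::setNames(rep(0, 5),
                            c("sig", "abc", "position", "coverage",
                              "orientation"))
  expect_error(combine_module_score(maxed, zero_w), "weights")

  # monotone non-decreasing in every component; invariant to rescaling
  set.seed(21)
  for (i in 1:10) {
    a <- list(sig_first = runif(1, 0, 300), sig_second = runif(1, 0, 300),
              abc = runif(1, -1, 1), position_score = runif(1),
              coverage = runif(1), orientation_f_same = runif(1, 0.5, 1))
    s <- combine_module_score(a)
    expect_equal(combine_module_score(a, score_weights(2, 2, 2, 2, 2)), s)
    b <- a
    b$coverage <- min(1, a$coverage + 0.1)
    b$abc <- min(1, a$abc + 0.1)
    expect_gte(combine_module_score(b), s)
  }
})

test_that("null distance sampler is deterministic and matches enumeration", {
  lens <- c(g1 = 40L, g2 = 40L)
  ca <- c(g1 = 1L, g2 = 1L); cb <- c(g1 = 1L, g2 = 1L)
  g1 <- sample_null_distances(lens, ca, cb, 6L, 6L, 30L, R = 50, seed = 99)
  g2 <- sample_null_distances(lens, ca, cb, 6L, 6L, 30L, R = 50, seed = 99)
  expect_identical(g1, g2)

  # region exactly wide enough: one forced arrangement, constant gap 0
  forced <- sample_null_distances(c(g1 = 12L), c(g1 = 1L), c(g1 = 1L),
                                  6L, 6L, 30L, R = 20, seed = 1)
  expect_true(all(forced == 0L))

  # 12 bp region, two 4 bp motifs: pooled null matches exhaustive
  # enumeration of all non-overlapping placements within 2% TV
  enum <- integer(0)
  for (s1 in 0:8) for (s2 in 0:8) {
    if (s2 >= s1 + 4 && s2 + 4 <= 12) enum <- c(enum, s2 - (s1 + 4))
  }
  samp <- sample_null_distances(c(g1 = 12L), c(g1 = 1L), c(g1 = 1L),
                                4L, 4L, 100L, R = 5000, seed = 5)
  lv <- 0:4
  tv <- 0.5 * sum(abs(prop.table(table(factor(samp, levels = lv))) -
                        prop.table(table(factor(enum, levels = lv)))))
  expect_lt(tv, 0.02)

  # too-short region is skipped with a warning
  expect_warning(
    out <- sample_null_distances(c(g1 = 8L), c(g1 = 1L), c(g1 = 1L),
                                 6L, 6L, 30L, R = 5, seed = 2),
    "too short")
  expect_length(out, 0L)
})

test_that("score_module assembles all attributes coherently", {
  motifs <- motif_set(RRPE = "TGAAAAWTTT", PAC = "GATGAG")
  sp <- plant_spec(n_genes = 60, coverage = 0.5, motifs = motifs,
                   order = c("RRPE", "PAC"), seed = 314)
  ds <- generate_dataset(sp)
  occ <- scan_regions(ds$regions, motifs)
  a <- score_module(ds$regions, occ, c("RRPE", "PAC"), motifs,
                    R = 200, seed = 17)
  expect_equal(a$order, "RRPE-PAC")
  expect_equal(a$median_gap, 12)
  expect_gte(a$coverage, 0.5)          # accidental modules can only add
  expect_true(a$module_score >= 0 && a$module_score <= 1)
  expect_gte(a$n_occurrences, a$coverage * a$n_genes)
  # same seed, same result
  b <- score_module(ds$regions, occ, c("RRPE", "PAC"), motifs,
                    R = 200, seed = 17)
  expect_identical(a, b)
  # absent order warns and yields NA score
  occ_no_pac2 <- occ[occ$motif != "PAC2", , drop = FALSE]
  expect_warning(z <- score_module(ds$regions, occ_no_pac2, c("PAC", "PAC2"),
                                   default_motifs(), R = 10, seed = 1),
                 "no modules")
  expect_true(is.na(z$module_score))
})
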
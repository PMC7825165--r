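# direct-arithmetic oracle: the two variance components spelled out
vst_oracle <- function(a, b) {
  vt <- var(c(a, b))
  if (vt == 0) return(0)
  vs <- (length(a) * var(a) + length(b) * var(b)) / (length(a) + length(b))
  (vt - vs) / vt
}

test_that("VST limits: identical groups give 0, disjoint constants give 1", {
  expect_equal(window_vst(c(2, 2, 2), c(2, 2, 2)), 0)
  expect_equal(window_vst(c(0, 0, 0), c(2, 2, 2)), 1)
  expect_error(window_vst(1, c(2, 2)), ">= 2 individuals")
})

test_that("the three-vs-three worked example matches direct arithmetic", {
  a <- c(1.8, 2.2, 2.0); b <- c(0.9, 1.1, 1.0)
  # by hand: var(a) = 0.04, var(b) = 0.01, pooled var of the six values
  vt <- var(c(a, b))
  expected <- (vt - (3 * 0.04 + 3 * 0.01) / 6) / vt
  expect_equal(window_vst(a, b), expected, tolerance = 1e-12)
  expect_equal(window_vst(a, b), vst_oracle(a, b), tolerance = 1e-15)
})

test_that("VST is invariant to shifts, relabeling and group swap", {
  set.seed(301)
  for (i in 1:20) {
    a <- rnorm(4, 2, 0.3); b <- rnorm(6, 1.4, 0.3)
    v <- window_vst(a, b)
    expect_equal(window_vst(a + 5, b + 5), v, tolerance = 1e-12)
    expect_equal(window_vst(sample(a), b), v)
    expect_equal(window_vst(b, a), v)
    expect_lte(v, 1)
  }
})

test_that("VST grows with between-group separation at fixed within-variance", {
  set.seed(302)
  a0 <- rnorm(8, 0, 0.25); a0 <- a0 - mean(a0) # centre so the separation
  b0 <- rnorm(8, 0, 0.25); b0 <- b0 - mean(b0) # between means is exactly d
  vals <- vapply(seq(0, 2, by = 0.25),
                 function(d) window_vst(a0, b0 + d), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("per-CNVR VST averages windows and matches single-window value", {
  lay <- genome_layout(c(chr1 = 6e4), 100)
  inds <- tibble::tibble(individual_id = paste0("i", 1:6),
                         group = rep(c("A", "B"), each = 3))
  set.seed(303)
  win <- layout_windows(lay)
  norm <- purrr::map_dfr(seq_len(6), function(k) {
    tibble::tibble(individual_id = paste0("i", k), chrom = win$chrom,
                   start = win$start, end = win$end,
                   rd = rnorm(nrow(win), mean = ifelse(k <= 3, 2, 1.2),
                              sd = 0.2))
  })
  one <- tibble::tibble(cnvr_id = "c1", chrom = "chr1", start = 300, end = 400)
  rec <- cnvr_vst(one, norm, inds)
  expect_equal(rec$n_windows_averaged, 1)
  w <- norm[norm$start == 300, ]
  expect_equal(rec$vst, window_vst(w$rd[w$individual_id %in% paste0("i", 1:3)],
                                   w$rd[w$individual_id %in% paste0("i", 4:6)]),
               tolerance = 1e-12)
  # multi-window CNVR: mean of per-window VST values, bounded by 1
  many <- tibble::tibble(cnvr_id = "c2", chrom = "chr1", start = 0, end = 5000)
  rec2 <- cnvr_vst(many, norm, inds)
  expect_equal(rec2$n_windows_averaged, 50)
  expect_lte(rec2$vst, 1)
  expect_error(cnvr_vst(tibble::tibble(cnvr_id = "c3", chrom = "chr9",
                                       start = 0, end = 100), norm, inds),
               "outside")
})

test_that("a CNVR with identical pooled signal has VST 0", {
  lay <- genome_layout(c(chr1 = 2e4), 100)
  inds <- tibble::tibble(individual_id = paste0("i", 1:4),
                         group = rep(c("A", "B"), each = 2))
  win <- layout_windows(lay)
  norm <- purrr::map_dfr(paste0("i", 1:4), function(id)
    tibble::tibble(individual_id = id, chrom = win$chrom, start = win$start,
                   end = win$end, rd = 2))
  rec <- cnvr_vst(tibble::tibble(cnvr_id = "c", chrom = "chr1", start = 0,
                                 end = 2e4), norm, inds)
  expect_equal(rec$vst, 0)
  expect_equal(rec$vt, 0)
})

test_that("candidate selection equals brute-force sort-and-cut with ties kept", {
  set.seed(304)
  rec <- tibble::tibble(cnvr_id = sprintf("c%02d", 1:20), chrom = "chr1",
                        start = 1:20 * 1000, end = 1:20 * 1000 + 500,
                        vst = round(runif(20), 2))
  sel <- select_candidates(rec, top_fraction = 0.25)
  want_thr <- sort(rec$vst, decreasing = TRUE)[ceiling(0.25 * 20)]
  expect_setequal(sel$cnvr_id, rec$cnvr_id[rec$vst >= want_thr])
  expect_equal(attr(sel, "vst_threshold"), want_thr)

  # 100 records, top 5% with unique values -> exactly 5
  r100 <- tibble::tibble(cnvr_id = sprintf("c%03d", 1:100), chrom = "chr1",
                         start = 0, end = 1, vst = seq(0.01, 1, by = 0.01))
  expect_equal(nrow(select_candidates(r100, top_fraction = 0.05)), 5)

  # a 3-way tie spanning rank 5 keeps all tied records under top_k
  tied <- tibble::tibble(cnvr_id = sprintf("t%02d", 1:10), chrom = "chr1",
                         start = 0, end = 1,
                         vst = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.5, 0.5, 0.2,
                                 0.1, 0.05))
  expect_equal(nrow(select_candidates(tied, top_k = 5)), 7)
  expect_error(select_candidates(tied, top_k = 0), "positive")
})

test_that("planted fully differentiated deletions score near-maximal VST", {
  lay <- genome_layout(c(chr1 = 4e5), 100)
  vsts <- vapply(1:3, function(s) {
    des <- population_design(n_per_group = 4, n_shared_cnvs = 0,
                             n_group_specific_cnvs = 0, seed = s)
    # every group-A individual homozygous-deleted over one 3 kb locus
    a_ids <- des$individuals$individual_id[des$individuals$group == "horned"]
    truth <- tibble::tibble(individual_id = a_ids, chrom = "chr1",
                            start = 2e5, end = 2.03e5, true_cn = 0,
                            differentiated = TRUE, locus = "locus_001")
    depth <- purrr::map_dfr(des$individuals$individual_id,
                            ~ simulate_depth(lay, truth, .x, des))
    norm <- normalize_depth(depth)
    cnvr <- tibble::tibble(cnvr_id = "planted", chrom = "chr1",
                           start = 2e5, end = 2.03e5)
    cnvr_vst(cnvr, norm, des$individuals)$vst
  }, numeric(1))
  expect_true(all(vsts > 0.5))
  expect_gte(mean(vsts), 0.8)
})
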
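mk_depth <- function(counts, q0 = 0, chrom = "chr1", id = "ind1") {
  n <- length(counts)
  tibble::tibble(individual_id = id, chrom = chrom,
                 start = (seq_len(n) - 1) * 100, end = seq_len(n) * 100,
                 count = counts, q0_frac = rep_len(q0, n))
}

test_that("normalization puts constant depth at rd = 2 exactly", {
  dep <- mk_depth(rep(30, 200))
  norm <- normalize_depth(dep)
  expect_equal(norm$rd, rep(2, 200))
  expect_equal(norm$global_mean_raw[1], 30)
})

test_that("a depressed region lands at the expected rd ratio", {
  counts <- c(rep(30, 490), rep(15, 10))
  norm <- normalize_depth(mk_depth(counts), trim = 0.1)
  # trimmed mean of the background is 30, so the region sits at 2*15/30 = 1
  expect_equal(unique(norm$rd[counts == 15]), 1, tolerance = 1e-12)
})

test_that("trimmed mean matches direct arithmetic on a toy track", {
  counts <- c(101:180, rep(1000, 20)) # 20% outliers at the top
  dep <- mk_depth(counts)
  norm <- normalize_depth(dep, trim = 0.1)
  m <- mean(sort(counts)[11:90]) # drop 10 lowest and 10 highest of 100
  expect_equal(norm$global_mean_raw[1], m)
  expect_equal(norm$rd, 2 * counts / m)
  # trim = 0: plain mean, so mean(rd) is exactly 2
  norm0 <- normalize_depth(dep, trim = 0)
  expect_equal(mean(norm0$rd), 2, tolerance = 1e-12)
})

test_that("degenerate depth tracks are rejected", {
  expect_error(normalize_depth(mk_depth(rep(0, 200))), "all-zero")
  expect_error(normalize_depth(mk_depth(rep(30, 50))), "at least 100")
})

test_that("sex chromosomes are excluded from the global mean", {
  dep <- dplyr::bind_rows(mk_depth(rep(30, 150)),
                          mk_depth(rep(15, 150), chrom = "chrX"))
  norm <- normalize_depth(dep, trim = 0)
  expect_equal(norm$global_mean_raw[1], 30) # X at half depth does not drag it
  expect_equal(unique(norm$rd[norm$chrom == "chrX"]), 1)
})

test_that("a constant track yields one segment per chromosome", {
  dep <- dplyr::bind_rows(mk_depth(rep(30, 150)),
                          mk_depth(rep(30, 120), chrom = "chr2"))
  segs <- segment_depth(normalize_depth(dep))
  expect_equal(nrow(segs), 2)
  expect_equal(segs$n_windows, c(150, 120))
  expect_equal(segs$mean_rd, c(2, 2))
})

test_that("a planted step is segmented at the right boundaries", {
  set.seed(42)
  counts <- rpois(120, c(rep(30, 50), rep(15, 20), rep(30, 50)))
  segs <- segment_depth(normalize_depth(mk_depth(counts), trim = 0.1))
  expect_equal(nrow(segs), 3)
  expect_lte(abs(segs$start[2] - 5000), 100) # breakpoints within one window
  expect_lte(abs(segs$end[2] - 7000), 100)
  # determinism
  segs2 <- segment_depth(normalize_depth(mk_depth(counts), trim = 0.1))
  expect_identical(segs, segs2)
})

test_that("segments always tile the windowed extent", {
  for (s in 1:5) {
    sim <- sim_one(seed = 300 + s, chrom_len = 3e5, n_cnvs = 3)
    segs <- segment_depth(normalize_depth(sim$depth))
    expect_equal(segs$start[1], 0)
    expect_equal(segs$end[nrow(segs)], 3e5)
    expect_equal(segs$start[-1], segs$end[-nrow(segs)]) # no gaps, no overlaps
    expect_equal(segs$end - segs$start, segs$n_windows * 100)
  }
})

test_that("diploid segments produce no calls", {
  dep <- mk_depth(rep(30, 200))
  norm <- normalize_depth(dep)
  calls <- call_cnvs(segment_depth(norm), norm)
  expect_equal(nrow(calls), 0)
})

test_that("planted deletions and duplications are called with correct CN", {
  sim <- sim_one(seed = 21, chrom_len = 1e6, n_cnvs = 6, dup_frac = 0.5)
  norm <- normalize_depth(sim$depth)
  calls <- call_cnvs(segment_depth(norm), norm)
  ev <- evaluate_calls(calls, sim$truth, sim$layout)
  expect_true(all(ev$per_event$recovered))
  expect_true(all(ev$per_event$cn_error <= 0.3))
  del <- sim$truth[sim$truth$true_cn < 2, ]
  if (nrow(del) > 0) {
    m <- calls[calls$start < del$end[1] & calls$end > del$start[1], ]
    expect_true(all(m$call_type == "deletion"))
    expect_true(all(m$e_val < 0.01))
  }
})

test_that("single-window segments cannot reach significance", {
  seg <- tibble::tibble(individual_id = "ind1", chrom = "chr1", start = 0,
                        end = 100, n_windows = 1L, mean_rd = 0.2)
  norm <- normalize_depth(mk_depth(c(3, rep(30, 199))))
  call <- call_cnvs(seg, norm)
  expect_equal(call$e_val, 1)
  expect_equal(nrow(filter_calls(call)), 0)
})

test_that("the three filters each remove their own failure mode", {
  base <- tibble::tibble(individual_id = "i", chrom = "chr1", start = 0,
                         call_type = "deletion", cn = 0.8)
  calls <- dplyr::bind_rows(
    dplyr::mutate(base, end = 800, e_val = 1e-5, q0 = 0.1),  # too small
    dplyr::mutate(base, end = 1500, e_val = 0.02, q0 = 0.1), # not significant
    dplyr::mutate(base, end = 1500, e_val = 1e-5, q0 = 0.6), # repeat-ridden
    dplyr::mutate(base, end = 1500, e_val = 1e-5, q0 = 0.1)) # keeper
  kept <- filter_calls(calls)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$end, 1500)
  # the 1000 bp boundary itself is excluded (strictly greater than 1 kb)
  at_bound <- dplyr::mutate(base, end = 1000, e_val = 1e-5, q0 = 0.1)
  expect_equal(nrow(filter_calls(at_bound)), 0)
})

test_that("filtering is a pure idempotent predicate", {
  sim <- sim_one(seed = 23, chrom_len = 5e5, n_cnvs = 4)
  norm <- normalize_depth(sim$depth)
  calls <- call_cnvs(segment_depth(norm), norm)
  f1 <- filter_calls(calls)
  expect_identical(filter_calls(f1), f1)
  expect_lte(nrow(f1), nrow(calls))
})

test_that("high-q0 regions are filtered by the q0 rule", {
  bad <- tibble::tibble(chrom = "chr1", start = 5e5, end = 5.1e5, q0 = 0.9)
  sim <- sim_one(seed = 25, chrom_len = 1e6, n_cnvs = 0, q0_inflate = bad)
  # plant a deletion inside the high-q0 region by editing the counts directly
  dep <- sim$depth
  hit <- dep$start >= 5e5 & dep$end <= 5.1e5
  dep$count[hit] <- rpois(sum(hit), 1)
  norm <- normalize_depth(dep)
  calls <- call_cnvs(segment_depth(norm), norm)
  inside <- calls[calls$start < 5.1e5 & calls$end > 5e5, ]
  expect_gt(nrow(inside), 0)       # it is called ...
  expect_true(all(inside$q0 > 0.5))
  expect_equal(nrow(filter_calls(inside)), 0) # ... and removed by q0
})
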
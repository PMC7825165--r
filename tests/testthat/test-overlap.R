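ref_set <- function(iv, name = "ref", labels = NULL) {
  iv$label <- labels %||% sprintf("r%03d", seq_len(nrow(iv)))
  interval_set(iv, name = name)
}

test_that("overlap accounting is reference-anchored", {
  q <- tibble::tibble(cnvr_id = "c1", chrom = "chr1", start = 1000, end = 5000)
  ref <- ref_set(tibble::tibble(chrom = "chr1",
                                start = c(1500, 2000, 9000),
                                end = c(2500, 4000, 9500)))
  rep <- overlap_sets(q, ref)
  expect_equal(rep$n_reference, 3)
  expect_equal(rep$n_reference_overlapped, 2)
  expect_equal(glance(rep)$overlap_percentage, 66.67)
  # a nested reference record is counted once however many queries hit it
  q2 <- dplyr::bind_rows(q, tibble::tibble(cnvr_id = "c2", chrom = "chr1",
                                           start = 1600, end = 1800))
  expect_equal(overlap_sets(q2, ref)$n_reference_overlapped, 2)
  # percentage recomputed from the pair list agrees with the report
  expect_equal(overlap_pct(dplyr::n_distinct(rep$pairs$reference_label),
                           rep$n_reference, digits = Inf),
               rep$overlap_percentage)
})

test_that("disjoint sets report zero overlap", {
  q <- tibble::tibble(cnvr_id = "c1", chrom = "chr1", start = 0, end = 100)
  ref <- ref_set(tibble::tibble(chrom = "chr2", start = 0, end = 100))
  rep <- overlap_sets(q, ref)
  expect_equal(rep$n_reference_overlapped, 0)
  expect_equal(glance(rep)$overlap_percentage, 0)
})

test_that("the published comparison percentages follow from the counts", {
  expect_equal(overlap_pct(132, 238), 55.46)
  expect_equal(overlap_pct(17, 135), 12.59)
  expect_equal(overlap_pct(153, 3488), 4.39)
})

test_that("overlap_sets matches the brute-force oracle on random sets", {
  set.seed(201)
  for (rep_i in 1:35) {
    q <- random_intervals(30, chrom_len = 1e5)
    q$cnvr_id <- sprintf("c%02d", seq_len(nrow(q)))
    r <- ref_set(random_intervals(20, chrom_len = 1e5))
    got <- overlap_sets(q, r)
    want <- oracle_overlapped_refs(q$start, q$end, r$start, r$end)
    expect_equal(got$n_reference_overlapped, sum(want))
    # pair list equals all-pairs intersection
    want_pairs <- sum(outer(seq_len(nrow(q)), seq_len(nrow(r)),
                            Vectorize(function(i, j)
                              oracle_overlap_bp(q$start[i], q$end[i],
                                                r$start[j], r$end[j]) > 0)))
    expect_equal(nrow(got$pairs), want_pairs)
  }
})

test_that("QTL association counts CNVRs and distinct QTL labels", {
  q <- tibble::tibble(cnvr_id = c("c1", "c2", "c3"), chrom = "chr1",
                      start = c(0, 5000, 9000), end = c(3000, 6000, 9500))
  qtl <- ref_set(tibble::tibble(chrom = "chr1", start = c(100, 2500),
                                end = c(600, 3500)),
                 labels = c("milk", "carcass"))
  res <- overlap_qtl(q, qtl)
  expect_equal(res$n_cnvrs_associated, 1) # only c1 touches any QTL
  expect_equal(res$n_qtls_hit, 2)
  empty <- overlap_qtl(q, ref_set(tibble::tibble(chrom = "chr9", start = 0,
                                                 end = 10), labels = "x"))
  expect_equal(empty$n_cnvrs_associated, 0)
  expect_equal(empty$n_qtls_hit, 0)
})

test_that("overlap_qtl matches brute force on random instances", {
  set.seed(202)
  for (rep_i in 1:35) {
    q <- random_intervals(100, chrom_len = 1e5)
    q$cnvr_id <- sprintf("c%03d", seq_len(nrow(q)))
    qtl <- ref_set(random_intervals(20, chrom_len = 1e5),
                   labels = sprintf("trait%02d", 1:20))
    res <- overlap_qtl(q, qtl)
    hit_q <- oracle_overlapped_refs(qtl$start, qtl$end, q$start, q$end)
    hit_r <- oracle_overlapped_refs(q$start, q$end, qtl$start, qtl$end)
    expect_equal(res$n_cnvrs_associated, sum(hit_q))
    expect_equal(res$n_qtls_hit, sum(hit_r))
  }
})

test_that("gene capture honours the >= 50% of gene length rule", {
  q <- tibble::tibble(cnvr_id = "c1", chrom = "chr1", start = 10000,
                      end = 30000)
  genes <- ref_set(tibble::tibble(
    chrom = "chr1",
    start = c(12000, 25000, 25100, 40000),
    end = c(14000, 35000, 35100, 41000)),
    labels = c("inside", "half", "justunder", "away"))
  cap <- annotate_genes(q, genes)
  expect_equal(cap$gene, c("half", "inside"))
  expect_equal(cap$overlap_fraction[cap$gene == "inside"], 1)
  expect_equal(cap$overlap_fraction[cap$gene == "half"], 0.5) # inclusive
  expect_error(annotate_genes(q, ref_set(tibble::tibble(chrom = "chr1",
                                                        start = 5, end = 5),
                                         labels = "null")),
               "end <= start")
})

test_that("gene capture matches brute force on random instances", {
  set.seed(203)
  for (rep_i in 1:30) {
    q <- random_intervals(25, chrom_len = 5e4)
    q$cnvr_id <- sprintf("c%02d", seq_len(nrow(q)))
    genes <- ref_set(random_intervals(15, chrom_len = 5e4, min_len = 200,
                                      max_len = 3000),
                     labels = sprintf("g%02d", 1:15))
    cap <- annotate_genes(q, genes, min_fraction = 0.5)
    for (j in seq_len(nrow(genes))) {
      for (i in seq_len(nrow(q))) {
        frac <- oracle_overlap_bp(q$start[i], q$end[i], genes$start[j],
                                  genes$end[j]) /
          (genes$end[j] - genes$start[j])
        in_cap <- any(cap$gene == genes$label[j] & cap$cnvr_id == q$cnvr_id[i])
        expect_equal(in_cap, frac >= 0.5)
      }
    }
  }
})

test_that("coordinate dialects are converted on load", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\t1\t100\tA", "chr1\t201\t300\tB"), f)
  one <- read_intervals(f, dialect = "one-based")
  expect_equal(one$start, c(0, 200)) # 1-based inclusive -> 0-based half-open
  expect_equal(one$end, c(100, 300))
  bed <- read_intervals(f, dialect = "bed")
  expect_equal(bed$start, c(1, 201))
  bad <- tempfile(fileext = ".tsv")
  writeLines("chr1\t500\t400\tA", bad)
  expect_error(read_intervals(bad), "end <= start")
})
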
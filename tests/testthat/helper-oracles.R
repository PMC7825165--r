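`%||%` <- function(x, y) if (is.null(x)) y else x

# Brute-force per-base oracles for the interval operations, deliberately
# naive: label every base of a toy chromosome, then read regions off the
# coverage mask. Only usable on genomes of ~1e5 bases.

# connected components of >= 1 bp overlapping intervals (one chromosome)
oracle_merge_1chrom <- function(start, end) {
  L <- max(end)
  cov <- logical(L)
  for (i in seq_along(start)) cov[(start[i] + 1):end[i]] <- TRUE
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  tibble::tibble(start = starts[r$values], end = ends[r$values])
}

# does reference record j overlap any query interval by >= 1 bp?
oracle_overlapped_refs <- function(q_start, q_end, r_start, r_end) {
  vapply(seq_along(r_start), function(j) {
    any(q_start < r_end[j] & r_start[j] < q_end)
  }, logical(1))
}

# per-pair overlap length in bp
oracle_overlap_bp <- function(s1, e1, s2, e2) {
  max(0, min(e1, e2) - max(s1, s2))
}

# random interval set on one toy chromosome
random_intervals <- function(n, chrom_len = 1e5, min_len = 50, max_len = 5000,
                             chrom = "chr1") {
  start <- sample.int(chrom_len - max_len, n, replace = TRUE)
  len <- sample(min_len:max_len, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(start + len))
}

# minimal call tibble for merge/classify tests
toy_calls <- function(start, end, individual = "ind1", cn = 1,
                      type = ifelse(cn < 2, "deletion", "duplication"),
                      chrom = "chr1") {
  tibble::tibble(individual_id = individual, chrom = chrom, start = start,
                 end = end, call_type = type, cn = cn, e_val = 1e-6, q0 = 0.01)
}

# one simulated individual with planted events, for caller tests
sim_one <- function(seed, chrom_len = 2e6, n_cnvs = 8, dup_frac = 0.1,
                    overdispersion = 20, q0_inflate = NULL) {
  lay <- genome_layout(c(chr1 = chrom_len), window_size = 100)
  des <- population_design(n_per_group = 2, n_shared_cnvs = n_cnvs,
                           n_group_specific_cnvs = 0, freq_shared = 1,
                           duplication_fraction = dup_frac,
                           overdispersion = overdispersion, seed = seed)
  truth <- plant_truth(lay, des)
  id <- des$individuals$individual_id[1]
  depth <- simulate_depth(lay, truth, id, des, q0_inflate = q0_inflate)
  list(layout = lay, design = des, id = id,
       truth = truth[truth$individual_id == id, ], depth = depth)
}
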
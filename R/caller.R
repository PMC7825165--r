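#' Normalize windowed read depth to the diploid copy-number scale
#'
#' Rescales per-window read counts so that the diploid expectation is 2.0:
#' `rd = 2 * count / m`, where `m` is the genome-wide mean count of the
#' individual's autosomal windows. By default `m` is a 10%-trimmed mean, so
#' that large planted or real CNVs do not drag the diploid baseline;
#' `trim = 0` gives the plain mean, under which `mean(rd)` is exactly 2.
#' Windows on sex chromosomes (X/Y and common aliases) are rescaled but do
#' not contribute to `m`.
#'
#' @param depth Per-window depth tibble for one or more individuals
#'   (`individual_id`, `chrom`, `start`, `end`, `count`, optionally
#'   `q0_frac`).
#' @param trim Trim fraction for the global mean (default 0.1).
#' @return The input tibble with an `rd` column appended and, per individual,
#'   attribute-free plain columns (`global_mean_raw` repeated on each row).
#' @export
normalize_depth <- function(depth, trim = 0.1) {
  stopifnot(all(c("individual_id", "chrom", "count") %in% names(depth)))
  dplyr::group_by(depth, .data$individual_id) |>
    dplyr::group_modify(function(d, key) {
      auto <- !(d$chrom %in% .SEX_CHROMS)
      if (sum(auto) < 100) stop("need at least 100 autosomal windows")
      m <- mean(d$count[auto], trim = trim)
      if (!is.finite(m) || m <= 0) {
        stop("all-zero depth track for ", key$individual_id)
      }
      d$rd <- 2 * d$count / m
      d$global_mean_raw <- m
      d
    }) |>
    dplyr::ungroup()
}

# Gaussian kernel smoothing over the window index, truncated at 3h and
# renormalized at the chromosome edges.
gaussian_smooth <- function(x, h) {
  r <- max(1L, ceiling(3 * h))
  k <- stats::dnorm(seq(-r, r) / h)
  n <- length(x)
  if (n == 1) return(x)
  pad <- function(v) c(rev(v[seq_len(min(r, n))]), v, rev(v[seq.int(n - min(r, n) + 1, n)]))
  xs <- stats::filter(pad(x), k / sum(k), sides = 2)
  as.numeric(xs[seq.int(min(r, n) + 1, min(r, n) + n)])
}

# Breakpoints on one chromosome's rd vector: multi-scale smoothed-difference
# detector. Returns boundary positions b meaning "cut between window b and
# b+1". The threshold is t standard deviations of the smoothed difference
# under window-level noise sigma: sd(diff(smooth(x, h))) = sigma * c_h with
# c_h = sqrt(sum(diff(kernel weights)^2)), so one t covers every bandwidth.
# Scales are visited fine to coarse; a coarser-scale candidate is kept only
# if no finer breakpoint already sits within h windows.
find_breakpoints <- function(rd, t, bandwidths, sigma) {
  n <- length(rd)
  if (n < 3) return(integer(0))
  bps <- integer(0)
  for (h in bandwidths) {
    r <- max(1L, ceiling(3 * h))
    k <- stats::dnorm(seq(-r, r) / h)
    c_h <- sqrt(sum(diff(k / sum(k))^2))
    s <- gaussian_smooth(rd, h)
    d <- abs(diff(s))
    cand <- which(d > t * sigma * c_h)
    if (length(cand) == 0) next
    # one breakpoint per run of consecutive candidates, at the steepest point
    runs <- split(cand, cumsum(c(1, diff(cand) != 1)))
    pk <- vapply(runs, function(r) r[which.max(d[r])], integer(1))
    for (b in pk) {
      if (length(bps) == 0 || min(abs(bps - b)) > h) bps <- c(bps, b)
    }
  }
  sort(unique(bps))
}

#' Segment a normalized depth track
#'
#' Deterministically partitions each chromosome's windows into contiguous
#' segments of near-constant normalized depth. The default detector:
#' (1) Gaussian-kernel smoothing of `rd` over the window index at a bandwidth
#' schedule `h` in \{2, 4, 8, 16\} windows; (2) a breakpoint wherever the
#' absolute difference between adjacent smoothed values exceeds `t` standard
#' deviations of that difference under window-level noise — `t * sigma * c_h`
#' with `sigma` the robust (MAD) standard deviation of `rd` and `c_h` the
#' noise-propagation factor of the difference-of-smoothed kernel at
#' bandwidth `h`, so one `t` is calibrated across all scales; (3) iterative
#' merging of adjacent segments whose mean `rd` differ by less than
#' `merge_eps`.
#'
#' @param norm Output of [normalize_depth()] (one or more individuals).
#' @param t Breakpoint threshold in noise standard deviations (default 3.5).
#' @param bandwidths Smoothing bandwidths in windows, fine to coarse.
#' @param merge_eps Mean-difference below which adjacent segments merge
#'   (default 0.3, about one sixth of a copy on the diploid scale).
#' @return A tibble of segments: `individual_id`, `chrom`, `start`, `end`
#'   (window-aligned, 0-based half-open), `n_windows`, `mean_rd`. Segments
#'   tile each chromosome.
#' @export
segment_depth <- function(norm, t = 3.5, bandwidths = c(2, 4, 8, 16),
                          merge_eps = 0.3) {
  stopifnot("rd" %in% names(norm))
  dplyr::group_by(norm, .data$individual_id, .data$chrom) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$start)
      rd <- d$rd
      n <- length(rd)
      sigma <- stats::mad(rd)
      if (sigma == 0) sigma <- stats::sd(rd)
      if (!is.finite(sigma) || sigma == 0) sigma <- 1e-9
      bps <- find_breakpoints(rd, t, bandwidths, sigma)
      bounds <- c(0L, bps, n) # segment i = windows (bounds[i], bounds[i+1]]
      segs <- tibble::tibble(from = bounds[-length(bounds)] + 1L,
                             to = bounds[-1])
      segs$mean_rd <- purrr::map2_dbl(segs$from, segs$to,
                                      ~ mean(rd[.x:.y]))
      # merge closest adjacent pair while below merge_eps
      while (nrow(segs) > 1) {
        dm <- abs(diff(segs$mean_rd))
        i <- which.min(dm)
        if (dm[i] >= merge_eps) break
        segs$to[i] <- segs$to[i + 1]
        segs$mean_rd[i] <- mean(rd[segs$from[i]:segs$to[i]])
        segs <- segs[-(i + 1), ]
      }
      tibble::tibble(start = d$start[segs$from], end = d$end[segs$to],
                     n_windows = segs$to - segs$from + 1L,
                     mean_rd = segs$mean_rd)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$individual_id, .data$chrom, .data$start)
}

#' Call candidate CNVs from segments
#'
#' Segments whose mean normalized depth deviates from the diploid value 2.0
#' by more than `call_margin` become candidate CNV calls. For each candidate:
#' the copy number `cn` is the segment mean `rd` (already on the diploid
#' scale); `e_val` is the two-sided one-sample t-test p-value of the
#' segment's per-window `rd` against the individual's genome-mean `rd`
#' (single-window segments cannot be tested and get `e_val = 1`); `q0` is the
#' read-weighted mean zero-mapping-quality fraction over the segment's
#' windows (0 when the segment has no reads at all, as in a clean homozygous
#' deletion). Calls on sex chromosomes are flagged.
#'
#' @param segments Output of [segment_depth()].
#' @param norm Output of [normalize_depth()] (provides per-window `rd` and
#'   `q0_frac`/`count` columns; `q0_frac` defaults to 0 when absent).
#' @param call_margin Minimum |mean_rd - 2| for a candidate (default 0.5).
#' @return A tibble of calls: `individual_id`, `chrom`, `start`, `end`,
#'   `call_type` ("deletion"/"duplication"), `cn`, `e_val`, `q0`,
#'   `n_windows`, `sex_chrom` flag.
#' @export
call_cnvs <- function(segments, norm, call_margin = 0.5) {
  if (!"q0_frac" %in% names(norm)) norm$q0_frac <- 0
  cand <- segments[abs(segments$mean_rd - 2) > call_margin, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble::tibble(individual_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          call_type = character(), cn = numeric(),
                          e_val = numeric(), q0 = numeric(),
                          n_windows = integer(), sex_chrom = logical()))
  }
  by_ind <- split(norm, norm$individual_id)
  gmean <- vapply(by_ind, function(d) mean(d$rd[!(d$chrom %in% .SEX_CHROMS)]),
                  numeric(1))
  out <- purrr::pmap_dfr(cand, function(individual_id, chrom, start, end,
                                        n_windows, mean_rd, ...) {
    d <- by_ind[[individual_id]]
    w <- d[d$chrom == chrom & d$start >= start & d$end <= end, ]
    e_val <- if (nrow(w) < 2) {
      1 # a one-window segment cannot be tested; never passes the filter
    } else if (stats::sd(w$rd) == 0) {
      if (isTRUE(all.equal(mean_rd, gmean[[individual_id]]))) 1 else 0
    } else {
      stats::t.test(w$rd, mu = gmean[[individual_id]])$p.value
    }
    tot <- sum(w$count %||% rep(1, nrow(w)))
    q0 <- if (is.null(w$count) || tot == 0) {
      if (all(w$q0_frac == 0)) 0 else mean(w$q0_frac)
    } else sum(w$q0_frac * w$count) / tot
    tibble::tibble(individual_id = individual_id, chrom = chrom,
                   start = start, end = end,
                   call_type = if (mean_rd < 2) "deletion" else "duplication",
                   cn = mean_rd, e_val = e_val, q0 = q0,
                   n_windows = as.integer(n_windows),
                   sex_chrom = chrom %in% .SEX_CHROMS)
  })
  if (any(out$sex_chrom)) {
    warning("calls on sex chromosomes are flagged; their diploid CN scale ",
            "may not apply")
  }
  dplyr::arrange(out, .data$individual_id, .data$chrom, .data$start)
}

#' Filter CNV calls by significance, size and mapping quality
#'
#' Retains a call iff its t-test p-value is below `max_pval`, its span is
#' strictly greater than `min_size` bases, and its zero-mapping-quality read
#' fraction is below `max_q0`. Defaults follow the standard read-depth
#' filtering regime: p < 0.01, size > 1 kb, q0 < 0.5. Order is preserved and
#' the filter is idempotent.
#'
#' @param calls A tibble from [call_cnvs()].
#' @param max_pval Significance threshold (exclusive).
#' @param min_size Minimum span in bases (exclusive: a 1000 bp call at the
#'   default is removed).
#' @param max_q0 Maximum q0 (exclusive).
#' @return The retained calls, in input order.
#' @export
filter_calls <- function(calls, max_pval = 0.01, min_size = 1000,
                         max_q0 = 0.5) {
  keep <- calls$e_val < max_pval &
    (calls$end - calls$start) > min_size &
    calls$q0 < max_q0
  calls[keep, , drop = FALSE]
}

#' Call CNVs for a cohort in one step
#'
#' normalize -> segment -> call -> filter, per individual.
#'
#' @param depth Long per-window depth tibble over one or more individuals.
#' @param trim,t,bandwidths,merge_eps,call_margin,max_pval,min_size,max_q0
#'   Stage parameters; see the stage functions.
#' @return Filtered calls for all individuals.
#' @export
call_cohort <- function(depth, trim = 0.1, t = 3.5,
                        bandwidths = c(2, 4, 8, 16), merge_eps = 0.3,
                        call_margin = 0.5, max_pval = 0.01, min_size = 1000,
                        max_q0 = 0.5) {
  norm <- normalize_depth(depth, trim = trim)
  segs <- segment_depth(norm, t = t, bandwidths = bandwidths,
                        merge_eps = merge_eps)
  calls <- call_cnvs(segs, norm, call_margin = call_margin)
  filter_calls(calls, max_pval = max_pval, min_size = min_size,
               max_q0 = max_q0)
}
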
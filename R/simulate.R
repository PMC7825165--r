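#' Describe a simulated study population
#'
#' Bundles the design of a two-group (or multi-group) cohort for the depth
#' simulator: who the individuals are, how many CNV loci to plant, how long
#' they are, and the noise model for windowed read depth. Defaults emulate a
#' moderate-coverage whole-genome resequencing study: 30 reads per 100 bp
#' window on the diploid background, mildly overdispersed counts, and a small
#' baseline fraction of zero-mapping-quality reads.
#'
#' @param individuals A data frame with columns `individual_id` and `group`,
#'   or NULL to build one from `n_per_group` and `groups`.
#' @param n_per_group Number of individuals per group when `individuals` is
#'   NULL (default 8, giving a 16-animal two-group cohort).
#' @param groups Group labels (default `c("horned", "polled")`).
#' @param n_shared_cnvs Number of CNV loci segregating in all groups.
#' @param n_group_specific_cnvs Number of group-differentiated loci.
#' @param cnv_length_range Min/max CNV length in bases; snapped to whole
#'   windows when truth is planted. Must be at least two windows.
#' @param duplication_fraction Probability a planted locus is a duplication
#'   rather than a deletion (deletions dominate in real read-depth call sets).
#' @param freq_shared Carrier frequency of a shared locus in every group.
#' @param freq_high,freq_low Carrier frequencies of a differentiated locus in
#'   its high- and low-frequency group.
#' @param mean_depth Mean read count per window at copy number 2.
#' @param overdispersion Negative-binomial size parameter for window counts;
#'   `Inf` gives Poisson counts.
#' @param q0_baseline Mean per-window fraction of zero-mapping-quality reads.
#' @param seed Integer seed; mandatory, every draw derives from it.
#'
#' @return A list of class `population_design`.
#' @export
population_design <- function(individuals = NULL,
                              n_per_group = 8,
                              groups = c("horned", "polled"),
                              n_shared_cnvs = 10,
                              n_group_specific_cnvs = 2,
                              cnv_length_range = c(1200, 8000),
                              duplication_fraction = 0.1,
                              freq_shared = 0.5,
                              freq_high = 0.9,
                              freq_low = 0.1,
                              mean_depth = 30,
                              overdispersion = 20,
                              q0_baseline = 0.05,
                              seed) {
  if (missing(seed)) stop("`seed` is mandatory in a population design")
  if (is.null(individuals)) {
    individuals <- tibble::tibble(
      individual_id = paste0(rep(groups, each = n_per_group), "_",
                             rep(seq_len(n_per_group), length(groups))),
      group = rep(groups, each = n_per_group)
    )
  } else {
    individuals <- tibble::as_tibble(individuals)
    stopifnot(all(c("individual_id", "group") %in% names(individuals)))
    groups <- unique(individuals$group)
  }
  if (anyDuplicated(individuals$individual_id)) {
    stop("individual ids must be unique")
  }
  props <- c(duplication_fraction, freq_shared, freq_high, freq_low, q0_baseline)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (length(cnv_length_range) != 2 || diff(cnv_length_range) < 0) {
    stop("`cnv_length_range` must be c(min, max)")
  }
  structure(list(individuals = individuals, groups = groups,
                 n_shared_cnvs = n_shared_cnvs,
                 n_group_specific_cnvs = n_group_specific_cnvs,
                 cnv_length_range = cnv_length_range,
                 duplication_fraction = duplication_fraction,
                 freq_shared = freq_shared, freq_high = freq_high,
                 freq_low = freq_low, mean_depth = mean_depth,
                 overdispersion = overdispersion, q0_baseline = q0_baseline,
                 seed = as.integer(seed)),
            class = "population_design")
}

#' @export
print.population_design <- function(x, ...) {
  cat(sprintf(paste0("<population_design> %d individuals in %d group(s); ",
                     "%d shared + %d differentiated CNV loci; depth %g, ",
                     "NB size %g, seed %d\n"),
              nrow(x$individuals), length(x$groups), x$n_shared_cnvs,
              x$n_group_specific_cnvs, x$mean_depth, x$overdispersion, x$seed))
  invisible(x)
}

# Deterministic sub-seed per individual so a profile does not depend on how
# many other individuals were simulated before it. Kept below 2^31.
.sub_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 2654435L + idx * 97L) %% 2147483563)
}

#' Plant a population CNV truth set
#'
#' Places `n_shared_cnvs + n_group_specific_cnvs` non-overlapping CNV loci on
#' the layout (boundaries snapped to windows, since the caller's resolution is
#' one window) and assigns carriers. Shared loci segregate at `freq_shared` in
#' every group, with at least one carrier per group; differentiated loci
#' segregate at `freq_high` in one group (cycled over groups) and `freq_low`
#' in the others. Each carrier receives an integer copy number: deletions draw
#' CN 0 or 1, duplications CN 3 or 4, equiprobably per carrier.
#'
#' @param layout A [genome_layout()].
#' @param design A [population_design()].
#' @return A tibble of planted truth records: `individual_id`, `chrom`,
#'   `start`, `end` (0-based half-open, window-aligned), `true_cn`,
#'   `differentiated`, and the locus id `locus`.
#' @export
plant_truth <- function(layout, design) {
  stopifnot(inherits(design, "population_design"))
  ws <- window_size(layout)
  if (design$cnv_length_range[1] < 2 * ws) {
    stop("minimum CNV length must be at least two windows")
  }
  empty <- tibble::tibble(individual_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          true_cn = numeric(), differentiated = logical(),
                          locus = character())
  n_loci <- design$n_shared_cnvs + design$n_group_specific_cnvs
  if (n_loci == 0) return(empty)
  set.seed(design$seed)

  # sample non-overlapping window-aligned loci, chromosomes weighted by size
  win_range <- pmax(2, round(design$cnv_length_range / ws))
  occupied <- stats::setNames(vector("list", nrow(layout)), layout$chrom)
  loci <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    placed <- FALSE
    for (try in seq_len(200)) {
      ci <- sample.int(nrow(layout), 1, prob = layout$n_windows)
      chrom <- layout$chrom[ci]
      len_w <- sample(seq(win_range[1], win_range[2]), 1)
      if (len_w > layout$n_windows[ci]) next
      start_w <- sample.int(layout$n_windows[ci] - len_w + 1, 1) - 1L
      iv <- c(start_w, start_w + len_w) # window units, half-open
      clash <- any(vapply(occupied[[chrom]],
                          function(o) iv[1] < o[2] && o[1] < iv[2], logical(1)))
      if (!clash) {
        occupied[[chrom]] <- c(occupied[[chrom]], list(iv))
        loci[[i]] <- tibble::tibble(chrom = chrom, start = iv[1] * ws,
                                    end = iv[2] * ws)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("genome too small to host the requested CNV loci without overlap")
    }
  }
  loci <- dplyr::bind_rows(loci)
  loci$locus <- sprintf("locus_%03d", seq_len(n_loci))
  loci$differentiated <- c(rep(FALSE, design$n_shared_cnvs),
                           rep(TRUE, design$n_group_specific_cnvs))
  loci$is_dup <- stats::runif(n_loci) < design$duplication_fraction
  # differentiated loci favour one group in turn
  loci$high_group <- NA_character_
  if (design$n_group_specific_cnvs > 0) {
    loci$high_group[loci$differentiated] <-
      rep(design$groups, length.out = design$n_group_specific_cnvs)
  }

  ind <- design$individuals
  rows <- purrr::pmap_dfr(loci, function(chrom, start, end, locus,
                                         differentiated, is_dup, high_group) {
    carriers <- purrr::map_dfr(split(ind, ind$group), function(g) {
      f <- if (!differentiated) design$freq_shared
           else if (g$group[1] == high_group) design$freq_high
           else design$freq_low
      take <- stats::runif(nrow(g)) < f
      if (!differentiated && f > 0 && !any(take)) take[sample.int(nrow(g), 1)] <- TRUE
      g[take, ]
    })
    if (nrow(carriers) == 0) return(NULL)
    cn_pool <- if (is_dup) c(3, 4) else c(0, 1)
    tibble::tibble(individual_id = carriers$individual_id, chrom = chrom,
                   start = start, end = end,
                   true_cn = sample(cn_pool, nrow(carriers), replace = TRUE),
                   differentiated = differentiated, locus = locus)
  })
  if (nrow(rows) == 0) return(empty)
  dplyr::arrange(rows, .data$individual_id, .data$chrom, .data$start)
}

#' Simulate a windowed read-depth profile for one individual
#'
#' Draws one read count per window from a negative binomial with mean
#' `mean_depth * cn / 2`, where `cn` is the individual's local true copy
#' number (2 outside planted CNVs), and size `overdispersion`
#' (`Inf` = Poisson). The per-window fraction of zero-mapping-quality reads is
#' drawn from a Beta distribution with mean `q0_baseline`; `q0_inflate` marks
#' intervals whose windows draw around a higher mean instead, to emulate
#' repeat-rich regions and exercise the q0 filter.
#'
#' @param layout A [genome_layout()].
#' @param truth Truth tibble from [plant_truth()] (may be empty).
#' @param individual_id One id present in `design$individuals`.
#' @param design A [population_design()].
#' @param q0_inflate Optional tibble (`chrom`, `start`, `end`, `q0`) of
#'   intervals whose windows use mean q0 `q0` instead of the baseline.
#' @return A tibble with one row per window: `individual_id`, `chrom`,
#'   `start`, `end`, `count`, `q0_frac`.
#' @export
simulate_depth <- function(layout, truth, individual_id, design,
                           q0_inflate = NULL) {
  stopifnot(inherits(design, "population_design"))
  idx <- match(individual_id, design$individuals$individual_id)
  if (is.na(idx)) stop("unknown individual: ", individual_id)
  set.seed(.sub_seed(design$seed, idx))

  win <- layout_windows(layout)
  cn <- rep(2, nrow(win))
  mine <- truth[truth$individual_id == individual_id, , drop = FALSE]
  if (nrow(mine) > 0) {
    for (j in seq_len(nrow(mine))) {
      hit <- win$chrom == mine$chrom[j] &
        win$start < mine$end[j] & win$end > mine$start[j]
      cn[hit] <- mine$true_cn[j]
    }
  }
  mu <- design$mean_depth * cn / 2
  counts <- if (is.finite(design$overdispersion)) {
    stats::rnbinom(length(mu), size = design$overdispersion, mu = mu)
  } else {
    stats::rpois(length(mu), lambda = mu)
  }

  q0_mean <- rep(design$q0_baseline, nrow(win))
  if (!is.null(q0_inflate) && nrow(q0_inflate) > 0) {
    for (j in seq_len(nrow(q0_inflate))) {
      hit <- win$chrom == q0_inflate$chrom[j] &
        win$start < q0_inflate$end[j] & win$end > q0_inflate$start[j]
      q0_mean[hit] <- q0_inflate$q0[j]
    }
  }
  conc <- 50 # Beta concentration: tight q0 noise around the window mean
  q0 <- ifelse(q0_mean <= 0, 0,
               ifelse(q0_mean >= 1, 1,
                      stats::rbeta(nrow(win), q0_mean * conc,
                                   (1 - q0_mean) * conc)))
  tibble::tibble(individual_id = individual_id, chrom = win$chrom,
                 start = win$start, end = win$end,
                 count = as.numeric(counts), q0_frac = q0)
}

#' Simulate a whole cohort
#'
#' Convenience wrapper: plants the truth set, then simulates every
#' individual's depth profile.
#'
#' @inheritParams simulate_depth
#' @return A list with `truth` (tibble) and `depth` (one long tibble over all
#'   individuals).
#' @export
simulate_cohort <- function(layout, design, q0_inflate = NULL) {
  truth <- plant_truth(layout, design)
  depth <- purrr::map_dfr(design$individuals$individual_id,
                          ~ simulate_depth(layout, truth, .x, design,
                                           q0_inflate = q0_inflate))
  list(truth = truth, depth = depth)
}
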
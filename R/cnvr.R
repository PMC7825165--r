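# IRanges helpers: internal coordinates are 0-based half-open, IRanges is
# 1-based closed, so [start, end) maps to IRanges(start + 1, end).
.as_iranges <- function(start, end) IRanges::IRanges(start + 1, end)

#' Merge per-individual CNV calls into CNVRs
#'
#' A copy number variable region (CNVR) is a connected component of the
#' interval-overlap graph over the cohort's filtered calls: calls sharing at
#' least one base are aggregated, and the region spans their union. Abutting
#' calls (`[100,200)` and `[200,300)`) share no base and are NOT merged.
#' Every input call is assigned to exactly one CNVR.
#'
#' @param calls Filtered calls (`individual_id`, `chrom`, `start`, `end`,
#'   `call_type`, `cn`, ...).
#' @return A tibble of class `cnvr_set`: `cnvr_id`, `chrom`, `start`, `end`,
#'   `n_calls`, `n_individuals`, and a list-column `supporting` holding each
#'   region's member calls. Sorted by (chrom, start).
#' @export
merge_cnv_calls <- function(calls) {
  if (any(calls$end <= calls$start)) {
    bad <- which(calls$end <= calls$start)[1]
    stop(sprintf("malformed call at row %d: %s %s:%g-%g", bad,
                 calls$individual_id[bad], calls$chrom[bad],
                 calls$start[bad], calls$end[bad]))
  }
  if (nrow(calls) == 0) {
    out <- tibble::tibble(cnvr_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_calls = integer(), n_individuals = integer(),
                          supporting = list())
    return(tibble::new_tibble(out, class = "cnvr_set"))
  }
  per_chrom <- lapply(split(calls, calls$chrom), function(cc) {
    ir <- .as_iranges(cc$start, cc$end)
    # min.gapwidth = 0L: merge only truly overlapping ranges, not abutting
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red, minoverlap = 1L)
    grp <- S4Vectors::subjectHits(hit)
    tibble::tibble(chrom = cc$chrom[1],
                   start = IRanges::start(red) - 1,
                   end = as.numeric(IRanges::end(red)),
                   supporting = unname(split(cc, grp)))
  })
  out <- dplyr::bind_rows(per_chrom) |>
    dplyr::arrange(.data$chrom, .data$start)
  out$cnvr_id <- sprintf("cnvr_%05d", seq_len(nrow(out)))
  out$n_calls <- purrr::map_int(out$supporting, nrow)
  out$n_individuals <- purrr::map_int(out$supporting,
                                      ~ dplyr::n_distinct(.x$individual_id))
  out <- out[, c("cnvr_id", "chrom", "start", "end", "n_calls",
                 "n_individuals", "supporting")]
  tibble::new_tibble(out, class = "cnvr_set")
}

#' Per-individual copy-number state from a CN estimate
#'
#' The classification thresholds for read-depth copy number on the diploid
#' scale: deleted below 0.4 (near-homozygous loss), conserved in
#' \[0.4, 1.6\] (bounds inclusive), duplicated above 1.6.
#'
#' @param cn Numeric vector of copy numbers (diploid = 2).
#' @param deleted_below,duplicated_above Class bounds.
#' @return Character vector: "deleted", "conserved" or "duplicated".
#' @export
cn_state <- function(cn, deleted_below = 0.4, duplicated_above = 1.6) {
  if (any(cn < 0)) stop("negative copy number")
  dplyr::case_when(cn < deleted_below ~ "deleted",
                   cn > duplicated_above ~ "duplicated",
                   TRUE ~ "conserved")
}

#' Classify CNVRs as deletion, duplication or both
#'
#' Each supporting individual's state is assigned from its CN estimate by
#' [cn_state()]; an individual with several member calls in one region gets
#' the length-weighted mean CN. The region type is "deletion" if only deleted
#' states occur among non-conserved states, "duplication" if only duplicated,
#' and "both" when at least one of each is present; conserved-state
#' individuals are recorded but never set the region type. A region whose
#' supporters are all conserved is typed from the direction of its calls
#' (deletion when every call is a deletion, etc.).
#'
#' @param cnvrs A `cnvr_set` from [merge_cnv_calls()].
#' @inheritParams cn_state
#' @return The input with `region_type` and a list-column `states`
#'   (per-individual `individual_id`, `cn`, `state`).
#' @export
classify_cnvrs <- function(cnvrs, deleted_below = 0.4, duplicated_above = 1.6) {
  res <- purrr::map(cnvrs$supporting, function(sup) {
    st <- sup |>
      dplyr::group_by(.data$individual_id) |>
      dplyr::summarise(
        cn = sum(.data$cn * (.data$end - .data$start)) /
          sum(.data$end - .data$start),
        .groups = "drop")
    st$state <- cn_state(st$cn, deleted_below, duplicated_above)
    has_del <- any(st$state == "deleted")
    has_dup <- any(st$state == "duplicated")
    type <- if (has_del && has_dup) "both"
    else if (has_del) "deletion"
    else if (has_dup) "duplication"
    else if (all(sup$call_type == "duplication")) "duplication"
    else if (all(sup$call_type == "deletion")) "deletion"
    else "both"
    list(states = st, region_type = type)
  })
  cnvrs$region_type <- purrr::map_chr(res, "region_type")
  cnvrs$states <- purrr::map(res, "states")
  cnvrs
}

#' Summarize a CNVR set
#'
#' Cohort- or group-level summary in the style of a published CNV-map table:
#' counts by region type, total length in Mb, mean length in kb, the
#' percentage of the analysed genome covered, per-chromosome counts, and the
#' coefficient of determination of the OLS regression of per-chromosome CNVR
#' count on chromosome length. Lengths and percentages are rounded to two
#' decimals at the reporting boundary ([glance()]/[render_summary_table()]);
#' the returned object keeps full precision.
#'
#' @param cnvrs A classified `cnvr_set` (needs `region_type`).
#' @param layout The [genome_layout()] analysed (denominator for the genome
#'   fraction: the sum of its raw chromosome lengths).
#' @param scope Label for the summary row (default "cohort").
#' @return A list of class `cnvr_summary` with fields `scope`, `n_cnvrs`,
#'   `n_deletion`, `n_duplication`, `n_both`, `total_length_mb`,
#'   `mean_length_kb`, `genome_fraction`, `per_chromosome` (tibble with
#'   `chrom`, `length`, `count`) and `count_length_r2`.
#' @export
summarize_cnvrs <- function(cnvrs, layout, scope = "cohort") {
  per_chrom <- dplyr::left_join(
    layout[, c("chrom", "length")],
    dplyr::count(tibble::as_tibble(cnvrs), .data$chrom, name = "count"),
    by = "chrom")
  per_chrom$count[is.na(per_chrom$count)] <- 0L
  n <- nrow(cnvrs)
  total_bp <- sum(cnvrs$end - cnvrs$start)
  r2 <- if (n == 0 || nrow(per_chrom) < 3 || stats::var(per_chrom$count) == 0) {
    NA_real_
  } else {
    # suppress summary.lm's "essentially perfect fit" note on exact data
    suppressWarnings(
      summary(stats::lm(count ~ length, data = per_chrom))$r.squared)
  }
  structure(list(
    scope = scope,
    n_cnvrs = n,
    n_deletion = sum(cnvrs$region_type == "deletion"),
    n_duplication = sum(cnvrs$region_type == "duplication"),
    n_both = sum(cnvrs$region_type == "both"),
    total_length_mb = total_bp / 1e6,
    mean_length_kb = if (n == 0) NA_real_ else total_bp / n / 1e3,
    genome_fraction = 100 * total_bp / sum(layout$length),
    per_chromosome = per_chrom,
    count_length_r2 = r2
  ), class = "cnvr_summary")
}

#' @export
print.cnvr_summary <- function(x, ...) {
  cat(sprintf(paste0("<cnvr_summary> %s: %d CNVRs (%d deletion, %d ",
                     "duplication, %d both), %.2f Mb total, %.2f kb mean, ",
                     "%.2f%% of genome, count~length R2 = %s\n"),
              x$scope, x$n_cnvrs, x$n_deletion, x$n_duplication, x$n_both,
              x$total_length_mb, x$mean_length_kb, x$genome_fraction,
              ifelse(is.na(x$count_length_r2), "n.a.",
                     sprintf("%.2f", x$count_length_r2))))
  invisible(x)
}

#' @rdname summarize_cnvrs
#' @param x A `cnvr_summary`.
#' @param ... Unused.
#' @export
glance.cnvr_summary <- function(x, ...) {
  tibble::tibble(scope = x$scope, n_cnvrs = x$n_cnvrs,
                 n_deletion = x$n_deletion, n_duplication = x$n_duplication,
                 n_both = x$n_both,
                 total_length_mb = round(x$total_length_mb, 2),
                 mean_length_kb = round(x$mean_length_kb, 2),
                 genome_fraction = round(x$genome_fraction, 2),
                 count_length_r2 = round(x$count_length_r2, 2))
}

#' @rdname summarize_cnvrs
#' @export
tidy.cnvr_summary <- function(x, ...) x$per_chromosome

#' Per-group CNVR presence and sharing
#'
#' A CNVR is present in a group iff at least one supporting individual
#' belongs to it. Returns the presence matrix and the counts of every
#' intersection cell (the Venn partition over groups), whose sum equals the
#' number of distinct CNVRs.
#'
#' @param cnvrs A `cnvr_set`.
#' @param individuals Population table (`individual_id`, `group`).
#' @return A list with `presence` (tibble: `cnvr_id` plus one logical column
#'   per group), `per_group` (named count of CNVRs present per group) and
#'   `cells` (tibble: `groups` label of the exact combination, `n`).
#' @export
group_presence <- function(cnvrs, individuals) {
  grp_of <- stats::setNames(individuals$group, individuals$individual_id)
  groups <- unique(individuals$group)
  pres <- purrr::map(cnvrs$supporting, function(sup) {
    g <- grp_of[unique(sup$individual_id)]
    if (anyNA(g)) {
      stop("individual(s) with unknown group: ",
           paste(unique(sup$individual_id)[is.na(g)], collapse = ", "))
    }
    stats::setNames(groups %in% g, groups)
  })
  mat <- do.call(rbind, pres)
  presence <- tibble::as_tibble(as.data.frame(mat))
  presence <- dplyr::bind_cols(tibble::tibble(cnvr_id = cnvrs$cnvr_id),
                               presence)
  combo <- apply(mat, 1, function(r) paste(groups[r], collapse = "&"))
  cells <- dplyr::count(tibble::tibble(groups = combo), .data$groups,
                        name = "n")
  list(presence = presence,
       per_group = colSums(mat),
       cells = dplyr::arrange(cells, dplyr::desc(.data$n)))
}
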
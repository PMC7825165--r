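#' VST: copy-number population differentiation between two groups
#'
#' `VST = (VT - VS) / VT`, where `VT` is the sample variance of the signal
#' pooled over both groups and `VS` is the mean within-group sample variance
#' weighted by group size: `VS = (n1 v1 + n2 v2) / (n1 + n2)`. Sample
#' variances use the n-1 denominator. When `VT = 0` (a monomorphic window)
#' the statistic is 0 by convention: an invariant site is undifferentiated.
#' VST is bounded above by 1 and behaves like an FST analogue for
#' copy-number signal.
#'
#' @param a,b Numeric signal values (one per individual) for the two groups;
#'   each group needs at least 2 members.
#' @return The VST value (scalar).
#' @examples
#' window_vst(c(0, 0, 0), c(2, 2, 2)) # 1: all variance is between groups
#' @export
window_vst <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs >= 2 individuals (variance undefined otherwise)")
  }
  vt <- stats::var(c(a, b))
  if (!is.finite(vt) || vt == 0) return(0)
  vs <- (length(a) * stats::var(a) + length(b) * stats::var(b)) /
    (length(a) + length(b))
  (vt - vs) / vt
}

#' Mean VST per CNVR from normalized depth tracks
#'
#' Evaluates [window_vst()] on every window inside each CNVR, using each
#' individual's normalized read depth (diploid = 2) as the copy-number
#' signal, and averages the per-window values (unweighted) into a single
#' statistic per region. Windows with zero pooled variance contribute 0.
#'
#' @param cnvrs A `cnvr_set` (or any tibble with `cnvr_id`, `chrom`,
#'   `start`, `end`).
#' @param norm Normalized tracks from [normalize_depth()] covering every
#'   individual in `individuals`.
#' @param individuals Population table (`individual_id`, `group`) with
#'   exactly two groups.
#' @return A tibble of class `vst_records`: `cnvr_id`, `chrom`, `start`,
#'   `end`, `vt` (mean pooled variance over windows), `vs` (mean weighted
#'   within-group variance), `vst` (mean per-window VST),
#'   `n_windows_averaged`, `n1`, `n2`.
#' @export
cnvr_vst <- function(cnvrs, norm, individuals) {
  groups <- unique(individuals$group)
  if (length(groups) != 2) stop("VST is defined between exactly two groups")
  ids1 <- individuals$individual_id[individuals$group == groups[1]]
  ids2 <- individuals$individual_id[individuals$group == groups[2]]
  if (length(ids1) < 2 || length(ids2) < 2) {
    stop("each group needs >= 2 individuals")
  }
  # wide matrix: windows x individuals
  keep <- norm$individual_id %in% c(ids1, ids2)
  wide <- tidyr::pivot_wider(norm[keep, c("individual_id", "chrom", "start",
                                          "end", "rd")],
                             names_from = "individual_id",
                             values_from = "rd")
  if (anyNA(wide)) stop("normalized tracks do not cover all individuals")
  out <- purrr::pmap_dfr(
    tibble::as_tibble(cnvrs)[, c("cnvr_id", "chrom", "start", "end")],
    function(cnvr_id, chrom, start, end) {
      w <- wide[wide$chrom == chrom & wide$start < end & wide$end > start, ]
      if (nrow(w) == 0) {
        stop("CNVR ", cnvr_id, " lies outside the normalized track extent")
      }
      m1 <- as.matrix(w[, ids1])
      m2 <- as.matrix(w[, ids2])
      v1 <- apply(m1, 1, stats::var)
      v2 <- apply(m2, 1, stats::var)
      vt <- apply(cbind(m1, m2), 1, stats::var)
      vs <- (length(ids1) * v1 + length(ids2) * v2) /
        (length(ids1) + length(ids2))
      vst_w <- ifelse(vt == 0, 0, (vt - vs) / vt)
      tibble::tibble(cnvr_id = cnvr_id, chrom = chrom, start = start,
                     end = end, vt = mean(vt), vs = mean(vs),
                     vst = mean(vst_w), n_windows_averaged = nrow(w),
                     n1 = length(ids1), n2 = length(ids2))
    })
  tibble::new_tibble(out, class = "vst_records")
}

#' Select top differentiated CNVRs
#'
#' Ranks VST records in decreasing order and keeps either the top fraction
#' (default 5%, `ceiling(fraction * n)` records) or the top `k`. Records tied
#' with the value at the cut are all kept, so the selection can exceed the
#' nominal count; the threshold actually applied is reported.
#'
#' @param records A `vst_records` tibble.
#' @param top_fraction Fraction to keep (used when `top_k` is NULL).
#' @param top_k Absolute number to keep (overrides `top_fraction`).
#' @return The selected records (with a `candidate` flag set), carrying
#'   attributes `vst_threshold` and `selection_mode`.
#' @export
select_candidates <- function(records, top_fraction = 0.05, top_k = NULL) {
  if (nrow(records) == 0) stop("no VST records to select from")
  n_keep <- if (!is.null(top_k)) {
    if (top_k <= 0) stop("`top_k` must be positive")
    min(as.integer(top_k), nrow(records))
  } else {
    if (top_fraction <= 0) stop("`top_fraction` must be positive")
    min(ceiling(top_fraction * nrow(records)), nrow(records))
  }
  ord <- records[order(-records$vst), ]
  thr <- ord$vst[n_keep]
  sel <- ord[ord$vst >= thr, ]
  sel$candidate <- TRUE
  attr(sel, "vst_threshold") <- thr
  attr(sel, "selection_mode") <-
    if (!is.null(top_k)) sprintf("top_k=%d", top_k)
    else sprintf("top_fraction=%g", top_fraction)
  sel
}

#' Manhattan-style plot of CNVR VST values
#'
#' @param records A `vst_records` tibble.
#' @param top_fraction Fraction marked by the dashed cutoff line.
#' @return A ggplot object: VST per CNVR along the genome, cut line at the
#'   top-fraction threshold.
#' @export
plot_vst <- function(records, top_fraction = 0.05) {
  sel <- select_candidates(records, top_fraction = top_fraction)
  thr <- attr(sel, "vst_threshold")
  df <- dplyr::mutate(tibble::as_tibble(records),
                      pos = (.data$start + .data$end) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$vst,
                                   colour = .data$chrom)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "red") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(V[ST])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.minor = ggplot2::element_blank())
}

#' @rdname plot_vst
#' @param object A `vst_records` tibble.
#' @param ... Passed to [plot_vst()].
#' @export
autoplot.vst_records <- function(object, ...) plot_vst(object, ...)
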
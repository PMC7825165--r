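#' Score recovered CNV calls against a planted truth set
#'
#' Matches each truth record to calls of the same individual on the same
#' chromosome that overlap it by at least one base and agree in direction
#' (deletion vs duplication). A truth event is recovered when such a call
#' exists; its CN error is |called cn - true cn| (length-weighted call cn if
#' several calls cover one event) and its boundary error is the mean of the
#' start and end discrepancies, in windows.
#'
#' @param calls Calls tibble (typically [filter_calls()] output).
#' @param truth Truth tibble from [plant_truth()].
#' @param layout The [genome_layout()] simulated on.
#' @return A list: `per_event` tibble (`individual_id`, `chrom`, `start`,
#'   `end`, `true_cn`, `recovered`, `cn_error`, `boundary_error_windows`),
#'   `sensitivity`, `median_cn_error`, `median_boundary_error_windows`
#'   (medians over recovered events), `n_calls_unmatched` (calls touching no
#'   truth event — false positives on a simulated genome).
#' @export
evaluate_calls <- function(calls, truth, layout) {
  ws <- window_size(layout)
  dir_of <- function(cn) ifelse(cn < 2, "deletion", "duplication")
  per_event <- purrr::pmap_dfr(
    truth[, c("individual_id", "chrom", "start", "end", "true_cn")],
    function(individual_id, chrom, start, end, true_cn) {
      m <- calls[calls$individual_id == individual_id &
                   calls$chrom == chrom &
                   calls$start < end & calls$end > start &
                   calls$call_type == dir_of(true_cn), , drop = FALSE]
      if (nrow(m) == 0) {
        return(tibble::tibble(individual_id = individual_id, chrom = chrom,
                              start = start, end = end, true_cn = true_cn,
                              recovered = FALSE, cn_error = NA_real_,
                              boundary_error_windows = NA_real_))
      }
      wlen <- m$end - m$start
      cn_hat <- sum(m$cn * wlen) / sum(wlen)
      tibble::tibble(individual_id = individual_id, chrom = chrom,
                     start = start, end = end, true_cn = true_cn,
                     recovered = TRUE, cn_error = abs(cn_hat - true_cn),
                     boundary_error_windows =
                       (abs(min(m$start) - start) + abs(max(m$end) - end)) /
                       (2 * ws))
    })
  matched_call <- rep(FALSE, nrow(calls))
  for (j in seq_len(nrow(truth))) {
    matched_call <- matched_call |
      (calls$individual_id == truth$individual_id[j] &
         calls$chrom == truth$chrom[j] &
         calls$start < truth$end[j] & calls$end > truth$start[j])
  }
  list(per_event = per_event,
       sensitivity = mean(per_event$recovered),
       median_cn_error = stats::median(per_event$cn_error, na.rm = TRUE),
       median_boundary_error_windows =
         stats::median(per_event$boundary_error_windows, na.rm = TRUE),
       n_calls_unmatched = sum(!matched_call))
}
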
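#' Copy number from a ddCt value
#'
#' Relative quantification for a diploid calibrator: the target-vs-reference
#' cycle-threshold difference of the test sample minus that of the
#' calibrator gives ddCt, and the copy number is `2 * 2^(-ddCt)` — 2 when
#' the test sample amplifies like the calibrator, halving per extra cycle.
#'
#' @param ddct Numeric ddCt value(s).
#' @return Estimated copy number(s).
#' @examples
#' copy_number_from_ddct(c(0, 1, -1)) # 2, 1, 4
#' @export
copy_number_from_ddct <- function(ddct) 2 * 2^(-ddct)

#' Estimate copy numbers from a qPCR Ct table
#'
#' Expects a tidy long table of cycle thresholds with one row per replicate:
#' columns `sample_id`, `target_id`, `gene` (`"target"` for the assayed locus
#' or `"reference"` for the single-copy reference gene) and `ct`. Replicates
#' are averaged on the Ct scale before any differencing. One sample is
#' designated the (diploid) calibrator; for every other sample and target,
#' dCt_test - dCt_calibrator gives ddCt and [copy_number_from_ddct()] the
#' copy number.
#'
#' @param ct Long Ct tibble as described above.
#' @param calibrator `sample_id` of the calibrator sample.
#' @param max_replicate_sd QC bound: triplicates with a Ct standard deviation
#'   above this are flagged (`qc_flag = TRUE`), not dropped.
#' @return A tibble: `sample_id`, `target_id`, `dct`, `ddct`, `cn`, `state`
#'   (via [cn_state()]), `qc_flag`.
#' @export
qpcr_copy_number <- function(ct, calibrator, max_replicate_sd = 0.5) {
  stopifnot(all(c("sample_id", "target_id", "gene", "ct") %in% names(ct)))
  if (!all(ct$gene %in% c("target", "reference"))) {
    stop("`gene` must be 'target' or 'reference'")
  }
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  if (!calibrator %in% ct$sample_id) {
    stop("calibrator sample not in the table: ", calibrator)
  }
  means <- ct |>
    dplyr::group_by(.data$sample_id, .data$target_id, .data$gene) |>
    dplyr::summarise(ct_mean = mean(.data$ct),
                     ct_sd = ifelse(dplyr::n() > 1, stats::sd(.data$ct), 0),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(means, names_from = "gene",
                             values_from = c("ct_mean", "ct_sd"))
  if (anyNA(wide$ct_mean_target) || anyNA(wide$ct_mean_reference)) {
    stop("missing target or reference Ct for some sample/target")
  }
  wide$dct <- wide$ct_mean_target - wide$ct_mean_reference
  cal <- wide[wide$sample_id == calibrator, c("target_id", "dct")]
  names(cal)[2] <- "dct_cal"
  out <- dplyr::inner_join(wide[wide$sample_id != calibrator, ], cal,
                           by = "target_id")
  out$ddct <- out$dct - out$dct_cal
  out$cn <- copy_number_from_ddct(out$ddct)
  out$state <- cn_state(out$cn)
  out$qc_flag <- out$ct_sd_target > max_replicate_sd |
    out$ct_sd_reference > max_replicate_sd
  out[, c("sample_id", "target_id", "dct", "ddct", "cn", "state", "qc_flag")]
}

#' Score concordance between predicted CNVR states and qPCR copy numbers
#'
#' qPCR copy numbers are mapped to deleted/conserved/duplicated states with
#' the same thresholds used for CNVR classification, and a target region
#' counts as confirmed when the qPCR state agrees with the predicted region
#' type in more than `majority` of its assayed samples. In `lenient` mode a
#' predicted deletion is also confirmed by a heterozygous-range qPCR value
#' (CN < 1.6), acknowledging that single-copy losses sit in the conserved
#' band of the strict thresholds.
#'
#' @param predicted Tibble (`target_id`, `predicted_type`) with
#'   `predicted_type` in deletion/duplication/both.
#' @param qpcr Tibble from [qpcr_copy_number()] (`target_id`, `sample_id`,
#'   `cn`).
#' @param mode `"strict"` or `"lenient"`.
#' @param majority Fraction of samples that must agree (exclusive bound;
#'   default 0.5).
#' @return A list of class `qpcr_concordance`: `per_target` tibble
#'   (`target_id`, `n_samples`, `n_agree`, `confirmed`), `n_confirmed`,
#'   `n_targets`, `rate` (NA when nothing was assayed), `mode`, plus
#'   `unmatched` target ids present on only one side.
#' @export
qpcr_concordance <- function(predicted, qpcr, mode = c("strict", "lenient"),
                             majority = 0.5) {
  mode <- match.arg(mode)
  unmatched <- union(setdiff(predicted$target_id, qpcr$target_id),
                     setdiff(qpcr$target_id, predicted$target_id))
  if (length(unmatched) > 0) {
    warning("unmatched target ids excluded: ",
            paste(unmatched, collapse = ", "))
  }
  joined <- dplyr::inner_join(predicted, qpcr, by = "target_id")
  agrees <- function(pred, cn) {
    st <- cn_state(cn)
    ok <- (pred == "deletion" & st == "deleted") |
      (pred == "duplication" & st == "duplicated") |
      (pred == "both" & st != "conserved")
    if (mode == "lenient") ok <- ok | (pred == "deletion" & cn < 1.6)
    ok
  }
  per_target <- joined |>
    dplyr::group_by(.data$target_id) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_agree = sum(agrees(.data$predicted_type, .data$cn)),
      confirmed = .data$n_agree > majority * .data$n_samples,
      .groups = "drop")
  n_t <- nrow(per_target)
  structure(list(per_target = per_target,
                 n_confirmed = sum(per_target$confirmed),
                 n_targets = n_t,
                 rate = if (n_t == 0) NA_real_
                        else sum(per_target$confirmed) / n_t,
                 mode = mode, unmatched = unmatched),
            class = "qpcr_concordance")
}

#' @export
print.qpcr_concordance <- function(x, ...) {
  cat(sprintf("<qpcr_concordance> %d / %d targets confirmed (%s, mode %s)\n",
              x$n_confirmed, x$n_targets,
              ifelse(is.na(x$rate), "n.a.",
                     sprintf("%.0f%%", 100 * x$rate)), x$mode))
  invisible(x)
}

#' @rdname qpcr_concordance
#' @param x A `qpcr_concordance`.
#' @param ... Unused.
#' @export
glance.qpcr_concordance <- function(x, ...) {
  tibble::tibble(n_targets = x$n_targets, n_confirmed = x$n_confirmed,
                 rate = x$rate, mode = x$mode)
}

#' @rdname qpcr_concordance
#' @export
tidy.qpcr_concordance <- function(x, ...) x$per_target

#' Read a qPCR Ct table from TSV
#'
#' Columns: `sample_id`, `target_id`, `gene` (target/reference), `replicate`,
#' `ct`.
#'
#' @param path TSV path with a header line.
#' @return A tibble in the layout [qpcr_copy_number()] expects.
#' @export
read_ct_table <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}
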
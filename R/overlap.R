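# Overlap pairs between two interval tables (>= 1 bp intersection), by
# chromosome. Returns row indices (query_idx, ref_idx) and overlap widths.
.overlap_pairs <- function(query, reference) {
  empty <- tibble::tibble(query_idx = integer(), ref_idx = integer(),
                          overlap_bp = numeric())
  chroms <- intersect(unique(query$chrom), unique(reference$chrom))
  if (length(chroms) == 0) return(empty)
  dplyr::bind_rows(empty, purrr::map_dfr(chroms, function(ch) {
    qi <- which(query$chrom == ch)
    ri <- which(reference$chrom == ch)
    qr <- .as_iranges(query$start[qi], query$end[qi])
    rr <- .as_iranges(reference$start[ri], reference$end[ri])
    hit <- IRanges::findOverlaps(qr, rr, minoverlap = 1L)
    if (length(hit) == 0) return(NULL)
    q <- S4Vectors::queryHits(hit)
    s <- S4Vectors::subjectHits(hit)
    ov <- pmin(IRanges::end(qr)[q], IRanges::end(rr)[s]) -
      pmax(IRanges::start(qr)[q], IRanges::start(rr)[s]) + 1
    tibble::tibble(query_idx = qi[q], ref_idx = ri[s], overlap_bp = ov)
  }))
}

#' Overlap a CNVR set with an external interval catalogue
#'
#' Counts how many records of the reference catalogue intersect (by at least
#' one base) at least one query CNVR — the accounting used when a CNV map is
#' compared against previously published catalogues, where the overlap
#' percentage is taken over the PREVIOUS study's region count.
#'
#' @param query A `cnvr_set` (or any tibble with `chrom`, `start`, `end` and
#'   an id column `cnvr_id`/`label`).
#' @param reference An [interval_set()].
#' @return A list of class `overlap_report`: `query_name`, `reference_name`,
#'   `n_reference`, `n_reference_overlapped`, `overlap_percentage`
#'   (full precision; rounded to 2 decimals by [glance()]), and `pairs`
#'   (tibble of `query_id`, `reference_label`, `overlap_bp`).
#' @export
overlap_sets <- function(query, reference) {
  qid <- query$cnvr_id %||% query$label %||% as.character(seq_len(nrow(query)))
  pairs <- .overlap_pairs(query, reference)
  n_ref <- nrow(reference)
  n_hit <- dplyr::n_distinct(pairs$ref_idx)
  structure(list(
    query_name = "query",
    reference_name = set_name(reference),
    n_reference = n_ref,
    n_reference_overlapped = n_hit,
    overlap_percentage = overlap_pct(n_hit, n_ref, digits = Inf),
    pairs = tibble::tibble(query_id = qid[pairs$query_idx],
                           reference_label = reference$label[pairs$ref_idx],
                           overlap_bp = pairs$overlap_bp)
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> vs %s: %d / %d reference records overlapped (%.2f%%)\n",
              x$reference_name, x$n_reference_overlapped, x$n_reference,
              x$overlap_percentage))
  invisible(x)
}

#' @rdname overlap_sets
#' @param x An `overlap_report`.
#' @param ... Unused.
#' @export
glance.overlap_report <- function(x, ...) {
  tibble::tibble(reference = x$reference_name, n_reference = x$n_reference,
                 n_overlapped = x$n_reference_overlapped,
                 overlap_percentage = round(x$overlap_percentage, 2))
}

#' @rdname overlap_sets
#' @export
tidy.overlap_report <- function(x, ...) x$pairs

#' Overlap percentage, reference-anchored
#'
#' `100 * overlapped / total`, the rounding rule used in published
#' comparison tables (two decimals).
#'
#' @param n_overlapped,n_total Counts.
#' @param digits Decimals to round to (default 2; `Inf` keeps full
#'   precision).
#' @export
overlap_pct <- function(n_overlapped, n_total, digits = 2) {
  p <- ifelse(n_total == 0, NA_real_, 100 * n_overlapped / n_total)
  if (is.infinite(digits)) p else round_half_up(p, digits)
}

#' Associate CNVRs with QTL intervals
#'
#' @param query A `cnvr_set`.
#' @param qtl An [interval_set()] whose `label` carries the QTL trait class.
#' @return A list with `n_cnvrs_associated` (query CNVRs hitting >= 1 QTL),
#'   `n_qtls_hit` (distinct QTL labels hit), and `label_freq` (tibble of
#'   label, n CNVRs overlapping it).
#' @export
overlap_qtl <- function(query, qtl) {
  pairs <- .overlap_pairs(query, qtl)
  qid <- query$cnvr_id %||% as.character(seq_len(nrow(query)))
  label_freq <- if (nrow(pairs) == 0) {
    tibble::tibble(label = character(), n = integer())
  } else {
    tibble::tibble(label = qtl$label[pairs$ref_idx],
                   query_id = qid[pairs$query_idx]) |>
      dplyr::distinct() |>
      dplyr::count(.data$label, name = "n") |>
      dplyr::arrange(dplyr::desc(.data$n))
  }
  list(n_cnvrs_associated = dplyr::n_distinct(pairs$query_idx),
       n_qtls_hit = dplyr::n_distinct(qtl$label[pairs$ref_idx]),
       label_freq = label_freq)
}

#' Capture genes overlapped by CNVRs
#'
#' A gene is captured when the fraction of ITS length covered by a CNVR is at
#' least `min_fraction` — completely contained genes and partially
#' (>= 50% by default) overlapped genes are kept.
#'
#' @param query A `cnvr_set`.
#' @param genes An [interval_set()] whose `label` is the gene identifier.
#' @param min_fraction Minimum covered fraction of the gene (inclusive).
#' @return A tibble: `cnvr_id`, `gene`, `overlap_bp`, `gene_length`,
#'   `overlap_fraction` (one row per captured CNVR-gene pair).
#' @export
annotate_genes <- function(query, genes, min_fraction = 0.5) {
  glen <- genes$end - genes$start
  if (any(glen <= 0)) stop("zero-length gene record")
  pairs <- .overlap_pairs(query, genes)
  qid <- query$cnvr_id %||% as.character(seq_len(nrow(query)))
  if (nrow(pairs) == 0) {
    return(tibble::tibble(cnvr_id = character(), gene = character(),
                          overlap_bp = numeric(), gene_length = numeric(),
                          overlap_fraction = numeric()))
  }
  out <- tibble::tibble(cnvr_id = qid[pairs$query_idx],
                        gene = genes$label[pairs$ref_idx],
                        overlap_bp = pairs$overlap_bp,
                        gene_length = glen[pairs$ref_idx]) |>
    dplyr::mutate(overlap_fraction = .data$overlap_bp / .data$gene_length) |>
    dplyr::filter(.data$overlap_fraction >= min_fraction)
  dplyr::arrange(out, .data$cnvr_id, .data$gene)
}
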
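#' Write and read windowed depth tracks
#'
#' Depth profiles travel as bedGraph-like 4-column text
#' (`chrom start end value`), one file for read counts and a parallel file
#' for the zero-mapping-quality fraction. Coordinates are 0-based half-open.
#'
#' @param depth A per-window depth tibble (one individual) as produced by
#'   [simulate_depth()].
#' @param count_file,q0_file Output paths.
#' @name depth_io
#' @return `write_depth_track()` returns the paths invisibly;
#'   `read_depth_track()` returns a per-window depth tibble.
#' @export
write_depth_track <- function(depth, count_file, q0_file) {
  stopifnot(length(unique(depth$individual_id)) == 1)
  utils::write.table(depth[, c("chrom", "start", "end", "count")], count_file,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(depth[, c("chrom", "start", "end", "q0_frac")], q0_file,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(count_file, q0_file))
}

#' @rdname depth_io
#' @param individual_id Id to stamp on the rows read back.
#' @export
read_depth_track <- function(count_file, q0_file, individual_id) {
  cnt <- utils::read.table(count_file, sep = "\t",
                           col.names = c("chrom", "start", "end", "count"))
  q0 <- utils::read.table(q0_file, sep = "\t",
                          col.names = c("chrom", "start", "end", "q0_frac"))
  if (nrow(cnt) != nrow(q0) || any(cnt$start != q0$start) ||
      any(cnt$chrom != q0$chrom)) {
    stop("count and q0 tracks do not describe the same windows")
  }
  tibble::tibble(individual_id = individual_id, chrom = as.character(cnt$chrom),
                 start = cnt$start, end = cnt$end, count = cnt$count,
                 q0_frac = q0$q0_frac)
}

#' Read a labelled interval set
#'
#' Loads external CNVR catalogues, QTL tables or gene annotations from
#' BED-like text. Two coordinate dialects are supported and must be declared
#' on load: `"bed"` (0-based half-open, the package's internal convention)
#' and `"one-based"` (1-based fully-closed, as printed in many published
#' tables); one-based records are converted on load. The set's name is kept
#' for reporting.
#'
#' @param path A tab-separated file whose first four columns are
#'   `chrom start end label`; extra columns are kept as `payload`.
#' @param name Name of the set (defaults to the file name).
#' @param dialect `"bed"` or `"one-based"`.
#' @return A tibble (`chrom`, `start`, `end`, `label`, `payload`) of class
#'   `interval_set` with attribute `set_name`; 0-based half-open.
#' @export
read_intervals <- function(path, name = basename(path),
                           dialect = c("bed", "one-based")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(raw) < 4) stop("interval file needs >= 4 columns: ", path)
  tbl <- tibble::tibble(chrom = as.character(raw[[1]]),
                        start = as.numeric(raw[[2]]),
                        end = as.numeric(raw[[3]]),
                        label = as.character(raw[[4]]),
                        payload = if (ncol(raw) >= 5) as.character(raw[[5]])
                                  else NA_character_)
  interval_set(tbl, name = name, dialect = dialect)
}

#' Construct an interval set from a data frame
#'
#' @param x A data frame with `chrom`, `start`, `end`, `label` (and optional
#'   `payload`).
#' @inheritParams read_intervals
#' @export
interval_set <- function(x, name = "intervals", dialect = c("bed", "one-based")) {
  dialect <- match.arg(dialect)
  x <- tibble::as_tibble(x)
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(x)))
  if (!"payload" %in% names(x)) x$payload <- NA_character_
  if (dialect == "one-based") {
    x$start <- x$start - 1 # 1-based closed -> 0-based half-open
  }
  if (any(x$end <= x$start)) {
    bad <- which(x$end <= x$start)[1]
    stop(sprintf("interval with end <= start at row %d (%s:%g-%g)",
                 bad, x$chrom[bad], x$start[bad], x$end[bad]))
  }
  out <- tibble::new_tibble(x[, c("chrom", "start", "end", "label", "payload")],
                            class = "interval_set")
  attr(out, "set_name") <- name
  out
}

set_name <- function(x) attr(x, "set_name") %||% "intervals"

#' Write calls, CNVRs or truth sets as BED-like TSV
#'
#' 0-based half-open coordinates; column order follows BED (chrom, start,
#' end) with the remaining columns appended.
#'
#' @param x A tibble carrying `chrom`, `start`, `end`.
#' @param path Output path.
#' @param col.names Write a header line (default TRUE).
#' @export
write_bedlike <- function(x, path, col.names = TRUE) {
  lead <- c("chrom", "start", "end")
  stopifnot(all(lead %in% names(x)))
  x <- x[, c(lead, setdiff(names(x), lead))]
  x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.list),
                                      ~ purrr::map_chr(.x, paste, collapse = ",")))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names)
  invisible(path)
}
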
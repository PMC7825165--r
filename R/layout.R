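#' Define a windowed genome layout
#'
#' A genome layout fixes the coordinate frame every other stage works in: an
#' ordered set of chromosomes, each divided into non-overlapping windows of
#' `window_size` bases starting at position 0. A trailing partial window
#' (fewer than `window_size` bases) is dropped, so the analysed extent of a
#' chromosome is `n_windows * window_size` bases. All coordinates in the
#' package are 0-based, half-open (BED convention).
#'
#' @param chroms Chromosome sizes: either a named numeric vector
#'   (`c(chr1 = 1e6, ...)`) or a data frame with columns `chrom` and `length`.
#' @param window_size Window width in bases (default 100).
#'
#' @return A tibble of class `genome_layout` with columns `chrom`, `length`
#'   (raw length in bases) and `n_windows`, and attribute `window_size`.
#' @examples
#' genome_layout(c(chr1 = 1050), window_size = 100) # 10 windows, 50 bp dropped
#' @export
genome_layout <- function(chroms, window_size = 100) {
  if (is.data.frame(chroms)) {
    stopifnot(all(c("chrom", "length") %in% names(chroms)))
    tbl <- tibble::tibble(chrom = as.character(chroms$chrom),
                          length = as.numeric(chroms$length))
  } else {
    if (is.null(names(chroms)) || any(!nzchar(names(chroms)))) {
      stop("`chroms` must be a named vector or a data frame with chrom/length")
    }
    tbl <- tibble::tibble(chrom = names(chroms), length = as.numeric(chroms))
  }
  if (anyDuplicated(tbl$chrom)) stop("chromosome names must be unique")
  if (!is.numeric(window_size) || length(window_size) != 1 || window_size <= 0) {
    stop("`window_size` must be a single positive number")
  }
  if (any(!is.finite(tbl$length)) || any(tbl$length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  if (any(tbl$length < window_size)) {
    stop("every chromosome must be at least one window long")
  }
  tbl$n_windows <- floor(tbl$length / window_size)
  out <- tibble::new_tibble(tbl, class = "genome_layout")
  attr(out, "window_size") <- as.numeric(window_size)
  out
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosome(s), window %g bp, %d windows\n",
              nrow(x), window_size(x), sum(x$n_windows)))
  NextMethod()
}

#' Window size of a genome layout
#' @param layout A [genome_layout()].
#' @return The window width in bases.
#' @export
window_size <- function(layout) {
  ws <- attr(layout, "window_size")
  if (is.null(ws)) stop("not a genome_layout: missing window_size attribute")
  ws
}

#' Enumerate the windows of a layout
#'
#' @param layout A [genome_layout()].
#' @return A tibble with one row per window: `chrom`, `start`, `end`
#'   (0-based half-open) and `window` (1-based index within the chromosome).
#' @export
layout_windows <- function(layout) {
  ws <- window_size(layout)
  purrr::pmap_dfr(layout[, c("chrom", "n_windows")], function(chrom, n_windows) {
    idx <- seq_len(n_windows)
    tibble::tibble(chrom = chrom, start = (idx - 1) * ws, end = idx * ws,
                   window = idx)
  })
}

# Total analysed genome size (windowed extent), in bases.
layout_extent <- function(layout) sum(layout$n_windows) * window_size(layout)
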
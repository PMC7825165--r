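#' Published sheep CNV-map summary tables
#'
#' Two small reference tables transcribed from the published literature on
#' CNVs in fine-wool sheep ship with the package as plain text. They are
#' printed numbers, not measurements made by this package, and serve as
#' inputs for the report arithmetic (per-group mean lengths, cohort totals,
#' cross-study overlap percentages).
#'
#' `sheep_cnv_map_summary()`: per-group CNV and CNVR counts for a 32-animal,
#' four-group fine-wool sheep cohort — duplication/deletion/both event
#' counts, total lengths in Mb and group sizes; the `cohort` row carries the
#' merged CNVR totals.
#'
#' `sheep_cnv_studies()`: six earlier sheep CNV catalogues (platform, breed
#' and sample counts, CNVR count and total length) together with how many of
#' each catalogue's CNVRs were rediscovered by the resequencing map.
#'
#' @return A tibble.
#' @name reference_tables
#' @export
sheep_cnv_map_summary <- function() {
  path <- system.file("extdata", "sheep_cnv_map_summary.tsv",
                      package = "cnvpop", mustWork = TRUE)
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}

#' @rdname reference_tables
#' @export
sheep_cnv_studies <- function() {
  path <- system.file("extdata", "sheep_cnv_studies.tsv",
                      package = "cnvpop", mustWork = TRUE)
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}

#' Report arithmetic: printed rounding and mean lengths
#'
#' Published summary tables round half away from zero (54612.625 prints as
#' 54612.63), unlike R's round-half-even; `round_half_up()` reproduces the
#' printed convention. `mean_length_kb()` applies it to the tables' mean
#' lengths: totals carried in Mb, means printed in kb to two decimals.
#'
#' @param x Numeric vector.
#' @param digits Decimals (default 2).
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' @rdname round_half_up
#' @param total_length_mb Total length in megabases.
#' @param n Number of regions or events.
#' @export
mean_length_kb <- function(total_length_mb, n, digits = 2) {
  round_half_up(total_length_mb * 1000 / n, digits)
}
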
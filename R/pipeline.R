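.CONFIG_DEFAULTS <- list(
  window_size = 100,
  seed = NULL,            # mandatory
  genome = NULL,          # named list chrom -> length (simulate mode)
  simulate = NULL,        # list of population_design overrides, or NULL
  depth_file = NULL,      # long per-window TSV (non-simulate mode)
  groups_file = NULL,     # TSV individual_id, group (non-simulate mode)
  caller = list(trim = 0.1, t = 3.5, merge_eps = 0.3, call_margin = 0.5,
                max_pval = 0.01, min_size = 1000, max_q0 = 0.5),
  cn_bounds = list(deleted_below = 0.4, duplicated_above = 1.6),
  vst = list(top_fraction = 0.05),
  compare = NULL,         # list of list(path, name, dialect, kind)
  output_dir = "cnvpop_out"
)

#' Build and validate a pipeline configuration
#'
#' All tunable constants of the pipeline live in one structured config:
#' window size (100 bp), the caller's filter thresholds (p < 0.01,
#' size > 1 kb, q0 < 0.5), the copy-number class bounds (0.4 / 1.6), the VST
#' selection cutoff (top 5%), the seed, and the input/output paths. Unknown
#' keys are rejected outright so a typo cannot silently fall back to a
#' default, and a config round-trips losslessly through
#' [write_config()]/[read_config()].
#'
#' @param ... Config entries overriding the defaults; nested lists
#'   (`caller`, `cn_bounds`, `vst`) are merged key-by-key.
#' @return A list of class `cnv_config`.
#' @export
cnv_config <- function(...) {
  over <- list(...)
  cfg <- .CONFIG_DEFAULTS
  for (k in names(over)) {
    if (!k %in% names(cfg)) stop("unknown config key: ", k)
    if (k %in% c("caller", "cn_bounds", "vst") && is.list(over[[k]])) {
      for (k2 in names(over[[k]])) {
        if (!k2 %in% names(cfg[[k]])) {
          stop("unknown config key: ", k, "$", k2)
        }
        cfg[[k]][[k2]] <- over[[k]][[k2]]
      }
    } else {
      cfg[k] <- list(over[[k]]) # keeps explicit NULLs as entries
    }
  }
  if (is.null(cfg$seed)) stop("`seed` is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  stopifnot(cfg$window_size > 0,
            cfg$caller$max_pval > 0, cfg$caller$max_pval <= 1,
            cfg$caller$min_size >= 0,
            cfg$caller$max_q0 >= 0, cfg$caller$max_q0 <= 1,
            cfg$cn_bounds$deleted_below >= 0,
            cfg$cn_bounds$duplicated_above > cfg$cn_bounds$deleted_below,
            cfg$vst$top_fraction > 0, cfg$vst$top_fraction <= 1)
  structure(cfg, class = "cnv_config")
}

#' @rdname cnv_config
#' @param config A `cnv_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname cnv_config
#' @export
read_config <- function(path) {
  do.call(cnv_config, yaml::read_yaml(path))
}

#' Run the whole CNV population pipeline
#'
#' Executes simulate (optional) -> call -> filter -> merge -> classify ->
#' summarize -> compare -> vst -> report, writing each stage's output as a
#' TSV under `config$output_dir` and returning a manifest that records the
#' seed, the parameters and every stage's record count. Outputs are
#' deterministic: rerunning with the same config reproduces them byte for
#' byte.
#'
#' @param config A [cnv_config()]. In simulate mode set `genome` (named list
#'   of chromosome lengths) and optionally `simulate` (design overrides);
#'   otherwise point `depth_file`/`groups_file` at per-window depth and group
#'   tables on disk.
#' @return The manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_cnv_pipeline <- function(config) {
  stopifnot(inherits(config, "cnv_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  stages <- list()
  note <- function(stage, n) stages[[stage]] <<- list(records = n)

  # --- simulate (optional) ---------------------------------------------
  if (!is.null(config$genome)) {
    layout <- genome_layout(unlist(config$genome),
                            window_size = config$window_size)
    sim_over <- config$simulate %||% list()
    sim_over$seed <- NULL # the pipeline seed governs
    design <- do.call(population_design,
                      c(sim_over, list(seed = config$seed)))
    sim <- simulate_cohort(layout, design)
    truth <- sim$truth; depth <- sim$depth
    individuals <- design$individuals
    write_bedlike(truth, out("truth.tsv"))
    note("simulate", nrow(truth))
  } else {
    if (is.null(config$depth_file) || is.null(config$groups_file)) {
      stop("need either `genome` (simulate mode) or `depth_file` + ",
           "`groups_file`")
    }
    depth <- tibble::as_tibble(
      utils::read.table(config$depth_file, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE))
    individuals <- tibble::as_tibble(
      utils::read.table(config$groups_file, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE))
    chrom_len <- dplyr::summarise(dplyr::group_by(depth, .data$chrom),
                                  len = max(.data$end), .groups = "drop")
    layout <- genome_layout(stats::setNames(chrom_len$len, chrom_len$chrom),
                            window_size = config$window_size)
    truth <- NULL
  }

  # --- call + filter ----------------------------------------------------
  cal <- config$caller
  norm <- normalize_depth(depth, trim = cal$trim)
  segs <- segment_depth(norm, t = cal$t, merge_eps = cal$merge_eps)
  calls_raw <- call_cnvs(segs, norm, call_margin = cal$call_margin)
  note("call", nrow(calls_raw))
  calls <- filter_calls(calls_raw, max_pval = cal$max_pval,
                        min_size = cal$min_size, max_q0 = cal$max_q0)
  write_bedlike(calls, out("calls.tsv"))
  note("filter", nrow(calls))

  # --- merge + classify -------------------------------------------------
  cnvrs <- merge_cnv_calls(calls)
  note("merge", nrow(cnvrs))
  cnvrs <- classify_cnvrs(cnvrs,
                          deleted_below = config$cn_bounds$deleted_below,
                          duplicated_above = config$cn_bounds$duplicated_above)
  write_bedlike(dplyr::select(tibble::as_tibble(cnvrs), -"supporting",
                              -"states"),
                out("cnvrs.tsv"))
  note("classify", nrow(cnvrs))

  # --- summarize --------------------------------------------------------
  summ <- summarize_cnvrs(cnvrs, layout)
  presence <- if (nrow(cnvrs) > 0) group_presence(cnvrs, individuals) else NULL
  summary_tbl <- render_summary_table(list(summ))
  utils::write.table(summary_tbl, out("summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  note("summarize", nrow(summary_tbl))

  # --- compare (optional external interval sets) ------------------------
  reports <- list()
  for (cmp in config$compare %||% list()) {
    ref <- read_intervals(cmp$path, name = cmp$name %||% basename(cmp$path),
                          dialect = cmp$dialect %||% "bed")
    kind <- cmp$kind %||% "cnvr"
    if (kind == "qtl") {
      q <- overlap_qtl(cnvrs, ref)
      utils::write.table(q$label_freq, out(paste0("qtl_", cmp$name, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (kind == "genes") {
      g <- annotate_genes(cnvrs, ref)
      write_bedlike(dplyr::inner_join(
        tibble::as_tibble(cnvrs)[, c("cnvr_id", "chrom", "start", "end")],
        g, by = "cnvr_id"), out(paste0("genes_", cmp$name, ".tsv")))
    } else {
      reports[[cmp$name]] <- overlap_sets(cnvrs, ref)
    }
  }
  if (length(reports) > 0) {
    utils::write.table(render_overlap_table(reports), out("overlaps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  note("compare", length(config$compare %||% list()))

  # --- vst --------------------------------------------------------------
  vst_n <- 0L
  if (nrow(cnvrs) > 0 && length(unique(individuals$group)) == 2 &&
      all(table(individuals$group) >= 2)) {
    vst <- cnvr_vst(cnvrs, norm, individuals)
    sel <- select_candidates(vst, top_fraction = config$vst$top_fraction)
    vst$candidate <- vst$cnvr_id %in% sel$cnvr_id
    write_bedlike(vst, out("vst.tsv"))
    vst_n <- nrow(vst)
  }
  note("vst", vst_n)

  # --- report -----------------------------------------------------------
  lines <- c(utils::capture.output(print(summ)),
             purrr::map_chr(reports,
                            ~ utils::capture.output(print(.x))[1]))
  writeLines(lines, out("report.txt"))
  note("report", length(lines))

  manifest <- list(package = "cnvpop",
                   version = as.character(utils::packageVersion("cnvpop")),
                   seed = config$seed,
                   parameters = unclass(config),
                   stages = stages)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Render a CNV/CNVR summary table
#'
#' One row per summary, with the table's rounding rules applied (Mb and kb
#' and percentages to two decimals).
#'
#' @param summaries A list of `cnvr_summary` objects.
#' @return A tibble.
#' @export
render_summary_table <- function(summaries) {
  dplyr::bind_rows(purrr::map(summaries, glance))
}

#' Render a cross-study overlap comparison table
#'
#' @param reports A list of `overlap_report` objects.
#' @return A tibble with one row per reference catalogue.
#' @export
render_overlap_table <- function(reports) {
  dplyr::bind_rows(purrr::map(reports, glance))
}
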
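# Report writing and end-to-end orchestration.

#' Write a funnel report to disk
#'
#' Emits `funnel.tsv` (one row per stage: surviving counts and rescues),
#' `trail.tsv` (per-variant decision trail), `candidates.tsv` (final
#' candidate table) and `summary.json` into `dir`.
#'
#' @param report A `funnel_report` from [run_cascade()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_funnel_report <- function(report, dir) {
  stopifnot(inherits(report, "funnel_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$stages, file.path(dir, "funnel.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(report$trail, file.path(dir, "trail.tsv"),
                     sep = "\t", quote = FALSE)
  cand <- report$candidates
  keep <- !grepl("^(gt|dp)_", names(cand))
  out <- as.data.frame(cand)[keep]
  for (cc in names(out)) {
    if (is.numeric(out[[cc]]) && !is.integer(out[[cc]])) {
      out[[cc]] <- fmt_num(out[[cc]])
    }
  }
  data.table::fwrite(out, file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, na = ".")
  summary <- list(
    n_input = report$n_input,
    stages = stats::setNames(as.list(report$stages$n_surviving),
                             report$stages$stage),
    n_candidates = nrow(report$candidates),
    candidate_ids = report$candidates$id,
    n_rescued = sum(report$candidates$rescued %||% logical(0))
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the prioritization pipeline end to end
#'
#' Reads the variant table, pedigree and optional configuration inputs, runs
#' the cascade, ranks candidates, and writes the funnel report plus a JSON
#' run manifest (inputs, canonical configuration hash, package version,
#' seed) and a grep-able log with per-stage counts. On error any partially
#' written output directory created by this call is removed.
#'
#' @param variants Path to a variant table (TSV or VCF).
#' @param ped Path to the extended PED file.
#' @param out_dir Report directory to create.
#' @param config Optional path to a JSON [filter_config()] file, or a
#'   `filter_config` object.
#' @param rescue Optional path to a rescue gene list (one symbol per line,
#'   `#` comments allowed); overrides `config`'s rescue list.
#' @param intolerance Optional path to an intolerance table
#'   ([read_intolerance_table()]).
#' @param seed Optional integer recorded in the manifest (the cascade itself
#'   is deterministic).
#' @param timestamp Record a wall-clock timestamp in the manifest; disable
#'   for byte-identical reruns.
#' @return Invisibly, list with `status` (0 on success), `out_dir` and the
#'   `funnel_report`.
#' @export
run_end_to_end <- function(variants, ped, out_dir, config = NULL,
                           rescue = NULL, intolerance = NULL, seed = NULL,
                           timestamp = TRUE) {
  if (!file.exists(variants)) stop("variant file not found: ", variants)
  if (!file.exists(ped)) stop("PED file not found: ", ped)
  cfg <- if (is.null(config)) {
    filter_config()
  } else if (inherits(config, "filter_config")) {
    config
  } else {
    read_filter_config(config)
  }
  if (!is.null(rescue)) {
    if (!file.exists(rescue)) stop("rescue gene list not found: ", rescue)
    genes <- readLines(rescue)
    genes <- trimws(sub("#.*$", "", genes))
    cfg$rescue_genes <- genes[nzchar(genes)]
  }
  intol <- if (!is.null(intolerance)) read_intolerance_table(intolerance)
  pedigree_obj <- read_ped(ped)
  vt <- read_variant_table(variants, pedigree_obj)

  existed <- dir.exists(out_dir)
  ok <- FALSE
  on.exit({
    if (!ok && !existed && dir.exists(out_dir)) {
      unlink(out_dir, recursive = TRUE)
    }
  }, add = TRUE)

  report <- run_cascade(vt, pedigree_obj, cfg, intolerance = intol)
  write_funnel_report(report, out_dir)
  manifest <- list(
    tool = "varfunnel::run_end_to_end",
    version = as.character(utils::packageVersion("varfunnel")),
    inputs = list(variants = variants, ped = ped, rescue = rescue,
                  intolerance = intolerance),
    seed = seed,
    config = canonicalize(unclass(cfg)),
    config_hash = config_hash(cfg)
  )
  if (isTRUE(timestamp)) {
    manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    sprintf("varfunnel run: %d variants in", report$n_input),
    sprintf("stage %s surviving=%d rescued=%d",
            report$stages$stage, report$stages$n_surviving,
            report$stages$n_rescued),
    sprintf("candidates=%d", nrow(report$candidates))
  )
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  message(paste(log_lines, collapse = "\n"))
  ok <- TRUE
  invisible(list(status = 0L, out_dir = out_dir, report = report))
}
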
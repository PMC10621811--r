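# End-to-end orchestration.  Stages communicate only through files so each
# phase is independently runnable and a real cohort CSV can replace the
# simulated one without code changes.  No stage writes timestamps: re-running
# with the same inputs and seed reproduces byte-identical outputs.

.cfg_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

.log <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Stage 1: simulate a cohort to disk
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Log cohort summaries at INFO level.
#' @return Invisibly, the paths written: `cohort.csv` and `manifest.json`.
#' @export
pipeline_simulate <- function(config = sim_config(), out_dir, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config)
  cohort_path <- file.path(out_dir, "cohort.csv")
  write_cohort(sim$cohort, cohort_path)
  manifest <- sim$manifest
  manifest$config_hash <- .cfg_hash(unclass(config))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  .log(verbose, "simulated %d children (%d deficit) -> %s",
       config$n_children, sum(sim$cohort$truth_label == "deficit") / 2,
       cohort_path)
  invisible(c(cohort = cohort_path, manifest = manifest_path))
}

#' Stage 2: estimate normative thresholds and the age trend
#'
#' @param cohort_path Path to a cohort CSV (the normative reference
#'   population).
#' @param out_dir Output directory.
#' @param verbose Log per-cell thresholds.
#' @inheritParams estimate_thresholds
#' @return Invisibly, the paths written: `thresholds.json` and
#'   `age_trend.json` (both versions' fits).
#' @export
pipeline_norms <- function(cohort_path, out_dir,
                           percentile_levels = default_percentile_levels(),
                           accuracy_cutoff = 4L, min_cell_size = 20L,
                           verbose = FALSE) {
  cohort <- read_cohort(cohort_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ts <- estimate_thresholds(cohort, percentile_levels, accuracy_cutoff,
                            min_cell_size)
  thr_path <- file.path(out_dir, "thresholds.json")
  write_threshold_set(ts, thr_path)
  trends <- lapply(VERSIONS, function(v) unclass(fit_age_trend(cohort, v)))
  trend_path <- file.path(out_dir, "age_trend.json")
  jsonlite::write_json(trends, trend_path, auto_unbox = TRUE, digits = NA)
  .log(verbose, "thresholds over %d runs -> %s", nrow(cohort), thr_path)
  invisible(c(thresholds = thr_path, age_trend = trend_path))
}

#' Stage 3: screen a cohort against thresholds
#'
#' @param cohort_path Path to a cohort CSV.
#' @param thresholds_path Path to a thresholds JSON from [pipeline_norms()].
#' @param out_dir Output directory.
#' @param verbose Log the number of flagged children.
#' @return Invisibly, the path of `screening.csv`.
#' @export
pipeline_screen <- function(cohort_path, thresholds_path, out_dir,
                            verbose = FALSE) {
  cohort <- read_cohort(cohort_path)
  ts <- read_threshold_set(thresholds_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- screen_cohort(cohort, ts)
  path <- file.path(out_dir, "screening.csv")
  write.csv(report, path, row.names = FALSE, quote = FALSE)
  .log(verbose, "flagged %d of %d children -> %s",
       sum(report$flagged), nrow(report), path)
  invisible(c(screening = path))
}

#' Stage 4: validate screening flags against a reference classification
#'
#' Cross-classifies the screener's flags against a per-child reference flag
#' (for a simulated cohort, the latent truth label), per age group and
#' overall, and computes kappa and sensitivity/specificity blocks.
#'
#' @param screening_path Path to a screening CSV from [pipeline_screen()].
#' @param cohort_path Path to the cohort CSV carrying `truth_label` (the
#'   reference classification).
#' @param out_dir Output directory.
#' @param verbose Log the per-group kappas.
#' @return Invisibly, the path of `validation.json`.
#' @export
pipeline_validate <- function(screening_path, cohort_path, out_dir,
                              verbose = FALSE) {
  screening <- read.csv(screening_path, stringsAsFactors = FALSE)
  cohort <- read_cohort(cohort_path)
  per_child <- cohort[!duplicated(cohort$child_id),
                      c("child_id", "age_years", "truth_label")]
  if (anyNA(per_child$truth_label))
    stop("cohort carries no reference classification (truth_label)",
         call. = FALSE)
  m <- match(screening$child_id, per_child$child_id)
  if (anyNA(m)) stop("screening report and cohort disagree on children",
                     call. = FALSE)
  ref <- setNames(per_child$truth_label[m] == "deficit", screening$child_id)
  idx <- setNames(screening$flagged, screening$child_id)
  grp <- as.character(assign_age_group(per_child$age_years[m]))

  block <- function(sel, label) {
    if (!any(sel)) return(NULL)
    tab <- build_contingency(ref[sel], idx[sel],
                             reference = "latent_deficit", index = "screener")
    ss <- sensitivity_specificity(tab)
    list(group = label, n = tab$n,
         counts = c(a = tab$a, b = tab$b, c = tab$c, d = tab$d),
         kappa = unclass(cohen_kappa(tab)),
         sensitivity = unclass(ss$sensitivity),
         specificity = unclass(ss$specificity))
  }
  blocks <- Filter(Negate(is.null),
                   c(lapply(AGE_GROUPS, function(g) block(grp == g, g)),
                     list(block(rep(TRUE, length(ref)), "all"))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, "validation.json")
  jsonlite::write_json(blocks, path, auto_unbox = TRUE, digits = NA)
  if (verbose) {
    for (b in blocks)
      .log(TRUE, "group %s: kappa = %.3f (n = %d)", b$group, b$kappa$kappa, b$n)
  }
  invisible(c(validation = path))
}

#' Run the full pipeline on a simulated cohort
#'
#' simulate -> norms -> screen -> validate, all under one seed and one
#' output directory.  Deterministic: re-running with the same config
#' produces byte-identical files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param verbose Log stage summaries.
#' @return Invisibly, a named vector of all paths written.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, verbose = FALSE) {
  p1 <- pipeline_simulate(config, out_dir, verbose)
  p2 <- pipeline_norms(p1[["cohort"]], out_dir, verbose = verbose)
  p3 <- pipeline_screen(p1[["cohort"]], p2[["thresholds"]], out_dir, verbose)
  p4 <- pipeline_validate(p3[["screening"]], p1[["cohort"]], out_dir, verbose)
  invisible(c(p1, p2, p3, p4))
}
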
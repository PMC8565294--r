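#' Run configuration for the end-to-end pipeline
#'
#' @param cohort a `cohort_config` to simulate from, or `NULL` when
#'   `input_dir` points at an existing cohort on disk.
#' @param input_dir directory with per-subject TSVs plus `clinical.csv`
#'   (ignored when `cohort` is given).
#' @param output_dir where stage outputs land.
#' @param grid_start,grid_stop,grid_step threshold band (defaults 0.05,
#'   0.40, 0.05; 0.01 is the fine-step robustness alternative).
#' @param n_nulls,null_seed null-ensemble spec for gamma/lambda/sigma.
#' @param t_variant,n_perm,alpha,covariates statistics spec.
#' @param seed master seed recorded in the report.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = NULL, input_dir = NULL, output_dir,
                       grid_start = 0.05, grid_stop = 0.40,
                       grid_step = 0.05,
                       n_nulls = 100, null_seed = 1L,
                       t_variant = "welch", n_perm = 5000, alpha = 0.05,
                       covariates = c("age", "sex", "head_motion",
                                      "duration"),
                       seed = 1L) {
  if (is.null(cohort) && is.null(input_dir))
    stop("provide either a cohort configuration or an input directory")
  structure(list(cohort = cohort, input_dir = input_dir,
                 output_dir = output_dir,
                 grid = threshold_grid(grid_start, grid_stop, grid_step),
                 n_nulls = n_nulls, null_seed = null_seed,
                 t_variant = t_variant, n_perm = n_perm, alpha = alpha,
                 covariates = covariates, seed = as.integer(seed)),
            class = "run_config")
}

#' Validate an on-disk cohort directory
#'
#' Checks per-subject T x N shape consistency, constant-signal columns,
#' clinical/time-series subject agreement, and node-table integrity.
#' Reports; never mutates.
#'
#' @param dir cohort directory.
#' @return list of class `validation_report`: `issues` (data.frame with
#'   `kind`, `subject`, `detail`), `n_issues`, `n_subjects`.
#' @export
validate_inputs <- function(dir) {
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  issues <- data.frame(kind = character(0), subject = character(0),
                       detail = character(0), stringsAsFactors = FALSE)
  add <- function(kind, subject, detail) {
    issues[nrow(issues) + 1L, ] <<- list(kind, subject, detail)
  }
  clin_path <- file.path(dir, "clinical.csv")
  clinical <- NULL
  if (!file.exists(clin_path)) {
    add("missing_file", "", "clinical.csv not found")
  } else {
    clinical <- utils::read.csv(clin_path, stringsAsFactors = FALSE)
  }
  ts_files <- list.files(dir, pattern = "^sub-.*\\.tsv$")
  ts_ids <- sub("\\.tsv$", "", ts_files)
  shapes <- list()
  for (id in ts_ids) {
    x <- utils::read.table(file.path(dir, paste0(id, ".tsv")),
                           header = TRUE, sep = "\t")
    shapes[[id]] <- dim(x)
    sds <- vapply(x, stats::sd, numeric(1))
    for (j in which(sds == 0))
      add("constant_column", id, paste0("node column ", names(x)[j],
                                        " has zero variance"))
  }
  if (length(shapes) > 1) {
    ref <- shapes[[1]]
    for (id in names(shapes))
      if (!identical(shapes[[id]], ref))
        add("shape_mismatch", id,
            sprintf("dims %dx%d differ from %dx%d",
                    shapes[[id]][1], shapes[[id]][2], ref[1], ref[2]))
  }
  if (!is.null(clinical)) {
    for (id in setdiff(clinical$subject_id, ts_ids))
      add("orphan_clinical_row", id, "clinical row without time-series file")
    for (id in setdiff(ts_ids, clinical$subject_id))
      add("orphan_series_file", id, "time-series file without clinical row")
  }
  nodes_path <- file.path(dir, "nodes.csv")
  if (file.exists(nodes_path)) {
    nodes <- utils::read.csv(nodes_path, stringsAsFactors = FALSE)
    need <- c("node_id", "x", "y", "z", "label")
    for (col in setdiff(need, names(nodes)))
      add("node_table", "", paste0("missing column ", col))
    if ("node_id" %in% names(nodes) && length(shapes) &&
        nrow(nodes) != shapes[[1]][2])
      add("node_table", "",
          sprintf("node table has %d rows but series have %d columns",
                  nrow(nodes), shapes[[1]][2]))
  }
  structure(list(issues = issues, n_issues = nrow(issues),
                 n_subjects = length(ts_ids)),
            class = "validation_report")
}

#' Run the full pipeline: simulate/load, connectivity, metrics, stats
#'
#' Stages write their outputs under `output_dir` (`cohort/`, `fc/`,
#' `metrics/`, `stats/`) and a `report.json` with per-stage output
#' checksums, seeds and collected warnings. Re-running with the same
#' configuration reproduces identical outputs; with `resume = TRUE`,
#' stages whose outputs already exist are skipped.
#'
#' @param cfg a `run_config`.
#' @param resume skip stages whose outputs already exist.
#' @param quiet suppress per-stage progress messages.
#' @return the run report (list), invisibly written to `report.json`.
#' @export
run_pipeline <- function(cfg, resume = FALSE, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  warn <- character(0)
  note <- function(...) if (!quiet) message(...)

  # stage 1: cohort
  cohort_dir <- if (!is.null(cfg$cohort)) file.path(out, "cohort")
                else cfg$input_dir
  if (!is.null(cfg$cohort)) {
    if (!(resume && file.exists(file.path(cohort_dir, "clinical.csv")))) {
      note("stage simulate: generating cohort (seed ", cfg$cohort$seed, ")")
      cohort <- tryCatch(generate_cohort(cfg$cohort), error = function(e)
        stop("stage simulate failed: ", conditionMessage(e)))
      write_cohort(cohort, cohort_dir)
    } else note("stage simulate: cached, skipping")
  }
  vr <- validate_inputs(cohort_dir)
  if (vr$n_issues > 0)
    stop("stage validate failed: ", vr$issues$kind[1], " (",
         vr$issues$subject[1], ": ", vr$issues$detail[1], ")")
  data <- read_cohort(cohort_dir)

  # stage 2: connectivity
  fc_dir <- file.path(out, "fc")
  dir.create(fc_dir, showWarnings = FALSE)
  fcs <- list()
  for (id in names(data$series)) {
    fcs[[id]] <- withCallingHandlers(
      tryCatch(compute_fc_matrix(list(subject_id = id,
                                      data = data$series[[id]])),
               error = function(e)
                 stop("stage fc failed for ", id, ": ",
                      conditionMessage(e))),
      warning = function(w) {
        warn <<- c(warn, paste0("fc/", id, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    write_fc_matrix(fcs[[id]], file.path(fc_dir, paste0(id, "_fc.tsv")))
  }
  note("stage fc: ", length(fcs), " matrices")

  # stage 3: metrics
  met_dir <- file.path(out, "metrics")
  profiles <- list()
  for (id in names(fcs)) {
    sub_dir <- file.path(met_dir, id)
    profiles[[id]] <- withCallingHandlers(
      tryCatch(profile_subject(fcs[[id]], cfg$grid, n_nulls = cfg$n_nulls,
                               seed = cfg$null_seed),
               error = function(e)
                 stop("stage metrics failed for ", id, ": ",
                      conditionMessage(e))),
      warning = function(w) {
        warn <<- c(warn, paste0("metrics/", id, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (any(profiles[[id]]$disconnected))
      warn <- c(warn, paste0("metrics/", id,
                             ": disconnected at some grid point"))
    write_profile(profiles[[id]], sub_dir)
  }
  note("stage metrics: ", length(profiles), " profiles at ",
       length(cfg$grid), " grid points")

  # stage 4: stats
  stats_dir <- file.path(out, "stats")
  cmp <- tryCatch(compare_groups(profiles, data$clinical,
                                 variant = cfg$t_variant,
                                 alpha = cfg$alpha, n_perm = cfg$n_perm,
                                 seed = cfg$seed,
                                 covariate_cols = cfg$covariates),
                  error = function(e)
                    stop("stage stats failed: ", conditionMessage(e)))
  write_comparison(cmp, stats_dir)
  note("stage stats: ", sum(cmp$global$significant),
       " significant global metrics")

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "report.json"]
  checksums <- tools::md5sum(files)
  names(checksums) <- substring(names(checksums), nchar(out) + 2)
  report <- list(
    seed = cfg$seed, null_seed = cfg$null_seed,
    grid = as.numeric(cfg$grid), n_nulls = cfg$n_nulls,
    t_variant = cfg$t_variant, n_perm = cfg$n_perm, alpha = cfg$alpha,
    n_subjects = length(profiles),
    significant_global = cmp$global$metric[cmp$global$significant],
    warnings = warn,
    checksums = as.list(checksums))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
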
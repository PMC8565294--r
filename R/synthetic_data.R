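#' Cohort configuration for the synthetic generator
#'
#' Defines a two-group resting-state cohort: per-subject regional time
#' series drawn from a modular multivariate normal, plus clinical scores
#' coupled to a per-subject lesion-severity scalar. Patients receive a
#' connectivity reduction inside designated modules; controls do not. The
#' defaults mirror a stroke-aphasia study design: 24 patients vs 19
#' controls, 150 retained volumes, and (for tests) a 60-node parcellation
#' partitioned into 6 equal modules; set `n_nodes = 264` with suitable
#' `module_sizes` to mirror a full Power-atlas network.
#'
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the configuration including this seed.
#' @param n_patients,n_controls group sizes.
#' @param n_nodes number of network nodes (brain regions).
#' @param n_timepoints time-series length per subject (volumes retained).
#' @param module_sizes integer vector partitioning the nodes into
#'   contiguous modules; must sum to `n_nodes`. Default: 6 near-equal
#'   blocks.
#' @param rho_within,rho_between inter-node correlation inside / across
#'   modules; `0 <= rho_between < rho_within < 1`.
#' @param lesion_nodes node indices (1-based) marking the lesioned
#'   territory; every module containing at least one such node has its
#'   within-module correlation reduced in patients. Default: the first
#'   two modules.
#' @param lesion_strength in `[0, 1]`; at full severity the within-module
#'   correlation of lesioned modules drops by
#'   `lesion_strength * (rho_within - rho_between)`.
#' @param subject_severity_spread in `[0, 1]`; patient severities are
#'   drawn uniformly from `[1 - spread, 1]` (controls have severity 0).
#' @param clinical_noise_sd Gaussian noise sd on clinical scores (score
#'   units).
#' @param coupling clinical score units gained per unit `(1 - severity)`.
#' @param abc_baselines named numeric: patient baseline for the four ABC
#'   sub-scores (spontaneous speech, auditory comprehension, repetition,
#'   naming) at full severity.
#' @param age_range,duration_range,head_motion_range uniform/clipped draw
#'   ranges for age (years), post-stroke duration (months) and mean head
#'   displacement (arbitrary units).
#' @param prob_male named numeric, probability of male sex per group.
#' @return A validated list of class `cohort_config`.
#' @seealso [generate_cohort()], [build_covariance()]
#' @export
cohort_config <- function(seed = 1L,
                          n_patients = 24L, n_controls = 19L,
                          n_nodes = 60L, n_timepoints = 150L,
                          module_sizes = NULL,
                          rho_within = 0.6, rho_between = 0.1,
                          lesion_nodes = NULL,
                          lesion_strength = 0.7,
                          subject_severity_spread = 0.8,
                          clinical_noise_sd = 10, coupling = 30,
                          abc_baselines = c(abc_spontaneous = 41,
                                            abc_auditory = 64,
                                            abc_repetition = 62,
                                            abc_naming = 42),
                          age_range = c(25, 69),
                          duration_range = c(1, 24),
                          head_motion_range = c(0.05, 0.3),
                          prob_male = c(patient = 16 / 24,
                                        control = 10 / 19)) {
  if (is.null(module_sizes)) {
    k <- 6L
    base <- n_nodes %/% k
    module_sizes <- rep(base, k)
    extra <- n_nodes - base * k
    if (extra > 0) module_sizes[seq_len(extra)] <- base + 1L
  }
  if (is.null(lesion_nodes)) {
    lesion_nodes <- seq_len(sum(module_sizes[seq_len(min(2L, length(module_sizes)))]))
  }
  cfg <- structure(list(
    seed = as.integer(seed),
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    n_nodes = as.integer(n_nodes),
    n_timepoints = as.integer(n_timepoints),
    module_sizes = as.integer(module_sizes),
    rho_within = rho_within, rho_between = rho_between,
    lesion_nodes = as.integer(sort(unique(lesion_nodes))),
    lesion_strength = lesion_strength,
    subject_severity_spread = subject_severity_spread,
    clinical_noise_sd = clinical_noise_sd,
    coupling = coupling,
    abc_baselines = abc_baselines,
    age_range = age_range, duration_range = duration_range,
    head_motion_range = head_motion_range,
    prob_male = prob_male), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @param config a `cohort_config` object.
#' @export
validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with(config, {
    if (sum(module_sizes) != n_nodes)
      stop("module_sizes must partition the node set exactly: sum is ",
           sum(module_sizes), ", n_nodes is ", n_nodes)
    if (any(module_sizes < 1L)) stop("module_sizes must be positive")
    if (length(lesion_nodes) &&
        (min(lesion_nodes) < 1L || max(lesion_nodes) > n_nodes))
      stop("lesion_nodes must be node indices in 1..n_nodes")
    if (!(rho_between >= 0 && rho_within < 1 && rho_between < rho_within))
      stop("need 0 <= rho_between < rho_within < 1")
    if (lesion_strength < 0 || lesion_strength > 1)
      stop("lesion_strength must be in [0, 1]")
    if (subject_severity_spread < 0 || subject_severity_spread > 1)
      stop("subject_severity_spread must be in [0, 1]")
    if (n_timepoints < 2L) stop("n_timepoints must be at least 2")
    if (n_patients < 1L || n_controls < 1L) stop("both groups must be non-empty")
  })
  invisible(config)
}

#' Module membership implied by a cohort configuration
#'
#' @param config a `cohort_config`.
#' @return integer vector of length `n_nodes`, module index per node.
#' @export
module_membership <- function(config) {
  rep(seq_along(config$module_sizes), config$module_sizes)
}

#' Build the node covariance matrix for one subject
#'
#' Block-structured correlation matrix: unit diagonal, `rho_within`
#' inside a module, `rho_between` across modules. For modules touched by
#' `lesion_nodes`, within-module entries are reduced to
#' `rho_within - severity * lesion_strength * (rho_within - rho_between)`.
#' The result is checked for positive semi-definiteness (smallest
#' eigenvalue >= -1e-10, tiny negatives clipped); an indefinite result
#' rejects the configuration.
#'
#' @param config a `cohort_config`.
#' @param severity lesion severity in `[0, 1]`; 0 for controls.
#' @return `n_nodes` x `n_nodes` covariance matrix.
#' @export
build_covariance <- function(config, severity = 0) {
  validate_cohort_config(config)
  stopifnot(severity >= 0, severity <= 1)
  n <- config$n_nodes
  mod <- module_membership(config)
  same <- outer(mod, mod, "==")
  S <- matrix(config$rho_between, n, n)
  S[same] <- config$rho_within
  if (severity > 0 && config$lesion_strength > 0 &&
      length(config$lesion_nodes)) {
    lesioned_mods <- unique(mod[config$lesion_nodes])
    hit <- mod %in% lesioned_mods
    rho_les <- config$rho_within -
      severity * config$lesion_strength *
      (config$rho_within - config$rho_between)
    block <- outer(hit, hit, "&") & same
    S[block] <- rho_les
  }
  diag(S) <- 1
  # PSD check: reject incompatible settings; eigenvalues above -1e-10
  # are numerical zeros the sampler tolerates
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("covariance is not positive semi-definite (min eigenvalue ",
         format(min(ev)), "); rho/lesion settings are incompatible")
  S
}

clip_score <- function(x, lo = 0, hi = 100) pmin(hi, pmax(lo, x))

#' Generate a synthetic two-group cohort
#'
#' Draws, under a single seed, per-subject regional time series (rows =
#' timepoints, columns = nodes; i.i.d. multivariate normal with the
#' subject's covariance from [build_covariance()]) and a clinical table.
#' Patients receive a severity scalar uniform on
#' `[1 - subject_severity_spread, 1]`; controls have severity 0. Each ABC
#' sub-score is `baseline + coupling * (1 - severity) + noise`, truncated
#' to `[0, 100]`; controls sit near ceiling. `language_ability` is the
#' arithmetic mean of the four ABC sub-scores. Demographics (age, sex,
#' duration, head motion) are drawn independently of severity.
#'
#' @param config a `cohort_config`.
#' @return list of class `synthetic_cohort` with elements `series` (named
#'   list of T x N matrices), `clinical` (data.frame, one row per
#'   subject), `nodes` (data.frame: node_id, x, y, z, label, module),
#'   `severity` (named numeric), and `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n_p <- config$n_patients
  n_c <- config$n_controls
  ids <- c(sprintf("sub-P%02d", seq_len(n_p)),
           sprintf("sub-C%02d", seq_len(n_c)))
  group <- c(rep("patient", n_p), rep("control", n_c))

  severity <- c(runif(n_p, 1 - config$subject_severity_spread, 1),
                rep(0, n_c))
  names(severity) <- ids

  # time series: controls share one covariance; each patient has their own
  sigma_control <- build_covariance(config, 0)
  series <- vector("list", n_p + n_c)
  names(series) <- ids
  for (k in seq_along(ids)) {
    S <- if (group[k] == "patient") build_covariance(config, severity[k])
         else sigma_control
    x <- MASS::mvrnorm(config$n_timepoints, mu = rep(0, config$n_nodes),
                       Sigma = S)
    if (any(apply(x, 2, stats::sd) == 0))
      stop("generated a constant-signal column for ", ids[k],
           "; increase n_timepoints")
    colnames(x) <- sprintf("node_%03d", seq_len(config$n_nodes))
    series[[k]] <- x
  }

  # clinical scores
  nb <- length(config$abc_baselines)
  abc <- matrix(NA_real_, n_p + n_c, nb,
                dimnames = list(ids, names(config$abc_baselines)))
  for (k in seq_along(ids)) {
    if (group[k] == "patient") {
      abc[k, ] <- clip_score(config$abc_baselines +
                               config$coupling * (1 - severity[k]) +
                               stats::rnorm(nb, 0, config$clinical_noise_sd))
    } else {
      abc[k, ] <- clip_score(stats::rnorm(nb, 99.6, 0.5))
    }
  }
  language_ability <- rowMeans(abc)
  mmse <- ifelse(group == "patient",
                 clip_score(round(stats::rnorm(length(ids), 29 - 24 * severity, 3)), 0, 30),
                 clip_score(round(stats::rnorm(length(ids), 29.2, 1)), 0, 30))
  moca <- ifelse(group == "patient",
                 clip_score(round(stats::rnorm(length(ids), 28.5 - 28 * severity, 3)), 0, 30),
                 clip_score(round(stats::rnorm(length(ids), 28.6, 1)), 0, 30))
  age <- pmin(config$age_range[2],
              pmax(config$age_range[1], stats::rnorm(length(ids), 50, 10)))
  pm <- ifelse(group == "patient", config$prob_male[["patient"]],
               config$prob_male[["control"]])
  sex <- ifelse(stats::runif(length(ids)) < pm, "M", "F")
  duration <- ifelse(group == "patient",
                     stats::runif(length(ids), config$duration_range[1],
                                  config$duration_range[2]), NA_real_)
  head_motion <- stats::runif(length(ids), config$head_motion_range[1],
                              config$head_motion_range[2])

  clinical <- data.frame(subject_id = ids, group = group,
                         age = age, sex = sex, duration = duration,
                         head_motion = head_motion,
                         abc, language_ability = language_ability,
                         mmse = mmse, moca = moca,
                         severity = unname(severity),
                         stringsAsFactors = FALSE, row.names = NULL)

  mod <- module_membership(config)
  nodes <- data.frame(node_id = seq_len(config$n_nodes),
                      x = round(stats::runif(config$n_nodes, -70, 70), 1),
                      y = round(stats::runif(config$n_nodes, -100, 70), 1),
                      z = round(stats::runif(config$n_nodes, -45, 75), 1),
                      label = sprintf("node_%03d", seq_len(config$n_nodes)),
                      module = mod, stringsAsFactors = FALSE)

  structure(list(series = series, clinical = clinical, nodes = nodes,
                 severity = severity, config = config),
            class = "synthetic_cohort")
}

#' Write / read a cohort as plain-text files
#'
#' One TSV per subject (T rows x N columns, no header beyond node ids),
#' plus `clinical.csv`, `nodes.csv`, and `config.json` recording the full
#' configuration and seed.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly (`write_cohort`); a list with `series`,
#'   `clinical`, `nodes` (`read_cohort`).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$series)) {
    utils::write.table(cohort$series[[id]],
                       file.path(dir, paste0(id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$nodes, file.path(dir, "nodes.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  clin_path <- file.path(dir, "clinical.csv")
  if (!file.exists(clin_path)) stop("missing clinical.csv in ", dir)
  clinical <- utils::read.csv(clin_path, stringsAsFactors = FALSE)
  nodes_path <- file.path(dir, "nodes.csv")
  nodes <- if (file.exists(nodes_path))
    utils::read.csv(nodes_path, stringsAsFactors = FALSE) else NULL
  series <- list()
  for (id in clinical$subject_id) {
    f <- file.path(dir, paste0(id, ".tsv"))
    if (!file.exists(f)) stop("missing time-series file for subject ", id)
    series[[id]] <- as.matrix(utils::read.table(f, header = TRUE, sep = "\t"))
  }
  list(series = series, clinical = clinical, nodes = nodes)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:",
      sum(x$clinical$group == "patient"), "patients,",
      sum(x$clinical$group == "control"), "controls;",
      x$config$n_nodes, "nodes x", x$config$n_timepoints, "timepoints",
      "(seed", x$config$seed, ")\n")
  invisible(x)
}
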
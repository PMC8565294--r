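#' Two-sample t-test from raw samples or printed summaries
#'
#' Accepts either raw numeric vectors or summary triples
#' `c(mean = , sd = , n = )` — the latter lets published tables that
#' report only mean +/- sd be re-tested. Welch uses per-group variances
#' with Satterthwaite degrees of freedom; Student pools the variance with
#' `df = n_a + n_b - 2`. Two-sided p from the t distribution.
#'
#' @param a,b numeric samples, or named vectors/lists with `mean`, `sd`,
#'   `n`.
#' @param variant `"welch"` (default) or `"student"`.
#' @return a `stat_result` list: `method`, `statistic`, `df`, `p_value`,
#'   `n_per_group`, `estimate` (mean difference a - b).
#' @examples
#' two_sample_t(c(mean = 14.42, sd = 6.86, n = 24),
#'              c(mean = 29.21, sd = 0.98, n = 19))
#' @export
two_sample_t <- function(a, b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  sa <- as_summary_triple(a)
  sb <- as_summary_triple(b)
  if (sa$n < 2 || sb$n < 2) stop("need n >= 2 per group")
  if (sa$sd < 0 || sb$sd < 0) stop("sd must be non-negative")
  diff <- sa$mean - sb$mean
  if (sa$sd == 0 && sb$sd == 0 && diff == 0)
    stop("zero variance in both groups with equal means: t undefined")
  if (variant == "welch") {
    va <- sa$sd^2 / sa$n
    vb <- sb$sd^2 / sb$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
    method <- "welch_t"
  } else {
    sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / (sa$n + sb$n - 2)
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    df <- sa$n + sb$n - 2
    method <- "student_t"
  }
  t <- if (se == 0) Inf * sign(diff) else diff / se
  p <- if (is.finite(t)) 2 * stats::pt(-abs(t), df) else 0
  stat_result(method, statistic = t, df = df, p_value = p,
              n_per_group = c(sa$n, sb$n), estimate = diff)
}

as_summary_triple <- function(x) {
  if (!is.null(names(x)) && all(c("mean", "sd", "n") %in% names(x)))
    return(list(mean = unname(x[["mean"]]), sd = unname(x[["sd"]]),
                n = unname(x[["n"]])))
  x <- as.numeric(x)
  if (anyNA(x)) stop("samples must not contain NA")
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

stat_result <- function(method, statistic, df = NA_real_, p_value,
                        n_per_group = NULL, n = NULL, estimate = NULL,
                        correction = "none", alpha_effective = NA_real_) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, n_per_group = n_per_group, n = n,
                 estimate = estimate, correction = correction,
                 alpha_effective = alpha_effective),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      if (!all(is.na(x$df))) paste0(", df = ", paste(format(x$df, digits = 4),
                                                     collapse = ", ")),
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Chi-square test on a 2 x 2 contingency table
#'
#' `chi2 = sum (O - E)^2 / E`, optionally with the Yates continuity
#' correction; p from the chi-square distribution with 1 df.
#'
#' @param counts 2 x 2 matrix of non-negative integer counts with all
#'   margins positive.
#' @param yates apply the continuity correction.
#' @return a `stat_result`.
#' @export
chi_square_2x2 <- function(counts, yates = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2), all(counts >= 0),
            all(counts == round(counts)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all margins must be positive")
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  dev <- abs(counts - E)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / E)
  stat_result(method = "chi_square", statistic = chi2, df = 1,
              p_value = stats::pchisq(chi2, 1, lower.tail = FALSE),
              n = sum(counts))
}

#' Mann-Whitney U test
#'
#' U for sample `a` (number of (a, b) pairs with a below b counts toward
#' `n_a * n_b - U`); midranks for ties. p by exhaustive enumeration of
#' group relabelings when `n_a + n_b <= 12`, otherwise by the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param a,b numeric samples.
#' @return a `stat_result` (statistic = U for `a`).
#' @export
mann_whitney_u <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 1, nb >= 1)
  u_of <- function(a, b) {
    r <- rank(c(a, b))
    sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  }
  u <- u_of(a, b)
  mu <- na * nb / 2
  if (na + nb <= 12) {
    pool <- c(a, b)
    idx <- utils::combn(na + nb, na)
    us <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    method <- "mann_whitney_u_exact"
  } else {
    nties <- table(c(a, b))
    n <- na + nb
    sig2 <- na * nb / 12 * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "mann_whitney_u"
  }
  stat_result(method, statistic = u, p_value = p,
              n_per_group = c(na, nb))
}

#' Permutation two-sample test
#'
#' Observed statistic is the Welch t; the null is built by relabeling
#' group membership. When the number of distinct relabelings
#' `choose(n_a + n_b, n_a)` is at most `exhaustive_limit`, all are
#' enumerated and p is exact; otherwise `n_perm` random relabelings give
#' the add-one estimate `p = (1 + #{|t*| >= |t|}) / (n_perm + 1)`, which
#' is never below `1/(n_perm + 1)` and never exactly zero.
#'
#' @param a,b numeric samples.
#' @param n_perm number of random relabelings (default 5000).
#' @param seed RNG seed.
#' @param exhaustive_limit enumerate exactly when the relabeling count is
#'   at most this (default 10000).
#' @return a `stat_result` with extra fields `n_perm` and `exhaustive`.
#' @export
permutation_two_sample <- function(a, b, n_perm = 5000, seed = 1L,
                                   exhaustive_limit = 10000) {
  na <- length(a); nb <- length(b)
  pool <- c(a, b)
  t_of <- function(x, y) {
    d <- mean(x) - mean(y)
    se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
    if (is.na(se) || se == 0) {
      if (d == 0) 0 else Inf * sign(d)
    } else d / se
  }
  t_obs <- t_of(a, b)
  if (is.nan(t_obs)) stop("degenerate groups: t undefined")
  n_total <- choose(na + nb, na)
  if (n_total <= exhaustive_limit) {
    idx <- utils::combn(na + nb, na)
    ts <- apply(idx, 2, function(i) t_of(pool[i], pool[-i]))
    p <- mean(abs(ts) >= abs(t_obs) - 1e-12)
    res <- stat_result("permutation_t", statistic = t_obs, p_value = p,
                       n_per_group = c(na, nb))
    res$n_perm <- n_total
    res$exhaustive <- TRUE
  } else {
    set.seed(seed)
    count <- 0L
    for (k in seq_len(n_perm)) {
      i <- sample.int(na + nb, na)
      if (abs(t_of(pool[i], pool[-i])) >= abs(t_obs) - 1e-12)
        count <- count + 1L
    }
    p <- (1 + count) / (n_perm + 1)
    res <- stat_result("permutation_t", statistic = t_obs, p_value = p,
                       n_per_group = c(na, nb))
    res$n_perm <- n_perm
    res$exhaustive <- FALSE
  }
  res
}

#' Pearson correlation with t-based p-value
#'
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` df, two-sided.
#'
#' @param x,y equal-length numeric samples (n >= 3, nonzero variance).
#' @return a `stat_result` (statistic = r, `df = n - 2`).
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  n <- length(x)
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  stat_result("pearson_r", statistic = r, df = n - 2, p_value = p, n = n)
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the residuals of `x` and `y` after
#' least-squares projection onto an intercept plus the covariates;
#' `df = n - 2 - #covariates`. Character/factor covariates (e.g. sex) are
#' encoded 0/1 via their first level.
#'
#' @param x,y numeric samples.
#' @param covariates data.frame of covariates (possibly zero columns).
#' @return a `stat_result` (statistic = partial r).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates) || NCOL(covariates) == 0 ||
      (is.data.frame(covariates) && ncol(covariates) == 0)) {
    res <- pearson_correlation(x, y)
    res$method <- "partial_r"
    return(res)
  }
  covariates <- as.data.frame(covariates)
  Z <- do.call(cbind, lapply(covariates, function(col) {
    if (is.numeric(col)) col
    else as.numeric(factor(col)) - 1
  }))
  k <- ncol(Z)
  if (n <= k + 2) stop("need n > #covariates + 2")
  X <- cbind(1, Z)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate design")
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  if (stats::sd(rx) <= 1e-10 * max(1, stats::sd(x)) ||
      stats::sd(ry) <= 1e-10 * max(1, stats::sd(y)))
    stop("zero residual variance: partial correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(t), df)
  }
  stat_result("partial_r", statistic = r, df = df, p_value = p, n = n)
}

#' Bonferroni significance levels for nodal tests
#'
#' The strict family-wise level `alpha / m` and the liberal exploratory
#' level `1 / m` (e.g. 0.05/264 = 0.000189 and 1/264 = 0.00379 for a
#' 264-node network).
#'
#' @param alpha nominal level in (0, 1).
#' @param m number of comparisons.
#' @return list: `strict`, `liberal`.
#' @export
bonferroni_levels <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  list(strict = alpha / m, liberal = 1 / m)
}

#' Group comparison of metric profiles plus brain-behavior correlations
#'
#' Reproduces the statistical layer of a two-group network study:
#' \itemize{
#' \item global AUCs (per metric): two-sample t (Welch by default),
#'   Mann-Whitney U, and permutation p, flagged at uncorrected
#'   `alpha`;
#' \item nodal AUCs (per node x metric): two-sample t flagged at the
#'   strict (`alpha/N`) and liberal (`1/N`) Bonferroni levels;
#' \item brain-behavior: Pearson and partial correlations (controlling
#'   for age, sex, head motion, duration by default) between each
#'   significant global AUC and each clinical score, within the patient
#'   group only.
#' }
#'
#' @param profiles named list of `metric_profile` (one per subject).
#' @param clinical data.frame with `subject_id`, `group`
#'   (patient/control) and clinical scores.
#' @param variant t-test variant for all comparisons.
#' @param alpha nominal significance level.
#' @param n_perm permutations for the global tests.
#' @param seed RNG seed for permutation tests.
#' @param scores clinical columns to correlate.
#' @param covariate_cols columns controlled for in partial correlations.
#' @return list of class `comparison_table`: `global`, `nodal`,
#'   `behavior` data.frames plus `alpha_levels`.
#' @export
compare_groups <- function(profiles, clinical,
                           variant = c("welch", "student"),
                           alpha = 0.05, n_perm = 5000, seed = 1L,
                           scores = c("abc_spontaneous", "abc_auditory",
                                      "abc_repetition", "abc_naming",
                                      "language_ability", "mmse", "moca"),
                           covariate_cols = c("age", "sex", "head_motion",
                                              "duration")) {
  variant <- match.arg(variant)
  clinical <- clinical[match(names(profiles), clinical$subject_id), ]
  if (anyNA(clinical$subject_id))
    stop("clinical table is missing subjects present in the profiles")
  is_pat <- clinical$group == "patient"
  if (sum(is_pat) < 2 || sum(!is_pat) < 2)
    stop("need at least 2 subjects per group")

  g_metrics <- names(profiles[[1]]$auc$global)
  auc_g <- t(vapply(profiles, function(p) p$auc$global,
                    numeric(length(g_metrics))))
  global <- do.call(rbind, lapply(g_metrics, function(m) {
    a <- auc_g[is_pat, m]; b <- auc_g[!is_pat, m]
    tt <- two_sample_t(a, b, variant)
    mw <- mann_whitney_u(a, b)
    pm <- permutation_two_sample(a, b, n_perm = n_perm, seed = seed)
    data.frame(metric = m,
               mean_patient = mean(a), mean_control = mean(b),
               t = tt$statistic, df = tt$df, p_t = tt$p_value,
               p_mwu = mw$p_value, p_perm = pm$p_value,
               significant = tt$p_value < alpha,
               stringsAsFactors = FALSE)
  }))

  n_metrics <- colnames(profiles[[1]]$auc$nodal)
  n_nodes <- nrow(profiles[[1]]$auc$nodal)
  lev <- bonferroni_levels(alpha, n_nodes)
  nodal <- do.call(rbind, lapply(n_metrics, function(m) {
    vals <- vapply(profiles, function(p) p$auc$nodal[, m], numeric(n_nodes))
    res <- lapply(seq_len(n_nodes), function(i) {
      a <- vals[i, is_pat]; b <- vals[i, !is_pat]
      if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
        return(list(statistic = 0, p_value = 1))
      two_sample_t(a, b, variant)
    })
    data.frame(node_id = seq_len(n_nodes), metric = m,
               t = vapply(res, function(r) r$statistic, numeric(1)),
               p = vapply(res, function(r) r$p_value, numeric(1)),
               stringsAsFactors = FALSE)
  }))
  nodal$flag_strict <- nodal$p < lev$strict
  nodal$flag_liberal <- nodal$p < lev$liberal

  sig_metrics <- global$metric[global$significant]
  pat <- clinical[is_pat, ]
  behavior <- NULL
  for (m in sig_metrics) {
    x <- auc_g[is_pat, m]
    for (sc in intersect(scores, names(pat))) {
      y <- pat[[sc]]
      if (stats::sd(y) == 0 || stats::sd(x) == 0) next
      pr <- pearson_correlation(x, y)
      cov_df <- pat[, intersect(covariate_cols, names(pat)), drop = FALSE]
      pc <- tryCatch(partial_correlation(x, y, cov_df),
                     error = function(e) NULL)
      behavior <- rbind(behavior, data.frame(
        metric = m, score = sc,
        r = pr$statistic, p_r = pr$p_value,
        partial_r = if (is.null(pc)) NA_real_ else pc$statistic,
        p_partial = if (is.null(pc)) NA_real_ else pc$p_value,
        stringsAsFactors = FALSE))
    }
  }

  structure(list(global = global, nodal = nodal, behavior = behavior,
                 alpha = alpha, alpha_levels = lev,
                 n_patients = sum(is_pat), n_controls = sum(!is_pat)),
            class = "comparison_table")
}

#' Write a comparison table to TSV files
#'
#' @param cmp a `comparison_table`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(cmp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cmp$global, file.path(dir, "group_global.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cmp$nodal, file.path(dir, "group_nodal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cmp$behavior))
    utils::write.table(cmp$behavior, file.path(dir, "brain_behavior.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(alpha = cmp$alpha,
                            alpha_strict = cmp$alpha_levels$strict,
                            alpha_liberal = cmp$alpha_levels$liberal,
                            n_patients = cmp$n_patients,
                            n_controls = cmp$n_controls,
                            significant_global = cmp$global$metric[cmp$global$significant]),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
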
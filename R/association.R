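#' Wilcoxon rank-sum group comparison
#'
#' Two-tailed rank-sum test with midrank ties. The p-value is exact when the
#' pooled sample has at most `exact_max` observations and no ties, and
#' otherwise uses the normal approximation with tie and continuity
#' corrections. The reported statistic is the rank sum of `x` in the pooled
#' midranking.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max largest pooled n for which the exact distribution is used.
#' @return list of class `group_comparison`: `statistic` (rank sum of `x`),
#'   `p_value`, `method`, `n_x`, `n_y`, `median_x`, `median_y`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 12) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact,
                       alternative = "two.sided"))
  rank_sum <- sum(rank(c(x, y))[seq_along(x)])
  structure(list(statistic = rank_sum, p_value = unname(wt$p.value),
                 method = if (exact) "exact" else "normal approximation",
                 n_x = length(x), n_y = length(y),
                 median_x = stats::median(x), median_y = stats::median(y)),
            class = "group_comparison")
}

#' Spearman correlation with a follow-up rule
#'
#' Pearson correlation of midranks after pairwise deletion of incomplete
#' pairs, with the t approximation for the p-value. Correlations of magnitude
#' `follow_up_threshold` or greater (a moderate effect) are flagged for
#' follow-up modeling.
#'
#' @param x,y paired numeric vectors.
#' @param follow_up_threshold magnitude triggering the follow-up flag.
#' @return list of class `correlation_result`: `rho`, `n`, `p_value`,
#'   `follow_up`.
#' @export
spearman_cor <- function(x, y, follow_up_threshold = 0.30) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) stop("insufficient data: need at least 3 complete pairs")
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("insufficient data: a variable is constant after ranking")
  rho <- stats::cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  structure(list(rho = rho, n = n, p_value = p,
                 follow_up = abs(rho) >= follow_up_threshold),
            class = "correlation_result")
}

#' Two-level random-intercept model of daily affect on exposure
#'
#' Fits, by maximum likelihood, a linear mixed model of a participant-day
#' outcome on the person-mean-centered exposure deviation, with a random
#' intercept per participant separating within- from between-person variance.
#' The person mean itself and further day-level covariates can enter as
#' additional fixed effects. Inference is Wald: two-tailed normal p-values
#' and 95% CIs. Standardized estimates rescale each slope by
#' `sd(predictor)/sd(outcome)` computed on the analysis sample (total SDs by
#' default, within-person SDs with `std = "within"`).
#'
#' @param data data.frame of participant-days.
#' @param outcome name of the outcome column.
#' @param predictor name of the person-centered predictor column; its
#'   person-centering is validated (per-participant mean within `1e-6` of 0).
#' @param between optional name of the person-mean column (between-person
#'   slope).
#' @param covariates optional character vector of covariate columns.
#' @param id participant identifier column.
#' @param std standardization variant: `"total"` or `"within"`.
#' @param recenter re-center the predictor per participant on the analysis
#'   sample (after missing-data deletion) instead of requiring it already
#'   centered. Useful when outcomes are missing on some exposure days.
#' @param reml use REML instead of ML.
#' @param conf_level Wald CI level.
#' @return list of class `mlm_result`: `fixed` (term, estimate, se, z,
#'   p_value, ci_low, ci_high, std_estimate, std_ci_low, std_ci_high),
#'   `var_intercept`, `var_residual`, `n_participants`, `n_days`,
#'   `converged`.
#' @export
fit_two_level <- function(data, outcome, predictor = "centered_log_ndvi",
                          between = NULL, covariates = NULL,
                          id = "participant_id", std = c("total", "within"),
                          reml = FALSE, conf_level = 0.95, recenter = FALSE) {
  std <- match.arg(std)
  cols <- c(id, outcome, predictor, between, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  tab <- table(d[[id]])
  if (sum(tab >= 2) < 2 || length(tab) < 2)
    stop("need at least 2 participants with at least 2 days each")
  pc <- tapply(d[[predictor]], d[[id]], mean)
  if (recenter) {
    d[[predictor]] <- d[[predictor]] - unname(pc[as.character(d[[id]])])
  } else if (max(abs(pc)) > 1e-6) {
    stop("`", predictor, "` is not person-mean-centered on the analysis sample")
  }

  rhs <- paste(c(sprintf("`%s`", c(predictor, between, covariates)),
                 sprintf("(1 | `%s`)", id)), collapse = " + ")
  form <- stats::as.formula(sprintf("`%s` ~ %s", outcome, rhs))
  warn <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(form, data = d, REML = reml),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  conv_msgs <- fit@optinfo$conv$lme4$messages
  singular <- lme4::isSingular(fit, tol = 1e-4)
  converged <- length(conv_msgs) == 0 && length(warn) == 0 && !singular

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- est / se
  terms_raw <- names(est)
  term_col <- gsub("`", "", terms_raw)
  sd_y <- if (std == "within") sd_within(d[[outcome]], d[[id]])
          else stats::sd(d[[outcome]])
  sd_x <- vapply(term_col, function(tm) {
    if (tm == "(Intercept)") return(NA_real_)
    if (std == "within") sd_within(d[[tm]], d[[id]]) else stats::sd(d[[tm]])
  }, numeric(1))
  scale <- sd_x / sd_y
  fixed <- data.frame(term = term_col, estimate = unname(est),
                      se = unname(se), z = unname(z),
                      p_value = unname(2 * stats::pnorm(-abs(z))),
                      ci_low = unname(est - zq * se),
                      ci_high = unname(est + zq * se),
                      std_estimate = unname(est * scale),
                      std_ci_low = unname((est - zq * se) * scale),
                      std_ci_high = unname((est + zq * se) * scale),
                      stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fixed = fixed,
                 var_intercept = vc$vcov[vc$grp == id & !is.na(vc$var1) &
                                           vc$var1 == "(Intercept)"][1],
                 var_residual = vc$vcov[vc$grp == "Residual"][1],
                 n_participants = length(tab), n_days = nrow(d),
                 converged = converged,
                 warnings = c(conv_msgs, warn)),
            class = "mlm_result")
}

sd_within <- function(x, id) {
  ctr <- x - as.vector(tapply(x, id, mean)[as.character(id)])
  stats::sd(ctr)
}

#' @export
print.mlm_result <- function(x, ...) {
  cat(sprintf("<mlm_result> %d participants, %d participant-days%s\n",
              x$n_participants, x$n_days,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$fixed, digits = 3, row.names = FALSE)
  cat(sprintf("random-intercept var %.4f, residual var %.4f\n",
              x$var_intercept, x$var_residual))
  invisible(x)
}

#' Full association report
#'
#' Reproduces the statistical battery over the pooled participant-day tables:
#' (a) Wilcoxon rank-sum group differences of participant-level means (EMA
#' affect, speech categories, NDVI, time at home), (b) per-group Spearman
#' correlations of study-mean exposure against affect and speech variables
#' with the 0.30 follow-up flag, and (c) per-group two-level models of each
#' daily outcome on person-centered log NDVI. Sensitivity reruns: pass
#' `exclude_days` (e.g. travel days) to drop participant-days before
#' modeling, or `adjust_time_at_home = TRUE` to add the covariate.
#'
#' @param exposure_daily centered cohort exposure table
#'   ([cohort_daily_exposure()] `$daily`).
#' @param affect_daily [daily_mean_affect()] output.
#' @param scores_daily [aggregate_daily_scores()] output (optional).
#' @param groups data.frame `participant_id`, `group`.
#' @param time_at_home optional [compute_time_at_home()] rows (pooled).
#' @param exclude_days optional data.frame `participant_id`, `date` of days
#'   to drop (travel-day sensitivity).
#' @param adjust_time_at_home add hours-at-home as a day-level covariate.
#' @param alpha two-tailed significance level (annotation only).
#' @return list of class `association_report`: `group_differences`,
#'   `correlations`, `mlm`, `n_days_used`.
#' @export
analysis_report <- function(exposure_daily, affect_daily, scores_daily = NULL,
                            groups, time_at_home = NULL, exclude_days = NULL,
                            adjust_time_at_home = FALSE, alpha = 0.05) {
  if (is.null(exposure_daily) || is.null(affect_daily) || is.null(groups))
    stop("dependency error: exposure, affect and group tables are required")
  if (adjust_time_at_home && is.null(time_at_home))
    stop("dependency error: adjust_time_at_home needs `time_at_home`")
  d <- merge(exposure_daily, affect_daily,
             by = c("participant_id", "date"), all = TRUE)
  if (!is.null(scores_daily))
    d <- merge(d, scores_daily, by = c("participant_id", "date"), all = TRUE)
  if (!is.null(time_at_home))
    d <- merge(d, time_at_home, by = c("participant_id", "date"), all.x = TRUE)
  if (!is.null(exclude_days) && nrow(exclude_days)) {
    drop <- paste(exclude_days$participant_id, exclude_days$date)
    d <- d[!(paste(d$participant_id, d$date) %in% drop), , drop = FALSE]
  }
  # re-center the predictor on the analysis sample (exclusions shift means)
  has_x <- !is.na(d$log_ndvi)
  pm <- tapply(d$log_ndvi[has_x], d$participant_id[has_x], mean)
  d$person_mean_log_ndvi <- as.vector(pm[d$participant_id])
  d$centered_log_ndvi <- d$log_ndvi - d$person_mean_log_ndvi
  d <- d[order(d$participant_id, d$date), ]
  d$group <- groups$group[match(d$participant_id, groups$participant_id)]
  if (any(is.na(d$group))) stop("unlabeled participant(s)")

  affect_vars <- setdiff(grep("^mean_", names(d), value = TRUE), "mean_ndvi")
  speech_vars <- intersect(c("word_count", "pct_positive", "pct_negative",
                             "pct_anxiety", "pct_anger", "pct_sadness"),
                           names(d))
  diff_vars <- c(affect_vars, speech_vars, "mean_ndvi",
                 intersect("hours_at_home", names(d)))

  pmean <- function(v) tapply(d[[v]], d$participant_id,
                              function(x) mean(x, na.rm = TRUE))
  glabel <- groups$group[match(names(pmean(diff_vars[1])),
                               groups$participant_id)]
  gd <- lapply(diff_vars, function(v) {
    pv <- pmean(v)
    gs <- split(pv[!is.na(pv)], glabel[!is.na(pv)])
    if (length(gs) != 2 || !all(lengths(gs) > 0)) return(NULL)
    w <- wilcoxon_rank_sum(gs[[1]], gs[[2]])
    data.frame(variable = v, group_1 = names(gs)[1], group_2 = names(gs)[2],
               mean_1 = mean(gs[[1]]), sd_1 = stats::sd(gs[[1]]),
               mean_2 = mean(gs[[2]]), sd_2 = stats::sd(gs[[2]]),
               statistic = w$statistic, p_value = w$p_value,
               significant = w$p_value < alpha, stringsAsFactors = FALSE)
  })
  group_differences <- do.call(rbind, gd)

  corr_vars <- c(affect_vars, speech_vars)
  cors <- list()
  for (g in sort(unique(d$group))) {
    ids_g <- unique(d$participant_id[d$group == g])
    ndvi_p <- pmean("mean_ndvi")[ids_g]
    for (v in corr_vars) {
      pv <- pmean(v)[ids_g]
      ok <- !is.na(pv) & !is.na(ndvi_p)
      if (sum(ok) < 3) next
      s <- spearman_cor(ndvi_p[ok], pv[ok])
      cors[[length(cors) + 1]] <-
        data.frame(group = g, variable = v, rho = s$rho, n = s$n,
                   p_value = s$p_value, follow_up = s$follow_up,
                   stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, cors)

  covs <- if (adjust_time_at_home) "hours_at_home" else NULL
  mlms <- list()
  for (g in sort(unique(d$group))) {
    dg <- d[d$group == g, , drop = FALSE]
    # person-centering must hold within the modeled subset
    okx <- !is.na(dg$log_ndvi)
    pmg <- tapply(dg$log_ndvi[okx], dg$participant_id[okx], mean)
    dg$centered_log_ndvi <- dg$log_ndvi - as.vector(pmg[dg$participant_id])
    for (v in corr_vars) {
      fit <- tryCatch(
        fit_two_level(dg, outcome = v, predictor = "centered_log_ndvi",
                      covariates = covs, recenter = TRUE),
        error = function(e) NULL)
      if (is.null(fit)) next
      row <- fit$fixed[fit$fixed$term == "centered_log_ndvi", ]
      mlms[[length(mlms) + 1]] <-
        data.frame(group = g, outcome = v, b = row$std_estimate,
                   b_ci_low = row$std_ci_low, b_ci_high = row$std_ci_high,
                   estimate_raw = row$estimate, se = row$se,
                   p_value = row$p_value, significant = row$p_value < alpha,
                   n_participants = fit$n_participants, n_days = fit$n_days,
                   converged = fit$converged, stringsAsFactors = FALSE)
    }
  }
  structure(list(group_differences = group_differences,
                 correlations = correlations,
                 mlm = do.call(rbind, mlms),
                 n_days_used = nrow(d)),
            class = "association_report")
}

#' Write an association report to CSV tables and a JSON bundle
#'
#' @param report an `association_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(report$group_differences,
            file.path(dir, "group_differences.csv"), row.names = FALSE)
  write.csv(report$correlations, file.path(dir, "correlations.csv"),
            row.names = FALSE)
  write.csv(report$mlm, file.path(dir, "mlm.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
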
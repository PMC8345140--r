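#' Cell density from an instance label map
#'
#' Counts the detected instances and converts the analysed pixel area to
#' mm2 via the microns-per-pixel scale:
#' `area_mm2 = n_pixels * (mpp / 1000)^2`.
#'
#' @param instances integer instance label map.
#' @param microns_per_pixel image scale in micrometres per pixel (0.25 for a
#'   40x scan by default).
#' @param analysed_mask optional binary matrix marking the analysed tissue
#'   region; defaults to the full image.
#' @return a list with `n_cells`, `area_mm2` and `density` (cells per mm2).
#' @examples
#' lab <- matrix(0L, 100, 100); lab[40:45, 40:45] <- 1L
#' cell_density(lab, microns_per_pixel = 10)
#' @export
cell_density <- function(instances, microns_per_pixel = 0.25,
                         analysed_mask = NULL) {
  if (microns_per_pixel <= 0) stop("microns_per_pixel must be > 0")
  n_cells <- length(unique(instances[instances > 0]))
  n_px <- if (is.null(analysed_mask)) length(instances) else sum(analysed_mask > 0)
  area_mm2 <- n_px * (microns_per_pixel / 1000)^2
  if (area_mm2 <= 0) stop("analysed area is empty")
  list(n_cells = n_cells, area_mm2 = area_mm2, density = n_cells / area_mm2)
}

#' Concordance of predicted and reference densities
#'
#' Pearson product-moment correlation between detected and ground-truth
#' densities across patients/cores.
#'
#' @param pred,gt numeric vectors of equal length (>= 3), neither constant.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
density_concordance <- function(pred, gt) {
  if (length(pred) != length(gt)) stop("pred and gt lengths differ")
  if (length(pred) < 3) stop("need at least 3 paired densities")
  if (stats::sd(pred) == 0 || stats::sd(gt) == 0)
    stop("constant input: correlation undefined")
  stats::cor(pred, gt)
}

#' Time-dependent ROC analysis and optimal density cutoff
#'
#' Cumulative-case / dynamic-control ROC at a fixed horizon for a continuous
#' marker under right censoring. Cases are patients with an observed event
#' by the horizon, controls are patients still at risk beyond it. By default
#' cases are weighted by inverse probability of censoring (reverse
#' Kaplan-Meier weights `1/G(T_i)`); `ipcw = FALSE` gives the naive
#' unweighted estimator. The optimal cutoff maximises Youden's J
#' (`sens + spec - 1`), ties broken toward the lower cutoff; patients with
#' marker `>= cutoff` form group 1, the rest group 2.
#'
#' @param marker numeric marker values (e.g. cell density).
#' @param time follow-up times in years.
#' @param event event indicator (1 = event).
#' @param horizon years (default 5).
#' @param ipcw use censoring weights (default) or the naive estimator.
#' @return a list with `roc` (data.frame `cutoff`, `sens`, `spec`), `auc`,
#'   `cutoff`, `youden` and `group` (integer 1/2 per patient).
#' @export
td_roc_cutoff <- function(marker, time, event, horizon = 5, ipcw = TRUE) {
  stopifnot(length(marker) == length(time), length(time) == length(event))
  cases <- which(time <= horizon & event == 1)
  ctrls <- which(time > horizon)
  if (length(cases) < 2) stop("need at least 2 events before the horizon")
  if (length(ctrls) < 1) stop("no controls beyond the horizon")
  w <- if (ipcw) {
    cf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
    G <- stats::stepfun(cf$time, c(1, cf$surv))
    1 / pmax(G(time[cases]), 1e-12)
  } else {
    rep(1, length(cases))
  }
  cuts <- sort(unique(marker))
  sens <- vapply(cuts, function(c0) sum(w[marker[cases] >= c0]) / sum(w),
                 numeric(1))
  spec <- vapply(cuts, function(c0) mean(marker[ctrls] < c0), numeric(1))
  J <- sens + spec - 1
  best <- which(J >= max(J) - 1e-12)[1]  # ties -> lower cutoff
  # integrate along the curve ordered by descending cutoff (fpr ascending)
  auc <- trapezoid(c(0, rev(1 - spec), 1), c(0, rev(sens), 1))
  list(roc = data.frame(cutoff = cuts, sens = sens, spec = spec),
       auc = auc, cutoff = cuts[best], youden = J[best],
       group = ifelse(marker >= cuts[best], 1L, 2L))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with right censoring, via
#' [survival::survfit()]. The returned step function starts at
#' `(time = 0, surv = 1)`.
#'
#' @param time follow-up times (>= 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `surv`.
#' @examples
#' km_curve(c(1, 2, 3), c(1, 1, 1))$surv  # 1, 2/3, 1/3, 0
#' @export
km_curve <- function(time, event) {
  if (any(time < 0)) stop("times must be >= 0")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = c(0, fit$time), n_risk = c(length(time), fit$n.risk),
             n_event = c(0, fit$n.event), surv = c(1, fit$surv))
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank statistic via [survival::survdiff()]. When a
#' horizon is given, all observations are administratively censored at that
#' time first ("5-year survival" testing).
#'
#' @param time1,event1 follow-up and event indicator of group 1.
#' @param time2,event2 follow-up and event indicator of group 2.
#' @param horizon optional administrative-censoring horizon in years.
#' @return a list with `chisq`, `df` and `p`.
#' @export
logrank_test <- function(time1, event1, time2, event2, horizon = NULL) {
  if (length(time1) == 0L || length(time2) == 0L)
    stop("both groups must be non-empty")
  time <- c(time1, time2)
  event <- c(event1, event2)
  grp <- rep(1:2, c(length(time1), length(time2)))
  if (!is.null(horizon)) {
    event <- ifelse(time > horizon, 0L, event)
    time <- pmin(time, horizon)
  }
  if (sum(event) == 0L)
    return(list(chisq = 0, df = 1L, p = 1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chisq <- as.numeric(sd$chisq)
  list(chisq = chisq, df = 1L, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

#' Survival stratification by marker cutoff
#'
#' The downstream clinical chain: pick the density cutoff by time-dependent
#' ROC (Youden's J), dichotomize the cohort (group 1 = high density),
#' estimate Kaplan-Meier curves per group and test the difference with the
#' log-rank test after administrative censoring at the horizon.
#'
#' Note that because the cutoff is optimised on the same cohort that is then
#' tested, the log-rank p-value is exploratory, not a calibrated
#' significance level.
#'
#' @param cohort data.frame with columns `density`, `time_years`, `event`
#'   (as from [generate_cohort()] or [read_cohort()]).
#' @param horizon years (default 5).
#' @param ipcw passed to [td_roc_cutoff()].
#' @return an object of class `"nq_strat"`: `cutoff`, `auc`, `roc`,
#'   `group` (1/2 per patient), `km` (list of two curves), `logrank`
#'   (`chisq`, `df`, `p`) and `horizon`.
#' @examples
#' co <- generate_cohort(synth_cohort_config(n_patients = 120, seed = 2))
#' st <- stratify_survival(co)
#' st$logrank$p
#' @export
stratify_survival <- function(cohort, horizon = 5, ipcw = TRUE) {
  need <- c("density", "time_years", "event")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort missing columns: ", paste(miss, collapse = ", "))
  roc <- td_roc_cutoff(cohort$density, cohort$time_years, cohort$event,
                       horizon = horizon, ipcw = ipcw)
  g1 <- roc$group == 1L
  lr <- logrank_test(cohort$time_years[g1], cohort$event[g1],
                     cohort$time_years[!g1], cohort$event[!g1],
                     horizon = horizon)
  structure(list(
    cutoff = roc$cutoff, auc = roc$auc, roc = roc$roc, group = roc$group,
    km = list(group1 = km_curve(cohort$time_years[g1], cohort$event[g1]),
              group2 = km_curve(cohort$time_years[!g1], cohort$event[!g1])),
    logrank = lr, horizon = horizon, n = c(sum(g1), sum(!g1))
  ), class = "nq_strat")
}

#' @export
print.nq_strat <- function(x, ...) {
  cat("Survival stratification by marker density\n")
  cat(sprintf("  optimal cutoff (Youden): %.2f cells/mm2 (td-ROC AUC %.3f)\n",
              x$cutoff, x$auc))
  cat(sprintf("  groups: n1 = %d (high), n2 = %d (low)\n", x$n[1], x$n[2]))
  cat(sprintf("  log-rank (%g-year): chi2 = %.3f, df = %d, p = %.4g\n",
              x$horizon, x$logrank$chisq, x$logrank$df, x$logrank$p))
  invisible(x)
}

#' @export
summary.nq_strat <- function(object, ...) {
  print(object)
  s5 <- function(km) {
    i <- findInterval(object$horizon, km$time)
    km$surv[max(i, 1)]
  }
  cat(sprintf("  survival at horizon: group 1 %.3f, group 2 %.3f\n",
              s5(object$km$group1), s5(object$km$group2)))
  invisible(object)
}

#' Plot Kaplan-Meier curves of a stratification
#'
#' @param x an `"nq_strat"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.nq_strat <- function(x, ...) {
  k1 <- x$km$group1; k2 <- x$km$group2
  graphics::plot(NA, xlim = c(0, max(k1$time, k2$time)), ylim = c(0, 1),
                 xlab = "years", ylab = "survival probability", ...)
  graphics::lines(k1$time, k1$surv, type = "s", col = "firebrick", lwd = 2)
  graphics::lines(k2$time, k2$surv, type = "s", col = "steelblue", lwd = 2)
  graphics::abline(v = x$horizon, lty = 3)
  graphics::legend("bottomleft", bty = "n", lwd = 2,
                   col = c("firebrick", "steelblue"),
                   legend = c(sprintf("group 1 (density >= %.1f)", x$cutoff),
                              "group 2"))
  invisible(x)
}
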
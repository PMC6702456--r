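.check_cohort_times <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("cohort must be a non-empty data.frame", call. = FALSE)
  need <- c("time_months", "event")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("cohort is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tm <- records$time_months
  if (any(!is.finite(tm)) || any(tm < 0))
    stop("time_months must be finite and non-negative", call. = FALSE)
  if (!all(records$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (cancer-specific death)",
         call. = FALSE)
  invisible(TRUE)
}

.new_survival_curve <- function(time, surv, n_risk = NULL, n_event = NULL,
                                n0 = NA_real_) {
  structure(list(time = as.numeric(time), surv = as.numeric(surv),
                 n_risk = if (is.null(n_risk)) rep(NA_real_, length(time))
                          else as.numeric(n_risk),
                 n_event = if (is.null(n_event)) rep(NA_real_, length(time))
                           else as.numeric(n_event),
                 n0 = n0),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Kaplan-Meier curve on", length(x$time), "grid points (",
      min(x$time), "to", max(x$time), "months ), n0 =", x$n0, "\n")
  cat("  S(last) =", signif(x$surv[length(x$surv)], 4), "\n")
  invisible(x)
}

#' Kaplan-Meier estimate on a monthly grid
#'
#' Product-limit estimator of cancer-specific survival, evaluated as a
#' right-continuous step function on a regular grid of months. Censored
#' subjects leave the risk set without a survival drop; at tied times,
#' deaths are processed before censorings (the standard product-limit
#' convention). The grid runs from `grid_step` to the last follow-up time,
#' with S(0) = 1 implicit.
#'
#' @param records Data.frame with numeric `time_months` (>= 0) and binary
#'   `event` columns (1 = cancer-specific death, 0 = censored).
#' @param grid_step Grid spacing in months (default 1).
#' @return A `survival_curve`: grid `time`, survival `surv`, number at risk
#'   at each grid point (`n_risk`), events within each grid interval
#'   (`n_event`), and the initial cohort size `n0`.
#' @examples
#' km_estimate(data.frame(time_months = c(2, 3, 4, 5),
#'                        event = c(1, 0, 1, 1)))
#' @export
km_estimate <- function(records, grid_step = 1) {
  .check_cohort_times(records)
  stopifnot(grid_step > 0)
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1,
    data = records, conf.type = "none")
  k <- max(1L, ceiling(max(records$time_months) / grid_step))
  grid <- seq_len(k) * grid_step
  s <- summary(fit, times = grid, extend = TRUE)
  .new_survival_curve(time = s$time, surv = s$surv, n_risk = s$n.risk,
                      n_event = s$n.event, n0 = nrow(records))
}

#' Survival probability at a horizon
#'
#' Right-continuous step evaluation of a survival curve: the value at the
#' last grid point at or before `horizon`, or 1 before the first grid
#' point. A horizon beyond the last follow-up returns the value at the last
#' observed point, flagged with attribute `extrapolated = TRUE` and a
#' warning.
#'
#' @param curve A `survival_curve`.
#' @param horizon Months (>= 0); 60 for 5-year CSS, 36 for 3-year CSS.
#' @return Survival probability in \[0, 1\].
#' @export
css_at <- function(curve, horizon) {
  stopifnot(inherits(curve, "survival_curve"), horizon >= 0)
  if (horizon > max(curve$time)) {
    warning("horizon ", horizon, " months is beyond the last follow-up (",
            max(curve$time), " months); value is extrapolated",
            call. = FALSE)
    return(structure(curve$surv[length(curve$surv)], extrapolated = TRUE))
  }
  i <- findInterval(horizon, curve$time)
  if (i == 0) 1.0 else curve$surv[i]
}

#' Re-evaluate a curve on a new grid
#'
#' Right-continuous step interpolation of a survival curve onto a new
#' strictly increasing grid; no new information is created. Beyond the last
#' original grid point the last value is carried forward. At-risk and event
#' counts do not transfer and are set to `NA`.
#'
#' @param curve A `survival_curve`.
#' @param grid Strictly increasing vector of month time points.
#' @return A `survival_curve` on `grid`.
#' @export
regrid <- function(curve, grid) {
  stopifnot(inherits(curve, "survival_curve"))
  if (any(diff(grid) <= 0) || any(grid <= 0))
    stop("grid must be positive and strictly increasing", call. = FALSE)
  s <- stats::approx(x = c(0, curve$time), y = c(1, curve$surv), xout = grid,
                     method = "constant", f = 0, rule = 2)$y
  .new_survival_curve(time = grid, surv = s, n0 = curve$n0)
}

.logrank_result <- function(chi2) {
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Two-sample log-rank test on patient-level records
#'
#' Classical log-rank statistic: at each distinct event time, the observed
#' minus hypergeometric-expected event count in group A, with the
#' hypergeometric variance; chi-squared = (sum(O - E))^2 / sum(V) on 1
#' degree of freedom. This is the patient-level reference against which the
#' curve-level distance ([curve_chi2_distance()]) is validated.
#'
#' @param group_a,group_b Data.frames with `time_months` and `event`.
#' @return List with `chi2` and two-sided `p` from chi-squared(1).
#' @export
logrank_patient <- function(group_a, group_b) {
  .check_cohort_times(group_a)
  .check_cohort_times(group_b)
  time <- c(group_a$time_months, group_b$time_months)
  event <- c(group_a$event, group_b$event)
  grp <- rep(0:1, c(nrow(group_a), nrow(group_b)))
  if (sum(event) == 0)
    stop("log-rank statistic undefined: no events in either group",
         call. = FALSE)
  dt <- sort(unique(time[event == 1]))
  oe <- 0; v <- 0
  for (ti in dt) {
    at <- time >= ti
    n <- sum(at)
    n1 <- sum(at & grp == 0)
    d <- sum(event == 1 & time == ti)
    d1 <- sum(event == 1 & time == ti & grp == 0)
    oe <- oe + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- if (v > 0) oe^2 / v else 0
  .logrank_result(chi2)
}

#' Log-rank chi-squared distance between two survival curves
#'
#' The curve-level log-rank statistic used as the distance between
#' Kaplan-Meier curves for stage regrouping: the two groups are assumed to
#' be of equal size N, with risk sets replaced by N times the accumulated
#' survival proportions a and b on a shared monthly grid. With
#' `Da_i = a_(i-1) - a_i`, `Db_i = b_(i-1) - b_i`, `d_i = Da_i + Db_i` and
#' `r_i = a_(i-1) + b_(i-1)`:
#' \deqn{O_i = Da_i, \quad E_i = a_{i-1} d_i / r_i, \quad
#'       V_i = a_{i-1} b_{i-1} d_i (a_i + b_i) / r_i^3,}
#' and the per-capita statistic is `(sum(O - E))^2 / sum(V)` — the large-N
#' limit of the hypergeometric log-rank variance (note `a_i + b_i` equals
#' `r_i - d_i` in the curve view, where every decrement counts as a death).
#' For finite `n_per_group = N` the statistic is N times the per-capita
#' value; `"infinite"` (the default) returns the per-capita distance
#' itself, which is what the clustering uses — the common factor N cannot
#' change the merge order. Intervals with `d_i = 0` or `r_i = 0` contribute
#' nothing.
#'
#' Censoring enters only through the KM estimation of the input curves; at
#' the curve level every decrement is treated as a death. With
#' `finite_correction = TRUE` the variance denominator uses `N r_i - 1` in
#' place of `N r_i`, which reproduces the patient-level log-rank exactly on
#' uncensored grid-aligned data.
#'
#' @param a,b `survival_curve` objects on identical grids.
#' @param n_per_group `"infinite"` for the per-capita distance, or a finite
#'   per-group size N.
#' @param finite_correction Use the exact finite-N hypergeometric variance
#'   (requires finite `n_per_group`).
#' @return List with `chi2` and two-sided `p` from chi-squared(1).
#' @export
curve_chi2_distance <- function(a, b, n_per_group = "infinite",
                                finite_correction = FALSE) {
  stopifnot(inherits(a, "survival_curve"), inherits(b, "survival_curve"))
  if (length(a$time) != length(b$time) ||
      any(abs(a$time - b$time) > 1e-8))
    stop("curves are on incompatible grids; regrid() them to a common ",
         "monthly grid first", call. = FALSE)
  for (cv in list(a, b)) {
    if (any(cv$surv > 1 + 1e-12) || any(cv$surv < -1e-12) ||
        any(diff(c(1, cv$surv)) > 1e-12))
      stop("curve must start at 1 and be non-increasing in [0, 1]",
           call. = FALSE)
  }
  infinite <- identical(n_per_group, "infinite")
  if (finite_correction && infinite)
    stop("finite_correction requires a finite n_per_group", call. = FALSE)
  if (!infinite) stopifnot(is.numeric(n_per_group), n_per_group > 0)

  al <- c(1, utils::head(a$surv, -1)); ar <- a$surv
  bl <- c(1, utils::head(b$surv, -1)); br <- b$surv
  da <- al - ar; db <- bl - br
  d <- da + db
  r <- al + bl
  keep <- d > 0 & r > 0
  if (!any(keep)) return(.logrank_result(0))
  oe <- sum((da - al * d / r)[keep])
  if (finite_correction) {
    n <- n_per_group
    v <- sum((n^2 * al * bl * d * (ar + br) / (r^2 * (n * r - 1)))[keep])
    chi2 <- if (v > 0) (n * oe)^2 / v else 0
  } else {
    v <- sum((al * bl * d * (ar + br) / r^3)[keep])
    chi1 <- if (v > 0) oe^2 / v else 0
    chi2 <- if (infinite) chi1 else n_per_group * chi1
  }
  .logrank_result(chi2)
}

#' Write a survival curve as TSV
#'
#' Columns `time_months`, `survival`, `n_at_risk`, `n_events`.
#'
#' @param curve A `survival_curve`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_curve_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "survival_curve"))
  utils::write.table(
    data.frame(time_months = curve$time, survival = curve$surv,
               n_at_risk = curve$n_risk, n_events = curve$n_event),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
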
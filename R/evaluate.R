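#' Two-group Cox proportional hazards fit
#'
#' Cox regression with a single binary covariate (1 = group B), Breslow
#' handling of tied event times by default (month-granular registry data is
#' heavily tied; Efron is available as an option). The returned hazard
#' ratio is h(B)/h(A). Monotone partial likelihood (complete separation of
#' event times) is flagged rather than raised: the result carries an
#' infinite-bound confidence interval and `flagged = TRUE`.
#'
#' @param group_a,group_b Data.frames with `time_months` and `event`; each
#'   must contain at least one subject, and the pooled data at least one
#'   event.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A `cox_fit`: `beta`, `se`, `hr`, `ci95` (lo, hi), Wald `p`,
#'   `flagged`.
#' @export
cox_two_group <- function(group_a, group_b, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  .check_cohort_times(group_a)
  .check_cohort_times(group_b)
  if (sum(group_a$event) + sum(group_b$event) < 1)
    stop("Cox fit undefined: no events in either group", call. = FALSE)
  dat <- data.frame(
    time_months = c(group_a$time_months, group_b$time_months),
    event = c(group_a$event, group_b$event),
    grp = rep(c(0, 1), c(nrow(group_a), nrow(group_b))))
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time_months, event) ~ grp, data = dat,
                    ties = ties, control = survival::coxph.control(
                      eps = 1e-9, iter.max = 50)),
    warning = function(w) invokeRestart("muffleWarning"))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  flagged <- !is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 50
  if (flagged) {
    ci <- if (is.finite(beta) && beta > 0) c(0, Inf) else c(0, Inf)
    hr <- if (is.finite(beta)) exp(beta) else NA_real_
    res <- list(beta = beta, se = se, hr = hr, ci95 = ci, p = NA_real_,
                flagged = TRUE)
  } else {
    hr <- exp(beta)
    ci <- exp(beta + c(-1, 1) * 1.96 * se)
    p <- 2 * stats::pnorm(-abs(beta / se))
    res <- list(beta = beta, se = se, hr = hr, ci95 = ci, p = p,
                flagged = FALSE)
  }
  structure(res, class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("HR = %.4f (95%% CI %.4f-%.4f), p = %s%s\n", x$hr,
              x$ci95[1], x$ci95[2], format.pval(x$p, digits = 4),
              if (x$flagged) " [flagged: monotone likelihood]" else ""))
  invisible(x)
}

.stage_records <- function(records, map, level) {
  .check_full_cohort(records)
  lk <- stage_lookup(map, records$histology, records$t, records$n,
                     records$m)
  if (level == "substage") lk$substage else lk$stage
}

#' Adjacent-stage hazard ratios under a staging system
#'
#' One two-group Cox fit per adjacent pair of stages (I-II, II-III, III-IV)
#' or sub-stages (the seven IA-IB ... IIIC-IV pairs), in ladder order. The
#' ratio is oriented as earlier stage over later stage, so values below 1
#' mean the earlier stage carries the lower hazard. Pairs with an empty
#' group are skipped with a warning.
#'
#' @param records Cohort data.frame.
#' @param map A `stage_map` assigning every record.
#' @param level `"stage"` or `"substage"`.
#' @param ties Passed to [cox_two_group()].
#' @return Data.frame with one row per fitted pair: `comparison`, `hr`,
#'   `lo`, `hi`, `p`, `flagged`.
#' @export
hazard_ratio_adjacent_stages <- function(records, map,
                                         level = c("stage", "substage"),
                                         ties = "breslow") {
  level <- match.arg(level)
  grp <- .stage_records(records, map, level)
  lev <- if (level == "substage") .substages else .stages
  out <- list()
  for (i in seq_len(length(lev) - 1)) {
    early <- records[grp == lev[i], , drop = FALSE]
    late <- records[grp == lev[i + 1], , drop = FALSE]
    cmp <- paste(lev[i], "to", lev[i + 1])
    if (nrow(early) == 0 || nrow(late) == 0) {
      warning("skipping ", cmp, ": empty stage group", call. = FALSE)
      next
    }
    f <- cox_two_group(group_a = late, group_b = early, ties = ties)
    out[[cmp]] <- data.frame(comparison = cmp, hr = f$hr, lo = f$ci95[1],
                             hi = f$ci95[2], p = f$p, flagged = f$flagged,
                             stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(comparison = character(), hr = numeric(),
                      lo = numeric(), hi = numeric(), p = numeric(),
                      flagged = logical(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Concordance counts for an ordinal risk rank under right censoring.
# Comparable pair: the strictly shorter observed time has event = 1.
# Concordant: the higher-rank (higher-risk) subject has the shorter time;
# rank ties count 1/2. For each event, the number of strictly longer
# survivors in each rank class is read off the class's sorted time vector
# with findInterval, so the cost is O(K n log n) for K rank classes.
.concordance_counts <- function(time, event, rank, n_rank) {
  ev <- event == 1
  te <- time[ev]
  re <- rank[ev]
  if (length(te) == 0) return(c(conc = 0, disc = 0, tied = 0))
  longer <- matrix(0, length(te), n_rank)
  for (k in seq_len(n_rank)) {
    sk <- sort(time[rank == k])
    longer[, k] <- length(sk) - findInterval(te, sk)
  }
  lower_tri <- outer(seq_len(n_rank), seq_len(n_rank), `<`)
  pick <- cbind(seq_along(te), re)
  below <- (longer %*% lower_tri)[pick]  # partners of strictly lower rank
  tied <- longer[pick]
  above <- rowSums(longer) - below - tied
  c(conc = sum(below), disc = sum(above), tied = sum(tied))
}

#' Harrell's concordance index for a staging system
#'
#' Discrimination of a staging system as an ordinal risk predictor: over
#' all comparable patient pairs (the strictly shorter observed time ends in
#' a cancer-specific death), the fraction in which the later-stage patient
#' dies first, with same-stage pairs counting one half. The confidence
#' interval is a seeded bootstrap percentile over patients.
#'
#' @param records Cohort data.frame.
#' @param map A `stage_map` assigning every record.
#' @param level `"stage"` or `"substage"` ordinal ranks.
#' @param B Bootstrap replicates for the CI (default 1000); `B = 0` skips
#'   the CI.
#' @param seed Integer seed for the bootstrap.
#' @return A `concordance_result`: `c`, `ci95`, `n_pairs`, `flagged`
#'   (`TRUE` when no comparable pairs exist and `c = 0.5` by convention).
#' @export
harrell_c <- function(records, map, level = c("stage", "substage"),
                      B = 1000, seed = 1L) {
  level <- match.arg(level)
  if (nrow(records) < 2 || sum(records$event) < 1)
    stop("need at least 2 records and 1 event", call. = FALSE)
  grp <- .stage_records(records, map, level)
  rank <- stage_rank(grp, level)
  n_rank <- length(if (level == "substage") .substages else .stages)
  cstat <- function(idx) {
    k <- .concordance_counts(records$time_months[idx], records$event[idx],
                             rank[idx], n_rank)
    np <- sum(k)
    if (np == 0) 0.5 else (k[["conc"]] + 0.5 * k[["tied"]]) / np
  }
  all_idx <- seq_len(nrow(records))
  k <- .concordance_counts(records$time_months, records$event, rank, n_rank)
  n_pairs <- sum(k)
  c_hat <- if (n_pairs == 0) 0.5 else (k[["conc"]] + 0.5 * k[["tied"]]) / n_pairs
  flagged <- n_pairs == 0
  ci <- c(NA_real_, NA_real_)
  if (B > 0 && !flagged) {
    set.seed(seed)
    boot <- vapply(seq_len(B), function(b) {
      cstat(sample(all_idx, replace = TRUE))
    }, numeric(1))
    ci <- unname(stats::quantile(boot, c(0.025, 0.975), names = FALSE))
  } else if (flagged) {
    ci <- c(0.5, 0.5)
  }
  structure(list(c = unname(c_hat), ci95 = ci, n_pairs = unname(n_pairs),
                 flagged = flagged, B = B, level = level),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("C-index (%s ranks) = %.4f (95%% CI %.4f-%.4f), %s pairs%s\n",
              x$level, x$c, x$ci95[1], x$ci95[2],
              format(x$n_pairs, big.mark = ","),
              if (x$flagged) " [no comparable pairs]" else ""))
  invisible(x)
}

#' Predicted-versus-observed survival calibration
#'
#' For every stage group and horizon: the predicted survival is the
#' training-cohort KM estimate, the observed survival is the test-cohort KM
#' estimate, with a seeded bootstrap percentile interval over test
#' patients. Stages absent from the test cohort are omitted with a warning.
#'
#' @param train,test Cohort data.frames stageable under `map`.
#' @param map A `stage_map`.
#' @param horizons Months (default 36 and 60: 3- and 5-year CSS).
#' @param level `"stage"` or `"substage"` grouping.
#' @param B Bootstrap replicates (default 1000); `B = 0` skips the CI.
#' @param seed Integer seed.
#' @return Data.frame with columns `group`, `horizon`, `predicted`,
#'   `observed`, `lo`, `hi`.
#' @export
calibration_points <- function(train, test, map, horizons = c(36, 60),
                               level = c("stage", "substage"), B = 1000,
                               seed = 1L) {
  level <- match.arg(level)
  gtr <- .stage_records(train, map, level)
  gte <- .stage_records(test, map, level)
  lev <- if (level == "substage") .substages else .stages
  set.seed(seed)
  out <- list()
  for (g in intersect(lev, unique(gtr))) {
    if (!(g %in% gte)) {
      warning("stage ", g, " absent from test cohort; row omitted",
              call. = FALSE)
      next
    }
    tr <- train[gtr == g, , drop = FALSE]
    te <- test[gte == g, , drop = FALSE]
    km_tr <- km_estimate(tr)
    km_te <- km_estimate(te)
    eval_css <- function(curve, h) {
      suppressWarnings(as.numeric(css_at(curve, min(h, max(curve$time)))))
    }
    boot <- if (B > 0) {
      vapply(seq_len(B), function(b) {
        bs <- te[sample(nrow(te), replace = TRUE), , drop = FALSE]
        kb <- km_estimate(bs)
        vapply(horizons, function(h) eval_css(kb, h), numeric(1))
      }, numeric(length(horizons)))
    } else NULL
    for (hi in seq_along(horizons)) {
      h <- horizons[hi]
      ci <- if (is.null(boot)) c(NA_real_, NA_real_) else
        stats::quantile(if (is.matrix(boot)) boot[hi, ] else boot,
                        c(0.025, 0.975), names = FALSE)
      out[[paste(g, h)]] <- data.frame(
        group = g, horizon = h,
        predicted = eval_css(km_tr, h),
        observed = eval_css(km_te, h),
        lo = ci[1], hi = ci[2], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full evaluation report for a staging system
#'
#' Bundles adjacent-stage hazard ratios, the C-index at stage and sub-stage
#' ranks, and the bootstrap self-calibration table for one staging system
#' on one cohort.
#'
#' @param records Cohort data.frame.
#' @param map A `stage_map`.
#' @param B Bootstrap replicates for C-index and calibration CIs.
#' @param seed Integer seed.
#' @return A list with elements `system`, `cox` (stage and substage
#'   tables), `c_index` (stage and substage results), `calibration`.
#' @export
evaluation_report <- function(records, map, B = 1000, seed = 1L) {
  stopifnot(inherits(map, "stage_map"))
  list(
    system = map$system,
    cox = list(
      stage = hazard_ratio_adjacent_stages(records, map, "stage"),
      substage = hazard_ratio_adjacent_stages(records, map, "substage")),
    c_index = list(
      stage = unclass(harrell_c(records, map, "stage", B = B, seed = seed)),
      substage = unclass(harrell_c(records, map, "substage", B = B,
                                   seed = seed + 1L))),
    calibration = calibration_points(records, records, map, B = B,
                                     seed = seed + 2L))
}
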
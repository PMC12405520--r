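#' @importFrom rlang .data
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Harrell's concordance index
#'
#' Fraction of comparable pairs whose predicted risks are correctly ordered.
#' Comparable pairs are `(i, j)` with `event_i = 1` and `t_i < t_j`: the
#' patient with the observed earlier event should carry the higher risk.
#' Risk ties count 0.5; two patients with identical times do not form a
#' comparable pair (Harrell's convention).
#'
#' @param risks Numeric risk scores (higher = worse prognosis).
#' @param times Follow-up times.
#' @param events Binary event indicators.
#' @return Scalar in `[0, 1]`, or `NA` with attribute `undefined = TRUE` when
#'   no comparable pair exists.
#' @export
harrell_cindex <- function(risks, times, events) {
  stopifnot(length(risks) == length(times), length(times) == length(events))
  cmp <- comparable_pairs(times, events)
  n_cmp <- sum(cmp)
  if (n_cmp == 0L) {
    return(structure(NA_real_, undefined = TRUE))
  }
  diff <- outer(risks, risks, "-")[cmp]   # r_i - r_j over comparable (i, j)
  (sum(diff > 0) + 0.5 * sum(diff == 0)) / n_cmp
}

# Kaplan-Meier estimate of the censoring distribution G(t) (events flipped),
# evaluated as a right-continuous step function; used for IPCW weights.
censoring_km <- function(times, events) {
  o <- order(times)
  t_s <- times[o]; c_s <- 1L - events[o]
  ut <- unique(t_s)
  n <- length(t_s)
  at_risk <- n - c(0L, cumsum(tabulate(match(t_s, ut))))[seq_along(ut)]
  d_c <- vapply(ut, function(u) sum(c_s[t_s == u]), numeric(1))
  surv <- cumprod(1 - d_c / at_risk)
  function(t, left = FALSE) {
    # G(t) (right-continuous) or G(t-) when left = TRUE
    vapply(t, function(x) {
      idx <- if (left) which(ut < x) else which(ut <= x)
      if (length(idx) == 0L) 1 else surv[max(idx)]
    }, numeric(1))
  }
}

#' Time-dependent cumulative/dynamic AUC
#'
#' At each evaluation time `t`, discriminates cases (event observed by `t`)
#' from controls (event-free beyond `t`) by pairwise comparison of risk
#' scores, optionally weighted by the inverse probability of censoring
#' computed from a Kaplan-Meier estimate of the censoring distribution
#' (IPCW; weights are all 1 in the absence of censoring). The evaluation grid
#' is `n_times` evenly spaced points between the 20th and 81st percentiles of
#' the observed follow-up times, and the summary is the unweighted mean of
#' the per-time AUCs. Grid times with no cases or no controls are dropped
#' with a warning.
#'
#' @inheritParams harrell_cindex
#' @param n_times Number of grid points (default 4).
#' @param ipcw Apply inverse-probability-of-censoring weights (default TRUE).
#' @return List with `mean_auc` and `grid` (tibble: `time`, `auc`, `n_cases`,
#'   `n_controls`). `mean_auc` is `NA` (flagged) if every grid point degenerates.
#' @export
time_dependent_auc <- function(risks, times, events, n_times = 4L, ipcw = TRUE) {
  qs <- quantile(times, c(0.20, 0.81), names = FALSE)
  grid <- seq(qs[1], qs[2], length.out = n_times)
  G <- if (ipcw) censoring_km(times, events) else function(t, left = FALSE) rep(1, length(t))
  rows <- lapply(grid, function(tt) {
    cases <- which(times <= tt & events == 1)
    controls <- which(times > tt)
    if (length(cases) == 0L || length(controls) == 0L) {
      return(tibble::tibble(time = tt, auc = NA_real_,
                            n_cases = length(cases), n_controls = length(controls)))
    }
    w_case <- 1 / G(times[cases], left = TRUE)
    w_ctrl <- rep(1 / G(tt), length(controls))
    cmp <- outer(risks[cases], risks[controls], "-")
    wmat <- outer(w_case, w_ctrl)
    auc <- sum(wmat * ((cmp > 0) + 0.5 * (cmp == 0))) / sum(wmat)
    tibble::tibble(time = tt, auc = auc,
                   n_cases = length(cases), n_controls = length(controls))
  })
  grid_df <- dplyr::bind_rows(rows)
  if (any(is.na(grid_df$auc))) {
    warn_pcm(sprintf("%d of %d AUC grid time(s) had no cases or no controls and were dropped",
                     sum(is.na(grid_df$auc)), n_times), "auc_grid_dropped")
  }
  ok <- !is.na(grid_df$auc)
  mean_auc <- if (any(ok)) mean(grid_df$auc[ok]) else structure(NA_real_, undefined = TRUE)
  list(mean_auc = mean_auc, grid = grid_df)
}

#' Kaplan-Meier survival curve with Greenwood confidence band
#'
#' Product-limit estimator with Greenwood's variance formula; the 95%
#' confidence interval is computed on the log(-log) scale (so bounds respect
#' `[0, 1]`) and clipped. With no events the curve is identically 1.
#'
#' @param times Follow-up times.
#' @param events Binary event indicators.
#' @param conf_level Confidence level (default 0.95).
#' @return A `pcm_km` tibble: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, `lower`, `upper` (one row per distinct observed time).
#' @export
km_curve <- function(times, events, conf_level = 0.95) {
  stopifnot(length(times) == length(events), length(times) >= 1L)
  ut <- sort(unique(times))
  n <- length(times)
  d <- vapply(ut, function(u) sum(times == u & events == 1), numeric(1))
  c_ <- vapply(ut, function(u) sum(times == u & events == 0), numeric(1))
  at_risk <- n - c(0, cumsum(d + c_))[seq_along(ut)]
  surv <- cumprod(1 - d / at_risk)
  # Greenwood: Var(S) = S^2 * sum d / (n (n - d)); CI on log(-log S)
  gw <- cumsum(ifelse(at_risk - d > 0, d / (at_risk * (at_risk - d)), 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lower <- upper <- rep(NA_real_, length(ut))
  pos <- surv > 0 & surv < 1
  se_loglog <- sqrt(gw[pos]) / abs(log(surv[pos]))
  lower[pos] <- pmin(1, pmax(0, surv[pos]^exp(z * se_loglog)))
  upper[pos] <- pmin(1, pmax(0, surv[pos]^exp(-z * se_loglog)))
  lower[surv == 1] <- 1; upper[surv == 1] <- 1
  lower[surv == 0] <- 0; upper[surv == 0] <- 0
  out <- tibble::tibble(time = ut, n_risk = at_risk, n_event = d,
                        n_censor = c_, surv = surv,
                        lower = lower, upper = upper)
  structure(out, class = c("pcm_km", class(out)), conf_level = conf_level)
}

#' Two-group log-rank test
#'
#' Standard two-sided log-rank test: at each distinct event time, observed
#' events in group A are compared with their hypergeometric expectation given
#' the at-risk counts; the chi-square statistic (1 df) sums the standardized
#' differences.
#'
#' @param groups Two-level grouping vector (factor, character or logical).
#' @param times Follow-up times.
#' @param events Binary event indicators.
#' @return List with `chisq`, `p`, `df`, `observed`, `expected`. `p` is a
#'   flagged `NA` when a group has no at-risk mass.
#' @export
logrank_test <- function(groups, times, events) {
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop_pcm("log-rank test needs exactly two groups",
                                 "validation_error")
  if (min(table(g)) == 0L) {
    return(list(chisq = NA_real_, p = structure(NA_real_, undefined = TRUE),
                df = 1L))
  }
  in_a <- g == levels(g)[1L]
  ut <- sort(unique(times[events == 1]))
  O_a <- E_a <- V <- 0
  for (u in ut) {
    at <- times >= u
    n_tot <- sum(at); n_a <- sum(at & in_a)
    d_tot <- sum(times == u & events == 1)
    d_a <- sum(times == u & events == 1 & in_a)
    if (n_tot < 2L) next
    O_a <- O_a + d_a
    E_a <- E_a + d_tot * n_a / n_tot
    V <- V + d_tot * (n_a / n_tot) * (1 - n_a / n_tot) * (n_tot - d_tot) / (n_tot - 1)
  }
  obs_exp <- c(O_a, E_a)
  if (V <= 0) {
    return(list(chisq = 0, p = 1, df = 1L, observed = O_a, expected = E_a))
  }
  chisq <- (O_a - E_a)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
       df = 1L, observed = O_a, expected = E_a)
}

#' Median risk split
#'
#' Dichotomizes patients at the median predicted risk: high risk means risk
#' at or above the middle order statistic (`sort(risks)[floor(n/2) + 1]`), so
#' `(1,2,3,4)` splits into low `{1,2}` / high `{3,4}` and `(1,2,3)` into low
#' `{1}` / high `{2,3}`. With all risks identical the split is degenerate and
#' flagged.
#'
#' @param risks Numeric risk scores.
#' @return Factor with levels `low`, `high`; attribute `degenerate = TRUE`
#'   when all risks are tied.
#' @export
median_risk_split <- function(risks) {
  if (length(risks) < 2L) stop_pcm("need at least two patients to split",
                                   "validation_error")
  thr <- sort(risks)[floor(length(risks) / 2) + 1L]
  out <- factor(ifelse(risks >= thr, "high", "low"), levels = c("low", "high"))
  if (length(unique(risks)) == 1L) {
    warn_pcm("all risks identical: degenerate median split", "degenerate_split")
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Paired bootstrap confidence intervals and z-test for two models
#'
#' Resamples patients with replacement (`n_boot` replicates, default 1000),
#' using the *same* resample indices for both models so the comparison is
#' paired. Each replicate yields a C-index per model; per-model 95% CIs are
#' the 2.5/97.5 percentiles, and the two-sided z-test statistic is
#' `mean(deltaC) / sd(deltaC)` over replicates with a normal reference.
#' Replicates with no comparable pairs are redrawn (logged). Identical models
#' give `deltaC = 0` and `p = 1` by convention.
#'
#' @param risks_a,risks_b Risk vectors of the two models, aligned to the same
#'   patients.
#' @param times Follow-up times.
#' @param events Binary event indicators.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return List with `ci_a`, `ci_b` (length-2 vectors), `c_a`, `c_b` (point
#'   estimates), `z`, `p`, `n_boot`, `n_redrawn`.
#' @export
bootstrap_ci_and_ztest <- function(risks_a, risks_b, times, events,
                                   n_boot = 1000L, seed = 0L) {
  stopifnot(length(risks_a) == length(risks_b),
            length(risks_a) == length(times))
  n <- length(times)
  res <- withr::with_seed(seed, {
    ca <- cb <- numeric(n_boot)
    redrawn <- 0L
    for (r in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        va <- harrell_cindex(risks_a[idx], times[idx], events[idx])
        vb <- harrell_cindex(risks_b[idx], times[idx], events[idx])
        if (!is.na(va) && !is.na(vb)) break
        redrawn <- redrawn + 1L
      }
      ca[r] <- va; cb[r] <- vb
    }
    list(ca = ca, cb = cb, redrawn = redrawn)
  })
  delta <- res$ca - res$cb
  sd_d <- sd(delta)
  if (is.na(sd_d) || sd_d == 0) {
    z <- 0; p <- 1
  } else {
    z <- mean(delta) / sd_d
    p <- 2 * pnorm(-abs(z))
  }
  if (res$redrawn > 0L) {
    warn_pcm(sprintf("%d bootstrap replicate(s) had no comparable pairs and were redrawn",
                     res$redrawn), "bootstrap_redraw")
  }
  list(ci_a = quantile(res$ca, c(0.025, 0.975), names = FALSE),
       ci_b = quantile(res$cb, c(0.025, 0.975), names = FALSE),
       c_a = harrell_cindex(risks_a, times, events),
       c_b = harrell_cindex(risks_b, times, events),
       z = z, p = p, n_boot = n_boot, n_redrawn = res$redrawn)
}

#' Mann-Whitney U comparison of per-fold scores
#'
#' Compares two models' per-fold performance (e.g. the five C-index values
#' from 5-fold cross-validation) with a two-sided Mann-Whitney U test. For
#' small samples the p-value is exact, computed by enumerating every group
#' assignment of the pooled midranked scores (this handles ties correctly:
#' identical score lists give `p = 1`, complete 5-vs-5 separation gives
#' `p = 2/252`); for large samples a tie-corrected normal approximation is
#' used.
#'
#' @param scores_a,scores_b Numeric vectors of per-fold scores.
#' @param max_enum Largest number of assignments enumerated exactly
#'   (default 50000).
#' @return List with `U` (number of `(a, b)` pairs with `a > b`, ties 0.5),
#'   two-sided `p`, and `exact` (logical).
#' @export
mannwhitney_compare <- function(scores_a, scores_b, max_enum = 50000L) {
  na <- length(scores_a); nb <- length(scores_b)
  if (na == 0L || nb == 0L) {
    stop_pcm("score vectors must be nonempty", "validation_error")
  }
  pooled <- c(scores_a, scores_b)
  r <- rank(pooled)   # midranks for ties
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  EU <- na * nb / 2
  n_assign <- choose(na + nb, na)
  if (n_assign <= max_enum) {
    idx <- utils::combn(na + nb, na)
    Us <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Us - EU) >= abs(U_obs - EU) - 1e-12)
    exact <- TRUE
  } else {
    # tie-corrected normal approximation on the midrank statistic
    nn <- na + nb
    ties <- table(pooled)
    sigma2 <- na * nb / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    p <- if (sigma2 <= 0) 1 else 2 * pnorm(-abs(U_obs - EU) / sqrt(sigma2))
    exact <- FALSE
  }
  list(U = U_obs, p = min(1, p), exact = exact)
}

#' Aggregate out-of-fold predictions into an evaluation report
#'
#' Pools the out-of-fold predictions from cross-validation (every patient
#' predicted exactly once) and computes the full evaluation protocol overall
#' and per cancer type: C-index, mean time-dependent AUC, median-risk-split
#' Kaplan-Meier curves with Greenwood bands, and the two-sided log-rank test
#' between the risk groups.
#'
#' @param predictions Tibble with columns `patient_id`, `risk`, `time`,
#'   `event`, and optionally `cancer_type`, `fold` (e.g. `pcm_fit$oof`).
#' @param expected_ids Optional character vector of patient ids that must be
#'   predicted exactly once (integrity check).
#' @param n_times AUC grid size (default 4).
#' @param by_cancer Compute per-cancer-type breakdowns (default TRUE).
#' @param km_split `"within"` (default: per-subset median when stratifying) or
#'   `"overall"` (reuse the whole-cohort median threshold).
#' @return A `pcm_eval_report`.
#' @export
aggregate_cv <- function(predictions, expected_ids = NULL, n_times = 4L,
                         by_cancer = TRUE, km_split = c("within", "overall")) {
  km_split <- match.arg(km_split)
  df <- tibble::as_tibble(predictions)
  for (col in c("patient_id", "risk", "time", "event")) {
    if (!col %in% names(df)) {
      stop_pcm(sprintf("predictions are missing column '%s'", col), "schema_error")
    }
  }
  if (anyDuplicated(df$patient_id) > 0L) {
    stop_pcm("duplicate out-of-fold predictions for some patients",
             "integrity_error")
  }
  if (!is.null(expected_ids)) {
    missing <- setdiff(expected_ids, df$patient_id)
    if (length(missing) > 0L) {
      stop_pcm(sprintf("missing out-of-fold predictions for %d patient(s)",
                       length(missing)), "integrity_error")
    }
  }
  eval_subset <- function(d, thr_risks = NULL) {
    grp <- if (is.null(thr_risks)) median_risk_split(d$risk) else {
      thr <- sort(thr_risks)[floor(length(thr_risks) / 2) + 1L]
      factor(ifelse(d$risk >= thr, "high", "low"), levels = c("low", "high"))
    }
    td <- time_dependent_auc(d$risk, d$time, d$event, n_times = n_times)
    lr <- if (nlevels(droplevels(grp)) == 2L) {
      logrank_test(grp, d$time, d$event)
    } else list(chisq = NA_real_, p = NA_real_, df = 1L)
    list(
      c_index = harrell_cindex(d$risk, d$time, d$event),
      td_auc = td$mean_auc, auc_grid = td$grid,
      km_low = km_curve(d$time[grp == "low"], d$event[grp == "low"]),
      km_high = km_curve(d$time[grp == "high"], d$event[grp == "high"]),
      logrank = lr, groups = grp,
      n = nrow(d), n_events = sum(d$event)
    )
  }
  overall <- suppressWarnings(eval_subset(df))
  per_cancer <- NULL
  if (by_cancer && "cancer_type" %in% names(df)) {
    per_cancer <- df |>
      dplyr::group_by(.data$cancer_type) |>
      dplyr::group_modify(function(d, key) {
        ev <- suppressWarnings(eval_subset(
          d, thr_risks = if (km_split == "overall") df$risk else NULL))
        tibble::tibble(n = ev$n, n_events = ev$n_events,
                       c_index = as.numeric(ev$c_index),
                       td_auc = as.numeric(ev$td_auc),
                       logrank_p = as.numeric(ev$logrank$p))
      }) |>
      dplyr::ungroup()
  }
  structure(list(overall = overall, per_cancer = per_cancer, predictions = df),
            class = "pcm_eval_report")
}

#' @export
print.pcm_eval_report <- function(x, ...) {
  ov <- x$overall
  cat(sprintf("<pcm_eval_report> n = %d (%d events)\n", ov$n, ov$n_events))
  cat(sprintf("  C-index  %.3f\n  td-AUC   %.3f\n  log-rank chi2 %.2f (p = %.3g)\n",
              ov$c_index, as.numeric(ov$td_auc), ov$logrank$chisq, ov$logrank$p))
  if (!is.null(x$per_cancer)) {
    cat(sprintf("  per-cancer breakdown over %d type(s)\n", nrow(x$per_cancer)))
  }
  invisible(x)
}

#' Tidy per-cancer evaluation metrics
#'
#' @param x A `pcm_eval_report`.
#' @param ... Unused.
#' @return Tibble of per-cancer rows plus an `overall` row.
#' @export
tidy.pcm_eval_report <- function(x, ...) {
  ov <- tibble::tibble(cancer_type = "overall", n = x$overall$n,
                       n_events = x$overall$n_events,
                       c_index = as.numeric(x$overall$c_index),
                       td_auc = as.numeric(x$overall$td_auc),
                       logrank_p = as.numeric(x$overall$logrank$p))
  if (is.null(x$per_cancer)) ov else dplyr::bind_rows(x$per_cancer, ov)
}

#' One-row summary of an evaluation report
#'
#' @param x A `pcm_eval_report`.
#' @param ... Unused.
#' @return Tibble with the overall metrics.
#' @export
glance.pcm_eval_report <- function(x, ...) {
  tibble::tibble(n = x$overall$n, n_events = x$overall$n_events,
                 c_index = as.numeric(x$overall$c_index),
                 td_auc = as.numeric(x$overall$td_auc),
                 logrank_chisq = x$overall$logrank$chisq,
                 logrank_p = as.numeric(x$overall$logrank$p))
}

km_plot_df <- function(km, label) {
  # step-function representation including the (0, 1) anchor
  tibble::tibble(time = c(0, km$time), surv = c(1, km$surv),
                 lower = c(1, km$lower), upper = c(1, km$upper),
                 group = label)
}

#' Kaplan-Meier plot of the median-split risk groups
#'
#' @param object A `pcm_eval_report`.
#' @param ... Unused.
#' @return A ggplot with step curves and 95% confidence bands.
#' @export
autoplot.pcm_eval_report <- function(object, ...) {
  df <- dplyr::bind_rows(km_plot_df(object$overall$km_low, "low risk"),
                         km_plot_df(object$overall$km_high, "high risk"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group, fill = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA, stat = "identity") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "survival probability",
                  subtitle = sprintf("log-rank p = %.3g", object$overall$logrank$p)) +
    ggplot2::theme_minimal()
}
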
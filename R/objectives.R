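#' Batch of survival-labelled risks
#'
#' Validated container for a batch of patient log-risks with their follow-up
#' times and event indicators, the arguments of the joint survival objective.
#'
#' @param risks Numeric vector of log-risks.
#' @param times Positive follow-up times (months).
#' @param events Binary event indicators.
#' @return A `pcm_batch` list.
#' @export
batch_survival <- function(risks, times, events) {
  if (!(length(risks) == length(times) && length(times) == length(events))) {
    stop_pcm("risks, times and events must have equal length", "validation_error")
  }
  if (length(risks) < 1L) stop_pcm("batch must be nonempty", "validation_error")
  check_finite(risks, "risks")
  if (!all(is.finite(times)) || any(times <= 0)) {
    stop_pcm("times must be positive and finite", "validation_error")
  }
  if (!all(events %in% c(0, 1))) {
    stop_pcm("events must be 0/1", "validation_error")
  }
  structure(list(risks = as.numeric(risks), times = as.numeric(times),
                 events = as.integer(events)), class = "pcm_batch")
}

as_batch <- function(batch) {
  if (inherits(batch, "pcm_batch")) return(batch)
  batch_survival(batch$risks, batch$times, batch$events)
}

# Shared machinery for the Breslow partial likelihood: per-subject risk-set
# log-sums and the event-indexed 1/S terms, computed with a max shift for
# numerical stability. Ties in event times share one risk set (Breslow).
cox_parts <- function(risks, times, events) {
  m <- max(risks)
  er <- exp(risks - m)
  ut <- sort(unique(times))
  # suffix sums of exp(risk) over t >= each unique time
  idx <- match(times, ut)
  sums <- numeric(length(ut))
  for (k in seq_along(ut)) sums[k] <- 0
  tab <- rowsum(er, idx)
  sums[as.integer(rownames(tab))] <- tab[, 1L]
  S <- rev(cumsum(rev(sums)))            # S[k] = sum_{t_j >= ut[k]} e^{r_j - m}
  list(m = m, er = er, ut = ut, idx = idx, S = S)
}

#' Cox negative log partial likelihood (Breslow ties)
#'
#' For each observed event i the contribution is
#' `-(r_i - log sum_{j: t_j >= t_i} exp(r_j))`; the loss is the mean over
#' events. Tied event times share one risk set (Breslow approximation). A
#' batch with no events has an undefined partial likelihood; it returns 0 with
#' the attribute `no_events = TRUE` so callers can skip vacuous steps.
#'
#' @param batch A [batch_survival()] (or list with `risks`, `times`, `events`).
#' @return Scalar loss with attribute `no_events`.
#' @export
cox_nll <- function(batch) {
  b <- as_batch(batch)
  ev <- which(b$events == 1L)
  if (length(ev) == 0L) {
    return(structure(0, no_events = TRUE))
  }
  cp <- cox_parts(b$risks, b$times, b$events)
  lse <- cp$m + log(cp$S)                 # log-sum-exp per unique time
  contrib <- b$risks[ev] - lse[cp$idx[ev]]
  structure(-mean(contrib), no_events = FALSE)
}

#' Analytic gradient of the Cox loss with respect to the risks
#'
#' `dL/dr_k = -(1/n_ev) * (e_k - exp(r_k) * sum over event times t_i <= t_k
#' of d_i / S_i)` with `S_i` the risk-set sum of `exp(r)`.
#'
#' @inheritParams cox_nll
#' @return Numeric gradient vector of length B.
#' @export
cox_nll_grad <- function(batch) {
  b <- as_batch(batch)
  nev <- sum(b$events)
  if (nev == 0L) return(numeric(length(b$risks)))
  cp <- cox_parts(b$risks, b$times, b$events)
  d_events <- rowsum(as.numeric(b$events), cp$idx)
  dcount <- numeric(length(cp$ut))
  dcount[as.integer(rownames(d_events))] <- d_events[, 1L]
  inv_terms <- cumsum(dcount / cp$S)      # sum over event times <= ut[k] of d_t/S_t
  grad <- -(b$events - cp$er * inv_terms[cp$idx]) / nev
  grad
}

comparable_pairs <- function(times, events) {
  # matrix [i, j] TRUE iff event_i = 1 and t_i < t_j
  outer(as.logical(events), rep(TRUE, length(times)), "&") &
    outer(times, times, "<")
}

#' Pairwise ranking loss over comparable pairs
#'
#' Preserves relative survival ordering: over comparable pairs
#' `P = {(i,j): event_i = 1, t_i < t_j}` the logistic surrogate
#' `log(1 + exp(-(r_i - r_j)))` is averaged; patients who die earlier should
#' carry higher risk. With no comparable pairs (e.g. an all-censored batch)
#' the loss is 0 with attribute `no_pairs = TRUE`. A hinge surrogate
#' `max(0, 1 - (r_i - r_j))` is available via `form`.
#'
#' @param batch A [batch_survival()].
#' @param form `"logistic"` (default) or `"hinge"`.
#' @return Scalar loss with attribute `no_pairs`.
#' @export
rank_loss <- function(batch, form = c("logistic", "hinge")) {
  form <- match.arg(form)
  b <- as_batch(batch)
  P <- comparable_pairs(b$times, b$events)
  if (!any(P)) return(structure(0, no_pairs = TRUE))
  margin <- outer(b$risks, b$risks, "-")[P]   # r_i - r_j over pairs
  loss <- if (form == "logistic") {
    # stable softplus(-margin) = log(1 + exp(-margin))
    mean(log1p(exp(-abs(margin))) + pmax(-margin, 0))
  } else {
    mean(pmax(0, 1 - margin))
  }
  structure(loss, no_pairs = FALSE)
}

#' Analytic gradient of the ranking loss with respect to the risks
#'
#' @inheritParams rank_loss
#' @return Numeric gradient vector of length B.
#' @export
rank_loss_grad <- function(batch, form = c("logistic", "hinge")) {
  form <- match.arg(form)
  b <- as_batch(batch)
  n <- length(b$risks)
  P <- comparable_pairs(b$times, b$events)
  grad <- numeric(n)
  np <- sum(P)
  if (np == 0L) return(grad)
  margin <- outer(b$risks, b$risks, "-")
  dM <- matrix(0, n, n)
  if (form == "logistic") {
    dM[P] <- -(1 - sigmoid(margin[P])) / np   # d/dm log(1+e^{-m})
  } else {
    dM[P] <- -as.numeric(margin[P] < 1) / np
  }
  rowSums(dM) - colSums(dM)
}

#' Joint survival objective
#'
#' The training loss `L = L_cox + L_rank`: the Cox partial likelihood models
#' absolute risk while the ranking term preserves relative survival ordering;
#' the two are summed unweighted. Both components are normalized (mean over
#' events, mean over comparable pairs) so their scales are comparable across
#' batch sizes. Degeneracy flags from both components are propagated.
#'
#' @inheritParams rank_loss
#' @return Scalar loss with attributes `cox`, `rank`, `no_events`, `no_pairs`.
#' @export
total_loss <- function(batch, form = c("logistic", "hinge")) {
  form <- match.arg(form)
  cx <- cox_nll(batch)
  rk <- rank_loss(batch, form = form)
  structure(as.numeric(cx) + as.numeric(rk),
            cox = as.numeric(cx), rank = as.numeric(rk),
            no_events = isTRUE(attr(cx, "no_events")),
            no_pairs = isTRUE(attr(rk, "no_pairs")))
}

#' @rdname total_loss
#' @export
total_loss_grad <- function(batch, form = c("logistic", "hinge")) {
  form <- match.arg(form)
  cox_nll_grad(batch) + rank_loss_grad(batch, form = form)
}
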
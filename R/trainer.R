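#' Training configuration
#'
#' Full-scale defaults follow the published setup: AdamW with learning rate
#' 1e-4, cosine-annealed schedule, 20 epochs, and an accumulated batch of 256
#' patients. Desk-scale runs (tests, the synthetic demonstrations) pass
#' smaller batches and a larger learning rate appropriate to their model size.
#'
#' @param lr Peak learning rate (default 1e-4).
#' @param epochs Training epochs (default 20).
#' @param batch_patients Patients per accumulated batch (default 256); Cox
#'   risk sets and ranking pairs always span the full accumulated batch.
#' @param weight_decay Decoupled weight decay (default 1e-2).
#' @param lr_min Learning-rate floor of the cosine schedule (default 0).
#' @param seed Integer seed controlling fold-model initialization and epoch
#'   shuffles.
#' @param schedule `"cosine"` (default) or `"constant"`.
#' @param rank_form Ranking surrogate passed to [rank_loss()].
#' @param gate_lr_scale Learning-rate multiplier for the router gate
#'   projection (default 0.1). Routing is kept on a slower clock than the
#'   experts it arbitrates between, the usual stabilization for
#'   mixture-of-experts gates: it prevents gate logits from drifting past the
#'   ln(K) own-cancer boost while the experts are still moving.
#' @return A `pcm_train_config` list.
#' @export
train_config <- function(lr = 1e-4, epochs = 20L, batch_patients = 256L,
                         weight_decay = 1e-2, lr_min = 0, seed = 0L,
                         schedule = c("cosine", "constant"),
                         rank_form = c("logistic", "hinge"),
                         gate_lr_scale = 0.1) {
  schedule <- match.arg(schedule)
  rank_form <- match.arg(rank_form)
  if (lr <= 0 || epochs < 1L || batch_patients < 1L || weight_decay < 0 ||
      lr_min < 0 || gate_lr_scale <= 0) {
    stop_pcm("training configuration values must be positive", "config_error")
  }
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_patients = as.integer(batch_patients),
                 weight_decay = weight_decay, lr_min = lr_min,
                 seed = as.integer(seed), schedule = schedule,
                 rank_form = rank_form, gate_lr_scale = gate_lr_scale),
            class = "pcm_train_config")
}

# Per-parameter learning-rate multipliers aligned with the flat vector:
# 1 everywhere, gate_lr_scale over the router gate block.
lr_scale_vec <- function(model, gate_lr_scale) {
  if (gate_lr_scale == 1) return(1)
  mask <- zero_grads(model$params)
  mask$gate$Wg[] <- 1
  mask$gate$bg[] <- 1
  1 + (gate_lr_scale - 1) * flatten_params(mask)
}

#' Cosine-annealed learning rate
#'
#' Closed form: `lr_min + (lr - lr_min) * (1 + cos(pi * (epoch-1)/(epochs-1))) / 2`,
#' so epoch 1 runs at `lr` and the final epoch at `lr_min`.
#'
#' @param epoch 1-based epoch index.
#' @param epochs Total epochs.
#' @param lr Peak learning rate.
#' @param lr_min Floor (default 0).
#' @return Scalar learning rate.
#' @export
cosine_lr <- function(epoch, epochs, lr, lr_min = 0) {
  if (epochs == 1L) return(lr)
  lr_min + 0.5 * (lr - lr_min) * (1 + cos(pi * (epoch - 1) / (epochs - 1)))
}

#' Stratified k-fold split plan
#'
#' Within each cancer type, patients are shuffled (seeded) and dealt
#' round-robin to folds, so per-type fold sizes differ by at most one and the
#' train/validation ratio is (k-1):1 up to rounding. Deterministic for a fixed
#' seed.
#'
#' @param cohort A `pcm_cohort`, or a data frame with columns `patient_id`
#'   and `cancer_type`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A `pcm_split` tibble with columns `patient_id`, `cancer_type`,
#'   `fold` (1..k).
#' @export
stratified_kfold <- function(cohort, k = 5L, seed = 0L) {
  if (k < 2L) stop_pcm("`k` must be at least 2", "config_error")
  df <- if (inherits(cohort, "pcm_cohort")) {
    tibble::tibble(
      patient_id = vapply(cohort$patients, `[[`, character(1), "patient_id"),
      cancer_type = vapply(cohort$patients, function(p) p$cancer$label, character(1))
    )
  } else {
    tibble::as_tibble(cohort[, c("patient_id", "cancer_type")])
  }
  small <- df |>
    dplyr::count(.data$cancer_type) |>
    dplyr::filter(.data$n < k)
  if (nrow(small) > 0L) {
    warn_pcm(sprintf("cancer type(s) with fewer than %d patients: %s (best-effort assignment)",
                     k, paste(small$cancer_type, collapse = ", ")),
             "small_stratum")
  }
  out <- withr::with_seed(seed, {
    df |>
      dplyr::group_by(.data$cancer_type) |>
      dplyr::slice_sample(prop = 1) |>
      dplyr::mutate(fold = ((dplyr::row_number() - 1L) %% k) + 1L) |>
      dplyr::ungroup()
  })
  out <- out[match(df$patient_id, out$patient_id), ]
  structure(out, class = c("pcm_split", class(out)), k = k, seed = seed)
}

#' Cancer-balanced batch composition
#'
#' Orders an epoch's training patients by a proportional interleave of cancer
#' types (each type's shuffled patients are spread evenly through the epoch)
#' and chunks the ordering into consecutive batches, so each full batch holds
#' every cancer type at its cohort proportion within one patient. The final
#' batch may be partial.
#'
#' @param patients Data frame with columns `patient_id`, `cancer_type`.
#' @param batch_patients Batch size; must be at least the number of cancer
#'   types.
#' @param seed Integer seed for the within-type shuffles.
#' @return List of character vectors of patient ids.
#' @export
make_balanced_batches <- function(patients, batch_patients, seed = 0L) {
  df <- tibble::as_tibble(patients[, c("patient_id", "cancer_type")])
  K <- dplyr::n_distinct(df$cancer_type)
  if (batch_patients < K) {
    stop_pcm(sprintf("batch_patients (%d) must be >= number of cancer types (%d)",
                     batch_patients, K), "config_error")
  }
  ordered <- withr::with_seed(seed, {
    df |>
      dplyr::group_by(.data$cancer_type) |>
      dplyr::slice_sample(prop = 1) |>
      dplyr::mutate(.key = (dplyr::row_number() - 0.5) / dplyr::n()) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$.key, .data$cancer_type)
  })
  ids <- ordered$patient_id
  split(ids, ceiling(seq_along(ids) / batch_patients))
}

# ---- optimizer ------------------------------------------------------------

adamw_init <- function(model) {
  n <- n_params(model)
  list(m = numeric(n), v = numeric(n), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adamw_update <- function(theta, grad, opt, lr, weight_decay, lr_scale = 1) {
  opt$t <- opt$t + 1L
  opt$m <- opt$beta1 * opt$m + (1 - opt$beta1) * grad
  opt$v <- opt$beta2 * opt$v + (1 - opt$beta2) * grad^2
  mhat <- opt$m / (1 - opt$beta1^opt$t)
  vhat <- opt$v / (1 - opt$beta2^opt$t)
  step <- lr * lr_scale
  theta <- theta - step * mhat / (sqrt(vhat) + opt$eps) -
    step * weight_decay * theta
  list(theta = theta, opt = opt)
}

# ---- batch loss / gradient with accumulation ------------------------------

#' Batch loss and parameter gradients with gradient accumulation
#'
#' Forwards every patient of the batch, computes the joint objective once
#' over the *whole* batch (Cox risk sets and ranking pairs span the full
#' accumulated batch, never a sub-chunk), then backpropagates each patient's
#' risk gradient and accumulates parameter gradients. Staging the per-patient
#' passes in chunks changes memory use only: the returned loss and gradients
#' are identical to a joint full-batch computation because the objective
#' couples patients solely through their scalar risks.
#'
#' @param model A `pcm_model`.
#' @param records List of prepared patient inputs (see [fit_survival_model()]),
#'   each with `features`, `clinical`, `cancer_index`, `time`, `event`.
#' @param rank_form Ranking surrogate.
#' @param chunk_size Number of patients whose forward caches are held at
#'   once (memory staging; default 32).
#' @return List with `loss` (with component attributes), `grad` (flat
#'   gradient vector), `risks`, and `skipped` (TRUE for an all-censored
#'   batch, whose Cox term is undefined).
#' @export
batch_gradient <- function(model, records, rank_form = "logistic",
                           chunk_size = 32L) {
  B <- length(records)
  if (B == 0L) stop_pcm("empty batch", "validation_error")
  times <- vapply(records, `[[`, numeric(1), "time")
  events <- vapply(records, function(r) as.numeric(r$event), numeric(1))

  # Pass 1: risks only (cheap, no caches) to form the full-batch objective.
  risks <- vapply(records, function(r) model_forward(r, model)$risk, numeric(1))
  batch <- batch_survival(risks, times, events)
  loss <- total_loss(batch, form = rank_form)
  if (attr(loss, "no_events")) {
    return(list(loss = loss, grad = NULL, risks = risks, skipped = TRUE))
  }
  drisk <- total_loss_grad(batch, form = rank_form)

  # Pass 2: per-patient backprop staged in chunks, gradients accumulated.
  grad <- numeric(n_params(model))
  for (start in seq(1L, B, by = chunk_size)) {
    idx <- start:min(B, start + chunk_size - 1L)
    for (i in idx) {
      fw <- model_forward(records[[i]], model, keep_cache = TRUE)
      grad <- grad + flatten_params(model_backward(fw$cache, model, drisk[i]))
    }
  }
  list(loss = loss, grad = grad, risks = risks, skipped = FALSE)
}

#' One accumulated optimization step
#'
#' Computes the full-batch gradient via [batch_gradient()] and applies one
#' AdamW update with decoupled weight decay. An all-censored batch is skipped
#' (the Cox term is undefined) with a warning rather than stepped with a
#' vacuous zero loss.
#'
#' @param model A `pcm_model`.
#' @param records Prepared patient inputs.
#' @param opt Optimizer state from `adamw_init()` (created if `NULL`).
#' @param lr Learning rate for this step.
#' @param weight_decay Decoupled weight decay.
#' @param rank_form Ranking surrogate.
#' @param lr_scale Optional per-parameter learning-rate multipliers (flat
#'   vector or scalar 1), see `train_config()$gate_lr_scale`.
#' @return List with updated `model`, `opt`, `loss`, `skipped`.
#' @export
accumulate_step <- function(model, records, opt = NULL, lr = 1e-4,
                            weight_decay = 1e-2, rank_form = "logistic",
                            lr_scale = 1) {
  if (is.null(opt)) opt <- adamw_init(model)
  bg <- batch_gradient(model, records, rank_form = rank_form)
  if (bg$skipped) {
    warn_pcm("all-censored batch: Cox loss undefined, step skipped",
             "all_censored_batch")
    return(list(model = model, opt = opt, loss = bg$loss, skipped = TRUE))
  }
  if (!is.finite(bg$loss)) {
    stop_pcm("non-finite training loss (divergence)", "divergence_error")
  }
  theta <- flatten_params(model$params)
  upd <- adamw_update(theta, bg$grad, opt, lr, weight_decay,
                      lr_scale = lr_scale)
  model$params <- unflatten_params(upd$theta, model$params)
  list(model = model, opt = upd$opt, loss = bg$loss, skipped = FALSE)
}

# Prepare lightweight per-patient inputs once: pooled bag, encoded clinical,
# cancer index/one-hot, label. `modality` implements the unimodal ablations:
# "histology" zeroes the clinical vector; "clinical" replaces the bag with
# seeded standard-normal noise of the same shape.
prepare_records <- function(cohort, modality = "fused", noise_seed = 0L) {
  lapply(seq_along(cohort$patients), function(i) {
    p <- cohort$patients[[i]]
    pooled <- pool_patient_bag(p)
    X <- pooled$features
    cvec <- p$clinical$values
    if (modality == "histology") cvec <- numeric(length(cvec))
    if (modality == "clinical") {
      X <- withr::with_seed(derive_seed(noise_seed, i),
                            matrix(rnorm(length(X)), nrow(X), ncol(X)))
    }
    list(patient_id = p$patient_id, features = X, clinical = cvec,
         cancer_index = p$cancer$index, onehot = p$cancer$onehot,
         cancer_type = p$cancer$label, provenance = pooled$provenance,
         time = p$survival$time, event = p$survival$event)
  })
}

#' Fit the survival model with stratified cross-validation
#'
#' Trains one model per fold on the fold's (k-1)/k training split with
#' cancer-balanced accumulated batches, AdamW and the cosine learning-rate
#' schedule, then predicts the held-out fold, so every patient receives
#' exactly one out-of-fold risk. Fully reproducible from the seeds in the
#' configs (fold-model initialization, epoch shuffles and ablation noise are
#' all derived from `train_config$seed`).
#'
#' @param cohort A `pcm_cohort` with loaded bags.
#' @param config A [model_config()]; `K` must match the cohort.
#' @param tconfig A [train_config()].
#' @param split Optional `pcm_split`; defaults to a stratified 5-fold plan
#'   seeded from `tconfig$seed`.
#' @param k Folds used when `split` is `NULL`.
#' @param modality `"fused"` (default), `"histology"` (clinical zeroed) or
#'   `"clinical"` (bags replaced by noise) for ablation runs.
#' @param verbose Print per-epoch losses.
#' @return A `pcm_fit` object: per-fold `models`, out-of-fold predictions
#'   `oof` (tibble: `patient_id`, `cancer_type`, `time`, `event`, `fold`,
#'   `risk`), training `logs`, the `split`, and both configs.
#' @export
fit_survival_model <- function(cohort, config, tconfig = train_config(),
                               split = NULL, k = 5L,
                               modality = c("fused", "histology", "clinical"),
                               verbose = FALSE) {
  modality <- match.arg(modality)
  stopifnot(inherits(cohort, "pcm_cohort"), inherits(config, "pcm_model_config"))
  if (config$K != cohort$K) {
    stop_pcm(sprintf("config K = %d but cohort has %d cancer types",
                     config$K, cohort$K), "config_error")
  }
  if (is.null(split)) split <- stratified_kfold(cohort, k = k, seed = tconfig$seed)
  k <- attr(split, "k")
  records <- prepare_records(cohort, modality = modality,
                             noise_seed = tconfig$seed)
  ids <- vapply(records, `[[`, character(1), "patient_id")
  types <- vapply(records, `[[`, character(1), "cancer_type")

  models <- vector("list", k)
  oof <- vector("list", k)
  logs <- list()
  for (f in seq_len(k)) {
    test_ids <- split$patient_id[split$fold == f]
    train_idx <- which(!(ids %in% test_ids))
    train_df <- tibble::tibble(patient_id = ids[train_idx],
                               cancer_type = types[train_idx])
    model <- init_model(config, seed = derive_seed(tconfig$seed, f),
                        cancer_levels = cohort$cancer_levels)
    opt <- adamw_init(model)
    scale_vec <- lr_scale_vec(model, tconfig$gate_lr_scale)
    for (epoch in seq_len(tconfig$epochs)) {
      lr <- if (tconfig$schedule == "cosine") {
        cosine_lr(epoch, tconfig$epochs, tconfig$lr, tconfig$lr_min)
      } else tconfig$lr
      batches <- make_balanced_batches(
        train_df, tconfig$batch_patients,
        seed = derive_seed(tconfig$seed, f * 10000L + epoch))
      for (bi in seq_along(batches)) {
        recs <- records[match(batches[[bi]], ids)]
        st <- accumulate_step(model, recs, opt, lr = lr,
                              weight_decay = tconfig$weight_decay,
                              rank_form = tconfig$rank_form,
                              lr_scale = scale_vec)
        model <- st$model; opt <- st$opt
        logs[[length(logs) + 1L]] <- tibble::tibble(
          fold = f, epoch = epoch, batch = bi, lr = lr,
          loss = as.numeric(st$loss),
          cox = attr(st$loss, "cox") %||% NA_real_,
          rank = attr(st$loss, "rank") %||% NA_real_,
          skipped = isTRUE(st$skipped))
      }
      if (verbose) {
        ep_loss <- mean(vapply(utils::tail(logs, length(batches)),
                               function(l) l$loss, numeric(1)))
        message(sprintf("fold %d epoch %2d lr %.2e loss %.4f", f, epoch, lr, ep_loss))
      }
    }
    models[[f]] <- model
    test_idx <- which(ids %in% test_ids)
    preds <- vapply(records[test_idx],
                    function(r) model_forward(r, model)$risk, numeric(1))
    oof[[f]] <- tibble::tibble(
      patient_id = ids[test_idx], cancer_type = types[test_idx],
      time = vapply(records[test_idx], `[[`, numeric(1), "time"),
      event = vapply(records[test_idx], function(r) as.integer(r$event), integer(1)),
      fold = f, risk = preds)
  }
  structure(list(models = models,
                 oof = dplyr::bind_rows(oof),
                 logs = dplyr::bind_rows(logs),
                 split = split, config = config, tconfig = tconfig,
                 modality = modality),
            class = "pcm_fit")
}

#' @export
print.pcm_fit <- function(x, ...) {
  cat(sprintf("<pcm_fit> %d folds, %d patients, modality = %s\n",
              length(x$models), nrow(x$oof), x$modality))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy out-of-fold predictions of a fitted model
#'
#' @param x A `pcm_fit`.
#' @param ... Unused.
#' @return The out-of-fold prediction tibble.
#' @export
tidy.pcm_fit <- function(x, ...) x$oof

#' One-row summary of a cross-validated fit
#'
#' @param x A `pcm_fit`.
#' @param ... Unused.
#' @return Tibble with patient/event counts, final training loss and the
#'   pooled out-of-fold C-index.
#' @export
glance.pcm_fit <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x$oof),
    n_events = sum(x$oof$event),
    k_folds = length(x$models),
    epochs = x$tconfig$epochs,
    final_loss = x$logs$loss[nrow(x$logs)],
    oof_cindex = harrell_cindex(x$oof$risk, x$oof$time, x$oof$event)
  )
}

#' Plot training loss curves
#'
#' @param object A `pcm_fit`.
#' @param ... Unused.
#' @return A ggplot of per-batch loss by fold.
#' @export
autoplot.pcm_fit <- function(object, ...) {
  df <- object$logs |>
    dplyr::group_by(.data$fold, .data$epoch) |>
    dplyr::summarise(loss = mean(.data$loss), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = factor(.data$fold))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean batch loss", colour = "fold") +
    ggplot2::theme_minimal()
}
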
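# Shared fixtures: tiny configs, random records, finite-difference helpers
# and brute-force metric oracles. Everything is generated in code under
# explicit seeds; no binary fixtures.

tiny_model_config <- function(...) {
  args <- utils::modifyList(
    list(D = 8L, K = 2L, M = 8L, d_slide = 8L, attn_hidden = 6L, d = 8L,
         n_tokens = 2L, n_heads = 2L, n_experts = 2L, top_k = 2L,
         boost = log(2), expert_hidden = 5L, token_hidden = 6L),
    list(...))
  do.call(model_config, args)
}

random_record <- function(cfg, N = 5L, seed = 1L, cancer_index = 1L) {
  withr::with_seed(seed, {
    list(features = matrix(rnorm(N * cfg$D), N, cfg$D),
         clinical = encode_clinical(60, "female", "II")$values,
         cancer_index = cancer_index,
         time = rexp(1, 0.05) + 0.1, event = rbinom(1, 1, 0.7))
  })
}

random_batch_records <- function(cfg, B = 6L, seed = 1L) {
  recs <- lapply(seq_len(B), function(i) {
    r <- random_record(cfg, N = 3L + (i %% 3L), seed = seed * 100 + i,
                       cancer_index = 1L + (i %% cfg$K))
    r$patient_id <- sprintf("P%02d", i)
    r
  })
  # guarantee at least one event so the Cox term is defined
  recs[[1L]]$event <- 1L
  recs
}

# Central finite differences of f at theta over coordinates idx.
numeric_grad <- function(f, theta, idx = seq_along(theta), eps = 1e-5) {
  vapply(idx, function(i) {
    up <- theta; up[i] <- up[i] + eps
    dn <- theta; dn[i] <- dn[i] - eps
    (f(up) - f(dn)) / (2 * eps)
  }, numeric(1))
}

rel_err <- function(a, b, floor = 1e-8) {
  abs(a - b) / pmax(floor, abs(a) + abs(b))
}

# Exhaustive-pair C-index oracle (plain double loop).
cindex_brute <- function(risks, times, events) {
  num <- 0; den <- 0
  n <- length(risks)
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    for (j in seq_len(n)) {
      if (times[i] < times[j]) {
        den <- den + 1
        if (risks[i] > risks[j]) num <- num + 1
        else if (risks[i] == risks[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) NA_real_ else num / den
}

# Brute-force cumulative/dynamic AUC at time t (unweighted).
auc_brute_at <- function(risks, times, events, t) {
  cases <- which(times <= t & events == 1)
  controls <- which(times > t)
  if (length(cases) == 0 || length(controls) == 0) return(NA_real_)
  num <- 0
  for (i in cases) for (j in controls) {
    num <- num + (risks[i] > risks[j]) + 0.5 * (risks[i] == risks[j])
  }
  num / (length(cases) * length(controls))
}

# Brute-force pairwise ranking loss (plain double loop).
rank_loss_brute <- function(risks, times, events, form = "logistic") {
  tot <- 0; np <- 0
  n <- length(risks)
  for (i in seq_len(n)) {
    if (events[i] != 1) next
    for (j in seq_len(n)) {
      if (times[i] < times[j]) {
        m <- risks[i] - risks[j]
        tot <- tot + if (form == "logistic") log(1 + exp(-m)) else max(0, 1 - m)
        np <- np + 1
      }
    }
  }
  if (np == 0) 0 else tot / np
}

# Exhaustive Otsu oracle: argmax of between-class variance over all 256
# candidate thresholds of an 8-bit histogram.
otsu_brute <- function(counts) {
  total <- sum(counts)
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:254) {
    w0 <- sum(counts[1:(t + 1)]) / total
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum((0:t) * counts[1:(t + 1)]) / sum(counts[1:(t + 1)])
    mu1 <- sum(((t + 1):255) * counts[(t + 2):256]) / sum(counts[(t + 2):256])
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best + 1e-12) { best <- bcv; best_t <- t }
  }
  best_t
}

tiny_sim <- function(K = 2L, n_per_type = 12L, seed = 5L, ...) {
  args <- utils::modifyList(
    list(K = K, n_per_type = n_per_type, D = 8L, bag_size_range = c(3L, 6L)),
    list(...))
  simulate_cohort(do.call(sim_config, args), seed = seed)
}

write_manifest_file <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
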
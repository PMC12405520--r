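#' Model configuration
#'
#' Architecture hyperparameters for the pancancer survival network. Defaults
#' follow the full-scale architecture (patch dim 2560, slide embedding 768,
#' fusion latent 256); tests and desk-scale runs shrink them via arguments.
#'
#' The cross-attention between the slide embedding and the clinical embedding
#' operates on `n_tokens` sub-tokens per modality: each 1 x d embedding is
#' reshaped into `n_tokens` tokens of size `d / n_tokens`, which keeps the
#' attention softmax non-degenerate (with a single token per modality the
#' softmax is over one key and the weight is identically 1; `n_tokens = 1`
#' remains available to reproduce that literal single-vector reading).
#'
#' @param D Patch embedding dimension fed to the attention-MIL block.
#' @param K Number of cancer types.
#' @param M Clinical vector length (default 8, see [encode_clinical()]).
#' @param d_slide Slide summary embedding dimension (default 768).
#' @param attn_hidden Hidden width of the gated-attention scorer (default 256).
#' @param d Fusion latent dimension (default 256).
#' @param n_tokens Sub-tokens per modality in cross-attention (default 4).
#' @param n_heads Attention heads (default 4); `d / n_tokens` must be
#'   divisible by `n_heads`.
#' @param n_experts Size of the shared expert pool (default `K`, one expert
#'   per cancer cohort).
#' @param top_k Number of experts kept after gating (default `min(2, n_experts)`).
#' @param boost Additive logit boost for the patient's own cancer expert
#'   before the gate softmax (default `log(K)`, the "logarithmic boost"; this
#'   guarantees the own expert survives top-k selection at initialization).
#' @param expert_hidden Hidden width of each expert head (default 128).
#' @param token_hidden Hidden width of the cancer-token network (default `d`).
#' @param gate_from `"token"` (default: gate logits are a linear projection of
#'   the cancer control token alone) or `"token_fused"` (logits conditioned on
#'   the concatenation of token and fused feature).
#' @return A `pcm_model_config` list.
#' @export
model_config <- function(D, K, M = 8L, d_slide = 768L, attn_hidden = 256L,
                         d = 256L, n_tokens = 4L, n_heads = 4L,
                         n_experts = K, top_k = min(2L, n_experts),
                         boost = log(K), expert_hidden = 128L,
                         token_hidden = d,
                         gate_from = c("token", "token_fused")) {
  gate_from <- match.arg(gate_from)
  cfg <- list(
    D = as.integer(D), K = as.integer(K), M = as.integer(M),
    d_slide = as.integer(d_slide), attn_hidden = as.integer(attn_hidden),
    d = as.integer(d), n_tokens = as.integer(n_tokens),
    n_heads = as.integer(n_heads), n_experts = as.integer(n_experts),
    top_k = as.integer(top_k), boost = as.numeric(boost),
    expert_hidden = as.integer(expert_hidden),
    token_hidden = as.integer(token_hidden), gate_from = gate_from
  )
  if (cfg$d %% cfg$n_tokens != 0L) {
    stop_pcm("`d` must be divisible by `n_tokens`", "config_error")
  }
  if ((cfg$d %/% cfg$n_tokens) %% cfg$n_heads != 0L) {
    stop_pcm("token size d/n_tokens must be divisible by `n_heads`", "config_error")
  }
  if (cfg$top_k < 1L || cfg$top_k > cfg$n_experts) {
    stop_pcm("`top_k` must lie in [1, n_experts]", "config_error")
  }
  if (cfg$boost < 0) stop_pcm("`boost` must be nonnegative", "config_error")
  if (cfg$d < 2L) stop_pcm("`d` must be at least 2 (instance norm)", "config_error")
  structure(cfg, class = "pcm_model_config")
}

rand_mat <- function(nr, nc) {
  matrix(rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
}

#' Initialize model parameters
#'
#' Weights are drawn from Normal(0, 1/fan_in); biases start at zero. Fully
#' reproducible from `seed`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @param cancer_levels Optional character vector of cancer labels persisted
#'   with the model (the one-hot basis).
#' @return A `pcm_model` list with `config`, `params`, `cancer_levels`.
#' @export
init_model <- function(config, seed = 0L, cancer_levels = NULL) {
  stopifnot(inherits(config, "pcm_model_config"))
  dt <- config$d %/% config$n_tokens
  params <- withr::with_seed(seed, {
    attn_block <- function() list(
      Wq = rand_mat(dt, dt), bq = numeric(dt),
      Wk = rand_mat(dt, dt), bk = numeric(dt),
      Wv = rand_mat(dt, dt), bv = numeric(dt),
      Wo = rand_mat(dt, dt), bo = numeric(dt)
    )
    gate_in <- if (config$gate_from == "token") config$d else 2L * config$d
    list(
      amil = list(
        Wp = rand_mat(config$D, config$d_slide), bp = numeric(config$d_slide),
        Wv = rand_mat(config$d_slide, config$attn_hidden), bv = numeric(config$attn_hidden),
        Wu = rand_mat(config$d_slide, config$attn_hidden), bu = numeric(config$attn_hidden),
        wa = rand_mat(config$attn_hidden, 1L), ba = 0
      ),
      fus = list(
        h1 = rand_mat(config$d_slide, config$d), hb1 = numeric(config$d),
        h2 = rand_mat(config$d, config$d), hb2 = numeric(config$d),
        c1 = rand_mat(config$M, config$d), cb1 = numeric(config$d),
        c2 = rand_mat(config$d, config$d), cb2 = numeric(config$d),
        att_ch = attn_block(),
        att_hc = attn_block(),
        Wf = rand_mat(2L * config$d, config$d), bf = numeric(config$d)
      ),
      tok = list(
        W1 = rand_mat(config$K, config$token_hidden), b1 = numeric(config$token_hidden),
        W2 = rand_mat(config$token_hidden, config$d), b2 = numeric(config$d)
      ),
      # gate projection starts at zero so routing is uniform at initialization
      # and the own-cancer boost (ln K) strictly dominates top-k selection
      gate = list(Wg = matrix(0, gate_in, config$n_experts),
                  bg = numeric(config$n_experts)),
      experts = lapply(seq_len(config$n_experts), function(e) list(
        W1 = rand_mat(2L * config$d, config$expert_hidden),
        b1 = numeric(config$expert_hidden),
        W2 = rand_mat(config$expert_hidden, 1L), b2 = 0
      ))
    )
  })
  structure(list(config = config, params = params,
                 cancer_levels = cancer_levels, seed = as.integer(seed)),
            class = "pcm_model")
}

#' @export
print.pcm_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0(
    "<pcm_model> D=%d -> slide %d -> fusion d=%d (%d tokens x %d heads), ",
    "K=%d cancers, %d experts (top-%d, boost=%.3f)\n"),
    cfg$D, cfg$d_slide, cfg$d, cfg$n_tokens, cfg$n_heads,
    cfg$K, cfg$n_experts, cfg$top_k, cfg$boost))
  invisible(x)
}

# ---- forward passes -------------------------------------------------------

#' Gated attention-MIL aggregation
#'
#' Aggregates an N x D bag of patch embeddings into a single slide-level
#' summary. Patches are first projected to the slide dimension; gated
#' attention scores (a tanh branch modulated elementwise by a sigmoid branch)
#' are softmax-normalized into weights that sum to one, and the summary is the
#' attention-weighted sum of projected patches. The result is permutation
#' invariant: shuffling bag rows permutes the weights but not the summary.
#'
#' @param bag N x D matrix of pooled patch embeddings.
#' @param params AMIL parameter block (from a `pcm_model`).
#' @param keep_cache Retain intermediates for backpropagation.
#' @return List with `H1` (1 x d_slide summary), `attn` (length-N weights),
#'   and optionally `cache`.
#' @export
amil_aggregate <- function(bag, params, keep_cache = FALSE) {
  bag <- as.matrix(bag)
  if (nrow(bag) < 1L) stop_pcm("empty bag", "validation_error")
  check_finite(bag, "bag")
  U <- bag %*% params$Wp
  U <- sweep(U, 2L, params$bp, "+")
  Av <- sweep(U %*% params$Wv, 2L, params$bv, "+")
  Au <- sweep(U %*% params$Wu, 2L, params$bu, "+")
  Vt <- tanh(Av)
  Gs <- sigmoid(Au)
  Z <- Vt * Gs
  s <- as.vector(Z %*% params$wa) + params$ba
  attn <- softmax_vec(s)
  H1 <- matrix(attn, 1L) %*% U
  out <- list(H1 = H1, attn = attn)
  if (keep_cache) {
    out$cache <- list(X = bag, U = U, Av = Av, Au = Au, Vt = Vt, Gs = Gs,
                      Z = Z, attn = attn)
  }
  out
}

mlp2_forward <- function(x, W1, b1, W2, b2) {
  A1 <- x %*% W1
  A1 <- sweep(A1, 2L, b1, "+")
  Z1 <- silu(A1)
  out <- sweep(Z1 %*% W2, 2L, b2, "+")
  list(out = out, A1 = A1, Z1 = Z1)
}

# Multi-head scaled dot-product cross-attention: queries from Tq over
# keys/values from Tkv. Token matrices are n_tokens x d_t; heads split d_t.
cross_attention_forward <- function(Tq, Tkv, pa, n_heads) {
  dt <- ncol(Tq)
  dh <- dt %/% n_heads
  Q <- sweep(Tq %*% pa$Wq, 2L, pa$bq, "+")
  K <- sweep(Tkv %*% pa$Wk, 2L, pa$bk, "+")
  V <- sweep(Tkv %*% pa$Wv, 2L, pa$bv, "+")
  O <- matrix(0, nrow(Tq), dt)
  P_list <- vector("list", n_heads)
  for (g in seq_len(n_heads)) {
    idx <- ((g - 1L) * dh + 1L):(g * dh)
    S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) / sqrt(dh)
    P <- softmax_rows(S)
    O[, idx] <- P %*% V[, idx, drop = FALSE]
    P_list[[g]] <- P
  }
  out <- sweep(O %*% pa$Wo, 2L, pa$bo, "+")
  list(out = out, Q = Q, K = K, V = V, O = O, P = P_list, dh = dh)
}

# 1 x d row vector <-> n_tokens x d_t token matrix (row-major reshape).
to_tokens <- function(e, n_tokens) {
  matrix(as.vector(e), n_tokens, length(e) %/% n_tokens, byrow = TRUE)
}
from_tokens <- function(Tm) matrix(as.vector(t(Tm)), 1L)

#' Cross-attention fusion of slide and clinical embeddings
#'
#' Projects the slide summary `H1` and the clinical vector `C` into a shared
#' latent space via two symmetric two-layer MLPs (SiLU), reshapes each
#' embedding into sub-tokens, and runs multi-head cross-attention in both
#' directions: clinical queries attending over histology tokens yield the
#' clinically contextualized image feature, and vice versa. The two attended
#' features are concatenated and linearly mapped back to the latent dimension.
#'
#' @param H1 1 x d_slide slide summary (from [amil_aggregate()]).
#' @param C Clinical vector of length M.
#' @param params Fusion parameter block.
#' @param config A [model_config()].
#' @param keep_cache Retain intermediates for backpropagation.
#' @return List with `E_h`, `E_c` (1 x d projections), `A_c_to_h`, `A_h_to_c`
#'   (1 x d attended features), `fused` (1 x d), optionally `cache`.
#' @export
fuse_modalities <- function(H1, C, params, config, keep_cache = FALSE) {
  H1 <- matrix(as.numeric(H1), 1L)
  C <- matrix(as.numeric(C), 1L)
  if (ncol(C) != config$M) {
    stop_pcm(sprintf("clinical vector has length %d but config M = %d",
                     ncol(C), config$M), "dimension_error")
  }
  check_finite(H1, "H1"); check_finite(C, "C")
  hm <- mlp2_forward(H1, params$h1, params$hb1, params$h2, params$hb2)
  cm <- mlp2_forward(C, params$c1, params$cb1, params$c2, params$cb2)
  E_h <- hm$out; E_c <- cm$out
  Th <- to_tokens(E_h, config$n_tokens)
  Tc <- to_tokens(E_c, config$n_tokens)
  ach <- cross_attention_forward(Tc, Th, params$att_ch, config$n_heads)
  ahc <- cross_attention_forward(Th, Tc, params$att_hc, config$n_heads)
  A_c_to_h <- from_tokens(ach$out)
  A_h_to_c <- from_tokens(ahc$out)
  cat2 <- cbind(A_c_to_h, A_h_to_c)
  fused <- sweep(cat2 %*% params$Wf, 2L, params$bf, "+")
  out <- list(E_h = E_h, E_c = E_c, A_c_to_h = A_c_to_h, A_h_to_c = A_h_to_c,
              fused = fused)
  if (keep_cache) {
    out$cache <- list(H1 = H1, C = C, hm = hm, cm = cm, Th = Th, Tc = Tc,
                      ach = ach, ahc = ahc, cat2 = cat2)
  }
  out
}

instance_norm <- function(x, eps = 1e-8) {
  mu <- mean(x)
  v <- mean((x - mu)^2)
  s <- sqrt(v + eps)
  list(y = (x - mu) / s, mu = mu, s = s)
}

#' Cancer control token
#'
#' Transforms the one-hot cancer-type vector into a latent control token via a
#' two-layer network with SiLU activation followed by instance normalization,
#' so every token has zero mean and unit (population) variance across its `d`
#' features. The token modulates expert routing and is concatenated with the
#' fused feature.
#'
#' @param onehot Length-K one-hot vector.
#' @param params Token parameter block.
#' @param keep_cache Retain intermediates for backpropagation.
#' @return List with `token` (1 x d) and optionally `cache`.
#' @export
cancer_control_token <- function(onehot, params, keep_cache = FALSE) {
  onehot <- as.numeric(onehot)
  if (!(sum(onehot) == 1 && all(onehot %in% c(0, 1)))) {
    stop_pcm("`onehot` must be a one-hot vector", "validation_error")
  }
  m <- mlp2_forward(matrix(onehot, 1L), params$W1, params$b1, params$W2, params$b2)
  nrm <- instance_norm(as.vector(m$out))
  out <- list(token = matrix(nrm$y, 1L))
  if (keep_cache) out$cache <- list(onehot = onehot, m = m, nrm = nrm)
  out
}

#' Cancer-aware expert routing
#'
#' Concatenates the fused feature with the cancer control token channelwise to
#' form the dynamic feature, computes gate logits (by default a linear
#' projection of the token alone), adds the logarithmic boost to the logit of
#' the patient's own cancer expert, softmaxes, keeps the `top_k` largest gates
#' and renormalizes them to sum to one, and returns the gate-weighted sum of
#' the expert heads (two-layer SiLU MLPs over the dynamic feature) as the
#' scalar log-risk.
#'
#' @param fused 1 x d fused feature (from [fuse_modalities()]).
#' @param token 1 x d cancer control token.
#' @param cancer_index 1-based index of the patient's cancer type.
#' @param params Full parameter list (`gate`, `experts` blocks used).
#' @param config A [model_config()].
#' @param keep_cache Retain intermediates for backpropagation.
#' @return List with `gates` (length n_experts, support of size top_k, sums to
#'   1), `expert_risks` (length n_experts), `risk` (scalar), `token`, and
#'   optionally `cache`.
#' @export
route_experts <- function(fused, token, cancer_index, params, config,
                          keep_cache = FALSE) {
  if (cancer_index < 1L || cancer_index > config$n_experts) {
    stop_pcm("`cancer_index` out of range for the expert pool", "validation_error")
  }
  x <- cbind(matrix(as.numeric(fused), 1L), matrix(as.numeric(token), 1L))
  gate_in <- if (config$gate_from == "token") matrix(as.numeric(token), 1L) else x
  g <- as.vector(gate_in %*% params$gate$Wg) + params$gate$bg
  g[cancer_index] <- g[cancer_index] + config$boost
  sel <- order(g, decreasing = TRUE)[seq_len(config$top_k)]
  gates <- numeric(config$n_experts)
  gates[sel] <- softmax_vec(g[sel])
  experts <- lapply(params$experts, function(pe) {
    mlp2_forward(x, pe$W1, pe$b1, pe$W2, pe$b2)
  })
  expert_risks <- vapply(experts, function(e) as.numeric(e$out), numeric(1))
  risk <- sum(gates * expert_risks)
  out <- list(gates = gates, expert_risks = expert_risks, risk = risk,
              selected = sel)
  if (keep_cache) {
    out$cache <- list(x = x, gate_in = gate_in, g = g, sel = sel, gates = gates,
                      experts = experts, expert_risks = expert_risks)
  }
  out
}

#' Full forward pass for one patient
#'
#' Pools the patient's bags, runs attention-MIL aggregation, cross-attention
#' fusion with the clinical vector, builds the cancer control token and routes
#' through the expert pool, returning the scalar log-risk together with the
#' interpretability outputs (per-patch attention with slide provenance, gate
#' weights).
#'
#' @param record A `pcm_patient` with loaded bags, or a list with elements
#'   `features` (N x D matrix), `clinical` (length-M vector), `cancer_index`,
#'   `onehot`.
#' @param model A `pcm_model`.
#' @param keep_cache Retain intermediates for backpropagation.
#' @return A `pcm_risk` list: `patient_id`, `risk`, `attn`, `provenance`,
#'   `gates`, `expert_risks`, and optionally `cache`.
#' @export
model_forward <- function(record, model, keep_cache = FALSE) {
  cfg <- model$config
  if (inherits(record, "pcm_patient")) {
    pooled <- pool_patient_bag(record)
    X <- pooled$features
    provenance <- pooled$provenance
    cvec <- record$clinical$values
    ci <- record$cancer$index
    onehot <- record$cancer$onehot
    pid <- record$patient_id
  } else {
    X <- as.matrix(record$features)
    provenance <- record$provenance %||% NULL
    cvec <- record$clinical
    ci <- record$cancer_index
    onehot <- record$onehot %||% {
      oh <- numeric(cfg$K); oh[ci] <- 1; oh
    }
    pid <- record$patient_id %||% NA_character_
  }
  if (ncol(X) != cfg$D) {
    stop_pcm(sprintf("bag has D = %d but config expects %d", ncol(X), cfg$D),
             "dimension_error")
  }
  am <- amil_aggregate(X, model$params$amil, keep_cache = keep_cache)
  fu <- fuse_modalities(am$H1, cvec, model$params$fus, cfg,
                        keep_cache = keep_cache)
  tk <- cancer_control_token(onehot, model$params$tok, keep_cache = keep_cache)
  ro <- route_experts(fu$fused, tk$token, ci, model$params, cfg,
                      keep_cache = keep_cache)
  out <- list(patient_id = pid, risk = ro$risk, attn = am$attn,
              provenance = provenance, gates = ro$gates,
              expert_risks = ro$expert_risks)
  if (keep_cache) {
    out$cache <- list(am = am$cache, fu = fu$cache, tk = tk$cache,
                      ro = ro$cache, cancer_index = ci)
  }
  structure(out, class = "pcm_risk")
}

#' Predict risks for many patients
#'
#' @param model A `pcm_model`.
#' @param patients List of `pcm_patient` records (or a `pcm_cohort`).
#' @return Tibble with `patient_id`, `risk`, plus list-columns `attn`,
#'   `gates`.
#' @export
predict_risks <- function(model, patients) {
  if (inherits(patients, "pcm_cohort")) patients <- patients$patients
  preds <- lapply(patients, model_forward, model = model)
  tibble::tibble(
    patient_id = vapply(preds, `[[`, character(1), "patient_id"),
    risk = vapply(preds, `[[`, numeric(1), "risk"),
    attn = lapply(preds, `[[`, "attn"),
    gates = lapply(preds, `[[`, "gates")
  )
}

# ---- checkpoints ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the config, all weights, the
#' cancer-label map (the one-hot basis must be stable between training and
#' inference) and a schema version stamp.
#'
#' @param model A `pcm_model`.
#' @param path File path.
#' @return `path` (save) or the restored `pcm_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pcm_model"))
  payload <- list(schema_version = 1L,
                  package_version = as.character(utils::packageVersion("pancanmil")),
                  model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  if (is.null(payload$schema_version) || is.null(payload$model)) {
    stop_pcm(sprintf("'%s' is not a model checkpoint", path), "format_error")
  }
  payload$model
}
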
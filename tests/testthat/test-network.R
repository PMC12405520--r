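test_that("attention-MIL satisfies softmax and symmetry contracts", {
  cfg <- tiny_model_config()
  model <- init_model(cfg, seed = 2)

  # singleton bag: softmax over one score is exactly 1
  one <- amil_aggregate(matrix(rnorm(cfg$D), 1L), model$params$amil)
  expect_identical(one$attn, 1)

  # identical rows: weights uniform by permutation symmetry
  row <- rnorm(cfg$D)
  same <- amil_aggregate(matrix(row, 6L, cfg$D, byrow = TRUE), model$params$amil)
  expect_equal(same$attn, rep(1 / 6, 6), tolerance = 1e-6)

  # random bag: weights normalized, summary permutation-invariant
  set.seed(3)
  X <- matrix(rnorm(7 * cfg$D), 7L)
  out <- amil_aggregate(X, model$params$amil)
  expect_equal(sum(out$attn), 1, tolerance = 1e-9)
  p <- sample(7)
  out_p <- amil_aggregate(X[p, ], model$params$amil)
  expect_equal(out_p$H1, out$H1, tolerance = 1e-9)
  expect_equal(out_p$attn, out$attn[p], tolerance = 1e-9)

  expect_error(amil_aggregate(matrix(numeric(), 0L, cfg$D), model$params$amil),
               class = "pcm_validation_error")
  expect_error(amil_aggregate(matrix(NA_real_, 2L, cfg$D), model$params$amil),
               class = "pcm_validation_error")
})

test_that("cross-attention fusion degenerates correctly and stays finite", {
  # n_tokens = 1: softmax over a single key has weight exactly 1, so the
  # attended feature is the value-projection (then output projection) of E_h
  cfg1 <- tiny_model_config(n_tokens = 1L, n_heads = 1L, d = 6L,
                            token_hidden = 6L)
  model <- init_model(cfg1, seed = 4)
  H1 <- matrix(rnorm(cfg1$d_slide), 1L)
  C <- encode_clinical(55, "male", "I")$values
  fu <- fuse_modalities(H1, C, model$params$fus, cfg1)
  pa <- model$params$fus$att_ch
  expected <- (fu$E_h %*% pa$Wv + matrix(pa$bv, 1L)) %*% pa$Wo + matrix(pa$bo, 1L)
  expect_equal(fu$A_c_to_h, expected, tolerance = 1e-10)

  # all-missing patient: zero clinical vector must still give finite outputs
  cfg <- tiny_model_config()
  m2 <- init_model(cfg, seed = 5)
  fu0 <- fuse_modalities(matrix(rnorm(cfg$d_slide), 1L), numeric(cfg$M),
                         m2$params$fus, cfg)
  expect_true(all(is.finite(fu0$fused)))
  expect_true(all(is.finite(fu0$A_h_to_c)))

  expect_error(fuse_modalities(H1, numeric(5), model$params$fus, cfg1),
               class = "pcm_dimension_error")
})

test_that("cross-attention matches a by-hand computation on two tokens", {
  # d = 4, n_tokens = 2, one head, hand-set weights
  cfg <- tiny_model_config(d = 4L, n_tokens = 2L, n_heads = 1L, d_slide = 4L,
                           token_hidden = 4L)
  model <- init_model(cfg, seed = 6)
  pa <- list(Wq = matrix(c(1, 0, 0.5, 1), 2, 2), bq = c(0.1, -0.2),
             Wk = matrix(c(0.3, 1, -1, 0.2), 2, 2), bk = c(0, 0.4),
             Wv = matrix(c(1, 0.2, 0, -1), 2, 2), bv = c(0.05, 0),
             Wo = matrix(c(0.7, -0.3, 0.1, 1), 2, 2), bo = c(0, 0.2))
  Tq <- matrix(c(0.5, -1, 0.2, 0.8), 2, 2)
  Tkv <- matrix(c(1, 0.1, -0.5, 0.3), 2, 2)

  got <- pancanmil:::cross_attention_forward(Tq, Tkv, pa, n_heads = 1L)

  # independent hand computation with explicit loops
  Q <- Tq %*% pa$Wq; K <- Tkv %*% pa$Wk; V <- Tkv %*% pa$Wv
  for (i in 1:2) { Q[i, ] <- Q[i, ] + pa$bq; K[i, ] <- K[i, ] + pa$bk
                   V[i, ] <- V[i, ] + pa$bv }
  O <- matrix(0, 2, 2)
  for (i in 1:2) {
    s <- c(sum(Q[i, ] * K[1, ]), sum(Q[i, ] * K[2, ])) / sqrt(2)
    w <- exp(s) / sum(exp(s))
    O[i, ] <- w[1] * V[1, ] + w[2] * V[2, ]
  }
  expected <- O %*% pa$Wo
  for (i in 1:2) expected[i, ] <- expected[i, ] + pa$bo
  expect_equal(got$out, expected, tolerance = 1e-12)
})

test_that("cancer control token is deterministic, normalized, and matches a hand oracle", {
  cfg <- tiny_model_config(K = 3L, n_experts = 3L)
  model <- init_model(cfg, seed = 7)
  oh <- c(0, 1, 0)
  t1 <- cancer_control_token(oh, model$params$tok)$token
  t2 <- cancer_control_token(oh, model$params$tok)$token
  expect_identical(t1, t2)
  expect_equal(mean(t1), 0, tolerance = 1e-5)
  expect_equal(mean(t1^2), 1, tolerance = 1e-5)   # unit population variance

  expect_error(cancer_control_token(c(1, 1, 0), model$params$tok),
               class = "pcm_validation_error")
  expect_error(cancer_control_token(c(0.5, 0.5, 0), model$params$tok),
               class = "pcm_validation_error")

  # K = 2, hand-set 2x2 weights: token = InstanceNorm(W2' silu(W1' onehot))
  params <- list(W1 = matrix(c(0.5, -1, 2, 0.3), 2, 2), b1 = c(0.1, 0),
                 W2 = matrix(c(1, 0.2, -0.5, 0.8), 2, 2), b2 = c(0, -0.1))
  tok <- cancer_control_token(c(1, 0), params)$token
  a1 <- c(0.5 * 1 + 0.1, 2 * 1 + 0)          # pre-activations
  z1 <- a1 * (1 / (1 + exp(-a1)))            # silu(x) = x * sigmoid(x)
  out <- c(z1[1] * 1 + z1[2] * 0.2 + 0,
           z1[1] * -0.5 + z1[2] * 0.8 - 0.1)
  hand <- (out - mean(out)) / sqrt(mean((out - mean(out))^2) + 1e-8)
  expect_equal(as.vector(tok), hand, tolerance = 1e-10)
})

test_that("expert routing matches a hand softmax/renormalization oracle", {
  cfg <- tiny_model_config(K = 3L, n_experts = 3L, top_k = 2L, boost = log(2))
  model <- init_model(cfg, seed = 8)
  # pin gate logits: zero weight matrix, logits come from the bias alone
  model$params$gate$Wg <- model$params$gate$Wg * 0
  model$params$gate$bg <- c(1.0, 0.5, 0.1)
  # pin scalar expert outputs
  outs <- c(2.0, -1.0, 0.5)
  for (e in 1:3) {
    model$params$experts[[e]]$W1 <- model$params$experts[[e]]$W1 * 0
    model$params$experts[[e]]$W2 <- model$params$experts[[e]]$W2 * 0
    model$params$experts[[e]]$b2 <- outs[e]
  }
  fused <- matrix(rnorm(cfg$d), 1L)
  token <- matrix(rnorm(cfg$d), 1L)
  ro <- route_experts(fused, token, cancer_index = 2L, model$params, cfg)

  # hand computation: boost ln 2 on logit 2, top-2 keeps {1, 2}, renormalize
  g <- c(1.0, 0.5 + log(2), 0.1)
  keep <- order(g, decreasing = TRUE)[1:2]
  w <- exp(g[keep]) / sum(exp(g[keep]))
  gates_hand <- numeric(3); gates_hand[keep] <- w
  expect_equal(ro$gates, gates_hand, tolerance = 1e-12)
  expect_equal(ro$expert_risks, outs, tolerance = 1e-12)
  expect_equal(ro$risk, sum(gates_hand * outs), tolerance = 1e-12)
})

test_that("router gate contracts hold across random configurations", {
  set.seed(9)
  for (rep in 1:8) {
    K <- sample(2:5, 1)
    top_k <- sample(seq_len(K), 1)
    cfg <- tiny_model_config(K = K, n_experts = K, top_k = top_k,
                             boost = runif(1, 0, 2))
    model <- init_model(cfg, seed = rep)
    fused <- matrix(rnorm(cfg$d), 1L)
    token <- matrix(rnorm(cfg$d), 1L)
    ci <- sample(K, 1)
    ro <- route_experts(fused, token, ci, model$params, cfg)
    expect_equal(sum(ro$gates != 0), min(top_k, K))
    expect_equal(sum(ro$gates), 1, tolerance = 1e-9)
    expect_true(all(ro$gates >= 0))
    expect_equal(ro$risk, sum(ro$gates * ro$expert_risks), tolerance = 1e-9)

    # boost monotonicity: own gate never decreases as boost grows
    gates_by_boost <- vapply(c(0, 0.5, 1, 2, 5), function(b) {
      cfg_b <- tiny_model_config(K = K, n_experts = K, top_k = top_k, boost = b)
      route_experts(fused, token, ci, model$params, cfg_b)$gates[ci]
    }, numeric(1))
    expect_true(all(diff(gates_by_boost) >= -1e-12))
  }

  # saturation: a huge boost routes everything to the own expert
  cfg <- tiny_model_config(K = 3L, n_experts = 3L, top_k = 2L, boost = 50)
  model <- init_model(cfg, seed = 10)
  ro <- route_experts(matrix(rnorm(cfg$d), 1L), matrix(rnorm(cfg$d), 1L),
                      3L, model$params, cfg)
  expect_equal(ro$gates[3L], 1, tolerance = 1e-6)
  expect_equal(ro$risk, ro$expert_risks[3L], tolerance = 1e-6)

  expect_error(tiny_model_config(top_k = 5L), class = "pcm_config_error")
})

test_that("full forward pass is deterministic and bag-symmetric", {
  cfg <- tiny_model_config()
  model <- init_model(cfg, seed = 11)
  rec <- random_record(cfg, N = 6L, seed = 12)

  r1 <- model_forward(rec, model)$risk
  r2 <- model_forward(rec, model)$risk
  expect_identical(r1, r2)

  perm <- rec; perm$features <- rec$features[sample(6), ]
  expect_equal(model_forward(perm, model)$risk, r1, tolerance = 1e-6)

  dup <- rec; dup$features <- rbind(rec$features, rec$features)
  expect_equal(model_forward(dup, model)$risk, r1, tolerance = 1e-5)

  expect_true(is.finite(r1))
  expect_length(model_forward(rec, model)$attn, 6L)
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_model_config()
  model <- init_model(cfg, seed = 13)
  rec <- random_record(cfg, N = 4L, seed = 14)
  fw <- model_forward(rec, model, keep_cache = TRUE)
  analytic <- flatten_params(model_backward(fw$cache, model, 1))
  theta <- flatten_params(model$params)
  f <- function(v) {
    m2 <- model
    m2$params <- unflatten_params(v, model$params)
    model_forward(rec, m2)$risk
  }
  num <- numeric_grad(f, theta)
  expect_lt(max(rel_err(analytic, num, floor = 1e-6)), 1e-4)
})

test_that("model shapes are total over valid configurations", {
  set.seed(15)
  for (rep in 1:4) {
    nt <- sample(c(1L, 2L, 4L), 1)
    nh <- if (nt == 4L) sample(c(1L, 2L), 1) else 1L
    d <- nt * nh * sample(2:3, 1)
    cfg <- tiny_model_config(d = d, n_tokens = nt, n_heads = nh,
                             token_hidden = d, K = 3L, n_experts = 3L,
                             top_k = sample(1:3, 1))
    model <- init_model(cfg, seed = rep)
    rec <- random_record(cfg, N = sample(1:8, 1), seed = rep,
                         cancer_index = sample(3, 1))
    fw <- model_forward(rec, model)
    expect_true(is.finite(fw$risk))
    expect_equal(sum(fw$gates), 1, tolerance = 1e-9)
  }
  expect_error(model_config(D = 8, K = 2, d = 7, n_tokens = 2),
               class = "pcm_config_error")
})

test_that("checkpoints round-trip the model and label map", {
  cfg <- tiny_model_config()
  model <- init_model(cfg, seed = 16, cancer_levels = c("BLCA", "BRCA"))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  expect_identical(back$cancer_levels, c("BLCA", "BRCA"))
  rec <- random_record(cfg, N = 3L, seed = 17)
  expect_identical(model_forward(rec, back)$risk, model_forward(rec, model)$risk)
})
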
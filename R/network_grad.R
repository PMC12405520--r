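# Hand-differentiated backward pass. Every forward operation in network.R has
# its adjoint here; gradients are verified against central finite differences
# in the test suite (rel. err < 1e-4 on tiny models), so changes to the
# forward code must be mirrored.

mlp2_backward <- function(x, cache, W1, W2, dout) {
  dZ1 <- dout %*% t(W2)
  dW2 <- t(cache$Z1) %*% dout
  db2 <- colSums(dout)
  dA1 <- dZ1 * silu_grad(cache$A1)
  dW1 <- t(x) %*% dA1
  db1 <- colSums(dA1)
  dx <- dA1 %*% t(W1)
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

cross_attention_backward <- function(Tq, Tkv, pa, cache, dOut, n_heads) {
  dt <- ncol(Tq); dh <- cache$dh
  dO <- dOut %*% t(pa$Wo)
  dWo <- t(cache$O) %*% dOut
  dbo <- colSums(dOut)
  dQ <- matrix(0, nrow(Tq), dt)
  dK <- matrix(0, nrow(Tkv), dt)
  dV <- matrix(0, nrow(Tkv), dt)
  for (g in seq_len(n_heads)) {
    idx <- ((g - 1L) * dh + 1L):(g * dh)
    P <- cache$P[[g]]
    dOg <- dO[, idx, drop = FALSE]
    Vg <- cache$V[, idx, drop = FALSE]
    dP <- dOg %*% t(Vg)
    dV[, idx] <- t(P) %*% dOg
    dS <- softmax_rows_backward(P, dP)
    dQ[, idx] <- (dS %*% cache$K[, idx, drop = FALSE]) / sqrt(dh)
    dK[, idx] <- (t(dS) %*% cache$Q[, idx, drop = FALSE]) / sqrt(dh)
  }
  list(
    dTq = dQ %*% t(pa$Wq),
    dTkv = dK %*% t(pa$Wk) + dV %*% t(pa$Wv),
    grads = list(
      Wq = t(Tq) %*% dQ, bq = colSums(dQ),
      Wk = t(Tkv) %*% dK, bk = colSums(dK),
      Wv = t(Tkv) %*% dV, bv = colSums(dV),
      Wo = dWo, bo = dbo
    )
  )
}

amil_backward <- function(cache, params, dH1) {
  dH1v <- as.vector(dH1)
  dU <- outer(cache$attn, dH1v)
  da <- as.vector(cache$U %*% matrix(dH1v, ncol = 1L))
  ds <- cache$attn * (da - sum(cache$attn * da))
  dsm <- matrix(ds, ncol = 1L)
  dZ <- dsm %*% t(params$wa)
  dwa <- t(cache$Z) %*% dsm
  dba <- sum(ds)
  dVt <- dZ * cache$Gs
  dGs <- dZ * cache$Vt
  dAv <- dVt * (1 - cache$Vt^2)
  dAu <- dGs * cache$Gs * (1 - cache$Gs)
  dU <- dU + dAv %*% t(params$Wv) + dAu %*% t(params$Wu)
  list(grads = list(
    Wp = t(cache$X) %*% dU, bp = colSums(dU),
    Wv = t(cache$U) %*% dAv, bv = colSums(dAv),
    Wu = t(cache$U) %*% dAu, bu = colSums(dAu),
    wa = dwa, ba = dba
  ))
}

fusion_backward <- function(cache, params, config, dfused) {
  dcat2 <- dfused %*% t(params$Wf)
  dWf <- t(cache$cat2) %*% dfused
  dbf <- colSums(dfused)
  d <- config$d
  dA_ch <- to_tokens(dcat2[1L, 1:d], config$n_tokens)
  dA_hc <- to_tokens(dcat2[1L, (d + 1L):(2L * d)], config$n_tokens)
  bch <- cross_attention_backward(cache$Tc, cache$Th, params$att_ch, cache$ach,
                                  dA_ch, config$n_heads)
  bhc <- cross_attention_backward(cache$Th, cache$Tc, params$att_hc, cache$ahc,
                                  dA_hc, config$n_heads)
  dTh <- bch$dTkv + bhc$dTq
  dTc <- bch$dTq + bhc$dTkv
  dE_h <- from_tokens(dTh)
  dE_c <- from_tokens(dTc)
  bh <- mlp2_backward(cache$H1, cache$hm, params$h1, params$h2, dE_h)
  bc <- mlp2_backward(cache$C, cache$cm, params$c1, params$c2, dE_c)
  list(
    dH1 = bh$dx,
    grads = list(
      h1 = bh$grads$W1, hb1 = bh$grads$b1, h2 = bh$grads$W2, hb2 = bh$grads$b2,
      c1 = bc$grads$W1, cb1 = bc$grads$b1, c2 = bc$grads$W2, cb2 = bc$grads$b2,
      att_ch = bch$grads, att_hc = bhc$grads,
      Wf = dWf, bf = dbf
    )
  )
}

token_backward <- function(cache, params, dtoken) {
  dy <- as.vector(dtoken)
  y <- cache$nrm$y
  dz <- (dy - mean(dy) - y * mean(dy * y)) / cache$nrm$s
  bm <- mlp2_backward(matrix(cache$onehot, 1L), cache$m, params$W1, params$W2,
                      matrix(dz, 1L))
  list(grads = bm$grads)
}

router_backward <- function(cache, params, config, drisk) {
  sel <- cache$sel
  p <- cache$gates[sel]
  dp <- drisk * cache$expert_risks[sel]
  dg_sel <- p * (dp - sum(p * dp))
  dg <- numeric(config$n_experts)
  dg[sel] <- dg_sel
  dg_row <- matrix(dg, 1L)
  dWg <- t(cache$gate_in) %*% dg_row
  dbg <- dg
  dgate_in <- dg_row %*% t(params$gate$Wg)

  dx <- matrix(0, 1L, 2L * config$d)
  expert_grads <- vector("list", config$n_experts)
  for (e in seq_len(config$n_experts)) {
    pe <- params$experts[[e]]
    if (e %in% sel && cache$gates[e] != 0) {
      be <- mlp2_backward(cache$x, cache$experts[[e]], pe$W1, pe$W2,
                          matrix(drisk * cache$gates[e], 1L, 1L))
      dx <- dx + be$dx
      expert_grads[[e]] <- be$grads
    } else {
      expert_grads[[e]] <- list(W1 = pe$W1 * 0, b1 = pe$b1 * 0,
                                W2 = pe$W2 * 0, b2 = pe$b2 * 0)
    }
  }
  d <- config$d
  dtoken <- matrix(dx[1L, (d + 1L):(2L * d)], 1L)
  if (config$gate_from == "token") {
    dtoken <- dtoken + dgate_in
  } else {
    dx <- dx + dgate_in
    dtoken <- matrix(dx[1L, (d + 1L):(2L * d)], 1L)
  }
  dfused <- matrix(dx[1L, 1:d], 1L)
  list(dfused = dfused, dtoken = dtoken,
       grads = list(gate = list(Wg = dWg, bg = dbg), experts = expert_grads))
}

#' Full-model adjoint pass
#'
#' Backpropagates a scalar risk gradient through the router, control token,
#' cross-attention fusion and attention-MIL blocks, returning the gradient of
#' `drisk * risk` with respect to every parameter (same nested structure as
#' `model$params`). The forward pass must have been run with
#' `keep_cache = TRUE`. Verified against central finite differences in the
#' test suite.
#'
#' @param cache The `cache` element of a [model_forward()] result.
#' @param model The `pcm_model` used for the forward pass.
#' @param drisk Upstream gradient of the loss with respect to this patient's
#'   risk.
#' @return Nested list of parameter gradients.
#' @export
model_backward <- function(cache, model, drisk) {
  cfg <- model$config
  ro <- router_backward(cache$ro, model$params, cfg, drisk)
  tk <- token_backward(cache$tk, model$params$tok, ro$dtoken)
  fu <- fusion_backward(cache$fu, model$params$fus, cfg, ro$dfused)
  am <- amil_backward(cache$am, model$params$amil, fu$dH1)
  list(amil = am$grads, fus = fu$grads, tok = tk$grads,
       gate = ro$grads$gate, experts = ro$grads$experts)
}

# ---- nested parameter-list utilities -------------------------------------

#' Flatten a nested parameter list into one numeric vector
#'
#' Deterministic depth-first order; the inverse is [unflatten_params()].
#' Used by the optimizer and for finite-difference gradient checks.
#'
#' @param params Nested list of numeric vectors/matrices.
#' @return Numeric vector.
#' @export
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

#' Rebuild a nested parameter list from a flat vector
#'
#' @param flat Numeric vector produced by [flatten_params()].
#' @param template Nested list providing structure and dimensions.
#' @return Nested list shaped like `template`.
#' @export
unflatten_params <- function(flat, template) {
  pos <- 0L
  rebuild <- function(x) {
    if (is.list(x)) {
      out <- lapply(x, rebuild)
      names(out) <- names(x)
      return(out)
    }
    n <- length(x)
    v <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(x)) dim(v) <- dim(x)
    v
  }
  out <- rebuild(template)
  stopifnot(pos == length(flat))
  out
}

zero_grads <- function(params) {
  unflatten_params(numeric(length(flatten_params(params))), params)
}

n_params <- function(model) length(flatten_params(model$params))
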
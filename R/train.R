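# Network training: full-batch Adam with deterministic, seeded
# initialization. Training is exactly reproducible for a given model state
# and data; no stochastic minibatching is used.

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  warm <- min(1, st$t / 10)   # warmup: avoids violent first steps
  if (length(lr) == 1) lr <- setNames(rep(lr, length(params)), names(params))
  for (k in names(params)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * grads[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * grads[[k]]^2
    mh <- st$m[[k]] / (1 - beta1^st$t)
    vh <- st$v[[k]] / (1 - beta2^st$t)
    params[[k]] <- params[[k]] - warm * lr[[k]] * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = st)
}

#' Training hyperparameters
#'
#' @param epochs maximum epochs per call.
#' @param lr Adam learning rate.
#' @param target_rel_rms stop once the relative RMS stress error drops below
#'   this value. The engine uses a lax value (0.20) for the first-pass MPN
#'   phase and a stringent value (0.02) thereafter.
#' @param w3_decay L2 weight decay on the MPN's tanh output layer. Keeps the
#'   nonlinear correction path small unless the data demand it, so the
#'   model's tangent stays well conditioned outside the trained strain range.
#' @param a_decay ridge decay of the MPN's linear term toward its isotropic
#'   initialization, plus an equal-strength symmetry penalty. FEA strain
#'   data lie close to a low-dimensional manifold (compression-dominated
#'   states), so components of the stiffness orthogonal to the data are
#'   unidentified; the decay anchors them to the elastic prior instead of
#'   letting them drift indefinite.
#' @param hidden_lr_frac fraction of `lr` applied to the MPN's tanh layers.
#'   The linear term learns at full rate; the nonlinear correction is a slow
#'   path, keeping the tangent well conditioned while small-strain responses
#'   are essentially linear.
#' @param lr_final_frac the learning rate decays exponentially to this
#'   fraction of `lr` over the epoch budget, so each training call ends with
#'   small, precise steps and successive calls are repeatable. Default 1
#'   (constant rate).
#' @param sn_weight_decay L2 decay on the SN's weight matrices (not biases).
#'   Acts as a smoothness prior on the scale-factor field: the spatial
#'   resolution of the learned modulus field is a few millimetres, so sharp
#'   network ridges between measurement planes are penalized.
#' @export
train_control <- function(epochs = 300, lr = 0.02, target_rel_rms = 0.02,
                          w3_decay = 0.1, a_decay = 0.03, hidden_lr_frac = 0.1,
                          lr_final_frac = 1, sn_weight_decay = 0) {
  list(epochs = as.integer(epochs), lr = lr, target_rel_rms = target_rel_rms,
       w3_decay = w3_decay, a_decay = a_decay, hidden_lr_frac = hidden_lr_frac,
       lr_final_frac = lr_final_frac, sn_weight_decay = sn_weight_decay)
}

#' Train the material property network
#'
#' Fits the MPN to paired (strain, stress) training data at matched
#' integration points, with the SN frozen at S = 1 (positions are not used).
#' Normalization constants are set from the first data seen (95th percentile
#' of absolute strain / stress). The zero-strain/zero-stress anchor is
#' structural, so all-zero pairs produce zero gradients.
#'
#' @param model a `cannccm`.
#' @param eps n x 6 strains (from the displacement-driven FEA).
#' @param sigma n x 6 stresses (kPa, from the force-driven FEA).
#' @param weights optional nonnegative per-point weights.
#' @param control see [train_control()].
#' @return the updated model; the loss trace is in
#'   `attr(, "history")` (per-epoch relative RMS stress error).
#' @export
train_mpn <- function(model, eps, sigma, weights = NULL, control = train_control()) {
  eps <- rbind(eps); sigma <- rbind(sigma)
  if (nrow(eps) == 0) stop("no training pairs")
  stopifnot(nrow(eps) == nrow(sigma), ncol(eps) == 6, ncol(sigma) == 6)
  n <- nrow(eps)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(w < 0) || sum(w) == 0) stop("weights must be nonnegative with positive sum")
  mpn <- model$mpn
  if (!isTRUE(mpn$scales_fixed)) {
    # adopt data-driven normalization, rescaling weights so the encoded
    # stress map is unchanged
    e_new <- max(stats::quantile(abs(eps), 0.95), 1e-12)
    s_new <- max(stats::quantile(abs(sigma), 0.95), 1e-12)
    mpn$W1 <- mpn$W1 * (e_new / mpn$eps_scale)
    mpn$W3 <- mpn$W3 * (mpn$sig_scale / s_new)
    mpn$A <- mpn$A * (e_new / mpn$eps_scale) * (mpn$sig_scale / s_new)
    mpn$A0 <- mpn$A0 * (e_new / mpn$eps_scale) * (mpn$sig_scale / s_new)
    mpn$eps_scale <- e_new
    mpn$sig_scale <- s_new
    mpn$scales_fixed <- TRUE
  }

  Z <- eps / mpn$eps_scale
  Yn <- sigma / mpn$sig_scale
  wn <- w / sum(w)
  y_ms <- sum(wn * rowSums(Yn^2))
  pk <- c("W1", "b1", "W2", "b2", "W3", "A")
  st <- if (!is.null(model$opt_mpn)) model$opt_mpn else adam_state(mpn[pk])
  hist <- numeric(0)
  loss0 <- NA_real_
  for (ep in seq_len(control$epochs)) {
    fw <- mpn_forward_z(mpn, Z, cache = TRUE)
    R <- fw$out - Yn
    loss <- sum(wn * rowSums(R^2))
    rel <- sqrt(loss / max(y_ms, 1e-300))
    hist <- c(hist, rel)
    if (ep == 1) loss0 <- loss
    if (loss > 10 * loss0 + 1e-300 && rel > 0.25)
      stop(sprintf("MPN training diverged at epoch %d (loss %.3g vs initial %.3g)", ep, loss, loss0))
    if (rel <= control$target_rel_rms) break
    G <- 2 * (wn * R)                       # n x 6
    gr <- mpn_backprop(mpn, fw, Z, G)
    gr$W3 <- gr$W3 + control$w3_decay * mpn$W3
    gr$A <- gr$A + control$a_decay * (mpn$A - mpn$A0) +
      control$a_decay * (mpn$A - t(mpn$A))
    lrs <- setNames(rep(control$lr * control$hidden_lr_frac, length(pk)), pk)
    lrs[["A"]] <- control$lr
    upd <- adam_step(mpn[pk], gr, st, lrs)
    mpn[pk] <- upd$params; st <- upd$state
  }
  model$mpn <- mpn
  model$opt_mpn <- st
  attr(model, "history") <- hist
  model
}

mpn_backprop <- function(mpn, fw, Z, G) {
  # data path
  dW3 <- crossprod(G, fw$H2)
  dA <- crossprod(G, Z)
  dH2 <- G %*% mpn$W3
  dp2 <- dH2 * (1 - fw$H2^2)
  dW2 <- crossprod(dp2, fw$H1)
  db2 <- colSums(dp2)
  dH1 <- dp2 %*% mpn$W2
  dp1 <- dH1 * (1 - fw$H1^2)
  dW1 <- crossprod(dp1, Z)
  db1 <- colSums(dp1)
  # zero-anchor path (output is net(Z) - net(0))
  g0 <- -colSums(G)
  dW3 <- dW3 + outer(g0, fw$h2_0)
  dp2_0 <- as.numeric(t(mpn$W3) %*% g0) * (1 - fw$h2_0^2)
  dW2 <- dW2 + outer(dp2_0, fw$h1_0)
  db2 <- db2 + dp2_0
  dp1_0 <- as.numeric(t(mpn$W2) %*% dp2_0) * (1 - fw$h1_0^2)
  db1 <- db1 + dp1_0
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, A = dA)
}

#' Train the spatial network
#'
#' Minimizes the weighted residual `sum w(x) || mpn(S(x) eps(x)) - sigma(x) ||^2`
#' over the SN parameters with the MPN frozen.
#'
#' @param model a `cannccm` whose MPN has been trained (scales set).
#' @param x n x 3 integration-point positions (mm).
#' @inheritParams train_mpn
#' @export
train_sn <- function(model, x, eps, sigma, weights = NULL, control = train_control()) {
  x <- rbind(x); eps <- rbind(eps); sigma <- rbind(sigma)
  if (nrow(x) == 0) stop("no training pairs")
  stopifnot(nrow(x) == nrow(eps), nrow(eps) == nrow(sigma))
  scales_ready(model)
  n <- nrow(x)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (any(w < 0)) stop("weights must be nonnegative")
  if (sum(w) == 0) stop("all training weights are zero")
  mpn <- model$mpn; sn <- model$sn
  E <- eps / mpn$eps_scale
  Yn <- sigma / mpn$sig_scale
  wn <- w / sum(w)
  y_ms <- sum(wn * rowSums(Yn^2))
  pk <- c("V1", "c1", "V2", "c2", "v3", "c3")
  st <- adam_state(sn[pk])   # fresh optimizer per call; warmup tames restarts
  hist <- numeric(0)
  loss0 <- NA_real_
  Xn <- sweep(sweep(x, 2, sn$center), 2, sn$halfw, "/")
  for (ep in seq_len(control$epochs)) {
    sf <- sn_forward(sn, x, cache = TRUE, Xn = Xn)
    Z <- E * sf$S
    fw <- mpn_forward_z(mpn, Z, cache = TRUE)
    R <- fw$out - Yn
    loss <- sum(wn * rowSums(R^2))
    rel <- sqrt(loss / max(y_ms, 1e-300))
    hist <- c(hist, rel)
    if (ep == 1) loss0 <- loss
    if (loss > 10 * loss0 + 1e-300 && rel > 0.25)
      stop(sprintf("SN training diverged at epoch %d", ep))
    if (rel <= control$target_rel_rms) break
    G <- 2 * (wn * R)
    # dL/dZ through the frozen MPN
    dH2 <- G %*% mpn$W3
    dp2 <- dH2 * (1 - fw$H2^2)
    dH1 <- dp2 %*% mpn$W2
    dp1 <- dH1 * (1 - fw$H1^2)
    dZ <- dp1 %*% mpn$W1 + G %*% mpn$A
    dS <- rowSums(dZ * E)
    da <- dS * stats::plogis(sf$a) / log(2)
    dv3 <- matrix(colSums(da * sf$H2), 1)
    dc3 <- sum(da)
    dq2 <- (da %*% sn$v3) * (1 - sf$H2^2)
    dV2 <- crossprod(dq2, sf$H1)
    dc2 <- colSums(dq2)
    dq1 <- (dq2 %*% sn$V2) * (1 - sf$H1^2)
    dV1 <- crossprod(dq1, sf$Xn)
    dc1 <- colSums(dq1)
    gr <- list(V1 = dV1, c1 = dc1, V2 = dV2, c2 = dc2, v3 = dv3, c3 = dc3)
    wd <- control$sn_weight_decay
    if (wd > 0) {   # hidden layers only: shape smoothness, not amplitude
      gr$V1 <- gr$V1 + wd * sn$V1
      gr$V2 <- gr$V2 + wd * sn$V2
    }
    lr_ep <- control$lr * control$lr_final_frac^((ep - 1) / max(control$epochs - 1, 1))
    upd <- adam_step(sn[pk], gr, st, lr_ep)
    sn[pk] <- upd$params; st <- upd$state
  }
  model$sn <- sn
  attr(model, "history") <- hist
  model
}
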
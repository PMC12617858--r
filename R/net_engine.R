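# Internal neural-network engine.
#
# A small 1-D convolutional regression network written directly against R's
# matrix primitives: im2col-style convolution, ReLU, width-p max pooling,
# inverted dropout, a fully connected reduction to a low-dimensional
# embedding, optional concatenation of a scalar auxiliary input (the
# reference phenotype), and a two-layer fully connected estimator with a
# single linear output. Trained by mini-batch Adam on mean squared error with
# hand-written backpropagation. Everything is deterministic given the RNG
# state; all stochastic parts (init, shuffling, dropout) run inside the
# caller's seeded scope.

net_dims <- function(n_features, conv_filters, conv_width, pool_width,
                     embed_dim, estimator_width, n_aux) {
  kw <- min(conv_width, n_features)
  out_len <- n_features - kw + 1L
  p <- min(pool_width, out_len)
  npool <- as.integer(ceiling(out_len / p))
  list(kw = kw, out_len = out_len, p = p, npool = npool,
       flat = npool * conv_filters,
       filters = conv_filters, embed = embed_dim, est = estimator_width,
       n_aux = n_aux)
}

net_init_params <- function(d) {
  rn <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  list(
    Wc = rn(d$kw, d$filters, sqrt(2 / d$kw)),
    bc = rep(0, d$filters),
    W1 = rn(d$flat, d$embed, sqrt(2 / d$flat)),
    b1 = rep(0, d$embed),
    W2 = rn(d$embed + d$n_aux, d$est, sqrt(2 / (d$embed + d$n_aux))),
    b2 = rep(0, d$est),
    W3 = rn(d$est, 1L, sqrt(1 / d$est)),
    b3 = 0)
}

net_n_params_list <- function(par) {
  sum(vapply(par, length, integer(1L)))
}

# column indices of the im2col patch matrix, precomputed once per model:
# idxvec is laid out so that X[, idxvec] reshaped to (B, kw, out_len) has
# patch position k varying fastest
net_patch_index <- function(d) {
  as.vector(outer(seq_len(d$kw), seq_len(d$out_len) - 1L, `+`))
}

# forward pass; when train = TRUE, dropout masks are drawn from the current
# RNG state and the intermediates needed by net_backward are returned
net_forward <- function(par, d, idxvec, X, aux, dropout, train = FALSE) {
  B <- nrow(X)
  A <- array(X[, idxvec], dim = c(B, d$kw, d$out_len))
  M <- matrix(aperm(A, c(1L, 3L, 2L)), ncol = d$kw)  # (B*out_len) x kw
  Cpre <- M %*% par$Wc
  Cpre <- sweep(Cpre, 2L, par$bc, `+`)
  Crelu <- pmax(Cpre, 0)

  # max pool width p along the position axis (pad with -Inf)
  Lp <- d$npool * d$p
  if (Lp == d$out_len) {
    Cpad <- Crelu
  } else {
    Cpad <- matrix(-Inf, B * Lp, d$filters)
    Cpad[seq_len(B * d$out_len), ] <- Crelu
  }
  dim(Cpad) <- c(B, d$p, d$npool, d$filters)
  P <- array(Cpad[, 1L, , , drop = FALSE], dim = c(B, d$npool, d$filters))
  if (d$p > 1L) {
    for (j in 2:d$p) {
      Sj <- array(Cpad[, j, , , drop = FALSE], dim = c(B, d$npool, d$filters))
      P <- pmax(P, Sj)
    }
  }
  Pf <- matrix(P, nrow = B)  # B x flat

  drop1 <- NULL
  H0 <- Pf
  if (train && dropout[1L] > 0) {
    drop1 <- (matrix(stats::runif(length(Pf)), nrow = B) >= dropout[1L]) /
      (1 - dropout[1L])
    H0 <- Pf * drop1
  }
  E_pre <- sweep(H0 %*% par$W1, 2L, par$b1, `+`)
  E <- pmax(E_pre, 0)

  Z <- if (d$n_aux > 0L) cbind(E, aux) else E
  H2pre <- sweep(Z %*% par$W2, 2L, par$b2, `+`)
  H2 <- pmax(H2pre, 0)
  drop2 <- NULL
  H2d <- H2
  if (train && dropout[2L] > 0) {
    drop2 <- (matrix(stats::runif(length(H2)), nrow = B) >= dropout[2L]) /
      (1 - dropout[2L])
    H2d <- H2 * drop2
  }
  out <- as.vector(H2d %*% par$W3 + par$b3)

  if (!train) return(out)
  list(out = out, M = M, Cpre = Cpre, Crelu = Crelu, P = P, Pf = Pf,
       drop1 = drop1, H0 = H0, E_pre = E_pre, E = E, Z = Z,
       H2pre = H2pre, H2 = H2, drop2 = drop2, H2d = H2d, B = B)
}

net_backward <- function(par, d, fw, dout) {
  B <- fw$B
  g <- list()
  # output layer
  g$W3 <- crossprod(fw$H2d, dout)
  g$b3 <- sum(dout)
  dH2d <- dout %*% t(par$W3)
  dH2 <- if (is.null(fw$drop2)) dH2d else dH2d * fw$drop2
  dH2pre <- dH2 * (fw$H2pre > 0)
  g$W2 <- crossprod(fw$Z, dH2pre)
  g$b2 <- colSums(dH2pre)
  dZ <- dH2pre %*% t(par$W2)
  dE <- if (d$n_aux > 0L) dZ[, seq_len(d$embed), drop = FALSE] else dZ
  dEpre <- dE * (fw$E_pre > 0)
  g$W1 <- crossprod(fw$H0, dEpre)
  g$b1 <- colSums(dEpre)
  dH0 <- dEpre %*% t(par$W1)
  dPf <- if (is.null(fw$drop1)) dH0 else dH0 * fw$drop1

  # route pooled gradient to the (first) argmax position in each pool group
  dP <- array(dPf, dim = c(B, d$npool, d$filters))
  Lp <- d$npool * d$p
  Cpad <- if (Lp == d$out_len) fw$Crelu else {
    tmp <- matrix(-Inf, B * Lp, d$filters)
    tmp[seq_len(B * d$out_len), ] <- fw$Crelu
    tmp
  }
  dim(Cpad) <- c(B, d$p, d$npool, d$filters)
  dCpad <- array(0, dim = c(B, d$p, d$npool, d$filters))
  found <- array(FALSE, dim = c(B, d$npool, d$filters))
  for (j in seq_len(d$p)) {
    Sj <- array(Cpad[, j, , , drop = FALSE], dim = c(B, d$npool, d$filters))
    sel <- (Sj == fw$P) & !found
    found <- found | sel
    dCpad[, j, , ] <- dP * sel
  }
  dim(dCpad) <- c(B * Lp, d$filters)
  dCrelu <- dCpad[seq_len(B * d$out_len), , drop = FALSE]
  dCpre <- dCrelu * (fw$Cpre > 0)
  g$Wc <- crossprod(fw$M, dCpre)
  g$bc <- colSums(dCpre)
  g
}

adam_init <- function(par) {
  list(m = lapply(par, function(x) x * 0),
       v = lapply(par, function(x) x * 0), t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

# one full training run over a materialized design; returns params + log
net_train_loop <- function(par, d, idxvec, X, aux, y, cfg) {
  n <- nrow(X)
  state <- adam_init(par)
  log_loss <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batch_losses <- c()
    for (start in seq(1L, n, by = cfg$batch_size)) {
      rows <- ord[start:min(n, start + cfg$batch_size - 1L)]
      fw <- net_forward(par, d, idxvec, X[rows, , drop = FALSE],
                        aux[rows], cfg$dropout, train = TRUE)
      resid <- fw$out - y[rows]
      batch_losses <- c(batch_losses, mean(resid^2))
      dout <- matrix(2 * resid / length(rows), ncol = 1L)
      grads <- net_backward(par, d, fw, dout)
      upd <- adam_step(par, grads, state, cfg$step_size)
      par <- upd$par
      state <- upd$state
    }
    log_loss[ep] <- mean(batch_losses)
    if (!is.finite(log_loss[ep]))
      stop("divergence error: non-finite training loss at epoch ", ep)
  }
  list(par = par, training_log = log_loss)
}

# batched inference (no dropout); chunked to bound peak memory
net_predict <- function(par, d, idxvec, X, aux, chunk = 4096L) {
  n <- nrow(X)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(n, start + chunk - 1L)
    out[rows] <- net_forward(par, d, idxvec, X[rows, , drop = FALSE],
                             if (is.null(aux)) NULL else aux[rows],
                             c(0, 0), train = FALSE)
  }
  out
}
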
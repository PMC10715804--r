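# Small dense-network machinery: the 2-layer perceptron used by the
# projector and the supervised head, softmax cross-entropy, and an Adam
# optimizer over nested parameter lists.

elu <- function(x) ifelse(x > 0, x, expm1(x))
elu_grad <- function(pre) ifelse(pre > 0, 1, exp(pre))

# H: n x d input; p: list(W1, b1, W2, b2); optionally L2-normalize rows
mlp_forward <- function(H, p, normalize = TRUE) {
  U1 <- sweep(H %*% p$W1, 2L, p$b1, "+")
  A1 <- elu(U1)
  U2 <- sweep(A1 %*% p$W2, 2L, p$b2, "+")
  if (normalize) {
    nrm <- sqrt(rowSums(U2^2))
    if (any(nrm < 1e-12))
      stopf("degenerate projection: pre-normalization output is (near) zero")
    Z <- U2 / nrm
  } else {
    nrm <- NULL
    Z <- U2
  }
  list(Z = Z, cache = list(H = H, U1 = U1, A1 = A1, U2 = U2, nrm = nrm,
                           normalize = normalize))
}

# dZ: gradient at the output of mlp_forward; returns parameter gradients
# and the gradient dH at the input
mlp_backward <- function(cache, p, dZ) {
  if (cache$normalize) {
    # z = u / |u|:  du = (dz - z (z . dz)) / |u|
    Z <- cache$U2 / cache$nrm
    dU2 <- (dZ - Z * rowSums(Z * dZ)) / cache$nrm
  } else {
    dU2 <- dZ
  }
  dW2 <- crossprod(cache$A1, dU2)
  db2 <- colSums(dU2)
  dA1 <- dU2 %*% t(p$W2)
  dU1 <- dA1 * elu_grad(cache$U1)
  dW1 <- crossprod(cache$H, dU1)
  db1 <- colSums(dU1)
  dH <- dU1 %*% t(p$W1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dH = dH)
}

# logits: n x K; y: integer 0..K-1; returns mean cross-entropy and the
# gradient at the logits
softmax_ce <- function(logits, y) {
  n <- nrow(logits)
  m <- apply(logits, 1L, max)
  E <- exp(logits - m)
  P <- E / rowSums(E)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(P[idx], .Machine$double.xmin)))
  dL <- P
  dL[idx] <- dL[idx] - 1
  list(loss = loss, grad = dL / n, prob = P)
}

adam_init <- function(params) {
  list(m = map_params(function(x) x * 0, params),
       v = map_params(function(x) x * 0, params),
       t = 0L)
}

# one Adam step with classic L2 weight decay folded into the gradient
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (weight_decay > 0)
    grads <- map_params(function(g, p) g + weight_decay * p, grads, params)
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map_params(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                    state$m, state$v)
  params_new <- map_params(function(p, u) p - u, params, upd)
  attributes(params_new) <- attributes(params)
  list(params = params_new, state = state)
}
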
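# The contrastive objective: Gaussian-kernel similarity, uniform /
# instance-aware / top-X world representations, the triplet margin loss,
# and the exponential-moving-average target update.

#' Configure the contrastive objective
#'
#' Collects the hyperparameters of the pretraining objective.  The
#' defaults are the reference configuration: batch size 256, kernel width
#' `sigma = 2`, temperature `T = 2`, margin `delta = 0.2`, learning rate
#' `2e-4`, weight decay `1e-4`.  Because the difference of two similarities
#' sharing an anchor is bounded by `1 - exp(-2/sigma^2)` (about 0.3935 at
#' `sigma = 2`), margins below 0.1 give the hinge little room to act; a
#' warning (not an error) is issued for `delta < 0.1` at `sigma = 2`.
#'
#' @param sigma Gaussian kernel width (> 0).
#' @param delta triplet margin (> 0).
#' @param temperature temperature T (> 0) of the instance-aware
#'   (softmax-weighted) world representation; large T recovers the
#'   uniform batch average, small T concentrates on the nearest sample.
#' @param ema_lambda target-network decay `lambda` in `[0, 1]`; the
#'   target parameters follow `phi <- lambda*phi + (1-lambda)*theta`.
#' @param lr learning rate of the online network.
#' @param weight_decay L2 penalty coefficient added to the gradient.
#' @param batch_size M (>= 2).
#' @param mode `"contrawr"` (uniform world representation),
#'   `"contrawr_plus"` (per-anchor instance-aware world representation)
#'   or `"avg_knn_topx"` (average of the anchor's top-X nearest batch
#'   neighbours as the negative).
#' @param topx X for `avg_knn_topx` mode (1 <= X <= batch size); at
#'   `X = M` the mode coincides with `"contrawr"`.
#' @param exclude_self if `TRUE`, each anchor's own positive is excluded
#'   from its world representation; the default `FALSE` keeps the plain
#'   batch average.
#' @return An object of class `contrastive_config`.
#' @export
contrastive_config <- function(sigma = 2, delta = 0.2, temperature = 2,
                               ema_lambda = 0.99, lr = 2e-4,
                               weight_decay = 1e-4, batch_size = 256L,
                               mode = c("contrawr", "contrawr_plus",
                                        "avg_knn_topx"),
                               topx = NULL, exclude_self = FALSE) {
  mode <- match.arg(mode)
  if (!is_number(sigma) || sigma <= 0)
    stopf("'sigma' must be > 0, got %s", format(sigma))
  if (!is_number(delta) || delta <= 0)
    stopf("'delta' must be > 0, got %s", format(delta))
  if (!is_number(temperature) || temperature <= 0)
    stopf("'temperature' must be > 0, got %s", format(temperature))
  if (!is_number(ema_lambda) || ema_lambda < 0 || ema_lambda > 1)
    stopf("'ema_lambda' must lie in [0, 1]")
  if (!is_number(lr) || lr <= 0) stopf("'lr' must be > 0")
  if (!is_number(weight_decay) || weight_decay < 0)
    stopf("'weight_decay' must be >= 0")
  if (!is_count(batch_size, min = 2L)) stopf("'batch_size' must be >= 2")
  if (mode == "avg_knn_topx") {
    if (is.null(topx) || !is_count(topx))
      stopf("avg_knn_topx mode requires a positive integer 'topx'")
    if (topx > batch_size)
      stopf("'topx' (%d) cannot exceed the batch size (%d)", topx, batch_size)
  }
  if (sigma == 2 && delta < 0.1)
    warnf("margin delta = %g is below the recommended 0.1 for sigma = 2", delta)
  structure(list(sigma = sigma, delta = delta, temperature = temperature,
                 ema_lambda = ema_lambda, lr = lr,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), mode = mode,
                 topx = if (is.null(topx)) NULL else as.integer(topx),
                 exclude_self = isTRUE(exclude_self)),
            class = "contrastive_config")
}

check_ball <- function(x, name) {
  n2 <- sum(x^2)
  if (!is.finite(n2) || n2 > 1 + 1e-6)
    stopf("'%s' must lie in the closed unit ball (|x| <= 1)", name)
  invisible(n2)
}

#' Gaussian-kernel similarity on the unit ball
#'
#' `sim(a, b) = exp(-|a - b|^2 / (2 sigma^2))`, a similarity in `(0, 1]`
#' that equals 1 exactly when `a = b`.  On unit vectors it is a strictly
#' increasing function of cosine similarity, so it induces the same
#' ordering at any width and flattens toward cosine similarity as
#' `sigma` grows.
#'
#' @param a,b numeric vectors in the closed unit ball (projections or
#'   their averages).
#' @param sigma kernel width (> 0).
#' @return A similarity value in `(0, 1]`.
#' @examples
#' e <- c(1, 0)
#' gaussian_similarity(e, -e, sigma = 2)  # exp(-0.5)
#' @export
gaussian_similarity <- function(a, b, sigma) {
  if (!is_number(sigma) || sigma <= 0)
    stopf("'sigma' must be > 0, got %s", format(sigma))
  if (length(a) != length(b)) stopf("'a' and 'b' must have equal length")
  check_ball(a, "a"); check_ball(b, "b")
  exp(-sum((a - b)^2) / (2 * sigma^2))
}

# rows of Z against a single vector w
gauss_sim_rows <- function(Z, w, sigma) {
  exp(-(rowSums(Z^2) - 2 * drop(Z %*% w) + sum(w^2)) / (2 * sigma^2))
}

#' Uniform world representation of a batch
#'
#' The arithmetic mean of the batch projections: the single negative
#' reference the anchor is contrasted against.  As a convex combination
#' of unit vectors it lies in the closed unit ball.
#'
#' @param Z an `M x m` matrix of projections (rows on the unit sphere),
#'   `M >= 2`.
#' @return A numeric vector of length m.
#' @export
world_representation <- function(Z) {
  if (!is.matrix(Z) || nrow(Z) == 0L) stopf("batch of projections is empty")
  if (nrow(Z) < 2L) stopf("the world representation needs a batch of M >= 2")
  colMeans(Z)
}

#' Instance-aware world representation
#'
#' A softmax-weighted batch average with weights proportional to
#' `exp(<z_k, anchor> / T)`: samples close to the anchor dominate, so the
#' negative reference is "harder".  As `T -> Inf` the weights flatten to
#' the uniform [world_representation()]; as `T -> 0+` the average
#' collapses onto the batch member nearest the anchor.
#'
#' @param anchor unit vector of length m.
#' @param Z an `M x m` matrix of projections.
#' @param temperature T (> 0).
#' @return A numeric vector of length m in the closed unit ball.
#' @export
instance_aware_world_representation <- function(anchor, Z, temperature) {
  if (!is_number(temperature) || temperature <= 0)
    stopf("'temperature' must be > 0, got %s", format(temperature))
  if (!is.matrix(Z) || nrow(Z) == 0L) stopf("batch of projections is empty")
  s <- drop(Z %*% anchor) / temperature
  w <- exp(s - max(s))
  w <- w / sum(w)
  drop(crossprod(Z, w))
}

#' Top-X nearest-neighbour negative
#'
#' The mean of the `X` batch members most similar to the anchor under the
#' Gaussian kernel (equivalently, smallest Euclidean distance).  Ties are
#' broken deterministically by ascending batch index.  At `X = M` this is
#' exactly the uniform [world_representation()].
#'
#' @param anchor unit vector of length m.
#' @param Z an `M x m` matrix of projections.
#' @param X number of neighbours, `1 <= X <= M`.
#' @param sigma kernel width (the kernel is monotone in distance, so it
#'   only fixes the ordering; any positive value gives the same result).
#' @return A numeric vector of length m.
#' @export
knn_topx_negative <- function(anchor, Z, X, sigma = 2) {
  if (!is.matrix(Z) || nrow(Z) == 0L) stopf("batch of projections is empty")
  M <- nrow(Z)
  if (!is_count(X) || X > M)
    stopf("'X' must be an integer in 1..%d, got %s", M, format(X))
  if (!is_number(sigma) || sigma <= 0) stopf("'sigma' must be > 0")
  d2 <- rowSums(Z^2) - 2 * drop(Z %*% anchor) + sum(anchor^2)
  sel <- sort(order(d2)[seq_len(X)])  # ascending-index summation order
  colMeans(Z[sel, , drop = FALSE])
}

#' Triplet margin loss against the world representation
#'
#' `max(0, sim(anchor, zw) + delta - sim(anchor, positive))`: zero
#' exactly when the positive's similarity beats the world similarity by
#' at least the margin `delta`.
#'
#' @param anchor,positive unit vectors of length m (the two views'
#'   projections).
#' @param zw world representation (any vector in the closed unit ball).
#' @param sigma kernel width.
#' @param delta margin (> 0).
#' @return A non-negative loss value.
#' @export
triplet_loss <- function(anchor, positive, zw, sigma, delta) {
  if (!is_number(delta) || delta <= 0) stopf("'delta' must be > 0")
  max(0, gaussian_similarity(anchor, zw, sigma) + delta -
        gaussian_similarity(anchor, positive, sigma))
}

#' Pair anchor and positive projections into a batch
#'
#' @param anchors,positives `M x m` matrices with unit-norm rows;
#'   `anchors[i, ]` and `positives[i, ]` must be the two views of the
#'   same epoch.
#' @return An object of class `projection_batch`.
#' @export
projection_batch <- function(anchors, positives) {
  if (!is.matrix(anchors) || !is.matrix(positives))
    stopf("'anchors' and 'positives' must be matrices")
  if (!all(dim(anchors) == dim(positives)))
    stopf("anchors are %d x %d but positives are %d x %d: misaligned batch",
          nrow(anchors), ncol(anchors), nrow(positives), ncol(positives))
  if (nrow(anchors) < 2L) stopf("a projection batch needs M >= 2 pairs")
  for (nm in c("anchors", "positives")) {
    Z <- get(nm)
    bad <- abs(rowSums(Z^2) - 1) > 1e-6
    if (any(bad))
      stopf("%s row %d is not unit-norm", nm, which(bad)[1L])
  }
  structure(list(anchors = anchors, positives = positives),
            class = "projection_batch")
}

# world representation(s) for a whole batch under a config: returns an
# M x m matrix (row i = the negative used by anchor i)
batch_world <- function(anchors, positives, cfg) {
  M <- nrow(positives)
  switch(cfg$mode,
    contrawr = {
      if (cfg$exclude_self) {
        tot <- colSums(positives)
        t(vapply(seq_len(M),
                 function(i) (tot - positives[i, ]) / (M - 1),
                 numeric(ncol(positives))))
      } else {
        matrix(colMeans(positives), M, ncol(positives), byrow = TRUE)
      }
    },
    contrawr_plus = {
      S <- anchors %*% t(positives) / cfg$temperature  # M x M, row = anchor
      if (cfg$exclude_self) diag(S) <- -Inf
      S <- S - apply(S, 1L, max)
      W <- exp(S)
      W <- W / rowSums(W)
      W %*% positives
    },
    avg_knn_topx = {
      X <- cfg$topx
      if (X > M) stopf("'topx' (%d) exceeds the batch size (%d)", X, M)
      out <- matrix(0, M, ncol(positives))
      for (i in seq_len(M)) {
        d2 <- rowSums(positives^2) - 2 * drop(positives %*% anchors[i, ]) +
          sum(anchors[i, ]^2)
        if (cfg$exclude_self) d2[i] <- Inf
        sel <- sort(order(d2)[seq_len(X)])
        out[i, ] <- colMeans(positives[sel, , drop = FALSE])
      }
      out
    })
}

# loss pieces shared by batch_loss() and the training gradient
batch_loss_pieces <- function(anchors, positives, cfg) {
  ZW <- batch_world(anchors, positives, cfg)
  simw <- exp(-rowSums((anchors - ZW)^2) / (2 * cfg$sigma^2))
  simp <- exp(-rowSums((anchors - positives)^2) / (2 * cfg$sigma^2))
  per <- pmax(0, simw + cfg$delta - simp)
  list(loss = mean(per), per = per, ZW = ZW, simw = simw, simp = simp)
}

#' Mean triplet loss of a projection batch
#'
#' Computes the per-anchor world representation according to
#' `cfg$mode`, evaluates each anchor's triplet loss, and returns the
#' batch mean.  In training both the positives and the world
#' representation come from the target network and receive no gradient.
#'
#' @param batch a [projection_batch()].
#' @param cfg a [contrastive_config()].
#' @return The mean loss (a non-negative scalar).
#' @export
batch_loss <- function(batch, cfg) {
  stopifnot(inherits(batch, "projection_batch"),
            inherits(cfg, "contrastive_config"))
  batch_loss_pieces(batch$anchors, batch$positives, cfg)$loss
}

# gradient of the mean triplet loss with respect to the anchors, with
# positives and world representations treated as constants (stop-gradient)
batch_loss_grad <- function(anchors, positives, cfg) {
  p <- batch_loss_pieces(anchors, positives, cfg)
  M <- nrow(anchors)
  act <- as.numeric(p$per > 0) / (M * cfg$sigma^2)
  dA <- act * (p$simp * (anchors - positives) - p$simw * (anchors - p$ZW))
  list(loss = p$loss, dAnchors = dA)
}

#' Exponential-moving-average update of the target parameters
#'
#' Replaces every target parameter by `lambda * phi + (1 - lambda) *
#' theta`, elementwise, using the just-updated online parameters
#' `theta`.  The target network therefore tracks a slowly moving convex
#' combination of the online network's history: at `lambda = 1` it never
#' moves, at `lambda = 0` it copies `theta` exactly.
#'
#' @param theta online parameters (nested list of numeric arrays).
#' @param phi target parameters, structurally identical to `theta`.
#' @param lambda decay in `[0, 1]`.
#' @return The updated target parameters (same structure).
#' @export
ema_update <- function(theta, phi, lambda) {
  if (!is_number(lambda) || lambda < 0 || lambda > 1)
    stopf("'lambda' must lie in [0, 1]")
  out <- map_params(function(th, ph) lambda * ph + (1 - lambda) * th,
                    theta, phi)
  attributes(out) <- attributes(phi)
  out
}
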
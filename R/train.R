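# Pretraining loop, frozen-encoder linear probe, supervised reference
# model, untrained baseline, and the label-fraction sweep protocol.

#' Split subjects into pretrain / train / test sets
#'
#' Splits at the subject level, so every epoch of a subject lands in
#' exactly one set (epochs of one participant are strongly correlated;
#' splitting them across sets would leak information).  Counts are
#' allocated by largest remainder so they sum to the number of subjects.
#'
#' @param subjects character vector of subject ids (one per epoch, or
#'   already unique).
#' @param fracs named numeric vector `c(pretrain = , train = , test = )`
#'   of proportions summing to 1.
#' @param seed integer seed for the shuffle.
#' @return A list with character elements `pretrain`, `train`, `test`.
#' @export
split_subjects <- function(subjects, fracs = c(pretrain = 0.6, train = 0.2,
                                               test = 0.2), seed = 1L) {
  ids <- unique(as.character(subjects))
  if (!is.numeric(fracs) || length(fracs) != 3L ||
      abs(sum(fracs) - 1) > 1e-8 || any(fracs < 0))
    stopf("'fracs' must be 3 non-negative proportions summing to 1")
  if (is.null(names(fracs))) names(fracs) <- c("pretrain", "train", "test")
  n <- length(ids)
  raw <- fracs * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1L
  }
  bad <- fracs > 0 & cnt < 1L
  if (any(bad))
    stopf("fraction %g yields < 1 subject in the '%s' split (n = %d subjects)",
          fracs[bad][1L], names(fracs)[bad][1L], n)
  perm <- with_seed(seed, sample(ids))
  ends <- cumsum(cnt)
  out <- list(pretrain = perm[seq_len(cnt[1L])],
              train = if (cnt[2L] > 0) perm[(ends[1L] + 1L):ends[2L]] else character(0),
              test = if (cnt[3L] > 0) perm[(ends[2L] + 1L):ends[3L]] else character(0))
  stopifnot(!anyDuplicated(unlist(out)))
  out
}

#' Partition a dataset according to a subject split
#'
#' @param ds an [epoch_dataset()].
#' @param split a list of subject-id vectors, as from [split_subjects()].
#' @return A list of `epoch_dataset`s named like `split`; the pretrain
#'   member has its labels stripped.
#' @export
split_dataset <- function(ds, split) {
  stopifnot(inherits(ds, "epoch_dataset"))
  out <- lapply(split, function(ids) {
    idx <- which(ds$subject %in% ids)
    if (!length(idx)) stopf("a split contains no epochs")
    subset_epochs(ds, idx)
  })
  if ("pretrain" %in% names(out))
    out$pretrain <- strip_labels(out$pretrain)
  out
}

# assemble the trainable parameter list and pull gradients into the same
# structure
encoder_grads <- function(conv_grads, proj_grads) {
  list(conv_w = conv_grads$dw, conv_b = conv_grads$db, proj = proj_grads)
}

# one forward/backward pass of the online branch on a spectrogram batch;
# returns anchors, loss and parameter gradients
online_step <- function(sp_online, positives, theta, cfg) {
  fw <- cnn_forward_cpp(sp_online, theta$conv_w, theta$conv_b, TRUE)
  pf <- mlp_forward(fw$h, theta$proj, normalize = TRUE)
  lg <- batch_loss_grad(pf$Z, positives, cfg)
  mb <- mlp_backward(pf$cache, theta$proj, lg$dAnchors)
  cg <- cnn_backward_cpp(fw$cache, theta$conv_w, theta$conv_b, mb$dH)
  list(loss = lg$loss, grads = encoder_grads(cg, mb$grads))
}

# target-branch projections (no gradient)
target_projections <- function(sp_target, phi) {
  fw <- cnn_forward_cpp(sp_target, phi$conv_w, phi$conv_b, FALSE)
  mlp_forward(fw$h, phi$proj, normalize = TRUE)$Z
}

# augment a batch (column layout) into two independent views, drawing
# from the ambient RNG stream
augment_batch_views <- function(X, n, C, fs, policy) {
  list(augment_views_cols(X, n, C, fs, policy),
       augment_views_cols(X, n, C, fs, policy))
}

#' Self-supervised pretraining of the encoder
#'
#' Runs the two-branch contrastive loop: each batch epoch is augmented
#' into two views; the online network encodes and projects one view into
#' the anchor, the target network the other into the positive; the
#' anchors are pulled toward their positives and pushed from the world
#' representation by the Gaussian-kernel triplet loss; the online
#' parameters take an Adam step and the target parameters follow by
#' exponential moving average.  Labels are stripped on entry and never
#' read.
#'
#' @param ds an [epoch_dataset()] (labels, if any, are ignored).
#' @param cfg a [contrastive_config()].
#' @param spec an [encoder_spec()] matching the epochs.
#' @param policy an [augmentation_policy()].
#' @param epochs number of passes over the pretrain set (a training
#'   epoch, not a signal epoch).
#' @param seed integer seed; fixes initialization, batch order and every
#'   augmentation draw, so two runs with the same seed produce identical
#'   loss histories.
#' @param verbose print the per-pass mean loss.
#' @return An object of class `contrawr_fit`: list with the online
#'   `params` (an `encoder_params`), the target `target_params`, the
#'   per-pass mean `loss_history`, and the call configuration.
#' @export
pretrain <- function(ds, cfg, spec, policy, epochs = 30L, seed = 1L,
                     verbose = FALSE) {
  stopifnot(inherits(ds, "epoch_dataset"), inherits(cfg, "contrastive_config"),
            inherits(spec, "encoder_spec"),
            inherits(policy, "augmentation_policy"))
  if (!is_count(epochs, min = 0L)) stopf("'epochs' must be a non-negative integer")
  ds <- strip_labels(ds)
  n <- n_epochs(ds)
  M <- cfg$batch_size
  if (M > n)
    stopf("batch size (%d) exceeds the pretrain set size (%d)", M, n)
  if (dim(ds$signals)[2L] != spec$C || dim(ds$signals)[3L] != spec$N)
    stopf("dataset epochs do not match the encoder spec geometry")

  with_seed(seed, {
    theta <- init_encoder(spec, seed = draw_seeds(1L))
    phi <- theta  # target initialized as a copy of the online network
    opt <- adam_init(theta)
    loss_history <- numeric(0)
    if (epochs > 0L) {
      for (pass in seq_len(epochs)) {
        perm <- sample.int(n)
        nb <- n %/% M  # trailing partial batch dropped
        losses <- numeric(nb)
        for (b in seq_len(nb)) {
          idx <- perm[((b - 1L) * M + 1L):(b * M)]
          Xb <- signals_to_cols(ds$signals[idx, , , drop = FALSE])
          views <- augment_batch_views(Xb, M, spec$C, ds$fs, policy)
          sp_on <- spect_input_cols(views[[1L]], M, spec)
          sp_tg <- spect_input_cols(views[[2L]], M, spec)
          positives <- target_projections(sp_tg, phi)
          st <- online_step(sp_on, positives, theta, cfg)
          upd <- adam_step(theta, st$grads, opt, lr = cfg$lr,
                           weight_decay = cfg$weight_decay)
          theta <- upd$params
          opt <- upd$state
          phi <- ema_update(theta, phi, cfg$ema_lambda)
          losses[b] <- st$loss
        }
        loss_history[pass] <- mean(losses)
        if (verbose)
          message(sprintf("pass %3d/%d  mean loss %.5f", pass, epochs,
                          loss_history[pass]))
      }
    }
    structure(list(params = theta, target_params = phi,
                   loss_history = loss_history, cfg = cfg, spec = spec,
                   policy = policy, epochs = as.integer(epochs),
                   seed = as.integer(seed)),
              class = "contrawr_fit")
  })
}

#' @export
print.contrawr_fit <- function(x, ...) {
  cat(sprintf("<contrawr_fit> mode %s | %d passes | final mean loss %s\n",
              x$cfg$mode, x$epochs,
              if (length(x$loss_history))
                sprintf("%.5f", x$loss_history[length(x$loss_history)])
              else "(not trained)"))
  invisible(x)
}

#' Freshly initialized (untrained) encoder baseline
#'
#' The control every pretrained encoder is compared against: the same
#' architecture with random parameters, never optimized, probed exactly
#' like a trained encoder.
#'
#' @param spec an [encoder_spec()].
#' @param seed integer seed.
#' @return An `encoder_params` object.
#' @export
untrained_baseline <- function(spec, seed = 1L) init_encoder(spec, seed)

#' Fit a multinomial logistic probe on fixed features
#'
#' Ridge-penalized multinomial logistic regression
#' ([glmnet::glmnet()] with `alpha = 0`), with the penalty strength
#' chosen by accuracy on a stratified validation fifth carved from the
#' training features (light, deterministic tuning), then refit on all
#' training rows.
#'
#' @param features numeric `n x d` matrix.
#' @param labels integer class codes of length n (at least 2 classes).
#' @param test_features,test_labels held-out rows to score.
#' @param seed integer seed for the validation carve-out.
#' @return A list: `accuracy`, `confusion` (K x K, rows = truth, columns
#'   = prediction), `per_class_recall`, `lambda` (chosen penalty),
#'   `classes`.
#' @export
fit_linear_probe <- function(features, labels, test_features, test_labels,
                             seed = 1L) {
  if (!is.matrix(features) || nrow(features) != length(labels))
    stopf("'features' must be a matrix with one row per label")
  classes <- sort(unique(as.integer(labels)))
  if (length(classes) < 2L)
    stopf("the probe needs at least 2 classes in the training set")
  missing <- setdiff(unique(as.integer(test_labels)), classes)
  if (length(missing))
    stopf("class %d present in the test set but absent from training",
          missing[1L])
  # standardize with training statistics
  mu <- colMeans(features)
  sg <- apply(features, 2L, sd)
  sg[!is.finite(sg) | sg < 1e-12] <- 1
  scale_f <- function(X) sweep(sweep(X, 2L, mu, "-"), 2L, sg, "/")
  Xtr <- scale_f(features)
  Xte <- scale_f(test_features)
  y <- factor(as.integer(labels), levels = classes)
  lam <- 10^seq(1, -5, length.out = 25)

  # stratified 80/20 carve-out to pick the penalty
  val_idx <- with_seed(seed, {
    unlist(lapply(classes, function(k) {
      rows <- which(as.integer(labels) == k)
      if (length(rows) >= 5L) sample(rows, max(1L, round(length(rows) / 5)))
      else integer(0)
    }))
  })
  pick <- length(lam)  # fall back to the smallest penalty
  if (length(val_idx) >= 2L &&
      length(unique(labels[-val_idx])) == length(classes)) {
    fit0 <- glmnet::glmnet(Xtr[-val_idx, , drop = FALSE],
                           droplevels(y[-val_idx]),
                           family = "multinomial", alpha = 0, lambda = lam,
                           standardize = FALSE)
    pred <- predict(fit0, Xtr[val_idx, , drop = FALSE], type = "class")
    acc <- apply(pred, 2L, function(p) mean(p == as.character(y[val_idx])))
    pick <- which.max(acc)  # ties -> largest penalty (earliest in path)
  }
  fit <- glmnet::glmnet(Xtr, y, family = "multinomial", alpha = 0,
                        lambda = lam, standardize = FALSE)
  yhat <- as.integer(predict(fit, Xte, type = "class", s = lam[pick]))
  truth <- as.integer(test_labels)
  accuracy <- mean(yhat == truth)
  confusion <- table(factor(truth, levels = classes),
                     factor(yhat, levels = classes))
  confusion <- matrix(confusion, nrow = length(classes),
                      dimnames = list(truth = classes, predicted = classes))
  recall <- diag(confusion) / pmax(rowSums(confusion), 1L)
  list(accuracy = accuracy, confusion = confusion,
       per_class_recall = recall, lambda = lam[pick], classes = classes)
}

#' Linear-probe evaluation of a frozen encoder
#'
#' The standard evaluation of a self-supervised encoder: representations
#' of the labeled training epochs are extracted with the frozen encoder,
#' a multinomial logistic classifier is fit on them, and accuracy is
#' reported on the test epochs.  The encoder parameters are never
#' updated.
#'
#' @param encoder encoder parameters or a [pretrain()] fit.
#' @param train_set,test_set labeled [epoch_dataset()]s drawn from the
#'   same classes.
#' @param seed integer seed for the probe's validation carve-out.
#' @return As [fit_linear_probe()].
#' @export
linear_probe <- function(encoder, train_set, test_set, seed = 1L) {
  params <- as_encoder_params(encoder)
  for (nm in c("train_set", "test_set")) {
    s <- get(nm)
    if (!inherits(s, "epoch_dataset") || is.null(s$labels))
      stopf("'%s' must be a labeled epoch_dataset", nm)
  }
  Htr <- encode_batch(train_set, params)
  Hte <- encode_batch(test_set, params)
  fit_linear_probe(Htr, train_set$labels, Hte, test_set$labels, seed = seed)
}

#' Supervised reference model
#'
#' Trains the same STFT-CNN encoder together with a 2-layer
#' fully-connected classification head, end to end from scratch with
#' cross-entropy on the labeled training set only (no pretraining, no
#' augmentation), as the supervised reference the self-supervised
#' pipeline is compared against.
#'
#' @param train_set a labeled [epoch_dataset()] with at least 2 classes.
#' @param spec an [encoder_spec()]; `spec$head_hidden` sets the head
#'   width.
#' @param epochs passes over the training set.
#' @param lr,weight_decay,batch_size optimizer settings.
#' @param seed integer seed.
#' @param verbose print per-pass loss.
#' @return An object of class `supervised_fit` with `params` (encoder),
#'   `head`, `classes` and `loss_history`.
#' @export
train_supervised <- function(train_set, spec, epochs = 30L, lr = 1e-3,
                             weight_decay = 1e-4, batch_size = 32L,
                             seed = 1L, verbose = FALSE) {
  stopifnot(inherits(train_set, "epoch_dataset"), inherits(spec, "encoder_spec"))
  if (is.null(train_set$labels)) stopf("supervised training needs labels")
  classes <- sort(unique(train_set$labels))
  if (length(classes) < 2L)
    stopf("supervised training needs at least 2 classes, got %d",
          length(classes))
  if (!is_count(epochs, min = 0L)) stopf("'epochs' must be a non-negative integer")
  n <- n_epochs(train_set)
  M <- min(as.integer(batch_size), n)
  K <- length(classes)
  y <- match(train_set$labels, classes) - 1L

  with_seed(seed, {
    enc <- init_encoder(spec, seed = draw_seeds(1L))
    head <- list(W1 = init_linear(spec$repr_dim, spec$head_hidden),
                 b1 = numeric(spec$head_hidden),
                 W2 = init_linear(spec$head_hidden, K),
                 b2 = numeric(K))
    params <- list(conv_w = enc$conv_w, conv_b = enc$conv_b, head = head)
    opt <- adam_init(params)
    loss_history <- numeric(0)
    if (epochs > 0L) {
      for (pass in seq_len(epochs)) {
        perm <- sample.int(n)
        nb <- max(1L, n %/% M)
        losses <- numeric(nb)
        for (b in seq_len(nb)) {
          idx <- perm[((b - 1L) * M + 1L):min(b * M, n)]
          sp <- spect_input(train_set$signals[idx, , , drop = FALSE], spec)
          fw <- cnn_forward_cpp(sp, params$conv_w, params$conv_b, TRUE)
          hf <- mlp_forward(fw$h, params$head, normalize = FALSE)
          ce <- softmax_ce(hf$Z, y[idx])
          hb <- mlp_backward(hf$cache, params$head, ce$grad)
          cg <- cnn_backward_cpp(fw$cache, params$conv_w, params$conv_b,
                                 hb$dH)
          grads <- list(conv_w = cg$dw, conv_b = cg$db, head = hb$grads)
          upd <- adam_step(params, grads, opt, lr = lr,
                           weight_decay = weight_decay)
          params <- upd$params
          opt <- upd$state
          losses[b] <- ce$loss
        }
        loss_history[pass] <- mean(losses)
        if (verbose)
          message(sprintf("pass %3d/%d  CE loss %.5f", pass, epochs,
                          loss_history[pass]))
      }
    }
    enc_out <- list(conv_w = params$conv_w, conv_b = params$conv_b,
                    proj = enc$proj)
    attr(enc_out, "spec") <- spec
    class(enc_out) <- "encoder_params"
    structure(list(params = enc_out, head = params$head, classes = classes,
                   loss_history = loss_history, spec = spec,
                   seed = as.integer(seed)),
              class = "supervised_fit")
  })
}

#' Predict classes with a supervised fit
#'
#' @param fit a [train_supervised()] fit.
#' @param ds an [epoch_dataset()].
#' @return A list with `labels` (predicted class codes), `prob`
#'   (`n x K` softmax matrix) and, when `ds` is labeled, `accuracy`.
#' @export
predict_supervised <- function(fit, ds) {
  stopifnot(inherits(fit, "supervised_fit"), inherits(ds, "epoch_dataset"))
  H <- encode_batch(ds, fit$params)
  logits <- mlp_forward(H, fit$head, normalize = FALSE)$Z
  m <- apply(logits, 1L, max)
  P <- exp(logits - m)
  P <- P / rowSums(P)
  pred <- fit$classes[max.col(P, ties.method = "first")]
  out <- list(labels = pred, prob = P)
  if (!is.null(ds$labels)) out$accuracy <- mean(pred == ds$labels)
  out
}

#' Label-fraction sweep
#'
#' Measures how probe accuracy depends on the amount of labeled training
#' data.  The test subjects are held fixed; for each fraction and seed
#' the remaining subjects are re-split into a labeled training set of
#' roughly `fraction` of all subjects and an unlabeled pretrain set of
#' the rest, the encoder is pretrained and probed, and the supervised
#' reference is trained on the same labeled subjects.
#'
#' @param ds a labeled [epoch_dataset()].
#' @param fractions numeric vector of training proportions in (0, 1).
#' @param cfg,spec,policy as for [pretrain()].
#' @param epochs pretraining passes per run.
#' @param supervised_epochs passes for the supervised reference.
#' @param seeds integer vector (>= 1) of run seeds; results aggregate
#'   over them.
#' @param test_frac held-out test proportion (fixed across fractions).
#' @param split_seed seed fixing the test subjects.
#' @param verbose print progress.
#' @return A list of class `label_fraction_sweep`: `results` (tidy
#'   data.frame: fraction, method, seed, accuracy) and `summary`
#'   (mean and SD per fraction x method).
#' @export
label_fraction_sweep <- function(ds, fractions, cfg, spec, policy,
                                 epochs = 15L, supervised_epochs = 30L,
                                 seeds = 1:3, test_frac = 0.2,
                                 split_seed = 1L, verbose = FALSE) {
  stopifnot(inherits(ds, "epoch_dataset"))
  if (is.null(ds$labels)) stopf("the sweep needs a labeled dataset")
  if (any(fractions <= 0 | fractions >= 1))
    stopf("'fractions' must lie strictly inside (0, 1)")
  if (!length(seeds)) stopf("'seeds' must not be empty")
  ids <- unique(ds$subject)
  n_sub <- length(ids)
  n_test <- max(1L, round(test_frac * n_sub))
  test_ids <- with_seed(split_seed, sample(ids, n_test))
  rest <- setdiff(ids, test_ids)
  test_set <- subset_epochs(ds, which(ds$subject %in% test_ids))

  rows <- list()
  for (f in fractions) {
    n_train <- round(f * n_sub)
    if (n_train < 1L)
      stopf("fraction %g yields < 1 training subject (n = %d subjects)",
            f, n_sub)
    if (n_train >= length(rest))
      stopf("fraction %g leaves an empty pretrain set", f)
    for (s in seeds) {
      train_ids <- with_seed(s * 1009L + round(1e4 * f),
                             sample(rest, n_train))
      pre_ids <- setdiff(rest, train_ids)
      train_set <- subset_epochs(ds, which(ds$subject %in% train_ids))
      pre_set <- strip_labels(subset_epochs(ds,
                                            which(ds$subject %in% pre_ids)))
      cfg_run <- cfg
      cfg_run$batch_size <- min(cfg$batch_size, n_epochs(pre_set))
      fit <- pretrain(pre_set, cfg_run, spec, policy, epochs = epochs,
                      seed = s)
      probe <- linear_probe(fit, train_set, test_set, seed = s)
      sup <- train_supervised(train_set, spec, epochs = supervised_epochs,
                              batch_size = cfg$batch_size, seed = s)
      sup_acc <- predict_supervised(sup, test_set)$accuracy
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, method = c(cfg$mode, "supervised"), seed = s,
        accuracy = c(probe$accuracy, sup_acc))
      if (verbose)
        message(sprintf("fraction %.3f seed %d: probe %.3f supervised %.3f",
                        f, s, probe$accuracy, sup_acc))
    }
  }
  results <- do.call(rbind, rows)
  agg_m <- stats::aggregate(accuracy ~ fraction + method, results, mean)
  agg_s <- stats::aggregate(accuracy ~ fraction + method, results, sd)
  summary <- data.frame(agg_m[, c("fraction", "method")],
                        mean_accuracy = agg_m$accuracy,
                        sd_accuracy = agg_s$accuracy)
  structure(list(results = results, summary = summary,
                 test_subjects = test_ids),
            class = "label_fraction_sweep")
}

#' @export
print.label_fraction_sweep <- function(x, ...) {
  cat("<label_fraction_sweep>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
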
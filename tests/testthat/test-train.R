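# Training protocol: subject-split integrity, pretraining determinism and
# loss descent, probe correctness, supervised reference, and the sweep
# bookkeeping.  All runs use the tiny two-class geometry so each test
# stays in the seconds range.

tiny_policy <- function() augmentation_policy(max_shift = 25)

tiny_cfg <- function(M = 16L, mode = "contrawr_plus")
  contrastive_config(batch_size = M, mode = mode, lr = 1e-3)

test_that("subject splits are disjoint, exhaustive and seeded", {
  subjects <- sprintf("S%02d", 1:17)
  sp <- split_subjects(subjects, c(pretrain = 0.6, train = 0.2, test = 0.2),
                       seed = 5)
  all_ids <- unlist(sp)
  expect_setequal(all_ids, subjects)
  expect_identical(anyDuplicated(all_ids), 0L)
  expect_identical(sp, split_subjects(subjects, seed = 5))
  expect_false(identical(sp, split_subjects(subjects, seed = 6)))
  expect_error(split_subjects(sprintf("S%d", 1:3),
                              c(pretrain = 0.9, train = 0.05, test = 0.05)),
               "< 1 subject")
})

test_that("split_dataset partitions epochs and strips pretrain labels", {
  ds <- tiny_dataset(n_subjects = 6, epochs_per_subject = 4)
  parts <- split_dataset(ds, split_subjects(ds$subject, seed = 2))
  expect_identical(sum(vapply(parts, n_epochs, 0L)), n_epochs(ds))
  expect_null(parts$pretrain$labels)
  expect_false(is.null(parts$train$labels))
  ids <- lapply(parts, function(p) unique(p$subject))
  expect_identical(anyDuplicated(unlist(ids)), 0L)
})

test_that("pretraining is reproducible and honours the epoch count", {
  ds <- tiny_dataset(n_subjects = 4, epochs_per_subject = 8)
  spec <- tiny_spec()
  f0 <- pretrain(ds, tiny_cfg(), spec, tiny_policy(), epochs = 0, seed = 3)
  expect_length(f0$loss_history, 0)
  expect_identical(unclass(f0$params), unclass(init_encoder(spec,
    with_seed(3, contrawr:::draw_seeds(1L)))))

  f1 <- pretrain(ds, tiny_cfg(), spec, tiny_policy(), epochs = 2, seed = 3)
  f2 <- pretrain(ds, tiny_cfg(), spec, tiny_policy(), epochs = 2, seed = 3)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$params, f2$params)
  f3 <- pretrain(ds, tiny_cfg(), spec, tiny_policy(), epochs = 2, seed = 4)
  expect_false(identical(f1$loss_history, f3$loss_history))

  expect_error(pretrain(subset_epochs(ds, 1:8), tiny_cfg(M = 16L), spec,
                        tiny_policy(), epochs = 1),
               "batch size")
})

test_that("pretraining never reads labels", {
  ds <- tiny_dataset(n_subjects = 4, epochs_per_subject = 8)
  unlabeled <- strip_labels(ds)
  f_lab <- pretrain(ds, tiny_cfg(), tiny_spec(), tiny_policy(),
                    epochs = 2, seed = 9)
  f_unl <- pretrain(unlabeled, tiny_cfg(), tiny_spec(), tiny_policy(),
                    epochs = 2, seed = 9)
  expect_identical(f_lab$loss_history, f_unl$loss_history)
  expect_identical(f_lab$params, f_unl$params)
})

test_that("the pretraining loss trends downward on separable data", {
  ds <- tiny_dataset(n_subjects = 8, epochs_per_subject = 25)  # 200 epochs
  spec <- tiny_spec()
  wins <- vapply(1:5, function(s) {
    fit <- pretrain(ds, tiny_cfg(M = 32L), spec, tiny_policy(),
                    epochs = 12, seed = s)
    lh <- fit$loss_history
    tail(lh, 1) < lh[1]
  }, TRUE)
  expect_gte(sum(wins), 4)
})

test_that("the target network stays a convex combination of the history", {
  ds <- tiny_dataset(n_subjects = 4, epochs_per_subject = 8)
  fit <- pretrain(ds, tiny_cfg(), tiny_spec(), tiny_policy(),
                  epochs = 2, seed = 5)
  # after EMA updates the target differs from both init and online params,
  # and every target weight lies between the componentwise extremes seen
  th <- fit$params$conv_w[[1]]
  ph <- fit$target_params$conv_w[[1]]
  init <- init_encoder(tiny_spec(),
                       with_seed(5, contrawr:::draw_seeds(1L)))$conv_w[[1]]
  expect_false(identical(ph, th))
  expect_false(identical(ph, init))
  expect_true(all(ph <= pmax(init, th) + 1e-6 |
                    ph >= pmin(init, th) - 1e-6))
})

test_that("the probe is exact on one-hot features and near chance on noise", {
  K <- 5L
  y <- rep_len(0:(K - 1L), 200L)
  X <- diag(K)[y + 1L, ] + matrix(rnorm(length(y) * K, sd = 0.01),
                                  ncol = K)
  probe <- fit_linear_probe(X[1:100, ], y[1:100], X[101:200, ], y[101:200])
  expect_identical(probe$accuracy, 1)
  expect_identical(sum(diag(probe$confusion)) / sum(probe$confusion),
                   probe$accuracy)

  # shuffled labels: accuracy within the chance band
  accs <- vapply(1:5, function(s) {
    set.seed(s)
    ys <- sample(y)
    Xr <- matrix(rnorm(length(y) * 8), ncol = 8)
    fit_linear_probe(Xr[1:100, ], ys[1:100], Xr[101:200, ],
                     ys[101:200], seed = s)$accuracy
  }, 0)
  expect_true(all(accs >= 0.1 & accs <= 0.3))
})

test_that("the probe errors when a test class is missing from training", {
  X <- matrix(rnorm(60 * 3), 60)
  y_tr <- rep(0:1, 15)
  y_te <- rep(0:2, 10)
  expect_error(fit_linear_probe(X[1:30, ], y_tr, X[31:60, ], y_te),
               "class 2")
})

test_that("linear_probe freezes the encoder and reports a consistent matrix", {
  ds <- tiny_dataset(n_subjects = 6, epochs_per_subject = 6)
  parts <- split_dataset(ds, split_subjects(ds$subject, seed = 1))
  params <- untrained_baseline(tiny_spec(), seed = 2)
  before <- contrawr:::param_sumsq(unclass(params))
  probe <- linear_probe(params, parts$train, parts$test)
  expect_identical(contrawr:::param_sumsq(unclass(params)), before)
  expect_identical(sum(probe$confusion), n_epochs(parts$test))
  expect_equal(sum(diag(probe$confusion)) / sum(probe$confusion),
               probe$accuracy)
  expect_error(linear_probe(params, strip_labels(parts$train), parts$test),
               "labeled")
})

test_that("the supervised reference fits separable data and is seeded", {
  ds <- tiny_dataset(n_subjects = 6, epochs_per_subject = 10)
  spec <- tiny_spec()
  fit <- train_supervised(ds, spec, epochs = 40, batch_size = 30, seed = 1)
  acc_train <- predict_supervised(fit, ds)$accuracy
  expect_gte(acc_train, 0.95)

  fit2 <- train_supervised(ds, spec, epochs = 40, batch_size = 30, seed = 1)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$head, fit2$head)

  single <- subset_epochs(ds, which(ds$labels == 0))
  expect_error(train_supervised(single, spec), "2 classes")
})

test_that("an untrained supervised head predicts near chance", {
  ds <- tiny_dataset(n_subjects = 6, epochs_per_subject = 10)
  accs <- vapply(1:5, function(s) {
    fit <- train_supervised(ds, tiny_spec(), epochs = 0, seed = s)
    predict_supervised(fit, ds)$accuracy
  }, 0)
  expect_gt(mean(accs), 0.25)
  expect_lt(mean(accs), 0.75)
})

test_that("untrained baselines differ across seeds but not within", {
  spec <- tiny_spec()
  expect_identical(untrained_baseline(spec, 3), untrained_baseline(spec, 3))
  expect_false(identical(untrained_baseline(spec, 3),
                         untrained_baseline(spec, 4)))
})

test_that("the label-fraction sweep keeps its bookkeeping straight", {
  ds <- tiny_dataset(n_subjects = 20, epochs_per_subject = 6)
  cfg <- tiny_cfg(M = 8L)
  sw <- label_fraction_sweep(ds, fractions = c(0.1, 0.2), cfg, tiny_spec(),
                             tiny_policy(), epochs = 2,
                             supervised_epochs = 2, seeds = 1:2)
  expect_identical(nrow(sw$results), 2L * 2L * 2L)  # fractions x methods x seeds
  expect_identical(nrow(sw$summary), 4L)
  expect_setequal(unique(sw$results$method), c("contrawr_plus", "supervised"))
  expect_true(all(sw$results$accuracy >= 0 & sw$results$accuracy <= 1))

  expect_error(label_fraction_sweep(ds, fractions = 0.01, cfg, tiny_spec(),
                                    tiny_policy(), seeds = 1),
               "< 1 training subject")
  expect_error(label_fraction_sweep(ds, fractions = 0.8, cfg, tiny_spec(),
                                    tiny_policy(), seeds = 1),
               "pretrain")
})
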
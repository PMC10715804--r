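# Gaussian-kernel similarity, world representations, triplet loss and the
# EMA target update, checked against closed forms and brute-force oracles.

test_that("gaussian similarity matches its closed form and bounds", {
  e <- c(1, 0, 0)
  expect_identical(gaussian_similarity(e, e, sigma = 2), 1)
  # antipodal unit vectors: distance 2
  expect_equal(gaussian_similarity(e, -e, sigma = 2), exp(-0.5))
  expect_equal(gaussian_similarity(e, -e, sigma = 1), exp(-2))

  set.seed(1)
  for (i in 1:50) {
    a <- random_unit(5); b <- random_unit(5)
    s <- gaussian_similarity(a, b, sigma = 2)
    expect_gt(s, 0); expect_lte(s, 1)
    expect_equal(s, gaussian_similarity(b, a, sigma = 2))  # symmetry
  }
  expect_error(gaussian_similarity(e, e, sigma = 0), "sigma")
  expect_error(gaussian_similarity(3 * e, e, sigma = 2), "unit ball")
})

test_that("similarity is monotone in cosine similarity on the sphere", {
  set.seed(2)
  a <- random_unit(4)
  cosines <- seq(-1, 1, length.out = 21)
  b0 <- random_unit(4)
  # construct vectors with prescribed cosine against a
  perp <- b0 - sum(b0 * a) * a
  perp <- perp / sqrt(sum(perp^2))
  sims <- vapply(cosines, function(cc)
    gaussian_similarity(a, cc * a + sqrt(1 - cc^2) * perp, sigma = 2), 0)
  expect_true(all(diff(sims) > 0))
})

test_that("world representation equals the brute-force mean", {
  Z <- unit_rows(8, 5, seed = 3)
  zw <- world_representation(Z)
  oracle <- vapply(seq_len(ncol(Z)), function(j) sum(Z[, j]) / nrow(Z), 0)
  expect_equal(zw, oracle, tolerance = 1e-12)
  expect_lte(sqrt(sum(zw^2)), 1 + 1e-12)

  expect_equal(world_representation(rbind(c(1, 0), c(-1, 0))), c(0, 0))
  z <- c(0.6, 0.8)
  expect_equal(world_representation(rbind(z, z, z)), z)
  expect_error(world_representation(matrix(numeric(0), 0, 3)), "empty")
})

test_that("instance-aware world representation matches a softmax oracle", {
  Z <- unit_rows(3, 4, seed = 4)
  anchor <- random_unit(4)
  zw <- instance_aware_world_representation(anchor, Z, temperature = 2)
  w <- exp(drop(Z %*% anchor) / 2)
  w <- w / sum(w)
  oracle <- w[1] * Z[1, ] + w[2] * Z[2, ] + w[3] * Z[3, ]
  expect_equal(zw, oracle, tolerance = 1e-10)
  expect_error(instance_aware_world_representation(anchor, Z, 0),
               "temperature")
})

test_that("instance-aware weights interpolate between mean and argmax", {
  Z <- unit_rows(6, 5, seed = 5)
  anchor <- random_unit(5)
  # T -> Inf: uniform mean
  expect_equal(instance_aware_world_representation(anchor, Z, 1e9),
               world_representation(Z), tolerance = 1e-6)
  # T -> 0: the unique nearest member
  nearest <- Z[which.max(drop(Z %*% anchor)), ]
  expect_equal(instance_aware_world_representation(anchor, Z, 1e-9),
               nearest, tolerance = 1e-6)
})

test_that("instance-aware weights are a monotone probability vector", {
  set.seed(6)
  for (i in 1:20) {
    Z <- unit_rows(7, 4)
    anchor <- random_unit(4)
    s <- drop(Z %*% anchor) / 2
    w <- exp(s - max(s)); w <- w / sum(w)
    expect_true(all(w > 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(diff(w[order(s)]) >= -1e-15))
  }
})

test_that("knn top-X negative matches a sort-and-average oracle", {
  Z <- unit_rows(4, 3, seed = 7)
  anchor <- random_unit(3)
  d2 <- rowSums(sweep(Z, 2, anchor)^2)
  ord <- order(d2)
  expect_equal(knn_topx_negative(anchor, Z, 2),
               colMeans(Z[sort(ord[1:2]), , drop = FALSE]), tolerance = 1e-12)
  expect_equal(knn_topx_negative(anchor, Z, 1), Z[ord[1], ])
  # X = M reduces to the uniform world representation, bitwise
  expect_identical(knn_topx_negative(anchor, Z, 4), colMeans(Z))
  expect_error(knn_topx_negative(anchor, Z, 5), "X")
})

test_that("triplet loss hinges at the margin", {
  e <- c(1, 0, 0)
  # positive identical to the world representation: loss = delta
  z <- random_unit(3)
  zw <- z
  expect_equal(triplet_loss(e, z, zw, sigma = 2, delta = 0.2), 0.2)
  # perfect positive, distant world: hinge inactive
  expect_equal(triplet_loss(e, e, -e, sigma = 2, delta = 0.2),
               max(0, exp(-0.5) + 0.2 - 1))
  expect_equal(triplet_loss(e, e, -e, sigma = 2, delta = 0.2), 0)
  # positive and world both antipodal: similarities cancel, loss = delta
  expect_equal(triplet_loss(e, -e, -e, sigma = 2, delta = 0.2), 0.2)
})

test_that("batch loss equals a per-anchor loop oracle in every mode", {
  set.seed(8)
  for (M in c(4, 9, 16)) {
    A <- unit_rows(M, 6)
    P <- unit_rows(M, 6)
    for (mode in c("contrawr", "contrawr_plus", "avg_knn_topx")) {
      cfg <- contrastive_config(batch_size = M, mode = mode,
                                topx = max(2L, M %/% 2L))
      batch <- projection_batch(A, P)
      loss <- batch_loss(batch, cfg)
      per <- vapply(seq_len(M), function(i) {
        zw <- switch(mode,
          contrawr = world_representation(P),
          contrawr_plus = instance_aware_world_representation(
            A[i, ], P, cfg$temperature),
          avg_knn_topx = knn_topx_negative(A[i, ], P, cfg$topx, cfg$sigma))
        triplet_loss(A[i, ], P[i, ], zw, cfg$sigma, cfg$delta)
      }, 0)
      expect_equal(loss, mean(per), tolerance = 1e-10)
    }
  }
})

test_that("avg_knn_topx with X = M is bitwise identical to contrawr", {
  set.seed(9)
  for (M in c(4, 8)) {
    A <- unit_rows(M, 5)
    P <- unit_rows(M, 5)
    batch <- projection_batch(A, P)
    l_wr <- batch_loss(batch, contrastive_config(batch_size = M,
                                                 mode = "contrawr"))
    l_knn <- batch_loss(batch, contrastive_config(batch_size = M,
                                                  mode = "avg_knn_topx",
                                                  topx = M))
    expect_identical(l_wr, l_knn)
  }
})

test_that("per-anchor loss respects the similarity-difference bound", {
  set.seed(10)
  for (i in 1:30) {
    M <- sample(3:10, 1)
    A <- unit_rows(M, 4); P <- unit_rows(M, 4)
    cfg <- contrastive_config(batch_size = M)
    p <- contrawr:::batch_loss_pieces(A, P, cfg)
    bound <- (1 - exp(-4 / (2 * cfg$sigma^2))) + cfg$delta
    expect_true(all(p$per <= bound + 1e-12))
  }
})

test_that("projection batch validates alignment and norms", {
  A <- unit_rows(4, 3, seed = 11)
  expect_error(projection_batch(A, unit_rows(5, 3)), "misaligned")
  bad <- A; bad[2, ] <- bad[2, ] * 2
  expect_error(projection_batch(A, bad), "unit-norm")
  expect_error(projection_batch(A[1, , drop = FALSE], A[1, , drop = FALSE]),
               "M >= 2")
})

test_that("the margin warning fires for delta below 0.1 at sigma 2", {
  expect_warning(contrastive_config(delta = 0.05), "0.1")
  expect_silent(contrastive_config(delta = 0.2))
})

test_that("EMA boundary identities are exact and decay is geometric", {
  theta <- list(a = matrix(1:6 / 7, 2, 3), b = c(0.5, -0.25))
  phi <- list(a = matrix(runif(6), 2, 3), b = c(1, 2))
  expect_identical(ema_update(theta, phi, lambda = 1), phi)
  expect_identical(ema_update(theta, phi, lambda = 0), theta)
  expect_equal(ema_update(1, 0, 0.9), 0.1)

  # constant theta: |phi - theta| shrinks by exactly lambda per step
  lam <- 0.8
  ph <- phi
  gap <- function(p) sqrt(sum((p$a - theta$a)^2) + sum((p$b - theta$b)^2))
  g0 <- gap(ph)
  for (k in 1:40) {
    ph <- ema_update(theta, ph, lam)
    expect_equal(gap(ph), g0 * lam^k, tolerance = 1e-12)
  }

  expect_error(ema_update(theta, list(a = theta$a), 0.5), "structures")
  expect_error(ema_update(theta, phi, 1.5), "lambda")
})
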
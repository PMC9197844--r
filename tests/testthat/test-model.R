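test_that("message passing follows the closed-form toy cases", {
  # zero weights give the zero matrix
  X <- matrix(c(1, 2), 2, 1)
  Tt <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(message_passing(X, Tt, matrix(0, 1, 1), matrix(0, 1, 1)),
               matrix(0, 2, 1))
  # identity pass-through with no graph term
  X2 <- matrix(abs(rnorm(6)), 3, 2)
  expect_equal(message_passing(X2, matrix(0, 3, 3), matrix(0, 2, 2), diag(2)),
               X2)
  # hand matrix arithmetic: ReLU([[2-3],[1-6]]) = 0
  expect_equal(message_passing(X, Tt, matrix(1), matrix(-3)),
               matrix(0, 2, 1))
  expect_error(message_passing(X, matrix(0, 3, 3), matrix(1), matrix(1)),
               "n x n")
})

test_that("CEPR pre-activation is additive over channels", {
  fx <- small_fixture()
  X <- fx$expr[1:30, ]
  toms <- build_tom_set(pearson_correlation(X), c(full = 2, pos = 2, neg = 2))
  m <- ncol(X); mp <- 4
  set.seed(9)
  W <- matrix(rnorm(m * mp, sd = 0.1), m, mp)
  zero <- matrix(0, m, mp)
  p_all <- list(W_c = W, W_p = W, W_n = W, W_s = zero)
  # with equal weights the three graph channels add linearly, so CEPR on
  # (T, Tp, Tn) equals message passing on their sum
  Tsum <- toms$norm_full + toms$norm_pos + toms$norm_neg
  expect_equal(cepr_embed(X, toms, p_all),
               message_passing(X, Tsum, W, zero))
  # all-zero weights give a zero embedding
  pz <- list(W_c = zero, W_p = zero, W_n = zero, W_s = zero)
  expect_equal(cepr_embed(X, toms, pz), matrix(0, nrow(X), mp),
               ignore_attr = TRUE)
})

test_that("CEPR is permutation equivariant", {
  fx <- small_fixture()
  X <- fx$expr[1:25, ]
  toms <- build_tom_set(pearson_correlation(X), c(full = 2, pos = 3, neg = 3))
  p <- init_gmcnet_params(ncol(X), 4, 2, seed = 2)
  perm <- sample(nrow(X))
  toms_p <- toms
  for (nm in c("norm_full", "norm_pos", "norm_neg", "tom_full"))
    toms_p[[nm]] <- toms[[nm]][perm, perm]
  expect_equal(cepr_embed(X, toms, p)[perm, ],
               cepr_embed(X[perm, ], toms_p, p), ignore_attr = TRUE)
})

test_that("module classifier is a row softmax with deterministic argmax", {
  Xb <- matrix(c(10, 0, 0), 1, 3)
  out <- classify_modules(Xb, diag(3))
  expect_equal(rowSums(out$probs), 1)
  expect_gt(out$probs[1, 1], 0.9999)
  expect_equal(out$labels, 1L)
  # zero weights give uniform rows
  u <- classify_modules(matrix(rnorm(8), 2, 4), matrix(0, 4, 5))
  expect_equal(unname(u$probs), matrix(1 / 5, 2, 5))
  expect_equal(u$labels, c(1L, 1L))   # ties break to the lowest index
  # shift invariance of the softmax
  z <- matrix(rnorm(6), 2, 3)
  expect_equal(classify_modules(z + 7, diag(3))$probs,
               classify_modules(z, diag(3))$probs)
})

test_that("cut loss matches closed forms and the formula oracle", {
  # one module captures everything
  A2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(cut_loss(matrix(1, 2, 1), A2), -1)
  # two disconnected dyads with matching hard assignment
  A4 <- matrix(0, 4, 4); A4[1, 2] <- A4[2, 1] <- A4[3, 4] <- A4[4, 3] <- 1
  M <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(cut_loss(M, A4), -1)
  # only between-module edges: numerator vanishes
  Ax <- matrix(0, 4, 4); Ax[1, 3] <- Ax[3, 1] <- Ax[2, 4] <- Ax[4, 2] <- 1
  expect_equal(cut_loss(M, Ax), 0)
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(4:10, 1); k <- sample(2:4, 1)
    A <- random_adjacency(n); diag(A) <- 0
    M <- random_assignment(n, k)
    expect_equal(cut_loss(M, A), oracle_cut_loss(M, A), tolerance = 1e-10)
    expect_gte(cut_loss(M, A), -1 - 1e-12)
    expect_lte(cut_loss(M, A), 0 + 1e-12)
  }
})

test_that("orthogonality loss matches closed forms and the oracle", {
  # balanced hard orthogonal assignment scores zero
  M <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(ortho_loss(M), 0)
  # degenerate single-cluster case: || diag(1,0) - I/sqrt(2) ||_F
  M1 <- cbind(rep(1, 4), rep(0, 4))
  expect_equal(ortho_loss(M1), sqrt((1 - 1 / sqrt(2))^2 + 1 / 2))
  # row scaling leaves the value unchanged
  set.seed(13)
  M2 <- random_assignment(6, 3)
  expect_equal(ortho_loss(M2 * 3.7), ortho_loss(M2))
  for (rep in 1:20) {
    M3 <- random_assignment(sample(4:10, 1), sample(2:4, 1))
    lo <- ortho_loss(M3)
    expect_equal(lo, oracle_ortho_loss(M3), tolerance = 1e-10)
    expect_gte(lo, 0); expect_lte(lo, 2)
  }
})

test_that("total loss is the exact lambda-weighted sum of its parts", {
  set.seed(14)
  A <- random_adjacency(6); diag(A) <- 0
  M <- random_assignment(6, 3)
  l <- total_loss(M, A, 2.6)
  expect_identical(l$total, 2.6 * l$cut + l$ortho)
  expect_equal(l$cut, oracle_cut_loss(M, A), tolerance = 1e-12)
  expect_equal(l$ortho, oracle_ortho_loss(M), tolerance = 1e-12)
  expect_equal(l$degree_tilde, rowSums(A))
  l0 <- total_loss(M, A, 0)
  expect_identical(l0$total, l0$ortho)
})

test_that("analytic loss gradient matches central finite differences", {
  set.seed(15)
  n <- 3; k <- 2; lam <- 2.6
  A <- random_adjacency(n); diag(A) <- 0
  M <- random_assignment(n, k)
  g <- gmcnet:::loss_grad_M(M, A, rowSums(A), lam)
  h <- 1e-6
  num <- matrix(0, n, k)
  for (i in 1:n) for (j in 1:k) {
    up <- M; up[i, j] <- up[i, j] + h
    dn <- M; dn[i, j] <- dn[i, j] - h
    num[i, j] <- (total_loss(up, A, lam)$total -
                  total_loss(dn, A, lam)$total) / (2 * h)
  }
  expect_equal(g$grad, num, tolerance = 1e-4)
})

test_that("training is seed-deterministic with the documented schedule", {
  fx <- small_fixture()
  toms <- build_tom_set(pearson_correlation(fx$expr))
  cfg <- training_config(max_epochs = 300, seed = 5)
  f1 <- gmcnet_train(fx$expr, toms, 3, cfg)
  f2 <- gmcnet_train(fx$expr, toms, 3, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$labels, f2$labels)
  # warm-up epochs run with lambda 0: total equals ortho there
  warm <- f1$history[f1$history$epoch <= cfg$warmup_epochs, ]
  expect_identical(warm$total, warm$ortho)
  expect_true(all(warm$lr == cfg$lr_warmup))
  main <- f1$history[f1$history$epoch > cfg$warmup_epochs, ]
  expect_true(all(main$lambda == cfg$lambda_main))
  # assignment rows stay stochastic
  expect_equal(rowSums(f1$probs), rep(1, nrow(fx$expr)), ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_error(gmcnet_train(fx$expr, toms, nrow(fx$expr) + 1, cfg), "exceeds")
})

test_that("training recovers planted modules on a small fixture", {
  fx <- small_fixture()
  toms <- build_tom_set(pearson_correlation(fx$expr))
  fit <- gmcnet_train(fx$expr, toms, 3,
                      training_config(max_epochs = 1200, seed = 5))
  keep <- fx$labels > 0
  expect_gte(ari(fit$labels[keep], fx$labels[keep]), 0.8)
  # modularity at least that of K-means at the same k
  km <- kmeans_cluster(fx$expr, 3, seed = 3)
  expect_gte(modularity_q(toms$tom_full, fit$labels)$q,
             modularity_q(toms$tom_full, km$labels)$q)
})

test_that("training is equivariant to gene permutation with shared weights", {
  fx <- small_fixture()
  X <- fx$expr[1:60, ]
  toms <- build_tom_set(pearson_correlation(X))
  p0 <- init_gmcnet_params(ncol(X), 4, 3, seed = 8)
  cfg <- training_config(max_epochs = 150, seed = 8, m_prime = 4)
  set.seed(31)
  perm <- sample(nrow(X))
  toms_p <- toms
  for (nm in c("tom_full", "tom_pos", "tom_neg",
               "norm_full", "norm_pos", "norm_neg"))
    toms_p[[nm]] <- toms[[nm]][perm, perm]
  f1 <- gmcnet_train(X, toms, 3, cfg, params = p0)
  f2 <- gmcnet_train(X[perm, ], toms_p, 3, cfg, params = p0)
  expect_equal(f1$probs[perm, ], f2$probs, ignore_attr = TRUE,
               tolerance = 1e-8)
})
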
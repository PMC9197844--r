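test_that("pearson correlation matches hand-computed values and contract", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(-1, -2, -3, -4), c = c(1, 3, 2, 4))
  colnames(x) <- paste0("s", 1:4)
  r <- pearson_correlation(x)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r["a", "b"], -1)
  expect_equal(r["a", "c"], 0.8)   # hand evaluation of the Pearson formula
  expect_equal(r, t(r))
})

test_that("zero-variance genes are rejected by name", {
  x <- rbind(flat = c(2, 2, 2, 2), ok = c(1, 2, 3, 4))
  colnames(x) <- paste0("s", 1:4)
  expect_error(pearson_correlation(x), "flat")
})

test_that("soft threshold channels follow sign masks and closed forms", {
  r <- matrix(c(1, -0.5, -0.5, 1), 2)
  expect_equal(soft_threshold(r, 6, "full")[1, 2], 0.5^6)
  expect_equal(soft_threshold(r, 6, "positive")[1, 2], 0)
  expect_equal(soft_threshold(r, 6, "negative")[1, 2], 0.5^6)
  r2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(soft_threshold(r2, 6, "negative")[1, 2], 0)
  expect_equal(soft_threshold(r2, 1, "full")[1, 2], 0.5)
  # diagonal forced to 1 in every channel
  for (ch in c("full", "positive", "negative"))
    expect_equal(diag(soft_threshold(r, 6, ch)), c(1, 1))
})

test_that("soft threshold is monotone decreasing in beta off-diagonal", {
  set.seed(4)
  r <- pearson_correlation(matrix(rnorm(80), 8, 10,
                                  dimnames = list(paste0("g", 1:8),
                                                  paste0("s", 1:10))))
  a1 <- soft_threshold(r, 3, "full")
  a2 <- soft_threshold(r, 7, "full")
  off <- row(r) != col(r)
  expect_true(all(a2[off] <= a1[off] + 1e-15))
})

test_that("tom matches hand-worked 3-gene cases", {
  # complete graph saturates TOM
  a <- matrix(1, 3, 3)
  expect_equal(tom_similarity(a)[1, 2], 1)
  # 3-node path: t_12 = (0 + 0.5) / (min(1, 0.5) + 1 - 0.5)
  a <- diag(3); a[1, 2] <- a[2, 1] <- 0.5; a[1, 3] <- a[3, 1] <- 0.5
  expect_equal(tom_similarity(a)[1, 2], 0.5)
  # empty graph: off-diagonal zero, isolated genes are not an error
  expect_equal(tom_similarity(diag(3))[1, 2], 0)
})

test_that("tom equals the triple-loop oracle and stays in [0, 1]", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(5:10, 1)
    a <- random_adjacency(n)
    t1 <- tom_similarity(a)
    expect_equal(t1, oracle_tom(a), tolerance = 1e-12)
    expect_true(all(t1 >= 0 & t1 <= 1 + 1e-12))
    expect_equal(t1, t(t1))
  }
})

test_that("normalize_tom matches the 2-gene closed form and contract", {
  t2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  nt <- normalize_tom(t2)
  expect_equal(nt[1, 2], 1)          # 0.5 / sqrt(0.5 * 0.5)
  expect_equal(diag(nt), c(0, 0))
  expect_equal(nt, t(nt))
  # fully disconnected gene is an explicit error naming the gene
  iso <- diag(3)
  dimnames(iso) <- list(paste0("g", 1:3), paste0("g", 1:3))
  expect_error(normalize_tom(iso), "g1")
})

test_that("tom_set channels are consistent and degree-normalized", {
  fx <- small_fixture()
  toms <- build_tom_set(pearson_correlation(fx$expr))
  for (nm in c("tom_full", "tom_pos", "tom_neg")) {
    expect_equal(diag(toms[[nm]]), rep(1, nrow(fx$expr)),
                 ignore_attr = TRUE)
    expect_equal(toms[[nm]], t(toms[[nm]]))
  }
  for (nm in c("norm_full", "norm_pos", "norm_neg")) {
    expect_equal(diag(toms[[nm]]), rep(0, nrow(fx$expr)), ignore_attr = TRUE)
    expect_true(all(toms[[nm]] >= 0))
    expect_equal(toms[[nm]], t(toms[[nm]]))
  }
})

test_that("gene filter keeps trait-correlated genes and honours alpha", {
  set.seed(21)
  m <- 20
  traits <- matrix(rnorm(m * 2), m, 2,
                   dimnames = list(sprintf("s%02d", 1:m), c("t1", "t2")))
  sig <- traits[, 1] + rnorm(m, sd = 0.05)  # ~ identical to trait 1
  x <- rbind(hit = sig, miss1 = rnorm(m), miss2 = rnorm(m))
  colnames(x) <- rownames(traits)
  kept <- filter_genes(x, traits, alpha = 1e-6)
  expect_equal(rownames(kept), "hit")
  # alpha = 1 is the identity on gene sets, order preserved
  expect_equal(rownames(filter_genes(x, traits, alpha = 1)),
               c("hit", "miss1", "miss2"))
  expect_error(filter_genes(x[2:3, ], traits, alpha = 1e-9), "raise alpha")
})

test_that("null gene retention matches the 1 - (1-alpha)^T family rate", {
  set.seed(22)
  n <- 4000; m <- 20
  x <- matrix(rnorm(n * m), n, m,
              dimnames = list(sprintf("g%04d", 1:n), sprintf("s%02d", 1:m)))
  traits <- matrix(rnorm(m * 4), m, 4,
                   dimnames = list(colnames(x), paste0("t", 1:4)))
  kept <- filter_genes(x, traits, alpha = 0.1)
  rate <- nrow(kept) / n
  # Monte-Carlo check; tests against the shared traits are correlated, so
  # the band is wider than a binomial SE
  expect_lt(abs(rate - (1 - 0.9^4)), 0.03)
  # "all" mode is far stricter
  p_all <- 0.1^4
  kept_all <- tryCatch(filter_genes(x, traits, alpha = 0.1, mode = "all"),
                       error = function(e) x[0, ])
  expect_lt(nrow(kept_all) / n, 0.01)
})

test_that("scale-free index is +1 for an exact decaying power law", {
  # connectivity values {1,2,4,8} with counts proportional to 1/k
  k <- rep(c(1, 2, 4, 8), times = c(40, 20, 10, 5))
  expect_equal(scale_free_r2(k), 1)
  # increasing law scores negative
  k2 <- rep(c(1, 2, 4, 8), times = c(5, 10, 20, 40))
  expect_equal(scale_free_r2(k2), -1)
  expect_true(is.na(scale_free_r2(c(1, 2))))
})

test_that("soft-threshold selection returns a finite candidate", {
  fx <- small_fixture()
  corm <- pearson_correlation(fx$expr)
  sf <- scale_free_fit(corm, c(2, 4, 6), "full")
  expect_equal(nrow(sf$table), 3)
  expect_true(sf$selected_beta %in% c(2, 4, 6))
  # a single candidate is returned regardless of fit
  expect_equal(scale_free_fit(corm, 6, "full")$selected_beta, 6)
})
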
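#' Training configuration for gmcNet
#'
#' Defaults follow the two-phase schedule used throughout: a warm-up of 100
#' epochs with the cut loss switched off (lambda = 0) at learning rate 0.01
#' to prevent empty modules, then lambda = 2.6 at learning rate 0.001 until
#' either 5,000 epochs elapse or the orthogonality loss exceeds the early
#' stopping threshold tau = 0.8 (checked only after warm-up, since the
#' randomly initialized assignment starts above tau).
#'
#' @param max_epochs Maximum full-batch epochs.
#' @param warmup_epochs Warm-up length.
#' @param lr_warmup,lr_main Adam learning rates per phase.
#' @param lambda_warmup,lambda_main Cut-loss weights per phase.
#' @param tau Orthogonality early-stopping threshold.
#' @param m_prime Embedding dimension.
#' @param seed Weight-initialization seed.
#' @return A list of class `training_config`.
#' @export
training_config <- function(max_epochs = 5000, warmup_epochs = 100,
                            lr_warmup = 0.01, lr_main = 0.001,
                            lambda_warmup = 0, lambda_main = 2.6,
                            tau = 0.8, m_prime = 8, seed = 1) {
  stopifnot(warmup_epochs < max_epochs, tau > 0, lambda_main >= 0,
            m_prime >= 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 lr_warmup = lr_warmup, lr_main = lr_main,
                 lambda_warmup = lambda_warmup, lambda_main = lambda_main,
                 tau = tau, m_prime = as.integer(m_prime),
                 seed = as.integer(seed)),
            class = "training_config")
}

glorot_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize gmcNet trainable weights
#'
#' Four CEPR weight matrices (m x m') for the full, positive and negative
#' co-expression channels plus the single-expression skip connection, and
#' the classifier weights (m' x k). Glorot-uniform, reproducible per seed.
#'
#' @param m Number of samples (input feature dimension).
#' @param m_prime Embedding dimension.
#' @param k Number of modules.
#' @param seed Integer seed.
#' @return Named list `W_c`, `W_p`, `W_n`, `W_s`, `W_m`.
#' @export
init_gmcnet_params <- function(m, m_prime = 8, k, seed = 1) {
  stopifnot(m >= 1, m_prime >= 1, k >= 2)
  set.seed(as.integer(seed))
  list(W_c = glorot_uniform(m, m_prime),
       W_p = glorot_uniform(m, m_prime),
       W_n = glorot_uniform(m, m_prime),
       W_s = glorot_uniform(m, m_prime),
       W_m = glorot_uniform(m_prime, k))
}

#' Message-passing layer
#'
#' `ReLU(T_tilde X W_co + X W_single)`: aggregates each gene's neighbours
#' through the normalized TOM and adds a single-expression skip term.
#'
#' @param X genes x samples feature matrix.
#' @param T_tilde Normalized (zero-diagonal) TOM.
#' @param W_co,W_single samples x m' weight matrices.
#' @return genes x m' nonnegative embedding.
#' @export
message_passing <- function(X, T_tilde, W_co, W_single) {
  check_shapes(X, T_tilde, W_co, W_single)
  h <- T_tilde %*% X %*% W_co + X %*% W_single
  pmax(h, 0)
}

check_shapes <- function(X, T_tilde, ...) {
  if (nrow(T_tilde) != ncol(T_tilde) || nrow(T_tilde) != nrow(X))
    stop_gmcnet("T_tilde must be n x n with n = nrow(X) = ", nrow(X),
                ", got ", nrow(T_tilde), " x ", ncol(T_tilde))
  for (w in list(...))
    if (nrow(w) != ncol(X))
      stop_gmcnet("weight matrix rows (", nrow(w),
                  ") must equal feature columns (", ncol(X), ")")
  invisible(TRUE)
}

#' CEPR embedding
#'
#' The co-expression pattern recognizer combines three message-passing
#' channels (full, positive-only and negative-only normalized TOMs) with a
#' single-expression skip connection:
#' \deqn{\bar X = ReLU(\tilde T X W_c + \tilde T_p X W_p + \tilde T_n X W_n
#'   + X W_s)}
#'
#' @param X genes x samples matrix.
#' @param toms A `tom_set` (see [build_tom_set()]).
#' @param params Weight list from [init_gmcnet_params()].
#' @return genes x m' nonnegative embedding.
#' @export
cepr_embed <- function(X, toms, params) {
  check_shapes(X, toms$norm_full, params$W_c, params$W_p, params$W_n,
               params$W_s)
  h <- toms$norm_full %*% X %*% params$W_c +
       toms$norm_pos  %*% X %*% params$W_p +
       toms$norm_neg  %*% X %*% params$W_n +
       X %*% params$W_s
  pmax(h, 0)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)            # shift invariance, numerical safety
  e <- exp(z)
  e / rowSums(e)
}

#' Module classifier
#'
#' Row-wise softmax of `X_bar %*% W_m`; the hard label of gene i is the
#' argmax of row i, ties broken toward the lowest module index.
#'
#' @param X_bar genes x m' embedding.
#' @param W_m m' x k classifier weights.
#' @return List with `probs` (n x k row-stochastic) and 1-based integer
#'   `labels`.
#' @export
classify_modules <- function(X_bar, W_m) {
  if (ncol(X_bar) != nrow(W_m))
    stop_gmcnet("embedding columns (", ncol(X_bar),
                ") must match classifier rows (", nrow(W_m), ")")
  probs <- softmax_rows(X_bar %*% W_m)
  rownames(probs) <- rownames(X_bar)
  list(probs = probs, labels = max.col(probs, ties.method = "first"))
}

#' MinCut-style cut loss
#'
#' \deqn{L_c = -\frac{Tr(M^T \tilde T M)}{Tr(M^T \tilde D M)}} with
#' \eqn{\tilde D = diag(\tilde T 1)}. Bounded in \[-1, 0\]; -1 when every
#' module captures all of its genes' degree mass.
#'
#' @param M n x k assignment probabilities (row-stochastic).
#' @param T_tilde Normalized zero-diagonal TOM, no zero-degree rows.
#' @return Scalar loss.
#' @export
cut_loss <- function(M, T_tilde) {
  d <- rowSums(T_tilde)
  den <- sum((M * M) * d)
  if (den <= 0) stop_gmcnet("degenerate graph: Tr(M' D M) = 0")
  num <- sum(M * (T_tilde %*% M))
  -num / den
}

#' Orthogonality loss
#'
#' \deqn{L_o = \left\| \frac{M^T M}{\|M^T M\|_F} - \frac{I_k}{\sqrt k}
#' \right\|_F \in [0, 2]}, zero exactly when the module sizes are balanced
#' and the soft assignments orthogonal.
#'
#' @param M n x k assignment probabilities.
#' @return Scalar loss.
#' @export
ortho_loss <- function(M) {
  g <- crossprod(M)
  f <- sqrt(sum(g * g))
  if (f == 0) stop_gmcnet("all-zero assignment matrix")
  b <- g / f - diag(ncol(M)) / sqrt(ncol(M))
  sqrt(sum(b * b))
}

#' Combined gmcNet loss
#'
#' @param M Assignment probabilities.
#' @param T_tilde Normalized TOM.
#' @param lambda Cut-loss weight.
#' @return List `cut`, `ortho`, `total` (= lambda * cut + ortho) and
#'   `degree_tilde` (diagonal of the degree matrix of `T_tilde`).
#' @export
total_loss <- function(M, T_tilde, lambda) {
  cut <- cut_loss(M, T_tilde)
  ortho <- ortho_loss(M)
  list(cut = cut, ortho = ortho, total = lambda * cut + ortho,
       degree_tilde = rowSums(T_tilde))
}

# Analytic gradient of lambda * L_c + L_o with respect to M.
# d(-num/den)/dM = -2 A M / den + (num/den^2) 2 d*M ;
# dL_o/dG = (1/L_o)(B/F - G <B,G>/F^3), dL_o/dM = 2 M S.
loss_grad_M <- function(M, T_tilde, d, lambda) {
  AM <- T_tilde %*% M
  num <- sum(M * AM)
  den <- sum((M * M) * d)
  grad_cut <- -2 * AM / den + (num / den^2) * 2 * (M * d)

  g <- crossprod(M)
  f <- sqrt(sum(g * g))
  b <- g / f - diag(ncol(M)) / sqrt(ncol(M))
  lo <- sqrt(sum(b * b))
  grad_ortho <- if (lo > 0) {
    s <- (b / f - g * sum(b * g) / f^3) / lo
    2 * (M %*% s)
  } else matrix(0, nrow(M), ncol(M))

  list(grad = lambda * grad_cut + grad_ortho,
       cut = -num / den, ortho = lo)
}

#' Train gmcNet
#'
#' Full-batch Adam on the CEPR + classifier weights under the combined
#' MinCut/orthogonality loss. Two phases: warm-up epochs use
#' `(lambda_warmup, lr_warmup)`, later epochs `(lambda_main, lr_main)`.
#' After warm-up, training stops at the first epoch whose orthogonality
#' loss exceeds `tau`; the assignment at that epoch is returned.
#'
#' @param X genes x samples expression matrix.
#' @param toms `tom_set` built from the same genes.
#' @param k Number of modules (at least 2, at most n).
#' @param config A [training_config()].
#' @param params Optional explicit initial weights (overrides seeded
#'   initialization; used e.g. for permutation-consistency checks).
#' @return An object of class `gmcnet_fit`: `params`, `probs`, `labels`,
#'   `history` (per-epoch data.frame), `stopped_early`, `epochs_run`.
#' @export
gmcnet_train <- function(X, toms, k, config = training_config(),
                         params = NULL) {
  n <- nrow(X); m <- ncol(X)
  if (k > n) stop_gmcnet("k = ", k, " exceeds number of genes n = ", n)
  if (k < 2) stop_gmcnet("k must be at least 2")
  if (nrow(toms$norm_full) != n)
    stop_gmcnet("tom_set was built for ", nrow(toms$norm_full),
                " genes, expression has ", n)
  if (is.null(params))
    params <- init_gmcnet_params(m, config$m_prime, k, config$seed)

  A <- toms$norm_full
  d <- rowSums(A)
  # channel features are constant across epochs
  XC <- toms$norm_full %*% X
  XP <- toms$norm_pos %*% X
  XN <- toms$norm_neg %*% X

  adam <- lapply(params, function(w) list(m = w * 0, v = w * 0))
  t_step <- 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  hist <- vector("list", config$max_epochs)
  stopped_early <- FALSE
  probs <- NULL
  epochs_run <- 0

  for (epoch in seq_len(config$max_epochs)) {
    warm <- epoch <= config$warmup_epochs
    lambda <- if (warm) config$lambda_warmup else config$lambda_main
    lr <- if (warm) config$lr_warmup else config$lr_main

    # forward
    H <- XC %*% params$W_c + XP %*% params$W_p + XN %*% params$W_n +
         X %*% params$W_s
    Xbar <- pmax(H, 0)
    Z <- Xbar %*% params$W_m
    M <- softmax_rows(Z)

    g <- loss_grad_M(M, A, d, lambda)
    total <- lambda * g$cut + g$ortho
    if (!is.finite(total))
      stop_gmcnet("non-finite loss at epoch ", epoch, class = "gmcnet_numerical")
    hist[[epoch]] <- c(epoch = epoch, lambda = lambda, lr = lr,
                       cut = g$cut, ortho = g$ortho, total = total)
    probs <- M
    epochs_run <- epoch

    if (!warm && g$ortho > config$tau) {
      stopped_early <- TRUE
      break
    }

    # backward: softmax rows, then linear layers through the ReLU
    dZ <- M * (g$grad - rowSums(g$grad * M))
    grads <- list(
      W_m = crossprod(Xbar, dZ),
      W_c = NULL, W_p = NULL, W_n = NULL, W_s = NULL)
    dXbar <- dZ %*% t(params$W_m)
    dH <- dXbar * (H > 0)
    grads$W_c <- crossprod(XC, dH)
    grads$W_p <- crossprod(XP, dH)
    grads$W_n <- crossprod(XN, dH)
    grads$W_s <- crossprod(X, dH)

    t_step <- t_step + 1
    for (w in names(params)) {
      adam[[w]]$m <- beta1 * adam[[w]]$m + (1 - beta1) * grads[[w]]
      adam[[w]]$v <- beta2 * adam[[w]]$v + (1 - beta2) * grads[[w]]^2
      mhat <- adam[[w]]$m / (1 - beta1^t_step)
      vhat <- adam[[w]]$v / (1 - beta2^t_step)
      params[[w]] <- params[[w]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }

  if (!stopped_early) {
    # assignment from the final (post-update) weights: M at the end of training
    Xbar <- pmax(XC %*% params$W_c + XP %*% params$W_p + XN %*% params$W_n +
                 X %*% params$W_s, 0)
    probs <- softmax_rows(Xbar %*% params$W_m)
  }
  rownames(probs) <- rownames(X)
  colnames(probs) <- paste0("K", seq_len(k))

  history <- as.data.frame(do.call(rbind, hist[seq_len(epochs_run)]))
  out <- list(params = params,
              probs = probs,
              labels = max.col(probs, ties.method = "first"),
              history = history,
              stopped_early = stopped_early,
              epochs_run = epochs_run,
              k = k,
              config = config)
  class(out) <- "gmcnet_fit"
  out
}

#' @export
print.gmcnet_fit <- function(x, ...) {
  sizes <- tabulate(x$labels, nbins = x$k)
  cat("gmcnet_fit: ", nrow(x$probs), " genes -> ", x$k, " modules; ",
      x$epochs_run, " epochs",
      if (x$stopped_early) " (early stop: L_o > tau)", "\n", sep = "")
  cat("module sizes:", paste(sizes, collapse = " "), "\n")
  tail1 <- x$history[nrow(x$history), ]
  cat(sprintf("final losses: cut %.4f ortho %.4f total %.4f\n",
              tail1$cut, tail1$ortho, tail1$total))
  invisible(x)
}
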
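#' Weighted graph modularity of a partition
#'
#' Newman modularity on the zero-diagonal topological overlap matrix:
#' \deqn{Q = \frac{1}{s}\sum_{ij}\left(t_{ij} - \frac{c_i c_j}{s}\right)
#' \delta[i,j]} with connectivities \eqn{c_i = \sum_u t_{iu}} and total
#' weight \eqn{s = \sum_{ij} t_{ij}}. Self-similarity is excluded (the
#' diagonal is zeroed before computing) because it adds a
#' partition-independent constant and the degree-matched null concerns
#' edges between distinct genes. `Q = 0` exactly for the single-module
#' partition.
#'
#' @param tom Symmetric nonnegative similarity matrix (unit or zero
#'   diagonal; the diagonal is zeroed internally).
#' @param labels Integer module labels (any coding; compared by equality).
#' @return List `q`, `total_weight_s`, `connectivities_c`.
#' @export
modularity_q <- function(tom, labels) {
  check_square_symmetric(tom, "tom")
  stopifnot(length(labels) == nrow(tom))
  tz <- tom
  diag(tz) <- 0
  s <- sum(tz)
  if (s <= 0) stop_gmcnet("graph has zero total weight")
  c_i <- rowSums(tz)
  q <- 0
  for (l in unique(labels)) {
    idx <- which(labels == l)
    q <- q + sum(tz[idx, idx]) - sum(c_i[idx])^2 / s
  }
  list(q = q / s, total_weight_s = s, connectivities_c = c_i)
}

#' Module eigengene
#'
#' First principal component of the module's gene-standardized expression
#' submatrix, giving one score per sample (unit norm). The sign is fixed so
#' that the eigengene correlates nonnegatively with the module's mean
#' standardized profile; if that profile is degenerate (e.g. the module is
#' half anti-correlated), the gene loading of largest magnitude is made
#' positive instead.
#'
#' @param X genes x samples expression matrix.
#' @param labels Integer module labels for the rows of `X`.
#' @param module_id Module to summarize.
#' @return List `module_id`, `values` (length m, unit norm),
#'   `explained_variance_ratio`, `loadings` (per-gene PC1 loadings).
#' @export
module_eigengene <- function(X, labels, module_id) {
  idx <- which(labels == module_id)
  if (!length(idx)) stop_gmcnet("module ", module_id, " is empty")
  sub <- X[idx, , drop = FALSE]
  s <- t(scale(t(sub)))                   # z-score each gene across samples
  if (anyNA(s)) stop_gmcnet("constant gene inside module ", module_id)
  sv <- svd(s, nu = 1, nv = 1)
  eig <- sv$v[, 1]
  evr <- sv$d[1]^2 / sum(sv$d^2)
  ref <- colMeans(s)
  al <- if (stats::sd(ref) > 0) stats::cor(eig, ref) else 0
  flip <- if (is.finite(al) && al != 0) sign(al) else {
    u <- sv$u[, 1]
    sign(u[which.max(abs(u))])
  }
  eig <- eig * flip
  names(eig) <- colnames(X)
  list(module_id = module_id, values = eig,
       explained_variance_ratio = evr,
       loadings = sv$u[, 1] * flip)
}

#' Differentially-expressed-module (DEM) signal
#'
#' For every module l and trait t, fits the simple linear regression of the
#' trait on the module eigengene and records the slope p-value. A cell is
#' significant when p is at or below `alpha` (raw, uncorrected, following
#' the star convention of module-trait heatmaps); the DEM signal is
#' \deqn{\sum_{l,t} -\log_{10}(p_{lt}) \, \rho[l,t]} summed over significant
#' cells. Constant eigengenes or traits yield NA cells (excluded, with a
#' warning).
#'
#' @param X genes x samples expression matrix.
#' @param labels Integer module labels in 1..k.
#' @param k Number of modules.
#' @param traits samples x traits matrix aligned to `X`.
#' @param alpha Per-cell significance level, default 0.05.
#' @return List of class `dem_result`: `pvalues`, `coefficients`,
#'   `significant` (k x traits), `dem_signal`, `eigengenes`
#'   (samples x k matrix, NA columns for empty modules).
#' @export
dem_signal <- function(X, labels, k, traits, alpha = 0.05) {
  stopifnot(alpha >= 0, alpha <= 1)
  traits <- align_traits(traits, X)
  nt <- ncol(traits)
  p <- coefs <- matrix(NA_real_, k, nt,
                       dimnames = list(paste0("K", seq_len(k)),
                                       colnames(traits)))
  eigs <- matrix(NA_real_, ncol(X), k,
                 dimnames = list(colnames(X), paste0("K", seq_len(k))))
  for (l in seq_len(k)) {
    if (!any(labels == l)) {
      warning("module ", l, " is empty; skipped in DEM signal")
      next
    }
    me <- module_eigengene(X, labels, l)
    eigs[, l] <- me$values
    if (stats::sd(me$values) == 0) {
      warning("constant eigengene for module ", l, "; cells excluded")
      next
    }
    for (t in seq_len(nt)) {
      fit <- stats::lm(traits[, t] ~ me$values)
      sm <- summary(fit)$coefficients
      if (nrow(sm) < 2) next
      coefs[l, t] <- sm[2, 1]
      p[l, t] <- sm[2, 4]
    }
  }
  sig <- !is.na(p) & p <= alpha
  dem <- sum(-log10(p[sig]))
  structure(list(pvalues = p, coefficients = coefs, significant = sig,
                 dem_signal = dem, eigengenes = eigs, alpha = alpha),
            class = "dem_result")
}

#' @export
print.dem_result <- function(x, ...) {
  cat("dem_result: ", nrow(x$pvalues), " modules x ", ncol(x$pvalues),
      " traits; ", sum(x$significant), " significant cell(s) at alpha = ",
      x$alpha, "; DEM signal = ", format(x$dem_signal, digits = 5),
      "\n", sep = "")
  invisible(x)
}

#' Hub genes of a module
#'
#' Ranks the module's genes by Pearson correlation between their expression
#' and the module eigengene, descending; the top `top_n` (default 25) are
#' the hub genes.
#'
#' @param X genes x samples expression matrix.
#' @param labels Integer module labels.
#' @param module_id Module of interest.
#' @param top_n Number of hub genes to return (all if the module is
#'   smaller).
#' @return data.frame `gene_id`, `cor`, ordered by decreasing correlation.
#' @export
hub_genes <- function(X, labels, module_id, top_n = 25) {
  stopifnot(top_n >= 1)
  idx <- which(labels == module_id)
  if (!length(idx)) stop_gmcnet("module ", module_id, " is empty")
  me <- module_eigengene(X, labels, module_id)
  r <- as.numeric(stats::cor(t(X[idx, , drop = FALSE]), me$values))
  ids <- rownames(X)[idx]
  if (is.null(ids)) ids <- as.character(idx)
  ord <- order(r, decreasing = TRUE)
  utils::head(data.frame(gene_id = ids[ord], cor = r[ord],
                         stringsAsFactors = FALSE), top_n)
}

#' Sweep the number of modules k across methods
#'
#' Runs gmcNet and the three baselines at each k, scoring every partition
#' with modularity (on the full-channel TOM) and DEM signal.
#'
#' @param X genes x samples expression matrix.
#' @param toms `tom_set` for the same genes.
#' @param traits samples x traits matrix.
#' @param k_values Integer vector of cluster counts (each at least 2).
#' @param seed Top-level seed.
#' @param config [training_config()] for the gmcNet runs.
#' @param dem_alpha DEM significance level.
#' @return data.frame with columns method, k, q, dem_signal.
#' @export
k_sweep <- function(X, toms, traits, k_values, seed = 1,
                    config = training_config(), dem_alpha = 0.05) {
  stopifnot(all(k_values >= 2), all(k_values <= nrow(X)))
  rows <- list()
  for (k in k_values) {
    cfg <- config
    cfg$seed <- derive_seed(seed, "init")
    fit <- gmcnet_train(X, toms, k, cfg)
    base <- run_baselines(X, toms$tom_full, k, seed = seed)
    parts <- c(list(gmcnet = fit$labels),
               lapply(base, function(b) b$labels))
    for (method in names(parts)) {
      lab <- parts[[method]]
      rows[[length(rows) + 1]] <- data.frame(
        method = method, k = k,
        q = modularity_q(toms$tom_full, lab)$q,
        dem_signal = dem_signal(X, lab, k, traits,
                                alpha = dem_alpha)$dem_signal)
    }
  }
  do.call(rbind, rows)
}
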
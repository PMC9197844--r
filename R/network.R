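#' Pearson correlation matrix of gene expression profiles
#'
#' @param expr Numeric genes x samples matrix (see [validate_expression()]).
#' @return Symmetric n x n correlation matrix with unit diagonal.
#' @export
pearson_correlation <- function(expr) {
  v <- row_vars(expr)
  if (any(v == 0))
    stop_gmcnet("zero-variance gene row(s): ",
                paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "))
  r <- stats::cor(t(expr))
  # guard tiny numerical asymmetries / overshoot
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Filter genes by trait correlation
#'
#' Retains genes whose Pearson-correlation test against the traits is
#' significant: under `mode = "any"` (default) a gene is kept when its
#' p-value is at or below `alpha` for at least one trait; under
#' `mode = "all"` it must be significant for every trait. P-values come from
#' the exact t-test on r with m - 2 degrees of freedom. Gene order is
#' preserved.
#'
#' @param expr genes x samples matrix.
#' @param traits samples x traits matrix, sample order matching `expr`.
#' @param alpha Significance threshold, default 0.1.
#' @param mode `"any"` or `"all"`.
#' @return The retained rows of `expr`.
#' @export
filter_genes <- function(expr, traits, alpha = 0.1, mode = c("any", "all")) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha <= 1)
  traits <- align_traits(traits, expr)
  p <- trait_cor_pvalues(expr, traits)
  keep <- if (mode == "any") {
    apply(p, 1, min) <= alpha
  } else {
    apply(p, 1, max) <= alpha
  }
  if (!any(keep))
    stop_gmcnet("no genes pass the trait-correlation filter at alpha = ", alpha,
                "; raise alpha")
  expr[keep, , drop = FALSE]
}

# genes x traits matrix of two-sided p-values for the Pearson r t-test
trait_cor_pvalues <- function(expr, traits) {
  m <- ncol(expr)
  df <- m - 2
  r <- stats::cor(t(expr), traits)
  r <- pmin(pmax(r, -1), 1)
  tt <- abs(r) * sqrt(df / pmax(1 - r * r, .Machine$double.eps))
  p <- 2 * stats::pt(tt, df, lower.tail = FALSE)
  p[abs(r) == 1] <- 0
  dimnames(p) <- list(rownames(expr), colnames(traits))
  p
}

#' Soft-threshold a correlation matrix into an adjacency channel
#'
#' The full channel is the classic unsigned WGCNA adjacency
#' \eqn{a_{ij} = |cor_{ij}|^\beta}; the positive channel keeps only positive
#' correlations (\eqn{cor_{ij}^\beta} there, 0 elsewhere) and the negative
#' channel only negative ones (\eqn{|cor_{ij}|^\beta}). The diagonal is set
#' to 1 in every channel.
#'
#' @param cor Correlation matrix.
#' @param beta Positive integer smoothing power.
#' @param channel `"full"`, `"positive"` or `"negative"`.
#' @return Symmetric adjacency matrix in \[0, 1\].
#' @export
soft_threshold <- function(cor, beta, channel = c("full", "positive", "negative")) {
  channel <- match.arg(channel)
  stopifnot(beta >= 1)
  a <- switch(channel,
    full     = abs(cor)^beta,
    positive = ifelse(cor > 0, cor^beta, 0),
    negative = ifelse(cor < 0, abs(cor)^beta, 0))
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' \deqn{t_{ij} = \frac{l_{ij} + a_{ij}}{\min\{k_i, k_j\} + 1 - a_{ij}}}
#' with \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and connectivity
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}: shared-neighbour sums exclude the two
#' endpoint genes and connectivity excludes self-adjacency, so that
#' \eqn{t_{ij} \in [0, 1]} with unit diagonal. An isolated gene gets
#' \eqn{t_{ij} = 0} off-diagonal (denominator 1), not an error.
#'
#' @param adj Symmetric adjacency matrix in \[0, 1\] with unit diagonal.
#' @return Symmetric TOM in \[0, 1\] with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  check_square_symmetric(adj, "adj")
  a <- adj
  diag(a) <- 0
  # with a_ii = 0 the u = i and u = j terms of sum_u a_iu a_uj vanish, so a
  # plain matrix square gives l_ij restricted to u != i, j
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  (tom + t(tom)) / 2
}

#' Zero-diagonal degree normalization of a TOM
#'
#' Computes \eqn{T_z = T - I} and \eqn{\tilde T = D^{-1/2} T_z D^{-1/2}}
#' where \eqn{D = diag(T_z 1)}; this is the message-passing operator of the
#' CEPR layer.
#'
#' @param tom Symmetric TOM with unit diagonal and nonnegative entries.
#' @return Symmetric matrix with exact zero diagonal.
#' @export
normalize_tom <- function(tom) {
  check_square_symmetric(tom, "tom")
  tz <- tom
  diag(tz) <- 0
  d <- rowSums(tz)
  if (any(d <= 0)) {
    genes <- rownames(tom)
    if (is.null(genes)) genes <- as.character(seq_len(nrow(tom)))
    stop_gmcnet("fully disconnected gene(s) in TOM: ",
                paste(utils::head(genes[d <= 0], 5), collapse = ", "),
                "; drop them or lower beta")
  }
  inv_sqrt <- 1 / sqrt(d)
  tt <- tz * tcrossprod(inv_sqrt)
  diag(tt) <- 0
  (tt + t(tt)) / 2
}

#' Build the three-channel TOM set
#'
#' Constructs the full, positive-only and negative-only topological overlap
#' matrices from one correlation matrix (each channel with its own
#' soft-threshold power) together with their degree-normalized,
#' zero-diagonal counterparts used by the CEPR layer.
#'
#' Genes whose positive (or negative) channel is fully disconnected would
#' make degree normalization undefined there; such channels keep those rows
#' at exactly zero instead (the gene simply receives no message through that
#' channel). The full channel must be connected and errors otherwise.
#'
#' @param cor Correlation matrix.
#' @param betas Named numeric vector `c(full=, pos=, neg=)`, default
#'   `c(6, 9, 10)`.
#' @return An object of class `tom_set` with elements `tom_full`, `tom_pos`,
#'   `tom_neg`, `norm_full`, `norm_pos`, `norm_neg`, `betas`.
#' @export
build_tom_set <- function(cor, betas = c(full = 6, pos = 9, neg = 10)) {
  stopifnot(all(c("full", "pos", "neg") %in% names(betas)))
  tom_full <- tom_similarity(soft_threshold(cor, betas[["full"]], "full"))
  tom_pos  <- tom_similarity(soft_threshold(cor, betas[["pos"]], "positive"))
  tom_neg  <- tom_similarity(soft_threshold(cor, betas[["neg"]], "negative"))
  out <- list(
    tom_full  = tom_full,
    tom_pos   = tom_pos,
    tom_neg   = tom_neg,
    norm_full = normalize_tom(tom_full),
    norm_pos  = normalize_tom_partial(tom_pos),
    norm_neg  = normalize_tom_partial(tom_neg),
    betas     = betas)
  class(out) <- "tom_set"
  out
}

# degree normalization tolerating isolated genes (rows left at zero);
# used for the sign-restricted channels where isolation is expected
normalize_tom_partial <- function(tom) {
  tz <- tom
  diag(tz) <- 0
  d <- rowSums(tz)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  tt <- tz * tcrossprod(inv_sqrt)
  diag(tt) <- 0
  (tt + t(tt)) / 2
}

#' @export
print.tom_set <- function(x, ...) {
  cat("tom_set:", nrow(x$tom_full), "genes; betas full/pos/neg =",
      paste(x$betas[c("full", "pos", "neg")], collapse = "/"), "\n")
  invisible(x)
}

#' Scale-free topology fit across candidate soft-threshold powers
#'
#' For each candidate power the channel adjacency is built, connectivities
#' \eqn{k_i} are binned (equal-width bins; distinct values get their own bin
#' when few), and the scale-free fit index is the R-squared of the
#' regression of log10 p(k) on log10 mean-k per bin, signed by the negative
#' of the slope (a decaying power law scores +R^2, as in standard WGCNA
#' soft-threshold picking). Selection returns the smallest power whose index
#' reaches `r2_threshold`, or the argmax when none qualifies.
#'
#' @param cor Correlation matrix.
#' @param candidate_betas Ascending positive integers.
#' @param channel Adjacency channel.
#' @param r2_threshold Qualification threshold, default 0.8.
#' @param nbins Number of connectivity bins, default 10.
#' @return List with `table` (data.frame beta, fit_r2, mean_connectivity)
#'   and `selected_beta`.
#' @export
scale_free_fit <- function(cor, candidate_betas, channel = "full",
                           r2_threshold = 0.8, nbins = 10) {
  stopifnot(length(candidate_betas) >= 1, !is.unsorted(candidate_betas))
  rows <- lapply(candidate_betas, function(b) {
    a <- soft_threshold(cor, b, channel)
    diag(a) <- 0
    k <- rowSums(a)
    data.frame(beta = b, fit_r2 = scale_free_r2(k, nbins = nbins),
               mean_connectivity = mean(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$fit_r2) & tab$fit_r2 >= r2_threshold)
  selected <- if (length(ok)) tab$beta[ok[1]] else
    tab$beta[which.max(replace(tab$fit_r2, is.na(tab$fit_r2), -Inf))]
  list(table = tab, selected_beta = selected)
}

#' Signed scale-free fit index of a connectivity vector
#'
#' @param k Nonnegative connectivities.
#' @param nbins Equal-width bins over the connectivity range (distinct
#'   values get their own bin when the vector has at most `nbins` distinct
#'   positive values).
#' @return Signed R^2 (positive for a decaying log-log relationship), or NA
#'   when fewer than 3 occupied bins remain.
#' @export
scale_free_r2 <- function(k, nbins = 10) {
  k <- k[k > 0]
  if (length(k) < 3) return(NA_real_)
  uk <- unique(k)
  if (length(uk) <= nbins) {
    centers <- sort(uk)
    pk <- as.numeric(table(factor(k, levels = centers))) / length(k)
  } else {
    # equal-width bins over the connectivity range (equal-count bins would
    # make p(k) constant by construction)
    br <- seq(min(k), max(k), length.out = nbins + 1)
    bin <- cut(k, br, include.lowest = TRUE)
    centers <- tapply(k, bin, mean)
    pk <- as.numeric(table(bin)) / length(k)
    keep <- !is.na(centers) & pk > 0
    centers <- centers[keep]; pk <- pk[keep]
  }
  if (length(centers) < 3) return(NA_real_)
  # simple regression: R^2 = cor^2, slope sign = correlation sign
  cc <- stats::cor(log10(centers), log10(pk))
  if (!is.finite(cc)) return(NA_real_)
  -sign(cc) * cc^2
}
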
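#' Specification of a planted-module expression fixture
#'
#' The generator draws one latent factor per module per sample; a gene in
#' module j is `sign * loading * factor_j + N(0, noise_sd)` where the sign
#' is negative for an anti-correlated fraction of the module's genes (these
#' exercise the negative co-expression channel), and the loading is set
#' from the requested within-module correlation via
#' `loading^2 / (loading^2 + noise_sd^2) = within_module_cor`. Genes beyond
#' `sum(module_sizes)` are i.i.d. background noise with the same marginal
#' variance as module genes. Each trait is a linear function of one
#' module's factor plus Gaussian noise.
#'
#' @param n_genes Total genes (module genes + background noise genes).
#' @param n_samples Samples.
#' @param module_sizes Integer vector of planted module sizes.
#' @param within_module_cor Target Pearson correlation between two same-sign
#'   genes of one module, in (0, 1).
#' @param anti_correlated_fraction Fraction of each module loading
#'   negatively.
#' @param noise_sd Gene-level noise standard deviation.
#' @param trait_effects data.frame with columns `module` and `effect`; one
#'   trait is generated per row.
#' @param trait_noise_sd Trait-level noise standard deviation.
#' @param seed Integer seed.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 500, n_samples = 20,
                         module_sizes = rep(100, 4),
                         within_module_cor = 0.8,
                         anti_correlated_fraction = 0.25,
                         noise_sd = 1,
                         trait_effects = data.frame(module = 1:4, effect = 2),
                         trait_noise_sd = 1,
                         seed = 1) {
  trait_effects <- as.data.frame(trait_effects)
  stopifnot(sum(module_sizes) <= n_genes,
            within_module_cor > 0, within_module_cor < 1,
            anti_correlated_fraction >= 0, anti_correlated_fraction <= 1,
            noise_sd > 0,
            all(trait_effects$module >= 1),
            all(trait_effects$module <= length(module_sizes)))
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 k_true = length(module_sizes),
                 module_sizes = as.integer(module_sizes),
                 within_module_cor = within_module_cor,
                 anti_correlated_fraction = anti_correlated_fraction,
                 noise_sd = noise_sd,
                 trait_effects = trait_effects,
                 trait_noise_sd = trait_noise_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a planted-module expression fixture
#'
#' @param spec A [fixture_spec()].
#' @return List: `expr` (genes x samples), `traits` (samples x traits),
#'   `labels` (true module of each gene, -1 for background noise genes),
#'   `factors` (samples x k_true latent factors), `spec`.
#' @export
simulate_expression <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  n <- spec$n_genes; m <- spec$n_samples; k <- spec$k_true
  w <- spec$within_module_cor
  loading <- spec$noise_sd * sqrt(w / (1 - w))
  gene_sd <- sqrt(loading^2 + spec$noise_sd^2)

  factors <- matrix(stats::rnorm(m * k), m, k,
                    dimnames = list(NULL, paste0("F", seq_len(k))))
  expr <- matrix(stats::rnorm(n * m, sd = spec$noise_sd), n, m)
  labels <- rep(-1L, n)
  row <- 1L
  for (j in seq_len(k)) {
    size <- spec$module_sizes[j]
    n_anti <- round(spec$anti_correlated_fraction * size)
    signs <- c(rep(1, size - n_anti), rep(-1, n_anti))
    idx <- row:(row + size - 1L)
    expr[idx, ] <- expr[idx, ] +
      (signs * loading) %o% factors[, j]
    labels[idx] <- j
    row <- row + size
  }
  n_noise <- n - sum(spec$module_sizes)
  if (n_noise > 0) {
    idx <- (n - n_noise + 1L):n
    # background genes: i.i.d., marginal variance matched to module genes
    expr[idx, ] <- matrix(stats::rnorm(n_noise * m, sd = gene_sd),
                          n_noise, m)
  }
  rownames(expr) <- sprintf("gene%04d", seq_len(n))
  colnames(expr) <- sprintf("s%02d", seq_len(m))

  te <- spec$trait_effects
  traits <- matrix(stats::rnorm(m * nrow(te), sd = spec$trait_noise_sd),
                   m, nrow(te))
  for (t in seq_len(nrow(te)))
    traits[, t] <- traits[, t] + te$effect[t] * factors[, te$module[t]]
  dimnames(traits) <- list(colnames(expr), paste0("trait", seq_len(nrow(te))))

  list(expr = expr, traits = traits, labels = labels, factors = factors,
       spec = spec)
}
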
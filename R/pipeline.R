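#' Default run configuration
#'
#' Collects the pipeline defaults: soft-threshold powers 6/9/10 for the
#' full/positive/negative channels, embedding dimension 8, lambda 2.6,
#' tau 0.8, 5,000 epochs with a 100-epoch warm-up at learning rates
#' 0.01 then 0.001, k = 8 modules, trait-filter alpha 0.1, DEM alpha 0.05
#' and 25 hub genes per module.
#'
#' @param ... Overrides for any field.
#' @return Named list.
#' @export
default_run_config <- function(...) {
  cfg <- list(betas = c(full = 6, pos = 9, neg = 10),
              candidate_betas = 1:12, r2_threshold = 0.8,
              k = 8, m_prime = 8,
              lambda = 2.6, tau = 0.8,
              max_epochs = 5000, warmup_epochs = 100,
              lr_warmup = 0.01, lr_main = 0.001,
              filter_alpha = 0.1, filter_mode = "any",
              dem_alpha = 0.05, hub_top_n = 25,
              seed = 1)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @return Named list merged over the defaults.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  cfg[names(user)] <- user
  if (!is.null(user$betas)) cfg$betas <- unlist(user$betas)
  cfg
}

#' @rdname read_run_config
#' @param cfg Configuration list.
#' @export
write_run_config <- function(cfg, path) {
  # named atomic vectors must become maps or yaml drops the names
  yaml::write_yaml(lapply(cfg, function(x)
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x), path)
  invisible(path)
}

#' Run the full gmcNet pipeline
#'
#' Optionally filters genes by trait correlation, builds the three-channel
#' TOM set, trains gmcNet, and evaluates the final partition (modularity on
#' the full TOM; DEM signal and hub genes when traits are given). When
#' `out_dir` is set, results are written via [write_outputs()].
#'
#' @param expr genes x samples expression matrix.
#' @param traits Optional samples x traits matrix.
#' @param config List from [default_run_config()].
#' @param filter Apply the trait-correlation gene filter (requires traits).
#' @param out_dir Optional output directory.
#' @return List of class `gmcnet_run`: `expr`, `toms`, `fit`, `modularity`,
#'   `dem` (or NULL), `config`, and `manifest` when written.
#' @export
run_gmcnet_pipeline <- function(expr, traits = NULL,
                                config = default_run_config(),
                                filter = !is.null(traits),
                                out_dir = NULL) {
  expr <- validate_expression(expr, drop_zero_variance = TRUE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (file.access(out_dir, 2) != 0)
      stop_gmcnet("output directory not writable: ", out_dir)
  }
  if (filter) {
    if (is.null(traits)) stop_gmcnet("gene filtering requires a trait table")
    expr <- filter_genes(expr, traits, alpha = config$filter_alpha,
                         mode = config$filter_mode)
  }
  corm <- pearson_correlation(expr)
  toms <- build_tom_set(corm, betas = config$betas)
  tcfg <- training_config(max_epochs = config$max_epochs,
                          warmup_epochs = config$warmup_epochs,
                          lr_warmup = config$lr_warmup,
                          lr_main = config$lr_main,
                          lambda_main = config$lambda,
                          tau = config$tau,
                          m_prime = config$m_prime,
                          seed = derive_seed(config$seed, "init"))
  fit <- gmcnet_train(expr, toms, k = config$k, config = tcfg)
  mod <- modularity_q(toms$tom_full, fit$labels)
  dem <- if (!is.null(traits))
    dem_signal(expr, fit$labels, config$k, traits, alpha = config$dem_alpha)
  out <- list(expr = expr, toms = toms, fit = fit, modularity = mod,
              dem = dem, config = config)
  class(out) <- "gmcnet_run"
  if (!is.null(out_dir)) out$manifest <- write_outputs(out, out_dir)
  out
}

#' @export
print.gmcnet_run <- function(x, ...) {
  cat("gmcnet_run:", nrow(x$expr), "genes x", ncol(x$expr), "samples\n")
  print(x$fit)
  cat(sprintf("modularity Q = %.4f", x$modularity$q))
  if (!is.null(x$dem)) cat(sprintf("; DEM signal = %.4f", x$dem$dem_signal))
  cat("\n")
  invisible(x)
}

#' Write pipeline outputs
#'
#' Writes `modules.tsv` (gene_id, module_label, max_probability),
#' `probs.tsv`, `loss_history.tsv`, `metrics.json`, `dem_table.tsv` and
#' per-module hub lists when traits were supplied, a `config.yaml`
#' snapshot, and a `manifest.tsv` listing every file with its MD5 checksum.
#'
#' @param run A `gmcnet_run`.
#' @param out_dir Output directory (created if needed).
#' @return data.frame manifest (file, md5), invisibly written as
#'   `manifest.tsv`.
#' @export
write_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- run$fit
  files <- character()

  modules <- data.frame(
    gene_id = rownames(run$expr),
    module_label = fit$labels,
    max_probability = sprintf("%.6f", apply(fit$probs, 1, max)),
    stringsAsFactors = FALSE)
  p <- file.path(out_dir, "modules.tsv")
  utils::write.table(modules, p, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, p)

  p <- file.path(out_dir, "probs.tsv")
  write_matrix_tsv(round(fit$probs, 8), p, id_col = "gene_id")
  files <- c(files, p)

  p <- file.path(out_dir, "loss_history.tsv")
  utils::write.table(fit$history, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, p)

  metrics <- list(modularity = run$modularity$q,
                  dem_signal = if (!is.null(run$dem)) run$dem$dem_signal,
                  k = fit$k,
                  n_genes = nrow(run$expr),
                  epochs_run = fit$epochs_run,
                  stopped_early = fit$stopped_early)
  p <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(metrics[!vapply(metrics, is.null, logical(1))],
                       p, auto_unbox = TRUE, digits = NA)
  files <- c(files, p)

  if (!is.null(run$dem)) {
    dd <- run$dem
    tab <- expand.grid(module = rownames(dd$pvalues),
                       trait = colnames(dd$pvalues),
                       stringsAsFactors = FALSE)
    tab$coefficient <- as.vector(dd$coefficients)
    tab$p_value <- as.vector(dd$pvalues)
    tab$star <- ifelse(is.na(tab$p_value), "",
                ifelse(tab$p_value <= 0.01, "**",
                ifelse(tab$p_value <= 0.05, "*", "")))
    p <- file.path(out_dir, "dem_table.tsv")
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, p)

    hub_dir <- file.path(out_dir, "hubs")
    dir.create(hub_dir, showWarnings = FALSE)
    for (l in seq_len(fit$k)) {
      if (!any(fit$labels == l)) next
      hp <- file.path(hub_dir, sprintf("K%d.tsv", l))
      utils::write.table(hub_genes(run$expr, fit$labels, l,
                                   run$config$hub_top_n),
                         hp, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, hp)
    }
  }

  p <- file.path(out_dir, "config.yaml")
  write_run_config(run$config, p)
  files <- c(files, p)

  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
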
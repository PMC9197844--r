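#' Hierarchical clustering on topological distance
#'
#' Agglomerative clustering (average linkage by default, the WGCNA
#' convention) on the distance `1 - T`, with the dendrogram cut to exactly
#' `k` clusters.
#'
#' @param tom_full Symmetric TOM with unit diagonal.
#' @param k Number of clusters.
#' @param linkage Passed to [stats::hclust()].
#' @return List of class `baseline_result`: `method`, `labels` (1..k), `k`.
#' @export
hc_cluster <- function(tom_full, k, linkage = "average") {
  n <- nrow(tom_full)
  if (k > n) stop_gmcnet("k = ", k, " exceeds n = ", n)
  d <- stats::as.dist(1 - tom_full)
  hc <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(hc, k = k)
  baseline_result("hc", unname(labels), k, names = rownames(tom_full))
}

#' K-means on expression profiles
#'
#' Standard Euclidean K-means on gene rows with Hartigan-Wong updates,
#' 10 random restarts, deterministic per seed.
#'
#' @param X genes x samples expression matrix.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param nstart Restarts.
#' @return `baseline_result`.
#' @export
kmeans_cluster <- function(X, k, seed = 1, nstart = 10) {
  if (k > nrow(X)) stop_gmcnet("k = ", k, " exceeds n = ", nrow(X))
  set.seed(as.integer(seed))
  km <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100)
  baseline_result("kmeans", unname(km$cluster), k, names = rownames(X))
}

#' PAM K-medoids on topological distance
#'
#' Partitioning around medoids on the precomputed distance `1 - T`.
#' PAM's build + swap phases are deterministic for a fixed distance matrix;
#' the seed argument is accepted for interface symmetry.
#'
#' @param tom_full Symmetric TOM with unit diagonal.
#' @param k Number of clusters.
#' @param seed Integer seed (PAM itself is deterministic).
#' @return `baseline_result`; medoid indices in `$medoids`.
#' @export
kmedoids_cluster <- function(tom_full, k, seed = 1) {
  n <- nrow(tom_full)
  if (k > n) stop_gmcnet("k = ", k, " exceeds n = ", n)
  if (k == n) {
    # every gene its own medoid; zero within-cluster distance
    out <- baseline_result("kmedoids", seq_len(n), k,
                           names = rownames(tom_full))
    out$medoids <- seq_len(n)
    return(out)
  }
  set.seed(as.integer(seed))
  pm <- cluster::pam(stats::as.dist(1 - tom_full), k = k, diss = TRUE)
  out <- baseline_result("kmedoids", unname(pm$clustering), k,
                         names = rownames(tom_full))
  out$medoids <- pm$id.med
  out
}

baseline_result <- function(method, labels, k, names = NULL) {
  structure(list(method = method, labels = as.integer(labels),
                 k = as.integer(k), gene_ids = names),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat("baseline_result [", x$method, "]: ", length(x$labels), " genes, k = ",
      x$k, "; sizes ", paste(tabulate(x$labels, x$k), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Run all baseline clusterers
#'
#' @param X Expression matrix (for K-means).
#' @param tom_full Full-channel TOM (for HC and K-medoids).
#' @param k Number of clusters.
#' @param seed Top-level seed; per-method seeds are derived.
#' @return Named list of `baseline_result`s.
#' @export
run_baselines <- function(X, tom_full, k, seed = 1) {
  list(hc = hc_cluster(tom_full, k),
       kmeans = kmeans_cluster(X, k, seed = derive_seed(seed, "kmeans")),
       kmedoids = kmedoids_cluster(tom_full, k,
                                   seed = derive_seed(seed, "kmedoids")))
}
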
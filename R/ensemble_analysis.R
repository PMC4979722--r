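# Cross-network statistics: the metric table, the Spearman correlation
# matrix, k-means/MDS clustering of metrics, hierarchical clustering with
# bootstrap support, and the end-to-end study pipeline.

metric_columns <- c("SPE", "CON", "NEST", "MOD", "RES", "ROB", "DIS",
                    "INVb", "INVn", "IMP")

#' Metric table of an ensemble
#'
#' Computes, for every assembled network, the four architecture metrics
#' (SPE, CON, NEST, MOD), the three stability metrics (RES, ROB, DIS),
#' invasibility (INVb over the `rtv` grid at glr = 1), and the reference
#' invasion record (INVn, IMP with the density-weighted mean native trait).
#'
#' @param ensemble a [generate_ensemble()] result (list of assemblies).
#' @param propagule_fraction,mode invasion settings shared by all trials.
#' @param seed base seed for the stochastic metric searches (per-network
#'   seeds are derived as `seed + index`).
#' @param rtv_points number of trait points for invasibility.
#' @param verbose print progress.
#' @return data frame with one row per network: the ten metrics, size
#'   class, kernel widths, morph counts, and whether the reference trial
#'   caused a native decline.
#' @export
metrics_table <- function(ensemble, propagule_fraction = 0.1, mode = 1,
                          seed = 1, rtv_points = 9, verbose = FALSE) {
  rows <- lapply(seq_along(ensemble), function(i) {
    log <- ensemble[[i]]
    comm <- log$community
    Q <- interaction_strength_matrix(comm)
    arch <- architecture_metrics(Q, seed = seed + i)
    rec <- ensemble_invasion_record(comm, propagule_fraction, mode)
    if (verbose) message("metrics for network ", i, "/", length(ensemble))
    data.frame(
      network = i,
      size_class = if (!is.null(log$size_class)) log$size_class else NA,
      n_events = log$n_events,
      n_animals = n_animals(comm), n_plants = n_plants(comm),
      sigma_C = log$params$sigma_C, sigma_m = log$params$sigma_m,
      sigma_A = log$params$sigma_A,
      SPE = arch$SPE, CON = arch$CON, NEST = arch$NEST, MOD = arch$MOD,
      RES = resilience(comm), ROB = robustness(Q),
      DIS = disruptiveness(comm),
      INVb = invasibility(comm, seq(0, 1, length.out = rtv_points),
                          propagule_fraction, mode),
      INVn = rec$INVn, IMP = rec$IMP,
      native_decline = rec$native_decline,
      metric_seed = seed + i)
  })
  do.call(rbind, rows)
}

#' Spearman rank-correlation matrix of network metrics
#'
#' Pairwise Spearman correlations (tie-corrected ranks) with p-values.
#' Constant columns yield `NA` (missing, not zero) for their pairs.
#'
#' @param table a [metrics_table()] data frame (or any data frame).
#' @param columns metric columns to correlate.
#' @return list with matrices `r` and `p`, and the row count `n`.
#' @export
spearman_matrix <- function(table, columns = metric_columns) {
  columns <- intersect(columns, names(table))
  X <- as.matrix(table[, columns, drop = FALSE])
  if (nrow(X) < 3) stop("need at least 3 records for correlations")
  k <- ncol(X)
  r <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  p <- r
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (stats::sd(X[, i]) == 0 || stats::sd(X[, j]) == 0) next
      ct <- suppressWarnings(cor.test(X[, i], X[, j], method = "spearman",
                                      exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p, n = nrow(X))
}

#' k-means clustering of metrics in the MDS embedding
#'
#' Embeds the metrics by classical multidimensional scaling of the distance
#' `d = 1 - r` (or `1 - |r|`), runs seeded k-means for each candidate k,
#' and selects the smallest k whose between-cluster variance share exceeds
#' the target (95% by default).
#'
#' @param corr_matrix correlation matrix (e.g. `spearman_matrix(t)$r`).
#' @param k_range candidate cluster counts.
#' @param seed RNG seed for k-means.
#' @param n_dim embedding dimension (2, matching the usual MDS plot).
#' @param var_target variance-explained threshold for selecting k.
#' @param abs_r use `1 - |r|` as the distance.
#' @param nstart k-means restarts.
#' @return list with `best_k`, `labels` (named), `variance_explained` (per
#'   k), and the `embedding` coordinates.
#' @export
cluster_metrics <- function(corr_matrix, k_range = 1:6, seed = 1, n_dim = 2,
                            var_target = 0.95, abs_r = FALSE, nstart = 50) {
  r <- corr_matrix
  if (any(is.na(r))) stop("correlation matrix contains missing values")
  d <- if (abs_r) 1 - abs(r) else 1 - r
  d[d < 0] <- 0
  emb <- if (max(d) < 1e-12) {
    # all metrics perfectly correlated: a single point, no scaling needed
    matrix(0, nrow(d), min(n_dim, nrow(d) - 1), dimnames = list(rownames(d), NULL))
  } else cmdscale(as.dist(d), k = min(n_dim, nrow(d) - 1))
  totss <- sum(scale(emb, scale = FALSE)^2)
  ve <- setNames(numeric(length(k_range)), k_range)
  fits <- vector("list", length(k_range))
  for (s in seq_along(k_range)) {
    k <- k_range[s]
    if (k == 1) {
      ve[s] <- if (totss < 1e-12) 1 else 0
      fits[[s]] <- list(cluster = setNames(rep(1L, nrow(emb)), rownames(r)))
      next
    }
    nd <- nrow(unique(round(emb, 12)))
    if (k >= nd) {  # at least as many centers as distinct points
      ve[s] <- 1
      grp <- match(apply(round(emb, 12), 1, paste, collapse = ","),
                   unique(apply(round(emb, 12), 1, paste, collapse = ",")))
      fits[[s]] <- list(cluster = setNames(grp, rownames(r)))
      next }
    km <- with_seed(seed + k, kmeans(emb, centers = k, nstart = nstart))
    ve[s] <- km$betweenss / km$totss
    fits[[s]] <- km
  }
  ok <- which(ve > var_target)
  best <- if (length(ok)) min(ok) else which.max(ve)
  labels <- fits[[best]]$cluster
  names(labels) <- rownames(r)
  list(best_k = k_range[best], labels = labels, variance_explained = ve,
       embedding = emb)
}

hclust_node_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    get1 <- function(v) if (v < 0) hc$labels[-v] else sets[[v]]
    sets[[i]] <- sort(c(get1(hc$merge[i, 1]), get1(hc$merge[i, 2])))
  }
  sets
}

#' Hierarchical clustering of metrics with bootstrap support
#'
#' Average-linkage hierarchical clustering on `d = 1 - r` of the metric
#' columns, with cluster support estimated by an ordinary bootstrap over
#' the table rows: the support of a cluster is the proportion of resamples
#' whose dendrogram contains exactly the same member set.
#'
#' @param table a [metrics_table()] data frame.
#' @param columns metric columns to cluster.
#' @param n_boot bootstrap resamples.
#' @param alpha support threshold for reporting a cluster.
#' @param seed RNG seed.
#' @return list with the `hclust` object, a data frame `clusters`
#'   (members, size, support), and `supported` (the subset with
#'   support > alpha).
#' @export
hierarchical_clusters <- function(table, columns = metric_columns,
                                  n_boot = 1000, alpha = 0.95, seed = 1) {
  columns <- intersect(columns, names(table))
  if (length(columns) < 3) stop("need at least 3 columns")
  X <- as.matrix(table[, columns, drop = FALSE])
  rmat <- suppressWarnings(cor(X, method = "spearman"))
  rmat[is.na(rmat)] <- 0; diag(rmat) <- 1
  hc <- hclust(as.dist(pmax(1 - rmat, 0)), method = "average")
  sets <- hclust_node_sets(hc)
  keys <- vapply(sets, paste, "", collapse = "|")
  counts <- setNames(numeric(length(keys)), keys)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(X), replace = TRUE)
      rb <- suppressWarnings(cor(X[idx, , drop = FALSE], method = "spearman"))
      rb[is.na(rb)] <- 0; diag(rb) <- 1
      hb <- hclust(as.dist(pmax(1 - rb, 0)), method = "average")
      kb <- vapply(hclust_node_sets(hb), paste, "", collapse = "|")
      hit <- keys %in% kb
      counts[hit] <- counts[hit] + 1
    }
  })
  clusters <- data.frame(members = keys,
                         size = lengths(sets),
                         support = counts / n_boot)
  # the root (all columns) is trivially present in every resample
  clusters <- clusters[clusters$size < length(columns), , drop = FALSE]
  list(hclust = hc, clusters = clusters,
       supported = clusters[clusters$support > alpha, , drop = FALSE])
}

#' Run the full study pipeline
#'
#' Orchestrates ensemble generation, metric computation, the Spearman
#' matrix, k-means/MDS clustering and hierarchical clustering, and
#' optionally writes the tables (metrics_table.csv, spearman.csv,
#' embedding.csv, clusters.json, manifest.json) to a directory. Re-running
#' with the same configuration reproduces the outputs bit-for-bit.
#'
#' @param config list with any of: `sizes` (named quota vector), `sweep`,
#'   `seed`, `propagule_fraction`, `mode`, `rtv_points`, `k_range`,
#'   `n_boot`, `alpha`, `max_attempts`.
#' @param out_dir optional output directory.
#' @param verbose print per-stage progress.
#' @return list with `ensemble`, `table`, `spearman`, `kmeans`, `hclust`,
#'   and the reproducibility `manifest`.
#' @export
run_full_study <- function(config = list(), out_dir = NULL, verbose = FALSE) {
  cfg <- modifyList(list(
    sizes = c(small = 4), sweep = exp(seq(-3, 1, by = 0.25)), seed = 1,
    propagule_fraction = 0.1, mode = 1, rtv_points = 9,
    k_range = 1:6, n_boot = 200, alpha = 0.95, max_attempts = 2000),
    config)
  stage <- function(name, expr) {
    if (verbose) message("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  ens <- stage("generate_ensemble",
               generate_ensemble(cfg$sizes, cfg$sweep, cfg$seed,
                                 max_attempts = cfg$max_attempts,
                                 verbose = verbose))
  tab <- stage("metrics_table",
               metrics_table(ens, cfg$propagule_fraction, cfg$mode,
                             seed = cfg$seed, rtv_points = cfg$rtv_points,
                             verbose = verbose))
  sp <- stage("spearman_matrix", spearman_matrix(tab))
  km <- stage("cluster_metrics",
              cluster_metrics(sp$r, cfg$k_range, seed = cfg$seed))
  hcl <- stage("hierarchical_clusters",
               hierarchical_clusters(tab, n_boot = cfg$n_boot,
                                     alpha = cfg$alpha, seed = cfg$seed))
  manifest <- list(package_version = as.character(utils::packageVersion("mutnet")),
                   seed = cfg$seed, sizes = as.list(cfg$sizes),
                   sweep = cfg$sweep,
                   propagule_fraction = cfg$propagule_fraction,
                   mode = cfg$mode, rtv_points = cfg$rtv_points,
                   n_networks = nrow(tab))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(tab, file.path(out_dir, "metrics_table.csv"), row.names = FALSE)
    write.csv(sp$r, file.path(out_dir, "spearman.csv"))
    write.csv(km$embedding, file.path(out_dir, "embedding.csv"))
    jsonlite::write_json(
      list(kmeans = list(best_k = km$best_k, labels = as.list(km$labels)),
           hierarchical = hcl$clusters),
      file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(ensemble = ens, table = tab, spearman = sp, kmeans = km, hclust = hcl,
       manifest = manifest)
}
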
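#' Stratified sampling schemes for group-level clustering
#'
#' Healthy subjects contribute 100 epochs as 48 wake + 13 from each sleep
#' stage; DOC subjects contribute 50 day-time + 50 night-time epochs.
#'
#' @param group "healthy" or "doc".
#' @return Named integer vector of per-stratum quotas (summing to 100).
#' @export
sampling_scheme <- function(group = c("healthy", "doc")) {
  switch(match.arg(group),
         healthy = c(W = 48L, N1 = 13L, N2 = 13L, N3 = 13L, R = 13L),
         doc = c(day = 50L, night = 50L))
}

#' Stratified per-subject epoch sampling
#'
#' Samples the scheme's quota from each stratum without replacement,
#' deterministically for a given seed; the selected epochs are ordered by
#' stratum (scheme order) and, within stratum, by their position in the
#' recording. Subjects with fewer epochs than a quota are sampled with
#' replacement with a warning (or error in strict mode).
#'
#' @param features epochs x channels feature matrix.
#' @param strata character vector of per-epoch stratum tags (stage or
#'   day/night).
#' @param scheme named quota vector from [sampling_scheme()].
#' @param seed integer seed.
#' @param strict error instead of sampling with replacement when a stratum
#'   is short (default FALSE).
#' @return List with `features` (quota-total x channels), `strata` and the
#'   selected `indices`.
#' @export
sample_epochs <- function(features, strata, scheme, seed = 1L, strict = FALSE) {
  assert_that(nrow(features) == length(strata),
              "one stratum tag per feature row is required")
  idx_out <- integer(0)
  with_preserved_seed(seed, {
    for (s in names(scheme)) {
      avail <- which(strata == s)
      if (length(avail) < scheme[[s]]) {
        if (strict) stop_docsleep("insufficient epochs in stratum ", s, ": ",
                                  length(avail), " < ", scheme[[s]])
        if (length(avail) == 0) stop_docsleep("no epochs in stratum ", s)
        warning("stratum ", s, " has only ", length(avail), " epochs; ",
                "sampling with replacement")
        take <- sample(avail, scheme[[s]], replace = TRUE)
      } else {
        take <- sample(avail, scheme[[s]], replace = FALSE)
      }
      idx_out <- c(idx_out, sort(take))
    }
  })
  list(features = features[idx_out, , drop = FALSE],
       strata = rep(names(scheme), scheme),
       indices = idx_out)
}

#' Average stratified samples across the subjects of a group
#'
#' Row k of the result is the mean, over subjects, of each subject's k-th
#' sampled epoch — i.e. epochs are paired position-wise within stratum (each
#' subject's sample is time-ordered within stratum). All subjects must have
#' been sampled with the same scheme.
#'
#' @param samples list of [sample_epochs()] results, one per subject.
#' @param group group label to attach.
#' @return A `group_features` matrix (rows = group-level epochs) with the
#'   stratum tags in attribute `"strata"`.
#' @export
group_average <- function(samples, group = NA_character_) {
  assert_that(length(samples) >= 1, "need at least one subject")
  strata <- samples[[1]]$strata
  for (s in samples)
    assert_that(identical(s$strata, strata), "subjects sampled with mixed schemes")
  m <- Reduce(`+`, lapply(samples, `[[`, "features")) / length(samples)
  structure(m, strata = strata, group = group,
            class = c("group_features", "matrix", "array"))
}

#' Agglomerative hierarchical clustering of group-level epochs
#'
#' Average-linkage agglomeration on Euclidean row distances: starting from
#' singletons, the two most similar clusters are merged and distances to the
#' new cluster updated (mean of all pairwise member distances) until a single
#' cluster remains.
#'
#' @param mat numeric matrix of group-level epochs x channels.
#' @return A `pe_cluster_tree`: the `stats::hclust` object, the merge
#'   heights, leaf count and a monotonicity flag.
#' @export
hcluster <- function(mat) {
  assert_that(nrow(mat) >= 2, "need at least two rows to cluster")
  assert_that(!anyNA(mat), "feature matrix contains missing values")
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"), method = "average")
  structure(list(hclust = hc, heights = hc$height, n = nrow(mat),
                 monotone = !is.unsorted(hc$height),
                 strata = attr(mat, "strata"), group = attr(mat, "group")),
            class = "pe_cluster_tree")
}

#' @export
print.pe_cluster_tree <- function(x, ...) {
  cat(sprintf("<pe_cluster_tree> %d leaves, root height %.4g%s\n", x$n,
              max(x$heights), if (x$monotone) "" else " (non-monotone merges!)"))
  invisible(x)
}

#' Dissimilarity cut-off yielding a target number of clusters
#'
#' Returns the midpoint of the open interval of heights between the
#' (n-k)-th and (n-k+1)-th merges, so cutting the dendrogram at the returned
#' height produces exactly `k` flat clusters. (On the study's healthy data
#' this anchored value was 0.035 for k = 5.)
#'
#' @param tree a `pe_cluster_tree`.
#' @param k target cluster count (default 5, one per expected sleep stage).
#' @return The cut-off height.
#' @export
select_cutoff <- function(tree, k = 5) {
  n <- tree$n
  assert_that(k >= 1 && k <= n, "k must be between 1 and the number of leaves")
  h <- sort(tree$heights)
  if (k == 1) return(max(h) * 1.001 + 1e-12)
  if (k == n) return(h[1] / 2)
  (h[n - k] + h[n - k + 1]) / 2
}

#' Cut a cluster tree at a dissimilarity threshold
#'
#' Flat clusters are the connected components of merges below the cut-off.
#'
#' @param tree a `pe_cluster_tree`.
#' @param cutoff dissimilarity threshold (>= 0).
#' @return Integer cluster assignment per leaf/row.
#' @export
cut_tree <- function(tree, cutoff) {
  assert_that(cutoff >= 0, "cutoff must be non-negative")
  as.integer(stats::cutree(tree$hclust, h = cutoff))
}

#' Summarize flat clusters of a group feature matrix
#'
#' Reports, per cluster: size, mean PE pooled across member epochs and
#' channels, two SDs (pooled across epochs x channels, and across epoch
#' means — published summaries are ambiguous between the two), and the
#' stratum composition. The root height (dissimilarity of the final merge,
#' i.e. between the two most distinct clusters) is attached.
#'
#' @param assignments integer cluster labels per row (from [cut_tree()]).
#' @param mat the clustered matrix.
#' @param strata optional per-row stratum tags.
#' @param root_height optional root merge height to record.
#' @return A `cluster_summary` list.
#' @export
summarize_clusters <- function(assignments, mat, strata = attr(mat, "strata"),
                               root_height = NULL) {
  assert_that(length(assignments) == nrow(mat),
              "assignments must cover all rows")
  ks <- sort(unique(assignments))
  per <- lapply(ks, function(k) {
    rows <- mat[assignments == k, , drop = FALSE]
    comp <- if (!is.null(strata)) {
      tb <- table(strata[assignments == k])
      as.list(tb / sum(tb))
    } else NULL
    list(cluster = k, size = nrow(rows),
         mean_pe = mean(rows),
         sd_pooled = stats::sd(as.vector(rows)),
         sd_epoch_means = stats::sd(rowMeans(rows)),
         composition = comp)
  })
  structure(list(clusters = per, n_clusters = length(ks),
                 root_height = root_height),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("<cluster_summary> %d clusters", x$n_clusters))
  if (!is.null(x$root_height)) cat(sprintf(", root height %.4g", x$root_height))
  cat("\n")
  for (cl in x$clusters)
    cat(sprintf("  cluster %d: size %d, mean PE %.3f (SD %.3f)\n",
                cl$cluster, cl$size, cl$mean_pe, cl$sd_pooled))
  invisible(x)
}

#' Export a cluster tree as a merge table (CSV) or Newick string
#'
#' @param tree a `pe_cluster_tree`.
#' @param file output path.
#' @return `file` (or the Newick string when `file` is NULL), invisibly.
#' @export
write_merge_table <- function(tree, file) {
  m <- tree$hclust$merge
  utils::write.csv(data.frame(step = seq_len(nrow(m)), left_id = m[, 1],
                              right_id = m[, 2], height = tree$heights),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_merge_table
#' @export
tree_to_newick <- function(tree, file = NULL) {
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(file)
}
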
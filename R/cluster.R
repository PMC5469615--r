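# Unbiased classification of response profiles: PCA on mean-centered
# standardized profiles, Euclidean distance on the first three principal
# components, complete-linkage agglomeration, and cluster labels sorted in
# descending order of the total z-score between 5 and 10 s after cue onset.
# The procedure is fully deterministic and invariant to input order.

#' Cluster standardized response profiles
#'
#' @param profiles units x timepoints matrix of standardized (z-scored)
#'   response profiles; rows may be named.
#' @param time_axis timepoint times (s relative to cue onset).
#' @param k number of clusters to cut (default 2, the two response types).
#' @param n_pc principal components used for the distance metric (default 3);
#'   when the profile matrix has lower rank the available components are used
#'   and the result is flagged.
#' @param ordering_window window (s) over which the total z-score orders the
#'   clusters (default `c(5, 10)`, the post-reward evaluation period).
#' @return A list of class `cluster_model`: `profiles`, `time_axis`,
#'   `pc_scores`, `linkage` (an [stats::hclust] tree), `labels` (1..k, with
#'   cluster 1 having the highest ordering statistic), `ordering_stat`
#'   (per-cluster mean of the per-unit summed z over the window), `k`,
#'   `rank_flagged`.
#' @export
cluster_profiles <- function(profiles, time_axis, k = 2, n_pc = 3,
                             ordering_window = c(5, 10)) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (k > n) stop("k must not exceed the number of units")
  if (ncol(profiles) < 3L) stop("need at least three timepoints")
  stopifnot(ncol(profiles) == length(time_axis))
  centered <- scale(profiles, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(centered, center = FALSE, scale. = FALSE)
  rank <- max(1L, sum(pc$sdev > pc$sdev[1] * 1e-8))
  avail <- min(n_pc, rank)
  rank_flagged <- avail < n_pc
  if (rank_flagged)
    warning(sprintf("profile matrix supports only %d principal component(s)",
                    avail))
  scores <- pc$x[, seq_len(avail), drop = FALSE]
  tree <- stats::hclust(stats::dist(scores), method = "complete")
  raw <- stats::cutree(tree, k = k)
  idx <- window_index(time_axis, ordering_window)
  unit_z <- rowSums(profiles[, idx, drop = FALSE])
  stat <- vapply(seq_len(k), function(g) mean(unit_z[raw == g]), 0)
  ord <- order(stat, decreasing = TRUE)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  structure(list(profiles = profiles, time_axis = time_axis,
                 pc_scores = scores, linkage = tree,
                 labels = relabel[raw], ordering_stat = sort(stat,
                                                            decreasing = TRUE),
                 k = k, ordering_window = ordering_window,
                 rank_flagged = rank_flagged),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d profiles -> %d clusters (sizes %s), %d PCs, complete linkage\n",
              nrow(x$profiles), x$k,
              paste(tabulate(x$labels, x$k), collapse = "/"),
              ncol(x$pc_scores)))
  invisible(x)
}

#' Assign response types from a two-cluster model
#'
#' The cluster with the higher total z-score in the post-reward window (the
#' rebound signature) is the inhibition-then-excitation `typeII`; the other is
#' the pure-inhibition `typeI`. Ties in the ordering statistic are broken
#' deterministically by cluster size (larger cluster becomes `typeI`), with a
#' flag; when the contrast between the two ordering statistics is small the
#' assignment is flagged as low-contrast.
#'
#' @param model a [cluster_model()] with `k = 2`.
#' @param min_contrast flag threshold on the difference of ordering
#'   statistics.
#' @return A list with `type` (per-unit factor `typeI`/`typeII`),
#'   `type_of_cluster`, and `flagged`.
#' @export
assign_type <- function(model, min_contrast = 1) {
  stopifnot(inherits(model, "cluster_model"))
  if (model$k != 2L) stop("type assignment requires k = 2")
  stat <- model$ordering_stat        # descending; cluster 1 has the highest
  sizes <- tabulate(model$labels, 2L)
  flagged <- FALSE
  type_of_cluster <- c("typeII", "typeI")   # cluster 1 = rebound cluster
  if (isTRUE(all.equal(stat[1], stat[2]))) {
    flagged <- TRUE
    type_of_cluster <- if (sizes[1] >= sizes[2]) c("typeI", "typeII")
                       else c("typeII", "typeI")
  } else if (abs(stat[1] - stat[2]) < min_contrast) flagged <- TRUE
  list(type = factor(type_of_cluster[model$labels],
                     levels = c("typeI", "typeII")),
       type_of_cluster = type_of_cluster, flagged = flagged)
}

#' Dendrogram export in Newick-like text form
#'
#' @param model a [cluster_model()].
#' @return A single Newick string with merge heights as branch lengths.
#' @export
dendrogram_newick <- function(model) {
  tree <- model$linkage
  lab <- tree$labels %||% as.character(seq_len(nrow(model$profiles)))
  node <- function(i, h_parent) {
    if (i < 0) sprintf("%s:%g", lab[-i], h_parent)
    else {
      h <- tree$height[i]
      sprintf("(%s,%s):%g", node(tree$merge[i, 1], h),
              node(tree$merge[i, 2], h), h_parent - h)
    }
  }
  top <- length(tree$height)
  h <- tree$height[top]
  paste0("(", node(tree$merge[top, 1], h), ",",
         node(tree$merge[top, 2], h), ");")
}
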
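# Dendrogram grouping of phase-aligned trials by Euclidean waveform distance.

#' Pairwise Euclidean distances between trials
#'
#' Distances are computed on the aligned, non-normalized waveforms so that
#' amplitude differences separate classes (low-amplitude trials form their
#' own branch of the tree).
#'
#' @param ensemble An [lfp_ensemble()] of aligned trials.
#' @return A `stats::dist` object (lower triangle of the symmetric,
#'   zero-diagonal distance matrix).
#' @export
pairwise_distances <- function(ensemble) {
  stopifnot(inherits(ensemble, "lfp_ensemble"))
  dist(ensemble_matrix(ensemble), method = "euclidean")
}

#' Build an agglomerative dendrogram of trials
#'
#' Hierarchical agglomerative clustering of the trial waveforms under the
#' chosen linkage (average/UPGMA by default). Merging is delegated to
#' [stats::hclust()], which is deterministic with index-order tie breaking.
#'
#' @param distances A `stats::dist` object or symmetric distance matrix.
#' @param linkage One of `"average"`, `"single"`, `"complete"`, `"ward"`
#'   (Ward's criterion on squared distances, `ward.D2`).
#' @return Object of class `lfp_dendrogram` wrapping the `hclust` fit, with
#'   `merges` (data frame `node_a`, `node_b`, `height`; negative entries
#'   are leaves), `n_leaves` and `linkage`.
#' @export
build_dendrogram <- function(distances,
                             linkage = c("average", "single", "complete",
                                         "ward")) {
  linkage <- match.arg(linkage)
  if (is.matrix(distances)) distances <- as.dist(distances)
  if (!inherits(distances, "dist")) stop("`distances` must be a dist object")
  n <- attr(distances, "Size")
  if (n < 2L) stop("need at least 2 trials to build a dendrogram")
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- hclust(distances, method = method)
  merges <- data.frame(node_a = hc$merge[, 1], node_b = hc$merge[, 2],
                       height = hc$height)
  structure(list(hclust = hc, merges = merges, n_leaves = n,
                 linkage = linkage,
                 labels = attr(distances, "Labels")),
            class = "lfp_dendrogram")
}

#' @export
print.lfp_dendrogram <- function(x, ...) {
  cat(sprintf("<lfp_dendrogram> %d leaves, %s linkage, root height %.4g\n",
              x$n_leaves, x$linkage, max(x$merges$height)))
  invisible(x)
}

#' Cut a dendrogram into groups
#'
#' Groups are the connected components left after removing all merges above
#' the cutoff height, or the unique `k`-group cut. Group labels are
#' renumbered in order of first appearance along the trial index.
#'
#' @param model An `lfp_dendrogram` from [build_dendrogram()].
#' @param cutoff Height threshold (merges strictly above it are removed).
#' @param k Target number of groups (alternative to `cutoff`).
#' @return Object of class `group_assignment` with `labels` (integer per
#'   trial), `group_sizes`, and the cut specification.
#' @export
cut_dendrogram <- function(model, cutoff = NULL, k = NULL) {
  stopifnot(inherits(model, "lfp_dendrogram"))
  if (is.null(cutoff) == is.null(k))
    stop("supply exactly one of `cutoff` or `k`")
  if (!is.null(k)) {
    if (k < 1 || k > model$n_leaves) stop("invalid group count `k`")
    raw <- cutree(model$hclust, k = k)
  } else {
    if (cutoff <= 0) stop("`cutoff` must be > 0")
    raw <- cutree(model$hclust, h = cutoff)
  }
  # renumber groups by first appearance
  labels <- as.integer(factor(raw, levels = unique(raw)))
  structure(list(labels = labels,
                 trial_ids = model$labels,
                 group_sizes = as.integer(table(labels)),
                 cutoff = cutoff, k = if (is.null(k)) max(labels) else k),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("<group_assignment> %d groups over %d trials (sizes: %s)\n",
              max(x$labels), length(x$labels),
              paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}

#' Pointwise mean waveform of each group
#'
#' @param ensemble An [lfp_ensemble()].
#' @param assignment A `group_assignment` from [cut_dendrogram()], or an
#'   integer vector of group labels.
#' @return Named list of [lfp_ts()] group averages, in group-label order.
#' @export
group_average <- function(ensemble, assignment) {
  stopifnot(inherits(ensemble, "lfp_ensemble"))
  labels <- if (inherits(assignment, "group_assignment"))
    assignment$labels else as.integer(assignment)
  if (length(labels) != length(ensemble$trials))
    stop("one label per trial required")
  m <- ensemble_matrix(ensemble)
  groups <- sort(unique(labels))
  out <- lapply(groups, function(g) {
    rows <- which(labels == g)
    if (length(rows) == 0L) stop("empty group ", g)
    lfp_ts(colMeans(m[rows, , drop = FALSE]), dt = ensemble$dt,
           t0 = ensemble$trials[[rows[1]]]$t0)
  })
  names(out) <- paste0("group_", groups)
  out
}
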
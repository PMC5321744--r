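#' k-means classification of genes
#'
#' Lloyd's algorithm with Euclidean distance, taking the best of
#' \code{nInit} seeded random initialisations by within-cluster sum of
#' squares; deterministic given \code{seed}. Features may be metagene
#' profile rows (genes x bins) or a single gene-level column (scalar
#' clustering) -- the caller's choice, recorded in the result.
#'
#' When the data admit fewer than \code{k} distinct points, the result is
#' returned with the \code{degenerate} flag set (one cluster per distinct
#' point) instead of failing.
#'
#' @param features numeric matrix with genes as (named) rows, or a named
#'   numeric vector.
#' @param k number of clusters.
#' @param seed integer seed for the initialisations.
#' @param nInit number of random restarts (default 10).
#' @return A \linkS4class{ClusterResult}.
#' @export
kmeansCluster <- function(features, k, seed = 1L, nInit = 10L) {
  if (is.null(dim(features)))
    features <- matrix(features, ncol = 1,
                       dimnames = list(names(features), "value"))
  if (anyNA(features))
    stop("features contain missing values; filter genes before clustering")
  if (is.null(rownames(features))) stop("feature rows must be named by gene")
  n <- nrow(features)
  if (k >= n && k > 1L) stop("k must be smaller than the number of genes")
  if (nInit < 1L) stop("nInit must be >= 1")
  nDistinct <- nrow(unique(features))
  if (nDistinct <= k) {
    ## degenerate: ties everywhere; one cluster per distinct feature point
    key <- apply(features, 1L, paste, collapse = "\r")
    lab <- as.integer(factor(key, levels = unique(key)))
    centers <- unique(features)
    return(new("ClusterResult",
               labels = stats::setNames(lab, rownames(features)),
               k = as.integer(k), centers = as.matrix(centers),
               inertia = 0, seed = as.integer(seed),
               nInit = as.integer(nInit), degenerate = nDistinct < k))
  }
  fit <- NULL
  for (attempt in 0:4) {
    set.seed(seed + attempt)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(features, centers = k, nstart = nInit,
                                     iter.max = 100L, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(fit) && length(unique(fit$cluster)) == k) break
    fit <- NULL
  }
  if (is.null(fit))
    stop("k-means failed to produce ", k,
         " non-empty clusters after repeated re-initialisation")
  new("ClusterResult",
      labels = stats::setNames(as.integer(fit$cluster), rownames(features)),
      k = as.integer(k), centers = fit$centers,
      inertia = fit$tot.withinss, seed = as.integer(seed),
      nInit = as.integer(nInit), degenerate = FALSE)
}

#' @describeIn kmeansCluster cluster label per gene.
#' @param x a ClusterResult.
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn kmeansCluster per-cluster mean feature vectors.
#' @export
clusterCenters <- function(x) x@centers

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: k=%d over %d genes (inertia %.4g%s)\n",
              object@k, length(object@labels), object@inertia,
              if (object@degenerate) ", DEGENERATE" else ""))
  print(table(cluster = object@labels))
})

#' Select the extreme-mean cluster as a GeneSet
#'
#' Picks the cluster whose mean feature value (mean over feature columns for
#' profile clustering) is maximal or minimal -- e.g. the "high RNAPII
#' occupancy" class of a k=3 profile clustering. Ties are broken toward the
#' larger cluster (reported via a message).
#'
#' @param result a \linkS4class{ClusterResult}.
#' @param direction \code{"highest"} or \code{"lowest"}.
#' @param name label for the returned set.
#' @return A \linkS4class{GeneSet} whose universe is all clustered genes.
#'   When the clustering was degenerate, the returned set carries the single
#'   flagged cluster and a warning is raised.
#' @export
selectExtremeCluster <- function(result, direction = c("highest", "lowest"),
                                 name = NULL) {
  direction <- match.arg(direction)
  if (result@degenerate)
    warning("clustering was degenerate; extreme-cluster selection is a ",
            "single flagged cluster")
  means <- rowMeans(result@centers)
  target <- if (direction == "highest") max(means) else min(means)
  cand <- which(means == target)
  if (length(cand) > 1L) {
    sizes <- table(result@labels)[as.character(cand)]
    message("tie among clusters ", paste(cand, collapse = ", "),
            "; choosing the larger cluster")
    cand <- cand[which.max(sizes)]
  }
  if (is.null(name)) name <- paste0(direction, "_cluster")
  geneSet(name, names(result@labels)[result@labels == cand],
          names(result@labels))
}
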
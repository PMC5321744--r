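#' Construct a GeneSet
#'
#' @param name set label.
#' @param members character vector of gene_ids.
#' @param universe character vector: the gene universe the set was selected
#'   from (members must be a subset).
#' @return A \linkS4class{GeneSet}.
#' @export
geneSet <- function(name, members, universe) {
  new("GeneSet", name = name, members = unique(as.character(members)),
      universe = unique(as.character(universe)))
}

#' @describeIn geneSet set members.
#' @param x a GeneSet.
#' @export
setMembers <- function(x) x@members

#' @describeIn geneSet universe size.
#' @export
universeSize <- function(x) length(x@universe)

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s': %d genes in a universe of %d\n",
              object@name, length(object@members), length(object@universe)))
})

#' Threshold-defined gene set from an occupancy-change column
#'
#' Selects genes whose change passes an inclusive cutoff (\code{<=} or
#' \code{>=}, matching threshold conventions such as log2 fold-change
#' <= -0.5). The universe is the set of genes with non-missing values in the
#' column.
#'
#' @param changes named numeric vector of per-gene changes, or an
#'   \linkS4class{OccupancyTable} plus \code{sample}.
#' @param cutoff threshold value.
#' @param direction \code{"le"} (<= cutoff) or \code{"ge"} (>= cutoff).
#' @param sample column name when \code{changes} is a table.
#' @param name set label.
#' @return A \linkS4class{GeneSet}.
#' @export
thresholdGeneSet <- function(changes, cutoff, direction = c("le", "ge"),
                             sample = NULL, name = NULL) {
  direction <- match.arg(direction)
  if (is(changes, "OccupancyTable")) {
    tag <- sampleTags(changes)[[sample]]
    if (tag != "log2_mutant_over_wt")
      warning("thresholding a column tagged '", tag,
              "', not a mutant/WT change column")
    changes <- occupancyColumn(changes, sample)
  }
  universe <- names(changes)[!is.na(changes)]
  if (length(universe) == 0L) stop("all change values are missing")
  vals <- changes[universe]
  hit <- if (direction == "le") vals <= cutoff else vals >= cutoff
  if (is.null(name))
    name <- sprintf("change_%s_%g", direction, cutoff)
  geneSet(name, universe[hit], universe)
}

#' Hypergeometric overlap of two gene sets
#'
#' Inclusive upper-tail (enrichment) hypergeometric probability of drawing at
#' least the observed overlap:
#' p = sum_{i >= k} C(K, i) C(N - K, n - i) / C(N, n), with N the shared
#' universe size, K = |A|, n = |B| and k = |A intersect B|. When the two
#' universes differ, their intersection is used (and the sets are restricted
#' to it), with a message.
#'
#' @param setA,setB \linkS4class{GeneSet}s.
#' @return An \linkS4class{OverlapResult}.
#' @export
hypergeometricOverlap <- function(setA, setB) {
  U <- setA@universe
  if (!setequal(setA@universe, setB@universe)) {
    U <- intersect(setA@universe, setB@universe)
    message("gene-set universes differ; using their intersection (",
            length(U), " genes)")
  }
  A <- intersect(setA@members, U)
  B <- intersect(setB@members, U)
  N <- length(U); K <- length(A); n <- length(B)
  k <- length(intersect(A, B))
  ## P[X >= k] for X ~ Hypergeometric(N, K, n), inclusive tail
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  new("OverlapResult", nUniverse = N, nA = K, nB = n,
      nOverlap = k, pValue = p)
}

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf(
    "OverlapResult: |A|=%d, |B|=%d, overlap=%d in universe of %d; P = %.4g\n",
    object@nA, object@nB, object@nOverlap, object@nUniverse, object@pValue))
})

#' Read / write a GeneSet as one-gene-per-line text
#'
#' The header comment carries the set name and universe size; the universe
#' itself is stored after a \code{##universe} separator so sets round-trip.
#'
#' @param path text file.
#' @export
writeGeneSet <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# name=%s universe_size=%d", x@name,
                       length(x@universe)),
               x@members, "##universe", x@universe), con)
  invisible(path)
}

#' @rdname writeGeneSet
#' @export
readGeneSet <- function(path) {
  lines <- readLines(path)
  nm <- sub(".*name=([^ ]+).*", "\\1", lines[1])
  body <- lines[-1]
  sep <- match("##universe", body)
  geneSet(nm, body[seq_len(sep - 1L)], body[-seq_len(sep)])
}
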
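#' Metagene (scale-regions) configuration
#'
#' Parameters of the flank--scaled-body--flank matrix: fixed-width flank bins
#' upstream of the TSS and downstream of the TES, and a gene body rescaled to
#' a fixed number of bins by length-weighted averaging. Defaults (500 bp
#' flanks, 10 bp flank bins, 60 body bins) suit compact yeast-sized genes.
#'
#' @param upstream_bp,downstream_bp flank lengths in bp; must be divisible by
#'   \code{flank_bin_bp}.
#' @param body_bins number of bins the gene body is rescaled to.
#' @param flank_bin_bp flank bin width in bp.
#' @param missing_policy what to do when a flank extends past a chromosome
#'   end: \code{"zero"} counts the missing stretch as zero signal (matrix
#'   shape is stable across gene sets), \code{"drop"} removes the gene's row.
#' @return list of validated settings.
#' @export
metageneConfig <- function(upstream_bp = 500L, downstream_bp = 500L,
                           body_bins = 60L, flank_bin_bp = 10L,
                           missing_policy = c("zero", "drop")) {
  missing_policy <- match.arg(missing_policy)
  if (body_bins < 1L) stop("body_bins must be >= 1")
  if (upstream_bp %% flank_bin_bp != 0L || downstream_bp %% flank_bin_bp != 0L)
    stop("flank lengths must be divisible by flank_bin_bp")
  list(upstream_bp = as.integer(upstream_bp),
       downstream_bp = as.integer(downstream_bp),
       body_bins = as.integer(body_bins),
       flank_bin_bp = as.integer(flank_bin_bp),
       missing_policy = missing_policy)
}

#' Scale-regions metagene matrix
#'
#' For every gene: the upstream flank is binned at \code{flank_bin_bp}, the
#' gene body is resampled to exactly \code{body_bins} bins by length-weighted
#' averaging of the overlapping track bins, and the downstream flank is
#' binned at \code{flank_bin_bp}. Minus-strand genes are reversed so that
#' column order is always 5'->3' (column 1 = promoter-distal upstream edge).
#' Genes shorter than one track bin are averaged over the single overlapping
#' bin.
#'
#' @param track a \linkS4class{CoverageTrack}.
#' @param genes named GRanges annotation.
#' @param config a \code{\link{metageneConfig}}.
#' @return A \linkS4class{MetageneMatrix}.
#' @export
scaleRegionsMatrix <- function(track, genes, config = metageneConfig()) {
  gi <- geneIntervals(genes)
  nUp <- config$upstream_bp %/% config$flank_bin_bp
  nDn <- config$downstream_bp %/% config$flank_bin_bp
  nCol <- nUp + config$body_bins + nDn
  if (nrow(gi) == 0L) {
    return(new("MetageneMatrix",
               matrix = matrix(numeric(), 0L, nCol),
               tssColumn = nUp + 1L, tesColumn = nUp + config$body_bins,
               config = config))
  }
  rows <- matrix(NA_real_, nrow(gi), nCol,
                 dimnames = list(gi$gene_id, NULL))
  dropRow <- logical(nrow(gi))
  cums <- lapply(names(track@values), function(cn)
    .trackCum(track@values[[cn]], track@seqlengths[[cn]], track@stepSize))
  names(cums) <- names(track@values)
  for (i in seq_len(nrow(gi))) {
    chrom <- gi$chrom[i]
    vals <- track@values[[chrom]]
    if (is.null(vals)) { dropRow[i] <- TRUE; next }
    len <- track@seqlengths[[chrom]]
    s <- gi$start[i]; e <- gi$end[i]
    if (gi$strand[i] == "+") {
      edges <- c(seq(s - config$upstream_bp, s, by = config$flank_bin_bp),
                 s + (e - s) * seq_len(config$body_bins) / config$body_bins,
                 seq(e + config$flank_bin_bp, e + config$downstream_bp,
                     length.out = nDn))
    } else {
      ## 5' end is `e`; walk right-to-left so columns stay 5'->3'
      edges <- c(seq(e + config$upstream_bp, e, by = -config$flank_bin_bp),
                 e - (e - s) * seq_len(config$body_bins) / config$body_bins,
                 seq(e - (e - s) - config$flank_bin_bp,
                     e - (e - s) - config$downstream_bp,
                     length.out = nDn))
    }
    if (config$missing_policy == "drop" &&
        (min(edges) < 0 || max(edges) > len)) {
      dropRow[i] <- TRUE
      next
    }
    Fe <- .trackCumIntegral(vals, len, track@stepSize, edges,
                            cum = cums[[chrom]])
    ## clipping in .trackCumIntegral makes out-of-range stretches contribute
    ## zero signal: exactly the `zero` missing policy
    rows[i, ] <- (Fe[-1] - Fe[-length(Fe)]) / diff(edges)
  }
  if (any(dropRow))
    message(sum(dropRow), " gene(s) dropped (missing_policy = 'drop' or ",
            "chromosome absent from track)")
  rows <- rows[!dropRow, , drop = FALSE]
  new("MetageneMatrix", matrix = rows,
      tssColumn = nUp + 1L, tesColumn = nUp + config$body_bins,
      config = config)
}

#' @describeIn scaleRegionsMatrix the genes x bins matrix.
#' @param x a MetageneMatrix.
#' @export
metageneMatrix <- function(x) x@matrix

#' @describeIn scaleRegionsMatrix TSS / TES anchor column indices.
#' @export
metageneAnchors <- function(x) c(tss = x@tssColumn, tes = x@tesColumn)

setMethod("show", "MetageneMatrix", function(object) {
  cat(sprintf(
    "MetageneMatrix: %d genes x %d bins (TSS at column %d, TES at %d)\n",
    nrow(object@matrix), ncol(object@matrix),
    object@tssColumn, object@tesColumn))
})

#' Mean metagene profile over a gene set
#'
#' Column-wise NaN-aware mean over the selected rows. Genes absent from the
#' matrix are reported and skipped.
#'
#' @param mat a \linkS4class{MetageneMatrix}.
#' @param geneSet character vector of gene_ids, a \linkS4class{GeneSet}, or
#'   NULL for all rows.
#' @return numeric profile vector (one value per bin column).
#' @export
meanProfile <- function(mat, geneSet = NULL) {
  m <- mat@matrix
  if (is.null(geneSet)) {
    sel <- rownames(m)
  } else {
    if (is(geneSet, "GeneSet")) geneSet <- geneSet@members
    missing <- setdiff(geneSet, rownames(m))
    if (length(missing))
      message(length(missing), " gene(s) in the set are absent from the ",
              "matrix and were skipped")
    sel <- intersect(geneSet, rownames(m))
  }
  if (length(sel) == 0L) stop("empty gene selection for profile")
  colMeans(m[sel, , drop = FALSE], na.rm = TRUE)
}

#' Write a metagene matrix or profile as TSV
#'
#' @param mat a \linkS4class{MetageneMatrix}.
#' @param path output TSV.
#' @export
writeMetageneMatrix <- function(mat, path) {
  m <- mat@matrix
  colnames(m) <- paste0("bin", seq_len(ncol(m)))
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a mean metagene profile with TSS/TES markers
#'
#' @param profile numeric vector from \code{\link{meanProfile}}.
#' @param anchors anchor indices from \code{\link{metageneAnchors}}.
#' @param main plot title.
#' @export
plotMeanProfile <- function(profile, anchors, main = "Metagene profile") {
  graphics::plot(seq_along(profile), profile, type = "l",
                 xlab = "bin (5' -> 3')", ylab = "mean signal", main = main)
  graphics::abline(v = anchors, lty = 2, col = "grey40")
  graphics::mtext(c("TSS", "TES"), at = anchors, side = 3, cex = 0.8)
}
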
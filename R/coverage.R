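#' @importFrom stats approx
NULL

## ---- internal: piecewise-constant signal machinery ------------------------
##
## A binned track is a piecewise-constant signal, so its running integral
## F(t) = int_0^t signal is piecewise linear. All length-weighted averaging
## (rasterization, ORF means, metagene resampling) reduces to evaluating F at
## interval edges by linear interpolation: mean over [a, b) = (F(b) - F(a)) /
## (b - a), exact to float precision.

## Cumulative integral of non-overlapping intervals (value elsewhere =
## baseline), evaluated at arbitrary positions. starts/ends half-open.
.intervalCumIntegral <- function(starts, ends, values, len, baseline, at) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; values <- values[o]
  knots <- c(0, rbind(starts, ends), len)
  segBase <- baseline * diff(knots)
  ## interval i occupies knot segment 2i (between starts[i] and ends[i])
  if (length(starts)) {
    idx <- seq_along(starts) * 2L
    segBase[idx] <- segBase[idx] + (values - baseline) * (ends - starts)
  }
  Fk <- c(0, cumsum(segBase))
  ## knots may repeat (touching intervals); approx requires increasing x
  keep <- !duplicated(knots, fromLast = TRUE)
  approx(knots[keep], Fk[keep], xout = pmin(pmax(at, 0), len),
         method = "linear", rule = 2)$y
}

## Rasterize non-overlapping scored intervals to fixed-step bins.
.rasterize <- function(starts, ends, values, len, step, baseline = 0) {
  nb <- as.integer(ceiling(len / step))
  edges <- c(seq(0, by = step, length.out = nb), len)
  widths <- diff(edges)
  Fe <- .intervalCumIntegral(starts, ends, values, len, baseline, edges)
  diff(Fe) / widths
}

## Widths of the bins of one chromosome (last bin may be partial).
.binWidths <- function(len, step) {
  nb <- as.integer(ceiling(len / step))
  w <- rep(as.numeric(step), nb)
  w[nb] <- len - (nb - 1L) * step
  w
}

## Cumulative integral of a *binned* chromosome at positions `at`.
## Bins are uniform (last possibly partial), so each query is O(1): locate
## the bin by integer division and add the within-bin linear part.
.trackCumIntegral <- function(vals, len, step, at, cum = NULL) {
  nb <- length(vals)
  if (is.null(cum)) cum <- .trackCum(vals, len, step)
  t <- pmin(pmax(at, 0), len)
  i <- pmin(floor(t / step), nb - 1)
  cum[i + 1] + (t - i * step) * vals[i + 1]
}

## Precomputed per-bin cumulative integral (cum[i] = integral up to the
## start of bin i); pass to .trackCumIntegral when querying repeatedly.
.trackCum <- function(vals, len, step) {
  c(0, cumsum(vals * .binWidths(len, step)))[seq_along(vals)]
}

## ---- constructor and accessors --------------------------------------------

#' Construct a CoverageTrack
#'
#' @param values named list of numeric vectors, one per chromosome, binned at
#'   \code{stepSize} bp from position 0.
#' @param stepSize bin width in bp.
#' @param seqlengths named numeric of true chromosome lengths; defaults to
#'   \code{length(values[[chr]]) * stepSize}.
#' @return A \linkS4class{CoverageTrack}.
#' @export
coverageTrack <- function(values, stepSize, seqlengths = NULL) {
  stepSize <- as.integer(stepSize)
  if (is.null(seqlengths))
    seqlengths <- vapply(values, length, 1L) * as.numeric(stepSize)
  new("CoverageTrack", values = values, stepSize = stepSize,
      seqlengths = seqlengths[names(values)])
}

#' @describeIn coverageTrack bin width in bp.
#' @param x a CoverageTrack.
#' @export
stepSize <- function(x) x@stepSize

#' @describeIn coverageTrack named list of per-chromosome bin values.
#' @export
trackValues <- function(x) x@values

#' @describeIn coverageTrack named chromosome lengths in bp.
#' @export
trackSeqlengths <- function(x) x@seqlengths

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf("CoverageTrack: %d chromosome(s), step %d bp\n",
              length(object@values), object@stepSize))
  for (chr in names(object@values))
    cat(sprintf("  %s: length %s bp (%d bins)\n", chr,
                format(object@seqlengths[[chr]]),
                length(object@values[[chr]])))
})

## Mean signal over [start, end) on one chromosome; NA if outside the track.
.trackIntervalMean <- function(track, chrom, start, end) {
  vals <- track@values[[chrom]]
  if (is.null(vals)) return(NA_real_)
  len <- track@seqlengths[[chrom]]
  if (start < 0 || end > len || start >= end) return(NA_real_)
  Fe <- .trackCumIntegral(vals, len, track@stepSize, c(start, end))
  (Fe[2] - Fe[1]) / (end - start)
}

## Vectorised interval means over a geneIntervals() data.frame.
.trackIntervalMeans <- function(track, gi) {
  out <- rep(NA_real_, nrow(gi))
  for (cn in unique(gi$chrom)) {
    vals <- track@values[[cn]]
    if (is.null(vals)) next
    len <- track@seqlengths[[cn]]
    sel <- which(gi$chrom == cn)
    ok <- gi$start[sel] >= 0 & gi$end[sel] <= len &
      gi$start[sel] < gi$end[sel]
    sel <- sel[ok]
    if (!length(sel)) next
    cum <- .trackCum(vals, len, track@stepSize)
    Fs <- .trackCumIntegral(vals, len, track@stepSize, gi$start[sel], cum)
    Fe <- .trackCumIntegral(vals, len, track@stepSize, gi$end[sel], cum)
    out[sel] <- (Fe - Fs) / (gi$end[sel] - gi$start[sel])
  }
  out
}

## ---- bedGraph I/O ----------------------------------------------------------

#' Read a bedGraph file into a fixed-step CoverageTrack
#'
#' Intervals are rasterized to \code{stepBp} bins by length-weighted
#' averaging; positions not covered by any record get value 0. Records must
#' be non-overlapping and lie within the declared chromosome sizes.
#'
#' @param path bedGraph file.
#' @param chromSizes named numeric of chromosome lengths, or the path of a
#'   two-column \code{chrom.sizes} TSV.
#' @param stepBp output bin width in bp.
#' @return A \linkS4class{CoverageTrack}.
#' @export
readCoverageBedGraph <- function(path, chromSizes, stepBp) {
  if (is.character(chromSizes) && length(chromSizes) == 1L &&
      file.exists(chromSizes))
    chromSizes <- readChromSizes(chromSizes)
  gr <- rtracklayer::import(path, format = "bedGraph")
  chr <- as.character(GenomicRanges::seqnames(gr))
  bad <- setdiff(unique(chr), names(chromSizes))
  if (length(bad))
    stop("bedGraph chromosomes absent from chrom sizes: ",
         paste(bad, collapse = ", "))
  s <- GenomicRanges::start(gr) - 1L   # to 0-based half-open
  e <- GenomicRanges::end(gr)
  if (any(e > chromSizes[chr]))
    stop("bedGraph interval extends beyond declared chromosome end")
  values <- lapply(names(chromSizes), function(cn) {
    sel <- chr == cn
    ss <- s[sel]; ee <- e[sel]
    if (sum(sel) > 1L) {
      o <- order(ss)
      if (any(ee[o][-sum(sel)] > ss[o][-1L]))
        stop("overlapping bedGraph intervals on ", cn,
             " (bedGraph must be non-overlapping)")
    }
    .rasterize(ss, ee, gr$score[sel], chromSizes[[cn]], stepBp, baseline = 0)
  })
  names(values) <- names(chromSizes)
  coverageTrack(values, stepBp, chromSizes)
}

#' Write a CoverageTrack as bedGraph
#'
#' Adjacent equal-valued bins are merged into single records; zero-valued
#' runs are emitted too so the file round-trips exactly.
#'
#' @param track a \linkS4class{CoverageTrack}.
#' @param path output file.
#' @export
writeCoverageBedGraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track@values)) {
    v <- track@values[[chr]]
    len <- track@seqlengths[[chr]]
    r <- rle(v)
    ends0 <- cumsum(r$lengths) * as.numeric(track@stepSize)
    ends0[length(ends0)] <- len
    starts0 <- c(0, ends0[-length(ends0)])
    writeLines(sprintf("%s\t%d\t%d\t%.17g", chr, as.integer(starts0),
                       as.integer(ends0), r$values), con)
  }
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path TSV with chromosome name and length columns.
#' @return named numeric of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$size, df$chrom)
}
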
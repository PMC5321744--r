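#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## Column metadata tags understood by OccupancyTable.
.OCCUPANCY_TAGS <- c("log2_ip_over_input", "log2_mutant_over_wt", "linear")

#' CoverageTrack: binned genomic signal
#'
#' Per-chromosome numeric signal at a fixed bin width, tiling each chromosome
#' contiguously from position 0. Raw coverage tracks are non-negative;
#' log-ratio tracks may hold any real value. The final bin of a chromosome may
#' be narrower than \code{stepSize} when the chromosome length is not a
#' multiple of the step.
#'
#' @slot values named list of numeric vectors, one per chromosome.
#' @slot stepSize integer(1), bin width in bp.
#' @slot seqlengths named numeric, true chromosome lengths in bp.
#' @exportClass CoverageTrack
setClass("CoverageTrack",
  representation(values = "list", stepSize = "integer", seqlengths = "numeric"))

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (length(object@stepSize) != 1L || is.na(object@stepSize) ||
      object@stepSize <= 0L)
    msg <- c(msg, "stepSize must be a single positive integer")
  if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
    msg <- c(msg, "values must be a uniquely named list of chromosomes")
  if (!identical(sort(names(object@values)), sort(names(object@seqlengths))))
    msg <- c(msg, "values and seqlengths must name the same chromosomes")
  for (chr in names(object@values)) {
    nb <- length(object@values[[chr]])
    expect <- ceiling(object@seqlengths[[chr]] / object@stepSize)
    if (nb != expect)
      msg <- c(msg, sprintf("chromosome %s: %d bins but %d expected for length %s",
                            chr, nb, expect, format(object@seqlengths[[chr]])))
  }
  if (length(msg)) msg else TRUE
})

#' OccupancyTable: genes x samples occupancy matrix
#'
#' A \linkS4class{SummarizedExperiment} holding one assay \code{"occupancy"}
#' (genes as rows, samples as columns) plus a per-column \code{tag} in
#' \code{colData} declaring the scale of each column:
#' \code{log2_ip_over_input}, \code{log2_mutant_over_wt} or \code{linear}.
#'
#' @exportClass OccupancyTable
setClass("OccupancyTable", contains = "SummarizedExperiment")

setValidity("OccupancyTable", function(object) {
  msg <- character()
  if (!"occupancy" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'occupancy' is required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene_ids (rownames) must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!"tag" %in% colnames(cd)) {
    msg <- c(msg, "colData must carry a 'tag' column")
  } else if (!all(cd$tag %in% .OCCUPANCY_TAGS)) {
    msg <- c(msg, paste0("tags must be one of: ",
                         paste(.OCCUPANCY_TAGS, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' GeneSet: a named set of genes within a universe
#'
#' @slot name character(1), set label.
#' @slot members character, gene identifiers in the set.
#' @slot universe character, the gene universe the set was drawn from.
#' @exportClass GeneSet
setClass("GeneSet",
  representation(name = "character", members = "character",
                 universe = "character"))

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (anyDuplicated(object@members)) msg <- c(msg, "duplicated members")
  if (anyDuplicated(object@universe)) msg <- c(msg, "duplicated universe ids")
  if (!all(object@members %in% object@universe))
    msg <- c(msg, "members must be a subset of the universe")
  if (length(msg)) msg else TRUE
})

#' ClusterResult: k-means classification of genes
#'
#' @slot labels named integer, cluster index per gene.
#' @slot k integer(1), requested number of clusters.
#' @slot centers matrix, per-cluster mean feature vectors (k rows).
#' @slot inertia numeric(1), total within-cluster sum of squares.
#' @slot seed integer(1) and @slot nInit integer(1): reproducibility metadata.
#' @slot degenerate logical(1), TRUE when fewer than k distinct clusters were
#'   attainable (e.g. all-identical features).
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(labels = "integer", k = "integer", centers = "matrix",
                 inertia = "numeric", seed = "integer", nInit = "integer",
                 degenerate = "logical"))

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (is.null(names(object@labels))) msg <- c(msg, "labels must be named")
  used <- sort(unique(object@labels))
  if (!object@degenerate && length(used) != object@k)
    msg <- c(msg, "non-degenerate result must have exactly k non-empty clusters")
  if (length(msg)) msg else TRUE
})

#' OverlapResult: hypergeometric gene-set overlap test
#'
#' Upper-tail (enrichment) hypergeometric probability of observing at least
#' the attained overlap between two gene sets drawn from a shared universe.
#'
#' @slot nUniverse,nA,nB,nOverlap integer counts.
#' @slot pValue numeric(1), inclusive upper-tail probability.
#' @exportClass OverlapResult
setClass("OverlapResult",
  representation(nUniverse = "integer", nA = "integer", nB = "integer",
                 nOverlap = "integer", pValue = "numeric"))

setValidity("OverlapResult", function(object) {
  msg <- character()
  if (object@nOverlap > min(object@nA, object@nB))
    msg <- c(msg, "overlap exceeds the smaller set")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue outside [0, 1]")
  if (length(msg)) msg else TRUE
})

#' MetageneMatrix: scale-regions signal matrix
#'
#' Genes x bins matrix covering upstream flank, length-rescaled gene body and
#' downstream flank, always oriented 5'->3' (column 1 is the promoter-distal
#' upstream edge). Anchor columns mark the TSS (first body bin) and TES (last
#' body bin).
#'
#' @slot matrix numeric matrix, one row per retained gene.
#' @slot tssColumn,tesColumn integer(1) anchor column indices.
#' @slot config list, the MetageneConfig the matrix was built with.
#' @exportClass MetageneMatrix
setClass("MetageneMatrix",
  representation(matrix = "matrix", tssColumn = "integer",
                 tesColumn = "integer", config = "list"))

setValidity("MetageneMatrix", function(object) {
  cfg <- object@config
  expect <- cfg$upstream_bp / cfg$flank_bin_bp + cfg$body_bins +
    cfg$downstream_bp / cfg$flank_bin_bp
  if (ncol(object@matrix) != expect)
    return(sprintf("matrix has %d columns, %d expected from config",
                   ncol(object@matrix), expect))
  TRUE
})

#' DisassemblyObservables: per-gene inputs to the decomposition model
#'
#' The three observable vectors the contribution estimator consumes: histone
#' H3 occupancy change in the remodeller-null genotype (\code{dH3Fft3}), H3
#' occupancy change in the reassembly-null genotype (\code{dH3Spt16}, same
#' scale), and a wild-type transcription proxy (\code{pol}; log2 IP/INPUT
#' RNAPII occupancy or any monotone transform).
#'
#' @slot geneIds character, shared gene universe.
#' @slot dH3Fft3,dH3Spt16,pol numeric vectors aligned to geneIds.
#' @exportClass DisassemblyObservables
setClass("DisassemblyObservables",
  representation(geneIds = "character", dH3Fft3 = "numeric",
                 dH3Spt16 = "numeric", pol = "numeric"))

setValidity("DisassemblyObservables", function(object) {
  n <- length(object@geneIds)
  if (length(object@dH3Fft3) != n || length(object@dH3Spt16) != n ||
      length(object@pol) != n)
    return("all observable vectors must share the gene universe")
  if (anyDuplicated(object@geneIds)) return("duplicated gene ids")
  TRUE
})

#' ContributionEstimate: grid-search estimate of the remodeller contribution
#'
#' Result of maximising the Pearson correlation r(x') between the
#' reconstructed reassembly-null disassembly D(x') = dH3Fft3/x' - dH3Spt16
#' and the transcription proxy over a grid of candidate contributions
#' x' in (0, 1].
#'
#' @slot grid numeric, candidate x' values.
#' @slot rCurve numeric, r(x') per grid point.
#' @slot xHat numeric(1), argmax x'.
#' @slot rMax numeric(1), r at xHat.
#' @slot flatness numeric(1), max(rCurve) - min(rCurve).
#' @slot identifiable logical(1), flatness >= flatnessTol.
#' @slot flatnessTol numeric(1), threshold used for the flag.
#' @slot dEstimates named numeric, per-gene reconstructed disassembly at xHat
#'   (arbitrary scale).
#' @slot nGenesUsed integer(1), genes with complete observables.
#' @exportClass ContributionEstimate
setClass("ContributionEstimate",
  representation(grid = "numeric", rCurve = "numeric", xHat = "numeric",
                 rMax = "numeric", flatness = "numeric",
                 identifiable = "logical", flatnessTol = "numeric",
                 dEstimates = "numeric", nGenesUsed = "integer"))

setValidity("ContributionEstimate", function(object) {
  msg <- character()
  if (!object@xHat %in% object@grid) msg <- c(msg, "xHat must lie on the grid")
  i <- match(object@xHat, object@grid)
  if (is.finite(object@rMax) &&
      !isTRUE(all.equal(object@rMax, object@rCurve[i])))
    msg <- c(msg, "rMax must equal rCurve at xHat")
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: latent ground truth of a generated cohort
#'
#' Per-gene steady-state disassembly (D), loss (L) and reassembly (R)
#' fractions for wild type, the remodeller-null and the reassembly-null
#' genotypes, the per-gene wild-type reassembly fraction rho, and the scalar
#' simulation parameters.
#'
#' @slot genes data.frame with columns gene_id, T, D_wt, L_wt, R_wt, rho,
#'   D_fft3, L_fft3, R_fft3, D_spt16, L_spt16, R_spt16.
#' @slot xPrimeTrue numeric(1), true relative contribution.
#' @slot beta numeric(1), reassembly-null disassembly scaling.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(genes = "data.frame", xPrimeTrue = "numeric",
                 beta = "numeric"))

setValidity("SyntheticTruth", function(object) {
  g <- object@genes
  need <- c("gene_id", "T", "D_wt", "L_wt", "R_wt", "rho",
            "D_fft3", "L_fft3", "R_fft3", "D_spt16", "L_spt16", "R_spt16")
  if (!all(need %in% names(g)))
    return(paste("missing truth columns:",
                 paste(setdiff(need, names(g)), collapse = ", ")))
  for (gt in c("wt", "fft3", "spt16")) {
    D <- g[[paste0("D_", gt)]]; L <- g[[paste0("L_", gt)]]
    R <- g[[paste0("R_", gt)]]
    if (!isTRUE(all.equal(D, L + R)))
      return(sprintf("conservation D = L + R violated in %s", gt))
    ## the reassembly-null fractions scale with beta, so their cap does too
    cap <- if (gt == "spt16") max(1, object@beta) else 1
    if (any(L < 0) || any(R < 0) || any(D > cap))
      return(sprintf("fractions outside [0, %g] bounds in %s", cap, gt))
  }
  TRUE
})

#' SyntheticCohort: a complete simulated data set
#'
#' @slot annotation GRanges of simulated genes (names = gene_id).
#' @slot tracks list of \linkS4class{CoverageTrack} (may be empty when track
#'   synthesis was skipped): \code{ip} (wild-type RNAPII IP) and
#'   \code{control}.
#' @slot geneTable \linkS4class{OccupancyTable} of observables.
#' @slot truth \linkS4class{SyntheticTruth}.
#' @slot config list, the generator configuration used.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(annotation = "GRanges", tracks = "list",
                 geneTable = "OccupancyTable", truth = "SyntheticTruth",
                 config = "list"))

setValidity("SyntheticCohort", function(object) {
  ids <- names(object@annotation)
  if (!identical(ids, rownames(object@geneTable)) ||
      !identical(ids, object@truth@genes$gene_id))
    return("annotation, gene table and truth must share the gene universe")
  TRUE
})
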
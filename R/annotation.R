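#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom IRanges IRanges
NULL

#' Read a gene annotation (GFF3 or BED)
#'
#' Returns a \code{GRanges} with one range per gene, named by gene_id.
#' Coordinates follow GRanges convention (1-based, closed); use
#' \code{\link{geneIntervals}} for the 0-based half-open view used by the
#' coverage machinery. For GFF3, only records of \code{featureType} are kept
#' and the gene identifier is taken from the \code{ID} attribute (falling
#' back to \code{Name}). BED names are used as-is.
#'
#' @param path annotation file.
#' @param format \code{"gff3"} or \code{"bed"}.
#' @param featureType GFF3 feature type to retain (default \code{"gene"}).
#' @return GRanges named by gene_id, with a \code{gene_id} metadata column.
#' @export
readGeneAnnotation <- function(path, format = c("gff3", "bed"),
                               featureType = "gene") {
  format <- match.arg(format)
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  if (format == "gff3") {
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == featureType]
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$Name
    if (length(gr) && (is.null(ids) || anyNA(ids)))
      stop("GFF3 ", featureType, " records must carry an ID (or Name) attribute")
  } else {
    ids <- gr$name
    if (length(gr) && is.null(ids))
      stop("BED annotation must have a name column (BED6)")
  }
  if (length(gr) == 0L) {
    warning("no ", if (format == "gff3") featureType else "BED",
            " records found in ", path, "; returning an empty annotation")
    out <- GRanges()
    names(out) <- character()
    return(out)
  }
  if (anyDuplicated(ids))
    stop("duplicate gene_id in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(as.character(strand(gr)) == "*"))
    stop("strand must be defined ('+' or '-') for every gene")
  names(gr) <- ids
  gr$gene_id <- ids
  S4Vectors::mcols(gr) <- S4Vectors::mcols(gr)["gene_id"]
  gr
}

#' 0-based half-open view of a gene annotation
#'
#' @param genes GRanges as returned by \code{\link{readGeneAnnotation}}.
#' @return data.frame with gene_id, chrom, start (0-based), end (half-open),
#'   strand.
#' @export
geneIntervals <- function(genes) {
  data.frame(gene_id = names(genes),
             chrom = as.character(seqnames(genes)),
             start = start(genes) - 1L,
             end = end(genes),
             strand = as.character(strand(genes)),
             stringsAsFactors = FALSE)
}

#' Write a gene annotation as GFF3
#'
#' @param genes named GRanges.
#' @param path output file.
#' @param source value for the GFF3 source column.
#' @export
writeGeneAnnotationGFF3 <- function(genes, path, source = "nucdis") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(genes))
    writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       as.character(seqnames(genes)), source,
                       start(genes), end(genes),
                       as.character(strand(genes)), names(genes)), con)
  invisible(path)
}
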
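#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Construct an OccupancyTable
#'
#' @param values numeric matrix, genes (rownames = gene_id) x samples
#'   (colnames).
#' @param tags character, one scale tag per column:
#'   \code{"log2_ip_over_input"}, \code{"log2_mutant_over_wt"} or
#'   \code{"linear"}.
#' @return An \linkS4class{OccupancyTable}.
#' @export
occupancyTable <- function(values, tags) {
  values <- as.matrix(values)
  if (length(tags) == 1L) tags <- rep(tags, ncol(values))
  se <- SummarizedExperiment(
    assays = list(occupancy = values),
    colData = S4Vectors::DataFrame(tag = tags, row.names = colnames(values)))
  new("OccupancyTable", se)
}

#' @describeIn occupancyTable the genes x samples matrix.
#' @param x an OccupancyTable.
#' @export
occupancyMatrix <- function(x) assay(x, "occupancy")

#' @describeIn occupancyTable per-column scale tags.
#' @export
sampleTags <- function(x) stats::setNames(colData(x)$tag, colnames(x))

#' @describeIn occupancyTable extract one sample column (named numeric).
#' @param sample column name.
#' @export
occupancyColumn <- function(x, sample) {
  m <- occupancyMatrix(x)
  if (!sample %in% colnames(m))
    stop("no sample named '", sample, "' in table")
  stats::setNames(m[, sample], rownames(m))
}

setMethod("show", "OccupancyTable", function(object) {
  cat(sprintf("OccupancyTable: %d genes x %d samples\n",
              nrow(object), ncol(object)))
  tg <- sampleTags(object)
  for (s in names(tg)) cat(sprintf("  %s [%s]\n", s, tg[[s]]))
})

#' Gene-level occupancy from IP and control coverage
#'
#' For each annotated gene, computes
#' \code{log2((mean IP over ORF + pseudocount) / (mean control + pseudocount))},
#' the per-base mean being taken over the annotated interval (so gene length
#' does not confound occupancy). Genes whose control mean is exactly zero
#' before the pseudocount, or which fall outside the track extent, are
#' reported in the exclusion list attached as
#' \code{metadata(result)$exclusions}; out-of-extent genes get NA.
#'
#' @param ip,control \linkS4class{CoverageTrack}s sharing step and
#'   chromosomes.
#' @param genes named GRanges annotation.
#' @param pseudocount added to both linear means before log2 (default 0.01).
#' @param sampleName output column name.
#' @return A one-column \linkS4class{OccupancyTable} tagged
#'   \code{log2_ip_over_input}.
#' @export
geneOccupancy <- function(ip, control, genes, pseudocount = 0.01,
                          sampleName = "occupancy") {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (ip@stepSize != control@stepSize)
    stop("IP and control tracks must share the bin step")
  gi <- geneIntervals(genes)
  mIP <- .trackIntervalMeans(ip, gi)
  mCtl <- .trackIntervalMeans(control, gi)
  outside <- is.na(mIP) | is.na(mCtl)
  zeroCtl <- !outside & mCtl == 0
  val <- log2((mIP + pseudocount) / (mCtl + pseudocount))
  val[outside] <- NA_real_
  excl <- data.frame(
    gene_id = c(gi$gene_id[outside], gi$gene_id[zeroCtl]),
    reason = c(rep("outside_track_extent", sum(outside)),
               rep("zero_control_coverage", sum(zeroCtl))),
    stringsAsFactors = FALSE)
  m <- matrix(val, ncol = 1, dimnames = list(gi$gene_id, sampleName))
  tab <- occupancyTable(m, "log2_ip_over_input")
  metadata(tab)$exclusions <- excl
  if (nrow(excl))
    message(nrow(excl), " gene(s) flagged for exclusion (",
            sum(outside), " outside track, ", sum(zeroCtl),
            " with zero control coverage)")
  tab
}

#' Mutant-versus-wild-type occupancy change
#'
#' \code{change = mutant_log2 - wildtype_log2} on the genes shared by both
#' columns (inner join on gene_id; the number dropped is reported).
#'
#' @param mutant,wildtype named numeric vectors of log2 occupancies (as
#'   returned by \code{\link{occupancyColumn}}).
#' @return named numeric vector of log2(mutant/WT) changes.
#' @export
occupancyChange <- function(mutant, wildtype) {
  shared <- intersect(names(mutant), names(wildtype))
  if (length(shared) == 0L)
    stop("mutant and wild-type columns share no genes")
  dropped <- length(union(names(mutant), names(wildtype))) - length(shared)
  if (dropped > 0L)
    message(dropped, " gene(s) absent from one column were dropped")
  mutant[shared] - wildtype[shared]
}

## ---- gene-table TSV --------------------------------------------------------

#' Read / write gene-level occupancy tables as TSV
#'
#' The file has a \code{gene_id} first column and one named column per
#' sample. Column scale tags are carried on an optional leading comment line
#' \code{#tags <sample>=<tag> ...}; absent tags default to \code{linear}.
#' Values are written at full float precision so tables round-trip
#' losslessly; NA values are written as empty fields.
#'
#' @param path TSV file.
#' @return \code{readGeneTable}: an \linkS4class{OccupancyTable}.
#' @export
readGeneTable <- function(path) {
  first <- readLines(path, n = 1L)
  tags <- NULL
  skip <- 0L
  if (startsWith(first, "#tags")) {
    skip <- 1L
    kv <- strsplit(trimws(sub("^#tags", "", first)), "[ \t]+")[[1]]
    kv <- strsplit(kv, "=", fixed = TRUE)
    tags <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  }
  lines <- readLines(path)
  if (skip > 0L) lines <- lines[-seq_len(skip)]
  if (length(lines) == 0L) stop("empty gene table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  headerN <- length(fields[[1]])
  bad <- which(vapply(fields, length, 1L) != headerN)
  if (length(bad))
    stop("gene table ", path, ": line ", bad[1] + skip,
         " has ", length(fields[[bad[1]]]), " fields, expected ", headerN)
  df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                          na.strings = "", check.names = FALSE,
                          colClasses = c("character",
                                         rep("numeric", headerN - 1L)))
  if (names(df)[1] != "gene_id")
    stop("gene table must have 'gene_id' as its first column")
  if (anyDuplicated(df$gene_id)) stop("duplicated gene_id in ", path)
  m <- as.matrix(df[-1])
  rownames(m) <- df$gene_id
  if (is.null(tags)) tags <- rep("linear", ncol(m))
  else tags <- unname(tags[colnames(m)])
  tags[is.na(tags)] <- "linear"
  occupancyTable(m, tags)
}

#' @rdname readGeneTable
#' @param table an \linkS4class{OccupancyTable}.
#' @export
writeGeneTable <- function(table, path) {
  m <- occupancyMatrix(table)
  tg <- sampleTags(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#tags ", paste(names(tg), tg, sep = "=", collapse = " ")),
             con)
  writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(row) {
    s <- sprintf("%.17g", row)
    s[is.na(row)] <- ""
    paste(s, collapse = "\t")
  })
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}
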
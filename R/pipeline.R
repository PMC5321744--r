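#' Pipeline configuration
#'
#' Wires the stages (simulate -> quantify -> metagene -> classify -> model ->
#' report) into one reproducible run. In synthetic mode no external inputs
#' are needed; in real-data mode an annotation plus either coverage tracks
#' or a pre-computed gene table must be supplied.
#'
#' @param outdir output directory.
#' @param seed global seed, recorded in every output.
#' @param mode \code{"synthetic"} or \code{"real"}.
#' @param stages subset of the stage names to run (\code{"all"} keeps all).
#' @param generator parameter overrides for \code{\link{generatorConfig}}
#'   (synthetic mode).
#' @param annotation,ipTrack,controlTrack,chromSizes,geneTable input paths
#'   (real mode); \code{geneTable} may replace the track inputs.
#' @param annotationFormat \code{"gff3"} or \code{"bed"}.
#' @param pseudocount for gene-level quantification.
#' @param metagene overrides for \code{\link{metageneConfig}}.
#' @param clusterK k for the RNAPII-profile classification (default 3).
#' @param changeColumn,changeCutoff column and inclusive cutoff defining the
#'   decreased-occupancy gene set (default \code{dpol_fft3 <= -0.5}).
#' @param modelColumns the dH3_fft3, dH3_spt16 and pol column names.
#' @param grid contribution grid for the model stage.
#' @param flatnessTol identifiability threshold.
#' @param logLevel \code{"debug"}, \code{"info"} or \code{"warn"}.
#' @return validated configuration list.
#' @export
pipelineConfig <- function(outdir, seed = 1L,
                           mode = c("synthetic", "real"),
                           stages = "all",
                           generator = list(),
                           annotation = NULL, ipTrack = NULL,
                           controlTrack = NULL, chromSizes = NULL,
                           geneTable = NULL, annotationFormat = "gff3",
                           pseudocount = 0.01,
                           metagene = list(),
                           clusterK = 3L,
                           changeColumn = "dpol_fft3",
                           changeCutoff = -0.5,
                           modelColumns = c("dH3_fft3", "dH3_spt16",
                                            "pol_wt"),
                           grid = seq(0.01, 1, by = 0.01),
                           flatnessTol = 1e-3,
                           logLevel = c("info", "debug", "warn")) {
  mode <- match.arg(mode)
  logLevel <- match.arg(logLevel)
  allStages <- c("simulate", "quantify", "metagene", "classify", "model",
                 "report")
  if (identical(stages, "all")) stages <- allStages
  if (!all(stages %in% allStages))
    stop("unknown stage(s): ",
         paste(setdiff(stages, allStages), collapse = ", "))
  if (mode == "real") {
    if (is.null(geneTable) && is.null(annotation))
      stop("real-data mode requires an annotation (plus tracks) or a gene ",
           "table")
    for (p in c(annotation, ipTrack, controlTrack, chromSizes, geneTable))
      if (!is.null(p) && !file.exists(p))
        stop("input file does not exist: ", p)
    stages <- setdiff(stages, "simulate")
  }
  list(outdir = outdir, seed = as.integer(seed), mode = mode,
       stages = stages, generator = generator, annotation = annotation,
       ipTrack = ipTrack, controlTrack = controlTrack,
       chromSizes = chromSizes, geneTable = geneTable,
       annotationFormat = annotationFormat, pseudocount = pseudocount,
       metagene = metagene, clusterK = as.integer(clusterK),
       changeColumn = changeColumn, changeCutoff = changeCutoff,
       modelColumns = modelColumns, grid = grid,
       flatnessTol = flatnessTol, logLevel = logLevel)
}

.plog <- function(config, level, ...) {
  ranks <- c(debug = 1L, info = 2L, warn = 3L)
  if (ranks[[level]] >= ranks[[config$logLevel]])
    message("[", level, "] ", ...)
}

#' Run the analysis pipeline
#'
#' Executes the selected stages and writes every artifact under
#' \code{config$outdir} together with a manifest (full configuration, seed,
#' package and R versions). Reruns with an identical configuration and seed
#' produce byte-identical gene tables and estimate JSON.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, the run report (also written as
#'   \code{report.json}).
#' @export
runPipeline <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, mode = config$mode,
                 stages = config$stages)
  stage <- "init"
  tryCatch({
    annotation <- NULL; tracks <- NULL; geneTable <- NULL; truth <- NULL

    if ("simulate" %in% config$stages && config$mode == "synthetic") {
      stage <- "simulate"
      gcfg <- do.call(generatorConfig,
                      c(list(seed = config$seed), config$generator))
      cohort <- generateCohort(gcfg)
      writeCohort(cohort, file.path(config$outdir, "cohort"))
      annotation <- cohort@annotation
      tracks <- cohort@tracks
      geneTable <- cohort@geneTable
      truth <- cohort@truth
      report$simulate <- list(n_genes = gcfg$n_genes,
                              x_prime_true = gcfg$x_prime_true)
      .plog(config, "info", "simulated cohort of ", gcfg$n_genes, " genes")
    }
    if (config$mode == "real") {
      stage <- "load"
      if (!is.null(config$annotation))
        annotation <- readGeneAnnotation(config$annotation,
                                         config$annotationFormat)
      if (!is.null(config$geneTable))
        geneTable <- readGeneTable(config$geneTable)
      if (!is.null(config$ipTrack)) {
        cs <- readChromSizes(config$chromSizes)
        step <- config$generator$track_bin_bp
        if (is.null(step)) step <- 10L
        tracks <- list(
          ip = readCoverageBedGraph(config$ipTrack, cs, step),
          control = readCoverageBedGraph(config$controlTrack, cs, step))
      }
    }

    if ("quantify" %in% config$stages && !is.null(tracks)) {
      stage <- "quantify"
      occ <- geneOccupancy(tracks$ip, tracks$control, annotation,
                           pseudocount = config$pseudocount,
                           sampleName = "pol_track")
      writeGeneTable(occ, file.path(config$outdir, "track_occupancy.tsv"))
      report$quantify <- list(
        n_genes = nrow(occ),
        n_excluded = nrow(metadata(occ)$exclusions))
      .plog(config, "info", "quantified ", nrow(occ), " genes from tracks")
    }

    mg <- NULL
    if ("metagene" %in% config$stages && !is.null(tracks)) {
      stage <- "metagene"
      mcfg <- do.call(metageneConfig, config$metagene)
      mg <- scaleRegionsMatrix(tracks$ip, annotation, mcfg)
      prof <- meanProfile(mg)
      utils::write.table(
        data.frame(bin = seq_along(prof), mean_signal = sprintf("%.17g", prof)),
        file.path(config$outdir, "metagene_profile.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      report$metagene <- list(n_genes = nrow(metageneMatrix(mg)),
                              n_bins = ncol(metageneMatrix(mg)))
      .plog(config, "info", "metagene matrix: ",
            nrow(metageneMatrix(mg)), " x ", ncol(metageneMatrix(mg)))
    }

    highSet <- NULL
    if ("classify" %in% config$stages && !is.null(mg)) {
      stage <- "classify"
      cl <- kmeansCluster(metageneMatrix(mg), k = config$clusterK,
                          seed = config$seed)
      highSet <- selectExtremeCluster(cl, "highest", name = "high_occupancy")
      writeGeneSet(highSet,
                   file.path(config$outdir, "high_occupancy_genes.txt"))
      report$classify <- list(
        k = config$clusterK,
        cluster_sizes = as.integer(table(clusterLabels(cl))),
        n_high = length(setMembers(highSet)))
      .plog(config, "info", "high-occupancy class: ",
            length(setMembers(highSet)), " genes")
    }

    if ("model" %in% config$stages && !is.null(geneTable)) {
      stage <- "model"
      obs <- observablesFromTable(geneTable, config$modelColumns)
      est <- estimateContribution(obs, grid = config$grid,
                                  flatnessTol = config$flatnessTol)
      writeContributionEstimate(
        est, file.path(config$outdir, "contribution_estimate.json"),
        genePath = file.path(config$outdir, "disassembly_levels.tsv"))
      grDevices::pdf(file.path(config$outdir, "contribution_curve.pdf"),
                     width = 5, height = 4)
      plotContributionCurve(est)
      grDevices::dev.off()
      levels <- fun30DisassemblyLevels(est)
      pol <- occupancyColumn(geneTable, config$modelColumns[3])
      fig4 <- list(
        r_dH3_vs_pol = dependenceSummary(
          pol, occupancyColumn(geneTable, config$modelColumns[1]))$r,
        r_disassembly_vs_pol = dependenceSummary(pol, levels)$r)
      if (config$changeColumn %in% colnames(geneTable)) {
        dpol <- occupancyColumn(geneTable, config$changeColumn)
        fig4$r_disassembly_vs_dpol <- dependenceSummary(dpol, levels)$r
        changeSet <- thresholdGeneSet(dpol, config$changeCutoff, "le",
                                      name = "decreased_occupancy")
        report$threshold_set <- list(cutoff = config$changeCutoff,
                                     n = length(setMembers(changeSet)))
        if (!is.null(highSet)) {
          ov <- hypergeometricOverlap(changeSet, highSet)
          report$overlap <- list(n_universe = ov@nUniverse, n_A = ov@nA,
                                 n_B = ov@nB, n_overlap = ov@nOverlap,
                                 p_value = ov@pValue)
        }
      }
      report$model <- list(x_hat = xHat(est), r_max = rMax(est),
                           flatness = est@flatness,
                           identifiable = isIdentifiable(est),
                           n_genes_used = est@nGenesUsed,
                           correlations = fig4)
      if (!is.null(truth))
        report$model$x_prime_true <- truth@xPrimeTrue
      .plog(config, "info", sprintf("x-hat = %.2f (r = %.3f)",
                                    xHat(est), rMax(est)))
    }

    if ("report" %in% config$stages) {
      stage <- "report"
      report$note <- paste(
        "synthetic observables use invented noise calibrations;",
        "they emulate gene-level observables, not read-level data")
      jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    manifest <- list(config = config[setdiff(names(config), "outdir")],
                     package_version =
                       as.character(utils::packageVersion("nucdis")),
                     r_version = R.version.string)
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         " (partial outputs, if any, are under ", config$outdir, ")",
         call. = FALSE)
  })
  invisible(report)
}
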
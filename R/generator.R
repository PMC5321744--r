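#' Synthetic-cohort generator configuration
#'
#' Parameterises the generative model behind every synthetic cohort: per-gene
#' wild-type transcription, transcription-coupled disassembly with a cap,
#' gene-to-gene heterogeneity in the reassembly fraction, genotype effects
#' (proportional reduction of disassembly/loss by the true contribution
#' \code{x_prime_true} in the remodeller-null genotype; reassembly abolished
#' in the reassembly-null genotype), and observation noise.
#'
#' @param n_genes number of genes (>= 2).
#' @param seed integer seed; one global stream governs all draws in a fixed,
#'   documented order.
#' @param x_prime_true true relative contribution, in (0, 1].
#' @param beta reassembly-null disassembly scaling (D_spt16 = beta * D_wt).
#' @param d_median target median wild-type disassembly fraction.
#' @param d_max cap on disassembly fractions.
#' @param rho_alpha,rho_beta Beta shape parameters of the per-gene wild-type
#'   reassembly fraction rho.
#' @param constant_rho if TRUE, rho is fixed at its Beta mean for every gene
#'   (the degenerate mode in which loss is exactly proportional to
#'   disassembly and x' becomes unidentifiable).
#' @param sigma_T sd of log2 wild-type RNAPII occupancy.
#' @param sigma_D lognormal sd of the disassembly--transcription coupling
#'   noise.
#' @param sigma_obs additive sd on the Delta-H3 observables.
#' @param sigma_P additive sd on observed log2 RNAPII occupancy.
#' @param sigma_E lognormal sd of the exchange-rate noise.
#' @param gamma coupling of the remodeller-null RNAPII-change observable to
#'   remodeller-mediated disassembly.
#' @param track_bin_bp coverage track step in bp.
#' @param n_chromosomes number of synthetic chromosomes.
#' @return validated configuration list.
#' @export
generatorConfig <- function(n_genes = 5000L, seed = 1L, x_prime_true = 0.84,
                            beta = 1.0, d_median = 0.10, d_max = 0.90,
                            rho_alpha = 8, rho_beta = 2,
                            constant_rho = FALSE,
                            sigma_T = 1.2, sigma_D = 0.3, sigma_obs = 0.01,
                            sigma_P = 0.2, sigma_E = 0.4, gamma = 1.0,
                            track_bin_bp = 10L, n_chromosomes = 2L) {
  cfg <- list(n_genes = as.integer(n_genes), seed = as.integer(seed),
              x_prime_true = x_prime_true, beta = beta,
              d_median = d_median, d_max = d_max,
              rho_alpha = rho_alpha, rho_beta = rho_beta,
              constant_rho = isTRUE(constant_rho),
              sigma_T = sigma_T, sigma_D = sigma_D, sigma_obs = sigma_obs,
              sigma_P = sigma_P, sigma_E = sigma_E, gamma = gamma,
              track_bin_bp = as.integer(track_bin_bp),
              n_chromosomes = as.integer(n_chromosomes))
  .validateGeneratorConfig(cfg)
  cfg
}

.validateGeneratorConfig <- function(cfg) {
  bad <- function(field, why)
    stop("invalid generator configuration: '", field, "' ", why,
         call. = FALSE)
  if (cfg$n_genes < 2L) bad("n_genes", "must be >= 2")
  if (!is.finite(cfg$x_prime_true) || cfg$x_prime_true <= 0 ||
      cfg$x_prime_true > 1)
    bad("x_prime_true", "must lie in (0, 1]")
  if (cfg$beta < 0) bad("beta", "must be >= 0")
  if (!(cfg$d_median > 0 && cfg$d_median < cfg$d_max && cfg$d_max <= 1))
    bad("d_median", "must satisfy 0 < d_median < d_max <= 1")
  if (cfg$rho_alpha <= 0 || cfg$rho_beta <= 0)
    bad("rho_alpha", "and rho_beta must be positive")
  for (s in c("sigma_T", "sigma_D", "sigma_obs", "sigma_P", "sigma_E"))
    if (cfg[[s]] < 0) bad(s, "must be >= 0")
  if (cfg$track_bin_bp < 1L) bad("track_bin_bp", "must be >= 1")
  if (cfg$n_chromosomes < 1L) bad("n_chromosomes", "must be >= 1")
  invisible(cfg)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Deterministic given \code{config$seed}. All draws come from one seeded
#' stream in a fixed order (log2 occupancy, coupling noise, reassembly
#' fractions, the four observable noises, exchange noise, then gene lengths,
#' intergenic gaps and strands), so cohorts are bit-identical across calls
#' and platforms for the same configuration.
#'
#' Generative recipe per gene g (draws independent across genes):
#' \itemize{
#'   \item P_g ~ Normal(0, sigma_T^2) is log2 WT RNAPII occupancy;
#'     T_g = 2^P_g.
#'   \item D_wt_g = min(kappa T_g e^(Normal(0, sigma_D^2)), d_max), kappa set
#'     so median(D_wt) = d_median.
#'   \item rho_g ~ Beta(rho_alpha, rho_beta); L_wt = (1 - rho) D_wt;
#'     R_wt = rho D_wt.
#'   \item Genotypes: L_fft3 = (1 - x') L_wt, D_fft3 = (1 - x') D_wt,
#'     R_fft3 = D_fft3 - L_fft3; R_spt16 = 0,
#'     L_spt16 = D_spt16 = beta D_wt.
#'   \item Observables: dH3_fft3 = x' L_wt + Normal(0, sigma_obs^2);
#'     dH3_spt16 = (L_wt - beta D_wt) + Normal(0, sigma_obs^2);
#'     pol_wt = P + Normal(0, sigma_P^2);
#'     dpol_fft3 = -gamma x' D_wt + Normal(0, sigma_obs^2);
#'     exchange = L_wt e^(Normal(0, sigma_E^2)).
#' }
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param tracks build coverage tracks too (default TRUE); skip for
#'   model-only simulation studies.
#' @return A \linkS4class{SyntheticCohort}.
#' @export
generateCohort <- function(config = generatorConfig(), tracks = TRUE) {
  .validateGeneratorConfig(config)
  n <- config$n_genes
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed))
    assign(".Random.seed", oldseed, .GlobalEnv))
  set.seed(config$seed)

  ## -- latent truth (draw order is part of the generator contract) ---------
  P <- stats::rnorm(n, 0, config$sigma_T)
  Tg <- 2^P
  eta <- exp(stats::rnorm(n, 0, config$sigma_D))
  rho <- stats::rbeta(n, config$rho_alpha, config$rho_beta)
  if (config$constant_rho)
    rho <- rep(config$rho_alpha / (config$rho_alpha + config$rho_beta), n)
  epsF <- stats::rnorm(n, 0, config$sigma_obs)
  epsS <- stats::rnorm(n, 0, config$sigma_obs)
  epsP <- stats::rnorm(n, 0, config$sigma_P)
  epsQ <- stats::rnorm(n, 0, config$sigma_obs)
  epsE <- exp(stats::rnorm(n, 0, config$sigma_E))
  geneLen <- pmax(300, round(stats::rlnorm(n, log(1400), 0.4)))
  gaps <- round(stats::runif(n, 200, 1000))
  strands <- sample(c("+", "-"), n, replace = TRUE)

  kappa <- config$d_median / stats::median(Tg * eta)
  D0 <- pmin(kappa * Tg * eta, config$d_max)
  Lwt <- (1 - rho) * D0
  Rwt <- rho * D0
  ## conservation D = L + R must hold exactly, so D is defined as the float
  ## sum of its parts (within one ulp of the capped draw)
  Dwt <- Lwt + Rwt
  xp <- config$x_prime_true
  truth <- new("SyntheticTruth",
    genes = data.frame(
      gene_id = sprintf("gene%05d", seq_len(n)),
      T = Tg, D_wt = Dwt, L_wt = Lwt, R_wt = Rwt, rho = rho,
      D_fft3 = (1 - xp) * Lwt + (1 - xp) * Rwt,
      L_fft3 = (1 - xp) * Lwt,
      R_fft3 = (1 - xp) * Rwt,
      D_spt16 = config$beta * Dwt, L_spt16 = config$beta * Dwt,
      R_spt16 = rep(0, n),
      stringsAsFactors = FALSE),
    xPrimeTrue = xp, beta = config$beta)

  ## -- observables ---------------------------------------------------------
  m <- cbind(pol_wt = P + epsP,
             dH3_fft3 = xp * Lwt + epsF,
             dH3_spt16 = (Lwt - config$beta * Dwt) + epsS,
             dpol_fft3 = -config$gamma * xp * Dwt + epsQ,
             exchange = Lwt * epsE)
  rownames(m) <- truth@genes$gene_id
  geneTable <- occupancyTable(
    m, c("log2_ip_over_input", "linear", "linear", "linear", "linear"))

  ## -- annotation: genes laid head-to-tail on synthetic chromosomes --------
  chromOf <- rep(seq_len(config$n_chromosomes),
                 each = ceiling(n / config$n_chromosomes))[seq_len(n)]
  start0 <- integer(n); end0 <- integer(n)
  chromLen <- numeric(config$n_chromosomes)
  for (cn in seq_len(config$n_chromosomes)) {
    idx <- which(chromOf == cn)
    ends <- cumsum(gaps[idx] + geneLen[idx])
    start0[idx] <- ends - geneLen[idx]
    end0[idx] <- ends
    chromLen[cn] <- if (length(idx)) ends[length(idx)] + 500 else 1000
  }
  chromNames <- paste0("chrS", seq_len(config$n_chromosomes))
  annotation <- GRanges(
    seqnames = factor(chromNames[chromOf], levels = chromNames),
    ranges = IRanges(start = start0 + 1L, end = end0),
    strand = strands,
    seqlengths = stats::setNames(chromLen, chromNames))
  names(annotation) <- truth@genes$gene_id
  annotation$gene_id <- truth@genes$gene_id

  cohort <- new("SyntheticCohort", annotation = annotation, tracks = list(),
                geneTable = geneTable, truth = truth, config = config)
  if (tracks) cohort@tracks <- generateTracks(cohort, config)
  cohort
}

#' Coverage tracks for a synthetic cohort
#'
#' The wild-type RNAPII IP track carries value T_g across each gene body
#' (flat unit-mean shape) on an intergenic baseline of 1.0; the control
#' track is flat 1.0. Values are emitted at \code{track_bin_bp} resolution
#' with length-weighted averaging at partially covered bins.
#'
#' @param cohort a \linkS4class{SyntheticCohort} (annotation + truth).
#' @param config its \code{\link{generatorConfig}}.
#' @return list with CoverageTracks \code{ip} and \code{control}.
#' @export
generateTracks <- function(cohort, config = cohort@config) {
  gi <- geneIntervals(cohort@annotation)
  Tg <- cohort@truth@genes$T
  sl <- GenomeInfoDb::seqlengths(cohort@annotation)
  step <- config$track_bin_bp
  ip <- lapply(names(sl), function(cn) {
    sel <- gi$chrom == cn
    .rasterize(gi$start[sel], gi$end[sel], Tg[sel], sl[[cn]], step,
               baseline = 1)
  })
  names(ip) <- names(sl)
  ctl <- lapply(sl, function(len) rep(1, ceiling(len / step)))
  list(ip = coverageTrack(ip, step, sl),
       control = coverageTrack(ctl, step, sl))
}

#' Summarise the latent truth of a cohort
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @return list with per-genotype means of D, L and R, the realised
#'   median(D_wt), and the scalar parameters.
#' @export
truthSummary <- function(truth) {
  g <- truth@genes
  means <- lapply(c(wt = "wt", fft3 = "fft3", spt16 = "spt16"), function(gt)
    c(D = mean(g[[paste0("D_", gt)]]), L = mean(g[[paste0("L_", gt)]]),
      R = mean(g[[paste0("R_", gt)]])))
  list(genotype_means = means,
       median_D_wt = stats::median(g$D_wt),
       x_prime_true = truth@xPrimeTrue,
       beta = truth@beta)
}

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf(
    "SyntheticCohort: %d genes on %d chromosome(s); true x' = %.2f%s\n",
    length(object@annotation), object@config$n_chromosomes,
    object@truth@xPrimeTrue,
    if (length(object@tracks)) ", with coverage tracks" else ""))
})

#' Write a cohort to disk
#'
#' Emits the annotation (GFF3), coverage tracks (bedGraph, one file per
#' sample), the observable gene table (TSV with header gene_id, pol_wt,
#' dH3_fft3, dH3_spt16, dpol_fft3, exchange) and the latent truth (JSON).
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(annotation = file.path(dir, "genes.gff3"),
             gene_table = file.path(dir, "gene_table.tsv"),
             truth = file.path(dir, "truth.json"))
  writeGeneAnnotationGFF3(cohort@annotation, paths[["annotation"]])
  writeGeneTable(cohort@geneTable, paths[["gene_table"]])
  tr <- truthSummary(cohort@truth)
  jsonlite::write_json(
    c(tr, list(per_gene = cohort@truth@genes)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  for (nm in names(cohort@tracks)) {
    p <- file.path(dir, paste0("track_", nm, ".bedGraph"))
    writeCoverageBedGraph(cohort@tracks[[nm]], p)
    paths[[paste0("track_", nm)]] <- p
  }
  sl <- GenomeInfoDb::seqlengths(cohort@annotation)
  paths[["chrom_sizes"]] <- file.path(dir, "chrom.sizes")
  utils::write.table(data.frame(names(sl), unname(sl)),
                     paths[["chrom_sizes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
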
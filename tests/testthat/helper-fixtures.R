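## Shared fixture builders and independent oracles. Everything is generated
## in code; no data files.

## A GRanges annotation from a compact spec (0-based half-open coordinates).
makeGenes <- function(chrom, start0, end, strand, ids = NULL,
                      seqlen = NULL) {
  if (is.null(ids)) ids <- paste0("g", seq_along(start0))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end),
                               strand = strand)
  if (!is.null(seqlen)) GenomeInfoDb::seqlengths(gr) <- seqlen
  names(gr) <- ids
  gr$gene_id <- ids
  gr
}

## One-chromosome track from a plain vector.
makeTrack <- function(values, step = 10L, chrom = "chr1", len = NULL) {
  coverageTrack(stats::setNames(list(values), chrom), step,
                if (is.null(len)) NULL else stats::setNames(len, chrom))
}

## Independent per-base metagene oracle: expands the track to base
## resolution conceptually and averages each target window with fractional
## base weights. O(gene length); shares no code with scaleRegionsMatrix.
bruteMetageneRow <- function(values, step, len, s, e, strand, cfg) {
  baseVal <- function(p) {           # signal at base [p, p+1); 0 outside
    idx <- pmax(pmin(floor(p / step) + 1, length(values)), 1)
    v <- values[idx]
    v[p < 0 | p >= len] <- 0
    v
  }
  winMean <- function(a, b) {        # mean over [a, b), fractional edges
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    bases <- seq(floor(a), ceiling(b) - 1)
    w <- pmin(bases + 1, b) - pmax(bases, a)
    sum(baseVal(bases) * w) / (b - a)
  }
  nUp <- cfg$upstream_bp / cfg$flank_bin_bp
  nDn <- cfg$downstream_bp / cfg$flank_bin_bp
  fb <- cfg$flank_bin_bp
  B <- cfg$body_bins
  if (strand == "+") {
    edges <- c(seq(s - cfg$upstream_bp, s, by = fb),
               s + (e - s) * seq_len(B) / B,
               if (nDn) seq(e + fb, e + cfg$downstream_bp, length.out = nDn))
  } else {
    edges <- c(seq(e + cfg$upstream_bp, e, by = -fb),
               e - (e - s) * seq_len(B) / B,
               if (nDn) seq(s - fb, s - cfg$downstream_bp, length.out = nDn))
  }
  vapply(seq_len(length(edges) - 1),
         function(i) winMean(edges[i], edges[i + 1]), 0)
}

## Exhaustive hypergeometric oracle: enumerate every size-n subset of an
## N-universe, count overlaps with the first K elements, and take the
## inclusive upper tail.
enumHyperTail <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  M <- utils::combn(N, n)
  counts <- colSums(M <= K)
  mean(counts >= k)
}

## Write a bedGraph from records (0-based half-open).
writeBedGraphLines <- function(path, chrom, s, e, v) {
  writeLines(sprintf("%s\t%d\t%d\t%g", chrom, s, e, v), path)
}
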
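#' Pearson correlation with explicit missing-pair handling
#'
#' Standard product-moment correlation after dropping pairs with any missing
#' value; the number of pairs actually used is reported. A zero variance in
#' either argument yields \code{r = NA} with \code{undefined = TRUE} rather
#' than an error.
#'
#' @param x,y paired numeric vectors.
#' @return list with \code{r}, \code{n_used} and \code{undefined}.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  keep <- is.finite(x) & is.finite(y)
  nUsed <- sum(keep)
  if (nUsed < 3L)
    stop("fewer than 3 complete pairs (", nUsed, "); correlation not computed")
  x <- x[keep]; y <- y[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n_used = nUsed, undefined = TRUE))
  list(r = stats::cor(x, y), n_used = nUsed, undefined = FALSE)
}

#' Transcription-dependence summary of a response column
#'
#' Pearson correlation between a reference column (e.g. wild-type RNAPII
#' occupancy) and a response column (e.g. a mutant occupancy change), with
#' the field's conventional call of a "meaningful" association when
#' \code{|r| >= threshold} (default 0.4; inclusive).
#'
#' @param reference,response named numeric vectors; pairing is by gene name
#'   when both are named, positional otherwise.
#' @param threshold absolute-correlation cutoff (default 0.4).
#' @return list with \code{r}, \code{n}, \code{meaningful}, and the paired
#'   scatter-ready data.frame in \code{pairs}.
#' @export
dependenceSummary <- function(reference, response, threshold = 0.4) {
  if (!is.null(names(reference)) && !is.null(names(response))) {
    shared <- intersect(names(reference), names(response))
    reference <- reference[shared]; response <- response[shared]
    ids <- shared
  } else {
    ids <- seq_along(reference)
  }
  pr <- pearsonR(reference, response)
  keep <- is.finite(reference) & is.finite(response)
  list(r = pr$r, n = pr$n_used,
       meaningful = isTRUE(abs(pr$r) >= threshold),
       pairs = data.frame(gene_id = ids[keep],
                          reference = unname(reference[keep]),
                          response = unname(response[keep]),
                          stringsAsFactors = FALSE))
}

#' Tukey HSD pairwise comparisons
#'
#' Standard Tukey honest-significant-difference test on the studentized
#' range distribution, for all pairs of the supplied groups.
#'
#' @param groups named list of numeric vectors (>= 2 groups of >= 2 values).
#' @return data.frame with columns \code{pair}, \code{diff} (difference of
#'   means) and \code{p_adj} (Tukey-adjusted p-value).
#' @export
tukeyPairwise <- function(groups) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs at least two values")
  value <- unlist(groups, use.names = FALSE)
  group <- factor(rep(names(groups), vapply(groups, length, 1L)),
                  levels = names(groups))
  pooledVar <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) /
    (length(value) - length(groups))
  if (pooledVar == 0)
    stop("zero pooled within-group variance; Tukey comparison degenerate")
  fit <- stats::aov(value ~ group)
  tk <- stats::TukeyHSD(fit)$group
  data.frame(pair = rownames(tk), diff = tk[, "diff"],
             p_adj = tk[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}
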
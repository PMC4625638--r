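# Source-specific feature filters applied before model selection:
#   EXPR/MIRNA: Spearman co-correlation filter, then a range-quantization
#     filter that removes invariant genes;
#   CNA: keep the top fraction of probes by univariate median-split
#     log-rank p-value;
#   MUT: keep the top fraction of most frequently mutated genes.

#' Filter configuration
#'
#' @param rhoThreshold absolute Spearman correlation a feature must exceed
#'   with at least one other feature to be kept (default 0.6).
#' @param nBins number of equal-width segments for the quantization filter
#'   (default 5).
#' @param minOccupiedBins minimum number of occupied segments, i.e. "more
#'   than two" = 3 (default 3).
#' @param cnaTopFraction fraction of CNA probes kept by smallest log-rank
#'   p-value (default 0.10).
#' @param mutTopFraction fraction of most frequently mutated genes kept;
#'   dataset-specific in practice (default 0.15).
#' @return A validated list of class \code{filter_config}.
#' @export
filterConfig <- function(rhoThreshold = 0.6, nBins = 5L,
                         minOccupiedBins = 3L, cnaTopFraction = 0.10,
                         mutTopFraction = 0.15) {
  assertFraction(rhoThreshold, "rhoThreshold", lo = 0, hi = 1,
                 lo_open = FALSE)
  assertScalarCount(nBins, "nBins")
  assertScalarCount(minOccupiedBins, "minOccupiedBins")
  if (nBins < 2L) stop("nBins must be >= 2")
  if (minOccupiedBins > nBins) stop("minOccupiedBins must be <= nBins")
  assertFraction(cnaTopFraction, "cnaTopFraction")
  assertFraction(mutTopFraction, "mutTopFraction")
  structure(list(rhoThreshold = rhoThreshold, nBins = as.integer(nBins),
                 minOccupiedBins = as.integer(minOccupiedBins),
                 cnaTopFraction = cnaTopFraction,
                 mutTopFraction = mutTopFraction),
            class = "filter_config")
}

#' Spearman co-correlation filter
#'
#' Keeps a feature iff its absolute Spearman correlation with at least one
#' other feature of the same matrix exceeds the threshold. Input order of
#' the kept ids is preserved.
#'
#' @param x an \linkS4class{OmicsMatrix} with a continuous source and at
#'   least two features.
#' @param rhoThreshold correlation threshold (kept iff max |rho| >
#'   threshold).
#' @return Character vector of kept feature ids.
#' @export
correlationFilter <- function(x, rhoThreshold = 0.6) {
  if (!omicsSource(x) %in% continuousSources)
    stop("correlation filter applies only to continuous sources")
  v <- omicsValues(x)
  if (nrow(v) < 2L)
    stop("correlation filter needs at least two features")
  rho <- cor(t(v), method = "spearman")
  diag(rho) <- 0
  keep <- apply(abs(rho), 1L, max) > rhoThreshold
  rownames(v)[keep]
}

#' Range-quantization (invariance) filter
#'
#' Cuts each feature's observed range into \code{nBins} equal-width
#' segments and keeps the feature iff at least \code{minOccupiedBins}
#' segments contain a value. Constant features (zero range) occupy a single
#' segment and are always dropped.
#'
#' @param x an \linkS4class{OmicsMatrix} with a continuous source.
#' @param nBins number of equal-width segments.
#' @param minOccupiedBins minimum occupied segments required to keep.
#' @return Character vector of kept feature ids.
#' @export
quantizationFilter <- function(x, nBins = 5L, minOccupiedBins = 3L) {
  if (!omicsSource(x) %in% continuousSources)
    stop("quantization filter applies only to continuous sources")
  v <- omicsValues(x)
  occupied <- apply(v, 1L, function(row) {
    rng <- range(row)
    if (rng[1] == rng[2]) return(1L)
    # right-closed bins over [min, max]; the minimum falls in bin 1
    b <- pmin(pmax(ceiling((row - rng[1]) / (rng[2] - rng[1]) * nBins), 1L),
              nBins)
    length(unique(b))
  })
  rownames(v)[occupied >= minOccupiedBins]
}

# univariate Cox + median-split log-rank p for one feature row; NA-safe
featureLogrankP <- function(values, survival) {
  x <- matrix(values, ncol = 1, dimnames = list(names(values), "f"))
  fit <- tryCatch(suppressWarnings(fitCox(x, survival)),
                  error = function(e) NULL)
  if (is.null(fit) || !fit@converged) return(NA_real_)
  pi <- prognosticIndex(fit, x)
  lr <- tryCatch(logrankMedianSplit(pi, survival), error = function(e) NULL)
  if (is.null(lr)) return(NA_real_)
  lr$p
}

#' Survival-association filter for copy-number probes
#'
#' For each feature: fit a univariate Cox model, split patients at the
#' median prognostic index, and score the feature with the log-rank
#' p-value. Keeps the \code{ceiling(topFraction * p)} features with the
#' smallest p-values; ties and failed (non-converging) fits rank last, with
#' remaining ties broken by feature id.
#'
#' @param x an \linkS4class{OmicsMatrix} (CNA source).
#' @param survival aligned \linkS4class{SurvivalData}.
#' @param topFraction fraction of features to keep.
#' @return Character vector of kept feature ids.
#' @export
cnaSurvivalFilter <- function(x, survival, topFraction = 0.10) {
  assertFraction(topFraction, "topFraction")
  v <- omicsValues(x)
  stopifnot(identical(colnames(v), patientIds(survival)))
  p <- vapply(rownames(v), function(f)
    featureLogrankP(setNames(v[f, ], colnames(v)), survival), numeric(1))
  failed <- !is.finite(p)
  if (any(failed)) p[failed] <- Inf   # ranked last
  k <- fractionCount(topFraction, nrow(v))
  ord <- order(p, rownames(v))
  sort_keep <- rownames(v)[ord[seq_len(k)]]
  rownames(v)[rownames(v) %in% sort_keep]
}

#' Mutation-frequency filter
#'
#' Ranks genes by mutation count (descending) and keeps the top
#' \code{ceiling(topFraction * p)}; ties broken by feature id
#' (lexicographically first wins).
#'
#' @param x an \linkS4class{OmicsMatrix} (MUT source, binary values).
#' @param topFraction fraction of genes to keep.
#' @return Character vector of kept feature ids (input order preserved);
#'   empty, with a warning, when no gene is mutated.
#' @export
mutationFrequencyFilter <- function(x, topFraction = 0.15) {
  assertFraction(topFraction, "topFraction")
  if (!identical(omicsSource(x), "MUT"))
    stop("mutation filter applies only to MUT matrices")
  v <- omicsValues(x)
  counts <- rowSums(v)
  if (all(counts == 0)) {
    warning("no mutated genes; empty filter result")
    return(character())
  }
  k <- fractionCount(topFraction, nrow(v))
  ord <- order(-counts, rownames(v))
  keep <- rownames(v)[ord[seq_len(k)]]
  rownames(v)[rownames(v) %in% keep]
}

#' Apply the full per-source filter pipeline
#'
#' EXPR and MIRNA: correlation filter first, then quantization filter.
#' CNA: survival-association filter. MUT: frequency filter.
#'
#' @param x an \linkS4class{OmicsMatrix}.
#' @param survival aligned \linkS4class{SurvivalData} (needed for CNA).
#' @param config a \code{\link{filterConfig}}.
#' @return The filtered \linkS4class{OmicsMatrix}.
#' @export
filterSource <- function(x, survival, config = filterConfig()) {
  keep <- switch(omicsSource(x),
    EXPR = ,
    MIRNA = {
      k1 <- correlationFilter(x, config$rhoThreshold)
      if (!length(k1)) character() else {
        sub <- OmicsMatrix(omicsValues(x)[k1, , drop = FALSE],
                           omicsSource(x))
        quantizationFilter(sub, config$nBins, config$minOccupiedBins)
      }
    },
    CNA = cnaSurvivalFilter(x, survival, config$cnaTopFraction),
    MUT = mutationFrequencyFilter(x, config$mutTopFraction),
    stop("unknown source ", omicsSource(x)))
  OmicsMatrix(omicsValues(x)[keep, , drop = FALSE], omicsSource(x))
}
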
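#' Well-above-background filter
#'
#' A probe passes only if both raw channels strictly exceed the 99th
#' percentile (nearest-rank) of the array's background signal population.
#'
#' @param red_raw,green_raw raw channel intensities.
#' @param background the array's background population (e.g. the per-probe
#'   local background estimates).
#' @param prob percentile of the background population; default 0.99.
#' @return logical vector.
#' @export
wellAboveBackground <- function(red_raw, green_raw, background, prob = 0.99) {
  if (length(background) == 0)
    stop("background population is empty")
  thr <- nearestRankQuantile(background, prob)
  red_raw > thr & green_raw > thr
}

#' Linear (global-scale) normalization of a two-color array
#'
#' Rescales the green channel so both channels have equal median intensity
#' over well-above-background probes. Scaling is monotone, so intensity order
#' within each channel is preserved.
#'
#' @param tbl probe-level data.frame with columns \code{red_raw},
#'   \code{green_raw}, \code{bg_mean}.
#' @return \code{tbl} with added columns \code{red_norm}, \code{green_norm},
#'   \code{wab}.
#' @export
linearNormalize <- function(tbl) {
  wab <- wellAboveBackground(tbl$red_raw, tbl$green_raw, tbl$bg_mean)
  mr <- stats::median(tbl$red_raw[wab])
  mg <- stats::median(tbl$green_raw[wab])
  if (!any(wab) || !is.finite(mr) || !is.finite(mg) || mr <= 0 || mg <= 0)
    stop("degenerate input: a channel has no usable signal")
  tbl$red_norm <- tbl$red_raw
  tbl$green_norm <- tbl$green_raw * (mr / mg)
  tbl$wab <- wab
  tbl
}

#' Intensity-dependent (LOWESS) normalization in the M-vs-A representation
#'
#' Fits a locally weighted regression of M = log2(red/green) on
#' A = mean log2 intensity (tricube weights, robustness iterations) and
#' subtracts the fit, removing smooth intensity-dependent dye bias. Apply
#' after [linearNormalize()].
#'
#' @param tbl output of [linearNormalize()].
#' @param span LOWESS span in (0, 1]; default 0.3.
#' @param iter robustness iterations; default 2.
#' @param correct if FALSE the fit is skipped and M is kept as is (e.g. for
#'   noiseless data with no dye bias, where the local fit would absorb real
#'   signal structure).
#' @return data.frame with columns probe_id, gene_symbol, red_norm,
#'   green_norm, M, A, wab. Probes with a non-positive channel get NA M/A and
#'   wab = FALSE.
#' @export
lowessNormalize <- function(tbl, span = 0.3, iter = 2, correct = TRUE) {
  if (!all(c("red_norm", "green_norm") %in% names(tbl)))
    stop("run linearNormalize() first")
  if (span <= 0 || span > 1)
    stop("configuration error: span must be in (0, 1]")
  ok <- tbl$red_norm > 0 & tbl$green_norm > 0
  M <- A <- rep(NA_real_, nrow(tbl))
  M[ok] <- log2(tbl$red_norm[ok] / tbl$green_norm[ok])
  A[ok] <- 0.5 * (log2(tbl$red_norm[ok]) + log2(tbl$green_norm[ok]))
  if (correct && sum(ok) >= 10) {
    fit <- stats::lowess(A[ok], M[ok], f = span, iter = iter)
    fhat <- stats::approx(fit$x, fit$y, xout = A[ok], rule = 2,
                          ties = mean)$y
    M[ok] <- M[ok] - fhat
  }
  data.frame(probe_id = tbl$probe_id, gene_symbol = tbl$gene_symbol,
             red_norm = tbl$red_norm, green_norm = tbl$green_norm,
             M = M, A = A, wab = tbl$wab & ok, stringsAsFactors = FALSE)
}

#' Technology error of a feature's log2 ratio
#'
#' Two-component (additive + multiplicative) error propagated to the log2
#' ratio: \code{sigma_tech^2 = [(sigma_add^2/red^2 + sigma_mult^2) +
#' (sigma_add^2/green^2 + sigma_mult^2)] / ln(2)^2}. Strictly decreasing in
#' each intensity; approaches \code{sqrt(2) * sigma_mult / ln 2} for bright
#' features. Non-positive intensities yield NA (the probe is excluded
#' downstream, never imputed).
#'
#' @param red,green normalized linear intensities.
#' @param noise a [noiseParams()] list (only sigma_add and sigma_mult used).
#' @return log2-scale SD vector.
#' @export
featureSigma <- function(red, green, noise) {
  s2 <- (noise$sigma_add^2 / red^2 + noise$sigma_mult^2 +
         noise$sigma_add^2 / green^2 + noise$sigma_mult^2) / log(2)^2
  s <- sqrt(s2)
  s[!(red > 0 & green > 0)] <- NA_real_
  s
}

#' Error-weighted combination of replicate ratios
#'
#' Given oriented log2 ratios and per-replicate errors, returns the
#' inverse-variance weighted mean, its combined error
#' \code{(sum 1/s_i^2)^(-1/2)}, and a two-sided normal-theory p-value for the
#' weighted mean (a z-type statistic; no small-sample t correction).
#'
#' @param r oriented log2 ratios (dye-swap replicates already negated into the
#'   common orientation).
#' @param s per-replicate log2-scale errors, same length as \code{r}.
#' @param sigma_floor numerical floor on \code{s} so that noise-free data do
#'   not divide by zero.
#' @return list with \code{weighted_log2_ratio}, \code{combined_sigma},
#'   \code{p_value}.
#' @export
combineReplicates <- function(r, s, sigma_floor = 1e-6) {
  if (length(r) == 0) stop("missing data: no replicate measurements")
  stopifnot(length(r) == length(s))
  s <- pmax(s, sigma_floor)
  w <- 1 / s^2
  wr <- sum(w * r) / sum(w)
  cs <- 1 / sqrt(sum(w))
  list(weighted_log2_ratio = wr, combined_sigma = cs,
       p_value = 2 * stats::pnorm(abs(wr) / cs, lower.tail = FALSE))
}

# Vectorized row-wise version: R and S are probes x replicates matrices.
.combineReplicatesMatrix <- function(R, S, sigma_floor = 1e-6) {
  S <- pmax(S, sigma_floor)
  W <- 1 / S^2
  W[is.na(R)] <- NA
  sw <- rowSums(W, na.rm = TRUE)
  sw[rowSums(!is.na(R)) == 0] <- NA
  wr <- rowSums(W * R, na.rm = TRUE) / sw
  cs <- 1 / sqrt(sw)
  list(ratio = wr, sigma = cs,
       p = 2 * stats::pnorm(abs(wr) / cs, lower.tail = FALSE))
}

#' Normalize all arrays and summarize every comparison
#'
#' The full array-processing stage: per array, linear then (optionally) LOWESS
#' normalization; per comparison, orientation of each replicate's M toward the
#' comparison's numerator sample, a per-feature technology error from the
#' normalized intensities, a single between-replicate variance pooled across
#' well-measured probes, per-replicate error \code{s_i^2 = max(sigma_tech_i^2,
#' sigma_rep^2)} (the max guards against under-estimating the error with few
#' replicates), and error-weighted combination into a ratio, combined sigma
#' and p-value per probe.
#'
#' @param arrays named list of probe-level data.frames (one per array).
#' @param manifest array manifest data.frame (see [simulateArrays()]).
#' @param comparisons comparison table (see [defaultComparisons()]).
#' @param noise [noiseParams()] describing the technology error components.
#' @param span LOWESS span.
#' @param lowess logical; apply the intensity-dependent correction.
#' @param sigma_floor numerical floor for per-replicate errors.
#' @return a \linkS4class{ComparisonSet}.
#' @export
summarizeComparisons <- function(arrays, manifest, comparisons,
                                 noise = noiseParams(), span = 0.3,
                                 lowess = TRUE, sigma_floor = 1e-6) {
  if (methods::is(arrays, "ArraySimulation")) {
    sim <- arrays
    arrays <- arrayTables(sim)
    manifest <- arrayManifest(sim)
    comparisons <- sim@design$comparisons
    if (missing(noise)) noise <- do.call(noiseParams, sim@noise)
  }
  norm <- lapply(arrays, function(a)
    lowessNormalize(linearNormalize(a), span = span, correct = lowess))

  n_probes <- nrow(norm[[1]])
  nc <- nrow(comparisons)
  mk <- function() matrix(NA_real_, n_probes, nc,
                          dimnames = list(norm[[1]]$probe_id,
                                          comparisons$label))
  ratio <- sig <- pv <- inten <- mk()
  wab <- matrix(FALSE, n_probes, nc,
                dimnames = dimnames(ratio))

  for (i in seq_len(nc)) {
    rows <- which(manifest$comparison == comparisons$id[i])
    if (length(rows) == 0) stop("missing data: no arrays for comparison ",
                                comparisons$label[i])
    k <- length(rows)
    R <- Stech <- matrix(NA_real_, n_probes, k)
    W <- matrix(FALSE, n_probes, k)
    I <- matrix(NA_real_, n_probes, k)
    for (j in seq_len(k)) {
      na <- norm[[rows[j]]]
      sgn <- if (manifest$red_sample[rows[j]] == comparisons$numerator[i]) 1 else -1
      R[, j] <- sgn * na$M
      Stech[, j] <- featureSigma(na$red_norm, na$green_norm, noise)
      W[, j] <- na$wab
      I[, j] <- 0.5 * (na$red_norm + na$green_norm)
    }
    # between-replicate scatter pooled across well-measured probes
    ok <- rowSums(is.na(R)) == 0 & rowSums(W) == k
    s_rep2 <- if (k >= 2 && any(ok)) {
      mean(apply(R[ok, , drop = FALSE], 1, stats::var))
    } else 0
    S <- sqrt(pmax(Stech^2, s_rep2))
    cmb <- .combineReplicatesMatrix(R, S, sigma_floor)
    ratio[, i] <- cmb$ratio
    sig[, i] <- cmb$sigma
    pv[, i] <- cmb$p
    inten[, i] <- rowMeans(I, na.rm = TRUE)
    wab[, i] <- rowSums(W) == k
  }
  wab[is.na(ratio)] <- FALSE

  se <- SummarizedExperiment(
    assays = list(ratio = ratio, sigma = sig, p = pv,
                  intensity = inten, wab = wab),
    rowData = DataFrame(probe_id = norm[[1]]$probe_id,
                        gene_symbol = norm[[1]]$gene_symbol),
    colData = DataFrame(comparisons, row.names = comparisons$label))
  methods::new("ComparisonSet", se)
}

#' Write a ComparisonSet as one TSV per comparison
#'
#' Columns: gene_id, probe_id, log2_ratio, sigma, p_value, intensity, wab.
#'
#' @param cs a \linkS4class{ComparisonSet}.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
writeComparisonSet <- function(cs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rd <- rowData(cs)
  files <- character(0)
  for (i in seq_len(ncol(cs))) {
    df <- data.frame(gene_id = rd$gene_symbol, probe_id = rd$probe_id,
                     log2_ratio = ratios(cs)[, i], sigma = sigmas(cs)[, i],
                     p_value = pValues(cs)[, i],
                     intensity = intensities(cs)[, i],
                     wab = wabFlags(cs)[, i])
    f <- file.path(dir, paste0("comparison_", colnames(cs)[i], ".tsv"))
    writeTSV(df, f)
    files <- c(files, f)
  }
  invisible(files)
}
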
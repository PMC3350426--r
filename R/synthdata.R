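#' The seven liver comparisons of the dye-swap design
#'
#' Returns the fixed comparison table: three same-age male-vs-female
#' hybridizations (3, 4 and 8 wk) and four developmental hybridizations within
#' each sex (3 or 4 wk against 8 wk). \code{sampleA}/\code{sampleB} record the
#' co-hybridized samples; \code{numerator}/\code{denominator} fix the reported
#' ratio orientation: male over female for the sex comparisons and 8 wk over
#' the younger age for the developmental ones, so that flag 1 ("up") always
#' means male-biased or up-regulated with age.
#'
#' @return data.frame with columns id, label, sampleA, sampleB, numerator,
#'   denominator.
#' @export
defaultComparisons <- function() {
  data.frame(
    id          = 1:7,
    label       = c("M3vF3", "M4vF4", "M8vF8", "M3vM8", "M4vM8", "F3vF8", "F4vF8"),
    sampleA     = c("M3", "M4", "M8", "M3", "M4", "F3", "F4"),
    sampleB     = c("F3", "F4", "F8", "M8", "M8", "F8", "F8"),
    numerator   = c("M3", "M4", "M8", "M8", "M8", "F8", "F8"),
    denominator = c("F3", "F4", "F8", "M3", "M4", "F3", "F4"),
    stringsAsFactors = FALSE)
}

#' Experiment design for a simulated dye-swap study
#'
#' @param n_probes total probes per array (the real platform has 39,429;
#'   simulations are scaled down).
#' @param n_redundant_genes number of genes carrying a second, redundant probe;
#'   the remaining \code{n_probes - n_redundant_genes} probes map one-to-one to
#'   genes.
#' @param replicates_per_comparison arrays per comparison; must be an even
#'   number >= 2 so that dye-swap pairs are complete.
#' @param seed integer seed governing all randomness of the simulation.
#' @param comparisons comparison table; defaults to [defaultComparisons()].
#'   Override only for special designs (e.g. self-self null calibration).
#' @return a list with class \code{"experiment_design"}.
#' @export
experimentDesign <- function(n_probes = 2000,
                             n_redundant_genes = round(0.05 * n_probes),
                             replicates_per_comparison = 2,
                             seed = 1,
                             comparisons = defaultComparisons()) {
  if (replicates_per_comparison < 2 || replicates_per_comparison %% 2 != 0)
    stop("configuration error: replicates_per_comparison must be even and >= 2")
  need <- c("id", "label", "sampleA", "sampleB", "numerator", "denominator")
  if (!all(need %in% names(comparisons)))
    stop("configuration error: comparisons table missing columns")
  if (n_redundant_genes >= n_probes)
    stop("configuration error: n_redundant_genes must be < n_probes")
  structure(list(n_probes = as.integer(n_probes),
                 n_redundant_genes = as.integer(n_redundant_genes),
                 replicates_per_comparison = as.integer(replicates_per_comparison),
                 seed = as.integer(seed),
                 comparisons = comparisons),
            class = "experiment_design")
}

#' Noise model parameters for simulated arrays
#'
#' The channel noise follows the additive + multiplicative (Rocke-Durbin) form:
#' observed = true * exp(N(0, sigma_mult^2)) + N(0, sigma_add^2), truncated at
#' zero. Dye bias is a smooth function of mean log2 intensity added to the red
#' and subtracted from the green channel (half each), so a dye swap reverses
#' its sign relative to the biological ratio.
#'
#' @param sigma_add additive intensity SD, linear units.
#' @param sigma_mult multiplicative coefficient of variation (dimensionless).
#' @param dye_bias_amplitude peak-to-zero dye-bias magnitude on the log2 scale.
#' @param background_mean,background_sd linear-unit mean and SD of the array's
#'   background signal population.
#' @param frac_low_expressed fraction of probes whose target is effectively
#'   unexpressed and sits at background level.
#' @return a list with class \code{"noise_params"}.
#' @export
noiseParams <- function(sigma_add = 3, sigma_mult = 0.1,
                        dye_bias_amplitude = 0.3,
                        background_mean = 20, background_sd = 3,
                        frac_low_expressed = 0.05) {
  p <- list(sigma_add = sigma_add, sigma_mult = sigma_mult,
            dye_bias_amplitude = dye_bias_amplitude,
            background_mean = background_mean, background_sd = background_sd,
            frac_low_expressed = frac_low_expressed)
  if (any(unlist(p) < 0))
    stop("configuration error: noise parameters must be non-negative")
  if (frac_low_expressed > 1)
    stop("configuration error: frac_low_expressed must be in [0, 1]")
  structure(p, class = "noise_params")
}

.devCall <- function(fold, cut = 1.5) {
  ifelse(fold > cut, "up", ifelse(fold < 1 / cut, "down", "none"))
}

.combineIntervalCalls <- function(c38, c48) {
  up <- c38 == "up" | c48 == "up"
  dn <- c38 == "down" | c48 == "down"
  ifelse(up & dn, "mixed", ifelse(up, "up", ifelse(dn, "down", "none")))
}

#' Generate per-gene truth for a simulated study
#'
#' Samples, per gene: a sex-specificity class, an onset age for sex-specific
#' genes, a sex-effect fold, a free developmental trajectory, and a base
#' expression level. For sex-independent genes both sexes' trajectories are
#' free; for a sex-specific gene the opposite sex's trajectory is free and the
#' same-sex trajectory follows from it and the onset (the six expression cells
#' leave no further freedom). The recorded \code{dev_change_male} /
#' \code{dev_change_female} are the realized calls read off the exact
#' expression matrix with the same 1.5-fold rule the classifier uses.
#'
#' @param n_genes number of genes.
#' @param class_proportions named proportions over \code{male-specific},
#'   \code{female-specific}, \code{sex-independent}; must sum to 1.
#' @param effect_fold_range linear fold range (>= 1) from which sex-effect and
#'   developmental folds are drawn log-uniformly.
#' @param onset_proportions proportions of onset at 3, 4 and 8 wk among
#'   sex-specific genes (Table-1-like: most onsets at 8 wk).
#' @param dev_change_prob direction probabilities (none/up/down) for the free
#'   trajectories of sex-independent genes. The defaults keep the regulated
#'   fraction per comparison near 10 percent, the upper end of what the
#'   whole-genome arrays being emulated show; intensity-dependent
#'   normalization relies on a near-null majority at every intensity, so a
#'   much denser regulation structure would be unrealistic.
#' @param opposite_dev_prob direction probabilities for the opposite-sex
#'   trajectory of sex-specific genes (mostly unchanged).
#' @param base_meanlog,base_sdlog log-normal parameters of the base expression
#'   level (linear array units); the default spread covers the several orders
#'   of magnitude a fluorescence array spans.
#' @param seed integer seed; same seed, same truth.
#' @return data.frame, one row per gene.
#' @export
generateTruth <- function(n_genes,
                          class_proportions = c("male-specific" = 0.05,
                                                "female-specific" = 0.05,
                                                "sex-independent" = 0.90),
                          effect_fold_range = c(2, 4),
                          onset_proportions = c("3wk" = 0.02, "4wk" = 0.13,
                                                "8wk" = 0.85),
                          dev_change_prob = c(none = 0.88, up = 0.06,
                                              down = 0.06),
                          opposite_dev_prob = c(none = 0.9, up = 0.05,
                                                down = 0.05),
                          base_meanlog = log(1000), base_sdlog = 1.2,
                          seed = 1) {
  checkProportions(class_proportions, "class_proportions")
  checkProportions(onset_proportions, "onset_proportions")
  checkProportions(dev_change_prob, "dev_change_prob")
  checkProportions(opposite_dev_prob, "opposite_dev_prob")
  if (min(effect_fold_range) < 1)
    stop("configuration error: effect_fold_range must lie in [1, Inf)")

  withSeed(seed, {
    cls <- sample(names(class_proportions), n_genes, replace = TRUE,
                  prob = class_proportions)
    sexspec <- cls != "sex-independent"
    onset <- rep("none", n_genes)
    onset[sexspec] <- sample(names(onset_proportions), sum(sexspec),
                             replace = TRUE, prob = onset_proportions)
    lo <- log(min(effect_fold_range)); hi <- log(max(effect_fold_range))
    rfold <- function(n) exp(stats::runif(n, lo, hi))
    effect <- ifelse(sexspec, rfold(n_genes), 1)

    sampleDev <- function(n, prob) {
      dir <- sample(names(prob), n, replace = TRUE, prob = prob)
      mag <- rfold(n)
      ifelse(dir == "none", 1, ifelse(dir == "up", mag, 1 / mag))
    }
    dev_m <- dev_f <- rep(NA_real_, n_genes)
    si <- !sexspec
    dev_m[si] <- sampleDev(sum(si), dev_change_prob)
    dev_f[si] <- sampleDev(sum(si), dev_change_prob)
    ms <- cls == "male-specific"; fs <- cls == "female-specific"
    dev_f[ms] <- sampleDev(sum(ms), opposite_dev_prob)
    dev_m[fs] <- sampleDev(sum(fs), opposite_dev_prob)

    base <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)

    truth <- data.frame(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      true_class = cls, onset_age = onset, effect_fold = effect,
      dev_fold_male = dev_m, dev_fold_female = dev_f,
      base_level = base, low_expressed = FALSE,
      stringsAsFactors = FALSE)

    em <- expressionMatrix(truth)
    truth$dev_change_male <- .combineIntervalCalls(
      .devCall(em[, "M8"] / em[, "M3"]), .devCall(em[, "M8"] / em[, "M4"]))
    truth$dev_change_female <- .combineIntervalCalls(
      .devCall(em[, "F8"] / em[, "F3"]), .devCall(em[, "F8"] / em[, "F4"]))
    truth
  })
}

#' True linear expression per gene and sample group
#'
#' Deterministically realizes each gene's declared class, onset and
#' trajectory as a 6-cell matrix over \{M3, M4, M8, F3, F4, F8\}. Trajectories
#' are anchored at 8 wk: the 3 and 4 wk cells of a sex equal the 8 wk cell
#' divided by that sex's developmental fold; a sex-specific gene's biased sex
#' is additionally multiplied by the sex-effect fold at every age at or after
#' onset, so e.g. a male-specific onset-4wk gene has M4/F4 = M8/F8 =
#' effect_fold and M3/F3 = 1.
#'
#' @param truth data.frame from [generateTruth()].
#' @return numeric matrix, genes x 6, columns M3, M4, M8, F3, F4, F8.
#' @export
expressionMatrix <- function(truth) {
  n <- nrow(truth)
  onsetAge <- c("3wk" = 3, "4wk" = 4, "8wk" = 8)[truth$onset_age]
  onsetAge[is.na(onsetAge)] <- Inf  # sex-independent: effect never active
  stepAt <- function(age) ifelse(age >= onsetAge, truth$effect_fold, 1)

  B <- truth$base_level
  ms <- truth$true_class == "male-specific"
  fs <- truth$true_class == "female-specific"

  F8 <- M8 <- B
  F3 <- F4 <- B / truth$dev_fold_female
  M3 <- M4 <- B / truth$dev_fold_male
  # sex-specific genes: free trajectory belongs to the opposite sex
  F3[ms] <- F4[ms] <- B[ms] / truth$dev_fold_female[ms]; F8[ms] <- B[ms]
  M3[ms] <- F3[ms] * stepAt(3)[ms]
  M4[ms] <- F4[ms] * stepAt(4)[ms]
  M8[ms] <- F8[ms] * stepAt(8)[ms]
  M3[fs] <- M4[fs] <- B[fs] / truth$dev_fold_male[fs]; M8[fs] <- B[fs]
  F3[fs] <- M3[fs] * stepAt(3)[fs]
  F4[fs] <- M4[fs] * stepAt(4)[fs]
  F8[fs] <- M8[fs] * stepAt(8)[fs]

  em <- cbind(M3 = M3, M4 = M4, M8 = M8, F3 = F3, F4 = F4, F8 = F8)
  rownames(em) <- truth$gene_id
  em
}

#' Simulate the probe-level arrays of a dye-swap experiment
#'
#' Builds every array of the design: for each comparison, replicate 1
#' hybridizes sampleA in the red channel against sampleB in green, replicate 2
#' swaps the dyes (and so on in pairs). Each observed channel intensity is
#' \code{true * exp(N(0, sigma_mult^2)) + N(0, sigma_add^2)}, truncated at 0,
#' after applying half the intensity-dependent dye bias to each channel with
#' opposite signs. Redundant probes share their gene's symbol and true level.
#' A \code{frac_low_expressed} fraction of probes (drawn only from fully null
#' genes, since an unexpressed transcript cannot carry an expression
#' difference) sits at background level. One RNG stream is split per array by
#' stable sub-seeding, so adding arrays does not perturb earlier ones.
#'
#' @param truth data.frame from [generateTruth()]; must have
#'   \code{design$n_probes - design$n_redundant_genes} rows.
#' @param design list from [experimentDesign()].
#' @param noise list from [noiseParams()].
#' @return an \linkS4class{ArraySimulation}.
#' @export
simulateArrays <- function(truth, design, noise = noiseParams()) {
  stopifnot(inherits(design, "experiment_design"))
  n_genes <- nrow(truth)
  if (n_genes != design$n_probes - design$n_redundant_genes)
    stop("truth must describe n_probes - n_redundant_genes genes")

  comp <- design$comparisons
  reps <- design$replicates_per_comparison
  n_arrays <- nrow(comp) * reps

  withSeed(design$seed, {
    # structural choices first, then one pre-drawn sub-seed per array
    eligible <- which(truth$true_class == "sex-independent" &
                      truth$dev_change_male == "none" &
                      truth$dev_change_female == "none")
    n_low <- round(noise$frac_low_expressed * design$n_probes)
    if (n_low > length(eligible)) {
      warning("fewer fully null genes than requested near-background probes")
      n_low <- length(eligible)
    }
    low <- if (n_low > 0) sample(eligible, n_low) else integer(0)
    truth$low_expressed[low] <- TRUE

    red_idx <- if (design$n_redundant_genes > 0)
      sample(n_genes, design$n_redundant_genes) else integer(0)
    array_seeds <- sample.int(.Machine$integer.max - 1L, n_arrays)

    em <- expressionMatrix(truth)
    em[truth$low_expressed, ] <- noise$background_mean
    gene_idx <- c(seq_len(n_genes), red_idx)
    probe_id <- sprintf("p%05d", seq_len(design$n_probes))

    manifest <- data.frame(
      array_id = character(n_arrays), comparison = integer(n_arrays),
      label = character(n_arrays), replicate = integer(n_arrays),
      red_sample = character(n_arrays), green_sample = character(n_arrays),
      dye = character(n_arrays), stringsAsFactors = FALSE)
    arrays <- vector("list", n_arrays)

    a <- 0L
    for (i in seq_len(nrow(comp))) {
      for (j in seq_len(reps)) {
        a <- a + 1L
        fwd <- j %% 2L == 1L
        red_s <- if (fwd) comp$sampleA[i] else comp$sampleB[i]
        green_s <- if (fwd) comp$sampleB[i] else comp$sampleA[i]
        tr <- em[gene_idx, red_s]
        tg <- em[gene_idx, green_s]
        arrays[[a]] <- withSeed(array_seeds[a],
          .simulateOneArray(tr, tg, probe_id, truth$gene_id[gene_idx], noise))
        manifest[a, ] <- list(sprintf("array_%02d_%s_r%d", a, comp$label[i], j),
                              comp$id[i], comp$label[i], j, red_s, green_s,
                              if (fwd) "fwd" else "rev")
      }
    }
    names(arrays) <- manifest$array_id
    methods::new("ArraySimulation", arrays = arrays, manifest = manifest,
                 truth = truth, design = unclass(design),
                 noise = unclass(noise))
  })
}

# One array: dye bias (opposite half-signs per channel) then channel noise.
.simulateOneArray <- function(tr, tg, probe_id, gene_symbol, noise) {
  n <- length(tr)
  A <- 0.5 * (log2(pmax(tr, 1e-12)) + log2(pmax(tg, 1e-12)))
  span <- diff(range(A))
  bias <- if (span > 0 && noise$dye_bias_amplitude > 0)
    noise$dye_bias_amplitude * sin(2 * pi * (A - min(A)) / span)
  else rep(0, n)
  chan <- function(x, sgn) {
    y <- x * 2^(sgn * bias / 2) * exp(stats::rnorm(n, 0, noise$sigma_mult)) +
      stats::rnorm(n, 0, noise$sigma_add)
    pmax(y, 0)
  }
  data.frame(probe_id = probe_id, gene_symbol = gene_symbol,
             red_raw = chan(tr, +1), green_raw = chan(tg, -1),
             bg_mean = pmax(stats::rnorm(n, noise$background_mean,
                                         noise$background_sd), 0),
             bg_sd = noise$background_sd, stringsAsFactors = FALSE)
}

#' Write a simulation to TSV files
#'
#' One probe-level TSV per array, plus \code{manifest.tsv} (comparison,
#' replicate, dye orientation) and \code{truth.tsv}.
#'
#' @param sim an \linkS4class{ArraySimulation}.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- arrayManifest(sim)
  for (i in seq_len(nrow(man)))
    writeTSV(sim@arrays[[i]], file.path(dir, paste0(man$array_id[i], ".tsv")))
  writeTSV(man, file.path(dir, "manifest.tsv"))
  writeTSV(simTruth(sim), file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read probe-level arrays written by [writeSimulation()]
#'
#' Accepts any directory holding a \code{manifest.tsv} plus one TSV per array
#' with the standard probe columns; \code{truth.tsv} is optional (absent for
#' real data).
#'
#' @param dir directory path.
#' @return a list with elements \code{arrays}, \code{manifest} and (possibly
#'   NULL) \code{truth}.
#' @export
readProbeTables <- function(dir) {
  man <- readTSV(file.path(dir, "manifest.tsv"))
  arrays <- lapply(man$array_id, function(a)
    readTSV(file.path(dir, paste0(a, ".tsv"))))
  names(arrays) <- man$array_id
  tf <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(tf)) readTSV(tf) else NULL
  list(arrays = arrays, manifest = man, truth = truth)
}
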
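#' Pipeline configuration
#'
#' A single validated configuration object drives [runPipeline()]. Either a
#' \code{simulate} block (design + truth + noise parameters) or an
#' \code{input} block (directory of probe-level TSVs with a manifest) must be
#' present. Threshold fields always carry the study defaults unless
#' overridden.
#'
#' @param seed integer master seed; mandatory when simulating.
#' @param simulate list with \code{n_probes}, \code{n_redundant_genes},
#'   \code{replicates_per_comparison}, optional \code{truth} (arguments for
#'   [generateTruth()]) and \code{noise} (arguments for [noiseParams()]).
#' @param input list with \code{dir}: probe tables written by
#'   [writeSimulation()] (or any conforming tables), plus optional
#'   \code{noise} for the technology error model.
#' @param normalize list: \code{span}, \code{lowess}, \code{sigma_floor}.
#' @param thresholds arguments for [tfsThresholds()].
#' @param profiles list: \code{run}, \code{m} (max model profiles, 30 or 50
#'   in the study; smaller for demos), \code{max_unit_change}, \code{B}
#'   permutations.
#' @param enrich NULL to skip, or a list with \code{external_sets} (named
#'   list of symbol vectors or file paths, one symbol per line) or
#'   \code{synthetic = TRUE} to generate planted external sets for
#'   demonstration.
#' @return a list with class \code{"pipeline_config"}.
#' @export
pipelineConfig <- function(seed = 1,
                           simulate = NULL, input = NULL,
                           normalize = list(), thresholds = list(),
                           profiles = list(), enrich = NULL) {
  if (is.null(simulate) && is.null(input))
    stop("configuration error: need a simulate or input block")
  if (!is.null(simulate) && is.null(seed))
    stop("configuration error: seed is mandatory when simulating")
  norm <- utils::modifyList(
    list(span = 0.3, lowess = TRUE, sigma_floor = 1e-6), normalize)
  prof <- utils::modifyList(
    list(run = TRUE, m = 10, max_unit_change = 2, B = 200), profiles)
  structure(list(seed = as.integer(seed), simulate = simulate, input = input,
                 normalize = norm, thresholds = do.call(tfsThresholds,
                                                        thresholds),
                 profiles = prof, enrich = enrich),
            class = "pipeline_config")
}

#' Demonstration configuration
#'
#' A small simulated experiment (default 2,000 probes) exercising every
#' stage. With \code{noiseless = TRUE} all noise components and the dye bias
#' are zero and the LOWESS stage is disabled (there is no dye bias to remove,
#' and on noise-free structured data a local fit would absorb real signal),
#' so the classification table must equal the simulation truth exactly.
#'
#' @param n_probes probes per array.
#' @param seed master seed.
#' @param noiseless logical.
#' @return a \code{"pipeline_config"}.
#' @export
demoConfig <- function(n_probes = 2000, seed = 11, noiseless = FALSE) {
  noise <- if (noiseless)
    list(sigma_add = 0, sigma_mult = 0, dye_bias_amplitude = 0,
         background_mean = 1, background_sd = 0, frac_low_expressed = 0)
  else list()
  # the zero-error limit demo keeps every gene well above background and away
  # from detection boundaries: a gene sitting exactly at an assay threshold
  # has no well-defined truth call for a thresholded assay
  truth <- if (noiseless)
    list(opposite_dev_prob = c(none = 1, up = 0, down = 0)) else list()
  pipelineConfig(
    seed = seed,
    simulate = list(n_probes = n_probes,
                    n_redundant_genes = round(0.05 * n_probes),
                    replicates_per_comparison = 2,
                    truth = truth, noise = noise),
    normalize = list(lowess = !noiseless),
    profiles = list(m = 10, B = 200),
    enrich = list(synthetic = TRUE))
}

# planted external sets for demonstration runs: dev-set genes enter with a
# boosted probability, so true fold enrichment ~ p1/p0 weighted by set size
.syntheticExternalSets <- function(master, seed, p0 = 0.08, p1 = 0.35) {
  withSeed(seed, {
    bg <- unique(tolower(master$gene_id))
    up_m <- unique(tolower(master$gene_id[master$dev_male_38 == "up"]))
    down_m <- unique(tolower(master$gene_id[master$dev_male_38 == "down"]))
    pick <- function(target) {
      pr <- ifelse(bg %in% target, p1, p0)
      bg[stats::runif(length(bg)) < pr]
    }
    list(ext_down_in_ko = pick(up_m), ext_up_in_ko = pick(down_m))
  })
}

.readGeneList <- function(x) {
  if (length(x) == 1 && is.character(x) && file.exists(x))
    readLines(x, warn = FALSE) else x
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> normalize -> summarize comparisons ->
#' classify -> profile clustering -> enrichment, writing every stage's tables
#' as TSV plus a run manifest (config hash, seed, versions). Output is a pure
#' function of the configuration: repeated runs produce byte-identical
#' tables.
#'
#' @param config a \code{"pipeline_config"}.
#' @param outdir output directory.
#' @param quiet suppress per-stage log messages.
#' @return invisibly, a list with the in-memory stage results and file paths.
#' @export
runPipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)

  # --- stage: simulate or load ------------------------------------------
  if (!is.null(config$simulate)) {
    sm <- config$simulate
    design <- experimentDesign(
      n_probes = sm$n_probes,
      n_redundant_genes = sm$n_redundant_genes %||% round(0.05 * sm$n_probes),
      replicates_per_comparison = sm$replicates_per_comparison %||% 2,
      seed = config$seed)
    noise <- do.call(noiseParams, sm$noise %||% list())
    truth <- do.call(generateTruth, c(
      list(n_genes = design$n_probes - design$n_redundant_genes,
           seed = config$seed), sm$truth %||% list()))
    sim <- simulateArrays(truth, design, noise)
    arrays <- arrayTables(sim)
    manifest <- arrayManifest(sim)
    comparisons <- design$comparisons
    writeTSV(simTruth(sim), file.path(outdir, "truth.tsv"))
    writeTSV(manifest, file.path(outdir, "manifest.tsv"))
    say("simulate: ", length(arrays), " arrays, ", design$n_probes,
        " probes (", sum(simTruth(sim)$true_class != "sex-independent"),
        " sex-specific genes)")
  } else {
    inp <- readProbeTables(config$input$dir)
    arrays <- inp$arrays; manifest <- inp$manifest
    comparisons <- defaultComparisons()
    noise <- do.call(noiseParams, config$input$noise %||% list())
    sim <- NULL
    say("load: ", length(arrays), " arrays from ", config$input$dir)
  }

  # --- stage: normalize + summarize comparisons -------------------------
  cs <- summarizeComparisons(arrays, manifest, comparisons, noise,
                             span = config$normalize$span,
                             lowess = config$normalize$lowess,
                             sigma_floor = config$normalize$sigma_floor)
  writeComparisonSet(cs, outdir)
  th <- config$thresholds
  nsig <- colSums(pValues(cs) < th$p_cut & wabFlags(cs), na.rm = TRUE)
  for (i in seq_along(nsig)) {
    fp <- expectedFalsePositives(th$p_cut, nrow(cs), nsig[i])
    say("comparisons: ", colnames(cs)[i], " p<", th$p_cut, ": ", nsig[i],
        " probes (", fp$expected_rounded, " expected by chance, FDR ",
        signif(fp$fdr_percent, 3), "%)")
  }

  # --- stage: classify --------------------------------------------------
  master <- masterTable(cs, th)
  writeTSV(master, file.path(outdir, "master.tsv"))
  summaries <- summarizeCounts(master)
  for (nm in names(summaries))
    writeTSV(summaries[[nm]], file.path(outdir, paste0("summary_", nm, ".tsv")))
  say("classify: ", nrow(master), " retained probes, ",
      sum(master$sex_class == "male-specific"), " male-specific / ",
      sum(master$sex_class == "female-specific"), " female-specific / ",
      sum(master$sex_class == "sex-independent"), " sex-independent")

  # --- stage: profiles --------------------------------------------------
  prof_out <- list()
  if (isTRUE(config$profiles$run)) {
    cand <- enumerateCandidateProfiles(ncol(cs), config$profiles$max_unit_change)
    universes <- list(
      sex_specific = master$sex_class != "sex-independent" & master$tfs_whole > 0,
      sex_independent = master$sex_class == "sex-independent" &
        master$tfs_whole > 0)
    for (u in names(universes)) {
      idx <- which(universes[[u]])
      if (length(idx) < 3) next
      X <- as.matrix(master[idx, grep("^log2_", names(master)), drop = FALSE])
      rownames(X) <- master$probe_id[idx]
      sel <- selectModelProfiles(cand, min(config$profiles$m, nrow(cand)))
      asg <- assignProfiles(X, sel$profiles)
      asg <- cbind(gene_id = master$gene_id[idx], asg[, -1, drop = FALSE],
                   probe_id = master$probe_id[idx])
      sig <- profileSignificance(X, sel$profiles, B = config$profiles$B,
                                 seed = config$seed + match(u, names(universes)))
      box <- do.call(rbind, lapply(which(sig$significant), function(pid) {
        rows <- which(asg$profile_id == pid)
        if (length(rows) == 0) return(NULL)
        cbind(profile_id = pid, profileBoxStats(X[rows, , drop = FALSE]))
      }))
      writeTSV(asg, file.path(outdir, paste0("profiles_", u, "_assignments.tsv")))
      writeTSV(sig, file.path(outdir, paste0("profiles_", u, "_table.tsv")))
      if (!is.null(box))
        writeTSV(box, file.path(outdir, paste0("profiles_", u, "_boxstats.tsv")))
      prof_out[[u]] <- list(assignments = asg, significance = sig)
      say("profiles[", u, "]: ", length(idx), " genes, ",
          sum(sig$significant), "/", nrow(sig), " profiles significant")
    }
  }

  # --- stage: enrichment ------------------------------------------------
  enr <- NULL
  if (!is.null(config$enrich)) {
    ext <- if (isTRUE(config$enrich$synthetic))
      .syntheticExternalSets(master, config$seed + 97)
    else lapply(config$enrich$external_sets, .readGeneList)
    dev_sets <- list(
      up_male_3to8 = master$gene_id[master$dev_male_38 == "up"],
      down_male_3to8 = master$gene_id[master$dev_male_38 == "down"],
      up_female_3to8 = master$gene_id[master$dev_female_38 == "up"],
      down_female_3to8 = master$gene_id[master$dev_female_38 == "down"])
    bg <- unique(tolower(master$gene_id))
    enr <- enrichmentMatrix(dev_sets, ext, bg)
    writeTSV(enr, file.path(outdir, "enrichment.tsv"))
    say("enrich: ", sum(enr$significant), "/", nrow(enr),
        " pairs significant at p<1e-4")
  }

  # --- run manifest -----------------------------------------------------
  cfg_file <- file.path(outdir, "config.yaml")
  yaml::write_yaml(.configAsList(config), cfg_file)
  manifest_txt <- c(
    paste0("config_md5: ", unname(tools::md5sum(cfg_file))),
    paste0("seed: ", config$seed),
    paste0("package: tfsarray ",
           as.character(utils::packageVersion("tfsarray"))),
    paste0("r_version: ", R.version.string))
  writeLines(manifest_txt, file.path(outdir, "run_manifest.txt"))

  invisible(list(sim = sim, comparison_set = cs, master = master,
                 summaries = summaries, profiles = prof_out,
                 enrichment = enr, outdir = outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip classes so the config serializes to stable YAML
.configAsList <- function(config) {
  x <- unclass(config)
  x$thresholds <- unclass(x$thresholds)
  x[!vapply(x, is.null, logical(1))]
}
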
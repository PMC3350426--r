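test_that("comparison flags apply strict fold, p and background filters", {
  th <- tfsThresholds()
  expect_equal(flagComparison(2.0, 1e-6, TRUE, th), 1L)
  expect_equal(flagComparison(0.5, 1e-6, TRUE, th), 2L)
  expect_equal(flagComparison(0.5, 1e-6, FALSE, th), 0L)  # below background
  expect_equal(flagComparison(1.5, 1e-9, TRUE, th), 0L)   # boundary: strict >
  expect_equal(flagComparison(1/1.5, 1e-9, TRUE, th), 0L)
  expect_equal(flagComparison(2.0, 1e-4, TRUE, th), 0L)   # p boundary: strict <
  expect_equal(flagComparison(c(2, 0.4, 1.1), c(1e-6, 1e-6, 1e-6),
                              c(TRUE, TRUE, TRUE), th), c(1L, 2L, 0L))
  expect_error(tfsThresholds(fold_cut = 0.9), "configuration error")
})

test_that("TFS encoding matches the worked example and round-trips", {
  expect_equal(encodeTFS(c(0, 0, 2, 2, 2, 0, 0)), "28.0022200")
  expect_equal(tfsWhole(c(0, 0, 2, 2, 2, 0, 0)), 28L)
  expect_equal(encodeTFS(rep(0, 7)), "0.0000000")
  expect_equal(tfsWhole(rep(1, 7)), 127L)

  # all 3^7 flag vectors: decode(encode(f)) == f, and the whole number equals
  # brute-force summation of the binary weights of nonzero positions
  all_flags <- as.matrix(expand.grid(rep(list(0:2), 7)))
  colnames(all_flags) <- NULL
  enc <- encodeTFS(all_flags)
  expect_equal(length(unique(enc)), nrow(all_flags))
  brute <- apply(all_flags, 1, function(f) sum(c(1, 2, 4, 8, 16, 32, 64)[f != 0]))
  expect_equal(tfsWhole(all_flags), as.integer(brute))
  idx <- c(1, 500, 1000, 2187)
  for (i in idx) expect_equal(decodeTFS(enc[i]), unname(all_flags[i, ]))

  expect_error(decodeTFS("28.00222"), "parse error")     # too few digits
  expect_error(decodeTFS("28.0032200"), "parse error")   # digit out of range
  expect_error(decodeTFS("27.0022200"), "parse error")   # inconsistent whole
})

test_that("redundant probes collapse to the lowest-p probe per TFS group", {
  flags <- rbind(c(0, 0, 1, 1, 0, 0, 0),
                 c(0, 0, 1, 1, 0, 0, 0),   # same gene, same TFS
                 c(0, 0, 2, 0, 0, 0, 0),   # same gene, different TFS
                 c(0, 0, 0, 0, 0, 0, 0))   # other gene
  pv <- rbind(c(.5, .5, 1e-5, 1e-3, .5, .5, .5),
              c(.5, .5, 1e-6, 1e-4, .5, .5, .5),  # lower p-sum: retained
              c(.5, .5, 1e-8, .5, .5, .5, .5),
              rep(.5, 7))
  keep <- removeRedundantProbes(flags, pv, c("a", "a", "a", "b"),
                                c("p1", "p2", "p3", "p4"))
  expect_equal(keep, c(FALSE, TRUE, TRUE, TRUE))
  # tie on the p-sum: lexicographically smallest probe id survives
  keep2 <- removeRedundantProbes(flags[c(1, 1), ], pv[c(1, 1), ],
                                 c("a", "a"), c("p9", "p2"))
  expect_equal(keep2, c(FALSE, TRUE))
  # single probe: identity
  expect_true(removeRedundantProbes(flags[1, , drop = FALSE],
                                    pv[1, , drop = FALSE], "a", "p1"))
})

test_that("gene classification derives sex class, onset and dev calls", {
  cls <- classifyGenes(rbind(
    c(0, 1, 1, 1, 0, 0, 0),
    c(0, 0, 2, 2, 2, 0, 0),
    rep(0, 7),
    c(1, 1, 1, 1, 1, 0, 0),
    c(2, 0, 1, 1, 2, 0, 1),   # early opposite bias; mixed male dev
    c(0, 1, 0, 0, 0, 2, 2)))  # transient bias without an 8wk call
  expect_equal(cls$sex_class[1], "male-specific")
  expect_equal(cls$onset[1], "4wk")
  expect_equal(cls$dev_male[1], "up")
  expect_equal(cls$dev_female[1], "none")

  # the worked TFS example 28.0022200: female-specific at 8 wk, down in male
  expect_equal(cls$sex_class[2], "female-specific")
  expect_equal(cls$onset[2], "8wk")
  expect_equal(cls$dev_male[2], "down")

  expect_equal(cls$sex_class[3], "sex-independent")
  expect_equal(cls$onset[3], "n/a")

  expect_equal(cls$onset[4], "3wk")
  # opposite-direction early bias is transient, not onset
  expect_equal(cls$onset[5], "8wk")
  expect_equal(cls$transient_bias[5], "F-at-3wk")
  expect_equal(cls$dev_male[5], "mixed")
  expect_equal(cls$transient_bias[6], "M-at-4wk")
  expect_equal(cls$dev_female[6], "down")
})

test_that("classification is a partition and invariant to probe order", {
  set.seed(11)
  flags <- matrix(sample(0:2, 700, replace = TRUE), ncol = 7)
  cls <- classifyGenes(flags)
  expect_true(all(cls$sex_class %in%
                  c("male-specific", "female-specific", "sex-independent")))
  expect_equal(sum(table(cls$sex_class)), nrow(flags))
  expect_true(all((cls$onset == "n/a") == (cls$sex_class == "sex-independent")))
  perm <- sample(nrow(flags))
  expect_equal(classifyGenes(flags[perm, ]), cls[perm, ],
               ignore_attr = TRUE)
})

test_that("stringent sex-independent call enforces all three bounds", {
  th <- tfsThresholds()
  expect_true(stringentSexIndependent(1.05, 0.5, 100, th))
  expect_false(stringentSexIndependent(1.05, 0.5, 10, th))   # dim signal
  expect_false(stringentSexIndependent(1.3, 0.5, 100, th))   # too much bias
  expect_false(stringentSexIndependent(1 / 1.3, 0.5, 100, th))
  expect_false(stringentSexIndependent(1.05, 0.005, 100, th))
  expect_true(stringentSexIndependent(1.2, 0.5, 25, th) == FALSE) # strict <
})

test_that("count summaries on a noiseless simulation equal the truth", {
  res <- runPipeline(demoConfig(n_probes = 700, seed = 13, noiseless = TRUE),
                     withr::local_tempdir(), quiet = TRUE)
  tr <- simTruth(res$sim)
  s <- summarizeCounts(res$master)
  truth_onset <- table(factor(tr$true_class,
                              c("male-specific", "female-specific",
                                "sex-independent")),
                       factor(ifelse(tr$onset_age == "none", "n/a",
                                     tr$onset_age),
                              c("3wk", "4wk", "8wk", "n/a")))
  got <- as.matrix(s$onset_table[, c("onset_3wk", "onset_4wk", "onset_8wk",
                                     "no_sex_specificity")])
  expect_equal(unname(got), unname(unclass(truth_onset)))
  expect_equal(sum(s$onset_table$total), nrow(res$master))
  # change-pattern counts partition the gene set
  expect_equal(sum(s$change_pattern$count), nrow(res$master))
  # dev counts match realized truth calls
  truth_up_m <- sum(tr$dev_change_male == "up")
  got_up_m <- sum(res$master$dev_male == "up")
  expect_equal(got_up_m, truth_up_m)
})

test_that("candidate regulator filter applies descriptor and fold rules", {
  master <- data.frame(
    gene_id = c("tf1", "tf2", "kin1", "tf3", "tf4"),
    sex_class = c("sex-independent", "male-specific", "sex-independent",
                  "male-specific", "sex-independent"),
    intensity_8wk = c(50, 50, 50, 50, 10),
    log2_M3vF3 = 0, log2_M4vF4 = 0,
    log2_M8vF8 = c(0, log2(2.5), 0, log2(1.8), 0),
    log2_M3vM8 = c(log2(3), log2(2.5), log2(3), log2(3), log2(3)),
    log2_M4vM8 = 0, log2_F3vF8 = 0, log2_F4vF8 = 0,
    p_M3vF3 = 1, p_M4vF4 = 1,
    p_M8vF8 = c(1, 1e-6, 1, 1e-6, 1),
    p_M3vM8 = 1e-6, p_M4vM8 = 1, p_F3vF8 = 1, p_F4vF8 = 1,
    stringsAsFactors = FALSE)
  ann <- data.frame(
    gene_id = c("tf1", "tf2", "kin1", "tf3", "tf4"),
    descriptor = c("sequence-specific DNA binding",
                   "regulation of transcription", "kinase activity",
                   "DNA binding", "transcription factor activity"),
    stringsAsFactors = FALSE)
  got <- filterCandidateRegulators(master, ann)
  expect_setequal(got$gene_id, c("tf1", "tf2"))
  # kin1 excluded on descriptor, tf3 on 8wk sex ratio < 2, tf4 on intensity
})

test_that("false positives under a pure null match the p-cut arithmetic", {
  n <- 8000
  tr <- nullTruth(n, seed = 14)
  des <- experimentDesign(n_probes = n, n_redundant_genes = 0, seed = 14)
  sim <- simulateArrays(tr, des,
                        noiseParams(sigma_add = 0, sigma_mult = 0.1,
                                    dye_bias_amplitude = 0,
                                    frac_low_expressed = 0))
  cs <- summarizeComparisons(sim, lowess = FALSE)
  th <- tfsThresholds()
  nsig <- colSums(pValues(cs) < th$p_cut, na.rm = TRUE)
  expected <- th$p_cut * n      # 0.8 per comparison
  expect_true(all(abs(nsig - expected) <= 3 * sqrt(expected) + 1))
})
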
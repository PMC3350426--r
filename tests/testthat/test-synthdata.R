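test_that("truth generation is deterministic and honors degenerate proportions", {
  t1 <- generateTruth(100, class_proportions = c("male-specific" = 0,
                                                 "female-specific" = 0,
                                                 "sex-independent" = 1),
                      seed = 1)
  expect_equal(nrow(t1), 100)
  expect_true(all(t1$true_class == "sex-independent"))
  expect_true(all(t1$onset_age == "none"))

  t2 <- generateTruth(200, seed = 42)
  t3 <- generateTruth(200, seed = 42)
  expect_identical(t2, t3)
  expect_false(identical(t2, generateTruth(200, seed = 43)))

  expect_error(generateTruth(10, class_proportions = c("male-specific" = 0.5,
                                                       "female-specific" = 0.5,
                                                       "sex-independent" = 0.5)),
               "configuration error")
  expect_error(generateTruth(10, effect_fold_range = c(0.5, 2)),
               "configuration error")
})

test_that("class counts follow the multinomial proportions", {
  tr <- generateTruth(1000, class_proportions = c("male-specific" = 0.1,
                                                  "female-specific" = 0.1,
                                                  "sex-independent" = 0.8),
                      seed = 7)
  cnt <- table(tr$true_class)
  # binomial SD ~ 9.5 for the 10% classes, ~12.6 for the 80% class
  expect_lt(abs(cnt[["male-specific"]] - 100), 3 * sqrt(1000 * .1 * .9))
  expect_lt(abs(cnt[["female-specific"]] - 100), 3 * sqrt(1000 * .1 * .9))
  expect_lt(abs(cnt[["sex-independent"]] - 800), 3 * sqrt(1000 * .8 * .2))
  # invariants: onset iff sex-specific; effect folds >= 1
  expect_true(all((tr$onset_age == "none") ==
                  (tr$true_class == "sex-independent")))
  expect_true(all(tr$effect_fold >= 1))
})

test_that("expression matrix realizes class, onset and trajectories exactly", {
  tr <- rbind(
    truthRow("a", "male-specific", "8wk", effect_fold = 2,
             dev_fold_female = 1),
    truthRow("b", "sex-independent", dev_fold_male = 1/3),  # down, fold 3
    truthRow("c", "sex-independent"),
    truthRow("d", "male-specific", "4wk", effect_fold = 3,
             dev_fold_female = 1))
  em <- expressionMatrix(tr)
  # male-specific onset 8wk, effect 2
  expect_equal(em["a", "M8"] / em["a", "F8"], 2)
  expect_equal(em["a", "M3"] / em["a", "F3"], 1)
  expect_equal(em["a", "M4"] / em["a", "F4"], 1)
  # developmental down in male, fold 3: M3/M8 = 3
  expect_equal(em["b", "M3"] / em["b", "M8"], 3)
  # fully null: all six cells equal
  expect_true(all(em["c", ] == em["c", 1]))
  # onset 4wk: biased at 4 and 8 wk only
  expect_equal(em["d", "M4"] / em["d", "F4"], 3)
  expect_equal(em["d", "M8"] / em["d", "F8"], 3)
  expect_equal(em["d", "M3"] / em["d", "F3"], 1)
})

test_that("noiseless arrays carry the true log2 ratio for every probe", {
  tr <- generateTruth(150, seed = 3)
  des <- experimentDesign(n_probes = 160, n_redundant_genes = 10, seed = 3)
  sim <- simulateArrays(tr, des, noiselessNoise())
  em <- expressionMatrix(simTruth(sim))
  man <- arrayManifest(sim)
  for (a in seq_len(nrow(man))) {
    tab <- arrayTables(sim)[[a]]
    want <- log2(em[tab$gene_symbol, man$red_sample[a]] /
                 em[tab$gene_symbol, man$green_sample[a]])
    expect_equal(log2(tab$red_raw / tab$green_raw), unname(want),
                 tolerance = 1e-12)
  }
  # redundant probes share their gene's true level
  dup <- tab$gene_symbol[duplicated(tab$gene_symbol)][1]
  rows <- tab[tab$gene_symbol == dup, ]
  expect_equal(rows$red_raw[1], rows$red_raw[2])
})

test_that("self-self simulation is centered and matches the error closed form", {
  n <- 10000
  tr <- nullTruth(n, seed = 5)
  des <- selfSelfDesign(n, seed = 5)
  sim <- simulateArrays(tr, des,
                        noiseParams(sigma_add = 0, sigma_mult = 0.1,
                                    dye_bias_amplitude = 0,
                                    frac_low_expressed = 0))
  tab <- arrayTables(sim)[[1]]
  M <- log2(tab$red_raw / tab$green_raw)
  sd_theory <- sqrt(2) * 0.1 / log(2)   # ~0.204
  expect_lt(abs(mean(M)), 3 * sd_theory / sqrt(n))
  expect_equal(sd(M), sd_theory, tolerance = 0.03)
})

test_that("dye-swap averaging cancels an injected dye bias", {
  n <- 4000
  tr <- nullTruth(n, seed = 9)
  # one null comparison of two distinct (but identically expressed) samples
  des <- experimentDesign(
    n_probes = n, n_redundant_genes = 0, seed = 9,
    comparisons = defaultComparisons()[1, ])
  sim <- simulateArrays(tr, des,
                        noiseParams(sigma_add = 0, sigma_mult = 0.02,
                                    dye_bias_amplitude = 0.5,
                                    frac_low_expressed = 0))
  tabs <- arrayTables(sim)
  M1 <- log2(tabs[[1]]$red_raw / tabs[[1]]$green_raw)  # red = M3
  M2 <- log2(tabs[[2]]$red_raw / tabs[[2]]$green_raw)  # red = F3 (swapped)
  # each array individually is biased ...
  expect_gt(mean(abs(M1)), 0.1)
  # ... but orienting replicate 2 toward the numerator negates its M, and the
  # channel-symmetric bias term cancels in the average
  expect_lt(abs(mean((M1 + (-M2)) / 2)), 0.02)
})

test_that("simulation is byte-identical under a fixed seed and extensible", {
  tr <- generateTruth(80, seed = 2)
  des <- experimentDesign(n_probes = 84, n_redundant_genes = 4, seed = 2)
  s1 <- simulateArrays(tr, des, noiseParams())
  s2 <- simulateArrays(tr, des, noiseParams())
  expect_identical(arrayTables(s1), arrayTables(s2))
  # per-array sub-seeding: the first arrays do not change when the design
  # grows by extra replicates
  des4 <- experimentDesign(n_probes = 84, n_redundant_genes = 4, seed = 2,
                           replicates_per_comparison = 4)
  s4 <- simulateArrays(tr, des4, noiseParams())
  expect_identical(arrayTables(s1)[[1]],
                   arrayTables(s4)[[which(arrayManifest(s4)$comparison == 1 &
                                          arrayManifest(s4)$replicate == 1)]])
})

test_that("simulation TSVs round-trip through write and read", {
  tr <- generateTruth(40, seed = 4)
  des <- experimentDesign(n_probes = 42, n_redundant_genes = 2, seed = 4)
  sim <- simulateArrays(tr, des, noiseParams())
  d <- withr::local_tempdir()
  writeSimulation(sim, d)
  back <- readProbeTables(d)
  expect_equal(length(back$arrays), nrow(arrayManifest(sim)))
  expect_equal(back$arrays[[1]]$red_raw, arrayTables(sim)[[1]]$red_raw,
               tolerance = 1e-8)
  expect_equal(back$truth$true_class, simTruth(sim)$true_class)
})
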
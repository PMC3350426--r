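# Shared fixture builders; everything is generated in code at test time.

# Hand-built truth rows with full control over every field.
truthRow <- function(gene_id, true_class = "sex-independent",
                     onset_age = "none", effect_fold = 1,
                     dev_fold_male = 1, dev_fold_female = 1,
                     base_level = 1000) {
  data.frame(gene_id = gene_id, true_class = true_class,
             onset_age = onset_age, effect_fold = effect_fold,
             dev_fold_male = dev_fold_male, dev_fold_female = dev_fold_female,
             base_level = base_level, low_expressed = FALSE,
             dev_change_male = NA_character_, dev_change_female = NA_character_,
             stringsAsFactors = FALSE)
}

# All-null truth: every gene sex-independent, no developmental change.
nullTruth <- function(n_genes, seed = 1) {
  generateTruth(n_genes,
                class_proportions = c("male-specific" = 0, "female-specific" = 0,
                                      "sex-independent" = 1),
                dev_change_prob = c(none = 1, up = 0, down = 0),
                seed = seed)
}

noiselessNoise <- function(...) {
  args <- utils::modifyList(
    list(sigma_add = 0, sigma_mult = 0, dye_bias_amplitude = 0,
         background_mean = 20, background_sd = 0, frac_low_expressed = 0),
    list(...))
  do.call(noiseParams, args)
}

# One-comparison self-self design (both channels carry the same sample).
selfSelfDesign <- function(n_probes, seed = 1) {
  experimentDesign(
    n_probes = n_probes, n_redundant_genes = 0,
    replicates_per_comparison = 2, seed = seed,
    comparisons = data.frame(id = 1L, label = "M3vM3",
                             sampleA = "M3", sampleB = "M3",
                             numerator = "M3", denominator = "M3",
                             stringsAsFactors = FALSE))
}

# Brute-force two-tail Fisher p by direct summation (oracle for N <= 200).
bruteFisherTwoTail <- function(k, n, K, N) {
  pt <- function(j) choose(K, j) * choose(N - K, n - j) / choose(N, n)
  jmin <- max(0, n + K - N); jmax <- min(n, K)
  probs <- vapply(jmin:jmax, pt, numeric(1))
  obs <- pt(k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
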
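#' Significance thresholds for flagging and classification
#'
#' Defaults follow the study design: differential expression requires
#' |fold| > 1.5 with p < 1e-4 on a well-above-background probe; the stringent
#' sex-independent definition requires sex ratio < 1.2, p > 0.01 and signal
#' intensity >= 25; candidate transcriptional regulators need > 2-fold
#' changes (and > 2-fold sex bias if sex-specific).
#'
#' @param fold_cut,p_cut differential-expression filters (linear fold, p).
#' @param stringent_fold,stringent_p stringent sex-independent bounds.
#' @param min_intensity minimum linear signal intensity.
#' @param regulator_fold,regulator_sex_fold regulator-candidate fold filters.
#' @return a list with class \code{"tfs_thresholds"}.
#' @export
tfsThresholds <- function(fold_cut = 1.5, p_cut = 1e-4,
                          stringent_fold = 1.2, stringent_p = 0.01,
                          min_intensity = 25,
                          regulator_fold = 2, regulator_sex_fold = 2) {
  if (fold_cut <= 1 || p_cut <= 0 || p_cut >= 1 ||
      stringent_fold >= fold_cut || stringent_p <= p_cut)
    stop("configuration error: inconsistent thresholds")
  structure(list(fold_cut = fold_cut, p_cut = p_cut,
                 stringent_fold = stringent_fold, stringent_p = stringent_p,
                 min_intensity = min_intensity, regulator_fold = regulator_fold,
                 regulator_sex_fold = regulator_sex_fold),
            class = "tfs_thresholds")
}

#' Ternary regulation flag for one comparison
#'
#' 1 = up-regulated (linear ratio > fold_cut, p < p_cut, well above
#' background); 2 = down-regulated (ratio < 1/fold_cut, same conditions);
#' 0 otherwise. Comparisons at the threshold exactly are not flagged (strict
#' inequalities).
#'
#' @param ratio linear expression ratio(s).
#' @param p_value p-value(s).
#' @param wab logical well-above-background flag(s).
#' @param th thresholds from [tfsThresholds()].
#' @return integer flag(s) in \{0, 1, 2\}.
#' @export
flagComparison <- function(ratio, p_value, wab, th = tfsThresholds()) {
  f <- integer(length(ratio))
  sig <- !is.na(ratio) & !is.na(p_value) & p_value < th$p_cut & wab
  f[sig & ratio > th$fold_cut] <- 1L
  f[sig & ratio < 1 / th$fold_cut] <- 2L
  f
}

#' Flag matrix for all comparisons of a ComparisonSet
#'
#' @param cs a \linkS4class{ComparisonSet} (ratios are log2; they are
#'   exponentiated before applying the linear fold filter).
#' @param th thresholds.
#' @return integer matrix, probes x comparisons, values in \{0, 1, 2\}.
#' @export
flagMatrix <- function(cs, th = tfsThresholds()) {
  r <- 2^ratios(cs)
  p <- pValues(cs)
  w <- wabFlags(cs)
  out <- matrix(0L, nrow(r), ncol(r), dimnames = dimnames(r))
  for (i in seq_len(ncol(r)))
    out[, i] <- flagComparison(r[, i], p[, i], w[, i], th)
  out
}

.TFS_WEIGHTS <- as.integer(2^(0:6))

#' Whole-number portion of a TFS code
#'
#' Sum of the binary weights 1, 2, 4, 8, 16, 32, 64 over the comparisons
#' (positions 1-7) whose flag is nonzero.
#'
#' @param flags integer vector of length 7 over \{0,1,2\}, or an n x 7 matrix.
#' @return integer in [0, 127] (vector for matrix input).
#' @export
tfsWhole <- function(flags) {
  if (is.matrix(flags)) as.integer((flags != 0) %*% .TFS_WEIGHTS)
  else as.integer(sum(.TFS_WEIGHTS[flags != 0]))
}

#' Encode seven comparison flags as a TFS decimal string
#'
#' Renders "W.f1f2f3f4f5f6f7": the whole number is the binary-weighted sum of
#' flagged positions, the seven digits after the point are the per-comparison
#' flags (0 none, 1 up, 2 down). The flag pattern (0,0,2,2,2,0,0), a gene
#' female-specific at 8 wk and down-regulated with age in male liver, encodes
#' as "28.0022200".
#'
#' @param flags length-7 integer vector over \{0,1,2\}, or an n x 7 matrix.
#' @return character TFS string(s).
#' @export
encodeTFS <- function(flags) {
  if (!is.matrix(flags)) flags <- matrix(flags, nrow = 1)
  if (ncol(flags) != 7 || !all(flags %in% 0:2))
    stop("flags must be 7 values in {0, 1, 2}")
  sprintf("%d.%s", tfsWhole(flags),
          apply(flags, 1, paste, collapse = ""))
}

#' Decode a TFS decimal string back to flags
#'
#' @param tfs character TFS string(s) like "28.0022200".
#' @return integer vector of length 7 (or n x 7 matrix for several strings).
#' @export
decodeTFS <- function(tfs) {
  m <- regmatches(tfs, regexec("^([0-9]+)\\.([012]{7})$", tfs))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) stop("parse error: malformed TFS string: ",
                     paste(tfs[bad], collapse = ", "))
  flags <- t(vapply(m, function(x)
    as.integer(strsplit(x[3], "")[[1]]), integer(7)))
  whole <- vapply(m, function(x) as.integer(x[2]), integer(1))
  if (any(whole != tfsWhole(flags)))
    stop("parse error: whole number inconsistent with flag digits")
  if (length(tfs) == 1) flags[1, ] else flags
}

#' Drop redundant probes of the same gene and regulation pattern
#'
#' Probes sharing a gene symbol and an identical TFS pattern are redundant:
#' within each (gene, TFS) group only the probe with the lowest set of
#' p-values survives, operationalized as the minimal sum of log10 p over the
#' flagged comparisons (ties broken by the lexicographically smallest probe
#' id). Probes of the same gene with different TFS patterns are all retained.
#'
#' @param flags integer matrix, probes x 7.
#' @param pvals numeric matrix, probes x 7.
#' @param gene_symbol,probe_id per-probe identifiers.
#' @return logical keep vector over probes.
#' @export
removeRedundantProbes <- function(flags, pvals, gene_symbol, probe_id) {
  key <- paste(tolower(gene_symbol), apply(flags, 1, paste, collapse = ""),
               sep = "|")
  score <- vapply(seq_len(nrow(flags)), function(i) {
    on <- flags[i, ] != 0
    if (!any(on)) 0 else sum(log10(pmax(pvals[i, on], 1e-300)))
  }, numeric(1))
  ord <- order(key, score, probe_id)
  keep <- logical(length(key))
  keep[ord[!duplicated(key[ord])]] <- TRUE
  keep
}

#' Classify genes from their seven-comparison flags
#'
#' Sex specificity is defined at 8 wk (comparison 3): flag 1 is male-specific,
#' 2 female-specific, 0 sex-independent. Onset is the earliest of the three
#' sex comparisons whose flag is nonzero and agrees in direction with the
#' 8 wk flag. Early sex bias that disagrees with (or lacks) an 8 wk call is
#' recorded separately as transient bias. Developmental change in male liver
#' comes from comparisons 4 and 5 (8 wk over 3 or 4 wk): any flag 1 means up,
#' any flag 2 down, both directions "mixed"; female liver likewise from
#' comparisons 6 and 7.
#'
#' @param flags integer matrix, genes x 7.
#' @return data.frame with sex_class, onset, transient_bias, dev_male,
#'   dev_female and the four per-interval calls.
#' @export
classifyGenes <- function(flags) {
  stopifnot(ncol(flags) == 7)
  f3 <- flags[, 3]
  sex_class <- c("sex-independent", "male-specific", "female-specific")[f3 + 1L]

  onset <- rep("n/a", nrow(flags))
  for (j in 3:1) {
    lab <- c("3wk", "4wk", "8wk")[j]
    hit <- f3 != 0 & flags[, j] == f3
    onset[hit] <- lab
  }

  transient <- rep("none", nrow(flags))
  for (j in 2:1) {
    fj <- flags[, j]
    mism <- fj != 0 & fj != f3
    age <- c("3wk", "4wk")[j]
    transient[mism & fj == 1] <- paste0("M-at-", age)
    transient[mism & fj == 2] <- paste0("F-at-", age)
  }

  devOne <- function(f) c("none", "up", "down")[f + 1L]
  comb <- function(a, b) .combineIntervalCalls(devOne(a), devOne(b))
  data.frame(
    sex_class = sex_class, onset = onset, transient_bias = transient,
    dev_male = comb(flags[, 4], flags[, 5]),
    dev_female = comb(flags[, 6], flags[, 7]),
    dev_male_38 = devOne(flags[, 4]), dev_male_48 = devOne(flags[, 5]),
    dev_female_38 = devOne(flags[, 6]), dev_female_48 = devOne(flags[, 7]),
    stringsAsFactors = FALSE)
}

#' Stringent sex-independent call at 8 wk
#'
#' TRUE iff the 8 wk male:female ratio is below the stringent fold bound in
#' both directions, the p-value exceeds the stringent cut, and signal
#' intensity meets the minimum — a conservative background definition that
#' excludes weakly sex-biased and dim genes.
#'
#' @param ratio linear 8 wk male/female expression ratio(s).
#' @param p_value 8 wk p-value(s).
#' @param intensity linear signal intensity.
#' @param th thresholds.
#' @return logical vector.
#' @export
stringentSexIndependent <- function(ratio, p_value, intensity,
                                    th = tfsThresholds()) {
  !is.na(ratio) & !is.na(p_value) &
    pmax(ratio, 1 / ratio) < th$stringent_fold &
    p_value > th$stringent_p & intensity >= th$min_intensity
}

#' Master per-gene classification table
#'
#' Runs the full flag -> TFS -> redundant-probe-removal -> classification
#' chain on a \linkS4class{ComparisonSet} and returns one row per retained
#' probe (a gene appears more than once only if distinct probes show distinct
#' TFS patterns). Includes the stringent sex-independent call and the log2
#' ratios, p-values and intensities that downstream stages need.
#'
#' @param cs a \linkS4class{ComparisonSet}.
#' @param th thresholds.
#' @return data.frame.
#' @export
masterTable <- function(cs, th = tfsThresholds()) {
  flags <- flagMatrix(cs, th)
  pv <- pValues(cs)
  rd <- rowData(cs)
  keep <- removeRedundantProbes(flags, pv, rd$gene_symbol, rd$probe_id)

  flags <- flags[keep, , drop = FALSE]
  cls <- classifyGenes(flags)
  r8 <- 2^ratios(cs)[keep, 3]
  p8 <- pv[keep, 3]
  i8 <- intensities(cs)[keep, 3]
  stringent <- cls$sex_class == "sex-independent" &
    stringentSexIndependent(r8, p8, i8, th)

  out <- data.frame(
    gene_id = rd$gene_symbol[keep], probe_id = rd$probe_id[keep],
    tfs = encodeTFS(flags), tfs_whole = tfsWhole(flags),
    cls, stringent_SI = stringent, intensity_8wk = i8,
    mean_intensity = rowMeans(intensities(cs)[keep, , drop = FALSE],
                              na.rm = TRUE),
    stringsAsFactors = FALSE)
  lr <- ratios(cs)[keep, , drop = FALSE]
  colnames(lr) <- paste0("log2_", colnames(lr))
  pvk <- pv[keep, , drop = FALSE]
  colnames(pvk) <- paste0("p_", colnames(pValues(cs)))
  cbind(out, as.data.frame(lr), as.data.frame(pvk))
}

#' Count summaries of a classification table
#'
#' Emits (a) gene counts by sex class and onset age, with both 3 wk counting
#' conventions (any same-direction 3 wk bias vs bias retained at 4 and 8 wk)
#' and transient early-bias counts for sex-independent genes; (b) up / down /
#' no-change / mixed counts per sex class for the 3-to-8 wk and 4-to-8 wk
#' intervals in each sex; (c) genes changing in male liver only, female liver
#' only, both, or neither.
#'
#' @param master data.frame from [masterTable()] (or any table with the
#'   classification columns).
#' @return list of data.frames: \code{onset_table}, \code{onset_conventions},
#'   \code{transient_table}, \code{dev_table}, \code{change_pattern}.
#' @export
summarizeCounts <- function(master) {
  classes <- c("male-specific", "female-specific", "sex-independent")
  sc <- factor(master$sex_class, classes)

  onset_table <- as.data.frame.matrix(table(
    sc, factor(master$onset, c("3wk", "4wk", "8wk", "n/a"))))
  names(onset_table) <- c("onset_3wk", "onset_4wk", "onset_8wk",
                          "no_sex_specificity")
  onset_table <- cbind(sex_class = rownames(onset_table), onset_table,
                       total = as.integer(table(sc)))
  rownames(onset_table) <- NULL

  spec <- master$sex_class != "sex-independent"
  fl <- decodeTFS(master$tfs)
  if (!is.matrix(fl)) fl <- matrix(fl, nrow = 1)
  retained3 <- spec & fl[, 1] == fl[, 3] & fl[, 2] == fl[, 3]
  onset_conventions <- data.frame(
    convention = c("any_3wk_same_direction", "retained_at_4_and_8wk"),
    count = c(sum(spec & master$onset == "3wk"), sum(retained3)))

  transient_table <- as.data.frame(table(
    sex_class = sc,
    transient = factor(master$transient_bias,
                       c("M-at-3wk", "F-at-3wk", "M-at-4wk", "F-at-4wk",
                         "none"))), responseName = "count")

  lv <- c("up", "down", "none", "mixed")
  devLong <- function(col, sex_liver, interval) {
    d <- as.data.frame(table(sex_class = sc, call = factor(master[[col]], lv)),
                       responseName = "count")
    cbind(liver = sex_liver, interval = interval, d)
  }
  dev_table <- rbind(
    devLong("dev_male_38", "male", "3to8"),
    devLong("dev_male_48", "male", "4to8"),
    devLong("dev_female_38", "female", "3to8"),
    devLong("dev_female_48", "female", "4to8"))

  chM <- master$dev_male != "none"
  chF <- master$dev_female != "none"
  change_pattern <- data.frame(
    pattern = c("male_only", "female_only", "both", "neither"),
    count = c(sum(chM & !chF), sum(!chM & chF), sum(chM & chF),
              sum(!chM & !chF)))

  list(onset_table = onset_table, onset_conventions = onset_conventions,
       transient_table = transient_table, dev_table = dev_table,
       change_pattern = change_pattern)
}

#' Candidate transcriptional regulators
#'
#' Filters a classified gene table to genes whose annotation descriptor
#' contains "DNA binding" or "transcription" (case-insensitive), with 8 wk
#' signal intensity at or above the minimum, an absolute linear fold change
#' beyond the regulator threshold on every comparison where the gene's
#' p-value is significant, and — for sex-specific genes — an 8 wk sex ratio
#' beyond the sex-fold threshold in the biased direction.
#'
#' @param master data.frame from [masterTable()].
#' @param annotations data.frame with columns \code{gene_id} and
#'   \code{descriptor}.
#' @param th thresholds.
#' @return the retained subset of \code{master}, with descriptors attached.
#' @export
filterCandidateRegulators <- function(master, annotations,
                                      th = tfsThresholds()) {
  ann <- annotations[grepl("DNA binding|transcription", annotations$descriptor,
                           ignore.case = TRUE), , drop = FALSE]
  m <- merge(master, ann, by = "gene_id")
  if (nrow(m) == 0) return(m)

  rat <- as.matrix(m[, grep("^log2_", names(master)), drop = FALSE])
  pv <- as.matrix(m[, grep("^p_", names(master)), drop = FALSE])
  foldOK <- vapply(seq_len(nrow(m)), function(i) {
    sig <- !is.na(pv[i, ]) & pv[i, ] < th$p_cut
    all(abs(rat[i, sig]) > log2(th$regulator_fold))
  }, logical(1))

  sexOK <- m$sex_class == "sex-independent" |
    abs(rat[, 3]) > log2(th$regulator_sex_fold)
  m[m$intensity_8wk >= th$min_intensity & foldOK & sexOK, , drop = FALSE]
}

#' Chance-positive and false-discovery arithmetic
#'
#' Number of probes expected to pass a p-value filter by chance
#' (\code{p_cut * n_probes}, reported rounded as in standard practice) and the
#' implied false-discovery rate against an observed significant count.
#'
#' @param p_cut p-value threshold.
#' @param n_probes probes tested.
#' @param n_significant observed count passing the filter (optional).
#' @return list with \code{expected}, \code{expected_rounded} and, when
#'   \code{n_significant} is given, \code{fdr_percent} (rounded expected /
#'   observed, as a percentage).
#' @export
expectedFalsePositives <- function(p_cut, n_probes, n_significant = NULL) {
  e <- p_cut * n_probes
  out <- list(expected = e, expected_rounded = round(e))
  if (!is.null(n_significant))
    out$fdr_percent <- 100 * round(e) / n_significant
  out
}
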
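#' Harmonized background for cross-study gene-set comparison
#'
#' Gene sets from different array platforms are only comparable on the genes
#' both platforms measure. \code{"all-common"} returns the case-normalized
#' symbol intersection; \code{"stringent-SI"} restricts that intersection to
#' the stringent sex-independent genes (the conservative background used when
#' scoring sex-independent developmental sets).
#'
#' @param platform_a,platform_b character vectors of gene symbols.
#' @param mode background rule.
#' @param stringent_genes symbols flagged stringent sex-independent (required
#'   for \code{"stringent-SI"}).
#' @return character vector of lower-cased symbols.
#' @export
harmonizeBackground <- function(platform_a, platform_b,
                                mode = c("all-common", "stringent-SI"),
                                stringent_genes = NULL) {
  mode <- match.arg(mode)
  bg <- intersect(unique(tolower(platform_a)), unique(tolower(platform_b)))
  if (mode == "stringent-SI") {
    if (is.null(stringent_genes))
      stop("configuration error: stringent_genes required for stringent-SI mode")
    bg <- intersect(bg, unique(tolower(stringent_genes)))
  }
  if (length(bg) == 0)
    stop("configuration error: empty background intersection")
  sort(bg)
}

#' Fold enrichment of a gene-set overlap
#'
#' Observed overlap divided by the overlap expected under independence:
#' \code{k * N / (n * K)} for an overlap of \code{k} between sets of sizes
#' \code{n} and \code{K} drawn from a background of \code{N}. Values below 1
#' indicate depletion.
#'
#' @param k overlap count.
#' @param n,K set sizes.
#' @param N background size.
#' @return dimensionless ratio.
#' @export
foldEnrichment <- function(k, n, K, N) {
  if (any(n * K == 0)) stop("undefined: a set is empty")
  if (any(k > pmin(n, K)) || any(k < 0) || any(n > N) || any(K > N))
    stop("invalid counts: need 0 <= k <= min(n, K) and n, K <= N")
  k * N / (n * K)
}

#' Exact two-tail Fisher p-value of a 2x2 overlap table
#'
#' Tests the table \code{[[k, n-k], [K-k, N-n-K+k]]} with the standard exact
#' two-sided rule: the sum of hypergeometric point probabilities not
#' exceeding that of the observed table. Point probabilities are evaluated in
#' log space, so extreme tails (p well below 1e-100) are computed without
#' underflow.
#'
#' @inheritParams foldEnrichment
#' @return p-value.
#' @export
fisherTwoTail <- function(k, n, K, N) {
  if (N - n - K + k < 0 || k > min(n, K) || k < 0)
    stop("invalid table: a cell would be negative")
  jmin <- max(0, n + K - N)
  jmax <- min(n, K)
  lp <- stats::dhyper(jmin:jmax, K, N - K, n, log = TRUE)
  lobs <- stats::dhyper(k, K, N - K, n, log = TRUE)
  sel <- lp <= lobs + 1e-7          # same relative tolerance as fisher.test
  mx <- max(lp[sel])
  min(1, exp(mx) * sum(exp(lp[sel] - mx)))
}

#' All pairwise enrichment results between two families of gene sets
#'
#' Cross-tabulates developmental gene sets against external regulation sets
#' on a common background, reporting the 2x2 counts, fold enrichment, exact
#' two-tail Fisher p, direction and a significance flag. Set membership is
#' matched case-insensitively and clipped to the background.
#'
#' @param dev_sets named list of character vectors (e.g. genes up-regulated
#'   in male liver from 3 to 8 wk).
#' @param external_sets named list of character vectors (e.g. genes
#'   down-regulated in a regulator-deficient liver).
#' @param background character vector of background symbols.
#' @param p_cut significance threshold on the Fisher p; default 1e-4.
#' @return data.frame, one row per (dev set, external set) pair.
#' @export
enrichmentMatrix <- function(dev_sets, external_sets, background,
                             p_cut = 1e-4) {
  bg <- unique(tolower(background))
  N <- length(bg)
  clip <- function(s) intersect(unique(tolower(s)), bg)
  dev_sets <- lapply(dev_sets, clip)
  external_sets <- lapply(external_sets, clip)

  grid <- expand.grid(set_A = names(dev_sets), set_B = names(external_sets),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    a <- dev_sets[[grid$set_A[i]]]
    b <- external_sets[[grid$set_B[i]]]
    k <- length(intersect(a, b))
    n <- length(a); K <- length(b)
    fold <- if (n * K > 0) foldEnrichment(k, n, K, N) else NA_real_
    p <- if (n * K > 0) fisherTwoTail(k, n, K, N) else NA_real_
    data.frame(set_A = grid$set_A[i], set_B = grid$set_B[i],
               k = k, n = n, K = K, N = N, fold_enrichment = fold,
               p_value = p,
               direction = ifelse(is.na(fold) | fold >= 1,
                                  "enriched", "depleted"),
               significant = !is.na(p) & p < p_cut,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
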
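#' Enumerate candidate model profiles
#'
#' All integer trajectories of length \code{T} that start at 0 and change by
#' at most \code{c} units between consecutive points, excluding the constant
#' zero trajectory; there are \code{(2c+1)^(T-1) - 1} of them. Enumeration
#' order is deterministic (first step varies fastest) and is used for
#' tie-breaking downstream.
#'
#' @param T series length (>= 2); the seven comparisons form an ordered
#'   pseudo-series.
#' @param c maximum unit change between adjacent points (the study used 2).
#' @return integer matrix, candidates x T.
#' @export
enumerateCandidateProfiles <- function(T = 7, c = 2) {
  stopifnot(T >= 2, c >= 1)
  steps <- as.matrix(do.call(expand.grid, rep(list(-c:c), T - 1)))
  vals <- if (T == 2) cbind(0L, steps) else cbind(0L, t(apply(steps, 1, cumsum)))
  vals <- vals[rowSums(vals != 0) > 0, , drop = FALSE]
  dimnames(vals) <- list(NULL, paste0("t", seq_len(T)))
  vals
}

# Pearson distance (1 - r) of each row of Z (standardized) to vector z.
.distTo <- function(Z, z, Tn) 1 - as.vector(Z %*% z) / (Tn - 1)

#' Greedy max-min selection of model profiles
#'
#' Picks \code{m} profiles from the candidates so that the selected set is
#' mutually distinctive: the first pick is the candidate with the largest
#' summed distance to all candidates, and each later pick maximizes its
#' minimum distance to the profiles already selected (a greedy approximation
#' to the max-min dispersion problem). Distance is 1 - Pearson correlation;
#' ties break by enumeration order. Fully deterministic.
#'
#' @param candidates integer matrix from [enumerateCandidateProfiles()].
#' @param m number of profiles to select (<= number of candidates; the study
#'   used 30 or 50).
#' @param seed accepted for interface symmetry; the selection is
#'   deterministic and does not consume randomness.
#' @return list with \code{profiles} (m x T matrix), \code{ids} (row indices
#'   into the candidate matrix).
#' @export
selectModelProfiles <- function(candidates, m, seed = NULL) {
  n <- nrow(candidates)
  stopifnot(m >= 1, m <= n)
  Tn <- ncol(candidates)
  Z <- rowStandardize(candidates)

  # summed distance to all candidates: n - z_i . colSums(Z) / (T-1)
  sumd <- n - as.vector(Z %*% colSums(Z)) / (Tn - 1)
  sel <- integer(m)
  sel[1] <- which.max(sumd)
  if (m > 1) {
    mind <- .distTo(Z, Z[sel[1], ], Tn)
    mind[sel[1]] <- -Inf
    for (i in 2:m) {
      sel[i] <- which.max(mind)
      mind <- pmin(mind, .distTo(Z, Z[sel[i], ], Tn))
      mind[sel[i]] <- -Inf
    }
  }
  list(profiles = candidates[sel, , drop = FALSE], ids = sel)
}

#' Assign gene ratio vectors to model profiles
#'
#' Each gene's log2-ratio vector goes to the profile minimizing
#' 1 - Pearson correlation (ties to the lowest profile id). Zero-variance
#' gene vectors cannot be correlated; they land in a dedicated flat bucket
#' (profile_id NA) and are excluded from significance testing.
#'
#' @param X numeric matrix, genes x T, of log2 ratios; rownames are gene ids.
#' @param profiles matrix of selected model profiles (m x T).
#' @return data.frame with gene_id, profile_id, distance.
#' @export
assignProfiles <- function(X, profiles) {
  stopifnot(ncol(X) == ncol(profiles), !anyNA(X))
  Tn <- ncol(X)
  flat <- apply(X, 1, function(r) stats::sd(r) == 0)
  Zg <- rowStandardize(X)
  Zp <- rowStandardize(profiles)
  C <- Zg %*% t(Zp) / (Tn - 1)
  best <- max.col(C, ties.method = "first")
  d <- 1 - C[cbind(seq_len(nrow(X)), best)]
  data.frame(gene_id = if (is.null(rownames(X))) seq_len(nrow(X)) else rownames(X),
             profile_id = ifelse(flat, NA_integer_, best),
             distance = ifelse(flat, NA_real_, d),
             stringsAsFactors = FALSE)
}

#' Permutation significance of profile memberships
#'
#' For each of \code{B} permutations every gene's values are independently
#' shuffled (preserving its value multiset — the exchangeable null) and all
#' genes are reassigned; the expected count per profile is the mean over
#' permutations. The observed count is tested against the upper binomial tail
#' P(X >= observed) with X ~ Binomial(n_genes, expected/n_genes), Bonferroni-
#' corrected over the number of profiles. Flat-bucket genes are quarantined
#' first.
#'
#' @param X genes x T log2-ratio matrix (as passed to [assignProfiles()]).
#' @param profiles selected model profiles.
#' @param B number of permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @param alpha familywise significance level before Bonferroni; default 0.05.
#' @return data.frame with profile_id, the profile values, observed_count,
#'   expected_count, p_value, significant.
#' @export
profileSignificance <- function(X, profiles, B = 200, seed = 1, alpha = 0.05) {
  stopifnot(B >= 100)
  flat <- apply(X, 1, function(r) stats::sd(r) == 0)
  X <- X[!flat, , drop = FALSE]
  n <- nrow(X)
  m <- nrow(profiles)
  Tn <- ncol(X)
  Zp <- rowStandardize(profiles)
  Zg <- rowStandardize(X)

  countAssign <- function(Z) {
    C <- Z %*% t(Zp) / (Tn - 1)
    tabulate(max.col(C, ties.method = "first"), nbins = m)
  }
  observed <- countAssign(Zg)

  perm_counts <- withSeed(seed, {
    acc <- matrix(0, B, m)
    for (b in seq_len(B)) {
      # shuffling within a row preserves its mean and sd, so the
      # standardized rows can be permuted directly
      ord <- apply(matrix(stats::runif(n * Tn), n, Tn), 1, order)
      Xb <- matrix(Zg[cbind(rep(seq_len(n), each = Tn), as.vector(ord))],
                   n, Tn, byrow = TRUE)
      acc[b, ] <- countAssign(Xb)
    }
    acc
  })
  expected <- colMeans(perm_counts)
  p <- stats::pbinom(observed - 1, n, pmin(1, expected / n),
                     lower.tail = FALSE)
  data.frame(profile_id = seq_len(m), profiles,
             observed_count = observed, expected_count = expected,
             p_value = p, significant = p < alpha / m)
}

#' Five-number summary of a cluster per comparison
#'
#' Min, lower quartile, median, upper quartile and max of the log2 ratios of
#' the cluster's genes, per comparison (quartiles by linear interpolation) —
#' the numbers behind a box-and-whisker rendering of a profile.
#'
#' @param X genes x T matrix of log2 ratios for one cluster (>= 1 gene).
#' @return data.frame, one row per comparison.
#' @export
profileBoxStats <- function(X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(nrow(X) >= 1)
  q <- apply(X, 2, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1),
             type = 7)
  data.frame(comparison = if (is.null(colnames(X))) seq_len(ncol(X))
             else colnames(X),
             min = q[1, ], q25 = q[2, ], median = q[3, ], q75 = q[4, ],
             max = q[5, ], row.names = NULL)
}

#' Agglomerative clustering by Pearson correlation
#'
#' Average-linkage hierarchical clustering with distance 1 - Pearson
#' correlation, for ordering genes (rows) or arrays (columns) of a log2-ratio
#' matrix. Constant vectors have undefined correlation; their distance to
#' everything is defined as 1. Deterministic leaf order.
#'
#' @param X numeric matrix of log2 ratios.
#' @param axis cluster \code{"genes"} (rows) or \code{"arrays"} (columns).
#' @return list with \code{hclust} (the merge tree), \code{order} (leaf
#'   ordering), \code{labels}.
#' @export
hierarchicalCluster <- function(X, axis = c("genes", "arrays")) {
  axis <- match.arg(axis)
  if (axis == "arrays") X <- t(X)
  stopifnot(nrow(X) >= 2)
  Z <- rowStandardize(X)
  D <- 1 - Z %*% t(Z) / (ncol(X) - 1)
  diag(D) <- 0
  labels <- if (is.null(rownames(X))) as.character(seq_len(nrow(X))) else rownames(X)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  hc$labels <- labels
  list(hclust = hc, order = hc$order, labels = labels[hc$order])
}

#' Export a merge tree as Newick text
#'
#' @param hc an \code{hclust} object (e.g. from [hierarchicalCluster()]).
#' @param file output path.
#' @return invisibly, the file path.
#' @export
exportNewick <- function(hc, file) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the ape package is required for Newick export")
  ape::write.tree(ape::as.phylo(hc), file = file)
  invisible(file)
}
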
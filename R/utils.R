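# Internal helpers shared across modules.

# Run code under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is untouched, so adding calls does not perturb unrelated draws.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Nearest-rank empirical percentile (no interpolation); used by the
# well-above-background rule.
nearestRankQuantile <- function(x, prob) {
  x <- sort(x)
  x[max(1L, ceiling(prob * length(x)))]
}

# Row-standardize a matrix for Pearson-correlation work. Constant rows map to
# the zero vector, so their dot product with anything is 0, i.e. the
# correlation is treated as 0 and 1 - cor distance as 1.
rowStandardize <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowSums(xc^2) / (ncol(x) - 1L))
  z <- xc / ifelse(sd > 0, sd, Inf)
  z[sd == 0, ] <- 0
  z
}

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTSV <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

checkProportions <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("configuration error: ", what, " must be non-negative and sum to 1",
         call. = FALSE)
  invisible(p)
}
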
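# Independent oracles and small builders shared across the suite.

# Brute-force Hyndman-Fan 7 quantile: sort + index arithmetic, written
# independently of the package implementation.
bruteQuantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  f <- floor(h)
  c <- ceiling(h)
  s[f] * (1 - (h - f)) + s[c] * (h - f)
}

# Brute-force Mann-Whitney U for group x: count pairwise wins (+ half ties).
bruteU <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Sum-of-minima overlap similarity: for two percent vectors both summing to
# 100, 100 x (1 - Bray-Curtis) equals the total overlapping abundance.
overlapSimilarity <- function(x, y) {
  keys <- union(names(x), names(y))
  xv <- yv <- setNames(numeric(length(keys)), keys)
  xv[names(x)] <- x
  yv[names(y)] <- y
  sum(pmin(xv, yv))
}

# Random percent composition over taxa named t1..tn (always sums to 100).
randomComposition <- function(n, rank = "species") {
  a <- stats::runif(n)
  Composition(setNames(a, paste0("Taxon sp", seq_len(n))), rank = rank)
}

writeTempTsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
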
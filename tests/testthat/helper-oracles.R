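# Independent oracles used to validate the package's core estimators.

# Knee point by explicit point-to-line distance: normalize both axes, then
# for every rank compute the perpendicular distance to the line through the
# first and last points via the 2x2 determinant (area / base length).
oracle_knee <- function(values) {
  n <- length(values)
  x <- (seq_len(n) - 1) / (n - 1)
  rng <- max(values) - min(values)
  if (rng == 0) return(values[1])
  y <- (values - min(values)) / rng
  x1 <- x[1]; y1 <- y[1]; x2 <- x[n]; y2 <- y[n]
  base <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- abs((x2 - x1) * (y1 - y[i]) - (x1 - x[i]) * (y2 - y1)) / base
  }
  values[which.max(d)]
}

# exact upper-tail hypergeometric by combinatorial enumeration
oracle_hyper_upper <- function(k, K, N, n) {
  js <- max(0, k):min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# r2 as the squared Pearson correlation of the two 0/1 haplotype columns
oracle_r2 <- function(a, b) stats::cor(a, b)^2

# a small, quick synthetic world for unit tests
tiny_config <- function(seed = 1L, ...) {
  args <- list(n_genes = 200L, chrom_length_bp = 2e6, n_gwas_leads = 80L,
               n_haplotypes = 60L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

tiny_world <- function(seed = 1L, ...) generate_world(tiny_config(seed, ...))

# random strictly-descending-sorted test list for knee checks
random_descending <- function(len) {
  sort(round(stats::runif(len, 0, 100), 3), decreasing = TRUE)
}
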
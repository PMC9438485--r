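# Independent oracles and small fixture builders shared across tests.
# Every oracle here deliberately takes a different computational route from
# the package implementation it checks.

# Weir-Cockerham theta via the nested-ANOVA sums-of-squares route
# (populations / individuals within populations / gametes within
# individuals), from genotype counts c(n0, n1, n2) per group.
theta_anova_oracle <- function(cA, cB) {
  r <- 2
  x <- list(rep(c(0, 1, 2), cA), rep(c(0, 1, 2), cB))
  n <- vapply(x, length, numeric(1))
  p <- vapply(x, function(v) sum(v) / (2 * length(v)), numeric(1))
  pbar <- sum(unlist(x)) / (2 * sum(n))
  SSG <- sum(unlist(x) * (2 - unlist(x)) / 2)
  SSI <- sum(mapply(function(v, pi) sum(v^2) / 2 - 2 * length(v) * pi^2, x, p))
  SSP <- sum(mapply(function(v, pi) 2 * length(v) * (pi - pbar)^2, x, p))
  N <- sum(n)
  MSP <- SSP / (r - 1)
  MSI <- SSI / (N - r)
  MSG <- SSG / N
  nc <- (N - sum(n^2) / N) / (r - 1)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  cc <- MSG
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# all genotype-count compositions c(n0, n1, n2) with total in n_min..n_max
genotype_count_tables <- function(n_min, n_max) {
  out <- list()
  for (t in n_min:n_max)
    for (i in 0:t) for (j in 0:(t - i))
      out[[length(out) + 1L]] <- c(i, j, t - i - j)
  do.call(rbind, out)
}

# Average pairwise per-site difference between two groups of explicit
# haplotype sequences (matrices: haplotypes x sites, 0/1 alleles), counted
# over all between-group haplotype pairs and all sites of an L-bp tag.
dxy_enumeration_oracle <- function(hapA, hapB, L) {
  tot <- 0
  for (i in seq_len(nrow(hapA)))
    for (j in seq_len(nrow(hapB)))
      tot <- tot + sum(hapA[i, ] != hapB[j, ])
  tot / (nrow(hapA) * nrow(hapB)) / L
}

# Average pairwise per-site difference among all haplotype pairs within one
# group (the sample-size-corrected pi).
pi_enumeration_oracle <- function(hap, L) {
  n <- nrow(hap)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(hap[i, ] != hap[j, ])
  tot / (n * (n - 1) / 2) / L
}

# pair haplotypes (rows) into diploid dosage genotypes; haplotypes 2k-1, 2k
# form individual k
haplotypes_to_genotypes <- function(hap) {
  n <- nrow(hap) / 2
  out <- matrix(0L, n, ncol(hap))
  for (k in seq_len(n))
    out[k, ] <- as.integer(hap[2 * k - 1, ] + hap[2 * k, ])
  out
}

# small default-condition simulation shared by several test files
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_dataset(
        read_sim_config(system.file("extdata", "sim_config_small.json",
                                    package = "hzclines")))
    cache
  }
})
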
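## Permutation null distributions for F_ST and distribution-level
## comparisons between observed theta vectors.

#' Permutation null distribution of per-SNP F_ST
#'
#' Randomly reassigns the pooled individuals of the two compared groups to
#' pseudo-groups of the original sizes and recomputes Weir-Cockerham theta
#' per marker for each permutation.  The pooled multiset of individuals is
#' conserved; only labels move.
#'
#' @param geno genotype matrix.
#' @param groupA,groupB disjoint sample id vectors (the observed comparison).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param filter a [filter_spec()] applied within each permutation.
#' @param quantiles theta quantiles summarized per permutation.
#' @param keep_thetas keep the full n_perm x n_marker theta matrix.
#' @return object of class `permuted_fst`: list with `quantiles` (one row
#'   per permutation), `sizes`, `n_perm`, `seed`, and optionally `thetas`.
#' @export
permuted_fst <- function(geno, groupA, groupB, n_perm = 1000, seed,
                         filter = filter_spec(),
                         quantiles = c(0.5, 0.9, 0.95, 0.99),
                         keep_thetas = FALSE) {
  if (n_perm < 1L) stop_input("n_perm must be >= 1")
  groupA <- resolve_group(geno, groupA)
  groupB <- resolve_group(geno, groupB)
  if (length(intersect(groupA, groupB)))
    stop_input("groups overlap: ", intersect(groupA, groupB)[1L])
  pooled <- c(groupA, groupB)
  nA <- length(groupA)
  set.seed(as.integer(seed))
  qmat <- matrix(NA_real_, n_perm, length(quantiles),
                 dimnames = list(NULL, paste0("q", quantiles)))
  thetas <- if (keep_thetas)
    matrix(NA_real_, n_perm, ncol(geno),
           dimnames = list(NULL, colnames(geno))) else NULL
  for (i in seq_len(n_perm)) {
    perm <- sample(pooled)
    tab <- fst_per_snp(geno, perm[seq_len(nA)], perm[-seq_len(nA)], filter)
    th <- tab$fst[tab$passed_filters]
    qmat[i, ] <- stats::quantile(th, probs = quantiles, na.rm = TRUE,
                                 names = FALSE)
    if (keep_thetas) thetas[i, ] <- tab$fst
  }
  structure(list(quantiles = as.data.frame(qmat), thetas = thetas,
                 sizes = c(nA = nA, nB = length(groupB)),
                 n_perm = n_perm, seed = as.integer(seed),
                 probs = quantiles),
            class = "permuted_fst")
}

#' @export
print.permuted_fst <- function(x, ...) {
  cat("Permutation F_ST null:", x$n_perm, "permutations, group sizes",
      x$sizes[1L], "vs", x$sizes[2L], "\n")
  print(round(colMeans(x$quantiles), 4))
  invisible(x)
}

#' Compare two observed F_ST distributions (Mann-Whitney)
#'
#' Two-sided unpaired rank-sum test with tie correction on two theta
#' vectors, e.g. a female-vs-female comparison against a male-vs-male one.
#'
#' @param obs_a,obs_b numeric theta vectors (NAs dropped).
#' @return list (statistic, p_value, n_a, n_b, flagged); `flagged` when the
#'   test is undefined (all values tied across both vectors).
#' @export
compare_fst_distributions <- function(obs_a, obs_b) {
  obs_a <- obs_a[!is.na(obs_a)]
  obs_b <- obs_b[!is.na(obs_b)]
  if (!length(obs_a) || !length(obs_b)) stop_input("empty theta vector")
  if (length(unique(c(obs_a, obs_b))) == 1L)
    return(list(statistic = NA_real_, p_value = NA_real_,
                n_a = length(obs_a), n_b = length(obs_b), flagged = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(obs_a, obs_b, exact = FALSE,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(obs_a), n_b = length(obs_b), flagged = is.na(wt$p.value))
}
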
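## Maximum-likelihood hybrid index.
##
## For sample i with genotypes g_l at loci with parental (inland/coastal)
## allele frequencies p_I,l and p_C,l, the allele-copy model is
## q_l(h) = h p_I,l + (1 - h) p_C,l and the likelihood is the product of
## Binomial(2, q_l) genotype probabilities at diploid loci and Bernoulli(q_l)
## at haploid (hemizygous) loci.  h-hat maximizes the log-likelihood over
## [0, 1]; the interval is the profile region within 1.92 log-units of the
## maximum.

#' Parental allele frequencies from pure population classes
#'
#' Estimates p_inland from pure-inland and p_coastal from pure-coastal
#' samples with a +0.5/+1 pseudocount per allele class, which keeps
#' near-diagnostic loci away from 0/1 so that no observed genotype has zero
#' probability.
#'
#' @param geno genotype matrix.
#' @param samples sample table.
#' @param pseudocount added alt-allele pseudo-copies (and twice that to the
#'   denominator); 0 disables smoothing.
#' @return data frame (marker_id, p_inland, p_coastal, n_inland, n_coastal).
#' @export
parental_frequencies <- function(geno, samples, pseudocount = 0.5) {
  est <- function(cls) {
    ids <- sample_group(samples, population_class = cls)
    ids <- intersect(ids, rownames(geno))
    if (!length(ids)) stop_input("no samples in class ", cls)
    g <- geno[ids, , drop = FALSE]
    n <- colSums(!is.na(g))
    alt <- colSums(g, na.rm = TRUE)
    list(p = (alt + pseudocount) / (2 * n + 2 * pseudocount), n = n)
  }
  inland <- est("pure_inland")
  coastal <- est("pure_coastal")
  data.frame(marker_id = colnames(geno),
             p_inland = inland$p, p_coastal = coastal$p,
             n_inland = inland$n, n_coastal = coastal$n,
             row.names = NULL, stringsAsFactors = FALSE)
}

## log-likelihood of h for one sample over its informative loci
## g: genotypes; haploid: logical per locus (TRUE: g in {0,2} read as 0/1 copy)
hindex_loglik <- function(h, g, pI, pC, haploid) {
  q <- h * pI + (1 - h) * pC
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  ll <- numeric(length(g))
  dip <- !haploid
  ll[dip] <- (g[dip] == 0L) * 2 * log(1 - q[dip]) +
    (g[dip] == 1L) * (log(2) + log(q[dip]) + log(1 - q[dip])) +
    (g[dip] == 2L) * 2 * log(q[dip])
  ll[haploid] <- ifelse(g[haploid] == 2L, log(q[haploid]), log(1 - q[haploid]))
  sum(ll)
}

#' Maximum-likelihood hybrid index
#'
#' Estimates, per sample, the proportion of inland ancestry h in [0, 1] by
#' maximizing the allele-copy log-likelihood over the called informative
#' loci (loci whose parental frequencies differ).  Optimization is a
#' 101-point grid bracket followed by golden-section refinement (tolerance
#' 1e-8), which also guards against non-unimodal profiles.  The reported
#' interval is the profile-likelihood region where the log-likelihood is
#' within 1.92 units of its maximum.
#'
#' @param geno genotype matrix.
#' @param pfreq parental frequency table ([parental_frequencies()] or
#'   equivalent with columns marker_id, p_inland, p_coastal).
#' @param ploidy optional named character vector per marker:
#'   `"codominant_diploid"` (default) or `"haploid_female_codominant_male"`
#'   (haploid in females, diploid in males; requires `sex`).
#' @param sex optional named character vector (F/M) per sample.
#' @param markers optional marker subset (e.g. linkage-thinned).
#' @return object of class `hybrid_index`: data frame (sample_id, h,
#'   log_lik, lower, upper, n_loci); samples with no informative called
#'   locus are omitted and listed in attribute `"dropped"`.
#' @export
hybrid_index <- function(geno, pfreq, ploidy = NULL, sex = NULL,
                         markers = NULL) {
  if (!is.null(markers)) geno <- geno[, colnames(geno) %in% markers, drop = FALSE]
  idx <- match(colnames(geno), pfreq$marker_id)
  if (anyNA(idx)) stop_input("parental frequencies missing for some markers")
  pI <- pfreq$p_inland[idx]
  pC <- pfreq$p_coastal[idx]
  ploidy_vec <- rep("codominant_diploid", ncol(geno))
  if (!is.null(ploidy)) {
    hit <- match(colnames(geno), names(ploidy))
    ploidy_vec[!is.na(hit)] <- ploidy[hit[!is.na(hit)]]
    if (any(ploidy_vec == "haploid_female_codominant_male") && is.null(sex))
      stop_input("sex must be given when any marker is female-haploid")
  }
  grid <- seq(0, 1, length.out = 101L)
  res <- vector("list", nrow(geno))
  dropped <- character(0)
  for (i in seq_len(nrow(geno))) {
    g <- geno[i, ]
    female <- !is.null(sex) && sex[[rownames(geno)[i]]] == "F"
    haploid <- ploidy_vec == "haploid_female_codominant_male" & female
    use <- !is.na(g) & pI != pC & !(haploid & g == 1L)
    if (!any(use)) { dropped <- c(dropped, rownames(geno)[i]); next }
    gu <- g[use]; pIu <- pI[use]; pCu <- pC[use]; hap <- haploid[use]
    f <- function(h) hindex_loglik(h, gu, pIu, pCu, hap)
    gl <- vapply(grid, f, numeric(1L))
    k <- which.max(gl)
    lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
    h_hat <- opt$maximum; ll_max <- opt$objective
    ## optimize() never returns an exact endpoint; accept 0/1 when better
    if (f(0) >= ll_max) { h_hat <- 0; ll_max <- f(0) }
    if (f(1) >= ll_max) { h_hat <- 1; ll_max <- f(1) }
    drop_ll <- ll_max - 1.92
    lower <- if (f(0) >= drop_ll) 0 else
      stats::uniroot(function(h) f(h) - drop_ll, c(0, h_hat),
                     tol = 1e-8)$root
    upper <- if (f(1) >= drop_ll) 1 else
      stats::uniroot(function(h) f(h) - drop_ll, c(h_hat, 1),
                     tol = 1e-8)$root
    res[[i]] <- data.frame(sample_id = rownames(geno)[i], h = h_hat,
                           log_lik = ll_max, lower = lower, upper = upper,
                           n_loci = sum(use), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (length(dropped))
    warning(length(dropped), " sample(s) had no informative called locus",
            call. = FALSE)
  structure(out, dropped = dropped,
            class = c("hybrid_index", "data.frame"))
}

#' @export
print.hybrid_index <- function(x, ...) {
  cat("Maximum-likelihood hybrid indices for", nrow(x), "samples\n")
  cat("  h: ", sprintf("median %.3f, range %.3f-%.3f",
                       stats::median(x$h), min(x$h), max(x$h)), "\n")
  NextMethod()
}

#' @export
coef.hybrid_index <- function(object, ...) {
  stats::setNames(object$h, object$sample_id)
}

#' @export
plot.hybrid_index <- function(x, ...) {
  ord <- order(x$h)
  n <- nrow(x)
  plot(seq_len(n), x$h[ord], ylim = c(0, 1), pch = 16, cex = 0.6,
       xlab = "samples (sorted)", ylab = "hybrid index (inland ancestry)",
       ...)
  graphics::segments(seq_len(n), x$lower[ord], seq_len(n), x$upper[ord],
                     col = "grey60")
  graphics::points(seq_len(n), x$h[ord], pch = 16, cex = 0.6)
  invisible(x)
}
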
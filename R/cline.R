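## Genomic clines: the modeled relationship between genotype-class
## probability at a locus and hybrid index h.  A locus whose genotypes track
## h the way neutral admixture predicts shows no likelihood gain over the
## h-free (intercept-only) model beyond chance; a locus under selection in
## the hybrid zone (directional, under- or overdominant) deviates, and the
## deviation is scored against a permutation null that decouples genotype
## from h.
##
## Model: multinomial-logit regression of genotype category on h.
##   diploid:  log(P(k)/P(0)) = b0_k + b1_k h,  k in {het, hom-alt}
##   haploid:  logit P(alt)   = b0 + b1 h
## Fit statistic: 2 (logL_fitted - logL_intercept-only).

COEF_CAP <- 25  # |coefficient| ceiling on the logit scale (separation guard)

## Newton-Raphson fit of the K-category baseline-logit model with a single
## covariate (compiled; see src/mlogit.cpp).  y: integer categories 0..K-1
## (0 = baseline); returns the 2 x (K-1) coefficient matrix, the
## log-likelihood, and a separation flag.
mlogit_fit <- function(y, h, K, cap = COEF_CAP) {
  .mlogit_fit_cpp(as.integer(y), as.numeric(h), as.integer(K), cap)
}

## intercept-only log-likelihood (closed form from category counts)
mlogit_null_loglik <- function(y, K) {
  cnt <- tabulate(y + 1L, nbins = K)
  n <- sum(cnt)
  sum(cnt[cnt > 0] * log(cnt[cnt > 0] / n))
}

## fast path used by the permutation loop: statistic only
cline_stat <- function(y, h, K) {
  .cline_stat_cpp(as.integer(y), as.numeric(h), as.integer(K), COEF_CAP)
}

## translate (genotype, ploidy, sex) into fit blocks; a block is a list
## (y, h, K, label).  Haploid genotypes come in 0/2 dosage coding; an
## (error) heterozygote at a haploid locus cannot be phrased in the haploid
## model and is dropped with a flag.
cline_blocks <- function(genotype, h, ploidy, sex) {
  ok <- !is.na(genotype) & !is.na(h)
  g <- genotype[ok]; hh <- h[ok]
  dropped_het <- 0L
  if (ploidy == "codominant_diploid") {
    blocks <- list(list(y = as.integer(g), h = hh, K = 3L, label = "all"))
  } else if (ploidy == "haploid") {
    keep <- g != 1L
    dropped_het <- sum(!keep)
    blocks <- list(list(y = as.integer(g[keep] == 2L), h = hh[keep], K = 2L,
                        label = "all"))
  } else { # haploid_female_codominant_male
    if (is.null(sex)) stop_input("sex is required for mixed-ploidy fits")
    sx <- sex[ok]
    fem <- sx == "F"
    keepf <- fem & g != 1L
    dropped_het <- sum(fem & g == 1L)
    blocks <- list(
      list(y = as.integer(g[keepf] == 2L), h = hh[keepf], K = 2L,
           label = "female"),
      list(y = as.integer(g[!fem]), h = hh[!fem], K = 3L, label = "male"))
    blocks <- Filter(function(b) length(b$y) > 0L, blocks)
  }
  list(blocks = blocks, n = length(g), dropped_het = dropped_het)
}

#' Fit a genomic cline at one locus
#'
#' Multinomial-logit regression of genotype category on hybrid index, fitted
#' by Newton-Raphson maximum likelihood with coefficients capped at +/- 25
#' on the logit scale (keeps completely separated loci finite and
#' rank-comparable; such fits are flagged).  For the mixed ploidy model the
#' female (haploid) and male (diploid) likelihood blocks share h but have
#' separate coefficients, and the fit statistic is the summed gain.
#'
#' @param genotype integer genotype vector (dosage coding 0/1/2, NA missing).
#' @param h hybrid index per individual, aligned with `genotype`.
#' @param ploidy `"codominant_diploid"`, `"haploid"` (hemizygous calls coded
#'   0/2), or `"haploid_female_codominant_male"`.
#' @param sex character vector (F/M) aligned with `genotype`; only needed
#'   for the mixed ploidy model.
#' @param min_n minimum individuals with called genotype and h (default 10).
#' @return object of class `genomic_cline` with coefficients, log-likelihood
#'   of fitted and intercept-only models, and the fit statistic
#'   `2 (logL_fitted - logL_intercept)`.
#' @seealso [cline_permutation_test()], [neutral_expectation()]
#' @export
genomic_cline <- function(genotype, h,
                          ploidy = c("codominant_diploid", "haploid",
                                     "haploid_female_codominant_male"),
                          sex = NULL, min_n = 10L) {
  ploidy <- match.arg(ploidy)
  stopifnot(length(genotype) == length(h))
  cb <- cline_blocks(genotype, h, ploidy, sex)
  if (cb$n < min_n)
    stop_input("fewer than ", min_n, " individuals with genotype and h")
  fits <- lapply(cb$blocks, function(b) {
    fit <- mlogit_fit(b$y, b$h, b$K)
    fit$null_logLik <- mlogit_null_loglik(b$y, b$K)
    fit$label <- b$label
    fit$K <- b$K
    fit$n <- length(b$y)
    fit
  })
  ll <- sum(vapply(fits, `[[`, numeric(1L), "logLik"))
  ll0 <- sum(vapply(fits, `[[`, numeric(1L), "null_logLik"))
  coefs <- lapply(fits, function(f) {
    cm <- f$coefficients
    dimnames(cm) <- list(c("(Intercept)", "h"),
                         if (f$K == 3L) c("het", "hom_alt") else "alt")
    cm
  })
  names(coefs) <- vapply(fits, `[[`, character(1L), "label")
  structure(list(
    coefficients = if (length(coefs) == 1L) coefs[[1L]] else coefs,
    logLik = ll, null_logLik = ll0,
    statistic = 2 * (ll - ll0),
    separated = any(vapply(fits, `[[`, logical(1L), "separated")),
    ploidy = ploidy, n = cb$n, dropped_het = cb$dropped_het,
    blocks = cb$blocks
  ), class = "genomic_cline")
}

#' @export
print.genomic_cline <- function(x, ...) {
  cat("Genomic cline (", x$ploidy, "), n = ", x$n,
      ", fit statistic = ", format(x$statistic, digits = 4), "\n", sep = "")
  if (x$separated) cat("  note: coefficients capped (separation)\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.genomic_cline <- function(object, ...) {
  cat("Multinomial-logit genomic cline\n")
  cat("  ploidy model :", object$ploidy, "\n")
  cat("  individuals  :", object$n, "\n")
  cat("  logLik fitted:", format(object$logLik, digits = 6),
      " intercept-only:", format(object$null_logLik, digits = 6), "\n")
  cat("  statistic 2*(logL1 - logL0):",
      format(object$statistic, digits = 5), "\n")
  if (object$dropped_het > 0L)
    cat("  dropped", object$dropped_het, "heterozygote(s) at haploid loci\n")
  print(object$coefficients)
  invisible(object)
}

#' @export
coef.genomic_cline <- function(object, ...) object$coefficients

#' @export
logLik.genomic_cline <- function(object, ...) {
  p <- if (is.list(object$coefficients) && !is.matrix(object$coefficients))
    sum(vapply(object$coefficients, length, integer(1L))) else
      length(object$coefficients)
  structure(object$logLik, df = p, nobs = object$n, class = "logLik")
}

## category probabilities of one coefficient matrix at hybrid indices hs
mlogit_probs <- function(B, hs) {
  eta <- cbind(1, hs) %*% B
  eta <- pmin(pmax(eta, -35), 35)
  expEta <- exp(eta)
  denom <- 1 + rowSums(expEta)
  cbind(`0` = 1 / denom, expEta / denom)
}

#' Predicted genotype-category probabilities along the hybrid index
#'
#' @param object a [genomic_cline()] fit.
#' @param newdata hybrid index values (default a fine grid over [0, 1]).
#' @param ... unused.
#' @return matrix of category probabilities (columns `0`, `1`, `2` for
#'   diploid; `0`, `2` for haploid), or a list of such matrices per block
#'   for the mixed ploidy model.
#' @export
predict.genomic_cline <- function(object, newdata = seq(0, 1, 0.01), ...) {
  one <- function(B, K) {
    pr <- mlogit_probs(B, newdata)
    colnames(pr) <- if (K == 3L) c("0", "1", "2") else c("0", "2")
    rownames(pr) <- NULL
    pr
  }
  if (is.list(object$coefficients) && !is.matrix(object$coefficients)) {
    out <- lapply(object$coefficients, function(cm)
      one(cm, K = ncol(cm) + 1L))
    return(out)
  }
  one(object$coefficients, K = ncol(object$coefficients) + 1L)
}

#' @export
fitted.genomic_cline <- function(object, ...) {
  ## fitted category probabilities at each individual's observed h
  res <- lapply(object$blocks, function(b) {
    fit <- mlogit_fit(b$y, b$h, b$K)
    pr <- mlogit_probs(fit$coefficients, b$h)
    colnames(pr) <- if (b$K == 3L) c("0", "1", "2") else c("0", "2")
    pr
  })
  if (length(res) == 1L) res[[1L]] else res
}

#' @export
residuals.genomic_cline <- function(object, ...) {
  ## observed minus expected alt-allele dosage at each individual's h
  res <- lapply(object$blocks, function(b) {
    fit <- mlogit_fit(b$y, b$h, b$K)
    pr <- mlogit_probs(fit$coefficients, b$h)
    expected <- if (b$K == 3L) pr[, 2L] + 2 * pr[, 3L] else 2 * pr[, 2L]
    observed <- if (b$K == 3L) b$y else 2 * b$y
    observed - expected
  })
  if (length(res) == 1L) res[[1L]] else res
}

#' Simulate genotypes from a fitted genomic cline
#'
#' @param object a [genomic_cline()] fit (single-block models).
#' @param nsim number of replicate genotype vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame with `nsim` columns of genotypes drawn at the
#'   observed hybrid indices.
#' @export
simulate.genomic_cline <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.list(object$coefficients) && !is.matrix(object$coefficients))
    stop_input("simulate() supports single-block fits")
  b <- object$blocks[[1L]]
  pr <- mlogit_probs(object$coefficients, b$h)
  codes <- if (b$K == 3L) 0:2 else c(0L, 2L)
  out <- replicate(nsim, {
    u <- stats::runif(length(b$h))
    cum1 <- pr[, 1L]
    if (b$K == 3L) codes[(u > cum1) + (u > cum1 + pr[, 2L]) + 1L]
    else codes[(u > cum1) + 1L]
  })
  as.data.frame(out)
}

#' Plot a fitted genomic cline against the neutral expectation
#'
#' @param x a [genomic_cline()] fit (single block).
#' @param neutral optional `c(p_inland, p_coastal)`; when given, the neutral
#'   admixture expectation is drawn dashed.
#' @param ... passed to [plot()].
#' @export
plot.genomic_cline <- function(x, neutral = NULL, ...) {
  hs <- seq(0, 1, 0.01)
  pr <- predict(x, hs)
  if (is.list(pr)) pr <- pr[[length(pr)]]  # male block for mixed fits
  cols <- c("#1b7837", "#762a83", "#2166ac")
  plot(hs, pr[, ncol(pr)], type = "l", ylim = c(0, 1), col = cols[1L],
       xlab = "hybrid index h", ylab = "genotype probability", lwd = 2, ...)
  for (j in seq_len(ncol(pr) - 1L))
    graphics::lines(hs, pr[, j], col = cols[j + 1L], lwd = 2)
  if (!is.null(neutral)) {
    ne <- neutral_expectation(hs, neutral[1L], neutral[2L],
                              ploidy = if (ncol(pr) == 3L)
                                "codominant_diploid" else "haploid")
    for (j in seq_len(ncol(ne)))
      graphics::lines(hs, ne[, j], lty = 2, col = "grey40")
  }
  graphics::legend("right", legend = colnames(pr), col = cols[c(2:ncol(pr), 1)],
                   lwd = 2, bty = "n", title = "genotype")
  invisible(x)
}

#' Neutral admixture expectation of genotype-category probabilities
#'
#' Under unrestricted gene flow, an individual with hybrid index h draws
#' allele copies with inland probability q(h) = h p_inland + (1-h)
#' p_coastal; diploid categories follow Hardy-Weinberg at q(h).
#'
#' @param h hybrid index values.
#' @param p_inland,p_coastal parental allele frequencies of the locus.
#' @param ploidy `"codominant_diploid"` or `"haploid"`.
#' @return matrix of category probabilities.
#' @export
neutral_expectation <- function(h, p_inland, p_coastal,
                                ploidy = c("codominant_diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  q <- h * p_inland + (1 - h) * p_coastal
  if (ploidy == "haploid")
    return(cbind(`0` = 1 - q, `2` = q))
  cbind(`0` = (1 - q)^2, `1` = 2 * q * (1 - q), `2` = q^2)
}

#' Permutation test of a genomic cline against genotype-h independence
#'
#' Permutes the genotype vector across individuals (within sex for the
#' mixed ploidy model), recomputes the fit statistic each time, and reports
#' `p_perm = (1 + #\{permuted >= observed\}) / (1 + n_perm)`.
#'
#' @inheritParams genomic_cline
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed (mandatory; makes the test reproducible).
#' @return list (p_perm, statistic, perm_stats, n_perm, seed, separated).
#' @export
cline_permutation_test <- function(genotype, h,
                                   ploidy = c("codominant_diploid", "haploid",
                                              "haploid_female_codominant_male"),
                                   sex = NULL, n_perm = 1000L, seed,
                                   min_n = 10L) {
  ploidy <- match.arg(ploidy)
  if (missing(seed)) stop_input("seed is required")
  if (n_perm < 1L) stop_input("n_perm must be >= 1")
  fit <- genomic_cline(genotype, h, ploidy, sex, min_n = min_n)
  obs <- fit$statistic
  set.seed(as.integer(seed))
  ok <- !is.na(genotype) & !is.na(h)
  g <- genotype[ok]; hh <- h[ok]
  sx <- if (!is.null(sex)) sex[ok] else NULL
  stat_of <- function(gperm) {
    cb <- cline_blocks(gperm, hh, ploidy, sx)
    sum(vapply(cb$blocks, function(b) cline_stat(b$y, b$h, b$K), numeric(1L)))
  }
  perm_stats <- numeric(n_perm)
  within_sex <- ploidy == "haploid_female_codominant_male"
  for (i in seq_len(n_perm)) {
    gp <- g
    if (within_sex) {
      for (s in unique(sx)) {
        idx <- which(sx == s)
        gp[idx] <- g[sample(idx)]
      }
    } else {
      gp <- g[sample(length(g))]
    }
    perm_stats[i] <- stat_of(gp)
  }
  p <- (1 + sum(perm_stats >= obs)) / (1 + n_perm)
  list(p_perm = p, statistic = obs, perm_stats = perm_stats,
       n_perm = n_perm, seed = as.integer(seed), separated = fit$separated)
}

#' Fit genomic clines with permutation tests across many loci
#'
#' Fits [genomic_cline()] at every marker, runs
#' [cline_permutation_test()] with a per-marker seed derived
#' deterministically from `seed` (results do not depend on marker order),
#' and collects the per-locus results.  For diploid fits the fitted
#' heterozygote probability at h = 0.5 is reported, which is the quantity
#' underdominant selection depresses relative to the neutral expectation.
#'
#' @param geno genotype matrix (typically one sex, thinned markers).
#' @param h named hybrid-index vector covering the rows of `geno`.
#' @param markers optional marker subset.
#' @param ploidy_map optional named vector per marker with values
#'   `"codominant_diploid"`, `"haploid"` or
#'   `"haploid_female_codominant_male"`; default codominant diploid.
#' @param sex optional named sex vector per sample (mixed-ploidy fits).
#' @param n_perm permutations per locus (default 1000).
#' @param seed master seed.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param min_n minimum called individuals per locus.
#' @return data frame of class `genomic_cline_set`: marker_id, ploidy, n,
#'   statistic, p_perm, significant, separated, p_het_mid.  Markers with
#'   fewer than `min_n` usable individuals are skipped and recorded in
#'   attribute `"skipped"`.
#' @export
genomic_clines <- function(geno, h, markers = NULL, ploidy_map = NULL,
                           sex = NULL, n_perm = 1000L, seed, alpha = 0.05,
                           min_n = 10L) {
  if (missing(seed)) stop_input("seed is required")
  if (is.null(names(h))) stop_input("h must be named by sample id")
  ids <- intersect(rownames(geno), names(h))
  geno <- geno[ids, , drop = FALSE]
  hvec <- h[ids]
  sx <- if (!is.null(sex)) sex[ids] else NULL
  use_markers <- if (is.null(markers)) colnames(geno) else
    intersect(colnames(geno), markers)
  rows <- vector("list", length(use_markers))
  skipped <- character(0)
  for (j in seq_along(use_markers)) {
    mk <- use_markers[j]
    pl <- if (!is.null(ploidy_map) && mk %in% names(ploidy_map))
      ploidy_map[[mk]] else "codominant_diploid"
    g <- geno[, mk]
    if (sum(!is.na(g)) < min_n) { skipped <- c(skipped, mk); next }
    pt <- tryCatch(
      cline_permutation_test(g, hvec, ploidy = pl, sex = sx,
                             n_perm = n_perm,
                             seed = derive_seed(seed, mk), min_n = min_n),
      error = function(e) NULL)
    if (is.null(pt)) { skipped <- c(skipped, mk); next }
    fit <- genomic_cline(g, hvec, ploidy = pl, sex = sx, min_n = min_n)
    p_het_mid <- NA_real_
    if (pl == "codominant_diploid")
      p_het_mid <- mlogit_probs(fit$coefficients, 0.5)[1L, 2L]
    rows[[j]] <- data.frame(
      marker_id = mk, ploidy = pl, n = fit$n, statistic = pt$statistic,
      p_perm = pt$p_perm, significant = pt$p_perm < alpha,
      separated = pt$separated, p_het_mid = p_het_mid,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(marker_id = character(0), ploidy = character(0),
                      n = integer(0), statistic = numeric(0),
                      p_perm = numeric(0), significant = logical(0),
                      separated = logical(0), p_het_mid = numeric(0))
  rownames(out) <- NULL
  structure(out, skipped = skipped, n_perm = n_perm, alpha = alpha,
            class = c("genomic_cline_set", "data.frame"))
}

#' @export
summary.genomic_cline_set <- function(object, ...) {
  n <- nrow(object)
  k <- sum(object$significant)
  cat("Genomic clines at", n, "loci;", attr(object, "n_perm"),
      "permutations per locus\n")
  cat(sprintf("  significant (p < %.2f): %d/%d (%.1f%%)\n",
              attr(object, "alpha"), k, n, if (n) 100 * k / n else 0))
  if (length(attr(object, "skipped")))
    cat("  skipped loci:", length(attr(object, "skipped")), "\n")
  invisible(data.frame(n_loci = n, n_significant = k,
                       fraction = if (n) k / n else NA_real_))
}
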
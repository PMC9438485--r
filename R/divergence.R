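## Per-SNP differentiation (Weir-Cockerham theta) and tag-based windowed
## divergence/diversity (DXY, pi), with the marker filters, linkage thinning
## and subsampling used around them.
##
## All statistics use diploid dosage coding, including for hemizygous calls
## carried as 0/2 ("run as diploid"); this is a documented, known bias.

#' Marker filter specification for differentiation analyses
#'
#' @param maf_min markers with pooled minor-allele frequency `<= maf_min`
#'   are excluded from F_ST (default 0.05).
#' @param max_missing markers with missing fraction `>= max_missing` over the
#'   two compared groups are excluded (default 0.50).
#' @param max_missing_neo stricter ceiling for neo-sex-chromosome markers:
#'   missing fraction must be `<= max_missing_neo` (default 0.10).
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(maf_min = 0.05, max_missing = 0.50,
                        max_missing_neo = 0.10) {
  vals <- c(maf_min, max_missing, max_missing_neo)
  if (any(vals < 0 | vals > 1)) stop_input("filter proportions must be in [0, 1]")
  structure(list(maf_min = maf_min, max_missing = max_missing,
                 max_missing_neo = max_missing_neo), class = "filter_spec")
}

#' Alt-allele frequencies within a sample group
#'
#' @param geno genotype matrix.
#' @param group character vector of sample ids.
#' @return data frame (marker_id, alt_freq, n_called); markers with zero
#'   called individuals carry NA frequency and are flagged.
#' @export
allele_frequencies <- function(geno, group) {
  group <- resolve_group(geno, group)
  g <- geno[group, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  freq <- ifelse(n_called > 0L, alt / (2 * n_called), NA_real_)
  data.frame(marker_id = colnames(geno), alt_freq = freq,
             n_called = n_called, flagged = n_called == 0L,
             row.names = NULL, stringsAsFactors = FALSE)
}

## per-marker genotype counts for one group
geno_counts <- function(geno, group) {
  g <- geno[group, , drop = FALSE]
  cbind(n0 = colSums(g == 0L, na.rm = TRUE),
        n1 = colSums(g == 1L, na.rm = TRUE),
        n2 = colSums(g == 2L, na.rm = TRUE))
}

#' Weir-Cockerham theta from two-population genotype counts
#'
#' Direct evaluation of the Weir & Cockerham (1984) two-population
#' variance-component estimator a / (a + b + c) from genotype counts.
#' Vectorized over markers.
#'
#' @param countsA,countsB matrices (or vectors for one marker) with columns
#'   n0, n1, n2: genotype counts per marker in each population.
#' @return numeric vector of theta; NA where the estimator is undefined
#'   (fewer than 2 individuals in a group, or no variation anywhere).
#' @export
fst_wc <- function(countsA, countsB) {
  if (is.null(dim(countsA))) countsA <- matrix(countsA, nrow = 1L)
  if (is.null(dim(countsB))) countsB <- matrix(countsB, nrow = 1L)
  nA <- rowSums(countsA)
  nB <- rowSums(countsB)
  pA <- (countsA[, 2L] + 2 * countsA[, 3L]) / (2 * nA)
  pB <- (countsB[, 2L] + 2 * countsB[, 3L]) / (2 * nB)
  hA <- countsA[, 2L] / nA
  hB <- countsB[, 2L] / nB
  r <- 2
  nbar <- (nA + nB) / r
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(nA < 2L | nB < 2L | denom == 0, NA_real_, a / denom)
  unname(theta)
}

#' Per-SNP F_ST between two groups with filters
#'
#' Computes Weir-Cockerham theta per marker between `groupA` and `groupB`,
#' applying the pooled-MAF and missingness filters of `filter`.  The MAF is
#' computed over the pooled pair (the filter is per pairwise comparison).
#' Markers failing a filter carry `passed_filters = FALSE` and no theta.
#'
#' @param geno genotype matrix.
#' @param groupA,groupB disjoint character vectors of sample ids.
#' @param filter a [filter_spec()].
#' @param neo_markers optional marker ids subject to the stricter
#'   `max_missing_neo` ceiling (markers on the neo-sex chromosome).
#' @return data frame (marker_id, fst, passed_filters, missing_fraction, maf).
#' @export
fst_per_snp <- function(geno, groupA, groupB, filter = filter_spec(),
                        neo_markers = NULL) {
  groupA <- resolve_group(geno, groupA)
  groupB <- resolve_group(geno, groupB)
  if (!length(groupA) || !length(groupB)) stop_input("empty group")
  if (length(intersect(groupA, groupB)))
    stop_input("groups overlap: ", intersect(groupA, groupB)[1L])
  cA <- geno_counts(geno, groupA)
  cB <- geno_counts(geno, groupB)
  nA <- rowSums(cA); nB <- rowSums(cB)
  pooled <- cA + cB
  n_pool <- nA + nB
  p_pool <- ifelse(n_pool > 0, (pooled[, 2L] + 2 * pooled[, 3L]) / (2 * n_pool), NA)
  maf <- pmin(p_pool, 1 - p_pool)
  miss <- 1 - n_pool / (length(groupA) + length(groupB))
  strict <- colnames(geno) %in% neo_markers
  passed <- nA >= 2L & nB >= 2L &
    !is.na(maf) & maf > filter$maf_min &
    ifelse(strict, miss <= filter$max_missing_neo, miss < filter$max_missing)
  theta <- rep(NA_real_, ncol(geno))
  theta[passed] <- fst_wc(cA[passed, , drop = FALSE], cB[passed, , drop = FALSE])
  data.frame(marker_id = colnames(geno), fst = theta, passed_filters = passed,
             missing_fraction = miss, maf = maf,
             row.names = NULL, stringsAsFactors = FALSE)
}

## Per-tag between-group divergence / within-group diversity, per site.
## Tags are the unique (chromosome, position, tag_length) triples of the map;
## every SNP marker at a tag contributes its per-SNP quantity, tag bases
## without SNPs count as invariant.  A tag with no computable SNP is skipped.
tag_stat <- function(map, per_snp_value) {
  ok <- !is.na(per_snp_value)
  if (!any(ok)) return(NULL)
  m <- map[ok, , drop = FALSE]
  v <- per_snp_value[ok]
  key <- paste(m$chromosome, m$position, m$tag_length, sep = "\r")
  agg <- rowsum(v, key)
  first <- !duplicated(key)
  tags <- m[first, c("chromosome", "position", "tag_length")]
  tags <- tags[match(rownames(agg), paste(tags$chromosome, tags$position,
                                          tags$tag_length, sep = "\r")), ]
  data.frame(chromosome = tags$chromosome, position = tags$position,
             tag_length = tags$tag_length, total = as.numeric(agg),
             per_site = as.numeric(agg) / tags$tag_length,
             row.names = NULL, stringsAsFactors = FALSE)
}

## aggregate per-tag totals into overlapping sliding windows
window_aggregate <- function(tags, window, step, statistic) {
  if (window <= 0 || step <= 0) stop_input("window and step must be positive")
  if (is.null(tags) || !nrow(tags)) {
    out <- data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), statistic = character(0),
                      value = numeric(0), n_tags = integer(0),
                      total_bases = numeric(0), stringsAsFactors = FALSE)
    return(out)
  }
  pieces <- lapply(split(tags, tags$chromosome), function(tc) {
    j_hi <- floor(tc$position / step)
    j_lo <- pmax(0, floor((tc$position - window) / step) + 1L)
    reps <- j_hi - j_lo + 1L
    idx <- rep(seq_len(nrow(tc)), reps)
    j <- unlist(lapply(seq_len(nrow(tc)),
                       function(i) seq(j_lo[i], j_hi[i])), use.names = FALSE)
    tot <- rowsum(tc$total[idx], j)
    bases <- rowsum(as.numeric(tc$tag_length[idx]), j)
    ntag <- rowsum(rep(1L, length(idx)), j)
    jj <- as.numeric(rownames(tot))
    data.frame(chromosome = tc$chromosome[1L], start = jj * step,
               end = jj * step + window, statistic = statistic,
               value = as.numeric(tot) / as.numeric(bases),
               n_tags = as.integer(ntag), total_bases = as.numeric(bases),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chromosome, out$start), ]
  rownames(out) <- NULL
  out
}

#' Sliding-window absolute divergence (D_XY) from tag sequences
#'
#' Per SNP, the between-group mismatch probability is
#' `pA (1 - pB) + pB (1 - pA)`; per tag, these are summed over the tag's
#' SNPs and divided by the tag length (bases without SNPs are invariant).
#' Tags are assigned to every overlapping window whose half-open interval
#' `[start, start + window)` contains the tag's mapped start position;
#' windows with no tags emit no record.  The per-tag values are attached as
#' the `"tags"` attribute for downstream block detection.
#'
#' @param geno genotype matrix.
#' @param map marker map.
#' @param groupA,groupB sample id vectors.
#' @param window,step window size and step in bp (defaults 100 kb / 50 kb).
#' @return data frame of window records (chromosome, start, end, statistic,
#'   value, n_tags, total_bases).
#' @export
dxy_windows <- function(geno, map, groupA, groupB,
                        window = 100000, step = 50000) {
  if (window <= 0 || step <= 0) stop_input("window and step must be positive")
  fA <- allele_frequencies(geno, groupA)
  fB <- allele_frequencies(geno, groupB)
  m <- map[match(colnames(geno), map$marker_id), ]
  d <- fA$alt_freq * (1 - fB$alt_freq) + fB$alt_freq * (1 - fA$alt_freq)
  tags <- tag_stat(m, d)
  out <- window_aggregate(tags, window, step, "dxy")
  attr(out, "tags") <- tags
  out
}

#' Sliding-window nucleotide diversity (pi) from tag sequences
#'
#' Per SNP, the sample-size-corrected heterozygosity `2 p (1 - p) n/(n - 1)`
#' over `n = 2 n_called` allele copies; window aggregation as in
#' [dxy_windows()].  Markers with fewer than 2 called individuals are
#' undefined and their tags are skipped when nothing else is computable.
#'
#' @inheritParams dxy_windows
#' @param group sample id vector.
#' @return data frame of window records.
#' @export
pi_windows <- function(geno, map, group, window = 100000, step = 50000) {
  if (window <= 0 || step <= 0) stop_input("window and step must be positive")
  f <- allele_frequencies(geno, group)
  n <- 2 * f$n_called
  p <- f$alt_freq
  ## at least 2 called individuals: a single diploid only exposes its own
  ## heterozygosity, not population diversity
  v <- ifelse(f$n_called >= 2, 2 * p * (1 - p) * n / pmax(n - 1, 1), NA_real_)
  m <- map[match(colnames(geno), map$marker_id), ]
  tags <- tag_stat(m, v)
  out <- window_aggregate(tags, window, step, "pi")
  attr(out, "tags") <- tags
  out
}

#' Count strongly differentiated markers and their overlaps
#'
#' @param fst_tables named list of tables from [fst_per_snp()].
#' @param threshold F_ST threshold defining strong differentiation
#'   (inclusive, default 0.2).
#' @return list with `counts` (per comparison) and `overlaps` (per pair of
#'   comparisons, size of the intersection of qualifying marker sets).
#' @export
count_differentiated <- function(fst_tables, threshold = 0.2) {
  if (!length(fst_tables)) stop_input("need at least one F_ST table")
  if (is.null(names(fst_tables)))
    names(fst_tables) <- paste0("comparison", seq_along(fst_tables))
  sets <- lapply(fst_tables, function(tab)
    tab$marker_id[tab$passed_filters & !is.na(tab$fst) & tab$fst >= threshold])
  counts <- data.frame(comparison = names(sets),
                       n_differentiated = vapply(sets, length, integer(1L)),
                       row.names = NULL, stringsAsFactors = FALSE)
  overlaps <- NULL
  if (length(sets) >= 2L) {
    pairs <- utils::combn(names(sets), 2L)
    overlaps <- data.frame(
      comparison_a = pairs[1L, ], comparison_b = pairs[2L, ],
      overlap = apply(pairs, 2L, function(p)
        length(intersect(sets[[p[1L]]], sets[[p[2L]]]))),
      stringsAsFactors = FALSE)
  }
  list(counts = counts, overlaps = overlaps, sets = sets)
}

#' Randomly subsample a group within a sample table
#'
#' Reduces one group (e.g. the males of a population class) to `target_n`
#' individuals by uniform sampling without replacement, reproducible by
#' seed; all other samples are retained.  Used to equalize male sample sizes
#' to the female ones before sex-compared statistics.
#'
#' @param samples sample table.
#' @param group character vector of sample ids forming the group.
#' @param target_n number to retain (must not exceed the group size).
#' @param seed integer seed.
#' @return reduced sample table.
#' @export
subsample_group <- function(samples, group, target_n, seed) {
  group <- intersect(group, samples$sample_id)
  if (target_n > length(group))
    stop_input("target_n (", target_n, ") exceeds group size (",
               length(group), ")")
  set.seed(as.integer(seed))
  keep_group <- if (target_n == length(group)) group else
    sample(group, target_n)
  keep <- samples$sample_id %in% keep_group |
    !samples$sample_id %in% group
  out <- samples[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank correlation between F_ST and per-marker missingness
#'
#' Spearman correlation between theta and the missing-data fraction among
#' markers with a defined estimate; a diagnostic for missingness-inflated
#' differentiation.
#'
#' @param fst_table table from [fst_per_snp()].
#' @return list (rho, n, fst, missing_fraction, flagged); fewer than 3
#'   usable markers, or a constant vector, yields NA rho with `flagged`.
#' @export
missingness_fst_correlation <- function(fst_table) {
  ok <- fst_table$passed_filters & !is.na(fst_table$fst)
  x <- fst_table$fst[ok]
  y <- fst_table$missing_fraction[ok]
  if (sum(ok) < 3L)
    return(list(rho = NA_real_, n = sum(ok), fst = x, missing_fraction = y,
                flagged = TRUE))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, n = sum(ok), fst = x, missing_fraction = y,
                flagged = TRUE))
  rho <- stats::cor(x, y, method = "spearman")
  list(rho = rho, n = sum(ok), fst = x, missing_fraction = y, flagged = FALSE)
}

#' Thin markers to at most one per spacing bin
#'
#' Retains at most one marker per non-overlapping `spacing`-sized bin per
#' chromosome (default 1 per 100 kb), to limit linkage between retained
#' markers.  Chromosomes listed in `exempt_chromosomes` are returned
#' unthinned (e.g. a neo-sex chromosome analysed without linkage filtering).
#'
#' @param map marker map.
#' @param markers optional subset of marker ids to consider (default all).
#' @param spacing bin width in bp.
#' @param selector `"first"` keeps the lowest-position marker per bin.
#' @param exempt_chromosomes chromosomes excluded from thinning.
#' @return character vector of retained marker ids (map order).
#' @export
thin_markers <- function(map, markers = NULL, spacing = 100000,
                         selector = c("first"), exempt_chromosomes = NULL) {
  selector <- match.arg(selector)
  if (spacing <= 0) stop_input("spacing must be positive")
  m <- if (is.null(markers)) map else map[map$marker_id %in% markers, ]
  exempt <- m$chromosome %in% exempt_chromosomes
  keep_exempt <- m$marker_id[exempt]
  m <- m[!exempt, , drop = FALSE]
  if (nrow(m)) {
    m <- m[order(m$chromosome, m$position, m$marker_id), ]
    bin <- paste(m$chromosome, floor(m$position / spacing))
    kept <- m$marker_id[!duplicated(bin)]
  } else kept <- character(0)
  ids <- c(kept, keep_exempt)
  map$marker_id[map$marker_id %in% ids]
}
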
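## Synthetic hybrid-zone generator for a ZW-system species with two
## mitolineages, four population classes, hemizygous W- and Z-linked markers,
## a non-recombining divergent block on a neo-Z chromosome, genotyping error
## and group-structured missingness.  Every dataset carries its ground truth
## (hybrid indices, marker classes, selection regimes, block genotypes), which
## is what the validation suite scores recovery against.

DEFAULT_GROUP_SIZES <- data.frame(
  sex = rep(c("M", "F"), each = 4L),
  population_class = rep(c("pure_inland", "hybrid_inland",
                           "hybrid_coastal", "pure_coastal"), 2L),
  n = c(72L, 54L, 55L, 110L, 41L, 24L, 40L, 46L),
  stringsAsFactors = FALSE
)

DEFAULT_CHROM_LENGTHS <- c(`2` = 150e6, `3` = 110e6, `4` = 70e6, `5` = 60e6,
                           Z = 75e6, `1A` = 73e6)

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_dataset()].  Defaults
#' emulate a two-mitolineage ZW hybrid-zone study: group sizes of
#' 72/54/55/110 males and 41/24/40/46 females across the pure-inland,
#' hybrid-inland, hybrid-coastal and pure-coastal classes, and an 8 MB
#' non-recombining divergent block at 51-59 MB on the neo-Z chromosome
#' ("1A").  Parental allele frequencies at ordinary markers are drawn from a
#' rescaled Beta so no ordinary marker is fixed between lineages; block
#' haplotypes are near-fixed (0.98 vs 0.02) and carried as two ancestral
#' non-recombining haplotypes (perfect within-block LD).
#'
#' @param n_autosomal_markers,n_z_markers,n_w_markers number of autosomal,
#'   Z-linked and W-linked (mismapped to autosomes) markers.
#' @param n_neo_w_markers,n_neo_z_markers,n_block_markers markers on the
#'   neo-W, the neo-Z outside the block, and inside the divergent block.
#' @param block_interval list(chromosome, start, end) in bp, half-open.
#' @param group_sizes data frame (sex, population_class, n).
#' @param divergence list of parental-frequency model parameters.  Each
#'   non-block marker draws a shared ancestral frequency `p0` from a
#'   Beta(`shape1`, `shape2`) rescaled into `[freq_min, freq_max]`; each
#'   lineage then drifts away by an independent Normal(0, `drift_sd`)
#'   deviation, clamped back into the range, so most markers are weakly
#'   differentiated and none is fixed between lineages.  `fixed_delta`
#'   (when non-NULL) instead separates the lineages deterministically by
#'   that allele-frequency difference (strongly informative loci);
#'   `null = TRUE` forces p_inland == p_coastal exactly.  Block copies draw
#'   alleles from `block_inland`/`block_coastal` conditional on the copy's
#'   haplotype type; setting these to 1 and 0 gives fully fixed,
#'   perfect-LD block haplotypes.
#' @param hybrid_h_distribution list of Beta(shape1, shape2) parameters for
#'   hybrid-index draws, one pair per hybrid class (`inland`, `coastal`).
#' @param selection optional data frame (marker_id, regime, s) with regime in
#'   neutral/underdominant/overdominant/directional; for directional, `s` is
#'   the shift applied to the effective hybrid index.
#' @param error_rate genotype miscall probability per called cell.
#' @param missing_rate missingness probability per (marker, group) cell;
#'   either a scalar or a named vector by population class.
#' @param block_hybrid_freq optional inland-haplotype frequency of the block
#'   shared by both hybrid classes; decouples block genotype from
#'   mitolineage (default NULL: block copies follow the individual's hybrid
#'   index).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param seed integer seed (mandatory).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_autosomal_markers = 600L,
                       n_z_markers = 300L,
                       n_w_markers = 40L,
                       n_neo_w_markers = 40L,
                       n_neo_z_markers = 180L,
                       n_block_markers = 160L,
                       block_interval = list(chromosome = "1A",
                                             start = 51e6, end = 59e6),
                       group_sizes = DEFAULT_GROUP_SIZES,
                       divergence = list(),
                       hybrid_h_distribution = list(inland = c(8, 2),
                                                    coastal = c(2, 8)),
                       selection = NULL,
                       error_rate = 0.01,
                       missing_rate = 0.05,
                       block_hybrid_freq = NULL,
                       chrom_lengths = DEFAULT_CHROM_LENGTHS,
                       seed) {
  if (missing(seed) || !is_scalar_number(seed))
    stop_input("sim_config requires an integer seed")
  div_default <- list(shape1 = 0.8, shape2 = 0.8, freq_min = 0.2,
                      freq_max = 0.8, drift_sd = 0.1, fixed_delta = NULL,
                      null = FALSE,
                      block_inland = 0.8, block_coastal = 0.2)
  divergence <- utils::modifyList(div_default, divergence)
  if (divergence$shape1 <= 0 || divergence$shape2 <= 0)
    stop_input("degenerate Beta parameters in divergence model")
  if (divergence$freq_min < 0 || divergence$freq_max > 1 ||
      divergence$freq_min > divergence$freq_max)
    stop_input("divergence frequency range must satisfy 0 <= min <= max <= 1")
  for (p in c(divergence$block_inland, divergence$block_coastal,
              error_rate, unname(missing_rate)))
    if (any(p < 0 | p > 1)) stop_input("probabilities must lie in [0, 1]")
  if (!is.null(block_hybrid_freq) &&
      (block_hybrid_freq < 0 || block_hybrid_freq > 1))
    stop_input("block_hybrid_freq must lie in [0, 1]")
  if (block_interval$start >= block_interval$end)
    stop_input("block_interval start must be < end")
  group_sizes$n <- as.integer(group_sizes$n)
  if (any(group_sizes$n < 0L) || sum(group_sizes$n) == 0L)
    stop_input("group_sizes must be non-negative and not all zero")
  for (hp in hybrid_h_distribution)
    if (any(hp <= 0)) stop_input("degenerate Beta parameters for hybrid h")
  if (!is.null(selection)) {
    stopifnot(all(c("marker_id", "regime", "s") %in% names(selection)))
    bad <- !selection$regime %in% c("neutral", "underdominant",
                                    "overdominant", "directional")
    if (any(bad)) stop_input("unknown selection regime: ",
                             selection$regime[bad][1L])
  }
  structure(list(
    n_autosomal_markers = as.integer(n_autosomal_markers),
    n_z_markers = as.integer(n_z_markers),
    n_w_markers = as.integer(n_w_markers),
    n_neo_w_markers = as.integer(n_neo_w_markers),
    n_neo_z_markers = as.integer(n_neo_z_markers),
    n_block_markers = as.integer(n_block_markers),
    block_interval = block_interval,
    group_sizes = group_sizes,
    divergence = divergence,
    hybrid_h_distribution = hybrid_h_distribution,
    selection = selection,
    error_rate = error_rate,
    missing_rate = missing_rate,
    block_hybrid_freq = block_hybrid_freq,
    chrom_lengths = chrom_lengths,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  n_markers <- x$n_autosomal_markers + x$n_z_markers + x$n_w_markers +
    x$n_neo_w_markers + x$n_neo_z_markers + x$n_block_markers
  cat("Hybrid-zone simulation config:", sum(x$group_sizes$n), "samples,",
      n_markers, "markers\n")
  cat("  block:", x$block_interval$chromosome,
      sprintf("%.0f-%.0f bp", x$block_interval$start, x$block_interval$end),
      sprintf("(%d markers)\n", x$n_block_markers))
  cat("  error_rate:", x$error_rate, " missing_rate:",
      paste(x$missing_rate, collapse = "/"), " seed:", x$seed, "\n")
  invisible(x)
}

## Marker table: ids, classes, map positions, parental frequencies and the
## two founder block haplotypes.  Deterministic given the config seed.
build_marker_table <- function(config) {
  set.seed(derive_seed(config$seed, "markers"))
  div <- config$divergence
  autos <- setdiff(names(config$chrom_lengths), c("Z", "1A"))
  blocks <- list(
    list(class = "autosomal", n = config$n_autosomal_markers, prefix = "aut"),
    list(class = "Z",         n = config$n_z_markers,        prefix = "z"),
    list(class = "W_linked",  n = config$n_w_markers,        prefix = "w"),
    list(class = "neo_W",     n = config$n_neo_w_markers,    prefix = "neow"),
    list(class = "neo_Z",     n = config$n_neo_z_markers,    prefix = "neoz"),
    list(class = "neo_Z_block", n = config$n_block_markers,  prefix = "blk")
  )
  out <- list()
  for (b in blocks) {
    if (b$n == 0L) next
    id <- sprintf("%s_%04d", b$prefix, seq_len(b$n))
    if (b$class %in% c("autosomal", "W_linked")) {
      chrom <- sample(autos, b$n, replace = TRUE,
                      prob = config$chrom_lengths[autos])
      pos <- floor(stats::runif(b$n) * config$chrom_lengths[chrom])
    } else if (b$class == "Z") {
      chrom <- rep("Z", b$n)
      pos <- floor(stats::runif(b$n) * config$chrom_lengths[["Z"]])
    } else if (b$class == "neo_Z_block") {
      chrom <- rep(config$block_interval$chromosome, b$n)
      pos <- floor(stats::runif(b$n, config$block_interval$start,
                                config$block_interval$end))
    } else { # neo_W, neo_Z: on the neo chromosome, outside the block
      chrom <- rep(config$block_interval$chromosome, b$n)
      len <- config$chrom_lengths[[config$block_interval$chromosome]]
      span_left <- config$block_interval$start
      span_right <- len - config$block_interval$end
      left <- stats::runif(b$n) < span_left / (span_left + span_right)
      pos <- ifelse(left,
                    floor(stats::runif(b$n) * span_left),
                    floor(config$block_interval$end +
                            stats::runif(b$n) * span_right))
    }
    if (b$class == "neo_Z_block") {
      p_i <- rep(div$block_inland, b$n)
      p_c <- rep(div$block_coastal, b$n)
    } else {
      clamp <- function(p) pmin(pmax(p, div$freq_min), div$freq_max)
      p0 <- div$freq_min + (div$freq_max - div$freq_min) *
        stats::rbeta(b$n, div$shape1, div$shape2)
      if (isTRUE(div$null)) {
        p_i <- p_c <- p0
      } else if (!is.null(div$fixed_delta)) {
        if (div$fixed_delta > div$freq_max - div$freq_min)
          stop_input("fixed_delta exceeds the allele-frequency range")
        p_i <- pmin(pmax(p0 + div$fixed_delta / 2,
                         div$freq_min + div$fixed_delta), div$freq_max)
        p_c <- p_i - div$fixed_delta
      } else {
        p_i <- clamp(p0 + stats::rnorm(b$n, 0, div$drift_sd))
        p_c <- clamp(p0 + stats::rnorm(b$n, 0, div$drift_sd))
      }
    }
    out[[b$class]] <- data.frame(
      marker_id = id, chromosome = chrom, position = as.integer(pos),
      tag_length = 69L, class = b$class,
      p_inland = p_i, p_coastal = p_c, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  ## order markers by chromosome and position (stable map order)
  tab <- tab[order(tab$chromosome, tab$position, tab$marker_id), ]
  rownames(tab) <- NULL
  tab
}

#' Parental allele frequencies of the simulated marker panel
#'
#' @param config a [sim_config()].
#' @return data frame (marker_id, class, p_inland, p_coastal); deterministic
#'   given the config seed.
#' @export
simulate_parental_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tab <- build_marker_table(config)
  tab[, c("marker_id", "class", "p_inland", "p_coastal")]
}

## selection lookup vectors aligned to the marker table
selection_vectors <- function(config, marker_ids) {
  w_het <- rep(1, length(marker_ids))
  shift <- rep(0, length(marker_ids))
  sel <- config$selection
  if (!is.null(sel) && nrow(sel)) {
    idx <- match(sel$marker_id, marker_ids)
    known <- !is.na(idx)
    under <- known & sel$regime == "underdominant"
    over <- known & sel$regime == "overdominant"
    dir <- known & sel$regime == "directional"
    w_het[idx[under]] <- 1 - sel$s[under]
    w_het[idx[over]] <- 1 + sel$s[over]
    shift[idx[dir]] <- sel$s[dir]
  }
  list(w_het = w_het, shift = shift)
}

#' Simulate a hybrid-zone dataset with known truth
#'
#' Pure-class individuals have hybrid index h = 1 (pure inland) or 0 (pure
#' coastal); hybrid-class individuals draw h from the configured Beta.  Each
#' locus follows the allele-copy model q(h) = h p_inland + (1 - h) p_coastal.
#' Autosomal loci are diploid Binomial(2, q); Z and neo-Z loci are haploid in
#' females (coded 0/2) and diploid in males; W and neo-W loci are haploid in
#' females (allele drawn from the female's mitolineage frequency, as W is
#' co-inherited with mtDNA) and missing in males.  Block loci inherit jointly
#' from the sample's block haplotype copies with no recombination.  Selection
#' regimes re-weight genotype probabilities before sampling; miscalls and
#' missingness are injected last.
#'
#' @param config a [sim_config()].
#' @return object of class `hz_sim`: list with `genotypes` (genotype matrix),
#'   `map` (marker map), `samples` (sample table), and `truth` (list with
#'   `samples`: per-sample true h, block genotype; `markers`: per-marker
#'   class, selection regime, parental frequencies; `block_interval`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  markers <- build_marker_table(config)
  n_mark <- nrow(markers)

  ## -- samples ---------------------------------------------------------
  set.seed(derive_seed(config$seed, "samples"))
  gs <- config$group_sizes[config$group_sizes$n > 0L, ]
  samples <- data.frame(
    sample_id = character(0), sex = character(0), mitolineage = character(0),
    population_class = character(0), site = character(0),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(gs))) {
    cls <- gs$population_class[i]
    mito <- if (grepl("inland$", cls)) "inland" else "coastal"
    samples <- rbind(samples, data.frame(
      sample_id = NA_character_, sex = gs$sex[i], mitolineage = mito,
      population_class = cls, site = cls, stringsAsFactors = FALSE)[rep(1L, gs$n[i]), ])
  }
  samples$sample_id <- sprintf("s%04d", seq_len(nrow(samples)))
  rownames(samples) <- NULL
  samples <- sample_table(samples)
  n_samp <- nrow(samples)

  ## true hybrid index
  h <- numeric(n_samp)
  h[samples$population_class == "pure_inland"] <- 1
  h[samples$population_class == "pure_coastal"] <- 0
  for (cls in c("hybrid_inland", "hybrid_coastal")) {
    idx <- which(samples$population_class == cls)
    hp <- config$hybrid_h_distribution[[sub("hybrid_", "", cls)]]
    h[idx] <- stats::rbeta(length(idx), hp[1L], hp[2L])
  }

  ## block haplotype copies: 2 in males, 1 in females (the other neo copy is
  ## the W-fused one); copies are inland with probability h, or with the
  ## configured shared hybrid frequency when the block is decoupled from
  ## ancestry/mitolineage
  is_male <- samples$sex == "M"
  p_copy <- h
  if (!is.null(config$block_hybrid_freq)) {
    hyb <- grepl("^hybrid", samples$population_class)
    p_copy[hyb] <- config$block_hybrid_freq
  }
  copies1 <- stats::rbinom(n_samp, 1L, p_copy)  # all individuals
  copies2 <- stats::rbinom(n_samp, 1L, p_copy)  # used for males only
  n_inland_copies <- copies1 + ifelse(is_male, copies2, 0L)
  block_geno <- ifelse(is_male,
                       c("CC", "IC", "II")[n_inland_copies + 1L],
                       c("CC", "II")[copies1 + 1L])

  ## -- genotypes -------------------------------------------------------
  set.seed(derive_seed(config$seed, "genotypes"))
  sel <- selection_vectors(config, markers$marker_id)
  calls <- matrix(NA_integer_, n_samp, n_mark,
                  dimnames = list(samples$sample_id, markers$marker_id))
  h_eff <- outer(h, sel$shift, function(hh, sh) pmin(pmax(hh + sh, 0), 1))
  q <- h_eff * rep(markers$p_inland, each = n_samp) +
    (1 - h_eff) * rep(markers$p_coastal, each = n_samp)

  cls <- markers$class
  diploid_cols <- which(cls == "autosomal")
  zlike_cols <- which(cls %in% c("Z", "neo_Z"))
  wlike_cols <- which(cls %in% c("W_linked", "neo_W"))
  blk_cols <- which(cls == "neo_Z_block")

  sample_diploid <- function(qm, w_het) {
    ## category probabilities with heterozygote re-weighting, renormalized
    p0 <- (1 - qm)^2
    p1 <- 2 * qm * (1 - qm) * rep(w_het, each = nrow(qm))
    p2 <- qm^2
    tot <- p0 + p1 + p2
    u <- stats::runif(length(qm)) * tot
    matrix((u > p0) + (u > p0 + p1), nrow(qm))
  }

  ## autosomal: everyone diploid
  if (length(diploid_cols))
    calls[, diploid_cols] <- sample_diploid(q[, diploid_cols, drop = FALSE],
                                            sel$w_het[diploid_cols])
  ## Z / neo-Z: males diploid, females haploid coded 0/2
  if (length(zlike_cols)) {
    qm <- q[, zlike_cols, drop = FALSE]
    g <- sample_diploid(qm, sel$w_het[zlike_cols])
    gf <- 2L * matrix(stats::rbinom(length(qm), 1L, qm), nrow(qm))
    g[!is_male, ] <- gf[!is_male, ]
    calls[, zlike_cols] <- g
  }
  ## W / neo-W: females haploid with allele frequency of their mitolineage
  ## (W travels with mtDNA); missing in males
  if (length(wlike_cols)) {
    p_mito <- ifelse(samples$mitolineage == "inland", 1, 0)
    qw <- p_mito %*% t(markers$p_inland[wlike_cols]) +
      (1 - p_mito) %*% t(markers$p_coastal[wlike_cols])
    gw <- 2L * matrix(stats::rbinom(length(qw), 1L, qw), nrow(qw))
    gw[is_male, ] <- NA_integer_
    calls[, wlike_cols] <- gw
  }
  ## block loci: each haplotype copy is inherited as a unit (its inland or
  ## coastal type never recombines); conditional on the type, the copy's
  ## allele at a locus follows the type-specific near-fixed frequency.
  ## With block frequencies 1/0 this collapses to fully fixed haplotypes
  ## (perfect LD across the block).
  if (length(blk_cols)) {
    pI_blk <- markers$p_inland[blk_cols]
    pC_blk <- markers$p_coastal[blk_cols]
    copy_allele <- function(copy_is_inland) {
      pmat <- outer(copy_is_inland, seq_along(blk_cols),
                    function(ci, j) ifelse(ci == 1L, pI_blk[j], pC_blk[j]))
      matrix(stats::rbinom(length(pmat), 1L, pmat), nrow(pmat))
    }
    g1 <- copy_allele(copies1)
    gb <- 2L * g1  # hemizygous females coded 0/2
    gb[is_male, ] <- g1[is_male, ] + copy_allele(copies2)[is_male, ]
    calls[, blk_cols] <- gb
  }

  ## -- error and missingness injection ---------------------------------
  set.seed(derive_seed(config$seed, "noise"))
  if (config$error_rate > 0) {
    called <- which(!is.na(calls))
    err <- called[stats::runif(length(called)) < config$error_rate]
    if (length(err)) {
      old <- calls[err]
      pick <- stats::runif(length(err))  # one of the two other codes
      other1 <- (old + 1L) %% 3L
      other2 <- (old + 2L) %% 3L
      calls[err] <- ifelse(pick < 0.5, other1, other2)
    }
  }
  mrate <- config$missing_rate
  if (any(mrate > 0)) {
    if (length(mrate) == 1L) {
      drop <- stats::runif(length(calls)) < mrate
    } else {
      rate_by_sample <- mrate[samples$population_class]
      drop <- matrix(stats::runif(length(calls)), n_samp, n_mark) <
        rate_by_sample
    }
    calls[drop] <- NA_integer_
  }

  structure(list(
    genotypes = genotype_matrix(calls),
    map = marker_map(markers[, c("marker_id", "chromosome", "position",
                                 "tag_length")]),
    samples = samples,
    truth = list(
      samples = data.frame(sample_id = samples$sample_id, true_h = h,
                           mitolineage = samples$mitolineage,
                           block_genotype = block_geno,
                           stringsAsFactors = FALSE),
      markers = data.frame(marker_id = markers$marker_id,
                           class = markers$class,
                           p_inland = markers$p_inland,
                           p_coastal = markers$p_coastal,
                           stringsAsFactors = FALSE),
      block_interval = config$block_interval
    ),
    config = config
  ), class = "hz_sim")
}

#' Read a simulation configuration from JSON
#'
#' The JSON mirrors the arguments of [sim_config()]; `group_sizes` is an
#' array of records (sex, population_class, n) and `block_interval` an
#' object (chromosome, start, end).
#'
#' @param path JSON file.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_input("file does not exist: ", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- js
  if (!is.null(js$group_sizes))
    args$group_sizes <- as.data.frame(js$group_sizes)
  if (!is.null(js$block_interval))
    args$block_interval <- as.list(js$block_interval)
  if (!is.null(js$divergence)) args$divergence <- as.list(js$divergence)
  if (!is.null(js$hybrid_h_distribution))
    args$hybrid_h_distribution <- lapply(js$hybrid_h_distribution, as.numeric)
  if (!is.null(js$chrom_lengths))
    args$chrom_lengths <- unlist(js$chrom_lengths)
  if (!is.null(js$selection)) args$selection <- as.data.frame(js$selection)
  do.call(sim_config, args)
}

#' @export
print.hz_sim <- function(x, ...) {
  cat("Simulated hybrid-zone dataset:", nrow(x$genotypes), "samples x",
      ncol(x$genotypes), "markers\n")
  print(table(x$truth$markers$class))
  invisible(x)
}
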
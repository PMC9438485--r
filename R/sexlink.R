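## Behavioral classification of markers into W-behaving, Z-behaving and
## autosomal-like categories, per population class and by cross-population
## consensus.  In a ZW system, a W-linked marker is present (hemizygous) in
## females and missing in males; a Z-linked marker is hemizygous -- hence
## apparently homozygous -- in females and het-or-hom in males.  The rules
## tolerate genotyping error through the 10% filters.

#' Thresholds for behavioral marker classification
#'
#' @param error_tolerance error filter applied to the missing-data and
#'   female-homozygosity criteria (default 0.10: rules require 90%).
#' @param min_male_het minimum male heterozygote fraction for the Z rule
#'   (default 0.10), which prevents monomorphic, autosomally behaving
#'   markers from passing as Z-linked.
#' @param min_called minimum called females, and scored-or-missing males,
#'   for a population to count (default 5); below this the population is
#'   skipped as no-data.
#' @return list of class `behavior_thresholds`.
#' @export
behavior_thresholds <- function(error_tolerance = 0.10, min_male_het = 0.10,
                                min_called = 5L) {
  if (error_tolerance < 0 || error_tolerance > 1 ||
      min_male_het < 0 || min_male_het > 1)
    stop_input("thresholds must be proportions in [0, 1]")
  if (min_called < 1L) stop_input("min_called must be >= 1")
  structure(list(error_tolerance = error_tolerance,
                 min_male_het = min_male_het,
                 min_called = as.integer(min_called)),
            class = "behavior_thresholds")
}

## Vectorized per-population classification over all markers.
## g: genotype matrix restricted to one population's samples.
## Returns list(label = character per marker, sufficient = logical).
classify_population_markers <- function(g, sex, thresholds) {
  keep <- 1 - thresholds$error_tolerance
  gF <- g[sex == "F", , drop = FALSE]
  gM <- g[sex == "M", , drop = FALSE]
  nF <- nrow(gF); nM <- nrow(gM)
  f_called <- colSums(!is.na(gF))
  m_called <- colSums(!is.na(gM))
  sufficient <- f_called >= thresholds$min_called & nM >= thresholds$min_called
  frac_f_called <- if (nF) f_called / nF else rep(0, ncol(g))
  frac_m_called <- if (nM) m_called / nM else rep(0, ncol(g))
  frac_m_missing <- 1 - frac_m_called
  f_hom <- colSums(gF == 0L | gF == 2L, na.rm = TRUE)
  frac_f_hom <- ifelse(f_called > 0L, f_hom / f_called, 0)
  m_het <- colSums(gM == 1L, na.rm = TRUE)
  frac_m_het <- ifelse(m_called > 0L, m_het / m_called, 0)

  is_w <- frac_f_called >= keep & frac_m_missing >= keep
  is_z <- !is_w & frac_f_hom >= keep & m_called > 0L &
    frac_m_het >= thresholds$min_male_het
  is_auto <- !is_w & !is_z & frac_f_called >= keep & frac_m_called >= keep
  label <- rep("indeterminate", ncol(g))
  label[is_auto] <- "autosomal_like"
  label[is_z] <- "Z_behaving"
  label[is_w] <- "W_behaving"
  list(label = label, sufficient = sufficient)
}

#' Classify one marker within one population
#'
#' Applies the behavioral rules to a single marker's genotypes restricted to
#' one population: W-behaving if at least `1 - error_tolerance` of females
#' are called and at least that fraction of males are missing; Z-behaving if
#' at least `1 - error_tolerance` of called females are homozygous and the
#' heterozygote fraction among called males is at least `min_male_het`;
#' autosomal-like if called at `1 - error_tolerance` in both sexes and
#' neither rule fires; indeterminate otherwise.  Populations with fewer than
#' `min_called` called females or scored males return their label with
#' attribute `sufficient = FALSE` (treated as no-data in consensus).
#'
#' @param genotypes integer genotype vector (one marker, one population).
#' @param sex character vector (F/M) aligned with `genotypes`.
#' @param thresholds a [behavior_thresholds()].
#' @return label string with logical attribute `sufficient`.
#' @export
classify_in_population <- function(genotypes, sex,
                                   thresholds = behavior_thresholds()) {
  stopifnot(length(genotypes) == length(sex))
  g <- matrix(as.integer(genotypes), ncol = 1L,
              dimnames = list(NULL, "m"))
  res <- classify_population_markers(g, sex, thresholds)
  structure(res$label, sufficient = res$sufficient)
}

#' Consensus behavioral classification across population classes
#'
#' Computes per-population labels over the population classes present in the
#' sample table and combines them: the consensus is W- or Z-behaving only if
#' every population with sufficient data yields that same label;
#' autosomal-like if all sufficient populations agree on it; markers that
#' cannot be cleanly categorized in all populations (disagreement, or an
#' indeterminate label in a population with sufficient data, or no
#' population with sufficient data) are `unclassified`.
#'
#' @param geno genotype matrix.
#' @param samples sample table.
#' @param thresholds a [behavior_thresholds()].
#' @return data frame: marker_id, one label column per population class
#'   (NA where the class is skipped as no-data), and `consensus`.
#' @export
classify_consensus <- function(geno, samples,
                               thresholds = behavior_thresholds()) {
  samples <- samples[samples$sample_id %in% rownames(geno), , drop = FALSE]
  pops <- intersect(VALID_CLASSES, unique(samples$population_class))
  if (!length(pops)) stop_input("no population classes present")
  per_pop <- list()
  for (pop in pops) {
    ids <- samples$sample_id[samples$population_class == pop]
    res <- classify_population_markers(geno[ids, , drop = FALSE],
                                       samples$sex[match(ids, samples$sample_id)],
                                       thresholds)
    lab <- res$label
    lab[!res$sufficient] <- NA_character_  # skipped as no-data
    per_pop[[pop]] <- lab
  }
  labmat <- do.call(cbind, per_pop)
  consensus <- apply(labmat, 1L, function(row) {
    row <- row[!is.na(row)]
    if (!length(row)) return("unclassified")
    u <- unique(row)
    if (length(u) == 1L && u %in% c("W_behaving", "Z_behaving", "autosomal_like"))
      u else "unclassified"
  })
  out <- data.frame(marker_id = colnames(geno), stringsAsFactors = FALSE)
  for (pop in pops) out[[pop]] <- per_pop[[pop]]
  out$consensus <- consensus
  out
}
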
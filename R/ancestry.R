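## Allelic ancestry matrices, divergence-block detection, block haplotype
## calls and the mitolineage-by-block association table.

#' Allelic ancestry matrix
#'
#' Per marker, the allele with the higher inland parental frequency is
#' labeled the inland-ancestry allele when the parental frequencies differ
#' by at least `delta_min`; otherwise the marker is unassigned.  Each
#' individual's genotype is then mapped to its inland-allele dosage
#' (2 = both alleles inland, 1 = heterozygous, 0 = both coastal).  Haploid
#' (hemizygous) calls map to 2/0; an apparent heterozygote at a haploid
#' locus is a data conflict and is left unassigned for that individual.
#'
#' @param geno genotype matrix.
#' @param pfreq parental frequency table (marker_id, p_inland, p_coastal).
#' @param delta_min minimum parental frequency difference for an ancestry
#'   assignment (default 0.3).
#' @param ploidy optional named vector per marker (`"codominant_diploid"` or
#'   `"haploid_female_codominant_male"`); with `sex`, hemizygous female
#'   calls are validated as haploid.
#' @param sex optional named sex vector per sample.
#' @return object of class `ancestry_matrix`: list with `codes` (samples x
#'   markers inland-allele dosage, NA = missing or unassigned) and
#'   `assignment` (per marker: inland allele and assignment status).
#' @export
ancestry_matrix <- function(geno, pfreq, delta_min = 0.3, ploidy = NULL,
                            sex = NULL) {
  idx <- match(colnames(geno), pfreq$marker_id)
  if (anyNA(idx)) stop_input("parental frequencies missing for some markers")
  pI <- pfreq$p_inland[idx]
  pC <- pfreq$p_coastal[idx]
  delta <- pI - pC
  assigned <- !is.na(delta) & abs(delta) >= delta_min
  inland_is_alt <- delta > 0
  codes <- geno
  flip <- which(assigned & !inland_is_alt)
  if (length(flip)) codes[, flip] <- 2L - codes[, flip, drop = FALSE]
  if (any(!assigned)) codes[, !assigned] <- NA_integer_
  ## haploid female entries: het is a conflict -> unassigned
  if (!is.null(ploidy) && !is.null(sex)) {
    hap_mk <- colnames(geno) %in%
      names(ploidy)[ploidy == "haploid_female_codominant_male"]
    fem <- sex[rownames(geno)] == "F"
    if (any(hap_mk) && any(fem)) {
      sub <- codes[fem, hap_mk, drop = FALSE]
      sub[sub == 1L] <- NA_integer_
      codes[fem, hap_mk] <- sub
    }
  }
  structure(list(
    codes = codes,
    assignment = data.frame(
      marker_id = colnames(geno),
      assigned = assigned,
      inland_allele = ifelse(assigned,
                             ifelse(inland_is_alt, "alt", "ref"),
                             NA_character_),
      delta = delta, stringsAsFactors = FALSE)
  ), class = "ancestry_matrix")
}

#' @export
print.ancestry_matrix <- function(x, ...) {
  cat("Ancestry matrix:", nrow(x$codes), "samples x", ncol(x$codes),
      "markers;", sum(x$assignment$assigned), "assigned\n")
  cat("  codes: 2 = inland hom, 1 = het, 0 = coastal hom, NA = unassigned\n")
  invisible(x)
}

#' Detect divergent blocks from windowed statistics
#'
#' Flags windows where the mean per-SNP theta of passed-filter markers
#' within the window is at least `fst_floor` and the minimum per-tag D_XY in
#' the window is at least the chromosome-wide lower-decile of tag D_XY (an
#' absence of low-divergence tags, the signature of a non-recombining
#' block/inversion); merges contiguous or overlapping flagged windows,
#' bridging gaps of at most `max_gap` windows.
#'
#' @param fst_table table from [fst_per_snp()].
#' @param dxy_win windows from [dxy_windows()] (per-tag values are taken
#'   from its `"tags"` attribute).
#' @param map marker map (to place F_ST markers into windows).
#' @param fst_floor mean-theta floor (default 0.2).
#' @param dxy_quantile lower-quantile defining "low D_XY" per chromosome
#'   (default 0.1).
#' @param max_gap flagged-window gaps of up to this many windows are
#'   bridged when merging (default 1).
#' @return data frame (chromosome, start, end) of merged block intervals;
#'   zero rows when nothing is flagged.
#' @export
detect_divergence_block <- function(fst_table, dxy_win, map,
                                    fst_floor = 0.2, dxy_quantile = 0.1,
                                    max_gap = 1L) {
  empty <- data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(dxy_win)) return(empty)
  tags <- attr(dxy_win, "tags")
  window <- dxy_win$end[1L] - dxy_win$start[1L]
  step <- if (nrow(dxy_win) > 1L)
    min(diff(sort(unique(dxy_win$start)))) else window
  m <- map[match(fst_table$marker_id, map$marker_id), ]
  th_ok <- fst_table$passed_filters & !is.na(fst_table$fst)
  flagged <- logical(nrow(dxy_win))
  for (i in seq_len(nrow(dxy_win))) {
    chr <- dxy_win$chromosome[i]
    lo <- dxy_win$start[i]; hi <- dxy_win$end[i]
    in_win <- th_ok & m$chromosome == chr & m$position >= lo & m$position < hi
    if (!any(in_win, na.rm = TRUE)) next
    mean_theta <- mean(fst_table$fst[which(in_win)])
    if (is.na(mean_theta) || mean_theta < fst_floor) next
    chr_tags <- tags[tags$chromosome == chr, ]
    dxy_floor <- stats::quantile(chr_tags$per_site, dxy_quantile,
                                 na.rm = TRUE, names = FALSE)
    wt <- chr_tags[chr_tags$position >= lo & chr_tags$position < hi, ]
    if (!nrow(wt)) next
    flagged[i] <- min(wt$per_site) >= dxy_floor
  }
  if (!any(flagged)) return(empty)
  fw <- dxy_win[flagged, c("chromosome", "start", "end")]
  fw <- fw[order(fw$chromosome, fw$start), ]
  out <- list()
  cur <- fw[1L, ]
  bridge <- max_gap * window
  for (i in seq_len(nrow(fw))[-1L]) {
    same <- fw$chromosome[i] == cur$chromosome &&
      fw$start[i] <= cur$end + bridge
    if (same) {
      cur$end <- max(cur$end, fw$end[i])
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- fw[i, ]
    }
  }
  out[[length(out) + 1L]] <- cur
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Call block haplotypes from ancestry codes
#'
#' For each individual, `f` is the fraction of inland alleles over its
#' called, assigned block markers; the block is called inland when
#' `f >= 0.8`, coastal when `f <= 0.2`, heterozygous otherwise, and
#' uncalled when fewer than `min_markers` block markers are called.
#' Hemizygous females are expected to come out inland/coastal; a
#' heterozygous female call indicates conflicting data (or genotyping
#' error) and is permitted but noteworthy.
#'
#' @param ancestry an [ancestry_matrix()].
#' @param block_markers marker ids inside the block.
#' @param min_markers minimum called block markers per individual (default 5).
#' @param inland_min,coastal_max thresholds on `f` (defaults 0.8 / 0.2).
#' @return data frame (sample_id, haplotype, inland_fraction,
#'   n_block_markers_called).
#' @export
call_block_haplotypes <- function(ancestry, block_markers, min_markers = 5L,
                                  inland_min = 0.8, coastal_max = 0.2) {
  use <- intersect(block_markers,
                   ancestry$assignment$marker_id[ancestry$assignment$assigned])
  if (!length(use)) stop_input("no assigned block markers")
  codes <- ancestry$codes[, use, drop = FALSE]
  n_called <- rowSums(!is.na(codes))
  f <- rowSums(codes, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  hap <- ifelse(n_called < min_markers, "uncalled",
                ifelse(f >= inland_min, "inland",
                       ifelse(f <= coastal_max, "coastal", "heterozygous")))
  data.frame(sample_id = rownames(codes), haplotype = hap,
             inland_fraction = ifelse(n_called > 0L, f, NA_real_),
             n_block_markers_called = n_called,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mitolineage-by-block-haplotype association table
#'
#' Counts and within-row proportions of block haplotype calls by sex and
#' mitolineage; uncalled individuals are excluded from the denominators and
#' reported separately.
#'
#' @param block_calls table from [call_block_haplotypes()].
#' @param samples sample table.
#' @return data frame (sex, mitolineage, haplotype, count, denominator,
#'   proportion) plus uncalled counts as haplotype `"uncalled"` with NA
#'   proportion.
#' @export
mito_block_association <- function(block_calls, samples) {
  df <- merge(block_calls, samples[, c("sample_id", "sex", "mitolineage")],
              by = "sample_id")
  if (!nrow(df))
    return(data.frame(sex = character(0), mitolineage = character(0),
                      haplotype = character(0), count = integer(0),
                      denominator = integer(0), proportion = numeric(0),
                      stringsAsFactors = FALSE))
  haps <- c("inland", "heterozygous", "coastal", "uncalled")
  out <- expand.grid(sex = c("M", "F"), mitolineage = c("inland", "coastal"),
                     haplotype = haps, stringsAsFactors = FALSE)
  out <- out[order(out$sex == "F", out$mitolineage, match(out$haplotype, haps)), ]
  cnt <- integer(nrow(out)); den <- integer(nrow(out))
  for (i in seq_len(nrow(out))) {
    grp <- df$sex == out$sex[i] & df$mitolineage == out$mitolineage[i]
    cnt[i] <- sum(grp & df$haplotype == out$haplotype[i])
    den[i] <- sum(grp & df$haplotype != "uncalled")
  }
  out$count <- cnt
  out$denominator <- den
  out$proportion <- ifelse(out$haplotype == "uncalled", NA_real_,
                           ifelse(den > 0L, cnt / den, NA_real_))
  keep <- out$count > 0L | out$haplotype != "uncalled"
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
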
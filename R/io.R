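## Genotype, marker-map and sample-metadata I/O.
##
## The central substrate is a plain integer matrix of alt-allele dosages
## (samples x markers) with codes 0 = hom-ref, 1 = het, 2 = hom-alt and NA =
## missing.  Hemizygous calls are carried in the same diploid coding (0 or 2),
## which is also how downstream statistics treat them unless a ploidy map
## says otherwise.  Internal coordinates are 0-based; windows are half-open.

VALID_SEXES <- c("F", "M")
VALID_MITO <- c("inland", "coastal")
VALID_CLASSES <- c("pure_inland", "hybrid_inland", "hybrid_coastal", "pure_coastal")

#' Construct and validate a genotype matrix
#'
#' @param calls matrix coercible to integer, one row per sample, one column
#'   per marker; entries must be 0, 1, 2 or NA (alt-allele dosage coding).
#' @param samples,markers optional identifier vectors; default to the
#'   dimnames of `calls`.
#' @return validated integer matrix with sample row names and marker column
#'   names.
#' @export
genotype_matrix <- function(calls, samples = rownames(calls),
                            markers = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(samples) || is.null(markers))
    stop_input("genotype matrix needs sample and marker identifiers")
  if (anyDuplicated(samples)) stop_input("duplicate sample identifiers")
  if (anyDuplicated(markers)) stop_input("duplicate marker identifiers")
  if (nrow(calls) != length(samples) || ncol(calls) != length(markers))
    stop_input("genotype matrix dimensions do not match identifier lengths")
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop_input("invalid genotype code at sample '", samples[idx[1L]],
               "', marker '", markers[idx[2L]], "' (must be 0, 1, 2 or NA)")
  }
  dimnames(calls) <- list(samples, markers)
  calls
}

#' Read a genotype matrix from VCF or wide CSV
#'
#' VCF records must be biallelic SNPs; a multi-allelic record is a validation
#' error naming the marker.  Phasing is ignored: genotypes are collapsed to
#' alt-allele dosage.  Haploid (hemizygous) VCF calls are coded 0/2 so that
#' they are representable in the diploid dosage coding.  The wide CSV dialect
#' has a `sample_id` first column, one column per marker, and cells in
#' \{0,1,2,NA\}.
#'
#' @param path file path.
#' @param format `"vcf"`, `"wide_csv"`, or `"auto"` (by file extension).
#' @return genotype matrix (see [genotype_matrix()]).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "wide_csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "wide_csv"
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_wide_csv(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single-record VCFs come back as a bare vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    stop_input("multi-allelic VCF record(s): ",
               paste(utils::head(ids[multi], 5L), collapse = ", "),
               "; only biallelic markers are supported")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- matrix(gt, nrow = nrow(fix), dimnames = dimnames(gt))
  code_one <- function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1L]]
    alleles <- alleles[alleles != ""]
    if (!length(alleles) || any(alleles == ".")) return(NA_integer_)
    if (!all(alleles %in% c("0", "1")))
      stop_input("unsupported allele index in GT '", g, "'")
    dose <- sum(alleles == "1")
    if (length(alleles) == 1L) dose * 2L else dose  # haploid -> 0/2
  }
  calls <- vapply(seq_len(nrow(gt)), function(i) {
    vapply(gt[i, ], code_one, integer(1L))
  }, integer(ncol(gt)))
  if (is.null(dim(calls))) calls <- matrix(calls, ncol = nrow(gt))
  genotype_matrix(calls, samples = colnames(gt), markers = ids)
}

read_genotypes_wide_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop_input("wide CSV needs a sample_id column plus at least one marker column")
  calls <- as.matrix(df[, -1L, drop = FALSE])
  genotype_matrix(calls, samples = as.character(df[[1L]]),
                  markers = colnames(df)[-1L])
}

#' Write a genotype matrix to VCF or wide CSV
#'
#' The wide CSV round-trips codes exactly.  The VCF writer emits a minimal
#' VCF v4.2 with placeholder alleles (A/T) and unphased diploid genotypes;
#' positions and chromosomes come from `map` when supplied, else markers are
#' placed consecutively on a single contig.
#'
#' @param geno genotype matrix.
#' @param path output file.
#' @param format `"wide_csv"` or `"vcf"`.
#' @param map optional marker map used for VCF CHROM/POS (1-based on output).
#' @export
write_genotypes <- function(geno, path, format = c("wide_csv", "vcf"), map = NULL) {
  format <- match.arg(format)
  if (format == "wide_csv") {
    df <- data.frame(sample_id = rownames(geno), check.names = FALSE)
    df <- cbind(df, as.data.frame(geno, check.names = FALSE))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  markers <- colnames(geno)
  if (!is.null(map)) {
    m <- map[match(markers, map$marker_id), ]
    chrom <- m$chromosome
    pos <- m$position + 1L  # back to 1-based at the boundary
  } else {
    chrom <- rep("un", length(markers))
    pos <- seq_along(markers)
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_along(markers), function(j) {
    g <- geno[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(chrom[j], pos[j], markers[j], "A", "T", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1L))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(geno)), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Construct and validate a marker map
#'
#' @param df data frame with columns `marker_id`, `chromosome`, `position`
#'   (0-based internal convention), `tag_length` (bp, >= 1, default 69).
#' @return validated data frame.
#' @export
marker_map <- function(df) {
  need <- c("marker_id", "chromosome", "position")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input("marker map missing column(s): ",
                               paste(miss, collapse = ", "))
  if (is.null(df$tag_length)) df$tag_length <- 69L
  df <- df[, c("marker_id", "chromosome", "position", "tag_length")]
  df$marker_id <- as.character(df$marker_id)
  df$chromosome <- as.character(df$chromosome)
  df$position <- as.integer(df$position)
  df$tag_length <- as.integer(df$tag_length)
  if (anyDuplicated(df$marker_id))
    stop_input("duplicate marker_id in marker map: ",
               df$marker_id[duplicated(df$marker_id)][1L])
  if (any(is.na(df$position)) || any(df$position < 0L))
    stop_input("marker positions must be non-negative")
  if (any(is.na(df$tag_length)) || any(df$tag_length < 1L))
    stop_input("tag_length must be >= 1")
  rownames(df) <- NULL
  df
}

#' Read a marker map (CSV or BED3+name)
#'
#' CSV columns: `marker_id,chromosome,position,tag_length`.  Positions are
#' converted to the 0-based internal convention; declare 1-based input with
#' `one_based = TRUE`.  With `bed = TRUE` the file is read as BED3+name
#' (chrom, start, end, name; start already 0-based, tag_length = end - start).
#'
#' @param path file path.
#' @param one_based logical; input positions are 1-based and are shifted.
#' @param bed logical; parse as BED3+name.
#' @return marker map data frame (see [marker_map()]).
#' @export
read_marker_map <- function(path, one_based = FALSE, bed = FALSE) {
  if (!file.exists(path)) stop_input("file does not exist: ", path)
  if (bed) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop_input("BED input needs 4 columns (BED3+name)")
    out <- data.frame(marker_id = as.character(df[[4L]]),
                      chromosome = as.character(df[[1L]]),
                      position = as.integer(df[[2L]]),
                      tag_length = as.integer(df[[3L]] - df[[2L]]),
                      stringsAsFactors = FALSE)
    return(marker_map(out))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (one_based) df$position <- df$position - 1L
  marker_map(df)
}

#' Write a marker map as CSV (positions stay 0-based)
#' @param map marker map.
#' @param path output file.
#' @export
write_marker_map <- function(map, path) {
  utils::write.csv(marker_map(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct and validate a sample metadata table
#'
#' Checks the categorical fields and the consistency between
#' `population_class` and `mitolineage` (a `hybrid_inland` bird must carry
#' the inland mitolineage, and so on).
#'
#' @param df data frame with columns `sample_id`, `sex` (F/M), `mitolineage`
#'   (inland/coastal), `population_class` (pure_inland, hybrid_inland,
#'   hybrid_coastal, pure_coastal) and optional `site`.
#' @return validated data frame.
#' @export
sample_table <- function(df) {
  need <- c("sample_id", "sex", "mitolineage", "population_class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input("sample table missing column(s): ",
                               paste(miss, collapse = ", "))
  if (is.null(df$site)) df$site <- NA_character_
  df <- df[, c("sample_id", "sex", "mitolineage", "population_class", "site")]
  for (col in names(df)) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$sample_id)) stop_input("duplicate sample_id")
  bad_sex <- !df$sex %in% VALID_SEXES
  if (any(bad_sex)) stop_input("unknown sex label: ", df$sex[bad_sex][1L])
  bad_mito <- !df$mitolineage %in% VALID_MITO
  if (any(bad_mito)) stop_input("unknown mitolineage: ", df$mitolineage[bad_mito][1L])
  bad_pop <- !df$population_class %in% VALID_CLASSES
  if (any(bad_pop)) stop_input("unknown population_class: ",
                               df$population_class[bad_pop][1L])
  expected_mito <- ifelse(grepl("inland$", df$population_class), "inland", "coastal")
  clash <- df$mitolineage != expected_mito
  if (any(clash))
    stop_input("population_class/mitolineage mismatch for sample '",
               df$sample_id[clash][1L], "'")
  rownames(df) <- NULL
  df
}

#' Read a sample metadata table (CSV)
#' @param path file path.
#' @return validated sample table (see [sample_table()]).
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop_input("file does not exist: ", path)
  sample_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Cross-check genotype samples against metadata
#'
#' Samples present in the genotype matrix but absent from the metadata are
#' returned (and warned about); they are excluded from group analyses rather
#' than raising an error, mirroring field datasets.
#'
#' @param geno genotype matrix.
#' @param samples sample table.
#' @return character vector of unmatched sample ids (invisibly if empty).
#' @export
check_sample_consistency <- function(geno, samples) {
  missing <- setdiff(rownames(geno), samples$sample_id)
  if (length(missing))
    warning(length(missing), " genotyped sample(s) lack metadata and are ",
            "excluded from group analyses: ",
            paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  invisible(missing)
}

#' Group sizes by sex and population class
#' @param samples sample table.
#' @return data frame of counts per (sex, population_class).
#' @export
group_sizes <- function(samples) {
  samples <- sample_table(samples)
  tab <- table(sex = samples$sex,
               population_class = factor(samples$population_class,
                                         levels = VALID_CLASSES))
  as.data.frame(tab, responseName = "n", stringsAsFactors = FALSE)
}

#' Select sample ids by metadata
#'
#' Convenience accessor used throughout: subset the sample table by
#' population class and/or sex and return the ids.
#'
#' @param samples sample table.
#' @param population_class,sex,mitolineage optional filters.
#' @return character vector of sample ids.
#' @export
sample_group <- function(samples, population_class = NULL, sex = NULL,
                         mitolineage = NULL) {
  keep <- rep(TRUE, nrow(samples))
  if (!is.null(population_class))
    keep <- keep & samples$population_class %in% population_class
  if (!is.null(sex)) keep <- keep & samples$sex %in% sex
  if (!is.null(mitolineage)) keep <- keep & samples$mitolineage %in% mitolineage
  samples$sample_id[keep]
}
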
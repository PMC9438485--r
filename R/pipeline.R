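## End-to-end orchestration: simulate/load -> behavioral classification ->
## per-sex divergence -> permutation nulls -> hybrid indices and genomic
## clines -> block detection and mitolineage association, with every stage
## seeded deterministically from one master seed and all outputs written as
## TSV plus a JSON run manifest.

#' Pipeline run configuration
#'
#' @param sim a [sim_config()] to generate the input dataset, or NULL.
#' @param paths list(genotypes, map, samples) of input files, or NULL;
#'   exactly one of `sim`/`paths` must be supplied.
#' @param out_dir output directory (created if needed).
#' @param seed master seed; per-stage seeds are derived deterministically
#'   from it, so any stage re-run in isolation reproduces its files.
#' @param stages character vector of enabled stages among `"classify"`,
#'   `"divergence"`, `"permtest"`, `"clines"`, `"block"`.
#' @param params named list overriding stage parameters: `window`, `step`,
#'   `fst_threshold`, `maf_min`, `max_missing`, `max_missing_neo`,
#'   `n_perm_fst`, `n_perm_cline`, `thin_spacing`, `delta_min`,
#'   `neo_chromosome`, `min_block_markers`.
#' @return list of class `hz_run_config`.
#' @export
hz_run_config <- function(sim = NULL, paths = NULL, out_dir, seed,
                          stages = c("classify", "divergence", "permtest",
                                     "clines", "block"),
                          params = list()) {
  if (is.null(sim) == is.null(paths))
    stop_input("supply exactly one of `sim` and `paths`")
  if (missing(seed) || !is_scalar_number(seed))
    stop_input("a master seed is required")
  defaults <- list(window = 100000, step = 50000, fst_threshold = 0.2,
                   maf_min = 0.05, max_missing = 0.50, max_missing_neo = 0.10,
                   n_perm_fst = 200L, n_perm_cline = 1000L,
                   thin_spacing = 100000, delta_min = 0.3,
                   neo_chromosome = "1A", min_block_markers = 5L)
  params <- utils::modifyList(defaults, params)
  structure(list(sim = sim, paths = paths, out_dir = out_dir,
                 seed = as.integer(seed), stages = stages, params = params),
            class = "hz_run_config")
}

## quick global screen for markers with W-linked behavior (used only to warn
## when the classification stage is disabled)
w_behavior_screen <- function(geno, samples) {
  fem <- sample_group(samples, sex = "F")
  mal <- sample_group(samples, sex = "M")
  fem <- intersect(fem, rownames(geno)); mal <- intersect(mal, rownames(geno))
  if (!length(fem) || !length(mal)) return(character(0))
  f_called <- colMeans(!is.na(geno[fem, , drop = FALSE]))
  m_missing <- colMeans(is.na(geno[mal, , drop = FALSE]))
  colnames(geno)[f_called >= 0.9 & m_missing >= 0.9]
}

#' Run the full hybrid-zone analysis pipeline
#'
#' Executes the enabled stages in dependency order.  Markers with consensus
#' W-linked behavior are removed from all diploid analyses; consensus
#' Z-behaving markers on the neo-sex chromosome are treated as haploid in
#' females and codominant in males for the cline stage.  Divergence and
#' cline stages run separately per sex.  Every stage writes its TSV outputs
#' into `out_dir`, and a JSON manifest records parameters, seeds, versions
#' and marker/sample counts after every filter.
#'
#' @param config a [hz_run_config()].
#' @return (invisibly) list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "hz_run_config"))
  p <- config$params
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_counts <- list()
  outfile <- function(name) file.path(config$out_dir, name)

  ## ---- data ----------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- simulate_dataset(config$sim)
    geno <- sim$genotypes; map <- sim$map; samples <- sim$samples
    write_tsv(sim$truth$samples, outfile("truth_samples.tsv"))
    write_tsv(sim$truth$markers, outfile("truth_markers.tsv"))
  } else {
    sim <- NULL
    geno <- read_genotypes(config$paths$genotypes)
    map <- read_marker_map(config$paths$map)
    samples <- read_sample_table(config$paths$samples)
  }
  unmatched <- check_sample_consistency(geno, samples)
  geno <- geno[setdiff(rownames(geno), unmatched), , drop = FALSE]
  samples <- samples[samples$sample_id %in% rownames(geno), , drop = FALSE]
  log_counts$samples <- nrow(geno)
  log_counts$markers_input <- ncol(geno)
  results <- list()

  sex_of <- stats::setNames(samples$sex, samples$sample_id)
  neo_mask <- map$chromosome == p$neo_chromosome
  neo_markers <- map$marker_id[neo_mask]

  ## ---- classification ------------------------------------------------
  w_remove <- character(0)
  z_behaving <- character(0)
  if ("classify" %in% config$stages) {
    classification <- classify_consensus(geno, samples)
    write_tsv(classification, outfile("classification.tsv"))
    w_remove <- classification$marker_id[classification$consensus == "W_behaving"]
    z_behaving <- classification$marker_id[classification$consensus == "Z_behaving"]
    results$classification <- classification
  } else {
    w_like <- w_behavior_screen(geno, samples)
    if (length(w_like))
      warning(length(w_like), " marker(s) show W-linked (hemizygous) ",
              "behavior; with classification disabled they contaminate ",
              "diploid statistics", call. = FALSE)
  }
  diploid_geno <- geno[, setdiff(colnames(geno), w_remove), drop = FALSE]
  log_counts$markers_after_w_removal <- ncol(diploid_geno)

  comparisons <- list(
    hybrid_F = list(a = c("hybrid_inland", "F"), b = c("hybrid_coastal", "F")),
    hybrid_M = list(a = c("hybrid_inland", "M"), b = c("hybrid_coastal", "M")),
    pure_F = list(a = c("pure_inland", "F"), b = c("pure_coastal", "F")),
    pure_M = list(a = c("pure_inland", "M"), b = c("pure_coastal", "M")))
  fspec <- filter_spec(p$maf_min, p$max_missing, p$max_missing_neo)

  ## ---- divergence ----------------------------------------------------
  if ("divergence" %in% config$stages) {
    fst_tabs <- list(); dxy_tabs <- list()
    for (nm in names(comparisons)) {
      cmp <- comparisons[[nm]]
      gA <- sample_group(samples, population_class = cmp$a[1L], sex = cmp$a[2L])
      gB <- sample_group(samples, population_class = cmp$b[1L], sex = cmp$b[2L])
      if (length(gA) < 2L || length(gB) < 2L) next
      fst_tabs[[nm]] <- fst_per_snp(diploid_geno, gA, gB, fspec,
                                    neo_markers = neo_markers)
      write_tsv(fst_tabs[[nm]], outfile(paste0("fst_", nm, ".tsv")))
      dxy_tabs[[nm]] <- dxy_windows(diploid_geno, map, gA, gB,
                                    window = p$window, step = p$step)
      write_tsv(dxy_tabs[[nm]], outfile(paste0("dxy_windows_", nm, ".tsv")))
      pi_a <- pi_windows(diploid_geno, map, gA, window = p$window, step = p$step)
      write_tsv(pi_a, outfile(paste0("pi_windows_", nm, "_a.tsv")))
    }
    diff_counts <- count_differentiated(fst_tabs, threshold = p$fst_threshold)
    write_tsv(diff_counts$counts, outfile("differentiated_counts.tsv"))
    if (!is.null(diff_counts$overlaps))
      write_tsv(diff_counts$overlaps, outfile("differentiated_overlaps.tsv"))
    results$fst <- fst_tabs
    results$dxy <- dxy_tabs
    results$differentiated <- diff_counts
    log_counts$fst_passed <- vapply(fst_tabs, function(t)
      sum(t$passed_filters), integer(1L))
  }

  ## ---- permutation nulls --------------------------------------------
  if ("permtest" %in% config$stages && length(results$fst) >= 2L) {
    perm <- list()
    for (nm in intersect(c("hybrid_F", "hybrid_M"), names(results$fst))) {
      cmp <- comparisons[[nm]]
      gA <- sample_group(samples, population_class = cmp$a[1L], sex = cmp$a[2L])
      gB <- sample_group(samples, population_class = cmp$b[1L], sex = cmp$b[2L])
      perm[[nm]] <- permuted_fst(diploid_geno, gA, gB,
                                 n_perm = p$n_perm_fst,
                                 seed = derive_seed(config$seed,
                                                    paste0("perm_", nm)),
                                 filter = fspec)
      qdf <- cbind(permutation = seq_len(p$n_perm_fst), perm[[nm]]$quantiles)
      write_tsv(qdf, outfile(paste0("perm_quantiles_", nm, ".tsv")))
    }
    cmp_report <- NULL
    if (all(c("hybrid_F", "hybrid_M") %in% names(results$fst))) {
      fF <- results$fst$hybrid_F; fM <- results$fst$hybrid_M
      cmp_report <- compare_fst_distributions(
        fF$fst[fF$passed_filters], fM$fst[fM$passed_filters])
      jsonlite::write_json(cmp_report, outfile("fst_comparison_report.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    results$permutation <- perm
    results$fst_comparison <- cmp_report
  }

  ## ---- hybrid indices and genomic clines -----------------------------
  if ("clines" %in% config$stages) {
    pfreq <- parental_frequencies(diploid_geno, samples)
    thinned <- thin_markers(map, markers = colnames(diploid_geno),
                            spacing = p$thin_spacing,
                            exempt_chromosomes = p$neo_chromosome)
    log_counts$markers_thinned <- length(thinned)
    ## Z-chromosome markers, plus Z-behaving markers on the neo-sex
    ## chromosome, are haploid in females and codominant in males
    hap_ids <- map$marker_id[map$chromosome == "Z" |
                               (map$chromosome == p$neo_chromosome &
                                  map$marker_id %in% z_behaving)]
    ploidy_map <- stats::setNames(
      rep("haploid_female_codominant_male", length(hap_ids)), hap_ids)
    hyb <- samples[grepl("^hybrid", samples$population_class), ]
    cline_sets <- list(); hindex <- list()
    for (sx in c("F", "M")) {
      ids <- hyb$sample_id[hyb$sex == sx]
      ids <- intersect(ids, rownames(diploid_geno))
      if (length(ids) < 10L) next
      g_sex <- diploid_geno[ids, , drop = FALSE]
      hi <- hybrid_index(g_sex, pfreq, ploidy = ploidy_map,
                         sex = sex_of, markers = thinned)
      hindex[[sx]] <- hi
      write_tsv(as.data.frame(hi), outfile(paste0("hybrid_index_", sx, ".tsv")))
      hvec <- stats::setNames(hi$h, hi$sample_id)
      per_sex_ploidy <- ploidy_map
      per_sex_ploidy[] <- if (sx == "F") "haploid" else "codominant_diploid"
      cs <- genomic_clines(g_sex, hvec, markers = thinned,
                           ploidy_map = per_sex_ploidy,
                           n_perm = p$n_perm_cline,
                           seed = derive_seed(config$seed,
                                              paste0("clines_", sx)))
      cline_sets[[sx]] <- cs
      write_tsv(as.data.frame(cs), outfile(paste0("clines_", sx, ".tsv")))
    }
    ## Table-3-shaped summary: significant fraction per sex x marker category
    summ <- list()
    for (sx in names(cline_sets)) {
      cs <- cline_sets[[sx]]
      cat_of <- ifelse(map$chromosome[match(cs$marker_id, map$marker_id)] ==
                         p$neo_chromosome, "neo_Z",
                       ifelse(map$chromosome[match(cs$marker_id,
                                                   map$marker_id)] == "Z",
                              "Z", "autosomal"))
      for (ct in unique(cat_of)) {
        sub <- cs[cat_of == ct, ]
        summ[[length(summ) + 1L]] <- data.frame(
          sex = sx, category = ct, n_loci = nrow(sub),
          n_significant = sum(sub$significant),
          fraction = if (nrow(sub)) sum(sub$significant) / nrow(sub) else NA,
          stringsAsFactors = FALSE)
      }
    }
    if (length(summ)) {
      summ <- do.call(rbind, summ)
      summ <- summ[order(summ$sex, summ$category), ]
      write_tsv(summ, outfile("cline_summary.tsv"))
      results$cline_summary <- summ
    }
    results$hybrid_index <- hindex
    results$clines <- cline_sets
    results$parental_frequencies <- pfreq

    ## ancestry matrices per sex (hybrid-zone individuals)
    anc <- ancestry_matrix(diploid_geno, pfreq, delta_min = p$delta_min,
                           ploidy = ploidy_map, sex = sex_of)
    results$ancestry <- anc
    anc_df <- data.frame(sample_id = rownames(anc$codes),
                         as.data.frame(anc$codes), check.names = FALSE)
    write_tsv(anc_df, outfile("ancestry_codes.tsv"))
  }

  ## ---- block detection and mito association --------------------------
  if ("block" %in% config$stages &&
      all(c("pure_F") %in% names(results$fst %||% list()))) {
    det <- detect_divergence_block(results$fst$pure_F,
                                   results$dxy$pure_F, map,
                                   fst_floor = p$fst_threshold)
    write_tsv(det, outfile("detected_blocks.tsv"))
    results$blocks <- det
    if (nrow(det) && !is.null(results$ancestry)) {
      blk <- det[which.max(det$end - det$start), ]
      blk_markers <- map$marker_id[map$chromosome == blk$chromosome &
                                     map$position >= blk$start &
                                     map$position < blk$end]
      calls <- call_block_haplotypes(results$ancestry, blk_markers,
                                     min_markers = p$min_block_markers)
      write_tsv(calls, outfile("block_calls.tsv"))
      assoc <- mito_block_association(calls, samples)
      write_tsv(assoc, outfile("mito_block_association.tsv"))
      results$block_calls <- calls
      results$mito_block <- assoc
    }
  }

  ## ---- manifest ------------------------------------------------------
  manifest <- list(
    package = "hzclines",
    version = as.character(utils::packageVersion("hzclines")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stages = config$stages,
    params = p,
    counts = log_counts,
    simulated = !is.null(config$sim)
  )
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
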
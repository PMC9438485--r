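mk_pop <- function(gF, gM) {
  list(g = c(gF, gM), sex = c(rep("F", length(gF)), rep("M", length(gM))))
}

test_that("per-population rules fire on their textbook patterns", {
  # all females called, all males missing -> W
  p <- mk_pop(rep(0L, 20), rep(NA_integer_, 20))
  expect_equal(as.character(classify_in_population(p$g, p$sex)), "W_behaving")

  # females 100% homozygous, 30% of males het -> Z
  p <- mk_pop(c(rep(0L, 10), rep(2L, 10)), c(rep(1L, 6), rep(0L, 14)))
  expect_equal(as.character(classify_in_population(p$g, p$sex)), "Z_behaving")

  # females homozygous but only 5% male het (below the 10% floor), all
  # called -> autosomal-like
  p <- mk_pop(rep(2L, 20), c(1L, rep(0L, 19)))
  expect_equal(as.character(classify_in_population(p$g, p$sex)),
               "autosomal_like")

  # 15% of males called (85% missing) fails the 90% male-missingness
  # requirement -> not W
  p <- mk_pop(rep(0L, 20), c(rep(0L, 3), rep(NA_integer_, 17)))
  lab <- as.character(classify_in_population(p$g, p$sex))
  expect_false(lab == "W_behaving")

  # ordinary autosomal pattern
  p <- mk_pop(c(rep(0L, 8), rep(1L, 8), rep(2L, 4)),
              c(rep(0L, 8), rep(1L, 8), rep(2L, 4)))
  expect_equal(as.character(classify_in_population(p$g, p$sex)),
               "autosomal_like")
})

test_that("insufficient data is flagged, not an error", {
  p <- mk_pop(rep(0L, 3), rep(NA_integer_, 20))
  lab <- classify_in_population(p$g, p$sex)
  expect_false(attr(lab, "sufficient"))
})

test_that("raising error tolerance never demotes a W or Z label", {
  set.seed(42)
  for (rep in 1:40) {
    nF <- sample(8:30, 1); nM <- sample(8:30, 1)
    gF <- sample(c(0L, 1L, 2L, NA), nF, replace = TRUE,
                 prob = c(0.4, 0.1, 0.4, 0.1))
    gM <- sample(c(0L, 1L, 2L, NA), nM, replace = TRUE,
                 prob = c(0.3, 0.2, 0.3, 0.2))
    p <- mk_pop(gF, gM)
    lab_lo <- as.character(classify_in_population(
      p$g, p$sex, behavior_thresholds(error_tolerance = 0.05)))
    lab_hi <- as.character(classify_in_population(
      p$g, p$sex, behavior_thresholds(error_tolerance = 0.20)))
    if (lab_lo %in% c("W_behaving", "Z_behaving"))
      expect_false(lab_hi == "indeterminate")
  }
})

test_that("labels are invariant to sample and marker order", {
  sim <- small_sim()
  cls <- classify_consensus(sim$genotypes, sim$samples)
  perm_s <- sample(nrow(sim$genotypes))
  perm_m <- sample(ncol(sim$genotypes))
  cls_perm <- classify_consensus(sim$genotypes[perm_s, perm_m],
                                 sim$samples[perm_s, ])
  cls_perm <- cls_perm[match(cls$marker_id, cls_perm$marker_id), ]
  expect_equal(cls$consensus, cls_perm$consensus)
})

test_that("consensus requires agreement across populations with data", {
  # one marker: W in pops 1-3 but clearly autosomal in pop 4 -> unclassified
  samples <- sample_table(data.frame(
    sample_id = sprintf("s%02d", 1:80),
    sex = rep(rep(c("F", "M"), each = 10), 4),
    mitolineage = rep(c("inland", "inland", "coastal", "coastal"), each = 20),
    population_class = rep(c("pure_inland", "hybrid_inland",
                             "hybrid_coastal", "pure_coastal"), each = 20),
    site = "x"))
  g_w <- c(rep(0L, 10), rep(NA_integer_, 10))   # W pattern per population
  g_auto <- rep(c(0L, 1L), 10)                   # autosomal pattern
  geno <- genotype_matrix(
    cbind(m_w = rep(g_w, 4),
          m_mixed = c(rep(g_w, 3), g_auto),
          m_auto = rep(g_auto, 4)),
    samples = samples$sample_id, markers = c("m_w", "m_mixed", "m_auto"))
  cls <- classify_consensus(geno, samples)
  expect_equal(cls$consensus, c("W_behaving", "unclassified", "autosomal_like"))
})

test_that("an indeterminate population with sufficient data vetoes consensus", {
  samples <- sample_table(data.frame(
    sample_id = sprintf("s%02d", 1:80),
    sex = rep(rep(c("F", "M"), each = 10), 4),
    mitolineage = rep(c("inland", "inland", "coastal", "coastal"), each = 20),
    population_class = rep(c("pure_inland", "hybrid_inland",
                             "hybrid_coastal", "pure_coastal"), each = 20),
    site = "x"))
  g_z <- c(rep(c(0L, 2L), 5), rep(1L, 3), rep(0L, 7))  # Z pattern
  # indeterminate pattern: half the females uncalled, males fully called
  g_ind <- c(rep(NA_integer_, 5), rep(0L, 5), rep(0L, 10))
  geno <- genotype_matrix(cbind(m = c(rep(g_z, 3), g_ind)),
                          samples = samples$sample_id, markers = "m")
  cls <- classify_consensus(geno, samples)
  expect_equal(cls$consensus, "unclassified")
})

test_that("consensus equals simulated truth on clean data", {
  cfg <- sim_config(seed = 31, n_autosomal_markers = 80L, n_z_markers = 50L,
                    n_w_markers = 10L, n_neo_w_markers = 10L,
                    n_neo_z_markers = 30L, n_block_markers = 30L,
                    error_rate = 0, missing_rate = 0)
  sim <- simulate_dataset(cfg)
  cls <- classify_consensus(sim$genotypes, sim$samples)
  truth <- sim$truth$markers$class[match(cls$marker_id,
                                         sim$truth$markers$marker_id)]
  expected <- ifelse(truth %in% c("W_linked", "neo_W"), "W_behaving",
                     ifelse(truth %in% c("Z", "neo_Z", "neo_Z_block"),
                            "Z_behaving", NA))
  sexlinked <- !is.na(expected)
  expect_identical(cls$consensus[sexlinked], expected[sexlinked])
})
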
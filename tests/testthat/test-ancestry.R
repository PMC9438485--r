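test_that("ancestry codes follow the inland-allele dosage convention", {
  g <- genotype_matrix(rbind(s1 = c(2L, 0L, 1L), s2 = c(0L, 2L, 1L)),
                       markers = c("inl_alt", "inl_ref", "flat"))
  pf <- data.frame(marker_id = c("inl_alt", "inl_ref", "flat"),
                   p_inland = c(0.9, 0.1, 0.5),
                   p_coastal = c(0.1, 0.9, 0.5))
  am <- ancestry_matrix(g, pf, delta_min = 0.3)
  expect_equal(unname(am$codes["s1", ]), c(2L, 2L, NA))  # ref is inland at m2
  expect_equal(unname(am$codes["s2", ]), c(0L, 0L, NA))
  expect_false(am$assignment$assigned[3])
})

test_that("pure parental samples are uniformly homozygous for their ancestry", {
  cfg <- sim_config(seed = 61, n_autosomal_markers = 40L, n_z_markers = 0L,
                    n_w_markers = 0L, n_neo_w_markers = 0L,
                    n_neo_z_markers = 0L, n_block_markers = 0L,
                    group_sizes = data.frame(
                      sex = "M",
                      population_class = c("pure_inland", "pure_coastal"),
                      n = c(15L, 15L)),
                    divergence = list(fixed_delta = 0.6, freq_min = 0,
                                      freq_max = 1),
                    error_rate = 0, missing_rate = 0)
  cfg$divergence$fixed_delta <- 1   # fully diagnostic loci
  sim <- simulate_dataset(cfg)
  pf <- sim$truth$markers[, c("marker_id", "p_inland", "p_coastal")]
  am <- ancestry_matrix(sim$genotypes, pf)
  inl <- sample_group(sim$samples, population_class = "pure_inland")
  expect_true(all(am$codes[inl, ] == 2L))
})

test_that("haploid female heterozygote calls become unassigned", {
  g <- genotype_matrix(rbind(f1 = 1L, m1 = 1L), markers = "z1")
  pf <- data.frame(marker_id = "z1", p_inland = 1, p_coastal = 0)
  am <- ancestry_matrix(g, pf,
                        ploidy = c(z1 = "haploid_female_codominant_male"),
                        sex = c(f1 = "F", m1 = "M"))
  expect_true(is.na(am$codes["f1", "z1"]))
  expect_equal(unname(am$codes["m1", "z1"]), 1L)
})

test_that("block calls follow the inland-fraction thresholds", {
  markers <- paste0("b", 1:6)
  pf <- data.frame(marker_id = markers, p_inland = 1, p_coastal = 0)
  g <- genotype_matrix(rbind(
    male_het = rep(1L, 6),
    fem_inland = rep(2L, 6),
    fem_coastal = rep(0L, 6),
    sparse = c(2L, rep(NA_integer_, 5))), markers = markers)
  am <- ancestry_matrix(g, pf)
  calls <- call_block_haplotypes(am, markers, min_markers = 5)
  expect_equal(calls$haplotype,
               c("heterozygous", "inland", "coastal", "uncalled"))
  expect_equal(calls$inland_fraction[1], 0.5)
})

test_that("block calls recover simulated truth at low error", {
  cfg <- sim_config(seed = 62, n_autosomal_markers = 0L, n_z_markers = 0L,
                    n_w_markers = 0L, n_neo_w_markers = 0L,
                    n_neo_z_markers = 0L, n_block_markers = 40L,
                    divergence = list(block_inland = 0.95,
                                      block_coastal = 0.05),
                    error_rate = 0.02, missing_rate = 0)
  sim <- simulate_dataset(cfg)
  pf <- sim$truth$markers[, c("marker_id", "p_inland", "p_coastal")]
  am <- ancestry_matrix(sim$genotypes, pf)
  calls <- call_block_haplotypes(am, pf$marker_id)
  truth <- sim$truth$samples$block_genotype[match(calls$sample_id,
                                                  sim$truth$samples$sample_id)]
  expected <- c(II = "inland", IC = "heterozygous", CC = "coastal")[truth]
  expect_gt(mean(calls$haplotype == expected), 0.99)
})

test_that("mito-block association table counts and proportions are coherent", {
  sim <- small_sim()
  calls <- data.frame(
    sample_id = sim$samples$sample_id,
    haplotype = ifelse(sim$samples$mitolineage == "inland",
                       "inland", "coastal"),
    inland_fraction = 0.5, n_block_markers_called = 10)
  assoc <- mito_block_association(calls, sim$samples)
  diag_rows <- assoc$mitolineage == "inland" & assoc$haplotype == "inland"
  expect_true(all(assoc$proportion[diag_rows] == 1))
  off <- assoc$mitolineage == "inland" & assoc$haplotype == "coastal"
  expect_true(all(assoc$proportion[off] == 0))
  expect_equal(nrow(mito_block_association(calls[0, ], sim$samples)), 0)
})

test_that("block merging bridges single-window gaps but not larger ones", {
  # construct window records and tags directly: two flagged stretches
  # separated by > 2 windows must remain two intervals
  map <- marker_map(data.frame(
    marker_id = paste0("m", 1:4),
    chromosome = "1A",
    position = c(100000, 150000, 800000, 850000),
    tag_length = 69))
  g <- genotype_matrix(
    rbind(matrix(2L, 6, 4), matrix(0L, 6, 4)),
    samples = c(paste0("a", 1:6), paste0("b", 1:6)),
    markers = paste0("m", 1:4))
  fst <- fst_per_snp(g, paste0("a", 1:6), paste0("b", 1:6))
  dxy <- dxy_windows(g, map, paste0("a", 1:6), paste0("b", 1:6))
  det <- detect_divergence_block(fst, dxy, map)
  expect_equal(nrow(det), 2)
  expect_true(all(det$chromosome == "1A"))

  # nothing above the floor -> empty result
  g0 <- genotype_matrix(
    matrix(rep(c(0L, 1L, 2L), 8), ncol = 2,
           dimnames = list(c(paste0("a", 1:6), paste0("b", 1:6)),
                           c("m1", "m2"))))
  map0 <- marker_map(data.frame(marker_id = c("m1", "m2"), chromosome = "2",
                                position = c(0, 10), tag_length = 69))
  fst0 <- fst_per_snp(g0, paste0("a", 1:6), paste0("b", 1:6))
  dxy0 <- dxy_windows(g0, map0, paste0("a", 1:6), paste0("b", 1:6))
  expect_equal(nrow(detect_divergence_block(fst0, dxy0, map0)), 0)
})
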
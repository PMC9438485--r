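test_that("simulation is bit-reproducible given the seed", {
  cfg <- read_sim_config(system.file("extdata", "sim_config_small.json",
                                     package = "hzclines"))
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$map, s2$map)
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_parental_frequencies(cfg),
                   simulate_parental_frequencies(cfg))
})

test_that("parental frequency model honors null and fixation modes", {
  cfg_null <- sim_config(seed = 3, divergence = list(null = TRUE))
  pf <- simulate_parental_frequencies(cfg_null)
  nb <- pf$class != "neo_Z_block"
  expect_identical(pf$p_inland[nb], pf$p_coastal[nb])

  cfg_fix <- sim_config(seed = 3, divergence = list(block_inland = 1,
                                                    block_coastal = 0))
  pfx <- simulate_parental_frequencies(cfg_fix)
  blk <- pfx$class == "neo_Z_block"
  expect_true(all(abs(pfx$p_inland[blk] - pfx$p_coastal[blk]) == 1))

  expect_error(sim_config(seed = 1, divergence = list(shape1 = -1)),
               "degenerate Beta")
  expect_error(sim_config(seed = 1,
                          block_interval = list(chromosome = "1A",
                                                start = 5, end = 5)),
               "start must be")
})

test_that("W-linked loci are missing in all males before noise injection", {
  cfg <- sim_config(seed = 7, error_rate = 0, missing_rate = 0)
  sim <- simulate_dataset(cfg)
  wl <- sim$truth$markers$marker_id[sim$truth$markers$class %in%
                                      c("W_linked", "neo_W")]
  males <- sample_group(sim$samples, sex = "M")
  females <- sample_group(sim$samples, sex = "F")
  expect_true(all(is.na(sim$genotypes[males, wl])))
  expect_true(all(!is.na(sim$genotypes[females, wl])))
  # hemizygous female calls are never het
  expect_false(any(sim$genotypes[females, wl] == 1L, na.rm = TRUE))
})

test_that("hybrids at h = 0.5 show Hardy-Weinberg heterozygosity at diagnostic loci", {
  cfg <- sim_config(seed = 8, n_autosomal_markers = 60L, n_z_markers = 0L,
                    n_w_markers = 0L, n_neo_w_markers = 0L,
                    n_neo_z_markers = 0L, n_block_markers = 0L,
                    group_sizes = data.frame(
                      sex = "F", population_class = "hybrid_inland", n = 500L),
                    divergence = list(fixed_delta = 0.6),
                    hybrid_h_distribution = list(inland = c(1e6, 1e6),
                                                 coastal = c(1, 1)),
                    error_rate = 0, missing_rate = 0)
  sim <- simulate_dataset(cfg)
  # h concentrated at 0.5, q = 0.5 at every fixed_delta locus
  het <- mean(sim$genotypes == 1L)
  expect_lt(abs(het - 0.5), 0.02)
})

test_that("underdominance with s = 1 suppresses all heterozygotes", {
  sel <- data.frame(marker_id = sprintf("aut_%04d", 1:20),
                    regime = "underdominant", s = 1)
  cfg <- sim_config(seed = 9, n_autosomal_markers = 20L, n_z_markers = 0L,
                    n_w_markers = 0L, n_neo_w_markers = 0L,
                    n_neo_z_markers = 0L, n_block_markers = 0L,
                    selection = sel, error_rate = 0, missing_rate = 0)
  sim <- simulate_dataset(cfg)
  expect_false(any(sim$genotypes == 1L, na.rm = TRUE))
})

test_that("pure-class allele frequencies converge to parental values", {
  cfg <- sim_config(seed = 10, n_autosomal_markers = 50L, n_z_markers = 0L,
                    n_w_markers = 0L, n_neo_w_markers = 0L,
                    n_neo_z_markers = 0L, n_block_markers = 0L,
                    group_sizes = data.frame(
                      sex = "M", population_class = "pure_inland", n = 2000L),
                    error_rate = 0, missing_rate = 0)
  sim <- simulate_dataset(cfg)
  freq <- allele_frequencies(sim$genotypes, sim$samples$sample_id)
  truth <- sim$truth$markers
  err <- abs(freq$alt_freq - truth$p_inland[match(freq$marker_id,
                                                  truth$marker_id)])
  # binomial SE at n = 2000 individuals is <= 0.0079; allow 4 SE
  expect_lt(max(err), 4 * sqrt(0.25 / 4000))
})

test_that("fully fixed block haplotypes are in perfect within-block LD", {
  cfg <- sim_config(seed = 11, n_autosomal_markers = 0L, n_z_markers = 0L,
                    n_w_markers = 0L, n_neo_w_markers = 0L,
                    n_neo_z_markers = 0L, n_block_markers = 30L,
                    divergence = list(block_inland = 1, block_coastal = 0),
                    error_rate = 0, missing_rate = 0)
  sim <- simulate_dataset(cfg)
  truth <- sim$truth$samples
  for (i in seq_len(nrow(sim$genotypes))) {
    g <- sim$genotypes[i, ]
    bg <- truth$block_genotype[i]
    expected <- switch(bg, II = 2L, CC = 0L, IC = 1L)
    expect_true(all(g == expected))
  }
})

test_that("block positions lie inside the configured interval", {
  sim <- small_sim()
  blk <- sim$truth$markers$marker_id[sim$truth$markers$class == "neo_Z_block"]
  pos <- sim$map$position[match(blk, sim$map$marker_id)]
  chrom <- sim$map$chromosome[match(blk, sim$map$marker_id)]
  expect_true(all(chrom == "1A"))
  expect_true(all(pos >= 51e6 & pos < 59e6))
})

test_that("block_hybrid_freq decouples block genotype from mitolineage", {
  cfg <- sim_config(seed = 12, block_hybrid_freq = 0.5,
                    error_rate = 0, missing_rate = 0)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth$samples
  hyb <- grepl("^hybrid", sim$samples$population_class)
  males <- sim$samples$sex == "M"
  inland_copies <- ifelse(tr$block_genotype == "II", 1,
                          ifelse(tr$block_genotype == "CC", 0, 0.5))
  m_i <- mean(inland_copies[hyb & males & tr$mitolineage == "inland"])
  m_c <- mean(inland_copies[hyb & males & tr$mitolineage == "coastal"])
  expect_lt(abs(m_i - m_c), 0.15)
  # pure classes remain anchored to their lineage
  expect_true(all(tr$block_genotype[sim$samples$population_class ==
                                      "pure_inland"] == "II"))
  expect_true(all(tr$block_genotype[sim$samples$population_class ==
                                      "pure_coastal"] == "CC"))
})
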
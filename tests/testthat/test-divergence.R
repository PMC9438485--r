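test_that("allele frequencies follow dosage counting and flag empty markers", {
  g <- genotype_matrix(rbind(s1 = c(0L, NA, 2L), s2 = c(1L, NA, 2L),
                             s3 = c(2L, NA, 2L)),
                       markers = c("m1", "m2", "m3"))
  f <- allele_frequencies(g, c("s1", "s2", "s3"))
  expect_equal(f$alt_freq, c(0.5, NA, 1))
  expect_true(f$flagged[2])
})

test_that("Weir-Cockerham theta hits its boundary and null cases", {
  expect_equal(fst_wc(c(10, 0, 0), c(0, 0, 10)), 1)
  expect_lte(fst_wc(c(4, 4, 2), c(4, 4, 2)), 0)
  # the spec'd count example agrees with the ANOVA-route oracle
  expect_equal(fst_wc(c(4, 4, 2), c(8, 2, 0)),
               theta_anova_oracle(c(4, 4, 2), c(8, 2, 0)),
               tolerance = 1e-12)
})

test_that("F_ST filters implement the MAF and missingness rules", {
  samples <- c(paste0("a", 1:10), paste0("b", 1:10))
  set.seed(1)
  g <- genotype_matrix(
    cbind(ok = rep(c(0L, 2L), 10),
          rare = c(1L, rep(0L, 19)),              # pooled MAF 0.025
          holey = c(rep(NA_integer_, 10), rep(c(0L, 1L), 5)),  # 50% missing
          neo_holey = c(rep(NA_integer_, 3), rep(c(0L, 2L), 8), 0L)),
    samples = samples, markers = c("ok", "rare", "holey", "neo_holey"))
  tab <- fst_per_snp(g, paste0("a", 1:10), paste0("b", 1:10),
                     neo_markers = "neo_holey")
  expect_true(tab$passed_filters[tab$marker_id == "ok"])
  expect_false(tab$passed_filters[tab$marker_id == "rare"])     # MAF <= 0.05
  expect_false(tab$passed_filters[tab$marker_id == "holey"])    # >= 50% missing
  expect_false(tab$passed_filters[tab$marker_id == "neo_holey"]) # > 10% on neo
  expect_true(is.na(tab$fst[tab$marker_id == "rare"]))
  expect_error(fst_per_snp(g, paste0("a", 1:10), c("a1", paste0("b", 1:9))),
               "overlap")
})

test_that("window DXY matches explicit pairwise counting on built tags", {
  # one 69-bp tag, reciprocal fixation at its single SNP
  g <- genotype_matrix(rbind(a1 = 0L, a2 = 0L, b1 = 2L, b2 = 2L),
                       markers = "m1")
  map <- marker_map(data.frame(marker_id = "m1", chromosome = "1",
                               position = 120000, tag_length = 69))
  d <- dxy_windows(g, map, c("a1", "a2"), c("b1", "b2"))
  expect_equal(nrow(d), 2)  # tag at 120 kb sits in [50k,150k) and [100k,200k)
  expect_equal(d$start, c(50000, 100000))
  expect_equal(d$value, rep(1 / 69, 2), tolerance = 1e-12)

  # multi-SNP tag against the enumeration oracle
  hapA <- rbind(c(0, 0, 1), c(0, 1, 1), c(1, 0, 0), c(0, 0, 0))
  hapB <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 1), c(1, 1, 1))
  gA <- haplotypes_to_genotypes(hapA)
  gB <- haplotypes_to_genotypes(hapB)
  g2 <- genotype_matrix(rbind(gA, gB),
                        samples = c("a1", "a2", "b1", "b2"),
                        markers = c("x1", "x2", "x3"))
  map2 <- marker_map(data.frame(marker_id = c("x1", "x2", "x3"),
                                chromosome = "2", position = 1000,
                                tag_length = 69))
  d2 <- dxy_windows(g2, map2, c("a1", "a2"), c("b1", "b2"))
  expect_equal(d2$value[1], dxy_enumeration_oracle(hapA, hapB, 69),
               tolerance = 1e-12)
  # symmetry in the two groups
  d2r <- dxy_windows(g2, map2, c("b1", "b2"), c("a1", "a2"))
  expect_equal(d2$value, d2r$value, tolerance = 1e-12)
})

test_that("DXY is zero between identical fixed groups", {
  g <- genotype_matrix(rbind(a1 = 2L, a2 = 2L, b1 = 2L, b2 = 2L),
                       markers = "m1")
  map <- marker_map(data.frame(marker_id = "m1", chromosome = "1",
                               position = 10, tag_length = 69))
  d <- dxy_windows(g, map, c("a1", "a2"), c("b1", "b2"))
  expect_equal(d$value, rep(0, nrow(d)))
})

test_that("window pi matches its closed form and the enumeration oracle", {
  g <- genotype_matrix(matrix(c(rep(1L, 5), rep(0L, 3), rep(2L, 2)), ncol = 1,
                              dimnames = list(paste0("s", 1:10), "m1")))
  map <- marker_map(data.frame(marker_id = "m1", chromosome = "1",
                               position = 0, tag_length = 69))
  p <- pi_windows(g, map, paste0("s", 1:10))
  phat <- 9 / 20
  expect_equal(p$value[1], 2 * phat * (1 - phat) * 20 / 19 / 69,
               tolerance = 1e-12)

  hap <- rbind(c(0, 1), c(1, 1), c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  gh <- genotype_matrix(haplotypes_to_genotypes(hap),
                        samples = paste0("s", 1:3), markers = c("y1", "y2"))
  maph <- marker_map(data.frame(marker_id = c("y1", "y2"), chromosome = "1",
                                position = 0, tag_length = 69))
  ph <- pi_windows(gh, maph, paste0("s", 1:3))
  expect_equal(ph$value[1], pi_enumeration_oracle(hap, 69), tolerance = 1e-12)

  # monomorphic group
  gm <- genotype_matrix(matrix(2L, 4, 1, dimnames = list(paste0("s", 1:4), "m1")))
  pm <- pi_windows(gm, map, paste0("s", 1:4))
  expect_equal(pm$value, rep(0, nrow(pm)))

  # single individual: undefined, tag skipped, no windows
  p1 <- pi_windows(g[1, , drop = FALSE], map, "s1")
  expect_equal(nrow(p1), 0)
  expect_error(pi_windows(g, map, paste0("s", 1:10), window = 0), "positive")
})

test_that("differentiated-marker counting is inclusive at the threshold", {
  tab <- function(th) data.frame(marker_id = paste0("m", seq_along(th)),
                                 fst = th, passed_filters = TRUE,
                                 missing_fraction = 0, maf = 0.5)
  res <- count_differentiated(list(a = tab(c(0.19, 0.20, 0.35))))
  expect_equal(res$counts$n_differentiated, 2L)
  res2 <- count_differentiated(list(a = tab(c(0.5, 0.01, 0.01)),
                                    b = tab(c(0.01, 0.6, 0.7))))
  expect_equal(res2$overlaps$overlap, 0L)
  res3 <- count_differentiated(list(a = tab(c(0.5, 0.3, 0.01)),
                                    b = tab(c(0.25, 0.01, 0.9))))
  expect_equal(res3$overlaps$overlap, 1L)
})

test_that("male subsampling reproduces sizes and is seed-stable", {
  sim <- small_sim()
  males <- sample_group(sim$samples, population_class = "hybrid_inland",
                        sex = "M")
  red <- subsample_group(sim$samples, males, 6, seed = 99)
  expect_equal(sum(red$population_class == "hybrid_inland" & red$sex == "M"), 6L)
  expect_identical(red, subsample_group(sim$samples, males, 6, seed = 99))
  expect_identical(subsample_group(sim$samples, males, length(males),
                                   seed = 1)$sample_id,
                   sim$samples$sample_id)
  expect_error(subsample_group(sim$samples, males, length(males) + 1, 1),
               "exceeds")
})

test_that("missingness correlation behaves on degenerate and clean input", {
  tab <- data.frame(marker_id = paste0("m", 1:10),
                    fst = seq(0.01, 0.1, length.out = 10),
                    passed_filters = TRUE,
                    missing_fraction = seq(0, 0.45, length.out = 10),
                    maf = 0.5)
  expect_equal(missingness_fst_correlation(tab)$rho, 1)
  tab$fst <- 0.2
  expect_true(missingness_fst_correlation(tab)$flagged)
  expect_true(missingness_fst_correlation(tab[1:2, ])$flagged)
})

test_that("marker thinning keeps one marker per bin and honors exemptions", {
  map <- marker_map(data.frame(
    marker_id = c("a", "b", "c", "n1", "n2"),
    chromosome = c("1", "1", "1", "1A", "1A"),
    position = c(10000, 90000, 110000, 100, 200),
    tag_length = 69))
  expect_identical(thin_markers(map), c("a", "c", "n1"))
  expect_identical(thin_markers(map, exempt_chromosomes = "1A"),
                   c("a", "c", "n1", "n2"))
})
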
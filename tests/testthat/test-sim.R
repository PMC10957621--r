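# Diallel-cross simulator: founder draws, tetrasomic gametes, read counts,
# phenotype heritability calibration.

test_that("founder dosages follow Binomial(4, p), including degenerate freqs", {
  cfg0 <- sim_config(n_parents = 5, markers_per_chromosome = 10,
                     n_chromosomes = 1, founder_allele_freqs = 0, seed = 3)
  expect_true(all(simulate_founders(cfg0)$dosages == 0))
  cfg1 <- sim_config(n_parents = 5, markers_per_chromosome = 10,
                     n_chromosomes = 1, founder_allele_freqs = 1, seed = 3)
  expect_true(all(simulate_founders(cfg1)$dosages == 4))
  cfg <- sim_config(n_parents = 10000, markers_per_chromosome = 4,
                    n_chromosomes = 1, founder_allele_freqs = 0.5, seed = 11)
  dos <- simulate_founders(cfg)$dosages
  expect_equal(mean(dos), 2.0, tolerance = 0.02)
})

test_that("gamete dosage distribution matches the bivalent-pair enumeration", {
  # oracle: a duplex parent has homologs {1,1,0,0}; a gamete takes one
  # chromatid from each of two random bivalents. Enumerating the 3 pairings
  # x strand choices gives dosage probabilities {0: 1/6, 1: 4/6, 2: 1/6}.
  pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  hom <- c(1L, 1L, 0L, 0L)
  counts <- integer(3)
  for (p in pairings) for (s1 in 1:2) for (s2 in 1:2) {
    d <- hom[p[s1]] + hom[p[2 + s2]]
    counts[d + 1] <- counts[d + 1] + 1L
  }
  oracle <- counts / sum(counts)
  expect_equal(oracle, c(1, 4, 1) / 6)

  set.seed(42)
  mother <- matrix(hom, nrow = 4)          # duplex at one marker
  father <- matrix(0L, nrow = 4, ncol = 1) # nulliplex
  map <- data.frame(chrom = "1", cm = 50)
  off <- simulate_cross(mother, father, map, n = 20000, length_morgans = 0)
  freq <- tabulate(off$dosages + 1L, nbins = 3) / 20000
  expect_equal(freq, oracle, tolerance = 0.02)
})

test_that("offspring dosage is the sum of two gametes, each in 0..2", {
  set.seed(5)
  mother <- matrix(rbinom(4 * 20, 1, 0.5), nrow = 4)
  father <- matrix(0L, nrow = 4, ncol = 20)  # nulliplex everywhere
  map <- data.frame(chrom = "1", cm = seq(5, 100, by = 5))
  off <- simulate_cross(mother, father, map, n = 50)
  expect_true(all(off$dosages >= 0 & off$dosages <= 2))  # paternal gamete is 0
  # nulliplex x nulliplex stays nulliplex
  off0 <- simulate_cross(father, father, map, n = 10)
  expect_true(all(off0$dosages == 0))
  # duplex x duplex at unlinked markers: mid-parent expectation 2
  duplex <- matrix(rep(c(1L, 1L, 0L, 0L), 20), nrow = 4)
  off2 <- simulate_cross(duplex, duplex, map, n = 2000, length_morgans = 1)
  expect_equal(mean(off2$dosages), 2, tolerance = 0.05)
})

test_that("read simulation reflects dosage/4 and records zero depth as missing", {
  cfg <- sim_config(n_parents = 2, mean_depth = 20,
                    depth_dispersion = Inf, sequencing_error = 0, seed = 2)
  set.seed(2)
  dos <- matrix(4L, 50, 20, dimnames = list(paste0("S", 1:50), NULL))
  vt <- simulate_reads(dos, cfg)
  expect_true(all(vt$ref_depth == 0))  # dosage 4, no error: alt reads = depth

  set.seed(3)
  dos2 <- matrix(2L, 500, 200, dimnames = list(paste0("S", 1:500), NULL))
  vt2 <- simulate_reads(dos2, cfg)
  af <- allele_frequency(vt2$ref_depth, vt2$alt_depth)
  expect_equal(mean(af, na.rm = TRUE), 0.5, tolerance = 0.005)

  # zero-depth cells appear as missing genotypes
  cfg_low <- sim_config(n_parents = 2, mean_depth = 1, depth_dispersion = 0.5,
                        sequencing_error = 0, seed = 4)
  set.seed(4)
  vt3 <- simulate_reads(matrix(2L, 30, 30), cfg_low)
  gm <- genotype_matrix(vt3)
  zero <- t(vt3$ref_depth + vt3$alt_depth) == 0
  expect_true(any(zero))
  expect_identical(unname(gm$missing), unname(zero))
})

test_that("phenotype noise is calibrated to the target heritability", {
  set.seed(9)
  tbv <- rnorm(800)
  truth <- list(tbv = setNames(tbv, paste0("C", 1:800)))
  cfg <- sim_config(n_parents = 2, heritability_target = 0.5,
                    year_effects = c(`2013` = 0), reps_per_year = 1, seed = 9)
  ph <- simulate_phenotypes(truth, cfg)
  y <- ph$records$value
  expect_equal(var(tbv) / var(y), 0.5, tolerance = 0.05)
  expect_equal(ph$realized_h2, 0.5, tolerance = 0.05)

  cfg1 <- sim_config(n_parents = 2, heritability_target = 1,
                     year_effects = c(`2013` = 0), reps_per_year = 1, seed = 9)
  ph1 <- simulate_phenotypes(truth, cfg1)
  expect_equal(ph1$records$value, cfg1$mu + tbv, ignore_attr = TRUE)
})

test_that("seeded simulations are reproducible", {
  cfg <- sim_config(n_parents = 4, offspring_per_cross = 2, n_chromosomes = 2,
                    markers_per_chromosome = 15, n_qtl = 3, seed = 77)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$truth$dosages, b$truth$dosages)
  expect_identical(a$reads$alt_depth, b$reads$alt_depth)
  expect_identical(a$phenotypes$value, b$phenotypes$value)
})

test_that("annotation classes approximate the configured fractions", {
  cfg <- sim_config(n_parents = 2, n_chromosomes = 12,
                    markers_per_chromosome = 400, seed = 21)
  map <- simulate_founders(cfg)$map
  frac <- table(map$annotation) / nrow(map)
  expect_lt(abs(frac[["noncoding"]] - 0.63), 0.1)
  expect_lt(abs(frac[["nonsynonymous"]] - 0.18), 0.07)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(annotation_fractions = c(a = 0.5, b = 0.2)),
               "sum to 1")
  expect_error(sim_config(heritability_target = 1.2), "0, 1")
  expect_error(sim_config(sequencing_error = 0.5), "0, 0.1")
  expect_error(sim_config(mean_depth = 0), "positive")
  expect_error(simulate_reads(matrix(5, 2, 2), sim_config(n_parents = 2)),
               "0..4")
})
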
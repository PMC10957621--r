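# Allele-frequency genotypes, marker/individual filters, annotation subsets
# and the marker-reduction series.

test_that("allele frequency is alt over total, missing at zero depth", {
  expect_equal(allele_frequency(6, 2), 0.25)
  expect_equal(allele_frequency(0, 10), 1.0)
  expect_true(is.na(allele_frequency(0, 0)))
  expect_error(allele_frequency(-1, 2), "non-negative")
  # scale-free in the depths
  for (k in c(2, 5, 17)) {
    r <- c(3, 8, 1); a <- c(9, 2, 5)
    expect_equal(allele_frequency(k * r, k * a), allele_frequency(r, a))
  }
})

test_that("marker filters apply MAF, depth and missingness thresholds", {
  # five markers with hand-set mean AFs; last has mean depth 3 (< 5)
  vt <- toy_variant_table(c(0.005, 0.25, 0.5, 0.995), depth = 200L)
  low <- variant_table(
    markers = data.frame(chrom = "1", pos = 5L, id = "T5",
                         annotation = "unannotated"),
    samples = vt$samples,
    ref_depth = matrix(2L, 1, 4), alt_depth = matrix(1L, 1, 4))
  five <- variant_table(rbind(vt$markers, low$markers), vt$samples,
                        rbind(vt$ref_depth, low$ref_depth),
                        rbind(vt$alt_depth, low$alt_depth))
  kept <- filter_markers(five)
  expect_identical(kept$markers$id, c("T2", "T3"))

  # monomorphic all-alt marker removed
  mono <- toy_variant_table(c(1.0, 0.4))
  expect_identical(filter_markers(mono)$markers$id, "T2")

  # 6 of 10 entries missing > 50% -> removed
  vt2 <- toy_variant_table(c(0.5, 0.5), depth = 20L, n_samples = 10)
  vt2$ref_depth[1, 1:6] <- 0L
  vt2$alt_depth[1, 1:6] <- 0L
  expect_identical(filter_markers(vt2, depth_min = 0)$markers$id, "T2")

  expect_error(filter_markers(vt, maf_min = 0.6), "0, 0.5")
})

test_that("marker filters are idempotent", {
  set.seed(10)
  cfg <- sim_config(n_parents = 4, offspring_per_cross = 3, n_chromosomes = 2,
                    markers_per_chromosome = 40, mean_depth = 4, seed = 10)
  vt <- simulate_study(cfg)$reads
  once <- filter_markers(vt)
  twice <- filter_markers(once)
  expect_identical(once$markers$id, twice$markers$id)
  fi_once <- filter_individuals(vt, missing_max = 0.3)
  fi_twice <- filter_individuals(fi_once, missing_max = 0.3)
  expect_identical(fi_once$samples, fi_twice$samples)
})

test_that("individual filter removes samples above the missingness bound", {
  vt <- toy_variant_table(rep(0.5, 100), depth = 10L, n_samples = 3)
  vt$ref_depth[1:71, 2] <- 0L
  vt$alt_depth[1:71, 2] <- 0L
  kept <- filter_individuals(vt)
  expect_identical(kept$samples, c("S1", "S3"))  # 71% missing removed
  all_complete <- toy_variant_table(rep(0.5, 10))
  expect_equal(length(filter_individuals(all_complete)$samples), 4)
})

test_that("annotation subsets partition and the non-coding set is thinned 1-in-3", {
  ann <- c(rep("nonsynonymous", 4), rep("synonymous", 5), rep("noncoding", 9))
  vt <- toy_variant_table(rep(0.4, 18), annotation = ann)
  nc <- subset_by_annotation(vt, "noncoding")
  expect_equal(n_markers(nc), 3)
  expect_identical(nc$markers$pos, c(10L, 13L, 16L))  # ranks 1, 4, 7 of the nc set

  comb <- subset_by_annotation(vt, "combination")
  expect_equal(n_markers(comb), 4 + 5 + 3)
  ns <- subset_by_annotation(vt, "nonsynonymous")
  s <- subset_by_annotation(vt, "synonymous")
  expect_setequal(comb$markers$id,
                  c(ns$markers$id, s$markers$id, nc$markers$id))
  red <- subset_by_annotation(vt, "combination-1in3")
  expect_equal(n_markers(red), 4)

  none <- subset_by_annotation(
    toy_variant_table(rep(0.4, 3), annotation = rep("synonymous", 3)),
    "noncoding")
  expect_equal(n_markers(none), 0)
  expect_error(subset_by_annotation(vt, "exotic"))
})

test_that("reduction series halves to interleaved bins until ~min_markers", {
  vt <- toy_variant_table(rep(0.4, 1000))
  rs <- reduce_markers(vt, min_markers = 150)
  sizes <- tapply(rs$table$n_markers, rs$table$level, unique)
  expect_equal(unname(sizes[["1"]]), 500)
  expect_equal(unname(sizes[["2"]]), 250)
  expect_equal(unname(sizes[["3"]]), 125)
  final <- rs$bins[[paste0(max(rs$table$level), ".1")]]
  expect_equal(length(final), 13)  # every 10th of a 125-marker bin

  # level-1 bins: disjoint, union is the full set, position-interleaved
  b1 <- rs$bins[["1.1"]]; b2 <- rs$bins[["1.2"]]
  expect_length(intersect(b1, b2), 0)
  expect_setequal(c(b1, b2), vt$markers$id)
  ranks <- match(b1, vt$markers$id)
  expect_true(all(ranks %% 2 == 1))

  # all level-2 bins disjoint
  l2 <- rs$bins[paste0("2.", 1:4)]
  expect_equal(length(unique(unlist(l2))), 1000)
})

test_that("reduction bins keep all chromosomes covered", {
  vt <- toy_variant_table(rep(0.4, 960),
                          chrom = rep(as.character(1:12), each = 80))
  rs <- reduce_markers(vt, min_markers = 100)
  for (b in rs$bins) {
    chroms <- vt$markers$chrom[match(b, vt$markers$id)]
    if (length(b) >= 24) expect_equal(length(unique(chroms)), 12)
  }
})

test_that("small tables give a single-level series", {
  vt <- toy_variant_table(rep(0.4, 50))
  rs <- reduce_markers(vt, min_markers = 150)
  expect_equal(nrow(rs$table), 1)
  expect_equal(rs$table$n_markers, 50)
})

test_that("filter pipeline report counts stages", {
  set.seed(12)
  cfg <- sim_config(n_parents = 4, offspring_per_cross = 4, n_chromosomes = 2,
                    markers_per_chromosome = 50, seed = 12)
  vt <- simulate_study(cfg)$reads
  fp <- filter_pipeline(vt)
  expect_identical(fp$report$stage,
                   c("input", "maf+depth+missing", "depth-band+individuals"))
  expect_true(all(diff(fp$report$n_markers) <= 0))
  expect_equal(fp$report$n_markers[3], n_markers(fp$table))
})

test_that("VCF and TSV round-trips preserve the table", {
  set.seed(13)
  cfg <- sim_config(n_parents = 3, offspring_per_cross = 2, n_chromosomes = 2,
                    markers_per_chromosome = 10, seed = 13)
  vt <- simulate_study(cfg)$reads
  f <- tempfile(fileext = ".vcf")
  write_variant_vcf(vt, f)
  back <- read_variant_vcf(f)
  expect_identical(unname(back$ref_depth), unname(vt$ref_depth))
  expect_identical(unname(back$alt_depth), unname(vt$alt_depth))
  expect_identical(back$markers$annotation, vt$markers$annotation)
  expect_identical(back$samples, vt$samples)

  f2 <- tempfile(fileext = ".tsv")
  write_variant_tsv(vt, f2)
  back2 <- read_variant_tsv(f2)
  expect_identical(unname(back2$alt_depth), unname(vt$alt_depth))
  expect_identical(back2$markers$id, vt$markers$id)
})
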
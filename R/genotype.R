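#' Allele frequency from read depths
#'
#' The genotype of a tetraploid sample at a biallelic site is taken as the
#' alternative-allele read fraction, AF = alt / (ref + alt), a continuous
#' dosage on [0, 1] (dosage/4 in expectation). Cells with zero total depth are
#' missing (`NA`).
#'
#' @param ref_depth,alt_depth non-negative integer vectors (recycled).
#' @return numeric vector in [0, 1], `NA` where both depths are 0.
#' @export
allele_frequency <- function(ref_depth, alt_depth) {
  if (any(ref_depth < 0, na.rm = TRUE) || any(alt_depth < 0, na.rm = TRUE))
    stop("read depths must be non-negative")
  tot <- ref_depth + alt_depth
  ifelse(tot > 0, alt_depth / tot, NA_real_)
}

#' Allele-frequency genotype matrix
#'
#' Converts a read-count table into a samples x markers matrix of
#' allele-frequency genotypes, with per-marker mean allele frequencies p_k
#' (over non-missing entries) and per-sample missing fractions.
#'
#' @param table variant_table.
#' @return Object of class `genotype_matrix` with fields `values`
#'   (samples x markers, `NA` = missing), `p` (marker means), `missing`
#'   (logical mask), `sample_missing`, `markers`, `samples`.
#' @export
genotype_matrix <- function(table) {
  af <- allele_frequency(table$ref_depth, table$alt_depth)
  x <- t(af)  # samples x markers
  structure(
    list(values = x,
         p = colMeans(x, na.rm = TRUE),
         missing = is.na(x),
         sample_missing = rowMeans(is.na(x)),
         markers = table$markers,
         samples = table$samples),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$values), "samples x", ncol(x$values),
      "markers;", sprintf("%.1f%%", 100 * mean(x$missing)), "missing\n")
  invisible(x)
}

marker_stats <- function(table) {
  af <- allele_frequency(table$ref_depth, table$alt_depth)
  dp <- total_depth(table)
  list(mean_af = rowMeans(af, na.rm = TRUE),
       mean_depth = rowMeans(dp),
       pooled_af = rowSums(table$alt_depth) / pmax(rowSums(dp), 1L),
       missing = rowMeans(dp == 0))
}

#' Marker quality filters
#'
#' Retains markers with mean allele frequency strictly inside
#' (maf_min, 1 - maf_min), mean read depth within the given bounds, and
#' missing fraction at most `missing_max`. Marker order is preserved.
#' The first-pass defaults are MAF 1%, depth > 5, missingness <= 50%; a
#' second pass conventionally adds an upper depth bound of 60.
#'
#' @param table variant_table.
#' @param maf_min minor-allele-frequency bound in [0, 0.5).
#' @param depth_min retain markers with mean depth strictly above this.
#' @param depth_max optional upper bound (strict); `NULL` for none.
#' @param missing_max maximum marker missing fraction.
#' @param maf_method `"mean_af"` (mean of per-sample allele frequencies,
#'   default) or `"pooled"` (ratio of pooled read counts).
#' @return Filtered variant_table.
#' @export
filter_markers <- function(table, maf_min = 0.01, depth_min = 5,
                           depth_max = NULL, missing_max = 0.5,
                           maf_method = c("mean_af", "pooled")) {
  if (maf_min < 0 || maf_min >= 0.5)
    stop("maf_min must lie in [0, 0.5)")
  maf_method <- match.arg(maf_method)
  st <- marker_stats(table)
  af <- if (maf_method == "mean_af") st$mean_af else st$pooled_af
  keep <- !is.na(af) & af > maf_min & af < 1 - maf_min &
    st$mean_depth > depth_min & st$missing <= missing_max
  if (!is.null(depth_max)) keep <- keep & st$mean_depth < depth_max
  subset_variants(table, markers = keep)
}

#' Individual missingness filter
#'
#' Removes samples whose fraction of missing (zero-depth) markers exceeds
#' `missing_max` (default 70%).
#'
#' @param table variant_table.
#' @param missing_max maximum per-sample missing fraction.
#' @return Filtered variant_table.
#' @export
filter_individuals <- function(table, missing_max = 0.7) {
  miss <- colMeans(total_depth(table) == 0)
  subset_variants(table, samples = miss <= missing_max)
}

#' Annotation-class marker subsets
#'
#' Splits markers by annotation class. The non-coding subset is thinned to
#' every third variant (ordered by chromosome then position), the convention
#' that keeps the three classes at comparable sizes; `"combination"` is the
#' union of the non-synonymous, synonymous and thinned non-coding subsets, and
#' `"combination-1in3"` additionally takes every third marker of that union
#' (the reduced set used for association scans).
#'
#' @param table variant_table with annotation labels.
#' @param class_spec one of `"nonsynonymous"`, `"synonymous"`, `"noncoding"`,
#'   `"combination"`, `"combination-1in3"`.
#' @return variant_table subset.
#' @export
subset_by_annotation <- function(table,
                                 class_spec = c("nonsynonymous", "synonymous",
                                                "noncoding", "combination",
                                                "combination-1in3")) {
  class_spec <- match.arg(class_spec)
  ord <- order(table$markers$chrom, table$markers$pos)
  thin3 <- function(idx) idx[seq_len(length(idx)) %% 3 == 1]
  # class indices in chromosome/position order (thinning is positional)
  pick <- function(cls) ord[table$markers$annotation[ord] == cls]
  idx <- switch(class_spec,
    nonsynonymous = pick("nonsynonymous"),
    synonymous = pick("synonymous"),
    noncoding = thin3(pick("noncoding")),
    combination = sort(c(pick("nonsynonymous"), pick("synonymous"),
                         thin3(pick("noncoding")))),
    `combination-1in3` = {
      comb <- sort(c(pick("nonsynonymous"), pick("synonymous"),
                     thin3(pick("noncoding"))))
      thin3(comb)
    })
  subset_variants(table, markers = sort(idx))
}

#' Iterative marker-density reduction series
#'
#' Produces nested, position-interleaved marker subsets for density-response
#' experiments. Level 1 splits the position-sorted set into two interleaved
#' half-density bins; level 2 into four quarter-density bins; each further
#' level splits the retained bins into interleaved halves and keeps
#' `replicates_per_level` of them (one child per parent bin, alternating
#' parity, so the kept bins cover distinct residue classes). Halving stops
#' when bins would fall below `min_markers`; a final level takes every 10th
#' marker of the first smallest bin.
#'
#' @param table variant_table (positions sorted within chromosome).
#' @param min_markers smallest bin size before the final 1-in-10 reduction.
#' @param replicates_per_level bins retained per level (default 4).
#' @return Object of class `reduction_series`: list with `table` (data.frame
#'   level, bin, n_markers) and `bins` (list of marker-id vectors, named
#'   "level.bin"; level 0 is the full set).
#' @export
reduce_markers <- function(table, min_markers = 150, replicates_per_level = 4) {
  ord <- order(match(table$markers$chrom, unique(table$markers$chrom)),
               table$markers$pos)
  ids <- table$markers$id[ord]
  m <- length(ids)
  bins <- list(`0.1` = ids)
  if (m >= min_markers) {
    current <- list(seq_len(m))  # index vectors into ids, level 0
    level <- 0
    # halve while the bins still hold at least min_markers markers, so the
    # last level produced sits just below the target size
    repeat {
      if (length(current[[1]]) < min_markers) break
      level <- level + 1
      children <- list()
      for (j in seq_along(current)) {
        b <- current[[j]]
        odd <- b[seq(1, length(b), by = 2)]
        even <- b[seq(2, length(b), by = 2)]
        # alternate which child is kept first so retained bins spread over
        # residue classes when more children exist than slots
        children <- c(children,
                      if (j %% 2 == 1) list(odd, even) else list(even, odd))
      }
      if (length(children) > replicates_per_level)
        # one child per parent bin (the alternation above makes their
        # sub-parities alternate, covering all residue classes)
        children <- children[seq(1, by = 2,
                                 length.out = replicates_per_level)]
      current <- children
      for (j in seq_along(current))
        bins[[paste0(level, ".", j)]] <- ids[current[[j]]]
    }
    final <- current[[1]][seq(1, length(current[[1]]), by = 10)]
    bins[[paste0(level + 1, ".1")]] <- ids[final]
  }
  lv <- as.integer(sub("\\..*", "", names(bins)))
  bn <- as.integer(sub(".*\\.", "", names(bins)))
  structure(list(
    table = data.frame(level = lv, bin = bn,
                       n_markers = vapply(bins, length, 0L)),
    bins = bins), class = "reduction_series")
}

#' @export
print.reduction_series <- function(x, ...) {
  cat("reduction_series with", length(x$bins), "bins:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Filter report
#'
#' Convenience wrapper applying the two-pass marker filters and the
#' individual filter, returning the filtered table together with a count
#' table per stage (markers and individuals retained).
#'
#' @param table variant_table.
#' @param maf_min,depth_min,depth_max,missing_max_marker,missing_max_sample
#'   thresholds; see [filter_markers()] and [filter_individuals()].
#' @return list with `table` (filtered variant_table) and `report`
#'   (data.frame stage, n_markers, n_samples).
#' @export
filter_pipeline <- function(table, maf_min = 0.01, depth_min = 5,
                            depth_max = 60, missing_max_marker = 0.5,
                            missing_max_sample = 0.7) {
  rep0 <- data.frame(stage = "input", n_markers = n_markers(table),
                     n_samples = n_samples(table))
  t1 <- filter_markers(table, maf_min = maf_min, depth_min = depth_min,
                       missing_max = missing_max_marker)
  rep1 <- data.frame(stage = "maf+depth+missing", n_markers = n_markers(t1),
                     n_samples = n_samples(t1))
  t2 <- filter_markers(t1, maf_min = 0, depth_min = depth_min,
                       depth_max = depth_max, missing_max = 1)
  t2 <- filter_individuals(t2, missing_max = missing_max_sample)
  rep2 <- data.frame(stage = "depth-band+individuals",
                     n_markers = n_markers(t2), n_samples = n_samples(t2))
  list(table = t2, report = rbind(rep0, rep1, rep2))
}
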
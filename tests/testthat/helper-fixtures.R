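# Fixture builders shared across test files. All fixtures are generated in
# code; none are stored on disk.

# genotype_matrix from a dosage matrix (samples x markers), with exact
# allele-frequency genotypes dosage/4 (read depth 20, no error) and no
# missingness
gm_from_dosages <- function(dos, n_chrom = 1) {
  n <- nrow(dos); m <- ncol(dos)
  if (is.null(rownames(dos))) rownames(dos) <- paste0("S", seq_len(n))
  if (is.null(colnames(dos))) colnames(dos) <- paste0("M", seq_len(m))
  per_chr <- ceiling(m / n_chrom)
  chrom <- as.character(rep(seq_len(n_chrom), each = per_chr)[seq_len(m)])
  pos <- as.integer(stats::ave(seq_len(m), chrom, FUN = seq_along))
  vt <- variant_table(
    markers = data.frame(chrom = chrom, pos = pos, id = colnames(dos),
                         annotation = "unannotated"),
    samples = rownames(dos),
    ref_depth = t(20L - 5L * dos), alt_depth = t(5L * dos))
  genotype_matrix(vt)
}

# iid HWE tetraploid panel: dosages Binomial(4, p_k)
hwe_panel <- function(n, m, freqs = NULL, n_chrom = 1) {
  if (is.null(freqs)) freqs <- stats::runif(m, 0.1, 0.9)
  dos <- matrix(stats::rbinom(n * m, 4L, rep(freqs, each = n)), n, m)
  gm_from_dosages(dos, n_chrom = n_chrom)
}

# polygenic phenotype on a genotype_matrix at a given heritability;
# returns list(y, g) with names matching the samples
polygenic_trait <- function(gm, h2) {
  cz <- center_genotypes(gm)
  g <- drop(cz$Z %*% stats::rnorm(ncol(cz$Z)))
  g <- g / stats::sd(g)
  e <- stats::rnorm(length(g), 0, sqrt((1 - h2) / h2))
  y <- stats::setNames(g + e, rownames(gm$values))
  list(y = y, g = stats::setNames(g, rownames(gm$values)))
}

# hand-built variant table: AFs per marker equal across samples
toy_variant_table <- function(afs, depth = 100L, n_samples = 4,
                              chrom = NULL, annotation = NULL) {
  m <- length(afs)
  alt <- round(afs * depth)
  vt_alt <- matrix(rep(alt, n_samples), m, n_samples)
  vt_ref <- matrix(rep(depth - alt, n_samples), m, n_samples)
  variant_table(
    markers = data.frame(
      chrom = chrom %||% rep("1", m),
      pos = as.integer(stats::ave(seq_len(m), chrom %||% rep("1", m),
                                  FUN = seq_along)),
      id = paste0("T", seq_len(m)),
      annotation = annotation %||% rep("unannotated", m)),
    samples = paste0("S", seq_len(n_samples)),
    ref_depth = vt_ref, alt_depth = vt_alt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
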
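#' Missing-data weights
#'
#' Per-sample correction factor for missing genotypes:
#' w_i = sum_k p_k (1 - p_k) over all loci / the same sum over the loci
#' non-missing in sample i. Samples with complete data get w_i = 1; weights
#' are always >= 1.
#'
#' @param genotypes genotype_matrix.
#' @return numeric vector of weights, one per sample.
#' @export
missing_weights <- function(genotypes) {
  pq <- genotypes$p * (1 - genotypes$p)
  tot <- sum(pq)
  n <- nrow(genotypes$values)
  if (tot == 0)  # no polymorphism anywhere: weights carry no information
    return(stats::setNames(rep(1, n), rownames(genotypes$values)))
  obs <- (!genotypes$missing) %*% pq
  if (any(obs == 0))
    stop("sample(s) with no observed loci: weight undefined")
  stats::setNames(as.numeric(tot / obs), rownames(genotypes$values))
}

#' Centered, missingness-weighted genotype matrix
#'
#' Z_ik = (X_ik - p_k) w_i for observed entries; missing entries are set to
#' 0, which is mean imputation on the centered scale.
#'
#' @param genotypes genotype_matrix.
#' @return Object of class `centered_genotypes`: `Z` (samples x markers),
#'   `w`, `p`, `imputed_fraction`, `markers`, `samples`.
#' @export
center_genotypes <- function(genotypes) {
  w <- missing_weights(genotypes)
  Z <- (genotypes$values - rep(genotypes$p, each = nrow(genotypes$values))) * w
  Z[genotypes$missing] <- 0
  structure(
    list(Z = Z, w = w, p = genotypes$p,
         imputed_fraction = mean(genotypes$missing),
         markers = genotypes$markers, samples = genotypes$samples),
    class = "centered_genotypes")
}

#' Tetraploid-scaled genomic relationship matrix
#'
#' G = Z Z' / c with the global scaling constant c = 0.25 sum_k p_k (1 - p_k),
#' the expected sum of genotypic variances for allele-frequency genotypes in a
#' tetraploid panel (and the expected average diagonal of Z Z'). This is the
#' allele-frequency analogue of the classic marker-based relationship matrix.
#'
#' @param x centered_genotypes or genotype_matrix (centered internally).
#' @return Object of class `grm`: `G` (samples x samples), `c` (scaling
#'   constant), `marker_ids`, `n_markers`.
#' @export
compute_grm <- function(x) {
  if (inherits(x, "genotype_matrix")) x <- center_genotypes(x)
  stopifnot(inherits(x, "centered_genotypes"))
  cc <- 0.25 * sum(x$p * (1 - x$p))
  if (cc <= 0) stop("all markers monomorphic: scaling constant is zero")
  G <- tcrossprod(x$Z) / cc
  dimnames(G) <- list(x$samples, x$samples)
  structure(list(G = G, c = cc, marker_ids = x$markers$id,
                 n_markers = ncol(x$Z)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$G), "samples from", x$n_markers,
      "markers; mean diagonal", sprintf("%.3f", mean(diag(x$G))), "\n")
  invisible(x)
}

#' Principal components of a relationship matrix
#'
#' Eigendecomposition of the symmetric G; scores are eigenvectors scaled by
#' the square roots of their eigenvalues, variance fractions are eigenvalues
#' over the total (negative eigenvalues truncated at zero).
#'
#' @param grm grm object.
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `variance_fraction`,
#'   `eigenvalues`.
#' @export
grm_pca <- function(grm, n_components = 3) {
  n <- nrow(grm$G)
  if (n_components > n) stop("n_components exceeds the number of samples")
  e <- eigen(grm$G, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  k <- seq_len(n_components)
  scores <- e$vectors[, k, drop = FALSE] %*% diag(sqrt(lam[k]), n_components)
  dimnames(scores) <- list(rownames(grm$G), paste0("PC", k))
  list(scores = scores,
       variance_fraction = lam[k] / sum(lam),
       eigenvalues = e$values)
}

#' Leave-one-chromosome-out relationship matrix
#'
#' Rebuilds G from all markers not on the target chromosome, so that a marker
#' tested on that chromosome is not also represented in the polygenic
#' covariance. Marker means and the scaling constant are recomputed on the
#' retained markers.
#'
#' @param genotypes genotype_matrix.
#' @param chromosome chromosome id to exclude.
#' @return grm built from the remaining markers.
#' @export
loco_grm <- function(genotypes, chromosome) {
  chrs <- unique(genotypes$markers$chrom)
  if (length(chrs) < 2)
    stop("leave-one-chromosome-out requires at least 2 chromosomes")
  keep <- genotypes$markers$chrom != as.character(chromosome)
  g <- genotypes
  g$values <- g$values[, keep, drop = FALSE]
  g$missing <- g$missing[, keep, drop = FALSE]
  g$p <- g$p[keep]
  g$markers <- g$markers[keep, , drop = FALSE]
  g$sample_missing <- rowMeans(g$missing)
  compute_grm(g)
}
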
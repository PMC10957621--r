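#' Single-marker mixed-model association scan
#'
#' Tests each marker with y = 1 mu + x_i b_i + g + e, where g ~ N(0, G s_g^2)
#' uses a leave-one-chromosome-out relationship matrix so the tested marker's
#' chromosome does not also feed the polygenic term. Variance components are
#' estimated once per LOCO matrix (null model) and held fixed across that
#' chromosome's markers; per-marker effects come from generalized least
#' squares in the rotated (diagonalized) model with Wald p-values. After the
#' scan, p-values are genomic-control corrected (see [correct_pvalues()]).
#'
#' Unplaced markers on chromosome "0" (pseudomolecules) are tested against
#' the genome-minus-chromosome-0 matrix and are never excluded when other
#' chromosomes are tested, since they cannot double-count a real chromosome.
#'
#' @param genotypes genotype_matrix.
#' @param y named phenotype vector (one value per clone).
#' @param correction `"loco"` (default, mixed model with leave-one-
#'   chromosome-out G), `"full"` (mixed model, single whole-genome G) or
#'   `"none"` (plain regression, no polygenic term — for demonstrating
#'   structure-driven inflation).
#' @param df_correction if `TRUE`, use a t reference with n - 2 df for the
#'   Wald test instead of the large-sample normal (default FALSE).
#' @return Object of class `gwas_scan`: `scan` data.frame (marker, chrom,
#'   pos, maf, beta, se, p_raw, chi2, p_corrected, tested), `lambda_gc`,
#'   `bonferroni` (threshold and -log10), `n_tested`, `n_skipped`.
#' @export
single_marker_scan <- function(genotypes, y,
                               correction = c("loco", "full", "none"),
                               df_correction = FALSE) {
  correction <- match.arg(correction)
  x_all <- genotypes$values
  if (!is.null(names(y)) && !is.null(rownames(x_all))) {
    if (!all(names(y) %in% rownames(x_all)))
      stop("phenotype names not found in genotypes")
    keep <- match(names(y), rownames(x_all))
    genotypes$values <- genotypes$values[keep, , drop = FALSE]
    genotypes$missing <- genotypes$missing[keep, , drop = FALSE]
    genotypes$p <- colMeans(genotypes$values, na.rm = TRUE)
    x_all <- genotypes$values
  }
  n <- length(y)
  mk <- genotypes$markers
  chrs <- unique(mk$chrom)
  if (correction == "loco" && length(chrs) < 2)
    stop("leave-one-chromosome-out requires at least 2 chromosomes")
  # mean imputation of missing genotype cells for testing
  ximp <- x_all
  for (j in which(colSums(is.na(ximp)) > 0))
    ximp[is.na(ximp[, j]), j] <- genotypes$p[j]
  res <- data.frame(marker = mk$id, chrom = mk$chrom, pos = mk$pos,
                    maf = pmin(genotypes$p, 1 - genotypes$p),
                    beta = NA_real_, se = NA_real_, p_raw = NA_real_,
                    tested = FALSE)
  scan_chrom <- function(cols, U, vfull) {
    # weighted (GLS) simple regression with intercept in the rotated model
    Xr <- crossprod(U, ximp[, cols, drop = FALSE])
    yr <- drop(crossprod(U, y))
    one <- drop(crossprod(U, rep(1, n)))
    w <- 1 / vfull
    sw <- sum(one * one * w)
    for (k in seq_along(cols)) {
      x <- Xr[, k]
      sxx <- sum(x * x * w); sx1 <- sum(x * one * w)
      sxy <- sum(x * yr * w); s1y <- sum(one * yr * w)
      det <- sw * sxx - sx1^2
      if (det <= 1e-12 * sw * max(sxx, 1e-300)) next
      beta <- (sw * sxy - sx1 * s1y) / det
      se <- sqrt(sw / det)
      res$beta[cols[k]] <<- beta
      res$se[cols[k]] <<- se
      z <- beta / se
      p <- if (df_correction) 2 * stats::pt(-abs(z), df = n - 2)
           else 2 * stats::pnorm(-abs(z))
      # guard against underflow so chi-squared back-conversion stays finite
      res$p_raw[cols[k]] <<- max(p, 1e-300)
      res$tested[cols[k]] <<- TRUE
    }
  }
  mono <- apply(ximp, 2, stats::var) == 0
  if (correction == "none") {
    U <- diag(n); vfull <- rep(1, n)
    scan_chrom(which(!mono), U, vfull)
  } else {
    for (ch in chrs) {
      cols <- which(mk$chrom == ch & !mono)
      if (!length(cols)) next
      grm <- if (correction == "loco") loco_grm(genotypes, ch)
             else compute_grm(genotypes)
      fit <- fit_gblup(grm, y)
      vfull <- fit$sigma_g2 * fit$d + fit$sigma_e2
      scan_chrom(cols, fit$eigen$vectors, vfull)
    }
  }
  res$chi2 <- ifelse(res$tested,
                     stats::qchisq(res$p_raw, 1, lower.tail = FALSE), NA)
  scan <- structure(list(scan = res,
                         lambda_gc = NA_real_,
                         bonferroni = NULL,
                         n_tested = sum(res$tested),
                         n_skipped = sum(!res$tested)),
                    class = "gwas_scan")
  correct_pvalues(scan)
}

#' Genomic inflation factor
#'
#' lambda_gc = median of the chi-squared quantiles of the p-values divided by
#' the expected null median, the 0.5 quantile of chi-squared(1) (0.45494).
#'
#' @param p_values raw p-values in (0, 1].
#' @return lambda_gc.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (!length(p_values)) stop("no p-values supplied")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  chi2 <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chi2) / stats::qchisq(0.5, df = 1)
}

#' Genomic-control p-value correction
#'
#' When lambda_gc > 1, each p-value's chi-squared quantile is divided by the
#' inflation factor and converted back through the chi-squared(1) tail:
#' p_corrected = 1 - F(chi2 / lambda). When lambda_gc <= 1 the p-values are
#' left unchanged. Also (re)computes the Bonferroni threshold 0.05/N.
#'
#' @param scan gwas_scan.
#' @param alpha overall significance level for the Bonferroni threshold.
#' @return gwas_scan with `lambda_gc`, `p_corrected` and `bonferroni` filled.
#' @export
correct_pvalues <- function(scan, alpha = 0.05) {
  res <- scan$scan
  tested <- which(res$tested)
  lam <- genomic_inflation(res$p_raw[tested])
  res$p_corrected <- res$p_raw
  if (lam > 1)
    res$p_corrected[tested] <- stats::pchisq(res$chi2[tested] / lam, df = 1,
                                             lower.tail = FALSE)
  scan$scan <- res
  scan$lambda_gc <- lam
  scan$bonferroni <- bonferroni_threshold(length(tested), alpha)
  scan
}

#' Bonferroni significance threshold
#'
#' @param n_markers number of markers tested.
#' @param alpha overall significance level.
#' @return list with `threshold` (alpha / N) and `neg_log10`.
#' @export
bonferroni_threshold <- function(n_markers, alpha = 0.05) {
  if (n_markers < 1) stop("n_markers must be >= 1")
  thr <- alpha / n_markers
  list(threshold = thr, neg_log10 = -log10(thr))
}

#' Percent phenotypic variance explained by a marker
#'
#' PVE = 2 b^2 f(1-f) / (2 b^2 f(1-f) + se^2 2 n f(1-f)), reported in
#' percent, with f the minor allele frequency, b the marker effect, se its
#' standard error and n the sample size.
#'
#' @param beta,se marker effect and standard error (se > 0).
#' @param maf minor allele frequency in (0, 0.5].
#' @param n sample size.
#' @return PVE in percent.
#' @export
pve <- function(beta, se, maf, n) {
  if (any(se <= 0) || any(maf <= 0) || any(maf > 0.5) || any(n < 1))
    stop("need se > 0, maf in (0, 0.5], n >= 1")
  fq <- 2 * maf * (1 - maf)
  100 * (beta^2 * fq) / (beta^2 * fq + se^2 * 2 * n * maf * (1 - maf))
}

#' Significant association hits
#'
#' Markers whose corrected p-value falls below the Bonferroni threshold,
#' with their percent variance explained.
#'
#' @param scan gwas_scan.
#' @param n sample size used for the PVE denominator.
#' @return data.frame (marker, chrom, pos, beta, se, p_corrected, pve).
#' @export
significant_hits <- function(scan, n) {
  res <- scan$scan
  hit <- which(res$tested & res$p_corrected < scan$bonferroni$threshold)
  if (!length(hit))
    return(data.frame(marker = character(0), chrom = character(0),
                      pos = integer(0), beta = numeric(0), se = numeric(0),
                      p_corrected = numeric(0), pve = numeric(0)))
  data.frame(marker = res$marker[hit], chrom = res$chrom[hit],
             pos = res$pos[hit], beta = res$beta[hit], se = res$se[hit],
             p_corrected = res$p_corrected[hit],
             pve = pve(res$beta[hit], res$se[hit],
                       pmax(pmin(res$maf[hit], 0.5), 1e-6), n))
}

#' Manhattan and QQ plot data
#'
#' @param scan gwas_scan.
#' @return list with `manhattan` (chrom, pos, neg_log10_p for each tested
#'   marker) and `qq` (expected, observed -log10 p pairs, ascending expected;
#'   expected quantiles -log10((rank - 0.5)/N)).
#' @export
export_plots_data <- function(scan) {
  res <- scan$scan[scan$scan$tested, ]
  obs <- sort(-log10(res$p_corrected))
  N <- nrow(res)
  list(
    manhattan = data.frame(chrom = res$chrom, pos = res$pos,
                           neg_log10_p = -log10(res$p_corrected)),
    qq = data.frame(expected = sort(-log10((seq_len(N) - 0.5) / N)),
                    observed = obs))
}

#' @export
print.gwas_scan <- function(x, ...) {
  cat(sprintf(
    "gwas_scan: %d markers tested (%d skipped), lambda_gc = %.3f, Bonferroni p < %.3g\n",
    x$n_tested, x$n_skipped, x$lambda_gc, x$bonferroni$threshold))
  invisible(x)
}
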
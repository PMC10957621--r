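# Single-ratio REML machinery for y = 1 mu + g + e, g ~ N(0, G sg2),
# e ~ N(0, I se2), worked on the eigendecomposition of G: with G = U D U',
# rotate y* = U'y, X* = U'1; then V* = sg2 (D + delta I) is diagonal with
# delta = se2/sg2 and the REML log-likelihood profiles sg2 out analytically.

reml_profile <- function(log_delta, d, yt, Xt) {
  delta <- exp(log_delta)
  v <- d + delta
  w <- 1 / v
  XtWX <- crossprod(Xt, Xt * w)
  XtWy <- crossprod(Xt, yt * w)
  beta <- solve(XtWX, XtWy)
  r <- yt - Xt %*% beta
  np <- length(yt) - ncol(Xt)
  ss <- sum(r^2 * w)
  sg2 <- ss / np
  ll <- -0.5 * (np * log(sg2) + sum(log(v)) +
                  determinant(XtWX, logarithm = TRUE)$modulus + np)
  list(ll = as.numeric(ll), beta = beta, sg2 = sg2, se2 = sg2 * delta,
       delta = delta)
}

reml_eigen <- function(d, yt, Xt, interval = c(-12, 12)) {
  opt <- stats::optimize(function(ld) reml_profile(ld, d, yt, Xt)$ll,
                         interval = interval, maximum = TRUE, tol = 1e-8)
  fit <- reml_profile(opt$maximum, d, yt, Xt)
  # boundary handling: delta at the edges means a (near-)degenerate ratio
  fit$loglik <- opt$objective
  fit$boundary <- abs(opt$maximum - interval[1]) < 1e-6 ||
    abs(opt$maximum - interval[2]) < 1e-6
  fit
}

grm_matrix <- function(G) {
  if (inherits(G, "grm")) G$G else as.matrix(G)
}

#' Fit an additive GBLUP model
#'
#' y = 1 mu + g + e with g ~ N(0, G sigma_g^2). Variance components are
#' estimated by REML with the variance ratio profiled on the
#' eigendecomposition of G (deterministic, no sampling); GEBVs are the BLUP
#' solutions g_hat = sigma_g^2 G V^{-1} (y - 1 mu_hat).
#'
#' @param G grm object or a symmetric relationship matrix.
#' @param y named numeric vector of (corrected) phenotypes; names are
#'   matched against G's sample ids when present.
#' @param ridge diagonal ridge added only if the eigenvalues indicate a
#'   numerically indefinite G (default 1e-6).
#' @return Object of class `trait_fit`: `mu`, `sigma_g2`, `sigma_e2`, `h2`,
#'   `gebv` (named, centered near 0), `loglik`, `boundary`, plus the
#'   eigendecomposition reused by predictors.
#' @export
fit_gblup <- function(G, y, ridge = 1e-6) {
  Gm <- grm_matrix(G)
  if (!is.null(names(y)) && !is.null(rownames(Gm))) {
    if (!all(names(y) %in% rownames(Gm)))
      stop("phenotype names not found in G")
    Gm <- Gm[names(y), names(y)]
  }
  n <- length(y)
  if (n < 10) stop("need at least 10 phenotyped samples")
  if (stats::var(y) == 0) stop("zero phenotypic variance")
  e <- eigen(Gm, symmetric = TRUE)
  d <- e$values
  if (min(d) < -1e-6 * max(abs(d))) d <- d + ridge
  d <- pmax(d, 0)
  yt <- crossprod(e$vectors, y)
  Xt <- crossprod(e$vectors, rep(1, n))
  fit <- reml_eigen(d, yt, Xt)
  res_t <- yt - Xt %*% fit$beta
  # g_hat = sg2 G V^-1 r = U diag(d/(d+delta)) U' r
  gebv <- e$vectors %*% (d / (d + fit$delta) * res_t)
  structure(list(
    mu = as.numeric(fit$beta), sigma_g2 = fit$sg2, sigma_e2 = fit$se2,
    h2 = fit$sg2 / (fit$sg2 + fit$se2),
    gebv = stats::setNames(as.numeric(gebv), names(y) %||% rownames(Gm)),
    loglik = fit$loglik, boundary = fit$boundary,
    eigen = e, d = d, delta = fit$delta),
    class = "trait_fit")
}

#' @export
print.trait_fit <- function(x, ...) {
  cat(sprintf(
    "trait_fit: mu = %.3f, sigma_g2 = %.4f, sigma_e2 = %.4f, h2 = %.3f\n",
    x$mu, x$sigma_g2, x$sigma_e2, x$h2))
  invisible(x)
}

# predict GEBVs for held-out samples by relationship propagation:
# g_test = sg2 G[test,train] V_train^{-1} (y_train - mu)
predict_masked <- function(Gm, train, test, y_train, fit) {
  Vtr <- fit$sigma_g2 * Gm[train, train, drop = FALSE]
  diag(Vtr) <- diag(Vtr) + fit$sigma_e2
  rhs <- solve(Vtr, y_train - fit$mu)
  fit$sigma_g2 * drop(Gm[test, train, drop = FALSE] %*% rhs)
}

#' Genomic heritability
#'
#' REML estimate of the genomic narrow-sense heritability
#' h_g^2 = sigma_g^2 / (sigma_g^2 + sigma_e^2).
#'
#' @param G grm or relationship matrix.
#' @param y phenotypes (one value per clone).
#' @return h_g^2 in [0, 1].
#' @export
genomic_heritability <- function(G, y) {
  fit <- fit_gblup(G, y)
  fit$h2
}

#' Prediction bias
#'
#' Ordinary least-squares slope of observed values on predicted values;
#' 1 means the predicted amplitude is calibrated, < 1 that extreme
#' predictions over-state the phenotype.
#'
#' @param observed,predicted numeric vectors.
#' @return slope beta.
#' @export
prediction_bias <- function(observed, predicted) {
  if (stats::var(predicted) == 0)
    stop("constant predictions: bias slope undefined")
  stats::cov(observed, predicted) / stats::var(predicted)
}

#' k-fold cross-validated genomic prediction
#'
#' Randomly partitions the clones into `folds` groups; each group in turn is
#' masked, the model is refit on the remainder and the masked GEBVs are
#' predicted through the relationship matrix. The scheme is repeated
#' `repeats` times with fresh partitions; the headline GEBV per clone is the
#' average across repeats.
#'
#' @param G grm or relationship matrix.
#' @param y named phenotype vector.
#' @param folds,repeats cross-validation layout (defaults 8 x 10).
#' @param seed optional seed for the partitions.
#' @return Object of class `cv_result`: `per_repeat` (data.frame repeat, r,
#'   bias), `mean_gebv`, `r_mean` (correlation of the averaged GEBVs with
#'   y), `bias_mean`, `folds`, `repeats`.
#' @export
cross_validate <- function(G, y, folds = 8, repeats = 10, seed = NULL) {
  if (folds < 2) stop("folds must be >= 2")
  Gm <- grm_matrix(G)
  if (!is.null(names(y)) && !is.null(rownames(Gm)))
    Gm <- Gm[names(y), names(y)]
  n <- length(y)
  if (n < folds) stop("more folds than samples")
  if (!is.null(seed)) set.seed(seed)
  pred <- matrix(NA_real_, n, repeats)
  per <- data.frame(rep = seq_len(repeats), r = NA_real_, bias = NA_real_)
  for (r in seq_len(repeats)) {
    grp <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      test <- which(grp == f)
      train <- which(grp != f)
      fit <- fit_gblup(Gm[train, train, drop = FALSE], y[train])
      pred[test, r] <- predict_masked(Gm, train, test, y[train], fit)
    }
    per$r[r] <- stats::cor(pred[, r], y)
    per$bias[r] <- prediction_bias(y, pred[, r])
  }
  mean_gebv <- rowMeans(pred)
  names(mean_gebv) <- names(y)
  structure(list(per_repeat = per, mean_gebv = mean_gebv,
                 r_mean = stats::cor(mean_gebv, y),
                 bias_mean = prediction_bias(y, mean_gebv),
                 folds = folds, repeats = repeats),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "cv_result (%d-fold x %d): r = %.3f +/- %.3f, bias = %.3f (mean-GEBV r = %.3f)\n",
    x$folds, x$repeats, mean(x$per_repeat$r), stats::sd(x$per_repeat$r),
    mean(x$per_repeat$bias), x$r_mean))
  invisible(x)
}

#' Pairwise Welch comparisons of prediction accuracies
#'
#' Welch two-sample t-tests between groups of per-repeat correlation
#' coefficients, with the significance level Bonferroni-corrected to
#' alpha / (number of pairs).
#'
#' @param r_samples named list of numeric vectors (per-repeat correlations
#'   per marker set).
#' @param alpha overall significance level.
#' @return data.frame with group pair, t, df, p, the corrected level and a
#'   significance flag.
#' @export
compare_accuracies <- function(r_samples, alpha = 0.05) {
  stopifnot(length(r_samples) >= 2)
  nm <- names(r_samples) %||% paste0("set", seq_along(r_samples))
  pairs <- utils::combn(seq_along(r_samples), 2)
  n_tests <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(n_tests), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a <- r_samples[[i]]; b <- r_samples[[j]]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b))))
        return(data.frame(group1 = nm[i], group2 = nm[j], t = 0,
                          df = length(a) + length(b) - 2, p = 1))
      stop("zero within-group variance in both groups")
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(group1 = nm[i], group2 = nm[j],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  }))
  out$alpha_corrected <- alpha / n_tests
  out$significant <- out$p < out$alpha_corrected
  out
}

#' Prediction response to marker density
#'
#' Runs cross-validated GBLUP on every bin of a marker-reduction series
#' (plus the full set), rebuilding the relationship matrix from each bin's
#' markers.
#'
#' @param genotypes genotype_matrix (all markers).
#' @param y named phenotype vector.
#' @param series reduction_series from [reduce_markers()].
#' @param folds,repeats,seed cross-validation settings.
#' @return data.frame (level, bin, n_markers, rep, r, bias) in long format.
#' @export
density_response <- function(genotypes, y, series, folds = 8, repeats = 10,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_along(series$bins), function(b) {
    ids <- series$bins[[b]]
    keep <- genotypes$markers$id %in% ids
    g <- genotypes
    g$values <- g$values[, keep, drop = FALSE]
    g$missing <- g$missing[, keep, drop = FALSE]
    g$p <- g$p[keep]
    g$markers <- g$markers[keep, , drop = FALSE]
    cv <- cross_validate(compute_grm(g), y, folds = folds, repeats = repeats)
    data.frame(level = series$table$level[b], bin = series$table$bin[b],
               n_markers = sum(keep), rep = cv$per_repeat$rep,
               r = cv$per_repeat$r, bias = cv$per_repeat$bias)
  })
  do.call(rbind, out)
}
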
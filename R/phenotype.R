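#' Tuber dry-matter content from under-water weighing
#'
#' Empirical conversion of the air and under-water weights of a tuber batch
#' to dry-matter percent:
#' DM\\[\\%\\] = 214 ((W_air / (W_air - W_water)) - 0.988).
#'
#' @param weight_air,weight_water batch weights (same units); requires
#'   weight_air > weight_water >= 0.
#' @return dry-matter content in percent.
#' @export
dry_matter <- function(weight_air, weight_water) {
  if (any(weight_water < 0) || any(weight_air <= weight_water))
    stop("need weight_air > weight_water >= 0")
  214 * (weight_air / (weight_air - weight_water) - 0.988)
}

#' Tuber length/width ratio
#'
#' Length is defined as the longest measure; inputs given the other way
#' round are re-oriented before division, so the ratio is always >= 1.
#'
#' @param length,width tuber measures (mm); both must be positive.
#' @return length/width ratio.
#' @export
lw_ratio <- function(length, width) {
  if (any(length <= 0) || any(width <= 0))
    stop("measures must be positive")
  pmax(length, width) / pmin(length, width)
}

# Dixon r10 two-tailed critical values (Rorabacher 1991), n = 3..30.
.dixon_q95 <- c(0.970, 0.829, 0.710, 0.625, 0.568, 0.526, 0.493, 0.466,
                0.444, 0.426, 0.410, 0.396, 0.384, 0.374, 0.365, 0.356,
                0.349, 0.342, 0.337, 0.331, 0.326, 0.321, 0.317, 0.312,
                0.308, 0.305, 0.301, 0.298)
.dixon_q99 <- c(0.994, 0.926, 0.821, 0.740, 0.680, 0.634, 0.598, 0.568,
                0.542, 0.522, 0.503, 0.488, 0.475, 0.463, 0.452, 0.442,
                0.433, 0.425, 0.418, 0.411, 0.404, 0.399, 0.393, 0.388,
                0.384, 0.380, 0.376, 0.372)

#' Dixon Q critical value
#'
#' Tabulated two-tailed r10 critical values for n <= 30; for 30 < n <= 200
#' the tabulated tail (n = 15..30) is extrapolated by a log-log regression
#' log Q = a + b log n, giving the smooth power-law decay the table follows.
#'
#' @param n batch size (3..200).
#' @param confidence 0.95 or 0.99.
#' @return critical Q value.
#' @export
dixon_qcrit <- function(n, confidence = 0.95) {
  tab <- if (abs(confidence - 0.95) < 1e-9) .dixon_q95
         else if (abs(confidence - 0.99) < 1e-9) .dixon_q99
         else stop("tabulated confidence levels are 0.95 and 0.99")
  if (any(n < 3) || any(n > 200)) stop("n must lie in 3..200")
  out <- numeric(length(n))
  small <- n <= 30
  out[small] <- tab[n[small] - 2]
  if (any(!small)) {
    nn <- 15:30
    fit <- stats::lm(log(tab[nn - 2]) ~ log(nn))
    out[!small] <- exp(stats::predict(fit,
                                      newdata = data.frame(nn = n[!small])))
  }
  out
}

#' Dixon's Q outlier test
#'
#' Two-tailed single-pass nearest-neighbour gap test on the batch extremes:
#' for each extreme, Q = gap to its nearest neighbour / range; the extreme is
#' flagged when Q exceeds the critical value. At most the two extremes can be
#' flagged per pass. Applied to tuber length and width batches before ratio
#' computation.
#'
#' @param values numeric vector (n >= 3; smaller batches pass through with a
#'   warning).
#' @param confidence confidence level for the critical value.
#' @return list with `values` (retained), `outlier` (logical flags aligned
#'   to the input), `q` (the two computed statistics, low/high).
#' @export
dixon_outliers <- function(values, confidence = 0.95) {
  n <- length(values)
  flag <- rep(FALSE, n)
  if (n < 3) {
    warning("fewer than 3 values: no outlier test performed")
    return(list(values = values, outlier = flag, q = c(low = NA, high = NA)))
  }
  s <- sort(values)
  rng <- s[n] - s[1]
  if (rng == 0)
    return(list(values = values, outlier = flag, q = c(low = 0, high = 0)))
  q_low <- (s[2] - s[1]) / rng
  q_high <- (s[n] - s[n - 1]) / rng
  crit <- dixon_qcrit(n, confidence)
  if (q_low > crit) flag[which(values == s[1])[1]] <- TRUE
  if (q_high > crit) flag[which(values == s[n])[1]] <- TRUE
  list(values = values[!flag], outlier = flag,
       q = c(low = q_low, high = q_high))
}

#' Year-effect correction of multi-year phenotypes
#'
#' Fits the linear mixed model y_ij = mu + genotype_i + year_j + e_ij by REML
#' (genotype random, year fixed) and carries forward one corrected value per
#' clone: the overall mean (average fitted fixed effect) plus the genotype
#' BLUP. Single-year data degenerates to centered clone means. With
#' `method = "means"`, estimated year effects are regressed out and the
#' per-clone residual means are used instead of BLUPs (no shrinkage).
#'
#' @param records data.frame with columns clone, trait, year, rep, value.
#' @param trait optional trait name to select from `records`.
#' @param method `"blup"` (default) or `"means"`.
#' @return Object of class `corrected_phenotypes`: `values` (named vector,
#'   one per clone), `mu`, `year_effects` (fixed-effect estimates),
#'   `var_genotype`, `var_residual`.
#' @export
correct_year_effects <- function(records, trait = NULL,
                                 method = c("blup", "means")) {
  method <- match.arg(method)
  if (!is.null(trait)) records <- records[records$trait == trait, ]
  records <- records[!is.na(records$value), ]
  if (nrow(records) < 2) stop("need at least two phenotype records")
  records$clone <- as.character(records$clone)
  records$year <- factor(records$year)
  if (nlevels(records$year) == 1 || length(unique(records$clone)) < 2 ||
      method == "means") {
    if (nlevels(records$year) > 1) {
      fit <- stats::lm(value ~ year, data = records)
      yr <- stats::coef(fit)[-1]
      adj <- records$value - stats::predict(fit) + mean(stats::fitted(fit))
    } else {
      yr <- numeric(0)
      adj <- records$value
    }
    vals <- tapply(adj, records$clone, mean)
    res <- structure(list(
      values = vals, mu = mean(adj), year_effects = yr,
      var_genotype = stats::var(vals),
      var_residual = mean(tapply(adj, records$clone, stats::var),
                          na.rm = TRUE)),
      class = "corrected_phenotypes")
    return(res)
  }
  fit <- lme4::lmer(value ~ year + (1 | clone), data = records, REML = TRUE)
  fe <- lme4::fixef(fit)
  mu <- mean(stats::model.matrix(fit) %*% fe)
  blup <- lme4::ranef(fit)$clone
  vc <- as.data.frame(lme4::VarCorr(fit))
  vals <- stats::setNames(mu + blup[, 1], rownames(blup))
  structure(list(
    values = vals[sort(unique(records$clone))], mu = mu,
    year_effects = fe[-1],
    var_genotype = vc$vcov[vc$grp == "clone"],
    var_residual = vc$vcov[vc$grp == "Residual"]),
    class = "corrected_phenotypes")
}

#' @export
print.corrected_phenotypes <- function(x, ...) {
  cat("corrected_phenotypes:", length(x$values), "clones; mu =",
      sprintf("%.3f", x$mu), "; var_g =", sprintf("%.3f", x$var_genotype),
      "; var_e =", sprintf("%.3f", x$var_residual), "\n")
  invisible(x)
}
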
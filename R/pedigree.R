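#' Mid-parent regression heritability
#'
#' Narrow-sense heritability estimated as the ordinary least-squares slope of
#' the offspring phenotype on the mid-parent value (the mean of the two
#' parental phenotypes), reported in percent. Trios with a missing parental
#' (or offspring) phenotype are excluded; reciprocal crosses count as
#' distinct trios.
#'
#' @param pedigree data.frame with columns clone, mother, father.
#' @param phenotypes named numeric vector (or data.frame clone, value) of
#'   per-clone phenotypes covering offspring and parents.
#' @return list with `h2_percent`, `slope`, `se`, `n_trios`, `n_excluded`.
#' @export
midparent_heritability <- function(pedigree, phenotypes) {
  if (is.data.frame(phenotypes))
    phenotypes <- stats::setNames(phenotypes$value, phenotypes$clone)
  off <- phenotypes[pedigree$clone]
  mo <- phenotypes[pedigree$mother]
  fa <- phenotypes[pedigree$father]
  ok <- !is.na(off) & !is.na(mo) & !is.na(fa)
  if (sum(ok) < 3) stop("need at least 3 complete trios")
  mid <- (mo[ok] + fa[ok]) / 2
  if (stats::var(mid) == 0) stop("constant mid-parent values: slope undefined")
  fit <- stats::lm(off[ok] ~ mid)
  sm <- summary(fit)$coefficients
  list(h2_percent = 100 * unname(sm["mid", "Estimate"]),
       slope = unname(sm["mid", "Estimate"]),
       se = unname(sm["mid", "Std. Error"]),
       n_trios = sum(ok), n_excluded = sum(!ok))
}
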
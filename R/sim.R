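#' Simulation configuration for a diallel-cross tetraploid population
#'
#' Defaults emulate the study design the package targets: 18 tetraploid
#' founders crossed in a full diallel (all ordered parent pairs, reciprocals
#' distinct, no selfing), 12 chromosomes with linked biallelic markers,
#' low-depth sequencing read counts whose alt-read fraction reflects allele
#' dosage/4, and additive polygenic + major-QTL phenotypes with year effects
#' scaled to a target heritability.
#'
#' @param n_parents number of tetraploid founders.
#' @param crosses `"full-diallel"` or a 2-column matrix/data.frame of
#'   (mother, father) founder indices; partial lists emulate sterile fathers.
#' @param offspring_per_cross clones per cross.
#' @param n_chromosomes,markers_per_chromosome genome layout.
#' @param chromosome_length_morgans genetic length per chromosome (Haldane
#'   map, crossovers Poisson with this mean per bivalent).
#' @param founder_allele_freqs per-marker allele frequencies in (0,1), a
#'   single value, or `NULL` to draw Uniform(0.05, 0.95).
#' @param annotation_fractions named proportions for nonsynonymous,
#'   synonymous and noncoding classes (must sum to 1).
#' @param n_qtl,qtl_effects number of QTL markers and their additive
#'   per-alt-allele-copy effects (`NULL` draws standard normal effects).
#' @param heritability_target narrow-sense heritability of simulated
#'   phenotypes in (0, 1]; residual variance is solved from it.
#' @param mu trait grand mean.
#' @param year_effects named numeric vector of additive year effects.
#' @param reps_per_year replicates per year (recycled over years).
#' @param mean_depth,depth_dispersion negative-binomial read-depth mean and
#'   size (dispersion; `Inf` gives Poisson depth).
#' @param sequencing_error per-read miscall rate in [0, 0.1].
#' @param seed integer seed applied by the simulation entry points.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_parents = 18, crosses = "full-diallel",
                       offspring_per_cross = 3, n_chromosomes = 12,
                       markers_per_chromosome = 100,
                       chromosome_length_morgans = 1.0,
                       founder_allele_freqs = NULL,
                       annotation_fractions = c(nonsynonymous = 0.18,
                                                synonymous = 0.19,
                                                noncoding = 0.63),
                       n_qtl = 5, qtl_effects = NULL,
                       heritability_target = 0.5, mu = 20,
                       year_effects = c(`2013` = 0, `2014` = 1.5),
                       reps_per_year = c(1, 2),
                       mean_depth = 8, depth_dispersion = 2,
                       sequencing_error = 0.005, seed = 1L) {
  if (abs(sum(annotation_fractions) - 1) > 1e-8)
    stop("annotation_fractions must sum to 1")
  if (heritability_target < 0 || heritability_target > 1)
    stop("heritability_target must lie in [0, 1]")
  if (heritability_target == 0 && n_qtl > 0)
    stop("heritability_target = 0 with QTL effects implies infinite noise")
  if (sequencing_error < 0 || sequencing_error > 0.1)
    stop("sequencing_error must lie in [0, 0.1]")
  if (min(n_parents, offspring_per_cross, n_chromosomes,
          markers_per_chromosome) < 1)
    stop("counts must be >= 1")
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (!is.null(founder_allele_freqs) &&
      (any(founder_allele_freqs < 0) || any(founder_allele_freqs > 1)))
    stop("founder_allele_freqs must lie in [0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

marker_map <- function(cfg) {
  m <- cfg$markers_per_chromosome
  # markers evenly spaced; physical coordinates at 1 Mb per cM for plotting
  data.frame(
    chrom = rep(as.character(seq_len(cfg$n_chromosomes)), each = m),
    pos = rep(round(seq_len(m) / (m + 1) *
                      cfg$chromosome_length_morgans * 1e8), cfg$n_chromosomes),
    cm = rep(seq_len(m) / (m + 1) * cfg$chromosome_length_morgans * 100,
             cfg$n_chromosomes),
    id = paste0("M", seq_len(m * cfg$n_chromosomes)))
}

assign_annotation <- function(map, fractions, segments_per_chrom = 20) {
  # genic intervals: each chromosome is tiled into segments, a segment is
  # genic with probability P(ns) + P(s); markers in genic segments split
  # ns : s, markers outside are noncoding
  p_genic <- fractions[["nonsynonymous"]] + fractions[["synonymous"]]
  p_ns <- fractions[["nonsynonymous"]] / max(p_genic, 1e-12)
  ann <- character(nrow(map))
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    seg <- pmin(floor(seq_along(i) / length(i) * segments_per_chrom) + 1,
                segments_per_chrom)
    genic <- stats::runif(segments_per_chrom) < p_genic
    g <- genic[seg]
    ann[i[!g]] <- "noncoding"
    ng <- sum(g)
    if (ng > 0)
      ann[i[g]] <- ifelse(stats::runif(ng) < p_ns,
                          "nonsynonymous", "synonymous")
  }
  ann
}

#' Simulate tetraploid founders
#'
#' Draws phased founders: at each marker the four homolog alleles are
#' independent Bernoulli(p) so dosage is Binomial(4, p).
#'
#' @param cfg sim_config.
#' @return list with `haplotypes` (array 4 homologs x markers x founders),
#'   `dosages` (founders x markers), `map` (marker data.frame with chrom,
#'   pos, cm, id, annotation), `freqs` (the founder allele frequencies used).
#' @export
simulate_founders <- function(cfg) {
  set.seed(cfg$seed)
  map <- marker_map(cfg)
  m <- nrow(map)
  freqs <- cfg$founder_allele_freqs
  if (is.null(freqs)) freqs <- stats::runif(m, 0.05, 0.95)
  freqs <- rep_len(freqs, m)
  map$annotation <- assign_annotation(map, cfg$annotation_fractions)
  hap <- array(stats::rbinom(4L * m * cfg$n_parents, 1L,
                             rep(freqs, each = 4L)),
               dim = c(4L, m, cfg$n_parents))
  dos <- t(apply(hap, 3, colSums))
  rownames(dos) <- paste0("P", seq_len(cfg$n_parents))
  colnames(dos) <- map$id
  list(haplotypes = hap, dosages = dos, map = map, freqs = freqs)
}

# one meiotic product of a bivalent: two homologs (rows of a 2 x m 0/1
# matrix) recombined under a Haldane map (Poisson crossovers, no
# interference), returning a single recombinant haplotype
bivalent_product <- function(pair, cm, length_morgans) {
  n_x <- stats::rpois(1L, length_morgans)
  strand <- stats::rbinom(1L, 1L, 0.5)
  if (n_x > 0) {
    bp <- sort(stats::runif(n_x, 0, length_morgans * 100))
    strand <- (strand + findInterval(cm, bp)) %% 2L
  }
  pair[cbind(strand + 1L, seq_along(cm))]
}

# a gamete carries two homologs: the four parental homologs pair at random
# into two bivalents (no double reduction), each contributing one product
simulate_gamete <- function(parent_hap, map_chrom, length_morgans) {
  perm <- sample.int(4L)
  cm <- map_chrom$cm
  rbind(
    bivalent_product(parent_hap[perm[1:2], , drop = FALSE], cm, length_morgans),
    bivalent_product(parent_hap[perm[3:4], , drop = FALSE], cm, length_morgans))
}

#' Simulate offspring of a tetraploid cross
#'
#' Each offspring receives a two-homolog gamete from each phased parent,
#' produced by random bivalent pairing (no double reduction) with Haldane
#' recombination.
#'
#' @param mother_hap,father_hap 4 x markers 0/1 homolog matrices (phased).
#' @param map marker data.frame (chrom, cm).
#' @param n number of offspring.
#' @param length_morgans chromosome genetic length.
#' @return list with `haplotypes` (array 4 x markers x n, maternal homologs
#'   first) and `dosages` (n x markers).
#' @export
simulate_cross <- function(mother_hap, father_hap, map, n,
                           length_morgans = 1.0) {
  if (nrow(mother_hap) != 4L || nrow(father_hap) != 4L)
    stop("parents must be phased into 4 homologs")
  m <- ncol(mother_hap)
  chroms <- unique(map$chrom)
  hap <- array(0L, dim = c(4L, m, n))
  for (k in seq_len(n)) {
    for (ch in chroms) {
      i <- which(map$chrom == ch)
      mc <- map[i, , drop = FALSE]
      hap[1:2, i, k] <- simulate_gamete(mother_hap[, i, drop = FALSE], mc,
                                        length_morgans)
      hap[3:4, i, k] <- simulate_gamete(father_hap[, i, drop = FALSE], mc,
                                        length_morgans)
    }
  }
  list(haplotypes = hap, dosages = t(apply(hap, 3, colSums)))
}

diallel_crosses <- function(cfg) {
  if (is.character(cfg$crosses) && identical(cfg$crosses, "full-diallel")) {
    g <- expand.grid(mother = seq_len(cfg$n_parents),
                     father = seq_len(cfg$n_parents))
    g[g$mother != g$father, ]
  } else {
    cr <- as.data.frame(cfg$crosses)
    names(cr)[1:2] <- c("mother", "father")
    cr
  }
}

#' Simulate a full diallel-cross population with known truth
#'
#' Runs founder simulation, all requested crosses, QTL assignment and
#' true-breeding-value computation.
#'
#' @param cfg sim_config.
#' @return Object of class `sim_truth`: founder dosages, offspring dosages
#'   (clones x markers), phased offspring haplotypes, marker `map`,
#'   `pedigree` (clone, mother, father), `qtl` (data.frame id, effect),
#'   `tbv` named vector of true breeding values.
#' @export
simulate_population <- function(cfg) {
  fnd <- simulate_founders(cfg)
  crosses <- diallel_crosses(cfg)
  n_off <- nrow(crosses) * cfg$offspring_per_cross
  m <- nrow(fnd$map)
  dos <- matrix(0L, n_off, m)
  ped <- data.frame(clone = character(n_off), mother = character(n_off),
                    father = character(n_off))
  row <- 0L
  for (cx in seq_len(nrow(crosses))) {
    mo <- crosses$mother[cx]; fa <- crosses$father[cx]
    off <- simulate_cross(fnd$haplotypes[, , mo], fnd$haplotypes[, , fa],
                          fnd$map, cfg$offspring_per_cross,
                          cfg$chromosome_length_morgans)
    idx <- row + seq_len(cfg$offspring_per_cross)
    dos[idx, ] <- off$dosages
    ped$clone[idx] <- sprintf("C%03dx%03d_%02d", mo, fa,
                              seq_len(cfg$offspring_per_cross))
    ped$mother[idx] <- paste0("P", mo)
    ped$father[idx] <- paste0("P", fa)
    row <- row + cfg$offspring_per_cross
  }
  rownames(dos) <- ped$clone
  colnames(dos) <- fnd$map$id
  effects <- cfg$qtl_effects
  if (is.null(effects) && cfg$n_qtl > 0) effects <- stats::rnorm(cfg$n_qtl)
  qtl_idx <- if (cfg$n_qtl > 0) sort(sample.int(m, cfg$n_qtl)) else integer(0)
  tbv_all <- if (length(qtl_idx)) {
    all_dos <- rbind(fnd$dosages, dos)
    drop(all_dos[, qtl_idx, drop = FALSE] %*% effects)
  } else stats::setNames(rep(0, cfg$n_parents + n_off),
                         c(rownames(fnd$dosages), ped$clone))
  structure(list(
    founder_dosages = fnd$dosages, dosages = dos, map = fnd$map,
    founder_haplotypes = fnd$haplotypes,
    pedigree = ped,
    qtl = data.frame(id = fnd$map$id[qtl_idx],
                     index = qtl_idx,
                     effect = if (length(qtl_idx)) effects else numeric(0)),
    tbv = stats::setNames(as.numeric(tbv_all[ped$clone]), ped$clone),
    tbv_all = stats::setNames(as.numeric(tbv_all), names(tbv_all))),
    class = "sim_truth")
}

#' Simulate sequencing read counts for dosage genotypes
#'
#' Per sample x marker, total depth is negative binomial with mean
#' `mean_depth` and size `depth_dispersion` (Poisson when `Inf`); alt reads
#' are Binomial(depth, d/4 (1 - e) + (1 - d/4) e) with per-read error e.
#' Zero-depth cells are missing.
#'
#' @param dosages samples x markers matrix of dosages in 0..4.
#' @param cfg sim_config.
#' @param map optional marker data.frame (defaults to a generic map).
#' @return variant_table of ref/alt depths.
#' @export
simulate_reads <- function(dosages, cfg, map = NULL) {
  if (any(dosages < 0 | dosages > 4)) stop("dosages must lie in 0..4")
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(map))
    map <- data.frame(chrom = "1", pos = seq_len(m),
                      id = colnames(dosages) %||% paste0("M", seq_len(m)),
                      annotation = "unannotated")
  depth <- if (is.finite(cfg$depth_dispersion))
    stats::rnbinom(n * m, mu = cfg$mean_depth, size = cfg$depth_dispersion)
  else stats::rpois(n * m, cfg$mean_depth)
  pr <- as.vector(t(dosages)) / 4
  pr <- pr * (1 - cfg$sequencing_error) + (1 - pr) * cfg$sequencing_error
  depth <- matrix(depth, nrow = m)        # markers x samples
  alt <- matrix(stats::rbinom(n * m, as.vector(depth), pr), nrow = m)
  variant_table(map[, c("chrom", "pos", "id", "annotation")],
                rownames(dosages) %||% paste0("S", seq_len(n)),
                ref_depth = depth - alt, alt_depth = alt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate phenotype records
#'
#' y = mu + TBV + year + e with residual variance solved from the target
#' heritability: sigma_e^2 = Var(TBV) (1 - h2) / h2.
#'
#' Records cover offspring and, when available (`tbv_all`), the founders as
#' well, so that mid-parent regression has parental phenotypes to draw on.
#'
#' @param truth sim_truth (or any list with a named `tbv` vector).
#' @param cfg sim_config.
#' @param trait trait label for the records.
#' @return list with `records` (data.frame clone, trait, year, rep, value)
#'   and `realized_h2` (clone-mean based).
#' @export
simulate_phenotypes <- function(truth, cfg, trait = "trait1") {
  tbv <- truth$tbv_all %||% truth$tbv
  v_g <- stats::var(tbv)
  h2 <- cfg$heritability_target
  if (h2 == 0 && v_g > 0)
    stop("heritability_target = 0 with genetic variance implies infinite noise")
  sigma_e2 <- if (v_g == 0 || h2 == 1) 0 else v_g * (1 - h2) / h2
  years <- names(cfg$year_effects)
  reps <- rep_len(cfg$reps_per_year, length(years))
  rec <- do.call(rbind, lapply(seq_along(years), function(j) {
    do.call(rbind, lapply(seq_len(reps[j]), function(r)
      data.frame(clone = names(tbv), trait = trait, year = years[j], rep = r,
                 value = cfg$mu + tbv + cfg$year_effects[[j]] +
                   stats::rnorm(length(tbv), 0, sqrt(sigma_e2)))))
  }))
  rownames(rec) <- NULL
  realized <- if (v_g == 0) NA_real_ else v_g / (v_g + sigma_e2)
  list(records = rec, realized_h2 = realized)
}

#' Simulate a complete study data set
#'
#' End-to-end generator: population, read counts and phenotypes, returned
#' together with the truth needed for validation.
#'
#' @param cfg sim_config.
#' @param trait trait label.
#' @return list with `truth` (sim_truth), `reads` (variant_table),
#'   `phenotypes` (records data.frame), `realized_h2`, `pedigree`.
#' @export
simulate_study <- function(cfg, trait = "trait1") {
  truth <- simulate_population(cfg)
  reads <- simulate_reads(truth$dosages, cfg, truth$map)
  ph <- simulate_phenotypes(truth, cfg, trait)
  list(truth = truth, reads = reads, phenotypes = ph$records,
       realized_h2 = ph$realized_h2, pedigree = truth$pedigree)
}

#' Write a simulated study to disk
#'
#' Writes the read counts as minimal VCF and TSV, phenotypes, pedigree and
#' truth tables as TSV.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, c("reads.vcf", "reads.tsv", "phenotypes.tsv",
                        "pedigree.tsv", "truth_qtl.tsv", "truth_tbv.tsv"))
  write_variant_vcf(study$reads, f[1])
  write_variant_tsv(study$reads, f[2])
  utils::write.table(study$phenotypes, f[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$pedigree, f[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$truth$qtl, f[5], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(clone = names(study$truth$tbv), tbv = study$truth$tbv),
    f[6], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(f)
}
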
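#' Run the full analysis pipeline from a config
#'
#' Orchestrates simulate (or load) -> filter -> annotation subsets -> GRM ->
#' GBLUP cross-validation -> heritability -> GWAS from a single YAML config
#' (or equivalent list), writing TSV/JSON reports to the output directory.
#' All randomness flows through the single `seed` entry, which is recorded in
#' the run report together with a hash of the configuration.
#'
#' Config keys (all optional unless noted): `seed`; `out_dir` (required);
#' `simulate` (sim_config fields — if absent, `inputs` with `vcf` or `tsv`,
#' `phenotypes`, `pedigree` paths is required); `filters` (maf_min,
#' depth_min, depth_max, missing_max_marker, missing_max_sample);
#' `marker_sets` (character, default "combination"); `traits` (default: all
#' in the phenotype table); `gblup` (folds, repeats); `gwas` (enabled, sets);
#' `reduction` (enabled, min_markers).
#'
#' @param config path to a YAML file or a named list.
#' @param seed optional override of the config seed.
#' @param out_dir optional override of the output directory.
#' @return Invisibly, a list with the filter report, CV summary, heritability
#'   table and GWAS summaries.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- seed %||% cfg$seed %||% 1L
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop("config must provide out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  cfg_hash <- substr(paste(
    as.hexmode(utils::head(utf8ToInt(paste(
      deparse(cfg[setdiff(names(cfg), "out_dir")]), collapse = "")), 8)),
    collapse = ""), 1, 16)

  # ---- acquire data -------------------------------------------------------
  pedigree <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- seed
    scfg <- do.call(sim_config, sim_args)
    study <- simulate_study(scfg)
    reads <- study$reads
    pheno_records <- study$phenotypes
    pedigree <- study$pedigree
    parent_tbv <- NULL
  } else {
    inp <- cfg$inputs
    if (is.null(inp)) stop("config needs either 'simulate' or 'inputs'")
    for (f in unlist(inp)) if (!file.exists(f)) stop("missing input: ", f)
    reads <- if (!is.null(inp$vcf)) read_variant_vcf(inp$vcf)
             else read_variant_tsv(inp$tsv)
    pheno_records <- utils::read.delim(inp$phenotypes,
                                       stringsAsFactors = FALSE)
    if (!is.null(inp$pedigree))
      pedigree <- utils::read.delim(inp$pedigree, stringsAsFactors = FALSE)
  }

  # ---- filtering ----------------------------------------------------------
  fl <- cfg$filters %||% list()
  fp <- filter_pipeline(reads,
                        maf_min = fl$maf_min %||% 0.01,
                        depth_min = fl$depth_min %||% 5,
                        depth_max = fl$depth_max %||% 60,
                        missing_max_marker = fl$missing_max_marker %||% 0.5,
                        missing_max_sample = fl$missing_max_sample %||% 0.7)
  filtered <- fp$table

  sets <- cfg$marker_sets %||% "combination"
  set_tables <- lapply(sets, function(s) subset_by_annotation(filtered, s))
  names(set_tables) <- sets
  filter_report <- rbind(
    fp$report,
    do.call(rbind, lapply(sets, function(s) data.frame(
      stage = paste0("subset:", s),
      n_markers = n_markers(set_tables[[s]]),
      n_samples = n_samples(set_tables[[s]])))))
  utils::write.table(filter_report, file.path(out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- phenotype correction ----------------------------------------------
  traits <- cfg$traits %||% unique(pheno_records$trait)
  corrected <- lapply(traits, function(tr)
    correct_year_effects(pheno_records, trait = tr))
  names(corrected) <- traits

  # ---- GBLUP cross-validation --------------------------------------------
  gb <- cfg$gblup %||% list()
  folds <- gb$folds %||% 8
  repeats <- gb$repeats %||% 10
  cv_rows <- list()
  herit_rows <- list()
  for (s in sets) {
    gm <- genotype_matrix(set_tables[[s]])
    grm <- compute_grm(gm)
    for (tr in traits) {
      y <- corrected[[tr]]$values
      y <- y[names(y) %in% rownames(grm$G)]
      cv <- cross_validate(grm, y, folds = folds, repeats = repeats,
                           seed = seed + match(s, sets) * 1000 +
                             match(tr, traits))
      cv_rows[[paste(tr, s)]] <- data.frame(
        trait = tr, marker_set = s, n_markers = grm$n_markers,
        r_mean = mean(cv$per_repeat$r), r_sd = stats::sd(cv$per_repeat$r),
        bias_mean = mean(cv$per_repeat$bias),
        summary = sprintf("%.3f +/- %.3f (%.3f)", mean(cv$per_repeat$r),
                          stats::sd(cv$per_repeat$r),
                          mean(cv$per_repeat$bias)))
      utils::write.table(
        data.frame(clone = names(cv$mean_gebv), gebv = cv$mean_gebv),
        file.path(out_dir, sprintf("gebv_%s_%s.tsv", tr, s)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      herit_rows[[paste(tr, s)]] <- data.frame(
        trait = tr, marker_set = s,
        h2_genomic = genomic_heritability(grm, y),
        h2_pedigree = if (!is.null(pedigree)) {
          hp <- tryCatch(midparent_heritability(pedigree, corrected[[tr]]$values),
                         error = function(e) NULL)
          if (is.null(hp)) NA_real_ else hp$slope
        } else NA_real_)
    }
  }
  cv_summary <- do.call(rbind, cv_rows)
  herit <- do.call(rbind, herit_rows)
  utils::write.table(cv_summary, file.path(out_dir, "cv_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(herit, file.path(out_dir, "heritability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- GWAS ---------------------------------------------------------------
  gwas_summaries <- list()
  gw <- cfg$gwas %||% list(enabled = FALSE)
  if (isTRUE(gw$enabled)) {
    gsets <- gw$sets %||% sets[1]
    for (s in gsets) {
      gm <- genotype_matrix(set_tables[[s]])
      for (tr in traits) {
        y <- corrected[[tr]]$values
        y <- y[names(y) %in% rownames(gm$values)]
        scan <- single_marker_scan(gm, y)
        base <- sprintf("gwas_%s_%s", tr, s)
        utils::write.table(scan$scan,
                           file.path(out_dir, paste0(base, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        hits <- significant_hits(scan, n = length(y))
        utils::write.table(hits,
                           file.path(out_dir, paste0(base, "_hits.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        pd <- export_plots_data(scan)
        utils::write.table(pd$manhattan,
                           file.path(out_dir, paste0(base, "_manhattan.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(pd$qq,
                           file.path(out_dir, paste0(base, "_qq.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        gwas_summaries[[paste(tr, s)]] <- list(
          trait = tr, marker_set = s, lambda_gc = scan$lambda_gc,
          bonferroni = scan$bonferroni$threshold,
          n_tested = scan$n_tested, n_hits = nrow(hits))
      }
    }
    jsonlite::write_json(gwas_summaries,
                         file.path(out_dir, "gwas_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  report <- list(seed = seed, config_hash = cfg_hash,
                 filter_report = filter_report, cv_summary = cv_summary,
                 heritability = herit, gwas = gwas_summaries)
  jsonlite::write_json(
    list(seed = seed, config_hash = cfg_hash,
         stages = c("filter", "gblup",
                    if (isTRUE(gw$enabled)) "gwas")),
    file.path(out_dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
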
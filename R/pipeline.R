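#' Pipeline configuration
#'
#' One object driving the full synthetic-cohort run: simulation, MET
#' assignment, QC thresholds, elastic-net / BSS settings, panel sizes for
#' the predictive comparison and the enrichment threshold. The global
#' `seed` is propagated to every stochastic stage (simulation, fold
#' assignment, bootstrapping, annotation).
#'
#' @param out_dir run directory (created if needed).
#' @param sim a [sim_config()]; its `family` defaults to `"lognormal"` here
#'   so that simulated phenotypes are positive and the questionnaire stage
#'   can invert them.
#' @param met a [met_assignment()].
#' @param qc a [qc_thresholds()].
#' @param en an [en_config()].
#' @param r2_sizes panel sizes for [build_r2_curves()].
#' @param enrich_threshold EASE significance threshold.
#' @param seed global integer seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = NULL,
                            met = met_assignment(),
                            qc = qc_thresholds(),
                            en = en_config(),
                            r2_sizes = c(0, 5, 10, 20, 50),
                            enrich_threshold = 0.1,
                            seed = 1L) {
  seed <- check_count(seed, "seed", min = 0L)
  if (is.null(sim))
    sim <- sim_config(n_samples = 500L, n_snps = 1000L,
                      family = "lognormal", seed = seed)
  sim$seed <- seed
  en$seed <- derive_seed(seed, 5L)
  structure(list(out_dir = out_dir, sim = sim, met = met, qc = qc, en = en,
                 r2_sizes = r2_sizes, enrich_threshold = enrich_threshold,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `out_dir`, `seed`, `r2_sizes`, `enrich_threshold` and
#' nested maps `sim`, `met`, `qc`, `en` whose entries are passed to the
#' respective constructors.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) stopf("config must set `out_dir`")
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim)
  met <- if (!is.null(y$met)) do.call(met_assignment, y$met) else met_assignment()
  qc <- if (!is.null(y$qc)) do.call(qc_thresholds, y$qc) else qc_thresholds()
  en <- if (!is.null(y$en)) do.call(en_config, y$en) else en_config()
  pipeline_config(out_dir = y$out_dir, sim = sim, met = met, qc = qc, en = en,
                  r2_sizes = y$r2_sizes %||% c(0, 5, 10, 20, 50),
                  enrich_threshold = y$enrich_threshold %||% 0.1,
                  seed = y$seed %||% 1L)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage `%s` failed: %s", stage, conditionMessage(e)))
}

#' Run the full pipeline
#'
#' Executes, in order: cohort simulation (genotypes, covariates,
#' questionnaire, truth record), phenotype construction from the
#' questionnaire, sample and marker QC, mode imputation, the single-SNP
#' scan, multi-stage elastic-net/BSS selection, the adjusted-R-squared
#' comparison, and pathway enrichment on a simulated annotation. Every
#' stage writes its table(s) into `out_dir` as TSV before the next stage
#' runs, so a failing stage leaves all earlier outputs on disk; a JSON
#' manifest records the seed, thresholds and per-stage counts.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the run directory, the manifest, and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stopf("`config` must be a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  message("stage simulate: generating cohort")
  sim <- run_stage("simulate", {
    geno <- simulate_genotypes(config$sim)
    cp <- simulate_covariates_and_phenotype(geno, config$sim)
    act <- simulate_questionnaire(cp$pheno, config$met, seed = config$seed)
    write_plink_text(geno, out("cohort"), pheno = cp$pheno)
    write_tsv_file(cp$pheno[, c("sample_id", covariate_names())],
                   out("covariates.tsv"))
    write_tsv_file(act, out("questionnaire.tsv"))
    jsonlite::write_json(cp$truth, out("truth.json"), auto_unbox = TRUE,
                         digits = NA)
    list(geno = geno, pheno = cp$pheno, truth = cp$truth, activity = act)
  })

  message("stage phenotype: aggregating questionnaire durations")
  pheno <- run_stage("phenotype", {
    pa <- compute_total_pa(sim$activity, config$met)
    ph <- merge(pa, sim$pheno[, c("sample_id", covariate_names())],
                by = "sample_id", sort = TRUE)
    summary_tab <- rbind(
      cbind(grouping = "all", summarize_cohort(ph)),
      cbind(grouping = "sex", summarize_cohort(ph, "sex")),
      cbind(grouping = "area", summarize_cohort(ph, "area")))
    write_tsv_file(summary_tab, out("phenotype_summary.tsv"))
    ph
  })

  message("stage qc: sample and marker filters")
  qc_res <- run_stage("qc", {
    meta <- data.frame(sample_id = sim$pheno$sample_id,
                       reported_sex = sim$pheno$sex,
                       inferred_sex = sim$pheno$sex,
                       stringsAsFactors = FALSE)
    sq <- sample_qc(sim$geno, meta, config$qc)
    mq <- marker_qc(sq$geno, config$qc)
    report <- rbind(cbind(level = "sample", as.data.frame(sq$report)),
                    cbind(level = "marker", as.data.frame(mq$report)))
    write_tsv_file(report, out("qc_report.tsv"))
    jsonlite::write_json(report, out("qc_report.json"), digits = NA)
    list(geno = mq$geno, report = report)
  })

  geno_c <- run_stage("impute", impute_missing(qc_res$geno))
  pheno <- pheno[pheno$sample_id %in% sample_ids(geno_c), , drop = FALSE]

  message(sprintf("stage assoc: scanning %d SNPs on %d samples",
                  n_snps(geno_c), n_samples(geno_c)))
  assoc <- run_stage("assoc", {
    a <- single_snp_scan(geno_c, pheno)
    write_tsv_file(as.data.frame(a), out("assoc.tsv"))
    manhattan_export(a, out("manhattan.tsv"))
    a
  })

  en <- config$en
  if (max(en$screen_depths) > nrow(assoc)) {
    message(sprintf("capping screen depths at the %d post-QC SNPs", nrow(assoc)))
    en$screen_depths <- unique(pmin(en$screen_depths, nrow(assoc)))
  }

  message(sprintf("stage stabsel: depths %s, B = %d",
                  paste(en$screen_depths, collapse = "/"), en$B))
  sel <- run_stage("stabsel", {
    s <- multi_stage_select(assoc, geno_c, pheno, en)
    write_tsv_file(s$bss_table, out("bss.tsv"))
    write_tsv_file(s$table, out("selection.tsv"))
    message(sprintf("  jointly identified: %s; common: %d; final: %d",
                    paste(s$counts$jointly_identified, collapse = ", "),
                    s$counts$common, s$counts$final))
    s
  })

  message("stage predeval: adjusted R-squared curves")
  curves <- run_stage("predeval", {
    cv <- build_r2_curves(sel, assoc, geno_c, pheno, sizes = config$r2_sizes)
    write_tsv_file(as.data.frame(cv), out("r2_curves.tsv"))
    cv
  })

  message("stage enrich: pathway over-representation")
  enr <- run_stage("enrich", {
    ann <- simulate_annotation(sim$geno$snp_info$snp_id, seed = config$seed)
    write_tsv_file(ann$gene_map, out("snp2gene.tsv"))
    genes <- map_snps_to_genes(sel$table$snp_id, ann$gene_map)
    e <- enrich_pathways(genes, ann$pathways, threshold = config$enrich_threshold)
    write_tsv_file(as.data.frame(e), out("enrichment.tsv"))
    list(genes = genes, table = e)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("stabselgwas")),
    seed = config$seed,
    thresholds = list(qc = unclass(config$qc),
                      en = unclass(en)[c("alpha", "nfolds", "B",
                                         "bss_threshold", "screen_depths",
                                         "lambda_choice", "bss_rule")],
                      enrich = config$enrich_threshold),
    counts = list(
      n_samples_simulated = config$sim$n_samples,
      n_snps_simulated = config$sim$n_snps,
      n_samples_post_qc = n_samples(geno_c),
      n_snps_post_qc = n_snps(geno_c),
      screened = sel$counts$screened,
      jointly_identified = sel$counts$jointly_identified,
      common = sel$counts$common,
      final = sel$counts$final,
      genes_mapped = length(enr$genes),
      pathways_tested = nrow(enr$table),
      pathways_significant = sum(enr$table$significant)),
    files = list.files(config$out_dir))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(dir = config$out_dir, manifest = manifest,
                 results = list(geno = geno_c, pheno = pheno, assoc = assoc,
                                selection = sel, curves = curves,
                                enrichment = enr, truth = sim$truth)))
}
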
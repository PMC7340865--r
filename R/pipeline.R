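#' Pipeline configuration
#'
#' Declares where the pipeline reads and writes, which regression models to
#' run, and the parameters of the synthetic demo data and the gene set
#' analysis. One master seed deterministically derives the per-stage seeds,
#' so a fixed seed makes the whole run reproducible byte for byte.
#'
#' @param out_dir output directory; inputs are written (or expected) under
#'   `<out_dir>/input`, results under `<out_dir>`.
#' @param synth a [synth_config()] for the simulate stage (its `seed` is
#'   overridden by the master seed).
#' @param models character vector, subset of `c("model1", "model2")`.
#' @param gsz a [gsz_params()].
#' @param crossreactive,snp_affected optional blacklist file paths.
#' @param seed master seed.
#' @param simulate if `FALSE`, skip the simulate stage and read existing
#'   inputs from `<out_dir>/input`.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(out_dir, synth = synth_config(),
                            models = c("model1", "model2"),
                            gsz = gsz_params(),
                            crossreactive = NULL, snp_affected = NULL,
                            seed = 1, simulate = TRUE) {
  models <- match.arg(models, c("model1", "model2"), several.ok = TRUE)
  structure(list(out_dir = out_dir, synth = synth, models = models,
                 gsz = gsz, crossreactive = crossreactive,
                 snp_affected = snp_affected, seed = as.integer(seed),
                 simulate = simulate),
            class = "PipelineConfig")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (optional) -> preprocess -> per-CpG
#' regression (model 1 and optionally model 2) -> gene proxy scores -> gene
#' set analysis -> region analysis. All stage outputs are plain TSV under
#' `out_dir`, plus a JSON manifest recording the seed, per-stage row counts,
#' the filter report, the genomic inflation factor per model, and — when both
#' models run — the overlap of their FDR < 0.05 probe lists.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out_dir <- config$out_dir
  input_dir <- file.path(out_dir, "input")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("methylGSZ")),
                   seed = config$seed, stages = list())

  ## simulate -----------------------------------------------------------------
  if (config$simulate) {
    manifest$stages$simulate <- run_stage("simulate", {
      cfg <- config$synth
      cfg$seed <- derive_seed(config$seed, 10)
      gen <- generate_dataset(cfg)
      write_synth_dataset(gen, input_dir)
      list(n_probes = nrow(gen$dataset$beta),
           n_samples = ncol(gen$dataset$beta),
           n_gene_sets = length(gen$genesets),
           n_causal_probes = length(gen$ground_truth$causal_probe_ids))
    })
  }

  ## preprocess ---------------------------------------------------------------
  pre <- run_stage("preprocess", {
    beta <- read_matrix_tsv(file.path(input_dir, "beta.tsv"))
    ann <- read_annotation(file.path(input_dir, "annotation.tsv"))
    sheet <- read_sample_sheet(file.path(input_dir, "sample_sheet.csv"))
    detp <- read_matrix_tsv(file.path(input_dir, "detection_p.tsv"))
    control <- read_matrix_tsv(file.path(input_dir, "control_probes.tsv"))
    ds <- methyl_dataset(beta, ann, sheet)
    cross <- if (is.null(config$crossreactive)) character() else
      read_blacklist(config$crossreactive)
    snps <- if (is.null(config$snp_affected)) character() else
      read_blacklist(config$snp_affected)
    flt <- filter_probes(ds, detp, crossreactive = cross, snp_affected = snps)
    pcs <- control_probe_pcs(control, k = 2)
    utils::write.table(flt$report, file.path(out_dir, "filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(ds = flt$dataset, report = flt$report, pcs = pcs, ann = ann)
  })
  manifest$stages$preprocess <- list(
    n_in = attr(pre$report, "n_in"), n_out = attr(pre$report, "n_out"),
    removed = stats::setNames(as.list(pre$report$n_removed), pre$report$rule))

  ## ewas ----------------------------------------------------------------------
  ewas_results <- list()
  for (mod in config$models) {
    ewas_results[[mod]] <- run_stage(paste0("ewas_", mod), {
      res <- fit_ewas(pre$ds, model_spec(mod), control_pcs = pre$pcs)
      write_ewas(res, file.path(out_dir, paste0("ewas_", mod, ".tsv")),
                 annotation = pre$ann)
      res
    })
    manifest$stages[[paste0("ewas_", mod)]] <- list(
      n_probes = nrow(ewas_results[[mod]]),
      n_samples_used = ewas_results[[mod]]$n_used[1],
      n_dropped_missing = attr(ewas_results[[mod]], "n_dropped"),
      n_fdr05 = sum(ewas_results[[mod]]$q < 0.05, na.rm = TRUE),
      lambda = genomic_lambda(ewas_results[[mod]]$p))
  }
  if (all(c("model1", "model2") %in% names(ewas_results))) {
    h1 <- ewas_results$model1$probe[which(ewas_results$model1$q < 0.05)]
    h2 <- ewas_results$model2$probe[which(ewas_results$model2$q < 0.05)]
    manifest$model2_overlap <- list(
      n_model1 = length(h1), n_model2 = length(h2),
      n_shared = length(intersect(h1, h2)))
  }

  ## genescore -----------------------------------------------------------------
  scores <- run_stage("genescore", {
    gm <- map_probes_to_genes(pre$ds$annotation)
    sc <- gene_proxy_scores(ewas_results[[1]], gm)
    utils::write.table(sc, file.path(out_dir, "gene_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sc
  })
  manifest$stages$genescore <- list(n_genes = nrow(scores))

  ## gsz ------------------------------------------------------------------------
  gsz_res <- run_stage("gsz", {
    sets <- read_gmt(file.path(input_dir, "gene_sets.gmt"))
    res <- analyze_collection(scores, sets, params = config$gsz,
                              seed = derive_seed(config$seed, 20))
    utils::write.table(res, file.path(out_dir, "gsz_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res
  })
  manifest$stages$gsz <- list(n_sets_analyzed = nrow(gsz_res),
                              n_fdr05 = sum(gsz_res$q <= 0.05))

  ## regions ---------------------------------------------------------------------
  regions <- run_stage("regions", {
    res <- region_analysis(pre$ds)
    utils::write.table(res, file.path(out_dir, "regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res
  })
  manifest$stages$regions <- list(n_regions = nrow(regions))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
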
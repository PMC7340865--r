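#' Configuration for the synthetic 450K-style generator
#'
#' The defaults emulate the study conditions the pipeline is designed for: a
#' whole-blood 450K cohort of 125 adults with 21 active smokers and 104 never
#' smokers, six estimated leukocyte proportions per sample, chip/array batch
#' structure mirrored into a control-probe matrix, a handful of strongly
#' smoking-responsive CpGs, and one gene set whose member genes carry a
#' milder but coherent methylation shift. The probe count is desk-scale
#' (20,000 rather than 485k) while preserving the multiplicity structure; the
#' BH test count always equals the post-filter probe count unless overridden
#' downstream.
#'
#' @param n_probes number of probes (default 20000).
#' @param n_samples number of samples (default 125).
#' @param n_smokers number of active smokers (default 21; the rest are never
#'   smokers).
#' @param n_genes number of gene symbols in the annotation (default 2000).
#' @param probes_per_gene mean of the (shifted) Poisson number of probes per
#'   gene, minimum 1 (default 8).
#' @param frac_intergenic fraction of probes with no gene annotation and
#'   OpenSea island relation (default 0.2).
#' @param n_sets number of gene sets written to the GMT (default 200).
#' @param set_size_range integer two-vector, min/max genes per set
#'   (default c(5, 50); min >= 2).
#' @param planted_cpg_ids integer indices (1-based) of probes given a direct
#'   smoking effect (default the first 25 probes).
#' @param planted_cpg_delta_m M-scale smoking shift at planted CpGs
#'   (default 0.5).
#' @param planted_set_name name of the set whose member genes' CpGs all
#'   receive a mild shift (default `"SET_001"`; `NULL` plants none).
#' @param planted_set_delta_m M-scale shift for the planted set's CpGs
#'   (default 0.15 — mild per CpG, coherent across the set).
#' @param planted_region optional region label (e.g. `"Shore"`); all probes
#'   whose collapsed island relation equals it receive
#'   `planted_region_delta_m` (default `NULL`).
#' @param planted_region_delta_m M-scale smoking shift for the planted
#'   region (default -0.15, i.e. hypomethylation, used only when
#'   `planted_region` is set).
#' @param noise_sd_m residual Gaussian noise SD on the M scale (default 0.3,
#'   a typical 450K probe-level residual spread).
#' @param covariate_effect_scale multiplier on the age/sex/cell-type probe
#'   response magnitudes (default 1; 0 gives a dataset whose only systematic
#'   sample-level signal besides batch is the planted smoking effect).
#' @param n_chips number of chips; samples are assigned in balanced blocks
#'   (default 11, about 12 samples per chip as on a physical BeadChip).
#' @param chip_effect_sd SD of the per-chip technical offsets (default 0.5).
#' @param n_control_probes rows of the control-probe matrix (default 200).
#' @param missing_covar_frac fraction of samples with alcohol and
#'   socioeconomic status jointly missing, completely at random
#'   (default 16/125, the typical questionnaire non-response in a cohort of
#'   this size).
#' @param frac_detp_fail fraction of probes that fail detection in all
#'   samples (default 0.005), so the detection filter has work to do.
#' @param seed integer seed; every generator draw derives from it.
#' @return a validated `SynthConfig` list.
#' @export
synth_config <- function(n_probes = 20000, n_samples = 125, n_smokers = 21,
                         n_genes = 2000, probes_per_gene = 8,
                         frac_intergenic = 0.2, n_sets = 200,
                         set_size_range = c(5, 50),
                         planted_cpg_ids = seq_len(25),
                         planted_cpg_delta_m = 0.5,
                         planted_set_name = "SET_001",
                         planted_set_delta_m = 0.15,
                         planted_region = NULL,
                         planted_region_delta_m = -0.15,
                         noise_sd_m = 0.3, covariate_effect_scale = 1,
                         n_chips = 11,
                         chip_effect_sd = 0.5, n_control_probes = 200,
                         missing_covar_frac = 16 / 125,
                         frac_detp_fail = 0.005, seed = 1) {
  cfg <- list(n_probes = n_probes, n_samples = n_samples,
              n_smokers = n_smokers, n_genes = n_genes,
              probes_per_gene = probes_per_gene,
              frac_intergenic = frac_intergenic, n_sets = n_sets,
              set_size_range = as.integer(set_size_range),
              planted_cpg_ids = as.integer(planted_cpg_ids),
              planted_cpg_delta_m = planted_cpg_delta_m,
              planted_set_name = planted_set_name,
              planted_set_delta_m = planted_set_delta_m,
              planted_region = planted_region,
              planted_region_delta_m = planted_region_delta_m,
              noise_sd_m = noise_sd_m,
              covariate_effect_scale = covariate_effect_scale,
              n_celltypes = 6L, n_chips = n_chips,
              chip_effect_sd = chip_effect_sd,
              n_control_probes = n_control_probes,
              missing_covar_frac = missing_covar_frac,
              frac_detp_fail = frac_detp_fail, seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "SynthConfig")
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (n_probes < 1 || n_samples < 1 || n_genes < 1) {
      stopf("counts must be positive")
    }
    if (n_smokers >= n_samples) stopf("n_smokers must be < n_samples")
    if (probes_per_gene < 1) stopf("probes_per_gene must be >= 1")
    if (frac_intergenic < 0 || frac_intergenic > 1) {
      stopf("frac_intergenic must be in [0, 1]")
    }
    if (missing_covar_frac < 0 || missing_covar_frac > 1) {
      stopf("missing_covar_frac must be in [0, 1]")
    }
    if (set_size_range[1] < 2 || set_size_range[2] < set_size_range[1]) {
      stopf("set_size_range must satisfy 2 <= min <= max")
    }
    if (length(planted_cpg_ids) &&
        (min(planted_cpg_ids) < 1 || max(planted_cpg_ids) > n_probes)) {
      stopf("planted_cpg_ids out of probe range")
    }
    if (anyDuplicated(planted_cpg_ids)) stopf("duplicated planted_cpg_ids")
    if (noise_sd_m < 0 || chip_effect_sd < 0) stopf("SDs must be non-negative")
    if (covariate_effect_scale < 0) {
      stopf("covariate_effect_scale must be non-negative")
    }
    if (abs(seed) >= 2^31 - 10) stopf("seed out of 32-bit range")
  })
  invisible(cfg)
}

.gene_region_groups <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR")
.island_relations <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                       "OpenSea")

#' Generate a synthetic probe annotation table
#'
#' Probes get a chromosome (1-22), a position, zero or more gene assignments
#' (semicolon-joined, with a matching gene-region group per assignment) and a
#' CpG-island relation. A `frac_intergenic` share of probes carries no gene
#' and is OpenSea by construction; about 5% of gene probes get a second gene,
#' exercising the multi-gene mapping rules downstream.
#'
#' @param config a [synth_config()].
#' @return annotation data.frame with Illumina-manifest column names.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  with_seed(derive_seed(config$seed, 1), {
    n <- config$n_probes
    probe_ids <- sprintf("cg%08d", seq_len(n))
    genes <- sprintf("GENE%04d", seq_len(config$n_genes))

    n_gene_probes <- round((1 - config$frac_intergenic) * n)
    gene_field <- character(n)
    group_field <- character(n)
    island <- character(n)

    if (n_gene_probes > 0) {
      counts <- 1 + stats::rpois(config$n_genes, config$probes_per_gene - 1)
      pool <- rep(genes, counts)
      primary <- if (length(pool) >= n_gene_probes) {
        sample(pool, n_gene_probes)
      } else {
        c(sample(pool), sample(genes, n_gene_probes - length(pool),
                               replace = TRUE))
      }
      idx <- seq_len(n_gene_probes)
      grp <- sample(.gene_region_groups, n_gene_probes, replace = TRUE,
                    prob = c(0.12, 0.12, 0.12, 0.08, 0.46, 0.10))
      gene_field[idx] <- primary
      group_field[idx] <- grp
      # some probes span two genes; both get their own region group
      second <- which(stats::runif(n_gene_probes) < 0.05)
      if (length(second)) {
        other <- sample(genes, length(second), replace = TRUE)
        keep <- other != primary[second]
        second <- second[keep]; other <- other[keep]
        gene_field[second] <- paste(primary[second], other, sep = ";")
        group_field[second] <- paste(
          group_field[second],
          sample(.gene_region_groups, length(second), replace = TRUE),
          sep = ";")
      }
      island[idx] <- sample(.island_relations, n_gene_probes, replace = TRUE,
                            prob = c(0.31, 0.12, 0.11, 0.05, 0.05, 0.36))
    }
    if (n_gene_probes < n) {
      island[(n_gene_probes + 1):n] <- "OpenSea"
    }

    ann <- data.frame(
      IlmnID = probe_ids,
      CHR = as.character(sample(1:22, n, replace = TRUE)),
      MAPINFO = sample.int(1e8, n, replace = TRUE),
      UCSC_RefGene_Name = gene_field,
      UCSC_RefGene_Group = group_field,
      Relation_to_UCSC_CpG_Island = island,
      stringsAsFactors = FALSE
    )
    # shuffle rows so planted indices are not systematically gene probes
    ann <- ann[sample.int(n), , drop = FALSE]
    ann$IlmnID <- probe_ids
    rownames(ann) <- NULL
    ann
  })
}

#' Generate synthetic gene sets and optionally write a GMT
#'
#' Samples `n_sets` sets from the annotated gene universe, each a
#' without-replacement draw of a size uniform on `set_size_range`.
#'
#' @param config a [synth_config()].
#' @param annotation annotation from [generate_annotation()].
#' @param path optional GMT output path.
#' @return named list of gene sets (names `SET_001`, ...).
#' @export
generate_genesets <- function(config, annotation, path = NULL) {
  stopifnot(inherits(config, "SynthConfig"))
  universe <- unique(unlist(strsplit(
    annotation$UCSC_RefGene_Name[nzchar(annotation$UCSC_RefGene_Name)],
    ";", fixed = TRUE)))
  if (length(universe) < config$set_size_range[2]) {
    stopf("gene universe (%d) smaller than max set size (%d)",
          length(universe), config$set_size_range[2])
  }
  sets <- with_seed(derive_seed(config$seed, 2), {
    size_choices <- seq.int(config$set_size_range[1], config$set_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), config$n_sets,
                                     replace = TRUE)]
    lapply(sizes, function(k) sample(universe, k))
  })
  names(sets) <- sprintf("SET_%03d", seq_len(config$n_sets))
  if (!is.null(path)) write_gmt(sets, path, description = "synthetic")
  sets
}

#' Generate a full synthetic methylation dataset with known ground truth
#'
#' The generative model, per probe j and sample i, works on the M scale:
#'
#'   M_ij = baseline_j + age-slope_j * (age_i - 44.5) + sex-offset_j * sex_i
#'          + sum_c cellsig_jc * (prop_ic - mean_c) + chip_j(chip_i)
#'          + smoking_i * effect_j + noise
#'
#' and is mapped to beta by the logistic transform, so betas are strictly
#' inside (0, 1). Baselines are drawn island-relation-dependently (Islands
#' low-methylated, beta around 0.2; Shores intermediate, around 0.45;
#' Shelves/OpenSea high, around 0.7 — the bimodal 450K landscape), so region
#' averages differ by construction. Chip effects are two per-chip factors
#' with per-probe loadings; the same factors drive the control-probe matrix,
#' so control-probe PCs can recover them. Covariate (age, sex, cell-type)
#' responses are linear in the covariates the regression models adjust for,
#' and the smoking effect vector is the ground truth: planted CpGs get
#' `planted_cpg_delta_m`, all CpGs of the planted set's member genes get
#' `planted_set_delta_m`, probes of `planted_region` get
#' `planted_region_delta_m`, everything else 0.
#'
#' @param config a [synth_config()].
#' @return list with `dataset` ([methyl_dataset()]), `control` (control-probe
#'   matrix), `detp` (detection p-value matrix), `genesets` (named list),
#'   `ground_truth` (list: `causal_probe_ids`, `causal_set_names`,
#'   `true_effect` named M-scale vector), and `annotation`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  ann <- generate_annotation(config)
  sets <- generate_genesets(config, ann)
  if (!is.null(config$planted_set_name) &&
      !config$planted_set_name %in% names(sets)) {
    stopf("planted_set_name '%s' is not among the generated sets",
          config$planted_set_name)
  }

  with_seed(derive_seed(config$seed, 3), {
    n <- config$n_probes
    ns <- config$n_samples
    probe_ids <- ann$IlmnID
    sample_ids <- sprintf("S%03d", seq_len(ns))

    ## --- sample sheet -----------------------------------------------------
    smoking <- c(rep(1L, config$n_smokers), rep(0L, ns - config$n_smokers))
    age <- round(stats::runif(ns, 40, 49), 1)
    sex <- stats::rbinom(ns, 1, 0.38)
    bmi <- round(pmin(pmax(stats::rnorm(ns, 26, 4.4), 16), 45), 1)
    mean_props <- c(CD8T = 0.08, CD4T = 0.17, NK = 0.06, Bcell = 0.06,
                    Mono = 0.08, Gran = 0.55)
    gam <- matrix(stats::rgamma(ns * 6, shape = rep(60 * mean_props,
                                                    each = ns)),
                  nrow = ns)
    props <- gam / rowSums(gam)
    colnames(props) <- names(mean_props)
    chip <- sprintf("chip%02d", rep_len(seq_len(config$n_chips), ns))
    array_pos <- sprintf("R%02d", rep_len(1:12, ns))
    alcohol <- round(stats::rgamma(ns, shape = 2, scale = 3), 1)
    ses <- sample(c("manual", "lower non-manual", "upper non-manual"),
                  ns, replace = TRUE)
    n_miss <- round(config$missing_covar_frac * ns)
    if (n_miss > 0) {
      miss <- sample.int(ns, n_miss)
      alcohol[miss] <- NA
      ses[miss] <- NA
    }
    sheet <- data.frame(sample_id = sample_ids, smoking = smoking, age = age,
                        sex = sex, bmi = bmi, props, chip = chip,
                        array_pos = array_pos, alcohol = alcohol, ses = ses,
                        stringsAsFactors = FALSE)

    ## --- per-probe parameters --------------------------------------------
    island <- collapse_island_relation(ann$Relation_to_UCSC_CpG_Island)
    base_beta <- numeric(n)
    for (grp in list(c("Island", 2, 8), c("Shore", 4.5, 5.5),
                     c("Shelf", 7, 3), c("OpenSea", 7, 3))) {
      idx <- which(island == grp[1])
      base_beta[idx] <- stats::rbeta(length(idx), as.numeric(grp[2]),
                                     as.numeric(grp[3]))
    }
    base_beta <- pmin(pmax(base_beta, 0.01), 0.99)
    baseline_m <- beta_to_m(base_beta)

    cs <- config$covariate_effect_scale
    age_slope <- cs * ifelse(stats::runif(n) < 0.2, stats::rnorm(n, 0, 0.02), 0)
    sex_off <- cs * ifelse(stats::runif(n) < 0.2, stats::rnorm(n, 0, 0.15), 0)
    cellsig <- matrix(0, n, 6)
    cell_idx <- which(stats::runif(n) < 0.1)
    cellsig[cell_idx, ] <- cs * stats::rnorm(length(cell_idx) * 6, 0, 0.5)

    # Methylation-probe batch loadings are centered at zero: the beta matrix
    # emulates *normalized* data, where any common per-chip shift has been
    # removed and what remains is probe-specific. Control probes (below)
    # emulate raw intensities and keep a common component.
    u1 <- stats::rnorm(config$n_chips, 0, config$chip_effect_sd)
    u2 <- stats::rnorm(config$n_chips, 0, config$chip_effect_sd)
    l1 <- stats::rnorm(n, 0, 0.3)
    l2 <- stats::rnorm(n, 0, 0.3)

    ## --- ground-truth smoking effects ------------------------------------
    effect <- numeric(n)
    if (length(config$planted_cpg_ids)) {
      effect[config$planted_cpg_ids] <-
        effect[config$planted_cpg_ids] + config$planted_cpg_delta_m
    }
    causal_sets <- character(0)
    if (!is.null(config$planted_set_name)) {
      member_genes <- sets[[config$planted_set_name]]
      gm <- map_probes_to_genes(ann)
      set_probes <- unique(gm$probe[gm$gene %in% member_genes])
      jdx <- match(set_probes, probe_ids)
      effect[jdx] <- effect[jdx] + config$planted_set_delta_m
      causal_sets <- config$planted_set_name
    }
    if (!is.null(config$planted_region)) {
      rdx <- which(island == config$planted_region)
      effect[rdx] <- effect[rdx] + config$planted_region_delta_m
    }

    ## --- assemble the signal ----------------------------------------------
    chip_num <- rep_len(seq_len(config$n_chips), ns)
    M <- matrix(baseline_m, n, ns)
    M <- M + outer(age_slope, age - 44.5)
    M <- M + outer(sex_off, sex)
    M <- M + cellsig %*% t(props - matrix(mean_props, ns, 6, byrow = TRUE))
    M <- M + outer(l1, u1[chip_num]) + outer(l2, u2[chip_num])
    M <- M + outer(effect, smoking)
    if (config$noise_sd_m > 0) {
      M <- M + matrix(stats::rnorm(n * ns, 0, config$noise_sd_m), n, ns)
    }
    beta <- m_to_beta(M)
    dimnames(beta) <- list(probe_ids, sample_ids)

    ## --- control probes and detection p ----------------------------------
    nc <- config$n_control_probes
    c1 <- stats::rnorm(nc, 1, 0.3)
    c2 <- stats::rnorm(nc, 0.5, 0.3)
    control <- outer(c1, u1[chip_num]) + outer(c2, u2[chip_num]) +
      matrix(stats::rnorm(nc * ns, 0, 0.1), nc, ns)
    dimnames(control) <- list(sprintf("ctrl%04d", seq_len(nc)), sample_ids)

    detp <- matrix(0, n, ns, dimnames = list(probe_ids, sample_ids))
    n_fail <- round(config$frac_detp_fail * n)
    if (n_fail > 0) detp[sample.int(n, n_fail), ] <- 1

    ground_truth <- list(
      causal_probe_ids = probe_ids[effect != 0],
      causal_set_names = causal_sets,
      true_effect = stats::setNames(effect, probe_ids)
    )
    list(dataset = methyl_dataset(beta, ann, sheet), control = control,
         detp = detp, genesets = sets, ground_truth = ground_truth,
         annotation = ann)
  })
}
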
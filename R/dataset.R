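#' Construct a MethylationDataset
#'
#' Bundles a beta-value matrix with its probe annotation and sample sheet and
#' validates that the three agree. This is the central object passed between
#' the filtering, regression, gene-scoring and region-analysis stages.
#'
#' @param beta numeric matrix of beta values in \[0, 1\], probes in rows and
#'   samples in columns; `rownames` are probe ids, `colnames` sample ids.
#' @param annotation data.frame in Illumina-manifest style with columns
#'   `IlmnID`, `CHR`, `MAPINFO`, `UCSC_RefGene_Name`, `UCSC_RefGene_Group`
#'   and `Relation_to_UCSC_CpG_Island`. Must cover every probe in `beta`.
#'   `CHR` is accepted with or without a `"chr"` prefix; `MAPINFO` positions
#'   are 1-based.
#' @param sample_sheet data.frame with one row per sample: `sample_id`,
#'   `smoking` (1 = active smoker, 0 = never smoker), `age`, `sex`, `bmi`,
#'   the six leukocyte proportions `CD8T`, `CD4T`, `NK`, `Bcell`, `Mono`,
#'   `Gran` (non-negative, summing to 1), `chip`, `array_pos`, and optionally
#'   `alcohol` (units/week, NA allowed) and `ses` (3-level category, NA
#'   allowed).
#' @return An object of class `MethylationDataset`: a list with elements
#'   `beta`, `annotation`, `sample_sheet`, `probe_ids`, `sample_ids`.
#' @export
methyl_dataset <- function(beta, annotation, sample_sheet) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stopf("`beta` must be a numeric matrix")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stopf("`beta` needs probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(beta))) stopf("duplicated probe ids in `beta`")
  if (anyDuplicated(colnames(beta))) stopf("duplicated sample ids in `beta`")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stopf("beta values outside [0, 1] (range %.4g..%.4g)", rng[1], rng[2])
  }
  ann_cols <- c("IlmnID", "CHR", "MAPINFO", "UCSC_RefGene_Name",
                "UCSC_RefGene_Group", "Relation_to_UCSC_CpG_Island")
  missing_cols <- setdiff(ann_cols, names(annotation))
  if (length(missing_cols)) {
    stopf("annotation lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  annotation$CHR <- sub("^chr", "", as.character(annotation$CHR))
  not_annotated <- setdiff(rownames(beta), annotation$IlmnID)
  if (length(not_annotated)) {
    stopf("%d probe(s) missing from annotation (first: %s)",
          length(not_annotated), not_annotated[1])
  }
  annotation <- annotation[match(rownames(beta), annotation$IlmnID), ,
                           drop = FALSE]
  rownames(annotation) <- NULL

  ss_cols <- c("sample_id", "smoking", "age", "sex", "bmi", cell_type_cols(),
               "chip", "array_pos")
  missing_ss <- setdiff(ss_cols, names(sample_sheet))
  if (length(missing_ss)) {
    stopf("sample sheet lacks column(s): %s", paste(missing_ss, collapse = ", "))
  }
  not_in_sheet <- setdiff(colnames(beta), sample_sheet$sample_id)
  if (length(not_in_sheet)) {
    stopf("%d sample(s) missing from sample sheet (first: %s)",
          length(not_in_sheet), not_in_sheet[1])
  }
  sample_sheet <- sample_sheet[match(colnames(beta), sample_sheet$sample_id), ,
                               drop = FALSE]
  rownames(sample_sheet) <- NULL
  if (anyNA(sample_sheet$smoking)) stopf("`smoking` must be non-missing")
  if (!all(sample_sheet$smoking %in% c(0, 1))) {
    stopf("`smoking` must be coded 0 (never) / 1 (active)")
  }
  props <- as.matrix(sample_sheet[, cell_type_cols()])
  if (any(props < 0)) stopf("cell-type proportions must be non-negative")
  bad_sum <- abs(rowSums(props) - 1) > 1e-6
  if (any(bad_sum)) {
    stopf("cell-type proportions do not sum to 1 for sample %s",
          sample_sheet$sample_id[which(bad_sum)[1]])
  }

  structure(
    list(beta = beta, annotation = annotation, sample_sheet = sample_sheet,
         probe_ids = rownames(beta), sample_ids = colnames(beta)),
    class = "MethylationDataset"
  )
}

# Canonical order of leukocyte proportion columns.
cell_type_cols <- function() c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran")

#' @export
print.MethylationDataset <- function(x, ...) {
  cat(sprintf("MethylationDataset: %d probes x %d samples\n",
              nrow(x$beta), ncol(x$beta)))
  cat(sprintf("  smokers: %d, never: %d\n",
              sum(x$sample_sheet$smoking == 1),
              sum(x$sample_sheet$smoking == 0)))
  invisible(x)
}

#' @export
dim.MethylationDataset <- function(x) dim(x$beta)

# Subset a dataset to a probe id vector, preserving order of `probes`.
subset_probes <- function(ds, probes) {
  keep <- intersect(ds$probe_ids, probes)
  methyl_dataset(ds$beta[keep, , drop = FALSE], ds$annotation, ds$sample_sheet)
}
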
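#' Read a GMT gene set file
#'
#' Standard tab-separated format: set name, description, then member genes.
#' Duplicate members within a set are collapsed.
#'
#' @param path GMT file path.
#' @return named list of character vectors; attribute `descriptions` holds
#'   the second column.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) stopf("GMT line %d has fewer than 3 fields", bad[1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2), names(sets))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description single string or named vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, description = "na") {
  desc <- if (length(description) == 1) {
    rep(description, length(sets))
  } else {
    description[names(sets)]
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read a probes-by-samples numeric matrix from TSV
#'
#' Layout: first column probe ids, header row sample ids. Used for both beta
#' and detection p-value matrices.
#'
#' @param path TSV path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a probes-by-samples matrix as TSV
#' @param m matrix with dimnames.
#' @param path output path.
#' @param id_col name of the id column (default `"probe"`).
#' @export
write_matrix_tsv <- function(m, path, id_col = "probe") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an Illumina-manifest-style annotation TSV
#' @param path TSV with columns IlmnID, CHR, MAPINFO, UCSC_RefGene_Name,
#'   UCSC_RefGene_Group, Relation_to_UCSC_CpG_Island.
#' @return annotation data.frame (CHR normalized to no "chr" prefix, gene
#'   fields as character with NA replaced by "").
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  ann$MAPINFO <- as.integer(ann$MAPINFO)
  ann$CHR <- sub("^chr", "", ann$CHR)
  for (col in c("UCSC_RefGene_Name", "UCSC_RefGene_Group")) {
    ann[[col]][is.na(ann[[col]])] <- ""
  }
  ann
}

#' Read a sample sheet (CSV or TSV, by extension)
#' @param path file path; `.csv` is comma-separated, anything else tab.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
}

#' Read a newline-delimited probe blacklist
#' @param path text file, one probe id per line; blank lines and `#` comments
#'   ignored.
#' @return character vector of probe ids.
#' @export
read_blacklist <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write all parts of a generated synthetic dataset to a directory
#'
#' Emits the beta matrix TSV, sample sheet CSV, annotation TSV, control-probe
#' TSV, detection-p TSV, gene set GMT and ground-truth TSV, i.e. the complete
#' plain-text input layout the pipeline reads back.
#'
#' @param gen result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_synth_dataset <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    beta = file.path(dir, "beta.tsv"),
    sample_sheet = file.path(dir, "sample_sheet.csv"),
    annotation = file.path(dir, "annotation.tsv"),
    control = file.path(dir, "control_probes.tsv"),
    detp = file.path(dir, "detection_p.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    ground_truth = file.path(dir, "ground_truth.tsv")
  )
  write_matrix_tsv(gen$dataset$beta, paths["beta"])
  utils::write.csv(gen$dataset$sample_sheet, paths["sample_sheet"],
                   row.names = FALSE, quote = TRUE)
  utils::write.table(gen$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(gen$control, paths["control"], id_col = "control_probe")
  write_matrix_tsv(gen$detp, paths["detp"])
  write_gmt(gen$genesets, paths["gmt"], description = "synthetic")
  gt <- data.frame(probe = names(gen$ground_truth$true_effect),
                   true_effect = unname(gen$ground_truth$true_effect),
                   stringsAsFactors = FALSE)
  utils::write.table(gt, paths["ground_truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Bundled reference table of smoking-associated CpG sites
#'
#' A published whole-blood 450K EWAS top table of 60 CpG sites significantly
#' associated with active smoking (effect size, standard error, p-value,
#' genome-wide FDR, gene/region annotation), shipped as a plain-text fixture.
#' Used to validate the step-up FDR arithmetic against an independent,
#' externally computed FDR column: the printed FDRs correspond to BH
#' adjustment of these p-values against the full autosomal test count of
#' 429,773 post-QC probes.
#'
#' @return data.frame with columns `probe`, `effect`, `se`, `p`, `fdr`,
#'   `gene`, `region`, `chr`, `in_model2`.
#' @export
smoking_dmps_reference <- function() {
  path <- system.file("extdata", "smoking_dmps_reference.tsv",
                      package = "methylGSZ", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Total autosomal probe count behind the bundled reference table's FDRs
#' @return integer test count (429,773).
#' @export
smoking_dmps_m_total <- function() 429773L
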
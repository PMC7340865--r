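#' Convert beta values to M-values
#'
#' M = log2(beta / (1 - beta)), the variance-stabilized scale on which the
#' per-CpG regressions operate. Quantile-normalised pipelines can emit values
#' at or numerically past the \[0, 1\] boundary, so betas are clamped to
#' `[clamp_eps, 1 - clamp_eps]` first (bounding M at about +/-19.9 for the
#' default eps); values outside \[0, 1\] are a hard error.
#'
#' @param beta numeric vector or matrix of beta values.
#' @param clamp_eps clamping margin; set to 0 to disable clamping, in which
#'   case boundary values are errors.
#' @return M-values with the same shape and dimnames as `beta`.
#' @seealso [m_to_beta()]
#' @export
beta_to_m <- function(beta, clamp_eps = 1e-6) {
  if (!is.numeric(beta)) stopf("`beta` must be numeric")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1))
  if (length(bad) == 0 && clamp_eps == 0) {
    bad <- which(!is.na(beta) & (beta <= 0 | beta >= 1))
  }
  if (length(bad)) {
    stopf("beta outside the valid range at %s (value %.6g)",
          offender_label(beta, bad[1]), beta[bad[1]])
  }
  b <- pmin(pmax(beta, clamp_eps), 1 - clamp_eps)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(out) <- dim(beta)
  dimnames_or_names(out, beta)
}

#' Convert M-values to beta values
#'
#' Inverse of [beta_to_m()]: beta = 2^M / (1 + 2^M), computed in the
#' numerically stable logistic form so large |M| maps to the open interval
#' boundary without overflow.
#'
#' @param m numeric vector or matrix of finite M-values.
#' @return beta values in (0, 1), same shape as `m`.
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) stopf("`m` must be numeric")
  if (any(!is.finite(m) & !is.na(m))) stopf("`m` must be finite")
  out <- 1 / (1 + 2^(-m))
  if (is.matrix(m)) dim(out) <- dim(m)
  dimnames_or_names(out, m)
}

dimnames_or_names <- function(out, src) {
  if (is.matrix(src)) dimnames(out) <- dimnames(src) else names(out) <- names(src)
  out
}

# "probe cgX / sample S" label for error messages on matrices, index otherwise
offender_label <- function(x, idx) {
  if (is.matrix(x) && !is.null(rownames(x)) && !is.null(colnames(x))) {
    rc <- arrayInd(idx, dim(x))
    sprintf("probe %s / sample %s", rownames(x)[rc[1]], colnames(x)[rc[2]])
  } else {
    sprintf("position %d", idx)
  }
}

#' Apply probe-level quality filters
#'
#' Removes probes in three sequential passes, mirroring standard 450K QC:
#' (1) probes whose detection p-value exceeds `detp_cutoff` in more than
#' `max_fail_frac` of samples (equivalently: kept only if detected at
#' p <= cutoff in at least `1 - max_fail_frac` of samples); (2) probes on
#' chromosomes X and Y; (3) probes on either blacklist (cross-reactive,
#' SNP-affected). Each pass counts only probes still present when it runs, so
#' the report counts sum to the total removed. Probe order is preserved.
#'
#' @param ds a [methyl_dataset()].
#' @param detp optional detection p-value matrix aligned to `ds$beta`
#'   (same dimnames); `NULL` skips the detection filter.
#' @param crossreactive,snp_affected character vectors of probe ids to drop;
#'   ids absent from the dataset are counted and ignored, not errors.
#' @param detp_cutoff per-measurement detection p cutoff (default 0.01).
#' @param max_fail_frac maximum tolerated fraction of samples failing the
#'   cutoff before the probe is removed (default 0.01, i.e. the probe must be
#'   detected in at least 99% of samples).
#' @param remove_sex_chr drop chrX/chrY probes (default TRUE).
#' @return list with `dataset` (filtered MethylationDataset) and `report`
#'   (data.frame of per-rule removal counts plus input/output totals).
#' @export
filter_probes <- function(ds, detp = NULL,
                          crossreactive = character(),
                          snp_affected = character(),
                          detp_cutoff = 0.01,
                          max_fail_frac = 0.01,
                          remove_sex_chr = TRUE) {
  stopifnot(inherits(ds, "MethylationDataset"))
  n_in <- length(ds$probe_ids)
  keep <- ds$probe_ids

  n_detp <- 0L
  if (!is.null(detp)) {
    if (!identical(dim(detp), dim(ds$beta))) {
      stopf("detection p matrix shape %dx%d does not match beta %dx%d",
            nrow(detp), ncol(detp), nrow(ds$beta), ncol(ds$beta))
    }
    if (min(detp) < 0 || max(detp) > 1) stopf("detection p-values outside [0, 1]")
    fail_frac <- rowMeans(detp[keep, , drop = FALSE] > detp_cutoff)
    drop_detp <- keep[fail_frac > max_fail_frac]
    n_detp <- length(drop_detp)
    keep <- setdiff(keep, drop_detp)
  }

  n_sex <- 0L
  if (remove_sex_chr) {
    chr <- ds$annotation$CHR[match(keep, ds$annotation$IlmnID)]
    drop_sex <- keep[chr %in% c("X", "Y")]
    n_sex <- length(drop_sex)
    keep <- setdiff(keep, drop_sex)
  }

  blacklist <- unique(c(crossreactive, snp_affected))
  n_unknown <- length(setdiff(blacklist, ds$probe_ids))
  drop_bl <- intersect(keep, blacklist)
  n_bl <- length(drop_bl)
  keep <- setdiff(keep, drop_bl)

  if (length(keep) == 0) {
    warnf("all %d probes removed by filtering", n_in)
  }
  if (n_unknown > 0) {
    message(sprintf("filter_probes: %d blacklist id(s) not in dataset, ignored",
                    n_unknown))
  }

  out <- if (length(keep)) {
    subset_probes(ds, keep)
  } else {
    ds_empty <- ds
    ds_empty$beta <- ds$beta[integer(0), , drop = FALSE]
    ds_empty$annotation <- ds$annotation[integer(0), , drop = FALSE]
    ds_empty$probe_ids <- character(0)
    ds_empty
  }
  report <- data.frame(
    rule = c("detection_p", "sex_chromosomes", "blacklist"),
    n_removed = c(n_detp, n_sex, n_bl)
  )
  attr(report, "n_in") <- n_in
  attr(report, "n_out") <- length(keep)
  attr(report, "n_blacklist_unknown") <- n_unknown
  list(dataset = out, report = report)
}

#' Control-probe principal components
#'
#' Computes per-sample scores on the first `k` principal components of the
#' control-probe intensity matrix. Control probes carry technical (chip,
#' position, batch) variation but no biology, so their leading PCs serve as
#' batch covariates in the regression models. The decomposition is an SVD of
#' the column-centered samples-by-probes matrix; each component's loading
#' vector is flipped, if needed, so its coefficients sum to a positive value,
#' giving a deterministic sign convention.
#'
#' @param control numeric matrix, control probes in rows, samples in columns.
#' @param k number of components to return (default 2).
#' @return numeric matrix samples x k of PC scores (columns `PC1`, ...). If
#'   the centered matrix has rank r < k, columns beyond r are zero and a
#'   warning is raised; an all-constant matrix yields all-zero scores.
#' @export
control_probe_pcs <- function(control, k = 2) {
  if (!is.matrix(control) || !is.numeric(control)) {
    stopf("`control` must be a numeric matrix")
  }
  x <- t(control)                       # samples as observations
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)
  tol <- max(dim(x)) * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > max(tol, 1e-12))
  scores <- matrix(0, nrow = nrow(x), ncol = k,
                   dimnames = list(colnames(control), paste0("PC", seq_len(k))))
  if (rank == 0) {
    warnf("control matrix has zero variance; returning zero scores")
    return(scores)
  }
  if (rank < k) {
    warnf("control matrix rank %d < requested k = %d; extra PCs set to zero",
          rank, k)
  }
  kk <- min(k, rank)
  for (j in seq_len(kk)) {
    flip <- if (sum(sv$v[, j]) < 0) -1 else 1
    scores[, j] <- flip * sv$u[, j] * sv$d[j]
  }
  scores
}
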
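#' Define a covariate model for the per-CpG regression
#'
#' Two standard specifications are built in. `model1` adjusts for age, sex,
#' body mass index, leukocyte composition (five of the six proportions —
#' granulocytes are dropped by default to avoid sum-to-one collinearity) and
#' the technical factors chip and array position. `model2` additionally
#' adjusts for alcohol use (units/week) and socioeconomic status; samples
#' missing either are dropped listwise at fit time. Smoking status is always
#' the exposure and never a covariate.
#'
#' @param name `"model1"`, `"model2"`, or `"custom"`.
#' @param covariates for `name = "custom"`, character vector of sample-sheet
#'   columns to adjust for.
#' @param include_control_pcs how many control-probe PCs to append (default 2).
#' @param drop_celltype which proportion column to leave out of the design
#'   (default `"Gran"`); set to `NA` to keep all six (will usually be
#'   collinear).
#' @return A `ModelSpec` list.
#' @export
model_spec <- function(name = c("model1", "model2", "custom"),
                       covariates = NULL,
                       include_control_pcs = 2,
                       drop_celltype = "Gran") {
  name <- match.arg(name)
  cells <- setdiff(cell_type_cols(), drop_celltype)
  base <- c("age", "sex", "bmi", cells, "chip", "array_pos")
  covariates <- switch(
    name,
    model1 = base,
    model2 = c(base, "alcohol", "ses"),
    custom = covariates %||% character(0)
  )
  if ("smoking" %in% covariates) {
    stopf("`smoking` is the exposure; it cannot also be a covariate")
  }
  structure(
    list(name = name, covariates = covariates,
         include_control_pcs = include_control_pcs),
    class = "ModelSpec"
  )
}

# Columns coded as factors (indicator coding, reference = first observed).
.categorical_fields <- c("chip", "array_pos", "ses")

build_design <- function(sample_sheet, spec, control_pcs = NULL) {
  need <- c("smoking", spec$covariates)
  missing_cols <- setdiff(need, names(sample_sheet))
  if (length(missing_cols)) {
    stopf("sample sheet lacks field(s) required by %s: %s",
          spec$name, paste(missing_cols, collapse = ", "))
  }
  df <- sample_sheet[, need, drop = FALSE]
  if (!is.null(control_pcs) && spec$include_control_pcs > 0) {
    k <- min(spec$include_control_pcs, ncol(control_pcs))
    pcs <- control_pcs[match(sample_sheet$sample_id, rownames(control_pcs)),
                       seq_len(k), drop = FALSE]
    colnames(pcs) <- paste0("ctrlPC", seq_len(k))
    df <- cbind(df, pcs)
  }
  complete <- stats::complete.cases(df)
  df <- df[complete, , drop = FALSE]
  for (f in intersect(.categorical_fields, names(df))) {
    df[[f]] <- factor(df[[f]], levels = unique(df[[f]]))
  }
  X <- stats::model.matrix(~ ., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  list(X = X, keep = which(complete), n_dropped = sum(!complete))
}

#' Per-CpG differential methylation regression
#'
#' Fits, for every probe, an ordinary least squares regression of M-values on
#' smoking status plus the covariates of `spec` (and optionally control-probe
#' PCs), and reports the smoking coefficient with its standard error,
#' t-statistic, two-sided p-value from the t reference distribution, and
#' Benjamini-Hochberg q-value. Samples with any missing required covariate
#' are dropped listwise before fitting (the same design is used for all
#' probes, so every probe sees the same samples).
#'
#' Smoking is coded 1 = active smoker, 0 = never smoker, so the effect is the
#' smoker-minus-never difference in M-units.
#'
#' @param ds a [methyl_dataset()].
#' @param spec a [model_spec()].
#' @param control_pcs optional samples x k score matrix from
#'   [control_probe_pcs()] (rownames = sample ids).
#' @param m_total number of tests for the BH adjustment; defaults to the
#'   number of probes with a defined p-value in this run. Supply the
#'   post-filter probe count explicitly when analysing a subset.
#' @return data.frame of class `EwasResult` with columns `probe`, `effect`,
#'   `se`, `t`, `df`, `p`, `q`, `n_used`, `model`. Probes with zero residual
#'   variance get NA statistics with a warning. Attribute `n_dropped` records
#'   samples removed for missingness.
#' @export
fit_ewas <- function(ds, spec = model_spec("model1"), control_pcs = NULL,
                     m_total = NULL) {
  stopifnot(inherits(ds, "MethylationDataset"), inherits(spec, "ModelSpec"))
  des <- build_design(ds$sample_sheet, spec, control_pcs)
  X <- des$X
  n <- nrow(X)
  df_resid <- n - ncol(X)
  if (df_resid < 1) stopf("no residual degrees of freedom (n = %d, p = %d)",
                          n, ncol(X))
  if (des$n_dropped > 0) {
    message(sprintf("fit_ewas (%s): dropped %d sample(s) with missing covariates; n = %d",
                    spec$name, des$n_dropped, n))
  }

  M <- beta_to_m(ds$beta[, des$keep, drop = FALSE])
  fit <- stats::lm.fit(X, t(M))
  coefs <- if (is.matrix(fit$coefficients)) fit$coefficients["smoking", ]
           else fit$coefficients[["smoking"]]
  res <- as.matrix(fit$residuals)
  sigma2 <- colSums(res^2) / df_resid
  xtx_inv <- chol2inv(chol(crossprod(X)))
  xtx_inv_ss <- xtx_inv[match("smoking", colnames(X)), match("smoking", colnames(X))]
  se <- sqrt(sigma2 * xtx_inv_ss)
  tstat <- coefs / se
  p <- 2 * stats::pt(-abs(tstat), df = df_resid)

  degenerate <- sigma2 < 1e-24
  if (any(degenerate)) {
    warnf("%d probe(s) with zero residual variance; statistics set to NA",
          sum(degenerate))
    se[degenerate] <- NA_real_
    tstat[degenerate] <- NA_real_
    p[degenerate] <- NA_real_
  }
  if (is.null(m_total)) m_total <- sum(!is.na(p))
  q <- bh_adjust(p, m_total = m_total)

  out <- data.frame(
    probe = ds$probe_ids, effect = unname(coefs), se = unname(se),
    t = unname(tstat), df = df_resid, p = unname(p), q = unname(q),
    n_used = n, model = spec$name, stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- des$n_dropped
  class(out) <- c("EwasResult", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment against an explicit total test count: sort p
#' ascending, compute `p_(i) * m_total / i`, take the cumulative minimum from
#' the largest rank downward, cap at 1, and return in input order. Passing
#' `m_total` larger than `length(p)` adjusts a printed subset (assumed to be
#' the smallest p-values) against the full experiment-wide test count, which
#' is how published top tables relate to their genome-wide FDR column.
#'
#' @param p numeric vector of p-values in \[0, 1\]; NAs are propagated.
#' @param m_total total number of tests (default `length(p)`, excluding NAs
#'   only when p contains NAs and m_total is unset).
#' @return adjusted p-values (q-values) in input order.
#' @export
bh_adjust <- function(p, m_total = NULL) {
  if (!is.numeric(p)) stopf("`p` must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values outside [0, 1]")
  n <- sum(ok)
  if (is.null(m_total)) m_total <- n
  if (m_total < n) stopf("m_total (%d) smaller than number of p-values (%d)",
                         m_total, n)
  q <- rep(NA_real_, length(p))
  if (n == 0) return(q)
  pv <- p[ok]
  o <- order(pv)
  raw <- pv[o] * m_total / seq_len(n)
  adj <- pmin(rev(cummin(rev(raw))), 1)
  qo <- numeric(n)
  qo[o] <- adj
  q[ok] <- qo
  q
}

#' Genomic inflation factor
#'
#' Lambda is the median of the observed 1-df chi-square statistics (obtained
#' from the two-sided p-values) divided by the null median of the chi-square
#' distribution with one degree of freedom. Lambda near 1 indicates
#' well-calibrated tests; lambda > 1 indicates inflation.
#'
#' @param p vector of p-values in (0, 1\]; NAs dropped.
#' @return the scalar lambda.
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) stopf("no p-values supplied")
  if (any(p <= 0 | p > 1)) stopf("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Export EWAS results as a table (optionally with plot coordinates)
#'
#' @param ewas an `EwasResult`.
#' @param path output TSV path.
#' @param annotation optional annotation to append `chr`, `pos` and
#'   `neg_log10_p` columns for external Manhattan/QQ plotting.
#' @return the written data.frame, invisibly.
#' @export
write_ewas <- function(ewas, path, annotation = NULL) {
  out <- as.data.frame(ewas)
  if (!is.null(annotation)) {
    idx <- match(out$probe, annotation$IlmnID)
    out$chr <- annotation$CHR[idx]
    out$pos <- annotation$MAPINFO[idx]
    out$neg_log10_p <- -log10(out$p)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
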
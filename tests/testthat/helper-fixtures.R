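# Shared fixture builders. Everything is generated in code; no stored data.

# A minimal hand-built dataset: `m` is an M-value matrix (probes x samples);
# covariates are filled with constants so a custom intercept-only model spec
# regresses M on smoking alone.
hand_dataset <- function(m, smoking, annotation = NULL) {
  beta <- m_to_beta(m)
  ns <- ncol(m)
  if (is.null(rownames(beta))) {
    rownames(beta) <- sprintf("cg%03d", seq_len(nrow(m)))
  }
  if (is.null(colnames(beta))) colnames(beta) <- sprintf("S%02d", seq_len(ns))
  if (is.null(annotation)) {
    annotation <- data.frame(
      IlmnID = rownames(beta), CHR = "1",
      MAPINFO = seq_len(nrow(beta)) * 1000L,
      UCSC_RefGene_Name = "", UCSC_RefGene_Group = "",
      Relation_to_UCSC_CpG_Island = "OpenSea",
      stringsAsFactors = FALSE
    )
  }
  sheet <- data.frame(
    sample_id = colnames(beta), smoking = smoking,
    age = 44, sex = 0L, bmi = 25,
    CD8T = 0.1, CD4T = 0.2, NK = 0.1, Bcell = 0.1, Mono = 0.1, Gran = 0.4,
    chip = "chip01", array_pos = "R01",
    alcohol = 2, ses = "manual",
    stringsAsFactors = FALSE
  )
  methyl_dataset(beta, annotation, sheet)
}

# Intercept-only regression spec (no covariates, no control PCs).
bare_spec <- function() {
  model_spec("custom", covariates = character(0), include_control_pcs = 0)
}

# Small, fast synthetic configuration for unit tests; any synth_config
# argument can be overridden (including to NULL).
tiny_config <- function(...) {
  defaults <- list(n_probes = 1200, n_samples = 60, n_smokers = 12,
                   n_genes = 150, probes_per_gene = 6, n_sets = 30,
                   set_size_range = c(5, 15), planted_cpg_ids = 1:5,
                   n_chips = 5, n_control_probes = 60)
  do.call(synth_config, utils::modifyList(defaults, list(...),
                                          keep.null = TRUE))
}

# Brute-force BH step-up: q_i = min over ranks j >= rank(i) of p_(j) * m / j.
bh_brute <- function(p, m_total = length(p)) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(o == i)
    vals <- vapply(rank_i:n, function(j) p[o[j]] * m_total / j, numeric(1))
    q[i] <- min(1, min(vals))
  }
  q
}

# Exhaustive running-sum moments: enumerate every m-subset of N positions.
moments_brute <- function(scores, m) {
  N <- length(scores)
  subsets <- utils::combn(N, m)
  X <- matrix(0, ncol(subsets), N)
  for (i in seq_len(ncol(subsets))) {
    x <- numeric(N)
    x[subsets[, i]] <- scores[subsets[, i]]
    X[i, ] <- cumsum(x)
  }
  list(E = colMeans(X),
       V = apply(X, 2, function(col) mean((col - mean(col))^2)))
}

# Independent GSZ reference: moments by enumeration, explicit smoothing loop,
# explicit max over both directions. O(C(N, m) * N); only for tiny N.
gsz_brute <- function(score_vec, members, params) {
  s <- score_vec
  ord <- order(-s, names(s))
  dir_max <- function(sorted, pos) {
    N <- length(sorted)
    mom <- moments_brute(sorted, length(pos))
    lam <- params$lambda_var
    vt <- numeric(N)
    vt[1] <- mom$V[1]
    for (k in 2:N) vt[k] <- lam * mom$V[k] + (1 - lam) * vt[k - 1]
    eps <- params$var_floor * stats::var(unname(s))
    x <- numeric(N)
    x[pos] <- sorted[pos]
    max((cumsum(x) - mom$E) / sqrt(vt + eps))
  }
  s_desc <- unname(s[ord])
  pos <- match(members, names(s)[ord])
  max(0,
      dir_max(s_desc, pos),
      dir_max(rev(s_desc), length(s) + 1 - pos))
}
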
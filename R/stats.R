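# Reproducibility and group-comparison statistics.

#' Standardized PCA of a descriptor table
#'
#' Parameters are z-standardized (zero-variance columns dropped with a
#' message) and decomposed with [stats::prcomp()]. Component signs are
#' fixed deterministically by making the largest-magnitude loading of
#' each component positive.
#'
#' @param table descriptor data.frame; non-numeric columns are treated as
#'   annotations and ignored.
#' @param n_components number of components to keep (default all).
#' @return list: `scores` (samples x components), `loadings` (parameters
#'   x components), `explained_variance_ratio`, `dropped` (zero-variance
#'   parameter names).
#' @export
pca_descriptors <- function(table, n_components = NULL) {
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, logical(1))
  X <- as.matrix(table[num])
  if (nrow(X) < 2) stop("PCA needs at least 2 rows")
  if (anyNA(X)) stop("PCA input must have no missing values")
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    message(sprintf("dropping %d zero-variance parameter(s): %s",
                    length(dropped), paste(head(dropped, 5), collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 1) stop("no parameters with variance remain")
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  if (!is.null(n_components)) {
    k <- min(n_components, ncol(scores))
    scores <- scores[, seq_len(k), drop = FALSE]
    loadings <- loadings[, seq_len(k), drop = FALSE]
  }
  list(scores = scores, loadings = loadings,
       explained_variance_ratio = evr, dropped = dropped,
       eigenvalues = pc$sdev^2)
}

#' Inter-assay standard deviation of the mean (SDm)
#'
#' Per parameter: the standard deviation of the per-experiment means
#' divided by the absolute grand mean (mean of experiment means), in
#' percent. Parameters with a zero grand mean are flagged undefined.
#'
#' @param table descriptor data.frame including an experiment column.
#' @param experiment_col name of the experiment id column.
#' @return data.frame: parameter, sdm_pct, grand_mean, n_experiments,
#'   flag.
#' @export
interassay_sdm <- function(table, experiment_col = "experiment") {
  table <- as.data.frame(table)
  if (!experiment_col %in% names(table))
    stop(sprintf("column '%s' not found", experiment_col))
  exps <- unique(table[[experiment_col]])
  if (length(exps) < 2) stop("SDm needs at least 2 experiments")
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  out <- lapply(num, function(nm) {
    m <- tapply(table[[nm]], table[[experiment_col]], mean, na.rm = TRUE)
    gm <- mean(m)
    if (!is.finite(gm) || gm == 0)
      data.frame(parameter = nm, sdm_pct = NA_real_, grand_mean = gm,
                 n_experiments = length(m), flag = "undefined")
    else
      data.frame(parameter = nm, sdm_pct = sd(m) / abs(gm) * 100,
                 grand_mean = gm, n_experiments = length(m), flag = "")
  })
  do.call(rbind, out)
}

#' Welch two-sample t test
#'
#' Unpaired two-tailed comparison with the Welch/Satterthwaite correction
#' for unequal variances (always applied; Student's pooled test is
#' available via `var_equal = TRUE`).
#'
#' @param a,b numeric samples, each with n >= 2.
#' @param var_equal use the pooled-variance Student test instead.
#' @return list: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
welch_ttest <- function(a, b, var_equal = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  tt <- t.test(a, b, var.equal = var_equal, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}
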
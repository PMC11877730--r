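# Scaled PCA with covariate association, PC-PR2 variance partitioning,
# per-CpG linear models with an effect-size gate, rank-sum group
# comparisons, and Benjamini-Hochberg FDR.

# Centre and scale each CpG row to unit variance; impute missing values
# with the CpG mean first and drop zero-variance CpGs. Returns the scaled
# matrix plus bookkeeping counts.
.scale_beta <- function(beta) {
  n_imputed <- sum(is.na(beta))
  if (n_imputed > 0L) {
    rm_ <- rowMeans(beta, na.rm = TRUE)
    idx <- which(is.na(beta), arr.ind = TRUE)
    beta[idx] <- rm_[idx[, 1L]]
  }
  sds <- apply(beta, 1L, stats::sd)
  zero <- !is.finite(sds) | sds == 0
  n_dropped <- sum(zero)
  beta <- beta[!zero, , drop = FALSE]
  scaled <- (beta - rowMeans(beta)) / sds[!zero]
  list(scaled = scaled, n_imputed = n_imputed, n_dropped = n_dropped)
}

#' Principal components of centred and scaled beta values
#'
#' Each CpG (row) is centred and scaled to unit variance, then the
#' samples-by-CpGs matrix is decomposed by SVD. Zero-variance CpGs are
#' dropped (count reported); missing values are imputed with the CpG mean
#' (count reported). The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making the result reproducible.
#'
#' @param beta Probes-by-samples beta matrix.
#' @param n_components Number of components to keep (default: all
#'   `min(n_samples, n_cpgs)`).
#' @return Object of class `pca_result`: list with `scores`
#'   (samples x components), `loadings` (CpGs x components),
#'   `variance_fraction`, `standardized_scores` (scores centred and scaled
#'   to unit variance per component), `n_imputed`, `n_dropped`.
#' @export
pca_scaled <- function(beta, n_components = NULL) {
  if (ncol(beta) < 2L) stop("PCA requires >= 2 samples")
  sc <- .scale_beta(beta)
  if (sc$n_imputed > 0L) message(sc$n_imputed, " missing values imputed with CpG means")
  if (sc$n_dropped > 0L) message(sc$n_dropped, " zero-variance CpGs dropped")
  m <- t(sc$scaled)  # samples x CpGs, columns centred
  k <- min(dim(m))
  if (!is.null(n_components)) k <- min(k, n_components)
  sv <- svd(m, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  scores <- sv$u %*% diag(d, k, k)
  loadings <- sv$v
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(colnames(beta), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(rownames(sc$scaled), paste0("PC", seq_len(k)))
  var_frac <- sv$d^2 / sum(sv$d^2)
  # components with singular values at numerical-noise level carry no
  # signal; their standardized scores are set to zero
  std <- scores
  for (j in seq_len(k)) {
    s <- stats::sd(scores[, j])
    std[, j] <- if (s == 0 || d[j] < d[1] * 1e-9) 0 else
      (scores[, j] - mean(scores[, j])) / s
  }
  dimnames(std) <- dimnames(scores)
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = var_frac[seq_len(k)],
                 standardized_scores = std,
                 n_imputed = sc$n_imputed, n_dropped = sc$n_dropped),
            class = "pca_result")
}

#' Associate principal components with sample variables
#'
#' Fits a simple linear model `PC ~ variable` for every (component,
#' variable) pair, reporting the model R-squared and F-test p-value.
#' Categorical variables enter as factors (k levels contribute k - 1
#' indicator columns; R-squared is the model R-squared). P-values are
#' adjusted by Benjamini-Hochberg FDR across the full component-by-variable
#' family. Constant variables are skipped with a note.
#'
#' @param pca A `pca_result` from [pca_scaled()].
#' @param samples data.frame of sample covariates with `sample_id`
#'   matching the PCA's sample order (reordered by id when possible).
#' @param variables Character vector of column names to test.
#' @param n_components Number of leading components to test (default 10,
#'   truncated to those available).
#' @return data.frame: `component`, `variable`, `r_squared`, `p_value`,
#'   `fdr`, `significant` (FDR < 0.05); skipped variables in attribute
#'   `skipped`.
#' @export
pc_association <- function(pca, samples, variables, n_components = 10L) {
  scores <- pca$scores
  if ("sample_id" %in% names(samples) && !is.null(rownames(scores))) {
    idx <- match(rownames(scores), samples$sample_id)
    if (anyNA(idx)) stop("samples sheet is missing ids present in the PCA")
    samples <- samples[idx, , drop = FALSE]
  }
  k <- min(n_components, ncol(scores))
  skipped <- character()
  rows <- list()
  for (v in variables) {
    if (!v %in% names(samples)) stop("variable not in sample sheet: ", v)
    x <- samples[[v]]
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 2L) {
      skipped <- c(skipped, v)
      next
    }
    if (is.character(x)) x <- factor(x)
    for (j in seq_len(k)) {
      y <- scores[, j]
      fit <- stats::lm(y[ok] ~ x[ok])
      sm <- suppressWarnings(summary(fit))
      fstat <- sm$fstatistic
      p <- if (is.null(fstat)) NA_real_ else
        stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        component = j, variable = v, r_squared = sm$r.squared,
        p_value = unname(p), stringsAsFactors = FALSE)
    }
  }
  if (length(skipped)) message("constant variables skipped: ",
                               paste(skipped, collapse = ", "))
  if (!length(rows)) stop("no testable variables")
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr < 0.05
  attr(out, "skipped") <- skipped
  out
}

#' PC-PR2 variance partitioning
#'
#' Decomposes the centred/scaled beta matrix, keeps the smallest number of
#' leading components whose cumulative variance reaches
#' `variance_threshold`, and for each kept component fits the full linear
#' model of the component score on all covariates and, per covariate, the
#' reduced model without it. The per-component partial R-squared is
#' `(RSS_reduced - RSS_full) / RSS_reduced`; the overall statistic per
#' covariate is the eigenvalue-weighted mean of the per-component partial
#' R-squared values, reported in percent.
#'
#' @param beta Probes-by-samples beta matrix.
#' @param covariates data.frame of >= 2 covariates (rows aligned with the
#'   samples; complete rows required). Character columns become factors.
#' @param variance_threshold Cumulative variance fraction to capture
#'   (default 0.9).
#' @return Object of class `pcpr2_result`: list with `partial_r2_pct`
#'   (named per covariate), `n_components_used`, `variance_captured`,
#'   `per_component` (matrix of per-PC partial R-squared),
#'   `eigenvalues`.
#' @export
pcpr2 <- function(beta, covariates, variance_threshold = 0.9) {
  if (ncol(covariates) < 2L) stop("pcpr2 requires >= 2 covariates")
  if (anyNA(covariates)) stop("pcpr2 requires complete covariate rows")
  if (nrow(covariates) != ncol(beta)) {
    stop("covariate rows must match beta samples")
  }
  covariates <- as.data.frame(covariates)
  for (j in seq_along(covariates)) {
    if (is.character(covariates[[j]])) covariates[[j]] <- factor(covariates[[j]])
  }
  # collinearity guard: full design must be of full column rank
  mm <- stats::model.matrix(~ ., data = covariates)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    num <- covariates[vapply(covariates, is.numeric, logical(1))]
    pair <- "a covariate pair"
    if (ncol(num) >= 2L) {
      cm <- abs(stats::cor(num))
      diag(cm) <- 0
      w <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
      pair <- paste(colnames(num)[w], collapse = " / ")
    }
    stop("collinear covariates (rank-deficient design): ", pair)
  }

  sc <- .scale_beta(beta)
  m <- t(sc$scaled)
  sv <- svd(m)
  lambda <- sv$d^2
  vf <- lambda / sum(lambda)
  cum <- cumsum(vf)
  q <- which(cum >= variance_threshold)[1L]
  if (is.na(q)) q <- length(vf)
  scores <- sv$u[, seq_len(q), drop = FALSE] %*% diag(sv$d[seq_len(q)], q, q)

  vars <- names(covariates)
  pr2 <- matrix(NA_real_, q, length(vars),
                dimnames = list(paste0("PC", seq_len(q)), vars))
  for (j in seq_len(q)) {
    y <- scores[, j]
    rss_full <- sum(stats::lm.fit(mm, y)$residuals^2)
    for (v in vars) {
      reduced <- covariates[setdiff(vars, v)]
      mm_red <- stats::model.matrix(~ ., data = reduced)
      rss_red <- sum(stats::lm.fit(mm_red, y)$residuals^2)
      pr2[j, v] <- (rss_red - rss_full) / rss_red
    }
  }
  w <- lambda[seq_len(q)] / sum(lambda[seq_len(q)])
  overall <- 100 * colSums(pr2 * w)
  structure(list(partial_r2_pct = overall, n_components_used = q,
                 variance_captured = cum[q], per_component = pr2,
                 eigenvalues = lambda[seq_len(q)]),
            class = "pcpr2_result")
}

# Fast OLS of every CpG (row of y) on a common design matrix.
# Returns slope (2nd column coefficient), its two-sided p-value, and df.
.row_ols <- function(y, X, coef_idx = 2L) {
  XtXi <- solve(crossprod(X))
  H <- X %*% XtXi        # n x p
  coefs <- y %*% H       # CpG x p
  fitted <- coefs %*% t(X)
  resid <- y - fitted
  rss <- rowSums(resid^2)
  df <- ncol(y) - ncol(X)
  sigma2 <- rss / df
  se <- sqrt(sigma2 * XtXi[coef_idx, coef_idx])
  slope <- coefs[, coef_idx]
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se == 0] <- NA_real_
  list(slope = slope, p = p, df = df)
}

#' Per-CpG linear models with an effect-size gate
#'
#' Ordinary least squares of each CpG's beta values on a numeric predictor
#' (typically gestational age in weeks) plus optional adjustment
#' covariates. The slope is in beta units per predictor unit. P-values are
#' two-sided; FDR is Benjamini-Hochberg across CpGs; a CpG is flagged
#' significant only when both FDR < `fdr_max` and
#' `|slope| >= effect_threshold`. Run sex-stratified by the caller.
#' CpGs with missing values are fitted on complete cases.
#'
#' @param beta Probes-by-samples beta matrix.
#' @param samples data.frame with `sample_id` and the predictor /
#'   adjustment columns, aligned to `beta` columns by id.
#' @param predictor Name of the numeric predictor column
#'   (default `"gestational_age"`; needs >= 3 distinct values).
#' @param adjustment Optional character vector of adjustment covariate
#'   names (e.g. ancestry coordinates, cell proportions).
#' @param effect_threshold Minimum absolute slope for significance
#'   (default 0.03, in beta units per predictor unit).
#' @param fdr_max FDR cut-off (default 0.05).
#' @return data.frame: `cpg_id`, `slope`, `p_value`, `fdr`, `significant`.
#' @export
cpg_linear_model <- function(beta, samples, predictor = "gestational_age",
                             adjustment = NULL, effect_threshold = 0.03,
                             fdr_max = 0.05) {
  idx <- match(colnames(beta), samples$sample_id)
  if (anyNA(idx)) stop("samples sheet is missing ids present in beta")
  samples <- samples[idx, , drop = FALSE]
  x <- samples[[predictor]]
  if (!is.numeric(x)) stop("predictor must be numeric")
  if (length(unique(x[!is.na(x)])) < 3L) {
    stop("predictor needs >= 3 distinct values")
  }
  covs <- data.frame(..pred.. = x)
  for (a in adjustment) {
    v <- samples[[a]]
    if (is.character(v)) v <- factor(v)
    covs[[a]] <- v
  }
  keep_rows <- stats::complete.cases(covs)
  covs <- covs[keep_rows, , drop = FALSE]
  X <- stats::model.matrix(~ ., data = covs)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  y <- beta[, keep_rows, drop = FALSE]

  has_na <- rowSums(is.na(y)) > 0L
  slope <- numeric(nrow(y)); p <- numeric(nrow(y))
  if (any(!has_na)) {
    res <- .row_ols(y[!has_na, , drop = FALSE], X)
    slope[!has_na] <- res$slope
    p[!has_na] <- res$p
  }
  for (i in which(has_na)) {
    ok <- !is.na(y[i, ])
    if (sum(ok) <= ncol(X)) { slope[i] <- NA; p[i] <- NA; next }
    fit <- stats::lm.fit(X[ok, , drop = FALSE], y[i, ok])
    rss <- sum(fit$residuals^2)
    df <- sum(ok) - ncol(X)
    XtXi <- solve(crossprod(X[ok, , drop = FALSE]))
    se <- sqrt(rss / df * XtXi[2L, 2L])
    slope[i] <- fit$coefficients[2L]
    p[i] <- if (se == 0) NA else 2 * stats::pt(-abs(slope[i] / se), df)
  }
  p[!is.na(p) & p > 1] <- 1
  fdr <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  fdr[ok] <- bh_fdr(p[ok])
  data.frame(cpg_id = rownames(beta), slope = slope, p_value = p, fdr = fdr,
             significant = !is.na(fdr) & fdr < fdr_max &
               abs(slope) >= effect_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank-sum comparisons of a reference group against all others
#'
#' Wilcoxon rank-sum tests of a per-sample summary value between a
#' reference group and every other group, with Benjamini-Hochberg FDR
#' across the family and significance stars (`*` FDR < 0.05, `**` < 0.01,
#' `***` < 0.001, `****` < 0.0001). Groups with fewer than 2 samples are
#' skipped with a note.
#'
#' @param values Numeric vector of per-sample summaries.
#' @param groups Character/factor vector of group labels, same length.
#' @param reference_group Label of the reference group.
#' @return data.frame: `group`, `n_ref`, `n_group`, `p_value`, `fdr`,
#'   `stars`; skipped groups in attribute `skipped`.
#' @export
group_compare <- function(values, groups, reference_group) {
  groups <- as.character(groups)
  ref <- values[groups == reference_group & !is.na(values)]
  if (length(ref) == 0L) stop("reference group is empty")
  others <- setdiff(unique(groups), reference_group)
  skipped <- character()
  rows <- list()
  for (g in others) {
    v <- values[groups == g & !is.na(values)]
    if (length(v) < 2L || length(ref) < 2L) {
      skipped <- c(skipped, g)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, n_ref = length(ref), n_group = length(v),
      p_value = .wilcox_p(ref, v), stringsAsFactors = FALSE)
  }
  if (length(skipped)) message("groups skipped (< 2 samples): ",
                               paste(skipped, collapse = ", "))
  if (!length(rows)) stop("no comparable groups")
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out$stars <- vapply(out$fdr, function(q) {
    if (q < 1e-4) "****" else if (q < 1e-3) "***"
    else if (q < 1e-2) "**" else if (q < 0.05) "*" else ""
  }, character(1))
  attr(out, "skipped") <- skipped
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, returned in
#' the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, elementwise >= input and <= 1.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
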
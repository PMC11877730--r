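# XCI status calling from allele-balance matrices and the methylation-XCI
# correlation battery.
#
# A gene is "subject" to XCI when most informative samples show strongly
# skewed (monoallelic) expression, "escape" when few do, and "variable"
# otherwise. Thresholds follow the allele-specific-expression convention:
# a sample is subject-like when its folded allele balance is >= 0.8.

#' Call XCI status per gene from allele balances
#'
#' For each gene, computes the number of informative (non-missing) samples,
#' the proportion of informative samples with balance `>= subject_balance`
#' ("proportion subject"), and the median balance. Categories:
#' subject when `proportion_subject > subject_prop` and median
#' `>= subject_median`; escape when `proportion_subject < escape_prop` and
#' median `<= escape_median`; otherwise variable. Genes with fewer than
#' `min_informative` informative samples are reported uncalled
#' (`called = FALSE`, category `NA`).
#'
#' @param ab Genes-by-samples allele-balance matrix on the folded scale
#'   \[0.5, 1\] (see [fold_balance()]); `NA` marks uninformative samples.
#' @param subject_balance Per-sample balance at or above which a sample is
#'   subject-like (default 0.8).
#' @param subject_prop Proportion-subject above which (strict) a gene may
#'   be called subject (default 0.7).
#' @param subject_median Median balance at or above which a gene may be
#'   called subject (default 0.8).
#' @param escape_prop Proportion-subject below which (strict) a gene may
#'   be called escape (default 0.3).
#' @param escape_median Median balance at or below which a gene may be
#'   called escape (default 0.75).
#' @param min_informative Minimum informative samples for a call
#'   (default 5).
#' @return data.frame: `gene_id`, `n_informative`, `proportion_subject`,
#'   `median_balance`, `category` (`escape`/`variable`/`subject`, `NA` when
#'   uncalled), `called`.
#' @export
call_xci <- function(ab, subject_balance = 0.8, subject_prop = 0.7,
                     subject_median = 0.8, escape_prop = 0.3,
                     escape_median = 0.75, min_informative = 5L) {
  if (is.null(dim(ab))) stop("ab must be a genes x samples matrix")
  if (nrow(ab) == 0L) {
    return(data.frame(gene_id = character(), n_informative = integer(),
                      proportion_subject = numeric(),
                      median_balance = numeric(), category = character(),
                      called = logical(), stringsAsFactors = FALSE))
  }
  rng <- range(ab, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0.5 - 1e-12 || rng[2] > 1 + 1e-12)) {
    stop("allele balances must be folded to [0.5, 1]; see fold_balance()")
  }
  informative <- !is.na(ab)
  n_inf <- rowSums(informative)
  prop_subject <- rowSums(ab >= subject_balance, na.rm = TRUE) / n_inf
  med <- apply(ab, 1L, stats::median, na.rm = TRUE)
  category <- ifelse(
    prop_subject > subject_prop & med >= subject_median, "subject",
    ifelse(prop_subject < escape_prop & med <= escape_median, "escape",
           "variable"))
  called <- n_inf >= min_informative
  category[!called] <- NA_character_
  prop_subject[n_inf == 0L] <- NA_real_
  data.frame(gene_id = rownames(ab), n_informative = as.integer(n_inf),
             proportion_subject = prop_subject, median_balance = med,
             category = category, called = called,
             stringsAsFactors = FALSE, row.names = NULL)
}

.xci_metric <- function(summaries, metric) {
  switch(metric,
         mean_XX = summaries$beta_mean_XX,
         median_XX = summaries$beta_median_XX,
         delta_beta = summaries$delta_beta,
         stop("unknown metric: ", metric))
}

.xci_filter <- function(merged, filter_spec, xy_beta_max) {
  keep <- rep(TRUE, nrow(merged))
  if (filter_spec %in% c("exclude_xy_high", "both")) {
    keep <- keep & !is.na(merged$beta_mean_XY) & merged$beta_mean_XY <= xy_beta_max
  }
  if (filter_spec %in% c("cgi_only", "both")) {
    if (!"cgi" %in% names(merged)) {
      stop("filter '", filter_spec, "' requires a cgi column in the summaries")
    }
    keep <- keep & !is.na(merged$cgi) & merged$cgi
  }
  merged[keep, , drop = FALSE]
}

#' Correlate region methylation with XCI status
#'
#' Pearson correlation, over genes present in both inputs, between a
#' region-level methylation metric (`mean_XX`, `median_XX` or `delta_beta`)
#' and an XCI outcome (`proportion_subject` or `median_balance`), after an
#' optional gene filter: `all` (none), `exclude_xy_high` (drop genes with
#' XY mean beta above `xy_beta_max`), `cgi_only` (keep promoters
#' overlapping HC/IC CpG islands), or `both`.
#'
#' @param summaries Region summary data.frame from [region_mean_beta()]
#'   (one region kind, e.g. promoters), keyed by `gene_id`.
#' @param calls XCI call data.frame from [call_xci()]; only called genes
#'   are used.
#' @param filter_spec One of `"all"`, `"exclude_xy_high"`, `"cgi_only"`,
#'   `"both"`.
#' @param metric Methylation metric name (see above).
#' @param outcome XCI outcome name (see above).
#' @param xy_beta_max XY mean beta cut-off for `exclude_xy_high`
#'   (default 0.1).
#' @return One-row data.frame: `filter_label`, `metric`, `outcome`,
#'   `n_genes`, `pearson_r`, `p_value`. `pearson_r` is `NA` (flagged via
#'   `degenerate = TRUE`) when either variable is constant.
#' @export
correlate_dname_xci <- function(summaries, calls,
                                filter_spec = c("all", "exclude_xy_high",
                                                "cgi_only", "both"),
                                metric = c("delta_beta", "mean_XX", "median_XX"),
                                outcome = c("proportion_subject",
                                            "median_balance"),
                                xy_beta_max = 0.1) {
  filter_spec <- match.arg(filter_spec)
  metric <- match.arg(metric)
  outcome <- match.arg(outcome)
  calls <- calls[calls$called, , drop = FALSE]
  merged <- merge(summaries, calls, by = "gene_id")
  merged <- .xci_filter(merged, filter_spec, xy_beta_max)
  x <- .xci_metric(merged, metric)
  y <- merged[[outcome]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("fewer than 3 genes survive filter '", filter_spec, "'")
  }
  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  if (degenerate) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  data.frame(filter_label = filter_spec, metric = metric, outcome = outcome,
             n_genes = length(x), pearson_r = r, p_value = p,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Run a methylation-XCI correlation battery
#'
#' Evaluates [correlate_dname_xci()] over every requested combination of
#' filter, metric and outcome and adjusts all p-values jointly with
#' Benjamini-Hochberg FDR — one FDR family per invocation.
#'
#' @inheritParams correlate_dname_xci
#' @param filters,metrics,outcomes Character vectors of combinations to
#'   run.
#' @return data.frame with one row per combination plus an `fdr` column
#'   and a `family_size` attribute.
#' @export
xci_battery <- function(summaries, calls,
                        filters = c("all", "exclude_xy_high", "cgi_only",
                                    "both"),
                        metrics = c("mean_XX", "median_XX", "delta_beta"),
                        outcomes = c("proportion_subject", "median_balance"),
                        xy_beta_max = 0.1) {
  combos <- expand.grid(filter = filters, metric = metrics,
                        outcome = outcomes, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    correlate_dname_xci(summaries, calls, combos$filter[i],
                        combos$metric[i], combos$outcome[i], xy_beta_max)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$p_value)
  out$fdr[ok] <- bh_fdr(out$p_value[ok])
  attr(out, "family_size") <- sum(ok)
  out
}

#' Compare methylation between XCI categories
#'
#' Pairwise Wilcoxon rank-sum tests of the sex difference in region
#' methylation (`delta_beta`) between escape, variable and subject genes,
#' plus a rank-sum comparison of XX vs XY mean beta within each category.
#' P-values in each table are adjusted jointly by Benjamini-Hochberg FDR.
#' Pairs (or categories) with fewer than 2 genes on either side are
#' skipped with a note.
#'
#' @inheritParams correlate_dname_xci
#' @return List with `pairwise` (category pair tests on `delta_beta`),
#'   `within` (XX vs XY per category), `category_means` (per-category
#'   summary of `delta_beta`, XX and XY means), `skipped` (character
#'   vector).
#' @export
compare_categories <- function(summaries, calls) {
  calls <- calls[calls$called, , drop = FALSE]
  merged <- merge(summaries, calls, by = "gene_id")
  cats <- c("escape", "variable", "subject")
  skipped <- character()

  category_means <- do.call(rbind, lapply(cats, function(cc) {
    sub <- merged[merged$category == cc, , drop = FALSE]
    data.frame(category = cc, n_genes = nrow(sub),
               mean_delta_beta = mean(sub$delta_beta, na.rm = TRUE),
               mean_beta_XX = mean(sub$beta_mean_XX, na.rm = TRUE),
               mean_beta_XY = mean(sub$beta_mean_XY, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))

  pairs <- utils::combn(cats, 2L, simplify = FALSE)
  pw <- list()
  for (p in pairs) {
    a <- merged$delta_beta[merged$category == p[1L]]
    b <- merged$delta_beta[merged$category == p[2L]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) {
      skipped <- c(skipped, paste(p, collapse = " vs "))
      next
    }
    pv <- .wilcox_p(a, b)
    pw[[length(pw) + 1L]] <- data.frame(
      group_a = p[1L], group_b = p[2L], n_a = length(a), n_b = length(b),
      p_value = pv, stringsAsFactors = FALSE)
  }
  pairwise <- if (length(pw)) do.call(rbind, pw) else NULL
  if (!is.null(pairwise)) pairwise$fdr <- bh_fdr(pairwise$p_value)

  wi <- list()
  for (cc in cats) {
    xx <- merged$beta_mean_XX[merged$category == cc]
    xy <- merged$beta_mean_XY[merged$category == cc]
    xx <- xx[!is.na(xx)]; xy <- xy[!is.na(xy)]
    if (length(xx) < 2L || length(xy) < 2L) {
      skipped <- c(skipped, paste0(cc, ": XX vs XY"))
      next
    }
    wi[[length(wi) + 1L]] <- data.frame(
      category = cc, n_genes = length(xx), p_value = .wilcox_p(xx, xy),
      stringsAsFactors = FALSE)
  }
  within <- if (length(wi)) do.call(rbind, wi) else NULL
  if (!is.null(within)) within$fdr <- bh_fdr(within$p_value)

  list(pairwise = pairwise, within = within,
       category_means = category_means, skipped = skipped)
}

# Two-sided rank-sum p-value: exact distribution when both groups have
# <= 12 observations and no ties, otherwise normal approximation with tie
# correction (wilcox.test's standard behaviour).
.wilcox_p <- function(a, b) {
  exact <- length(a) <= 12L && length(b) <= 12L
  suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                      correct = !exact)$p.value)
}

#' Cross-tissue XCI concordance
#'
#' Cross-classifies the XCI categories of the genes called in two tissues,
#' tests whether the per-tissue category counts differ (chi-square on the
#' 2 x 3 counts-by-tissue table), and lists discordant genes. "Fully
#' discordant" genes flip between escape and subject.
#'
#' @param calls_a,calls_b XCI call data.frames from [call_xci()].
#' @param labels Length-2 character vector naming the tissues.
#' @return List: `cross_table` (3 x 3, rows = tissue A), `counts_by_tissue`
#'   (2 x 3), `chisq_p`, `fully_discordant`, `partially_discordant`
#'   (gene id vectors), `n_shared`.
#' @export
cross_tissue_concordance <- function(calls_a, calls_b,
                                     labels = c("tissue_a", "tissue_b")) {
  a <- calls_a[calls_a$called, c("gene_id", "category")]
  b <- calls_b[calls_b$called, c("gene_id", "category")]
  merged <- merge(a, b, by = "gene_id", suffixes = c("_a", "_b"))
  if (nrow(merged) == 0L) stop("no shared called genes between tissues")
  lev <- c("escape", "variable", "subject")
  fa <- factor(merged$category_a, levels = lev)
  fb <- factor(merged$category_b, levels = lev)
  cross <- table(fa, fb, dnn = labels)
  counts <- rbind(table(fa), table(fb))
  rownames(counts) <- labels
  chisq_p <- suppressWarnings(stats::chisq.test(counts)$p.value)
  fully <- merged$gene_id[(merged$category_a == "escape" &
                             merged$category_b == "subject") |
                            (merged$category_a == "subject" &
                               merged$category_b == "escape")]
  partially <- merged$gene_id[merged$category_a != merged$category_b]
  partially <- setdiff(partially, fully)
  list(cross_table = cross, counts_by_tissue = counts, chisq_p = chisq_p,
       fully_discordant = fully, partially_discordant = partially,
       n_shared = nrow(merged))
}
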
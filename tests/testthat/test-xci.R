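ab_matrix <- function(values, gene = "G1") {
  matrix(values, nrow = 1, dimnames = list(gene, paste0("S", seq_along(values))))
}

test_that("XCI calls follow the stated threshold rules on forced examples", {
  sub <- call_xci(ab_matrix(c(0.90, 0.85, 0.95, 0.82)), min_informative = 4)
  expect_equal(sub$proportion_subject, 1.0)
  expect_equal(sub$median_balance, 0.875)
  expect_equal(sub$category, "subject")
  esc <- call_xci(ab_matrix(c(0.55, 0.60, 0.50, 0.81)), min_informative = 4)
  expect_equal(esc$proportion_subject, 0.25)
  expect_equal(esc$median_balance, 0.575)
  expect_equal(esc$category, "escape")
})

test_that("XCI call boundaries are strict/inclusive exactly as posted", {
  # proportion exactly 0.7 with median >= 0.8 is NOT subject (strict >)
  b <- c(rep(0.9, 7), rep(0.79, 3))
  r <- call_xci(ab_matrix(b), min_informative = 5)
  expect_equal(r$proportion_subject, 0.7)
  expect_equal(r$category, "variable")
  # proportion just above 0.7, median exactly 0.8 IS subject (inclusive >=)
  b2 <- c(rep(0.62, 2), rep(0.8, 8))
  r2 <- call_xci(ab_matrix(b2), min_informative = 5)
  expect_equal(r2$median_balance, 0.8)
  expect_true(r2$proportion_subject > 0.7)
  expect_equal(r2$category, "subject")
  # proportion exactly 0.3 is NOT escape (strict <)
  b3 <- c(rep(0.9, 3), rep(0.55, 7))
  r3 <- call_xci(ab_matrix(b3), min_informative = 5)
  expect_equal(r3$proportion_subject, 0.3)
  expect_equal(r3$category, "variable")
  # proportion < 0.3 with median exactly 0.75 IS escape (inclusive <=)
  b4 <- c(0.9, 0.9, rep(0.75, 8))
  r4 <- call_xci(ab_matrix(b4), min_informative = 5)
  expect_equal(r4$median_balance, 0.75)
  expect_equal(r4$category, "escape")
  # below the informative floor: uncalled
  r5 <- call_xci(ab_matrix(c(0.9, 0.9, 0.9)), min_informative = 5)
  expect_false(r5$called)
  expect_true(is.na(r5$category))
})

test_that("XCI calls match the literal rule evaluator on random matrices", {
  set.seed(8)
  for (rep in 1:300) {
    ng <- sample(1:10, 1)
    ns <- sample(5:20, 1)
    ab <- matrix(0.5 + 0.5 * runif(ng * ns), ng, ns,
                 dimnames = list(sprintf("G%02d", 1:ng),
                                 sprintf("S%02d", 1:ns)))
    ab[runif(ng * ns) < 0.2] <- NA
    calls <- call_xci(ab)
    for (g in seq_len(ng)) {
      want <- oracle_call_xci_gene(ab[g, ])
      expect_identical(calls$category[g], want$category)
      expect_equal(calls$n_informative[g], want$n)
    }
  }
})

test_that("calls are invariant to sample order", {
  set.seed(9)
  ab <- matrix(0.5 + 0.5 * runif(60), 6, 10,
               dimnames = list(paste0("G", 1:6), paste0("S", 1:10)))
  c1 <- call_xci(ab)
  c2 <- call_xci(ab[, sample(10)])
  expect_equal(c1$category, c2$category)
  expect_equal(c1$proportion_subject, c2$proportion_subject)
})

make_summary <- function(genes, xx, xy, cgi = TRUE) {
  data.frame(region_id = paste0("promoter:", genes), gene_id = genes,
             region_kind = "promoter", n_cpgs = 3L,
             beta_mean_XX = xx, beta_mean_XY = xy,
             beta_median_XX = xx, beta_median_XY = xy,
             delta_beta = xx - xy, cgi = cgi, stringsAsFactors = FALSE)
}

make_calls <- function(genes, prop, med = NULL) {
  if (is.null(med)) med <- 0.5 + 0.5 * prop
  data.frame(gene_id = genes, n_informative = 20L,
             proportion_subject = prop, median_balance = med,
             category = ifelse(prop > 0.7, "subject",
                               ifelse(prop < 0.3, "escape", "variable")),
             called = TRUE, stringsAsFactors = FALSE)
}

test_that("correlation battery recovers identity and flags degeneracy", {
  genes <- sprintf("G%02d", 1:20)
  prop <- seq(0, 1, length.out = 20)
  sm <- make_summary(genes, xx = prop, xy = rep(0, 20))
  calls <- make_calls(genes, prop)
  r <- correlate_dname_xci(sm, calls, "all", "mean_XX", "proportion_subject")
  expect_equal(r$pearson_r, 1.0)
  const <- make_calls(genes, rep(0.5, 20))
  rc <- correlate_dname_xci(sm, const, "all", "mean_XX", "proportion_subject")
  expect_true(rc$degenerate)
  expect_true(is.na(rc$pearson_r))
  expect_error(correlate_dname_xci(sm[1:2, ], calls, "all", "mean_XX",
                                   "proportion_subject"), "fewer than 3")
})

test_that("battery correlations equal the closed-form Pearson formula", {
  set.seed(12)
  genes <- sprintf("G%02d", 1:40)
  xx <- runif(40); xy <- runif(40, 0, 0.3)
  prop <- pmin(pmax(xx - xy + rnorm(40, 0, 0.2), 0), 1)
  sm <- make_summary(genes, xx, xy, cgi = runif(40) < 0.7)
  calls <- make_calls(genes, prop)
  res <- xci_battery(sm, calls)
  direct_r <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  row <- res[res$filter_label == "all" & res$metric == "delta_beta" &
               res$outcome == "proportion_subject", ]
  expect_equal(row$pearson_r, direct_r(xx - xy, prop), tolerance = 1e-12)
  # exclude_xy_high filter really excludes XY mean beta > 0.1
  row2 <- res[res$filter_label == "exclude_xy_high" &
                res$metric == "delta_beta" &
                res$outcome == "proportion_subject", ]
  keep <- xy <= 0.1
  expect_equal(row2$n_genes, sum(keep))
  expect_equal(row2$pearson_r, direct_r((xx - xy)[keep], prop[keep]),
               tolerance = 1e-12)
  # cgi filter keeps flagged promoters only
  row3 <- res[res$filter_label == "cgi_only" & res$metric == "mean_XX" &
                res$outcome == "median_balance", ]
  expect_equal(row3$n_genes, sum(sm$cgi))
  # FDR family covers all non-degenerate rows
  expect_equal(attr(res, "family_size"), sum(!is.na(res$p_value)))
  expect_equal(res$fdr[!is.na(res$p_value)],
               oracle_bh(res$p_value[!is.na(res$p_value)]))
})

test_that("delta_beta correlation is invariant to adding a constant to both sexes", {
  set.seed(13)
  genes <- sprintf("G%02d", 1:25)
  xx <- runif(25, 0, 0.5); xy <- runif(25, 0, 0.2)
  prop <- pmin(pmax((xx - xy) * 2 + rnorm(25, 0, 0.1), 0), 1)
  calls <- make_calls(genes, prop)
  r1 <- correlate_dname_xci(make_summary(genes, xx, xy), calls, "all",
                            "delta_beta", "proportion_subject")
  r2 <- correlate_dname_xci(make_summary(genes, xx + 0.2, xy + 0.2), calls,
                            "all", "delta_beta", "proportion_subject")
  expect_equal(r1$pearson_r, r2$pearson_r, tolerance = 1e-12)
})

test_that("category comparisons detect separation and match exact rank-sum", {
  genes <- sprintf("G%02d", 1:30)
  cat <- rep(c("escape", "subject", "variable"), each = 10)
  delta <- ifelse(cat == "escape", 0, ifelse(cat == "subject", 0.4, 0.2)) +
    seq(0, 0.001, length.out = 30)  # break ties deterministically
  sm <- make_summary(genes, xx = delta, xy = rep(0, 30))
  calls <- data.frame(gene_id = genes, n_informative = 20L,
                      proportion_subject = 0.5, median_balance = 0.8,
                      category = cat, called = TRUE)
  res <- compare_categories(sm, calls)
  es <- res$pairwise[res$pairwise$group_a == "escape" &
                       res$pairwise$group_b == "subject", ]
  expect_lt(es$p_value, 0.01)
  expect_equal(res$category_means$n_genes, c(10L, 10L, 10L))
  # 4+4 exact enumeration oracle
  a <- c(0.01, 0.05, 0.11, 0.19)
  b <- c(0.22, 0.31, 0.42, 0.55)
  sm2 <- make_summary(sprintf("H%d", 1:8), xx = c(a, b), xy = rep(0, 8))
  calls2 <- data.frame(gene_id = sprintf("H%d", 1:8), n_informative = 10L,
                       proportion_subject = 0.5, median_balance = 0.8,
                       category = rep(c("escape", "subject"), each = 4),
                       called = TRUE)
  res2 <- compare_categories(sm2, calls2)
  p_pkg <- res2$pairwise$p_value[res2$pairwise$group_a == "escape" &
                                   res2$pairwise$group_b == "subject"]
  expect_equal(p_pkg, oracle_ranksum_exact_p(a, b), tolerance = 1e-12)
  # small categories are skipped with a note
  calls3 <- calls2; calls3$category[1:4] <- c("escape", rep("variable", 3))
  res3 <- compare_categories(sm2, calls3)
  expect_true(any(grepl("escape", res3$skipped)))
})

test_that("cross-tissue concordance counts categories and discordant flips", {
  genes <- sprintf("G%02d", 1:78)
  cat_a <- c(rep("escape", 4), rep("variable", 7), rep("subject", 67))
  cat_b <- cat_a
  cat_b[1] <- "subject"  # one full escape->subject flip
  cat_b[5] <- "escape"   # one partial flip
  calls_a <- data.frame(gene_id = genes, n_informative = 20L,
                        proportion_subject = 0.5, median_balance = 0.8,
                        category = cat_a, called = TRUE)
  calls_b <- transform(calls_a, category = cat_b)
  res <- cross_tissue_concordance(calls_a, calls_b)
  expect_equal(res$n_shared, 78L)
  expect_equal(res$fully_discordant, genes[1])
  expect_equal(res$partially_discordant, genes[5])
  expect_equal(unname(res$counts_by_tissue["tissue_a", ]),
               c(4L, 7L, 67L))
  expect_equal(sum(res$cross_table), 78L)
  expect_equal(res$cross_table["subject", "subject"], 67L)
  expect_gt(res$chisq_p, 0.05)
  # identical calls: off-diagonal zero
  res2 <- cross_tissue_concordance(calls_a, calls_a)
  expect_equal(length(res2$fully_discordant), 0L)
  expect_equal(sum(res2$cross_table) - sum(diag(res2$cross_table)), 0L)
  # random calls vs hand-built table
  set.seed(14)
  cat_r <- sample(c("escape", "variable", "subject"), 78, TRUE)
  calls_r <- transform(calls_a, category = cat_r)
  res3 <- cross_tissue_concordance(calls_a, calls_r)
  expect_equal(as.vector(res3$cross_table),
               as.vector(table(factor(cat_a, c("escape", "variable", "subject")),
                               factor(cat_r, c("escape", "variable", "subject")))))
})
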
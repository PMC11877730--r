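# Independent brute-force oracles used by the equivalence tests. These
# re-evaluate the stated rules directly, without interval containers or
# the package's fast paths.

# All-pairs promoter assignment: PLS [start, end) overlaps the closed
# position window [tss - flank, tss + flank] on the same chromosome.
oracle_assign_promoters <- function(pls, tss, flank = 200L) {
  rows <- list()
  for (i in seq_len(nrow(pls))) for (j in seq_len(nrow(tss))) {
    if (pls$chrom[i] != tss$chrom[j]) next
    lo <- tss$pos[j] - flank
    hi <- tss$pos[j] + flank
    # interval covers positions start .. end-1
    if (pls$start[i] <= hi && (pls$end[i] - 1L) >= lo) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = pls$chrom[i], start = pls$start[i], end = pls$end[i],
        gene_id = tss$gene_id[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(chrom = character(),
                                       start = integer(), end = integer(),
                                       gene_id = character()))
  unique(do.call(rbind, rows))
}

# All-pairs enhancer assignment: TSS position in [start - flank, end + flank).
oracle_assign_enhancers <- function(pels, tss, flank = 2000L) {
  rows <- list()
  for (i in seq_len(nrow(pels))) for (j in seq_len(nrow(tss))) {
    if (pels$chrom[i] != tss$chrom[j]) next
    if (tss$pos[j] >= pels$start[i] - flank &&
        tss$pos[j] < pels$end[i] + flank) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = pels$chrom[i], start = pels$start[i], end = pels$end[i],
        gene_id = tss$gene_id[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(chrom = character(),
                                       start = integer(), end = integer(),
                                       gene_id = character()))
  unique(do.call(rbind, rows))
}

# Direct three-clause CGI rule evaluator.
oracle_classify_cgi <- function(len, gc, oe) {
  if (len > 500 && gc > 0.55 && oe > 0.75) return("HC")
  if (len > 200 && gc > 0.50 && oe > 0.48) return("IC")
  "none"
}

# Distance-based TSS window oracle for one CpG.
oracle_tss_window <- function(pos, chrom, tss) {
  lab <- "none"
  band <- FALSE
  for (j in seq_len(nrow(tss))) {
    if (!is.null(tss$chrom) && tss$chrom[j] != chrom) next
    d <- if (tss$strand[j] == "+") tss$pos[j] - pos else pos - tss$pos[j]
    if (d >= 1 && d <= 200) return("TSS200")
    if (d >= 201 && d <= 1500) band <- TRUE
  }
  if (band) "TSS200_1500" else "none"
}

# Point-in-interval membership (0-based half-open) over a track.
oracle_in_track <- function(pos, chrom, track) {
  if (is.null(track) || nrow(track) == 0L) return(FALSE)
  any(track$chrom == chrom & track$start <= pos & pos < track$end)
}

# Literal two-clause XCI rule evaluator for one gene's balances.
oracle_call_xci_gene <- function(balances, min_informative = 5L) {
  b <- balances[!is.na(balances)]
  n <- length(b)
  if (n < min_informative) return(list(category = NA_character_, n = n))
  prop <- sum(b >= 0.8) / n
  med <- median(b)
  cat <- if (prop > 0.7 && med >= 0.8) "subject"
  else if (prop < 0.3 && med <= 0.75) "escape"
  else "variable"
  list(category = cat, n = n, prop = prop, med = med)
}

# Literal three-clause probe-filter evaluator.
oracle_filter_probes <- function(beta, detp, beads, mask, mappable,
                                 frac = 0.05) {
  keep <- character()
  for (i in seq_len(nrow(beta))) {
    fails <- (detp[i, ] > 0.01) | (beads[i, ] < 3) | is.na(beta[i, ])
    drop <- mean(fails) > frac ||
      rownames(beta)[i] %in% mask ||
      (!is.null(mappable) && !(rownames(beta)[i] %in% mappable))
    if (!drop) keep <- c(keep, rownames(beta)[i])
  }
  keep
}

# Exact two-sided rank-sum p-value by complete enumeration of group
# assignments (no ties assumed).
oracle_ranksum_exact_p <- function(a, b) {
  all_v <- c(a, b)
  n <- length(all_v)
  ranks <- rank(all_v)
  w_obs <- sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combs <- combn(n, length(a))
  ws <- apply(combs, 2L, function(idx) {
    sum(rank(all_v)[idx]) - length(a) * (length(a) + 1) / 2
  })
  mu <- length(a) * length(b) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# Step-up BH adjustment computed directly from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Random interval set on a small genome.
random_intervals <- function(n, chroms = c("chrX", "chr1"), max_pos = 10000L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample.int(300L, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = start,
             end = start + width, stringsAsFactors = FALSE)
}

random_tss <- function(n, chroms = c("chrX", "chr1"), max_pos = 10000L) {
  data.frame(gene_id = sprintf("G%03d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             pos = sample.int(max_pos, n, replace = TRUE) - 1L,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

pair_key <- function(df) {
  if (nrow(df) == 0L) return(character())
  sort(paste(df$chrom, df$start, df$end, df$gene_id, sep = ":"))
}
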
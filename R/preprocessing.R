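# Probe quality control, intensity-based sex inference, and region-level
# per-sex beta summaries.

#' Filter probes on quality control criteria
#'
#' A probe is dropped when the fraction of samples in which it fails QC
#' (detection p > `detection_p_max`, bead count < `bead_count_min`, or a
#' missing beta value) exceeds `frac_threshold` (strictly), when it appears
#' in `mask_list`, or when it is absent from `mappable` (if supplied). The
#' retained set preserves the input probe order.
#'
#' @param beta Probes-by-samples beta matrix (dimnames required).
#' @param qc List with probes-by-samples matrices `detection_p` and
#'   `bead_count` (either may be `NULL`, in which case that criterion never
#'   fails); an optional logical `missing` matrix is OR-ed with `is.na(beta)`.
#' @param mask_list Character vector of probe ids to exclude outright
#'   (e.g. a general-mask annotation of polymorphic / non-specific probes).
#' @param mappable Character vector of probe ids with valid genomic
#'   mappings; `NULL` (default) keeps all.
#' @param frac_threshold Maximum tolerated failing-sample fraction
#'   (default 0.05; comparison is strict `>`).
#' @param detection_p_max Detection p-value above which a sample fails
#'   (default 0.01).
#' @param bead_count_min Bead count below which a sample fails (default 3).
#' @return Character vector of retained probe ids, in input order.
#' @export
filter_probes <- function(beta, qc = list(), mask_list = character(),
                          mappable = NULL, frac_threshold = 0.05,
                          detection_p_max = 0.01, bead_count_min = 3) {
  if (ncol(beta) == 0L) stop("beta matrix has no samples")
  if (nrow(beta) == 0L) return(character())
  if (is.null(rownames(beta))) stop("beta matrix requires probe ids as rownames")
  fail <- is.na(beta)
  if (!is.null(qc$missing)) fail <- fail | qc$missing
  if (!is.null(qc$detection_p)) {
    stopifnot(all(dim(qc$detection_p) == dim(beta)))
    fail <- fail | qc$detection_p > detection_p_max
  }
  if (!is.null(qc$bead_count)) {
    stopifnot(all(dim(qc$bead_count) == dim(beta)))
    fail <- fail | qc$bead_count < bead_count_min
  }
  frac <- rowMeans(fail)
  keep <- frac <= frac_threshold
  keep <- keep & !(rownames(beta) %in% mask_list)
  if (!is.null(mappable)) keep <- keep & rownames(beta) %in% mappable
  rownames(beta)[keep]
}

#' Infer sample sex from X/Y probe intensities
#'
#' Normalises median X and Y chromosome probe intensities by the median
#' autosomal intensity and partitions samples into two clusters on
#' `(x_norm, y_norm)` with 2-means (fixed seed). The cluster with the
#' higher mean `y_norm` is labelled XY. When the clusters are degenerate
#' (centres separated by < 0.25 in `y_norm`, as happens when all samples
#' are one sex) the function falls back to the fixed threshold
#' `y_norm > 0.5 => XY` with a warning.
#'
#' @param intensities data.frame with columns `sample_id`, `med_x`,
#'   `med_y`, `med_auto` (all intensities positive).
#' @param reported_sex Optional character vector (`XX`/`XY`/`unknown`)
#'   aligned with `intensities`; mismatches against the inferred sex are
#'   flagged.
#' @param seed Seed for the 2-means initialisation (default 17).
#' @return data.frame with `sample_id`, `x_norm`, `y_norm`,
#'   `inferred_sex`, and `mismatch` (NA where no reported sex).
#' @export
infer_sex <- function(intensities, reported_sex = NULL, seed = 17L) {
  req <- c("sample_id", "med_x", "med_y", "med_auto")
  if (!all(req %in% names(intensities))) {
    stop("intensities must have columns sample_id, med_x, med_y, med_auto")
  }
  if (any(intensities$med_x <= 0 | intensities$med_y <= 0 |
          intensities$med_auto <= 0)) {
    stop("intensities must be positive")
  }
  x_norm <- intensities$med_x / intensities$med_auto
  y_norm <- intensities$med_y / intensities$med_auto
  n <- length(x_norm)
  if (n < 2L) {
    inferred <- ifelse(y_norm > 0.5, "XY", "XX")
  } else {
    xy_mat <- cbind(x_norm, y_norm)
    set.seed(seed)
    km <- stats::kmeans(xy_mat, centers = 2L, nstart = 10L)
    sep <- abs(diff(km$centers[, 2L]))
    if (sep < 0.25) {
      warning("sex clusters degenerate; falling back to y_norm > 0.5 threshold")
      inferred <- ifelse(y_norm > 0.5, "XY", "XX")
    } else {
      xy_cluster <- which.max(km$centers[, 2L])
      inferred <- ifelse(km$cluster == xy_cluster, "XY", "XX")
    }
  }
  mismatch <- rep(NA, n)
  if (!is.null(reported_sex)) {
    known <- reported_sex %in% c("XX", "XY")
    mismatch[known] <- inferred[known] != reported_sex[known]
  }
  data.frame(sample_id = intensities$sample_id, x_norm = x_norm,
             y_norm = y_norm, inferred_sex = inferred, mismatch = mismatch,
             stringsAsFactors = FALSE)
}

#' Expand CpG annotations into region membership tables
#'
#' Converts comma-collapsed gene memberships from [annotate_cpgs()] into a
#' long (region, gene, cpg) table for one region kind. Promoter regions
#' additionally carry a `cgi` flag: `TRUE` when any member CpG lies in an
#' HC or IC density CpG island.
#'
#' @param annotation data.frame from [annotate_cpgs()].
#' @param kind One of `"promoter"`, `"enhancer"`, `"gene_body"`,
#'   `"tss_window"`. For `tss_window`, regions are the two window labels
#'   (gene-agnostic).
#' @return data.frame with `region_id`, `gene_id`, `region_kind`, `cpg_id`
#'   and (for promoters) `cgi`.
#' @export
build_regions <- function(annotation,
                          kind = c("promoter", "enhancer", "gene_body",
                                   "tss_window")) {
  kind <- match.arg(kind)
  if (kind == "tss_window") {
    keep <- annotation$tss_window != "none"
    out <- data.frame(region_id = annotation$tss_window[keep],
                      gene_id = NA_character_,
                      region_kind = "tss_window",
                      cpg_id = annotation$cpg_id[keep],
                      stringsAsFactors = FALSE)
    return(out)
  }
  col <- switch(kind, promoter = "promoter_genes", enhancer = "enhancer_genes",
                gene_body = "body_genes")
  keep <- nzchar(annotation[[col]])
  genes <- strsplit(annotation[[col]][keep], ",", fixed = TRUE)
  # one region per gene: all CpGs annotated to that gene for this kind
  gene_id <- unlist(genes, use.names = FALSE)
  out <- data.frame(
    region_id = paste0(kind, ":", gene_id),
    gene_id = gene_id,
    region_kind = kind,
    cpg_id = rep(annotation$cpg_id[keep], lengths(genes)),
    stringsAsFactors = FALSE
  )
  if (kind == "promoter") {
    cgi_cpg <- annotation$cpg_id[annotation$cgi_class %in% c("HC", "IC")]
    cgi_by_region <- tapply(out$cpg_id %in% cgi_cpg, out$region_id, any)
    out$cgi <- as.logical(cgi_by_region[out$region_id])
  }
  unique(out)
}

#' Region-level per-sex beta summaries
#'
#' For each region, computes per-sample mean and median beta over its CpGs
#' (missing values ignored), then averages the per-sample statistics
#' within each sex, weighting samples equally. `delta_beta` is the XX mean
#' minus the XY mean. Regions with no covered CpGs in `beta` are omitted
#' (their count is reported in a message).
#'
#' @param beta Probes-by-samples beta matrix.
#' @param regions Long membership table from [build_regions()] (or any
#'   data.frame with `region_id`, `gene_id`, `region_kind`, `cpg_id`, and
#'   optionally `cgi`).
#' @param samples data.frame with `sample_id` and `reported_sex`
#'   (`XX`/`XY`); samples absent from `beta` are ignored.
#' @return data.frame (one row per region): `region_id`, `gene_id`,
#'   `region_kind`, `n_cpgs`, `beta_mean_XX`, `beta_mean_XY`,
#'   `beta_median_XX`, `beta_median_XY`, `delta_beta` and optional `cgi`.
#'   Per-sample mean/median matrices are attached as attributes
#'   `per_sample_mean` and `per_sample_median`.
#' @export
region_mean_beta <- function(beta, regions, samples) {
  stopifnot(all(c("region_id", "cpg_id") %in% names(regions)))
  covered <- regions$cpg_id %in% rownames(beta)
  n_dropped <- length(setdiff(unique(regions$region_id[!covered]),
                              unique(regions$region_id[covered])))
  regions <- regions[covered, , drop = FALSE]
  if (n_dropped > 0L) message(n_dropped, " region(s) without covered CpGs omitted")
  if (nrow(regions) == 0L) stop("no region has covered CpGs")

  ids <- colnames(beta)
  sex <- samples$reported_sex[match(ids, samples$sample_id)]
  split_cpgs <- split(regions$cpg_id, regions$region_id)
  region_ids <- names(split_cpgs)
  n_regions <- length(region_ids)

  per_mean <- matrix(NA_real_, n_regions, ncol(beta),
                     dimnames = list(region_ids, ids))
  per_median <- per_mean
  for (i in seq_len(n_regions)) {
    sub <- beta[split_cpgs[[i]], , drop = FALSE]
    per_mean[i, ] <- colMeans(sub, na.rm = TRUE)
    per_median[i, ] <- apply(sub, 2L, stats::median, na.rm = TRUE)
  }
  per_mean[is.nan(per_mean)] <- NA_real_

  grp <- function(m, which_sex) {
    cols <- which(!is.na(sex) & sex == which_sex)
    if (length(cols) == 0L) return(rep(NA_real_, n_regions))
    rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
  }
  meta <- regions[!duplicated(regions$region_id), , drop = FALSE]
  meta <- meta[match(region_ids, meta$region_id), , drop = FALSE]
  out <- data.frame(
    region_id = region_ids,
    gene_id = meta$gene_id,
    region_kind = meta$region_kind,
    n_cpgs = lengths(lapply(split_cpgs, unique)),
    beta_mean_XX = grp(per_mean, "XX"),
    beta_mean_XY = grp(per_mean, "XY"),
    beta_median_XX = grp(per_median, "XX"),
    beta_median_XY = grp(per_median, "XY"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$delta_beta <- out$beta_mean_XX - out$beta_mean_XY
  if ("cgi" %in% names(meta)) out$cgi <- meta$cgi
  attr(out, "per_sample_mean") <- per_mean
  attr(out, "per_sample_median") <- per_median
  out
}

#' Stratified per-sample mean beta
#'
#' Partitions CpGs into the 2 x 2 x 2 strata (chrX vs autosomal) x (PMD vs
#' non-PMD) x (repetitive vs non-repetitive, where repetitive means LINE-1
#' or SINE) and computes the per-sample mean beta in each stratum, missing
#' values ignored. The strata are a partition: every CpG falls in exactly
#' one cell.
#'
#' @param beta Probes-by-samples beta matrix.
#' @param annotation data.frame from [annotate_cpgs()] (needs `cpg_id`,
#'   `chrom`, `in_pmd`, `in_line1`, `in_sine`).
#' @param chrx Chromosome name treated as the X (default `"chrX"`).
#' @return Long data.frame: `sample_id`, `chrom_class`, `pmd`,
#'   `repetitive`, `n_cpgs`, `mean_beta` (NA with a warning for empty
#'   strata).
#' @export
stratified_mean_beta <- function(beta, annotation, chrx = "chrX") {
  ann <- annotation[match(rownames(beta), annotation$cpg_id), , drop = FALSE]
  if (anyNA(ann$cpg_id)) stop("beta matrix contains probes absent from the annotation")
  chrom_class <- ifelse(ann$chrom == chrx, "chrX", "autosomal")
  pmd <- ifelse(ann$in_pmd, "PMD", "non-PMD")
  rep_ <- ifelse(ann$in_line1 | ann$in_sine, "repetitive", "non-repetitive")
  out <- list()
  for (cc in c("autosomal", "chrX")) for (pm in c("non-PMD", "PMD"))
    for (rr in c("non-repetitive", "repetitive")) {
      sel <- chrom_class == cc & pmd == pm & rep_ == rr
      if (!any(sel)) {
        warning("empty stratum: ", cc, "/", pm, "/", rr)
        mb <- rep(NA_real_, ncol(beta))
      } else {
        mb <- colMeans(beta[sel, , drop = FALSE], na.rm = TRUE)
      }
      out[[length(out) + 1L]] <- data.frame(
        sample_id = colnames(beta), chrom_class = cc, pmd = pm,
        repetitive = rr, n_cpgs = sum(sel), mean_beta = as.numeric(mb),
        stringsAsFactors = FALSE)
    }
  do.call(rbind, out)
}
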
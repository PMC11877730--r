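# Synthetic methylome generator emulating active/inactive X (Xa/Xi)
# methylation mixtures, with exported ground truth for parameter-recovery
# tests.
#
# The generative model: per X-linked gene an XCI category (escape /
# variable / subject) is drawn; the Xa promoter is lowly methylated; the
# Xi promoter follows the coupling mode. In "somatic" mode Xi promoter
# methylation tracks XCI status (high when subject, low when escape); in
# "placenta" mode it is low regardless of status, shifted further down by
# a depletion term. Measured XX beta is the Xa/Xi average; XY beta comes
# from the Xa alone. Allele balances are emitted per gene and XX sample on
# the folded [0.5, 1] scale.

#' Build a simulation configuration
#'
#' Returns a validated configuration list with the defaults used by the
#' study-scale simulations. All randomness is split over named streams
#' (metadata, methylation, allele balance) derived from `seed`, so one
#' component can be varied while holding the others fixed.
#'
#' @param seed Base seed (integer).
#' @param n_genes Number of X-linked genes with promoters.
#' @param n_cpgs_per_promoter CpGs per promoter (default 5).
#' @param n_cpgs_per_enhancer CpGs per proximal enhancer (default 2).
#' @param n_cpgs_per_body CpGs per gene body (default 3).
#' @param n_intergenic_cpgs Intergenic CpGs, split evenly between chrX and
#'   chr1 (default 500).
#' @param n_samples_per_sex Samples of each sex (default 30).
#' @param tissue_effects Named numeric vector of per-tissue beta offsets;
#'   samples are assigned tissues round-robin (default a single
#'   `placenta = 0`).
#' @param xci_fractions Named fractions (`escape`, `variable`, `subject`)
#'   summing to 1 (default 0.10 / 0.15 / 0.75).
#' @param coupling_mode `"somatic"`, `"placenta"` or `"custom"`; custom
#'   blends the two Xi patterns with weight `coupling_rho` on the somatic
#'   pattern.
#' @param coupling_rho Blend weight in \[0, 1\] for `"custom"` mode.
#' @param xa_promoter_beta_params,xi_subject_beta_params,xi_escape_beta_params
#'   Beta-distribution shape pairs for Xa promoter, somatic-mode Xi
#'   subject, and low/escape promoter methylation.
#' @param placenta_xi_depletion Downward shift of Xi promoter methylation
#'   in placenta mode (default 0.15).
#' @param pmd_fraction Fraction of intergenic CpG blocks inside partially
#'   methylated domains (default 0.3).
#' @param pmd_hypomethylation Beta shift subtracted inside PMDs
#'   (default 0.15).
#' @param noise_sd SD of the truncated-Gaussian measurement noise on beta
#'   (default 0.05; 0 gives the exact two-allele mixture).
#' @param cell_dirichlet Dirichlet concentrations for the six placental
#'   cell types (nRBC, Hofbauer, endothelial, stromal, cytotrophoblast,
#'   syncytiotrophoblast).
#' @param cell_offset_sd SD of per-cell-type beta offset profiles
#'   (default 0.02; offsets are applied on the beta scale per cell type
#'   before linear mixing).
#' @param ga_range_weeks Gestational-age range sampled uniformly
#'   (default 8-42 weeks).
#' @param ga_effect Beta change per week of gestational age (default 0,
#'   the null).
#' @param ab_subject_params,ab_escape_params Beta shape pairs for folded
#'   allele balances (`0.5 + 0.5 * rbeta(...)`) of subject-like and
#'   escape-like expression.
#' @param variable_propensity_range Range of the per-gene propensity
#'   `pi_g` with which a variable-escape gene behaves subject-like in a
#'   given sample.
#' @param informative_rate Probability a gene/sample pair is informative
#'   (non-missing allele balance; default 0.8).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       n_cpgs_per_promoter = 5L,
                       n_cpgs_per_enhancer = 2L,
                       n_cpgs_per_body = 3L,
                       n_intergenic_cpgs = 500L,
                       n_samples_per_sex = 30L,
                       tissue_effects = c(placenta = 0),
                       xci_fractions = c(escape = 0.10, variable = 0.15,
                                         subject = 0.75),
                       coupling_mode = c("placenta", "somatic", "custom"),
                       coupling_rho = 0.5,
                       xa_promoter_beta_params = c(2, 18),
                       xi_subject_beta_params = c(18, 2),
                       xi_escape_beta_params = c(2, 18),
                       placenta_xi_depletion = 0.15,
                       pmd_fraction = 0.3,
                       pmd_hypomethylation = 0.15,
                       noise_sd = 0.05,
                       cell_dirichlet = c(nrbc = 0.5, hofbauer = 2,
                                          endothelial = 8, stromal = 11,
                                          cytotrophoblast = 18,
                                          syncytiotrophoblast = 60),
                       cell_offset_sd = 0.02,
                       ga_range_weeks = c(8, 42),
                       ga_effect = 0,
                       ab_subject_params = c(18, 2),
                       ab_escape_params = c(1, 9),
                       variable_propensity_range = c(0.3, 0.7),
                       informative_rate = 0.8) {
  coupling_mode <- match.arg(coupling_mode)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_cpgs_per_promoter = as.integer(n_cpgs_per_promoter),
              n_cpgs_per_enhancer = as.integer(n_cpgs_per_enhancer),
              n_cpgs_per_body = as.integer(n_cpgs_per_body),
              n_intergenic_cpgs = as.integer(n_intergenic_cpgs),
              n_samples_per_sex = as.integer(n_samples_per_sex),
              tissue_effects = tissue_effects,
              xci_fractions = xci_fractions,
              coupling_mode = coupling_mode, coupling_rho = coupling_rho,
              xa_promoter_beta_params = xa_promoter_beta_params,
              xi_subject_beta_params = xi_subject_beta_params,
              xi_escape_beta_params = xi_escape_beta_params,
              placenta_xi_depletion = placenta_xi_depletion,
              pmd_fraction = pmd_fraction,
              pmd_hypomethylation = pmd_hypomethylation,
              noise_sd = noise_sd, cell_dirichlet = cell_dirichlet,
              cell_offset_sd = cell_offset_sd,
              ga_range_weeks = ga_range_weeks, ga_effect = ga_effect,
              ab_subject_params = ab_subject_params,
              ab_escape_params = ab_escape_params,
              variable_propensity_range = variable_propensity_range,
              informative_rate = informative_rate)
  .validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

.validate_sim_config <- function(cfg) {
  fr <- cfg$xci_fractions
  if (!setequal(names(fr), c("escape", "variable", "subject"))) {
    stop("xci_fractions must be named escape/variable/subject")
  }
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
    stop("xci_fractions must be non-negative and sum to 1")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$informative_rate < 0 || cfg$informative_rate > 1) {
    stop("informative_rate must lie in [0, 1]")
  }
  if (cfg$pmd_fraction < 0 || cfg$pmd_fraction > 1) {
    stop("pmd_fraction must lie in [0, 1]")
  }
  if (cfg$placenta_xi_depletion < 0 || cfg$placenta_xi_depletion > 1) {
    stop("placenta_xi_depletion must lie in [0, 1]")
  }
  if (cfg$coupling_rho < 0 || cfg$coupling_rho > 1) {
    stop("coupling_rho must lie in [0, 1]")
  }
  if (length(cfg$ga_range_weeks) != 2L ||
      cfg$ga_range_weeks[1] > cfg$ga_range_weeks[2]) {
    stop("ga_range_weeks must be an increasing length-2 range")
  }
  if (cfg$n_samples_per_sex < 1L) stop("need >= 1 sample per sex")
  invisible(cfg)
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

# Beta draw with point-mass edge cases: shape pair (0, b) is a point mass
# at 0 and (a, 0) a point mass at 1, so noiseless configurations can pin
# allele methylation states exactly.
.rbeta_pm <- function(n, pars) {
  if (pars[1] == 0) return(rep(0, n))
  if (pars[2] == 0) return(rep(1, n))
  stats::rbeta(n, pars[1], pars[2])
}

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), ncol = k, byrow = TRUE)
  g / rowSums(g)
}

# Deterministic genome layout for the simulated study. Genes sit on chrX,
# 10 kb apart, all + strand; each carries a promoter-like element, a
# proximal enhancer-like element inside the gene body, and a CpG island
# over the promoter.
.sim_layout <- function(cfg) {
  g <- seq_len(cfg$n_genes)
  tss <- 1000000L + (g - 1L) * 10000L
  gene_id <- sprintf("GENE%04d", g)
  chrx <- rep("chrX", length(g))
  list(
    gene_id = gene_id, tss = tss,
    tss_table = data.frame(gene_id = gene_id, chrom = chrx, pos = tss,
                           strand = rep("+", length(g)),
                           stringsAsFactors = FALSE),
    pls = data.frame(chrom = chrx, start = tss - 150L, end = tss + 50L,
                     stringsAsFactors = FALSE),
    pels = data.frame(chrom = chrx, start = tss + 1000L, end = tss + 1350L,
                      stringsAsFactors = FALSE),
    body = data.frame(chrom = chrx, start = tss, end = tss + 5000L,
                      gene_id = gene_id, stringsAsFactors = FALSE),
    cgi_interval = data.frame(chrom = chrx, start = tss - 400L,
                              end = tss + 200L, stringsAsFactors = FALSE)
  )
}

#' Simulate a methylation + XCI study
#'
#' Generates a beta matrix, all-pass QC matrices, a sample sheet, a CpG
#' annotation (computed from the emitted tracks via [annotate_cpgs()]), an
#' allele-balance matrix over XX samples, and the ground truth used by
#' parameter-recovery tests. See [sim_config()] for the generative
#' parameters; the measured XX beta is `(Xa + Xi) / 2` before noise, XY
#' beta is the Xa value alone.
#'
#' @param config A `sim_config` list.
#' @return List with elements `beta`, `qc` (list of `detection_p`,
#'   `bead_count`), `samples`, `manifest` (1-based positions),
#'   `annotation`, `tracks`, `tss`, `allele_balance`, `ground_truth`.
#' @export
simulate_study <- function(config) {
  cfg <- config
  .validate_sim_config(cfg)
  lay <- .sim_layout(cfg)
  ng <- cfg$n_genes

  ## ---- metadata stream -------------------------------------------------
  set.seed(cfg$seed)
  n_per <- cfg$n_samples_per_sex
  n <- 2L * n_per
  sex <- rep(c("XX", "XY"), each = n_per)
  sample_id <- sprintf("S%03d_%s", seq_len(n), sex)
  tissues <- names(cfg$tissue_effects)
  tissue <- rep(tissues, length.out = n)
  ga <- stats::runif(n, cfg$ga_range_weeks[1], cfg$ga_range_weeks[2])
  cells <- .rdirichlet(n, cfg$cell_dirichlet)
  colnames(cells) <- paste0("prop_", names(cfg$cell_dirichlet))
  anc_raw <- .rdirichlet(n, c(1, 3, 16))
  samples <- data.frame(
    sample_id = sample_id, reported_sex = sex, tissue = tissue,
    gestational_age = ga, cohort = "SIM", cells,
    ancestry_1 = anc_raw[, 1], ancestry_2 = anc_raw[, 2],
    ancestry_3 = anc_raw[, 3],
    birthweight_z = stats::rnorm(n, 0, 1),
    placental_weight_g = stats::rnorm(n, 620, 120),
    maternal_age = stats::rnorm(n, 32, 5),
    epi_age_accel = stats::rnorm(n, 0, 1),
    stringsAsFactors = FALSE
  )

  # gene categories (counts fixed by the fractions, order shuffled)
  counts <- floor(cfg$xci_fractions * ng)
  rem <- ng - sum(counts)
  if (rem > 0) {
    order_frac <- names(sort(cfg$xci_fractions * ng - counts,
                             decreasing = TRUE))
    for (i in seq_len(rem)) {
      counts[order_frac[(i - 1L) %% 3L + 1L]] <-
        counts[order_frac[(i - 1L) %% 3L + 1L]] + 1L
    }
  }
  category <- sample(rep(names(counts), counts))
  pi_g <- stats::runif(ng, cfg$variable_propensity_range[1],
                       cfg$variable_propensity_range[2])
  pi_g[category == "subject"] <- 1
  pi_g[category == "escape"] <- 0

  # PMD blocks over intergenic CpGs (runs of 50 consecutive CpGs)
  n_int <- cfg$n_intergenic_cpgs
  n_int_x <- ceiling(n_int / 2)
  n_int_a <- n_int - n_int_x
  block_of <- function(k) (seq_len(k) - 1L) %/% 50L + 1L
  n_blocks <- function(k) if (k > 0L) (k - 1L) %/% 50L + 1L else 0L
  pmd_block_x <- stats::runif(n_blocks(n_int_x)) < cfg$pmd_fraction
  pmd_block_a <- stats::runif(n_blocks(n_int_a)) < cfg$pmd_fraction
  u_rep_x <- stats::runif(n_int_x)
  u_rep_a <- stats::runif(n_int_a)

  ## ---- methylation stream ---------------------------------------------
  set.seed(cfg$seed + 1L)
  m_a <- .rbeta_pm(ng, cfg$xa_promoter_beta_params)
  hi <- .rbeta_pm(ng, cfg$xi_subject_beta_params)
  lo <- .rbeta_pm(ng, cfg$xi_escape_beta_params)
  m_i_somatic <- ifelse(category == "subject", hi,
                        ifelse(category == "escape", lo,
                               pi_g * hi + (1 - pi_g) * lo))
  m_i_placenta <- .clip01(lo - cfg$placenta_xi_depletion)
  m_i <- switch(cfg$coupling_mode,
                somatic = m_i_somatic,
                placenta = m_i_placenta,
                custom = cfg$coupling_rho * m_i_somatic +
                  (1 - cfg$coupling_rho) * m_i_placenta)
  m_body <- stats::rbeta(ng, 5, 5)
  m_enh <- stats::rbeta(ng, 3, 7)

  # CpG table: promoters, enhancers, bodies, intergenic (chrX then chr1)
  cpg <- list()
  add <- function(lst, chrom, pos0, type, gene, xa, xi) {
    if (length(pos0) == 0L) return(lst)
    lst[[length(lst) + 1L]] <- data.frame(
      chrom = rep_len(chrom, length(pos0)), pos0 = pos0,
      type = rep_len(type, length(pos0)),
      gene_id = rep_len(gene, length(pos0)),
      xa = xa, xi = xi, stringsAsFactors = FALSE)
    lst
  }
  for (j in seq_len(cfg$n_cpgs_per_promoter)) {
    cpg <- add(cpg, "chrX", lay$tss - 20L * j, "promoter", lay$gene_id,
               m_a, m_i)
  }
  for (j in seq_len(cfg$n_cpgs_per_enhancer)) {
    cpg <- add(cpg, "chrX", lay$tss + 1000L + 100L * j, "enhancer",
               lay$gene_id, m_enh, .clip01(m_enh + (m_i - m_a) * 0.5))
  }
  for (j in seq_len(cfg$n_cpgs_per_body)) {
    cpg <- add(cpg, "chrX", lay$tss + 1500L + 500L * j, "gene_body",
               lay$gene_id, m_body, m_body)
  }
  # intergenic: trimodal base levels shared by both alleles
  tri_levels <- c(0.03, 0.5, 0.97)
  if (n_int_x > 0L) {
    mode_x <- sample(tri_levels, n_int_x, replace = TRUE,
                     prob = c(0.45, 0.15, 0.40))
    base_x <- .clip01(mode_x + stats::rnorm(n_int_x, 0, 0.02))
    pos_x <- 20000000L + (seq_len(n_int_x) - 1L) * 1000L
    cpg <- add(cpg, "chrX", pos_x, "intergenic", NA_character_,
               base_x, base_x)
  }
  if (n_int_a > 0L) {
    mode_a <- sample(tri_levels, n_int_a, replace = TRUE,
                     prob = c(0.35, 0.15, 0.50))
    base_a <- .clip01(mode_a + stats::rnorm(n_int_a, 0, 0.02))
    pos_a <- 1000000L + (seq_len(n_int_a) - 1L) * 1000L
    cpg <- add(cpg, "chr1", pos_a, "intergenic", NA_character_,
               base_a, base_a)
  }
  cpg <- do.call(rbind, cpg)
  cpg$cpg_id <- sprintf("cg%06d", seq_len(nrow(cpg)))

  # PMD / repeat membership of intergenic CpGs (from metadata-stream draws)
  cpg$in_pmd <- FALSE
  cpg$in_line1 <- FALSE
  cpg$in_sine <- FALSE
  ix <- which(cpg$type == "intergenic" & cpg$chrom == "chrX")
  ia <- which(cpg$type == "intergenic" & cpg$chrom == "chr1")
  if (length(ix)) {
    cpg$in_pmd[ix] <- pmd_block_x[block_of(length(ix))]
    cpg$in_line1[ix] <- u_rep_x < 0.08
    cpg$in_sine[ix] <- u_rep_x >= 0.08 & u_rep_x < 0.16
  }
  if (length(ia)) {
    cpg$in_pmd[ia] <- pmd_block_a[block_of(length(ia))]
    cpg$in_line1[ia] <- u_rep_a < 0.08
    cpg$in_sine[ia] <- u_rep_a >= 0.08 & u_rep_a < 0.16
  }
  shift <- ifelse(cpg$in_pmd, cfg$pmd_hypomethylation, 0)
  cpg$xa <- .clip01(cpg$xa - shift)
  cpg$xi <- .clip01(cpg$xi - shift)

  # measured beta: XX = (Xa + Xi)/2, XY = Xa; + tissue & GA terms,
  # per-cell-type offsets, linear mixing, truncated-Gaussian noise
  nc <- nrow(cpg)
  base_xx <- (cpg$xa + cpg$xi) / 2
  base_xy <- cpg$xa
  base <- matrix(0, nc, n)
  base[, sex == "XX"] <- base_xx
  base[, sex == "XY"] <- base_xy
  t_off <- cfg$tissue_effects[match(tissue, names(cfg$tissue_effects))]
  ga_term <- cfg$ga_effect * (ga - mean(ga))
  base <- base + rep(t_off + ga_term, each = nc)
  k6 <- length(cfg$cell_dirichlet)
  if (cfg$cell_offset_sd > 0) {
    beta <- matrix(0, nc, n)
    for (k in seq_len(k6)) {
      delta_k <- stats::rnorm(nc, 0, cfg$cell_offset_sd)
      beta <- beta + .clip01(base + delta_k) *
        rep(cells[, k], each = nc)
    }
  } else {
    beta <- .clip01(base)
  }
  if (cfg$noise_sd > 0) {
    beta <- beta + stats::rnorm(nc * n, 0, cfg$noise_sd)
  }
  beta <- .clip01(beta)
  dimnames(beta) <- list(cpg$cpg_id, sample_id)

  ## ---- allele-balance stream ------------------------------------------
  set.seed(cfg$seed + 2L)
  xx_ids <- sample_id[sex == "XX"]
  ab <- matrix(NA_real_, ng, length(xx_ids),
               dimnames = list(lay$gene_id, xx_ids))
  for (g in seq_len(ng)) {
    inf <- stats::runif(length(xx_ids)) < cfg$informative_rate
    if (!any(inf)) next
    k <- sum(inf)
    subject_like <- stats::runif(k) < pi_g[g]
    vals <- numeric(k)
    vals[subject_like] <- 0.5 + 0.5 * stats::rbeta(sum(subject_like),
                                                   cfg$ab_subject_params[1],
                                                   cfg$ab_subject_params[2])
    vals[!subject_like] <- 0.5 + 0.5 * stats::rbeta(sum(!subject_like),
                                                    cfg$ab_escape_params[1],
                                                    cfg$ab_escape_params[2])
    ab[g, inf] <- vals
  }

  ## ---- tracks, annotation, ground truth -------------------------------
  tracks <- list(
    pls = lay$pls, pels = lay$pels, body = lay$body,
    cgi = {
      # island descriptors drawn in the methylation stream would disturb
      # reproducibility of beta draws; derive deterministically from gene
      # index so the same layout always classifies the same way
      gidx <- seq_len(ng)
      cbind(lay$cgi_interval,
            data.frame(length_bp = lay$cgi_interval$end - lay$cgi_interval$start,
                       gc_fraction = 0.50 + 0.20 * ((gidx * 7L) %% 11L) / 10,
                       obs_exp_ratio = 0.40 + 0.50 * ((gidx * 5L) %% 13L) / 12))
    },
    pmd = .intervals_from_points(cpg[cpg$in_pmd, , drop = FALSE]),
    line1 = .intervals_from_points(cpg[cpg$in_line1, , drop = FALSE]),
    sine = .intervals_from_points(cpg[cpg$in_sine, , drop = FALSE])
  )
  manifest <- data.frame(cpg_id = cpg$cpg_id, chrom = cpg$chrom,
                         pos = cpg$pos0 + 1L, stringsAsFactors = FALSE)
  annotation <- annotate_cpgs(manifest, tracks, lay$tss_table)

  qc <- list(
    detection_p = matrix(0, nc, n, dimnames = dimnames(beta)),
    bead_count = matrix(10, nc, n, dimnames = dimnames(beta))
  )
  p_sub_subject <- 1 - stats::pbeta((0.8 - 0.5) / 0.5,
                                    cfg$ab_subject_params[1],
                                    cfg$ab_subject_params[2])
  p_sub_escape <- 1 - stats::pbeta((0.8 - 0.5) / 0.5,
                                   cfg$ab_escape_params[1],
                                   cfg$ab_escape_params[2])
  ground_truth <- list(
    genes = data.frame(gene_id = lay$gene_id, category = category,
                       propensity = pi_g * p_sub_subject +
                         (1 - pi_g) * p_sub_escape,
                       xa_promoter = m_a, xi_promoter = m_i,
                       stringsAsFactors = FALSE),
    cpgs = data.frame(cpg_id = cpg$cpg_id, chrom = cpg$chrom,
                      pos = cpg$pos0, type = cpg$type,
                      gene_id = cpg$gene_id, in_pmd = cpg$in_pmd,
                      in_line1 = cpg$in_line1, in_sine = cpg$in_sine,
                      xa = cpg$xa, xi = cpg$xi, stringsAsFactors = FALSE),
    samples = samples,
    coupling_mode = cfg$coupling_mode,
    seed = cfg$seed
  )
  list(beta = beta, qc = qc, samples = samples, manifest = manifest,
       annotation = annotation, tracks = tracks, tss = lay$tss_table,
       allele_balance = ab, ground_truth = ground_truth)
}

# Collapse CpG points to +/- 100 bp intervals (0-based half-open) for the
# emitted BED tracks; CpGs are >= 1 kb apart so intervals never overlap.
.intervals_from_points <- function(cpg) {
  if (nrow(cpg) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  data.frame(chrom = cpg$chrom, start = pmax(cpg$pos0 - 100L, 0L),
             end = cpg$pos0 + 100L, stringsAsFactors = FALSE)
}

.write_bed <- function(df, path, extra = NULL) {
  cols <- df[c("chrom", "start", "end")]
  if (!is.null(extra)) {
    for (e in extra) cols[[e]] <- if (is.numeric(df[[e]]))
      sprintf("%.10g", df[[e]]) else df[[e]]
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Export a simulated study as pipeline input files
#'
#' Runs [simulate_study()] and writes every matrix and track in the
#' formats the analysis readers consume: beta / detection-p / bead-count
#' TSVs, a sample-sheet CSV, a 1-based manifest TSV, BED tracks (PLS,
#' pELS, gene bodies with gene ids, CGI with length/GC/obs-exp columns,
#' PMD, LINE-1, SINE), a TSS TSV, the allele-balance TSV and a
#' ground-truth JSON. Re-running with the same configuration is
#' byte-identical.
#'
#' @param config A `sim_config` list.
#' @param outdir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory
#'   (default `FALSE`).
#' @return Invisibly, the named vector of written paths.
#' @export
export_fixture <- function(config, outdir, overwrite = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) > 0L && !overwrite) {
    stop("output directory exists and is not empty: ", outdir,
         " (use overwrite = TRUE)")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_study(config)
  p <- function(f) file.path(outdir, f)
  paths <- c(beta = p("beta.tsv"), detection_p = p("detection_p.tsv"),
             bead_count = p("bead_count.tsv"),
             sample_sheet = p("sample_sheet.csv"),
             manifest = p("manifest.tsv"), tss = p("tss.tsv"),
             pls = p("pls.bed"), pels = p("pels.bed"),
             body = p("gene_body.bed"), cgi = p("cgi.bed"),
             pmd = p("pmd.bed"), line1 = p("line1.bed"),
             sine = p("sine.bed"),
             allele_balance = p("allele_balance.tsv"),
             ground_truth = p("ground_truth.json"))
  .write_matrix_tsv(sim$beta, paths["beta"], "cpg_id")
  .write_matrix_tsv(sim$qc$detection_p, paths["detection_p"], "cpg_id")
  .write_matrix_tsv(sim$qc$bead_count, paths["bead_count"], "cpg_id")
  utils::write.csv(sim$samples, paths["sample_sheet"], row.names = FALSE,
                   quote = FALSE)
  utils::write.table(sim$manifest, paths["manifest"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$tss, paths["tss"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .write_bed(sim$tracks$pls, paths["pls"])
  .write_bed(sim$tracks$pels, paths["pels"])
  .write_bed(sim$tracks$body, paths["body"], extra = "gene_id")
  .write_bed(sim$tracks$cgi, paths["cgi"],
             extra = c("length_bp", "gc_fraction", "obs_exp_ratio"))
  .write_bed(sim$tracks$pmd, paths["pmd"])
  .write_bed(sim$tracks$line1, paths["line1"])
  .write_bed(sim$tracks$sine, paths["sine"])
  .write_matrix_tsv(sim$allele_balance, paths["allele_balance"], "gene_id")
  gt <- sim$ground_truth
  jsonlite::write_json(gt, paths["ground_truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
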
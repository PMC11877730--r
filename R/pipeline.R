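# End-to-end orchestration: annotate -> QC -> summarize -> XCI battery ->
# stats, plus the differential-window export for external motif tools.

#' Select windows around differentially methylated CpGs
#'
#' Emits a fixed-width window centred on every CpG whose group methylation
#' difference exceeds `threshold` (strictly), alongside the background set
#' of all processed CpGs, for use with external motif-enrichment tools.
#' Windows running off the chromosome start are clipped at 0 and flagged.
#'
#' @param cpgs data.frame with `cpg_id`, `chrom`, `pos` (0-based) and
#'   `delta_beta` (group A mean minus group B mean per CpG).
#' @param threshold Minimum difference, strict (default 0.20).
#' @param width Total window width in bp (default 100; the window is
#'   `[pos - width/2, pos + width/2)`).
#' @param genome Optional named `Biostrings::DNAStringSet`; when given,
#'   window sequences are returned upper-case with an `has_n` flag.
#' @return List: `windows` (BED-like data.frame with `clipped` flag),
#'   `background` (windows around all input CpGs), and `sequences`
#'   (data.frame with `seq`, `has_n`) when a genome is supplied.
#' @export
select_differential_windows <- function(cpgs, threshold = 0.20,
                                        width = 100L, genome = NULL) {
  stopifnot(all(c("cpg_id", "chrom", "pos", "delta_beta") %in% names(cpgs)))
  half <- as.integer(width / 2)
  mk <- function(df) {
    start <- df$pos - half
    clipped <- start < 0L
    data.frame(chrom = df$chrom, start = pmax(start, 0L),
               end = df$pos + half, cpg_id = df$cpg_id,
               delta_beta = df$delta_beta, clipped = clipped,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  hits <- cpgs[!is.na(cpgs$delta_beta) & cpgs$delta_beta > threshold, ,
               drop = FALSE]
  out <- list(windows = mk(hits), background = mk(cpgs))
  if (!is.null(genome)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("Biostrings is required to extract window sequences")
    }
    seqs <- vapply(seq_len(nrow(out$windows)), function(i) {
      w <- out$windows[i, ]
      toupper(as.character(Biostrings::subseq(
        genome[[w$chrom]], w$start + 1L, min(w$end, length(genome[[w$chrom]])))))
    }, character(1))
    out$sequences <- data.frame(cpg_id = out$windows$cpg_id, seq = seqs,
                                has_n = grepl("N", seqs, fixed = TRUE),
                                stringsAsFactors = FALSE)
  }
  out
}

.default_thresholds <- function() {
  list(frac_threshold = 0.05, detection_p_max = 0.01, bead_count_min = 3,
       subject_balance = 0.8, subject_prop = 0.7, subject_median = 0.8,
       escape_prop = 0.3, escape_median = 0.75, min_informative = 5,
       xy_beta_max = 0.1, effect_threshold = 0.03, fdr_max = 0.05,
       window_delta = 0.20, window_width = 100, n_pcs = 10)
}

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or a path to a JSON file) with an
#' `inputs` block of file paths (`beta`, `detection_p`, `bead_count`,
#' `sample_sheet`, `manifest`, `tss`, `pls`, `pels`, `body`, `cgi`, `pmd`,
#' `line1`, `sine`, optional `allele_balance`), an `out_dir`, a `seed`,
#' and optional `thresholds` overriding the documented defaults. All
#' referenced paths must exist at validation time.
#'
#' @param config Named list or JSON path.
#' @return The normalised configuration (class `run_config`).
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$inputs) || is.null(config$out_dir)) {
    stop("run config requires 'inputs' and 'out_dir'")
  }
  required <- c("beta", "sample_sheet", "manifest", "tss")
  missing <- setdiff(required, names(config$inputs))
  if (length(missing)) stop("run config missing inputs: ",
                            paste(missing, collapse = ", "))
  for (nm in names(config$inputs)) {
    path <- config$inputs[[nm]]
    if (!is.null(path) && !file.exists(path)) {
      stop("input path does not exist (", nm, "): ", path)
    }
  }
  if (is.null(config$seed)) config$seed <- 1L
  th <- .default_thresholds()
  for (nm in names(config$thresholds)) th[[nm]] <- config$thresholds[[nm]]
  config$thresholds <- th
  class(config) <- "run_config"
  config
}

# Stable short hash of the configuration (for output headers): md5 of the
# canonical JSON serialisation of the run-defining fields (inputs,
# thresholds, seed). The output directory is deliberately excluded so the
# same run into two directories produces identical tables.
.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  key <- list(inputs = config$inputs, thresholds = config$thresholds,
              seed = config$seed)
  writeLines(jsonlite::toJSON(key, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.stage <- function(name, log, expr) {
  log(paste0("stage: ", name))
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes the fixed stage order annotate -> qc -> summarize -> xci ->
#' stats -> windows on the configured inputs, writing every output table
#' as TSV with a `#`-prefixed metadata header (package version, config
#' hash, seed), a JSON run manifest of all thresholds, and a log of
#' CpG/gene counts at each filter. Outputs are deterministic given the
#' configuration and inputs; the log file is the only non-deterministic
#' artefact excluded from that guarantee.
#'
#' @param config A run configuration (list or JSON path); see
#'   [validate_run_config()].
#' @return Invisibly, a list of the main in-memory results.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  log <- function(msg) writeLines(format(msg), log_con)
  meta <- c(config_hash = .config_hash(config),
            seed = as.character(config$seed))
  set.seed(config$seed)

  inputs <- config$inputs
  dat <- .stage("load", log, {
    list(
      beta = read_beta_matrix(inputs$beta),
      detection_p = if (!is.null(inputs$detection_p))
        read_qc_matrix(inputs$detection_p),
      bead_count = if (!is.null(inputs$bead_count))
        read_qc_matrix(inputs$bead_count),
      samples = read_sample_sheet(inputs$sample_sheet),
      manifest = utils::read.delim(inputs$manifest,
                                   stringsAsFactors = FALSE),
      tss = read_tss(inputs$tss),
      ab = if (!is.null(inputs$allele_balance))
        read_allele_balance(inputs$allele_balance)
    )
  })
  tracks <- .stage("load_tracks", log, {
    rb <- function(nm, cols = NULL) {
      if (is.null(inputs[[nm]])) NULL else read_bed(inputs[[nm]], cols)
    }
    list(pls = rb("pls"), pels = rb("pels"),
         body = rb("body", "gene_id"),
         cgi = rb("cgi", c("length_bp", "gc_fraction", "obs_exp_ratio")),
         pmd = rb("pmd"), line1 = rb("line1"), sine = rb("sine"))
  })

  annotation <- .stage("annotate", log,
                       annotate_cpgs(dat$manifest, tracks, dat$tss))
  write_tsv_header(annotation, file.path(out_dir, "annotation.tsv"), meta)
  log(paste0("annotated CpGs: ", nrow(annotation)))

  retained <- .stage("qc", log, {
    filter_probes(dat$beta,
                  qc = list(detection_p = dat$detection_p,
                            bead_count = dat$bead_count),
                  frac_threshold = th$frac_threshold,
                  detection_p_max = th$detection_p_max,
                  bead_count_min = th$bead_count_min)
  })
  log(paste0("probes retained after QC: ", length(retained), " / ",
             nrow(dat$beta)))
  beta <- dat$beta[retained, , drop = FALSE]
  write_tsv_header(data.frame(cpg_id = retained),
                   file.path(out_dir, "retained_probes.tsv"), meta)

  summaries <- .stage("summarize", log, {
    res <- list()
    for (kind in c("promoter", "enhancer", "gene_body")) {
      regions <- build_regions(annotation, kind)
      if (nrow(regions) == 0L) next
      rs <- suppressMessages(region_mean_beta(beta, regions, dat$samples))
      res[[kind]] <- rs
      tab <- rs
      attr(tab, "per_sample_mean") <- NULL
      attr(tab, "per_sample_median") <- NULL
      write_tsv_header(tab, file.path(out_dir,
                                      paste0("summary_", kind, ".tsv")), meta)
      log(paste0(kind, " regions summarised: ", nrow(rs)))
    }
    strat <- stratified_mean_beta(beta, annotation)
    write_tsv_header(strat, file.path(out_dir, "stratified_means.tsv"), meta)
    res$stratified <- strat
    res
  })

  xci <- NULL
  if (!is.null(dat$ab) && !is.null(summaries$promoter)) {
    xci <- .stage("xci", log, {
      calls <- call_xci(dat$ab, subject_balance = th$subject_balance,
                        subject_prop = th$subject_prop,
                        subject_median = th$subject_median,
                        escape_prop = th$escape_prop,
                        escape_median = th$escape_median,
                        min_informative = th$min_informative)
      write_tsv_header(calls, file.path(out_dir, "xci_calls.tsv"), meta)
      log(paste0("genes called: ", sum(calls$called), " / ", nrow(calls)))
      battery <- xci_battery(summaries$promoter, calls,
                             xy_beta_max = th$xy_beta_max)
      write_tsv_header(battery, file.path(out_dir, "xci_battery.tsv"), meta)
      cats <- compare_categories(summaries$promoter, calls)
      if (!is.null(cats$pairwise)) {
        write_tsv_header(cats$pairwise,
                         file.path(out_dir, "xci_category_tests.tsv"), meta)
      }
      list(calls = calls, battery = battery, categories = cats)
    })
  }

  stats_res <- .stage("stats", log, {
    pca <- suppressMessages(pca_scaled(beta))
    scores <- data.frame(sample_id = rownames(pca$scores),
                         pca$standardized_scores,
                         stringsAsFactors = FALSE)
    write_tsv_header(scores, file.path(out_dir, "pc_scores.tsv"), meta)
    assoc_vars <- intersect(
      c("tissue", "cohort", "gestational_age", "birthweight_z",
        "maternal_age", "reported_sex",
        grep("^prop_|^ancestry_", names(dat$samples), value = TRUE)),
      names(dat$samples))
    assoc <- suppressMessages(
      pc_association(pca, dat$samples, assoc_vars, n_components = th$n_pcs))
    write_tsv_header(assoc, file.path(out_dir, "pc_associations.tsv"), meta)
    ga <- NULL
    if ("gestational_age" %in% names(dat$samples)) {
      ga <- list()
      for (sx in c("XX", "XY")) {
        ids <- dat$samples$sample_id[dat$samples$reported_sex == sx]
        ids <- intersect(ids, colnames(beta))
        if (length(ids) < 4L) next
        fit <- cpg_linear_model(beta[, ids, drop = FALSE], dat$samples,
                                predictor = "gestational_age",
                                effect_threshold = th$effect_threshold,
                                fdr_max = th$fdr_max)
        write_tsv_header(fit, file.path(out_dir,
                                        paste0("ga_model_", sx, ".tsv")), meta)
        log(paste0("GA model ", sx, ": ", sum(fit$significant),
                   " significant CpGs"))
        ga[[sx]] <- fit
      }
    }
    list(pca = pca, associations = assoc, ga = ga)
  })

  windows <- .stage("windows", log, {
    sex <- dat$samples$reported_sex[match(colnames(beta),
                                          dat$samples$sample_id)]
    dxx <- rowMeans(beta[, sex == "XX", drop = FALSE], na.rm = TRUE) -
      rowMeans(beta[, sex == "XY", drop = FALSE], na.rm = TRUE)
    ann <- annotation[match(rownames(beta), annotation$cpg_id), ]
    tab <- data.frame(cpg_id = rownames(beta), chrom = ann$chrom,
                      pos = ann$pos, delta_beta = dxx,
                      stringsAsFactors = FALSE)
    w <- select_differential_windows(tab, threshold = th$window_delta,
                                     width = th$window_width)
    .write_bed(w$windows, file.path(out_dir, "differential_windows.bed"),
               extra = "cpg_id")
    .write_bed(w$background, file.path(out_dir, "background_windows.bed"),
               extra = "cpg_id")
    log(paste0("differential windows: ", nrow(w$windows), " of ",
               nrow(w$background), " CpGs"))
    w
  })

  manifest_json <- list(
    package = "xcimeth",
    version = as.character(utils::packageVersion("xcimeth")),
    config_hash = unname(meta["config_hash"]),
    seed = config$seed,
    thresholds = th,
    inputs = inputs,
    stages = c("load", "annotate", "qc", "summarize",
               if (!is.null(xci)) "xci", "stats", "windows")
  )
  jsonlite::write_json(manifest_json, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(annotation = annotation, retained = retained,
                 summaries = summaries, xci = xci, stats = stats_res,
                 windows = windows))
}
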
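# Genomic annotation of CpGs: promoter/enhancer/gene-body assignment,
# CpG-island density classes, PMD and repeat membership, TSS windows.
#
# Coordinate convention: all intervals are 0-based half-open [start, end),
# matching BED. Array manifests are 1-based and shifted by -1 on ingest.
# Overlap queries go through IRanges/GenomicRanges after converting to the
# 1-based closed convention those containers use.

# Convert 0-based half-open intervals to a GRanges for overlap queries.
# Starts are clamped at base 1; queries are points at position >= 0, so
# clamping never changes the overlap set.
.as_granges <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pmax(start0 + 1L, 1L), end = end0)
  )
}

# Point (0-based position) to a width-1 GRanges.
.points_granges <- function(chrom, pos0) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos0 + 1L, width = 1L)
  )
}

#' Read a BED file of genomic intervals
#'
#' Parses a (3+)-column tab-separated BED file. Coordinates are taken
#' verbatim as 0-based half-open. Blank lines and lines starting with `#`
#' are skipped; remaining input order is preserved.
#'
#' @param path Path to a BED file.
#' @param col_names Optional names for columns beyond the third (e.g.
#'   `c("name", "score", "strand")`). Extra columns present in the file but
#'   not named here are kept as `V4`, `V5`, ...
#' @return A data.frame with columns `chrom`, `start`, `end` and any extra
#'   columns, one row per interval in file order.
#' @export
read_bed <- function(path, col_names = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3L)) {
    bad <- idx[which(nfield < 3L)[1L]]
    stop("malformed BED line ", bad, ": fewer than 3 tab-separated fields")
  }
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | !nzchar(chrom))
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1L]], ": non-integer coordinates")
  }
  bad <- which(start < 0L | start >= end)
  if (length(bad)) {
    stop("malformed BED line ", idx[bad[1L]],
         ": requires 0 <= start < end (empty intervals are not allowed)")
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  max_extra <- max(nfield) - 3L
  if (max_extra > 0L) {
    for (j in seq_len(max_extra)) {
      vals <- vapply(parts, function(p) {
        if (length(p) >= j + 3L) p[[j + 3L]] else NA_character_
      }, character(1))
      num <- suppressWarnings(as.numeric(vals))
      nm <- if (!is.null(col_names) && j <= length(col_names)) col_names[j]
            else paste0("V", j + 3L)
      out[[nm]] <- if (!anyNA(num[!is.na(vals)])) num else vals
    }
  }
  out
}

#' Read a transcription start site table
#'
#' Reads a tab-separated table with columns `gene_id`, `chrom`, `pos`
#' (0-based) and `strand` (`+`/`-`).
#'
#' @param path Path to the TSV file (header required).
#' @return A data.frame with the four columns above.
#' @export
read_tss <- function(path) {
  tss <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "pos", "strand")
  missing <- setdiff(required, names(tss))
  if (length(missing)) stop("TSS table missing columns: ",
                            paste(missing, collapse = ", "))
  tss$pos <- as.integer(tss$pos)
  if (anyNA(tss$pos) || any(tss$pos < 0L)) stop("TSS positions must be non-negative integers")
  if (!all(tss$strand %in% c("+", "-"))) stop("TSS strand must be '+' or '-'")
  tss[required]
}

#' Assign promoter-like sequences to genes
#'
#' A promoter-like sequence (PLS) interval is paired with a gene when it
#' overlaps the closed window of +/- `flank` bp around that gene's TSS on
#' the same chromosome. One PLS may pair with several genes and vice versa;
#' the output is deduplicated.
#'
#' @param pls data.frame of PLS intervals (`chrom`, `start`, `end`;
#'   0-based half-open).
#' @param tss data.frame of TSS records (`gene_id`, `chrom`, `pos`).
#' @param flank Window half-width in bp around each TSS (default 200).
#' @return data.frame with columns `chrom`, `start`, `end`, `gene_id`, one
#'   row per (promoter interval, gene) pair.
#' @export
assign_promoters <- function(pls, tss, flank = 200L) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), gene_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(pls) == 0L || nrow(tss) == 0L) return(empty)
  gr_pls <- .as_granges(pls$chrom, pls$start, pls$end)
  # closed window of positions [pos - flank, pos + flank] -> 1-based bases
  gr_win <- .as_granges(tss$chrom, pmax(tss$pos - flank, 0L), tss$pos + flank + 1L)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_pls, gr_win))
  if (length(hits) == 0L) return(empty)
  out <- data.frame(
    chrom = pls$chrom[S4Vectors::queryHits(hits)],
    start = pls$start[S4Vectors::queryHits(hits)],
    end = pls$end[S4Vectors::queryHits(hits)],
    gene_id = tss$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
  unique(out)
}

#' Assign proximal enhancer-like sequences to genes
#'
#' An enhancer-like sequence (pELS) is paired with a gene when the gene's
#' TSS position lies in `[start - flank, end + flank)` of the pELS interval
#' (half-open on the right).
#'
#' @inheritParams assign_promoters
#' @param pels data.frame of pELS intervals (`chrom`, `start`, `end`).
#' @param flank Extension in bp on both sides (default 2000).
#' @return data.frame with columns `chrom`, `start`, `end`, `gene_id`.
#' @export
assign_enhancers <- function(pels, tss, flank = 2000L) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), gene_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(pels) == 0L || nrow(tss) == 0L) return(empty)
  # TSS pos in [start - flank, end + flank) <=> 1-based base pos + 1 in
  # [start - flank + 1, end + flank]
  gr_ext <- .as_granges(pels$chrom, pels$start - flank, pels$end + flank)
  gr_tss <- .points_granges(tss$chrom, tss$pos)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_ext, gr_tss))
  if (length(hits) == 0L) return(empty)
  out <- data.frame(
    chrom = pels$chrom[S4Vectors::queryHits(hits)],
    start = pels$start[S4Vectors::queryHits(hits)],
    end = pels$end[S4Vectors::queryHits(hits)],
    gene_id = tss$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  )
  unique(out)
}

#' Classify CpG islands by density
#'
#' Applies the length / GC-content / observed-expected CpG ratio criteria
#' that split CpG islands into high-density (HC) and intermediate-density
#' (IC) classes. All comparisons are strict:
#' HC requires length > 500 bp, GC > 0.55 and obs/exp > 0.75;
#' otherwise IC requires length > 200 bp, GC > 0.50 and obs/exp > 0.48;
#' anything else is `"none"`.
#'
#' @param length_bp Island length(s) in bp.
#' @param gc_fraction GC content fraction(s) in \[0, 1\].
#' @param obs_exp_ratio Observed/expected CpG ratio(s), non-negative.
#' @return Character vector of `"HC"`, `"IC"` or `"none"`.
#' @export
classify_cgi <- function(length_bp, gc_fraction, obs_exp_ratio) {
  if (any(!is.finite(length_bp)) || any(!is.finite(gc_fraction)) ||
      any(!is.finite(obs_exp_ratio))) {
    stop("classify_cgi inputs must be finite")
  }
  if (any(length_bp < 0)) stop("island length must be non-negative")
  hc <- length_bp > 500 & gc_fraction > 0.55 & obs_exp_ratio > 0.75
  ic <- length_bp > 200 & gc_fraction > 0.50 & obs_exp_ratio > 0.48
  ifelse(hc, "HC", ifelse(ic, "IC", "none"))
}

#' Label CpGs by TSS window
#'
#' Strand-aware upstream window labels relative to the nearest TSS. For a
#' `+` strand TSS at position t, `TSS200` covers positions `[t - 200, t)`
#' and `TSS200_1500` covers `[t - 1500, t - 200)`; for a `-` strand TSS the
#' windows are mirrored downstream (`(t, t + 200]` and `(t + 200, t + 1500]`).
#' A CpG inside the TSS200 window of any gene is labelled `TSS200`;
#' otherwise `TSS200_1500` if it lies in that band of any gene; else
#' `"none"`.
#'
#' @param cpg_pos Integer vector of CpG positions (0-based).
#' @param tss data.frame with `pos` and `strand` (single chromosome), or
#'   with `chrom` when `cpg_chrom` is supplied.
#' @param cpg_chrom Optional chromosome per CpG; when given only TSS on the
#'   same chromosome are considered.
#' @return Character vector of `"TSS200"`, `"TSS200_1500"` or `"none"`.
#' @export
tss_window_label <- function(cpg_pos, tss, cpg_chrom = NULL) {
  n <- length(cpg_pos)
  out <- rep("none", n)
  if (nrow(tss) == 0L || n == 0L) return(out)
  use_chrom <- !is.null(cpg_chrom) && "chrom" %in% names(tss)
  for (i in seq_len(n)) {
    t_sub <- if (use_chrom) tss[tss$chrom == cpg_chrom[i], , drop = FALSE] else tss
    if (nrow(t_sub) == 0L) next
    p <- cpg_pos[i]
    # signed upstream distance from the CpG to each TSS
    d <- ifelse(t_sub$strand == "+", t_sub$pos - p, p - t_sub$pos)
    if (any(d >= 1 & d <= 200)) {
      out[i] <- "TSS200"
    } else if (any(d >= 201 & d <= 1500)) {
      out[i] <- "TSS200_1500"
    }
  }
  out
}

# Build strand-aware TSS window intervals (0-based half-open) for fast
# membership queries: kind "TSS200" or "TSS200_1500".
.tss_window_intervals <- function(tss, kind) {
  plus <- tss$strand == "+"
  if (kind == "TSS200") {
    start0 <- ifelse(plus, tss$pos - 200L, tss$pos + 1L)
    end0 <- ifelse(plus, tss$pos, tss$pos + 201L)
  } else {
    start0 <- ifelse(plus, tss$pos - 1500L, tss$pos + 201L)
    end0 <- ifelse(plus, tss$pos - 200L, tss$pos + 1501L)
  }
  keep <- end0 > 0L
  data.frame(chrom = tss$chrom[keep], start = pmax(start0[keep], 0L),
             end = end0[keep], stringsAsFactors = FALSE)
}

# Genes of intervals (pair table from assign_promoters/assign_enhancers)
# containing each query point; returns comma-collapsed sorted unique ids.
.genes_at_points <- function(points_gr, pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    return(rep("", length(points_gr)))
  }
  gr <- .as_granges(pairs$chrom, pairs$start, pairs$end)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(points_gr, gr))
  out <- rep("", length(points_gr))
  if (length(hits) == 0L) return(out)
  ids <- split(pairs$gene_id[S4Vectors::subjectHits(hits)],
               S4Vectors::queryHits(hits))
  collapsed <- vapply(ids, function(g) paste(sort(unique(g)), collapse = ","),
                      character(1))
  out[as.integer(names(ids))] <- collapsed
  out
}

.in_intervals <- function(points_gr, track) {
  if (is.null(track) || nrow(track) == 0L) return(rep(FALSE, length(points_gr)))
  gr <- .as_granges(track$chrom, track$start, track$end)
  suppressWarnings(IRanges::overlapsAny(points_gr, gr))
}

#' Annotate array CpGs with genomic context
#'
#' Assigns every manifest CpG its functional context: gene ids of
#' containing promoters (promoter-like sequences paired to genes within
#' +/- 200 bp of a TSS), enhancers (pELS paired to genes within 2 kb), and
#' gene bodies; strand-aware TSS window label; CpG island density class of
#' the containing island; and partially-methylated-domain / LINE-1 / SINE
#' membership. Membership is point-in-interval on the 0-based half-open
#' convention.
#'
#' @param manifest data.frame with `cpg_id`, `chrom` and `pos` (1-based,
#'   the array-manifest convention; shifted by -1 internally).
#' @param tracks Named list of interval data.frames (each `chrom`, `start`,
#'   `end` plus extras): `pls`, `pels`, `body` (requires a `gene_id`
#'   column), `cgi` (requires `length_bp`, `gc_fraction`, `obs_exp_ratio`
#'   or a precomputed `density_class`), `pmd`, `line1`, `sine`. Any element
#'   may be `NULL` or absent.
#' @param tss data.frame of TSS records (`gene_id`, `chrom`, `pos`,
#'   `strand`).
#' @return data.frame with one row per manifest CpG: `cpg_id`, `chrom`,
#'   `pos` (0-based), `promoter_genes`, `enhancer_genes`, `body_genes`
#'   (comma-separated, empty when none), `tss_window`, `cgi_class`,
#'   `in_pmd`, `in_line1`, `in_sine`.
#' @export
annotate_cpgs <- function(manifest, tracks = list(), tss = NULL) {
  required <- c("cpg_id", "chrom", "pos")
  if (!all(required %in% names(manifest))) {
    stop("manifest must have columns cpg_id, chrom, pos")
  }
  if (anyDuplicated(manifest$cpg_id)) {
    stop("duplicate cpg_id in manifest: ",
         manifest$cpg_id[duplicated(manifest$cpg_id)][1L])
  }
  pos0 <- as.integer(manifest$pos) - 1L
  if (any(pos0 < 0L)) stop("manifest positions must be 1-based (>= 1)")
  pts <- .points_granges(manifest$chrom, pos0)

  if (is.null(tss)) tss <- data.frame(gene_id = character(), chrom = character(),
                                      pos = integer(), strand = character(),
                                      stringsAsFactors = FALSE)
  prom_pairs <- if (!is.null(tracks$pls)) assign_promoters(tracks$pls, tss) else NULL
  enh_pairs <- if (!is.null(tracks$pels)) assign_enhancers(tracks$pels, tss) else NULL
  body <- tracks$body
  if (!is.null(body) && nrow(body) > 0L) {
    if (!"gene_id" %in% names(body)) stop("gene body track requires a gene_id column")
  }

  # CGI class of the containing island; HC beats IC when islands overlap
  cgi_class <- rep("none", nrow(manifest))
  cgi <- tracks$cgi
  if (!is.null(cgi) && nrow(cgi) > 0L) {
    if (!"density_class" %in% names(cgi)) {
      if (!all(c("length_bp", "gc_fraction", "obs_exp_ratio") %in% names(cgi))) {
        stop("CGI track requires length_bp, gc_fraction, obs_exp_ratio (or density_class)")
      }
      cgi$density_class <- classify_cgi(cgi$length_bp, cgi$gc_fraction,
                                        cgi$obs_exp_ratio)
    }
    gr_cgi <- .as_granges(cgi$chrom, cgi$start, cgi$end)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(pts, gr_cgi))
    if (length(hits)) {
      cls <- split(cgi$density_class[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits))
      best <- vapply(cls, function(x) {
        if ("HC" %in% x) "HC" else if ("IC" %in% x) "IC" else "none"
      }, character(1))
      cgi_class[as.integer(names(best))] <- best
    }
  }

  tw <- rep("none", nrow(manifest))
  if (nrow(tss) > 0L) {
    in200 <- .in_intervals(pts, .tss_window_intervals(tss, "TSS200"))
    in1500 <- .in_intervals(pts, .tss_window_intervals(tss, "TSS200_1500"))
    tw[in1500] <- "TSS200_1500"
    tw[in200] <- "TSS200"
  }

  data.frame(
    cpg_id = manifest$cpg_id,
    chrom = manifest$chrom,
    pos = pos0,
    promoter_genes = .genes_at_points(pts, prom_pairs),
    enhancer_genes = .genes_at_points(pts, enh_pairs),
    body_genes = .genes_at_points(pts, body),
    tss_window = tw,
    cgi_class = cgi_class,
    in_pmd = .in_intervals(pts, tracks$pmd),
    in_line1 = .in_intervals(pts, tracks$line1),
    in_sine = .in_intervals(pts, tracks$sine),
    stringsAsFactors = FALSE
  )
}

#' Compute CpG island descriptors from sequence
#'
#' Given island intervals and a genome, derives the length, GC fraction and
#' observed/expected CpG ratio used by [classify_cgi()]. The obs/exp ratio
#' is `n_CpG * length / (n_C * n_G)`, zero when the island contains no C or
#' no G.
#'
#' @param cgi data.frame of island intervals (`chrom`, `start`, `end`).
#' @param genome A named `Biostrings::DNAStringSet` (names matching
#'   `chrom`).
#' @return The input with `length_bp`, `gc_fraction`, `obs_exp_ratio` and
#'   `density_class` columns appended.
#' @export
cgi_descriptors <- function(cgi, genome) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required to compute CGI descriptors from sequence")
  }
  n <- nrow(cgi)
  len <- cgi$end - cgi$start
  gc <- numeric(n)
  oe <- numeric(n)
  for (i in seq_len(n)) {
    seq <- Biostrings::subseq(genome[[cgi$chrom[i]]], cgi$start[i] + 1L, cgi$end[i])
    s <- toupper(as.character(seq))
    nc <- lengths(regmatches(s, gregexpr("C", s, fixed = TRUE)))
    ng <- lengths(regmatches(s, gregexpr("G", s, fixed = TRUE)))
    ncg <- lengths(regmatches(s, gregexpr("CG", s, fixed = TRUE)))
    gc[i] <- (nc + ng) / len[i]
    oe[i] <- if (nc > 0 && ng > 0) ncg * len[i] / (nc * ng) else 0
  }
  cgi$length_bp <- len
  cgi$gc_fraction <- gc
  cgi$obs_exp_ratio <- oe
  cgi$density_class <- classify_cgi(len, gc, oe)
  cgi
}
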
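# Read-depth copy number: the single-copy baseline X_SC is the modal
# per-base depth over BUSCO single-copy Complete genes; a region's copy
# number is N_reg = X_reg / X_SC where X_reg is its mean non-gap depth.

#' Fit the single-copy depth model from BUSCO Complete genes
#'
#' Pools the per-base depths of every Complete BUSCO gene (off the excluded
#' sequences, gap bases dropped) and takes the mode of the integer depth
#' histogram as the single-copy baseline `X_SC`; ties on the mode break
#' toward the lower depth. Per-gene copy numbers `CN_g = mean depth of gene
#' g / X_SC` provide the dispersion used for region-level uncertainty.
#'
#' @param depth A `depth_track`.
#' @param busco BUSCO tibble from [read_busco_table()].
#' @param exclude_seqs Additional sequence ids to exclude (genes already
#'   flagged `on_excluded_seq` are always excluded).
#' @return A `single_copy_model`: `X_SC`, `per_gene` tibble
#'   (`busco_id`, `mean_depth`, `cn`), `n_genes`, `mean_cn`, `sd_cn`,
#'   `ci95_halfwidth` (`1.96 * sd_cn / sqrt(n_genes)`).
#' @export
fit_single_copy_model <- function(depth, busco, exclude_seqs = character()) {
  genes <- busco |>
    filter(.data$status == "Complete", !.data$on_excluded_seq,
           !(.data$seq_id %in% exclude_seqs), !is.na(.data$start))
  genes <- genes[genes$seq_id %in% names(depth$depth), , drop = FALSE]
  if (nrow(genes) == 0) abort("no eligible Complete BUSCO genes")
  pooled <- integer(0)
  mean_depths <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    idx <- (genes$start[i] + 1):genes$end[i]
    d <- depth$depth[[genes$seq_id[i]]][idx]
    ok <- !depth$gap[[genes$seq_id[i]]][idx]
    d <- d[ok]
    pooled <- c(pooled, d)
    mean_depths[i] <- mean(d)
  }
  tab <- table(pooled)
  x_sc <- as.integer(names(tab)[which.max(tab)])  # which.max: first max = lowest depth
  if (x_sc == 0) abort("insufficient coverage: modal single-copy depth is 0")
  per_gene <- tibble(busco_id = genes$busco_id, seq_id = genes$seq_id,
                     mean_depth = mean_depths, cn = mean_depths / x_sc)
  n <- nrow(per_gene)
  sd_cn <- if (n >= 2) sd(per_gene$cn) else NA_real_
  structure(list(
    X_SC = x_sc,
    per_gene = per_gene,
    n_genes = n,
    mean_cn = mean(per_gene$cn),
    sd_cn = sd_cn,
    ci95_halfwidth = if (n >= 2) 1.96 * sd_cn / sqrt(n) else NA_real_
  ), class = "single_copy_model")
}

#' @export
print.single_copy_model <- function(x, ...) {
  cat(sprintf(
    "<single_copy_model> X_SC = %d reads (modal depth over %d BUSCO genes)\n",
    x$X_SC, x$n_genes))
  cat(sprintf("  mean CN %.3f +/- %.3f (95%% CI), sd %.3f\n",
              x$mean_cn, x$ci95_halfwidth, x$sd_cn))
  invisible(x)
}

#' @describeIn fit_single_copy_model Per-gene copy numbers as a tibble.
#' @param x A `single_copy_model`.
#' @param ... Unused.
#' @export
tidy.single_copy_model <- function(x, ...) x$per_gene

#' @describeIn fit_single_copy_model One-row model summary.
#' @export
glance.single_copy_model <- function(x, ...) {
  tibble(X_SC = x$X_SC, n_genes = x$n_genes, mean_cn = x$mean_cn,
         sd_cn = x$sd_cn, ci95_halfwidth = x$ci95_halfwidth)
}

#' BUSCO-wide copy-number summary
#'
#' Sanity check on the single-copy baseline: over a well-behaved assembly
#' the mean predicted copy number of single-copy genes should be ~1.
#'
#' @param model A `single_copy_model`.
#' @return Tibble with `mean_cn` and `ci95_halfwidth` (NA when fewer than
#'   two genes).
#' @export
busco_cn_summary <- function(model) {
  tibble(mean_cn = model$mean_cn, ci95_halfwidth = model$ci95_halfwidth)
}

#' Estimate copy number for genomic regions
#'
#' `N_reg = X_reg / X_SC`, with `X_reg` the mean depth over the region's
#' non-gap bases. The standard error scales the BUSCO copy-number
#' dispersion by the estimate (coefficient-of-variation scaling):
#' `se = (sd_cn / mean_cn) * N_reg`; `ci95 = 1.96 * se`. The BUSCO-mean CI
#' half-width is carried alongside so both uncertainty views are visible.
#'
#' @param depth A `depth_track`.
#' @param regions Tibble with `seq_id`, `start`, `end` (0-based half-open);
#'   extra columns pass through.
#' @param model A `single_copy_model`.
#' @return `regions` with `X_reg`, `N_reg`, `se`, `ci95`, `X_SC`,
#'   `n_busco`, `busco_ci95` columns appended.
#' @export
region_cn <- function(depth, regions, model) {
  xr <- map_dbl(seq_len(nrow(regions)), function(i) {
    region_mean_depth(depth, regions$seq_id[i], regions$start[i],
                      regions$end[i])
  })
  nreg <- xr / model$X_SC
  cv <- model$sd_cn / model$mean_cn
  regions |>
    mutate(X_reg = xr, N_reg = nreg,
           se = cv * nreg, ci95 = 1.96 * cv * nreg,
           X_SC = model$X_SC, n_busco = model$n_genes,
           busco_ci95 = model$ci95_halfwidth)
}

#' Summed gene-family copy number from homology hits
#'
#' Each genomic hit of the family query contributes
#' `N_reg * query_coverage` copies (the region copy number weighted by the
#' fraction of the query the hit covers); the family estimate is the sum
#' over hits. Overlapping hits are collapsed first (merged span, maximum
#' query coverage of the members).
#'
#' @param depth A `depth_track`.
#' @param hits Tibble with `seq_id`, `start`, `end`, `query_coverage`
#'   (fraction of the family query covered by the hit, in (0, 1]).
#' @param model A `single_copy_model`.
#' @return A list: `per_hit` tibble (hit columns + `X_reg`, `N_reg`,
#'   `copies`) and `total_copies`.
#' @export
gene_family_cn <- function(depth, hits, model) {
  if (nrow(hits) == 0) {
    warn("gene_family_cn: empty hit list; total 0")
    return(list(per_hit = tibble(), total_copies = 0))
  }
  stopifnot(all(hits$query_coverage > 0 & hits$query_coverage <= 1))
  collapsed <- list()
  for (id in unique(hits$seq_id)) {
    h <- hits[hits$seq_id == id, , drop = FALSE]
    ir <- IRanges::IRanges(h$start + 1, h$end)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    qc <- tapply(h$query_coverage[S4Vectors::queryHits(ov)],
                 S4Vectors::subjectHits(ov), max)
    collapsed[[id]] <- tibble(seq_id = id,
                              start = IRanges::start(red) - 1,
                              end = as.numeric(IRanges::end(red)),
                              query_coverage = as.numeric(qc))
  }
  ch <- bind_rows(collapsed)
  if (nrow(ch) < nrow(hits)) {
    inform(sprintf("gene_family_cn: collapsed %d overlapping hits to %d",
                   nrow(hits), nrow(ch)))
  }
  per_hit <- region_cn(depth, ch, model) |>
    mutate(copies = .data$N_reg * .data$query_coverage)
  list(per_hit = per_hit, total_copies = sum(per_hit$copies))
}

#' Filter read alignments by read length
#'
#' Supports re-running depth analyses restricted to long reads (e.g. at
#' least 5 kb or 10 kb) to damp repeat-driven depth fluctuations.
#'
#' @param reads Read alignment tibble with a `read_len` column.
#' @param min_len Minimum read length in bp.
#' @return Filtered tibble.
#' @export
filter_reads_by_length <- function(reads, min_len = 0) {
  filter(reads, .data$read_len >= min_len)
}

#' Rebuild a depth track from read alignment intervals
#'
#' Pile-up of alignment intervals, so that depth can be recomputed after
#' [filter_reads_by_length()].
#'
#' @param reads Read alignment tibble (`seq_id`, `start`, `end`).
#' @param genome Genome tibble.
#' @return A `depth_track`.
#' @export
depth_from_reads <- function(reads, genome) {
  depths <- list()
  for (id in genome$seq_id) {
    len <- genome$length[genome$seq_id == id]
    r <- reads[reads$seq_id == id, , drop = FALSE]
    if (nrow(r) == 0) {
      depths[[id]] <- integer(len)
    } else {
      cov <- IRanges::coverage(IRanges::IRanges(r$start + 1, r$end),
                               width = len)
      depths[[id]] <- as.integer(cov)
    }
  }
  depth_track(depths, genome)
}

#' Short-read depth-ratio copy number
#'
#' Whole-individual copy number of an annotated gene family from short
#' reads: the summed mean depth of the annotated gene copies divided by the
#' genome-wide mean depth.
#'
#' @param depth A `depth_track` (short-read pile-up).
#' @param gene_regions Tibble of annotated gene copies (`seq_id`, `start`,
#'   `end`).
#' @param genome_mean Genome-wide mean depth; computed from `depth` via
#'   [genome_mean_depth()] when NULL.
#' @return Estimated copies (double).
#' @export
short_read_ratio_cn <- function(depth, gene_regions, genome_mean = NULL) {
  if (is.null(genome_mean)) genome_mean <- genome_mean_depth(depth)
  if (!is.finite(genome_mean) || genome_mean <= 0) {
    abort("genome mean depth must be positive")
  }
  means <- map_dbl(seq_len(nrow(gene_regions)), function(i) {
    region_mean_depth(depth, gene_regions$seq_id[i], gene_regions$start[i],
                      gene_regions$end[i])
  })
  sum(means) / genome_mean
}

#' Bin a gene coverage/copy value into reporting categories
#'
#' Assembly mode (mapped-assembly coverage, rounded to the nearest integer):
#' `Missing` (exactly 0), `Partial(<50%)` (0 < value < 0.5), `1n`, `2n`,
#' `3n+`. Long-read mode (depth-based copy number, rounded to the nearest
#' 0.5): `0n`, `0.5n`, `1n`, `1.5n`, `2n`, `2.5n+`; values above zero but
#' under 50% always land in `0.5n`. Midpoints round half up; values above
#' the top bin collapse into it.
#'
#' @param value Non-negative numeric vector.
#' @param mode `"assembly"` or `"longread"`.
#' @return Character vector of bin labels.
#' @export
bin_gene_coverage <- function(value, mode = c("assembly", "longread")) {
  mode <- match.arg(mode)
  if (any(value < 0)) abort("coverage value must be non-negative")
  round_half_up <- function(x) floor(x + 0.5)
  if (mode == "assembly") {
    n <- round_half_up(value)
    dplyr::case_when(
      value == 0 ~ "Missing",
      value < 0.5 ~ "Partial(<50%)",
      n >= 3 ~ "3n+",
      TRUE ~ paste0(n, "n")
    )
  } else {
    h <- round_half_up(value * 2) / 2
    dplyr::case_when(
      value == 0 ~ "0n",
      value < 0.5 ~ "0.5n",
      h >= 2.5 ~ "2.5n+",
      TRUE ~ sprintf("%gn", h)
    )
  }
}
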
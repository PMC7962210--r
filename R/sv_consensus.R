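# Two-platform structural-variant consensus, cross-sample overlap counting,
# gene/exon overlap annotation, comparative mapping statistics and
# annotation QC (reciprocal best hits, protein length ratios).

# Greedy injective matching between two SV sets. DEL/INV/DUP pair when both
# reciprocal overlaps reach `recip`; INS pair when breakpoints are within
# `ins_dist` and min(len)/max(len) >= `size_ratio`. Pairs are taken best
# first (largest reciprocal overlap / smallest distance, ties by position),
# each record used at most once.
match_sv_sets <- function(a, b, recip = 0.5, ins_dist = 1000,
                          size_ratio = 0.5) {
  stopifnot(is.data.frame(a), is.data.frame(b))
  pairs <- list()
  types <- intersect(unique(a$sv_type), unique(b$sv_type))
  for (ty in setdiff(types, "BND")) {
    ai <- which(a$sv_type == ty)
    bi <- which(b$sv_type == ty)
    if (length(ai) == 0 || length(bi) == 0) next
    if (ty == "INS") {
      cand <- expand.grid(i = ai, j = bi)
      cand <- cand[a$seq_id[cand$i] == b$seq_id[cand$j], , drop = FALSE]
      if (nrow(cand) == 0) next
      dist <- abs(a$start[cand$i] - b$start[cand$j])
      sr <- pmin(a$sv_len[cand$i], b$sv_len[cand$j]) /
        pmax(a$sv_len[cand$i], b$sv_len[cand$j])
      ok <- dist <= ins_dist & sr >= size_ratio
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0) next
      metric <- dist[ok]
      ord <- order(metric, a$start[cand$i], b$start[cand$j])
    } else {
      ra <- IRanges::IRanges(a$start[ai] + 1, a$end[ai])
      rb <- IRanges::IRanges(b$start[bi] + 1, b$end[bi])
      ov <- IRanges::findOverlaps(ra, rb)
      if (length(ov) == 0) next
      qi <- ai[S4Vectors::queryHits(ov)]
      sj <- bi[S4Vectors::subjectHits(ov)]
      same <- a$seq_id[qi] == b$seq_id[sj]
      qi <- qi[same]; sj <- sj[same]
      if (length(qi) == 0) next
      ovlen <- pmin(a$end[qi], b$end[sj]) - pmax(a$start[qi], b$start[sj])
      r1 <- ovlen / (a$end[qi] - a$start[qi])
      r2 <- ovlen / (b$end[sj] - b$start[sj])
      rr <- pmin(r1, r2)
      ok <- rr >= recip
      qi <- qi[ok]; sj <- sj[ok]
      if (length(qi) == 0) next
      cand <- data.frame(i = qi, j = sj)
      metric <- -rr[ok]  # larger reciprocal overlap first
      ord <- order(metric, a$start[qi], b$start[sj])
    }
    cand <- cand[ord, , drop = FALSE]
    metric <- metric[ord]
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    for (k in seq_len(nrow(cand))) {
      i <- cand$i[k]; j <- cand$j[k]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      pairs[[length(pairs) + 1]] <- tibble(
        idx_a = i, idx_b = j, sv_type = ty,
        metric = abs(metric[k])
      )
    }
  }
  if (length(pairs) == 0) {
    return(tibble(idx_a = integer(), idx_b = integer(),
                  sv_type = character(), metric = numeric()))
  }
  bind_rows(pairs)
}

#' Intersect SV call sets from two platforms
#'
#' High-confidence consensus: each call in set A is matched to at most one
#' call of the same type in set B (greedy best match: largest reciprocal
#' overlap for DEL/INV/DUP, smallest breakpoint distance for INS);
#' unmatched calls are dropped. The representative record of a pair is the
#' partner with the smaller start (tie: the A record).
#'
#' @param set_a,set_b SV tibbles (e.g. from [read_sv_vcf()]), on the same
#'   reference.
#' @param recip Minimum reciprocal overlap for DEL/INV/DUP (both ratios).
#' @param ins_dist Maximum insertion breakpoint distance in bp.
#' @param size_ratio Minimum insertion size ratio min/max.
#' @param chroms Optional allow-list of sequence ids (e.g. main nuclear
#'   chromosomes) applied to both sets first.
#' @return Tibble of consensus SVs: representative `sv_type`, `seq_id`,
#'   `start`, `end`, `sv_len` plus `id_a`, `id_b`, `match_stat` (reciprocal
#'   overlap or breakpoint distance).
#' @export
intersect_platforms <- function(set_a, set_b, recip = 0.5, ins_dist = 1000,
                                size_ratio = 0.5, chroms = NULL) {
  if (!is.null(chroms)) {
    set_a <- filter(set_a, .data$seq_id %in% chroms)
    set_b <- filter(set_b, .data$seq_id %in% chroms)
  }
  shared_ref <- length(intersect(unique(set_a$seq_id),
                                 unique(set_b$seq_id))) > 0
  if (nrow(set_a) > 0 && nrow(set_b) > 0 && !shared_ref) {
    abort("SV sets share no sequence ids; are they on the same reference?")
  }
  m <- match_sv_sets(set_a, set_b, recip, ins_dist, size_ratio)
  if (nrow(m) == 0) return(mutate(empty_svs(), id_a = character(),
                                  id_b = character(), match_stat = numeric()))
  rows <- lapply(seq_len(nrow(m)), function(k) {
    ra <- set_a[m$idx_a[k], ]
    rb <- set_b[m$idx_b[k], ]
    rep <- if (rb$start < ra$start) rb else ra
    tibble(sv_id = paste0("cons_", rep$sv_id), sv_type = rep$sv_type,
           seq_id = rep$seq_id, start = rep$start, end = rep$end,
           sv_len = rep$sv_len, sample_id = rep$sample_id,
           platform = "consensus", id_a = ra$sv_id, id_b = rb$sv_id,
           match_stat = m$metric[k])
  })
  bind_rows(rows) |> arrange(.data$seq_id, .data$start)
}

#' Length-filter an SV set
#'
#' @param svs SV tibble.
#' @param min_len Length cutoff in bp.
#' @param strict Keep `sv_len > min_len` when TRUE (the default,
#'   "longer than"), `>=` otherwise. BND records (no length) are always
#'   dropped.
#' @return Filtered tibble.
#' @export
filter_sv_length <- function(svs, min_len = 100, strict = TRUE) {
  svs <- filter(svs, .data$sv_type != "BND", !is.na(.data$sv_len))
  if (strict) filter(svs, .data$sv_len > min_len)
  else filter(svs, .data$sv_len >= min_len)
}

#' Cross-sample SV overlap (Venn counts per type)
#'
#' Applies the same matching rules as [intersect_platforms()] between two
#' consensus sets (e.g. two breeds against one reference) and reports
#' per-type shared/unique counts with shared percentages.
#'
#' @param set_a,set_b SV tibbles on the same reference.
#' @inheritParams intersect_platforms
#' @return Tibble: `sv_type`, `n_a`, `n_b`, `shared`, `only_a`, `only_b`,
#'   `pct_shared_a`, `pct_shared_b` (to 2 dp).
#' @export
overlap_samples <- function(set_a, set_b, recip = 0.5, ins_dist = 1000,
                            size_ratio = 0.5) {
  m <- match_sv_sets(set_a, set_b, recip, ins_dist, size_ratio)
  types <- sort(union(unique(set_a$sv_type), unique(set_b$sv_type)))
  types <- setdiff(types, "BND")
  rows <- lapply(types, function(ty) {
    na <- sum(set_a$sv_type == ty)
    nb <- sum(set_b$sv_type == ty)
    sh <- sum(m$sv_type == ty)
    tibble(sv_type = ty, n_a = na, n_b = nb, shared = sh,
           only_a = na - sh, only_b = nb - sh,
           pct_shared_a = if (na > 0) round(100 * sh / na, 2) else NA_real_,
           pct_shared_b = if (nb > 0) round(100 * sh / nb, 2) else NA_real_)
  })
  bind_rows(rows)
}

#' Annotate SVs with gene and exon overlap
#'
#' An SV overlaps a feature when their intervals share at least one base
#' (an insertion breakpoint inside an intron overlaps the gene but no
#' exon).
#'
#' @param svs SV tibble.
#' @param genes Gene-model tibble from [read_gene_models()].
#' @return A list: `per_sv` (`svs` plus `gene_overlap`, `n_genes`,
#'   `n_exons`) and `summary` (total SVs overlapping genes/exons and
#'   distinct exon count).
#' @export
annotate_gene_overlap <- function(svs, genes) {
  exons <- genes |>
    select("gene_id", "seq_id", "exons") |>
    tidyr::unnest("exons")
  sv_gr <- GenomicRanges::GRanges(svs$seq_id,
                                  IRanges::IRanges(svs$start + 1, svs$end))
  gene_gr <- GenomicRanges::GRanges(genes$seq_id,
                                    IRanges::IRanges(genes$start + 1,
                                                     genes$end))
  exon_gr <- GenomicRanges::GRanges(exons$seq_id,
                                    IRanges::IRanges(exons$start + 1,
                                                     exons$end))
  og <- GenomicRanges::findOverlaps(sv_gr, gene_gr)
  oe <- GenomicRanges::findOverlaps(sv_gr, exon_gr)
  n_genes <- tabulate(S4Vectors::queryHits(og), nbins = nrow(svs))
  n_exons <- tabulate(S4Vectors::queryHits(oe), nbins = nrow(svs))
  per_sv <- mutate(svs, gene_overlap = n_genes > 0, n_genes = n_genes,
                   n_exons = n_exons)
  exon_key <- paste(exons$seq_id, exons$start, exons$end)
  distinct_exons <- length(unique(exon_key[S4Vectors::subjectHits(oe)]))
  list(per_sv = per_sv,
       summary = tibble(n_sv = nrow(svs),
                        n_sv_gene = sum(n_genes > 0),
                        n_sv_exon = sum(n_exons > 0),
                        n_distinct_exons = distinct_exons))
}

#' Reference-centred relative mapping statistics
#'
#' For each sample the mean percent-mapped across the references is
#' subtracted from each reference's value, so each sample's row sums to
#' zero and references are compared free of per-sample mapping-rate
#' differences.
#'
#' @param scores Long tibble with `sample`, `reference`, `pct_mapped`, or a
#'   numeric matrix (samples x references).
#' @return Long tibble with `rel_mapped` appended; samples with missing
#'   cells are excluded with a warning.
#' @export
relative_mapping <- function(scores) {
  if (is.matrix(scores)) {
    scores <- as_tibble(scores, rownames = "sample") |>
      tidyr::pivot_longer(-"sample", names_to = "reference",
                          values_to = "pct_mapped")
  }
  n_ref <- length(unique(scores$reference))
  if (n_ref < 2) abort("need at least 2 references per sample")
  counts <- scores |>
    filter(!is.na(.data$pct_mapped)) |>
    dplyr::count(.data$sample)
  bad <- counts$sample[counts$n < n_ref]
  bad <- union(bad, setdiff(unique(scores$sample), counts$sample))
  if (length(bad) > 0) {
    warn(sprintf("relative_mapping: excluded %d samples with missing cells",
                 length(bad)))
    scores <- filter(scores, !(.data$sample %in% bad))
  }
  scores |>
    group_by(.data$sample) |>
    mutate(rel_mapped = .data$pct_mapped - mean(.data$pct_mapped)) |>
    ungroup()
}

#' Annotation QC: reciprocal best hits and protein length ratios
#'
#' A predicted gene is marked an orthologue when its best reference hit's
#' own best hit is that gene (reciprocal best hit). The length ratio
#' (predicted protein length / reference protein length) flags truncated or
#' fused predictions.
#'
#' @param best_ab Tibble `query`, `hit`: best reference hit per predicted
#'   gene.
#' @param best_ba Tibble `query`, `hit`: best predicted-gene hit per
#'   reference protein.
#' @param protein_lengths Tibble `id`, `length` covering both sets.
#' @return `best_ab` with `rbh` flag and `length_ratio` appended.
#' @export
annotation_qc <- function(best_ab, best_ba, protein_lengths) {
  len <- setNames(protein_lengths$length, protein_lengths$id)
  back <- setNames(best_ba$hit, best_ba$query)
  out <- best_ab |>
    mutate(rbh = unname(!is.na(back[.data$hit]) &
                          back[.data$hit] == .data$query),
           pred_len = unname(len[.data$query]),
           ref_len = unname(len[.data$hit]))
  if (any(!is.na(out$ref_len) & out$ref_len == 0)) {
    abort("zero reference protein length")
  }
  mutate(out, length_ratio = .data$pred_len / .data$ref_len)
}
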
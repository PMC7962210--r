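# NUMT fragment discovery: doubled circular query, e-value filtering, greedy
# compression of homology hits to unique genomic intervals, 8 kb block
# merging, mtDNA coverage profiling and long-read spanning support.

#' Build the doubled query sequence for a circular mtDNA
#'
#' Concatenating the mitochondrial unit with itself lets a single local
#' alignment capture NUMTs that span the (arbitrary) origin of the circular
#' genome, so a contiguous insertion is never split into two hits.
#'
#' @param mtdna One-row genome tibble with `circular = TRUE`.
#' @return A list with `doubled` (one-row genome tibble, id suffixed
#'   `_x2`) and `unit` (a `circular_unit`: `mt_id`, `unit_length`,
#'   `doubled_length`).
#' @export
build_doubled_query <- function(mtdna) {
  stopifnot(nrow(mtdna) == 1)
  if (!isTRUE(mtdna$circular[1])) {
    abort("mtDNA must be flagged circular to build a doubled query")
  }
  L <- mtdna$length[1]
  unit <- structure(list(mt_id = mtdna$seq_id[1], unit_length = L,
                         doubled_length = 2L * L),
                    class = "circular_unit")
  doubled <- tibble(
    seq_id = paste0(mtdna$seq_id[1], "_x2"),
    length = 2L * L,
    circular = FALSE,
    n_ambiguous = 2L * mtdna$n_ambiguous[1],
    residues = paste0(mtdna$residues[1], mtdna$residues[1])
  )
  list(doubled = doubled, unit = unit)
}

#' Filter homology hits by e-value
#'
#' @param hits Hit tibble from [read_hits()].
#' @param max_evalue Retain hits with `evalue < max_evalue`.
#' @return Filtered hit tibble; the retention count is reported.
#' @export
filter_hits <- function(hits, max_evalue = 1e-4) {
  out <- filter(hits, .data$evalue < max_evalue)
  inform(sprintf("filter_hits: retained %d/%d hits at e < %g",
                 nrow(out), nrow(hits), max_evalue))
  out
}

#' Wrap an interval on the doubled query back onto the circular unit
#'
#' @param q_start,q_end Interval on the doubled query, 0-based half-open,
#'   with `q_end - q_start <= L`.
#' @param unit A `circular_unit`.
#' @return Tibble of 1 or 2 rows (`start`, `end` on `[0, L)`); two rows when
#'   the interval crosses position L (an origin-spanning fragment).
#' @export
wrap_to_unit <- function(q_start, q_end, unit) {
  L <- unit$unit_length
  stopifnot(q_start >= 0, q_end > q_start, q_end <= 2 * L)
  if (q_end - q_start > L) {
    abort("interval longer than the circular unit cannot be wrapped")
  }
  s <- q_start %% L
  e <- s + (q_end - q_start)
  if (e <= L) {
    tibble(start = s, end = e)
  } else {
    tibble(start = c(s, 0), end = c(L, e - L))
  }
}

#' Compress homology hits to unique, non-overlapping NUMT fragments
#'
#' Greedy best-hit compression: hits are ranked by descending bitscore, then
#' descending subject length, then ascending (`s_id`, `s_start`) for
#' determinism. Each accepted hit is trimmed on the subject (genomic) side
#' against everything already accepted; its query interval is trimmed
#' proportionally. Surviving pieces shorter than `min_frag` are discarded.
#' The two copies of a hit generated by the doubled query occupy the same
#' genomic interval, so the duplicate collapses automatically.
#'
#' @param hits Hit tibble (all sharing the doubled-mtDNA query).
#' @param unit Optional `circular_unit`; when given, each fragment's query
#'   interval is wrapped to mt-unit segments (`mt_segments` list-column).
#' @param min_frag Minimum retained fragment length in bp.
#' @param seq_lengths Optional named vector of scaffold lengths; hits on
#'   unknown scaffolds raise an error.
#' @return Tibble of fragments: `fragment_id`, `seq_id`, `start`, `end`,
#'   `strand`, `length`, `q_start`, `q_end`, `source_hit`, and
#'   `mt_segments` (list-column) when `unit` is supplied.
#' @export
compress_unique <- function(hits, unit = NULL, min_frag = 25,
                            seq_lengths = NULL) {
  if (!is.null(seq_lengths)) {
    unknown <- setdiff(unique(hits$s_id), names(seq_lengths))
    if (length(unknown) > 0) {
      abort(paste0("hits reference unknown scaffold: ", unknown[1]))
    }
  }
  if (nrow(hits) == 0) return(empty_fragments(!is.null(unit)))
  h <- hits |>
    mutate(.hit = row_number(), .slen = .data$s_end - .data$s_start) |>
    arrange(dplyr::desc(.data$bitscore), dplyr::desc(.data$.slen),
            .data$s_id, .data$s_start)
  accepted <- list()  # per s_id IRanges of claimed genomic bases
  frags <- list()
  for (i in seq_len(nrow(h))) {
    row <- h[i, ]
    cur <- IRanges::IRanges(start = row$s_start + 1, end = row$s_end)
    prior <- accepted[[row$s_id]]
    rem <- if (is.null(prior)) cur else IRanges::setdiff(cur, prior)
    if (length(rem) == 0) next
    accepted[[row$s_id]] <- if (is.null(prior)) rem else
      IRanges::reduce(c(prior, rem))
    keep <- IRanges::width(rem) >= min_frag
    rem <- rem[keep]
    if (length(rem) == 0) next
    ratio <- (row$q_end - row$q_start) / (row$s_end - row$s_start)
    for (j in seq_along(rem)) {
      p_start <- IRanges::start(rem)[j] - 1
      p_end <- IRanges::end(rem)[j]
      if (row$strand == "+") {
        qs <- row$q_start + round((p_start - row$s_start) * ratio)
        qe <- row$q_start + round((p_end - row$s_start) * ratio)
      } else {
        qs <- row$q_end - round((p_end - row$s_start) * ratio)
        qe <- row$q_end - round((p_start - row$s_start) * ratio)
      }
      qe <- max(qe, qs + 1)
      frags[[length(frags) + 1]] <- tibble(
        seq_id = row$s_id, start = p_start, end = p_end,
        strand = row$strand, length = p_end - p_start,
        q_start = qs, q_end = qe, source_hit = row$.hit
      )
    }
  }
  if (length(frags) == 0) return(empty_fragments(!is.null(unit)))
  out <- bind_rows(frags) |> arrange(.data$seq_id, .data$start)
  out$fragment_id <- sprintf("numt%04d", seq_len(nrow(out)))
  out <- select(out, "fragment_id", dplyr::everything())
  if (!is.null(unit)) {
    out$mt_segments <- map2(out$q_start, out$q_end,
                            function(a, b) wrap_to_unit(a, b, unit))
  }
  out
}

empty_fragments <- function(with_mt = FALSE) {
  out <- tibble(fragment_id = character(), seq_id = character(),
                start = numeric(), end = numeric(), strand = character(),
                length = numeric(), q_start = numeric(), q_end = numeric(),
                source_hit = integer())
  if (with_mt) out$mt_segments <- list()
  out
}

#' Merge NUMT fragments into blocks
#'
#' Consecutive fragments on the same scaffold whose genomic gap is at most
#' `merge_gap` join one block, transitively and regardless of strand or
#' mtDNA order. Blocks never span scaffolds.
#'
#' @param fragments Fragment tibble from [compress_unique()].
#' @param merge_gap Maximum inter-fragment gap in bp (default 8 kb).
#' @return Tibble of blocks: `block_id`, `seq_id`, `start`, `end`,
#'   `block_length` (span), `fragment_bp` (summed member lengths),
#'   `n_fragments`, `members` (list of fragment ids).
#' @export
merge_blocks <- function(fragments, merge_gap = 8000) {
  if (nrow(fragments) == 0) {
    return(tibble(block_id = character(), seq_id = character(),
                  start = numeric(), end = numeric(),
                  block_length = numeric(), fragment_bp = numeric(),
                  n_fragments = integer(), members = list()))
  }
  fr <- arrange(fragments, .data$seq_id, .data$start)
  gap_prev <- c(Inf, fr$start[-1] - fr$end[-nrow(fr)])
  new_block <- fr$seq_id != dplyr::lag(fr$seq_id, default = "") |
    gap_prev > merge_gap
  fr$.block <- cumsum(new_block)
  out <- fr |>
    group_by(.data$.block, .data$seq_id) |>
    summarise(start = min(.data$start), end = max(.data$end),
              fragment_bp = sum(.data$length), n_fragments = dplyr::n(),
              members = list(.data$fragment_id), .groups = "drop") |>
    mutate(block_length = .data$end - .data$start) |>
    arrange(.data$seq_id, .data$start)
  out$block_id <- sprintf("block%04d", seq_len(nrow(out)))
  select(out, "block_id", "seq_id", "start", "end", "block_length",
         "fragment_bp", "n_fragments", "members")
}

#' Per-base mtDNA coverage by NUMT fragments
#'
#' @param fragments Fragment tibble carrying an `mt_segments` list-column.
#' @param unit A `circular_unit`.
#' @return An `mt_coverage` object: `coverage` (integer vector over
#'   `[0, L)`, `coverage[i]` is the number of mt segments containing
#'   position `i - 1`), `copies_equivalent` (total fragment genomic bp / L,
#'   1 decimal) and `unit_length`.
#' @export
mtdna_coverage <- function(fragments, unit) {
  L <- unit$unit_length
  cov <- integer(L)
  if (nrow(fragments) > 0) {
    stopifnot("mt_segments" %in% names(fragments))
    segs <- bind_rows(fragments$mt_segments)
    for (i in seq_len(nrow(segs))) {
      idx <- (segs$start[i] + 1):segs$end[i]
      cov[idx] <- cov[idx] + 1L
    }
  }
  total_bp <- sum(fragments$length)
  structure(list(coverage = cov,
                 copies_equivalent = round(total_bp / L, 1),
                 total_fragment_bp = total_bp,
                 unit_length = L),
            class = "mt_coverage")
}

#' @export
print.mt_coverage <- function(x, ...) {
  cat(sprintf(
    "<mt_coverage> unit %d bp; %.0f fragment bp = %.1f copies; mean depth %.2f\n",
    x$unit_length, x$total_fragment_bp, x$copies_equivalent,
    mean(x$coverage)))
  invisible(x)
}

#' Count long reads spanning each NUMT fragment plus a flank
#'
#' A read supports a fragment at flank `f` when its alignment covers the
#' whole interval `[start - f', end + f')` where `f'` is `f` truncated at
#' the scaffold boundaries; a fragment near a scaffold end can therefore
#' still collect 5 kb-flank support from reads reaching the end.
#'
#' @param reads Read alignment tibble with `seq_id`, `start`, `end`
#'   (0-based half-open genomic intervals), e.g. from [read_hits()] PAF
#'   output with the read as query.
#' @param fragments Fragment tibble.
#' @param flanks Integer vector of flank sizes in bp.
#' @param seq_lengths Named vector of scaffold lengths (for truncation).
#' @return Long tibble: `fragment_id`, `flank`, `n_spanning`.
#' @export
count_spanning_reads <- function(reads, fragments,
                                 flanks = c(0, 100, 1000, 5000),
                                 seq_lengths) {
  rows <- list()
  for (i in seq_len(nrow(fragments))) {
    fid <- fragments$fragment_id[i]
    sid <- fragments$seq_id[i]
    slen <- seq_lengths[[sid]]
    r <- reads[reads$seq_id == sid, , drop = FALSE]
    for (f in flanks) {
      lo <- max(0, fragments$start[i] - f)
      hi <- min(slen, fragments$end[i] + f)
      n <- sum(r$start <= lo & r$end >= hi)
      rows[[length(rows) + 1]] <- tibble(fragment_id = fid, flank = f,
                                         n_spanning = n)
    }
  }
  bind_rows(rows)
}

#' Classify reads by their relationship to the mitochondrial genome
#'
#' Used to pick reads for mitochondrial assembly while avoiding NUMT
#' contamination: `pure_complete` reads have at least 99% of their length
#' aligned to the mtDNA *and* cover at least 99% of the unit; `partial`
#' reads pass only the read-length criterion; everything else is `non_mt`.
#'
#' @param read_hits Hit tibble of read-vs-mtDNA alignments with the read as
#'   query (`query_id`, `q_start`, `q_end`) and mt coordinates as subject.
#' @param read_lengths Named vector of read lengths.
#' @param unit_length Length of the mitochondrial unit in bp.
#' @param min_frac Threshold for both fractions (default 0.99).
#' @return Tibble: `read_id`, `read_frac` (aligned fraction of the read),
#'   `mt_frac` (fraction of the unit covered), `class`.
#' @export
classify_mt_reads <- function(read_hits, read_lengths, unit_length,
                              min_frac = 0.99) {
  ids <- names(read_lengths)
  rows <- lapply(ids, function(id) {
    h <- read_hits[read_hits$query_id == id, , drop = FALSE]
    if (nrow(h) == 0) {
      return(tibble(read_id = id, read_frac = 0, mt_frac = 0,
                    class = "non_mt"))
    }
    qcov <- IRanges::reduce(IRanges::IRanges(h$q_start + 1, h$q_end))
    scov <- IRanges::reduce(IRanges::IRanges(h$s_start + 1, h$s_end))
    rf <- sum(IRanges::width(qcov)) / read_lengths[[id]]
    mf <- sum(IRanges::width(scov)) / unit_length
    cls <- if (rf >= min_frac && mf >= min_frac) "pure_complete"
           else if (rf >= min_frac) "partial" else "non_mt"
    tibble(read_id = id, read_frac = rf, mt_frac = mf, class = cls)
  })
  bind_rows(rows)
}

#' Run the full NUMT discovery pipeline
#'
#' Convenience wrapper: e-value filter, unique-hit compression against the
#' doubled query, mt-unit wrapping, block merging and mtDNA coverage.
#'
#' @param hits Hit tibble (doubled-mtDNA query vs assembly).
#' @param mtdna One-row circular genome tibble.
#' @param max_evalue,min_frag,merge_gap Pipeline parameters.
#' @param seq_lengths Optional named scaffold lengths for validation.
#' @return List with `fragments`, `blocks`, `mt_coverage`, `unit`.
#' @export
numt_pipeline <- function(hits, mtdna, max_evalue = 1e-4, min_frag = 25,
                          merge_gap = 8000, seq_lengths = NULL) {
  dq <- build_doubled_query(mtdna)
  kept <- filter_hits(hits, max_evalue)
  frags <- compress_unique(kept, unit = dq$unit, min_frag = min_frag,
                           seq_lengths = seq_lengths)
  blocks <- merge_blocks(frags, merge_gap = merge_gap)
  cov <- mtdna_coverage(frags, dq$unit)
  list(fragments = frags, blocks = blocks, mt_coverage = cov,
       unit = dq$unit)
}
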
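# Fixtures built in code: tiny genomes, depth tracks, BUSCO tables, and the
# independent per-base best-hit oracle used against compress_unique().

make_genome <- function(..., circular = character()) {
  seqs <- list(...)
  tibble::tibble(
    seq_id = names(seqs),
    length = nchar(unlist(seqs, use.names = FALSE)),
    circular = names(seqs) %in% circular,
    n_ambiguous = 0L,
    residues = unlist(seqs, use.names = FALSE)
  )
}

flat_genome <- function(lengths, base = "A") {
  # uniform-residue scaffolds: handy when only coordinates matter
  do.call(make_genome, lapply(lengths, function(n) strrep(base, n)))
}

uniform_track <- function(genome, depth) {
  depths <- lapply(seq_len(nrow(genome)), function(i) {
    rep(as.integer(depth), genome$length[i])
  })
  names(depths) <- genome$seq_id
  depth_track(depths, genome)
}

make_busco <- function(seq_id, starts, ends, status = "Complete",
                       excluded = FALSE) {
  tibble::tibble(
    busco_id = sprintf("busco%04d", seq_along(starts)),
    status = status, seq_id = seq_id, start = starts, end = ends,
    on_excluded_seq = excluded
  )
}

make_hit <- function(s_id, s_start, s_end, bitscore, q_start = s_start,
                     q_end = s_end, strand = "+", evalue = 1e-50) {
  tibble::tibble(query_id = "mt_x2", q_start = q_start, q_end = q_end,
                 q_len = NA_real_, s_id = s_id, s_start = s_start,
                 s_end = s_end, strand = strand, identity_pct = 100,
                 aln_len = s_end - s_start, evalue = evalue,
                 bitscore = bitscore)
}

# Independent oracle for unique-hit compression: every genomic base is
# assigned to the best hit covering it (bitscore desc, subject length desc,
# s_id/s_start asc); fragments are the maximal runs of a single winner, with
# runs shorter than min_frag discarded.
perbase_best_hit_fragments <- function(hits, seq_lengths, min_frag = 25) {
  h <- hits[order(-hits$bitscore, -(hits$s_end - hits$s_start), hits$s_id,
                  hits$s_start), ]
  out <- list()
  for (sid in names(seq_lengths)) {
    winner <- rep(NA_integer_, seq_lengths[[sid]])
    hh <- which(h$s_id == sid)
    for (k in hh) {
      idx <- (h$s_start[k] + 1):h$s_end[k]
      free <- is.na(winner[idx])
      winner[idx[free]] <- k
    }
    r <- rle(winner)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- !is.na(r$values) & r$lengths >= min_frag
    if (any(keep)) {
      out[[sid]] <- tibble::tibble(seq_id = sid, start = starts[keep],
                                   end = ends[keep])
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(seq_id = character(), start = numeric(),
                          end = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), seq_id, start)
}

random_hits <- function(n, seq_lengths, max_len = 800) {
  sids <- sample(names(seq_lengths), n, replace = TRUE)
  len <- sample(30:max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(seq_lengths[[sids[i]]] - len[i], 1) - 1L
  }, integer(1))
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_hit(sids[i], start[i], start[i] + len[i],
             bitscore = sample(50:500, 1))
  }))
}
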
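# NUMT discovery: doubled query, hit filtering, unique-hit compression
# (against the per-base best-hit oracle), circular wrapping, block merging,
# mtDNA coverage and spanning-read support.

test_that("doubled query duplicates the circular unit exactly", {
  mt <- make_genome(mt = "ACGTACGTAG", circular = "mt")
  dq <- build_doubled_query(mt)
  expect_equal(dq$doubled$length, 20L)
  expect_equal(dq$unit$unit_length, 10L)
  expect_equal(dq$unit$doubled_length, 20L)
  expect_equal(substr(dq$doubled$residues, 1, 10),
               substr(dq$doubled$residues, 11, 20))
  mt$circular <- FALSE
  expect_error(build_doubled_query(mt), "circular")
})

test_that("e-value filter keeps strictly sub-threshold hits", {
  hits <- dplyr::bind_rows(
    make_hit("s", 0, 100, 100, evalue = 1e-5),
    make_hit("s", 200, 300, 100, evalue = 1e-3),
    make_hit("s", 400, 500, 100, evalue = 1e-180),
    make_hit("s", 600, 700, 100, evalue = 1e-4),
    make_hit("s", 800, 900, 100, evalue = 0.5)
  )
  expect_message(kept <- filter_hits(hits, 1e-4), "retained 2/5")
  expect_equal(kept$s_start, c(0, 400))
})

test_that("wrap_to_unit conserves length and splits at the origin", {
  L <- 16761
  unit <- structure(list(mt_id = "mt", unit_length = L,
                         doubled_length = 2L * L), class = "circular_unit")
  expect_equal(wrap_to_unit(10, 100, unit),
               tibble::tibble(start = 10, end = 100))
  expect_equal(wrap_to_unit(L + 10, L + 100, unit),
               tibble::tibble(start = 10, end = 100))
  sp <- wrap_to_unit(L - 50, L + 30, unit)
  expect_equal(nrow(sp), 2)
  expect_equal(sp$start, c(L - 50, 0))
  expect_equal(sp$end, c(L, 30))
  expect_equal(sum(sp$end - sp$start), 80)
  expect_error(wrap_to_unit(0, L + 1, unit), "longer than")
  # per-base modular mapping oracle on random intervals
  set.seed(5)
  for (i in 1:25) {
    a <- sample.int(2 * L - 200, 1)
    w <- sample.int(min(L, 2 * L - a), 1)
    segs <- wrap_to_unit(a, a + w, unit)
    covered <- unlist(purrr::map2(segs$start, segs$end, ~seq(.x, .y - 1)))
    expect_equal(covered, (a:(a + w - 1)) %% L)
  }
})

test_that("doubled-query duplicate hits collapse to one fragment", {
  L <- 1000
  unit <- structure(list(mt_id = "mt", unit_length = L,
                         doubled_length = 2L * L), class = "circular_unit")
  hits <- dplyr::bind_rows(
    make_hit("s", 500, 700, bitscore = 400, q_start = 100, q_end = 300),
    make_hit("s", 500, 700, bitscore = 400, q_start = 1100, q_end = 1300)
  )
  fr <- compress_unique(hits, unit = unit)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$start, 500)
  expect_equal(fr$end, 700)
  expect_equal(fr$mt_segments[[1]], tibble::tibble(start = 100, end = 300))
})

test_that("overlapping hits are trimmed by score precedence", {
  hits <- dplyr::bind_rows(
    make_hit("s", 0, 500, bitscore = 100),
    make_hit("s", 400, 900, bitscore = 90)
  )
  fr <- compress_unique(hits)
  expect_equal(fr$start, c(0, 500))
  expect_equal(fr$end, c(500, 900))
  # single hit is the identity case
  one <- compress_unique(make_hit("s", 10, 200, 50))
  expect_equal(one[, c("start", "end")],
               tibble::tibble(start = 10, end = 200))
})

test_that("compression equals the per-base best-hit oracle on random instances", {
  seq_lengths <- c(sA = 6000L, sB = 4000L)
  set.seed(99)
  for (rep in 1:200) {
    hits <- random_hits(sample(2:12, 1), seq_lengths)
    got <- compress_unique(hits, seq_lengths = seq_lengths)
    want <- perbase_best_hit_fragments(hits, seq_lengths)
    expect_equal(got[, c("seq_id", "start", "end")],
                 want[, c("seq_id", "start", "end")],
                 info = sprintf("instance %d", rep))
  }
})

test_that("fragments shorter than min_frag are discarded after trimming", {
  hits <- dplyr::bind_rows(
    make_hit("s", 100, 400, bitscore = 100),
    make_hit("s", 90, 410, bitscore = 50)  # leaves 10 bp slivers both sides
  )
  fr <- compress_unique(hits, min_frag = 25)
  expect_equal(nrow(fr), 1)
  expect_equal(c(fr$start, fr$end), c(100, 400))
  fr2 <- compress_unique(hits, min_frag = 5)
  expect_equal(nrow(fr2), 3)
})

test_that("hits on unknown scaffolds are rejected", {
  expect_error(
    compress_unique(make_hit("ghost", 0, 100, 50),
                    seq_lengths = c(s = 1000)),
    "ghost")
})

test_that("block merging joins fragments within the gap, transitively", {
  fr <- tibble::tibble(
    fragment_id = c("f1", "f2", "f3", "f4"),
    seq_id = c("s1", "s1", "s1", "s2"),
    start = c(0, 5000, 13000, 0), end = c(100, 5100, 13100, 50),
    strand = "+", length = c(100, 100, 100, 50))
  bl <- merge_blocks(fr, merge_gap = 8000)
  expect_equal(nrow(bl), 2)
  b1 <- bl[bl$seq_id == "s1", ]
  expect_equal(c(b1$start, b1$end), c(0, 13100))
  expect_equal(b1$n_fragments, 3L)
  expect_equal(b1$fragment_bp, 300)
  expect_equal(b1$block_length, 13100)
  # 8001 bp gap stays split; 8000 merges (boundary)
  fr2 <- fr[1:2, ]
  fr2$start <- c(0, 8101); fr2$end <- c(100, 8200)
  expect_equal(nrow(merge_blocks(fr2, 8000)), 2)
  fr2$start <- c(0, 8100); fr2$end <- c(100, 8200)
  expect_equal(nrow(merge_blocks(fr2, 8000)), 1)
})

test_that("every fragment lands in exactly one block and lengths are conserved", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    starts <- sort(sample.int(200000, n))
    lens <- sample(30:400, n, replace = TRUE)
    ends <- pmin(starts + lens, c(starts[-1], Inf))  # keep non-overlapping
    keep <- ends > starts
    fr <- tibble::tibble(fragment_id = sprintf("f%d", seq_len(sum(keep))),
                         seq_id = "s", start = starts[keep],
                         end = ends[keep], strand = "+",
                         length = (ends - starts)[keep])
    bl <- merge_blocks(fr, merge_gap = 3000)
    expect_equal(sort(unlist(bl$members)), sort(fr$fragment_id))
    expect_true(all(bl$block_length >= bl$fragment_bp - 1e-9))
    expect_lte(nrow(bl), nrow(fr))
  }
})

test_that("mtDNA coverage counts segments per base and copy equivalents", {
  L <- 1000
  unit <- structure(list(mt_id = "mt", unit_length = L,
                         doubled_length = 2L * L), class = "circular_unit")
  fr <- tibble::tibble(
    fragment_id = c("f1", "f2"), seq_id = "s",
    start = c(0, 2000), end = c(1000, 2500), strand = "+",
    length = c(1000, 500),
    mt_segments = list(tibble::tibble(start = 0, end = 1000),
                       tibble::tibble(start = 250, end = 750)))
  cov <- mtdna_coverage(fr, unit)
  expect_equal(cov$coverage[1], 1L)
  expect_equal(cov$coverage[500], 2L)
  expect_equal(cov$copies_equivalent, 1.5)
  empty <- mtdna_coverage(fr[0, ], unit)
  expect_equal(sum(empty$coverage), 0L)
  expect_equal(empty$copies_equivalent, 0)
})

test_that("spanning-read counts respect flanks, boundaries and monotonicity", {
  seq_lengths <- c(s = 20000)
  fr <- tibble::tibble(fragment_id = "f1", seq_id = "s",
                       start = 4000, end = 4100)
  reads <- tibble::tibble(read_id = c("r1", "r2"), read_len = c(10000, 200),
                          seq_id = "s", start = c(0, 3950),
                          end = c(10000, 4150))
  sp <- count_spanning_reads(reads, fr, flanks = c(0, 100, 1000),
                             seq_lengths = seq_lengths)
  expect_equal(sp$n_spanning[sp$flank == 1000], 1L)  # only r1
  expect_equal(sp$n_spanning[sp$flank == 100], 1L)   # r2 misses [3900,4200]
  expect_equal(sp$n_spanning[sp$flank == 0], 2L)
  # brute-force oracle on a random read set + monotonicity in flank
  set.seed(8)
  reads2 <- tibble::tibble(
    read_id = sprintf("r%02d", 1:20), read_len = 6000, seq_id = "s",
    start = sample.int(14000, 20) - 1) |>
    dplyr::mutate(end = start + 6000)
  flanks <- c(0, 100, 1000, 5000)
  sp2 <- count_spanning_reads(reads2, fr, flanks, seq_lengths)
  for (f in flanks) {
    lo <- max(0, 4000 - f); hi <- min(20000, 4100 + f)
    brute <- sum(reads2$start <= lo & reads2$end >= hi)
    expect_equal(sp2$n_spanning[sp2$flank == f], brute)
  }
  expect_true(all(diff(sp2$n_spanning) <= 0))
})

test_that("flank truncation at scaffold ends keeps edge fragments supportable", {
  seq_lengths <- c(s = 6000)
  fr <- tibble::tibble(fragment_id = "f1", seq_id = "s",
                       start = 50, end = 150)
  reads <- tibble::tibble(read_id = "r1", read_len = 6000, seq_id = "s",
                          start = 0, end = 6000)
  sp <- count_spanning_reads(reads, fr, flanks = 5000,
                             seq_lengths = seq_lengths)
  expect_equal(sp$n_spanning, 1L)
})

test_that("mitochondrial read classification uses both 99% fractions", {
  L <- 16700
  read_lengths <- c(full = 16500, small = 2000, half = 10000)
  hits <- dplyr::bind_rows(
    tibble::tibble(query_id = "full", q_start = 0, q_end = 16500,
                   q_len = 16500, s_id = "mt", s_start = 0, s_end = 16620,
                   strand = "+", identity_pct = 99, aln_len = 16500,
                   evalue = 0, bitscore = 3e4),
    tibble::tibble(query_id = "small", q_start = 0, q_end = 2000,
                   q_len = 2000, s_id = "mt", s_start = 100, s_end = 2100,
                   strand = "+", identity_pct = 99, aln_len = 2000,
                   evalue = 0, bitscore = 4e3),
    tibble::tibble(query_id = "half", q_start = 0, q_end = 5000,
                   q_len = 10000, s_id = "mt", s_start = 0, s_end = 5000,
                   strand = "+", identity_pct = 99, aln_len = 5000,
                   evalue = 0, bitscore = 1e4))
  cls <- classify_mt_reads(hits, read_lengths, L)
  expect_equal(cls$class[cls$read_id == "full"], "pure_complete")
  expect_equal(cls$class[cls$read_id == "small"], "partial")
  expect_equal(cls$class[cls$read_id == "half"], "non_mt")
})
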
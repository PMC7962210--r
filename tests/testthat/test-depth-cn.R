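# Single-copy depth model, region / gene-family / depth-ratio copy number,
# and gene coverage binning.

test_that("modal single-copy depth is recovered from uniform coverage", {
  g <- flat_genome(list(chr1 = 20000L))
  tr <- uniform_track(g, 34)
  busco <- make_busco("chr1", seq(0, 9000, by = 1000),
                      seq(800, 9800, by = 1000))
  m <- fit_single_copy_model(tr, busco)
  expect_equal(m$X_SC, 34L)
  expect_equal(m$mean_cn, 1)
  expect_equal(m$sd_cn, 0)
  expect_equal(m$ci95_halfwidth, 0)
})

test_that("modal depth ties break toward the lower depth", {
  g <- flat_genome(list(chr1 = 100L))
  d <- c(rep(10L, 40), rep(20L, 40), rep(30L, 20))
  tr <- depth_track(list(chr1 = d), g)
  busco <- make_busco("chr1", 0, 100)
  expect_equal(fit_single_copy_model(tr, busco)$X_SC, 10L)
})

test_that("excluded sequences and non-Complete genes stay out of the model", {
  g <- flat_genome(list(chr1 = 2000L, chrX = 2000L))
  tr <- depth_track(list(chr1 = rep(30L, 2000), chrX = rep(15L, 2000)), g)
  busco <- dplyr::bind_rows(
    make_busco("chr1", c(0, 1000), c(800, 1800)),
    make_busco("chrX", 0, 1800, excluded = TRUE),
    make_busco("chr1", 500, 900, status = "Fragmented"))
  m <- fit_single_copy_model(tr, busco)
  expect_equal(m$n_genes, 2L)
  expect_equal(m$X_SC, 30L)
  # generic exclude-list works the same way
  busco2 <- dplyr::bind_rows(make_busco("chr1", 0, 800),
                             make_busco("chrX", 0, 1800))
  m2 <- fit_single_copy_model(tr, busco2, exclude_seqs = "chrX")
  expect_equal(m2$n_genes, 1L)
})

test_that("zero coverage and empty gene sets raise errors", {
  g <- flat_genome(list(chr1 = 1000L))
  tr <- uniform_track(g, 0)
  busco <- make_busco("chr1", 0, 900)
  expect_error(fit_single_copy_model(tr, busco), "insufficient coverage")
  expect_error(fit_single_copy_model(tr, busco[0, ]), "no eligible")
})

test_that("region copy number is X_reg / X_SC with the documented identities", {
  g <- flat_genome(list(chr1 = 30000L))
  # region with mean depth exactly 97.5 (alternating 97/98), baseline 34
  d <- rep(34L, 30000)
  d[20001:21000] <- rep(c(97L, 98L), 500)
  tr <- depth_track(list(chr1 = d), g)
  busco <- make_busco("chr1", seq(0, 9000, by = 1000),
                      seq(800, 9800, by = 1000))
  m <- fit_single_copy_model(tr, busco)
  rc <- region_cn(tr, tibble::tibble(seq_id = "chr1", start = 20000,
                                     end = 21000), m)
  expect_equal(rc$X_reg, 97.5)
  expect_equal(round(rc$N_reg, 2), 2.87)
  # identity and zero cases
  rc1 <- region_cn(tr, tibble::tibble(seq_id = "chr1", start = 0,
                                      end = 800), m)
  expect_equal(rc1$N_reg, 1)
  d0 <- d; d0[25001:25200] <- 0L
  tr0 <- depth_track(list(chr1 = d0), g)
  rc0 <- region_cn(tr0, tibble::tibble(seq_id = "chr1", start = 25000,
                                       end = 25200), m)
  expect_equal(rc0$N_reg, 0)
})

test_that("scale invariance: multiplying all depths by k leaves N_reg unchanged", {
  g <- flat_genome(list(chr1 = 20000L))
  set.seed(3)
  d <- rpois(20000, 30)
  busco <- make_busco("chr1", seq(0, 9000, by = 1000),
                      seq(900, 9900, by = 1000))
  region <- tibble::tibble(seq_id = "chr1", start = 15000, end = 18000)
  n_reg <- sapply(c(1L, 3L), function(k) {
    tr <- depth_track(list(chr1 = d * k), g)
    m <- fit_single_copy_model(tr, busco)
    region_cn(tr, region, m)$N_reg
  })
  expect_equal(n_reg[1], n_reg[2])
})

test_that("all-gap regions are rejected and gap bases excluded from means", {
  res <- paste0(strrep("A", 500), strrep("N", 200), strrep("A", 300))
  g <- make_genome(chr1 = res)
  d <- c(rep(30L, 500), rep(0L, 200), rep(60L, 300))
  tr <- depth_track(list(chr1 = d), g)
  expect_error(region_mean_depth(tr, "chr1", 500, 700), "gap")
  # mean over [400, 800): 100 bases at 30 + 100 at 60, 200 gap bases dropped
  expect_equal(region_mean_depth(tr, "chr1", 400, 800), 45)
})

test_that("BUSCO-mean summary reproduces the hand-computed CI", {
  m <- structure(list(X_SC = 30L,
                      per_gene = tibble::tibble(cn = c(0.9, 1.1)),
                      n_genes = 2L, mean_cn = 1, sd_cn = sd(c(0.9, 1.1)),
                      ci95_halfwidth = 1.96 * sd(c(0.9, 1.1)) / sqrt(2)),
                 class = "single_copy_model")
  s <- busco_cn_summary(m)
  expect_equal(s$mean_cn, 1)
  expect_equal(s$ci95_halfwidth, 1.96 * 0.1414214 / sqrt(2),
               tolerance = 1e-5)
})

test_that("gene-family copy number sums coverage-weighted hits", {
  g <- flat_genome(list(chr1 = 40000L))
  d <- rep(34L, 40000)
  d[20001:21000] <- rep(c(97L, 98L), 500)
  d[30001:31000] <- rep(c(97L, 98L), 500)
  tr <- depth_track(list(chr1 = d), g)
  busco <- make_busco("chr1", seq(0, 9000, by = 1000),
                      seq(800, 9800, by = 1000))
  m <- fit_single_copy_model(tr, busco)
  hits <- tibble::tibble(seq_id = "chr1", start = c(20000, 30000),
                         end = c(21000, 31000), query_coverage = 1)
  est <- gene_family_cn(tr, hits, m)
  expect_equal(est$total_copies, 2 * 97.5 / 34)
  expect_equal(round(est$total_copies, 2), 5.74)
  # a single full-coverage hit reduces exactly to region_cn
  one <- gene_family_cn(tr, hits[1, ], m)
  rc <- region_cn(tr, hits[1, c("seq_id", "start", "end")], m)
  expect_equal(one$total_copies, rc$N_reg)
  # weighting by query coverage
  hits$query_coverage <- c(0.9, 0.5)
  est2 <- gene_family_cn(tr, hits, m)
  expect_equal(est2$total_copies, (0.9 + 0.5) * 97.5 / 34)
  expect_warning(z <- gene_family_cn(tr, hits[0, ], m), "empty")
  expect_equal(z$total_copies, 0)
})

test_that("overlapping family hits are collapsed before estimation", {
  g <- flat_genome(list(chr1 = 10000L))
  tr <- uniform_track(g, 60)
  busco <- make_busco("chr1", 0, 1000)
  m0 <- structure(list(X_SC = 30L, per_gene = tibble::tibble(cn = 1),
                       n_genes = 1L, mean_cn = 1, sd_cn = 0,
                       ci95_halfwidth = 0), class = "single_copy_model")
  hits <- tibble::tibble(seq_id = "chr1", start = c(2000, 2500),
                         end = c(3000, 3500), query_coverage = c(1, 0.8))
  expect_message(est <- gene_family_cn(tr, hits, m0), "collapsed")
  expect_equal(nrow(est$per_hit), 1)
  expect_equal(est$per_hit$start, 2000)
  expect_equal(est$per_hit$end, 3500)
  expect_equal(est$total_copies, 2)  # depth 60 / X_SC 30 * max coverage 1
})

test_that("read-length filtering feeds recomputed depth", {
  reads <- tibble::tibble(read_id = c("a", "b", "c"),
                          read_len = c(3000, 6000, 12000),
                          seq_id = "s", start = c(0, 1000, 2000),
                          end = c(3000, 7000, 14000))
  expect_equal(nrow(filter_reads_by_length(reads, 0)), 3)
  expect_equal(filter_reads_by_length(reads, 5000)$read_id, c("b", "c"))
  expect_equal(filter_reads_by_length(reads, 10000)$read_id, "c")
  g <- flat_genome(list(s = 20000L))
  tr <- depth_from_reads(filter_reads_by_length(reads, 5000), g)
  expect_equal(tr$depth$s[1], 0L)
  expect_equal(tr$depth$s[2500], 2L)  # reads b and c
})

test_that("short-read depth-ratio copy number is the summed gene/genome ratio", {
  g <- flat_genome(list(chr1 = 10000L))
  d <- rep(30L, 10000)
  d[1001:1500] <- 60L
  d[3001:3500] <- 60L
  tr <- depth_track(list(chr1 = d), g)
  regions <- tibble::tibble(seq_id = "chr1", start = c(1000, 3000),
                            end = c(1500, 3500))
  expect_equal(short_read_ratio_cn(tr, regions, genome_mean = 30), 4)
  one <- tibble::tibble(seq_id = "chr1", start = 6000, end = 6500)
  expect_equal(short_read_ratio_cn(tr, one, genome_mean = 30), 1)
  expect_error(short_read_ratio_cn(tr, one, genome_mean = 0), "positive")
})

test_that("planted 5-copy array is recovered by the depth-ratio method", {
  set.seed(17)
  g <- flat_genome(list(chr1 = 60000L))
  cn <- rep(1, 60000)
  cn[40001:45000] <- 5
  d <- rpois(60000, 30 * cn)
  tr <- depth_track(list(chr1 = d), g)
  est <- short_read_ratio_cn(tr,
                             tibble::tibble(seq_id = "chr1", start = 40000,
                                            end = 45000),
                             genome_mean = 30)
  expect_gt(est, 4.5)
  expect_lt(est, 5.5)
})

test_that("gene coverage bins follow the assembly-mode rules", {
  v <- c(0, 0.2, 0.4, 0.5, 0.9, 1.4, 1.5, 2.4, 2.5, 7)
  expect_equal(
    bin_gene_coverage(v, "assembly"),
    c("Missing", "Partial(<50%)", "Partial(<50%)", "1n", "1n", "1n",
      "2n", "2n", "3n+", "3n+"))
  expect_error(bin_gene_coverage(-1, "assembly"), "non-negative")
})

test_that("gene coverage bins follow the long-read half-integer rules", {
  v <- c(0, 0.1, 0.49, 0.6, 1.2, 1.25, 1.3, 2.2, 2.8, 9)
  expect_equal(
    bin_gene_coverage(v, "longread"),
    c("0n", "0.5n", "0.5n", "0.5n", "1n", "1.5n", "1.5n", "2n", "2.5n+",
      "2.5n+"))
  # totality: every non-negative value maps to exactly one label
  set.seed(2)
  x <- c(runif(200, 0, 5), 0, 0.5, 1.25, 2.5)
  labs <- bin_gene_coverage(x, "longread")
  expect_false(anyNA(labs))
  labs2 <- bin_gene_coverage(x, "assembly")
  expect_false(anyNA(labs2))
})
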
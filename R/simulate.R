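# Deterministic synthetic data: toy genomes with planted NUMTs (including
# origin-spanning ones), a tandem gene array, haplotig scaffolds, Poisson
# per-base depth with region CN multipliers, uniformly placed reads, and
# jittered two-platform SV call sets — all with exact truth tables.

DNA <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(DNA, n, replace = TRUE), collapse = "")

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulation configuration
#'
#' Defaults mirror the scale of the dog-genome audit this toolkit is built
#' around: a ~16.7 kb circular mitochondrial unit, NUMT insertions from
#' 34 bp to 6.6 kb, a two-copy tandem gene array whose underlying genome
#' carries six copies, half-depth haplotigs, and ~30x Poisson base depth.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @param n_scaffolds,scaffold_len Nuclear toy genome dimensions.
#' @param mt_len Mitochondrial unit length (bp).
#' @param n_numts Number of planted NUMT fragments.
#' @param numt_len_range Fragment length range, sampled log-uniformly.
#' @param include_origin_spanning Force at least one NUMT whose mt segment
#'   crosses the circular origin.
#' @param n_tandem_gene_copies Assembled copies of the tandem gene array.
#' @param tandem_true_copies Copies actually present in the simulated
#'   individual (sets the depth multiplier over the array).
#' @param gene_len Length of the arrayed gene (bp).
#' @param base_depth Poisson depth rate lambda at copy number 1.
#' @param planted_cn Copy numbers for extra planted CN regions.
#' @param cn_region_len Length of each planted CN region (bp).
#' @param n_haplotigs,haplotig_len Half-depth duplicate scaffolds.
#' @param sv_n Named vector of planted SV counts per type.
#' @param sv_len_range SV length range, log-uniform.
#' @param read_len,read_coverage Read simulation parameters.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_scaffolds = 3, scaffold_len = 120000,
                       mt_len = 16700, n_numts = 8,
                       numt_len_range = c(34, 6580),
                       include_origin_spanning = TRUE,
                       n_tandem_gene_copies = 2, tandem_true_copies = 6,
                       gene_len = 1500, base_depth = 30,
                       planted_cn = c(2, 3, 6), cn_region_len = 2000,
                       n_haplotigs = 2, haplotig_len = 20000,
                       sv_n = c(DEL = 25, INS = 25, INV = 8, DUP = 8),
                       sv_len_range = c(150, 5000),
                       read_len = 10000, read_coverage = 30) {
  stopifnot(numt_len_range[1] >= 25, numt_len_range[2] <= mt_len,
            n_tandem_gene_copies >= 1,
            tandem_true_copies >= n_tandem_gene_copies,
            base_depth > 0)
  structure(as.list(environment()), class = "sim_config")
}

sample_log_uniform <- function(n, range) {
  round(exp(runif(n, log(range[1]), log(range[2]))))
}

#' Simulate a toy assembly with planted features
#'
#' Builds a random circular mtDNA and nuclear scaffolds, then plants:
#' NUMT copies (subsegments of the mt unit, some reverse-strand, optionally
#' origin-spanning, some pairs within 8 kb so they merge into blocks), a
#' tandem array of an amylase-like gene, and haplotig scaffolds duplicating
#' segments of the primaries. Sequence is overwritten in place so scaffold
#' coordinates are static and the truth table is exact.
#'
#' @param config A [sim_config()].
#' @return A list: `genome` (assembly tibble incl. haplotig scaffolds),
#'   `mtdna` (one-row circular genome tibble), `truth` (list of tibbles:
#'   `numts`, `cn_regions`, `genes`, `haplotigs`), `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$mt_len
  mt_res <- random_dna(L)
  scafs <- paste0("scaf", seq_len(config$n_scaffolds))
  res <- setNames(vapply(scafs, function(s) random_dna(config$scaffold_len),
                         character(1)), scafs)

  # --- NUMTs: confined to the first 60% of each scaffold ------------------
  lens <- sample_log_uniform(config$n_numts, config$numt_len_range)
  mt_starts <- sample.int(L, config$n_numts) - 1L
  if (config$include_origin_spanning) {
    mt_starts[1] <- L - max(25L, lens[1] %/% 2L)
  }
  strands <- rep(c("+", "-"), length.out = config$n_numts)
  scaf_of <- rep(scafs, length.out = config$n_numts)
  numt_rows <- list()
  cursor <- setNames(rep(1000, length(scafs)), scafs)
  limit <- 0.6 * config$scaffold_len
  for (i in seq_len(config$n_numts)) {
    sc <- scaf_of[i]
    gap <- if (i %% 2 == 0) round(runif(1, 500, 6000)) else
      round(runif(1, 9000, 14000))
    start <- cursor[[sc]] + gap
    end <- start + lens[i]
    if (end > limit) {
      abort("planted NUMT exceeds scaffold bounds; enlarge scaffold_len")
    }
    cursor[[sc]] <- end
    mt_a <- mt_starts[i]
    q_end <- mt_a + lens[i]  # on the doubled unit, may exceed L
    seg <- if (q_end <= L) substr(mt_res, mt_a + 1, q_end) else
      paste0(substr(mt_res, mt_a + 1, L), substr(mt_res, 1, q_end - L))
    insert <- if (strands[i] == "+") seg else revcomp(seg)
    substr(res[[sc]], start + 1, end) <- insert
    numt_rows[[i]] <- tibble(
      numt_id = sprintf("truth%03d", i), seq_id = sc,
      start = start, end = end, strand = strands[i], length = lens[i],
      mt_start = mt_a, mt_end_doubled = q_end,
      origin_spanning = q_end > L
    )
  }
  numts <- bind_rows(numt_rows) |> arrange(.data$seq_id, .data$start)

  # --- tandem gene array on the last scaffold's top 30% -------------------
  gene_res <- random_dna(config$gene_len)
  arr_scaf <- scafs[length(scafs)]
  arr_start <- round(0.65 * config$scaffold_len)
  gene_rows <- list()
  for (k in seq_len(config$n_tandem_gene_copies)) {
    gs <- arr_start + (k - 1) * config$gene_len
    substr(res[[arr_scaf]], gs + 1, gs + config$gene_len) <- gene_res
    gene_rows[[k]] <- tibble(gene_id = sprintf("amy_like_%d", k),
                             seq_id = arr_scaf, start = gs,
                             end = gs + config$gene_len)
  }
  genes <- bind_rows(gene_rows)
  array_cn <- config$tandem_true_copies / config$n_tandem_gene_copies
  cn_regions <- tibble(region_id = "tandem_array", seq_id = arr_scaf,
                       start = arr_start,
                       end = arr_start +
                         config$n_tandem_gene_copies * config$gene_len,
                       cn = array_cn)

  # --- extra planted CN regions on scaffold 1's top 30% -------------------
  pos <- round(0.65 * config$scaffold_len)
  for (j in seq_along(config$planted_cn)) {
    st <- pos + (j - 1) * (config$cn_region_len + 3000)
    en <- st + config$cn_region_len
    if (en > config$scaffold_len) {
      abort("planted CN region exceeds scaffold bounds")
    }
    cn_regions <- bind_rows(cn_regions, tibble(
      region_id = sprintf("cn_region_%d", j), seq_id = scafs[1],
      start = st, end = en, cn = config$planted_cn[j]))
  }

  # --- haplotig scaffolds -------------------------------------------------
  hap_rows <- list()
  for (k in seq_len(config$n_haplotigs)) {
    src <- scafs[(k - 1) %% length(scafs) + 1]
    s0 <- 2000 + (k - 1) * 5000
    hid <- sprintf("hap%d", k)
    res[[hid]] <- substr(res[[src]], s0 + 1, s0 + config$haplotig_len)
    hap_rows[[k]] <- tibble(hap_id = hid, source_seq = src,
                            src_start = s0,
                            src_end = s0 + config$haplotig_len)
  }
  haplotigs <- if (config$n_haplotigs > 0) bind_rows(hap_rows) else
    tibble(hap_id = character(), source_seq = character(),
           src_start = numeric(), src_end = numeric())

  genome <- tibble(seq_id = names(res), length = nchar(unname(res)),
                   circular = FALSE, n_ambiguous = 0L,
                   residues = unname(res))
  mtdna <- tibble(seq_id = "mt_unit", length = L, circular = TRUE,
                  n_ambiguous = 0L, residues = mt_res)
  list(genome = genome, mtdna = mtdna,
       truth = list(numts = numts, cn_regions = cn_regions, genes = genes,
                    haplotigs = haplotigs),
       config = config)
}

#' Emit exact homology hits for the planted NUMTs
#'
#' Produces the hit table a perfect aligner would report for the doubled
#' mtDNA query against the assembly: one hit per planted NUMT, plus its
#' duplicate offset by the unit length L whenever the duplicate still fits
#' on the doubled query (this exercises the compression step). Synthetic
#' scores: bitscore = 2 x length, evalue 1e-180, identity 100.
#'
#' @param sim Output of [simulate_genome()].
#' @param decoys Number of low-significance decoy hits (evalue 1e-3) to
#'   append, which [filter_hits()] must remove.
#' @return Hit tibble in the [read_hits()] schema.
#' @export
simulate_hits <- function(sim, decoys = 0) {
  L <- sim$config$mt_len
  nm <- sim$truth$numts
  rows <- list()
  qid <- paste0(sim$mtdna$seq_id[1], "_x2")
  for (i in seq_len(nrow(nm))) {
    qs <- nm$mt_start[i]; qe <- nm$mt_end_doubled[i]
    offs <- c(0L, L)
    offs <- offs[qe + offs <= 2 * L]
    for (o in offs) {
      rows[[length(rows) + 1]] <- tibble(
        query_id = qid, q_start = qs + o, q_end = qe + o, q_len = 2 * L,
        s_id = nm$seq_id[i], s_start = nm$start[i], s_end = nm$end[i],
        strand = nm$strand[i], identity_pct = 100,
        aln_len = nm$length[i], evalue = 1e-180,
        bitscore = 2 * nm$length[i])
    }
  }
  hits <- bind_rows(rows)
  if (decoys > 0) {
    set.seed(sim$config$seed + 7L)
    dk <- tibble(
      query_id = qid,
      q_start = sample.int(L, decoys) - 1,
      s_id = sample(sim$genome$seq_id, decoys, replace = TRUE),
      strand = "+", identity_pct = 80, aln_len = 40,
      evalue = 1e-3, bitscore = 45, q_len = 2 * L
    ) |>
      mutate(q_end = .data$q_start + 40,
             s_start = round(runif(decoys, 0, 1000)),
             s_end = .data$s_start + 40)
    hits <- bind_rows(hits, dk[, names(hits)])
  }
  hits
}

#' Tile truth BUSCO genes over the copy-number-1 territory
#'
#' Emits a synthetic BUSCO table of Complete single-copy genes tiled across
#' every primary scaffold, skipping planted CN regions (and haplotig
#' scaffolds entirely), so the single-copy depth model can be fitted
#' against a known-clean baseline. Pooling several hundred kilobases
#' matters: the modal-depth estimator needs enough bases for the histogram
#' mode to stabilise at the true rate.
#'
#' @param sim Output of [simulate_genome()].
#' @param gene_len Gene length in bp (genes are tiled back to back).
#' @return Tibble in the [read_busco_table()] schema.
#' @export
sim_busco_truth <- function(sim, gene_len = 1000) {
  hap_ids <- sim$truth$haplotigs$hap_id
  rows <- list()
  for (i in seq_len(nrow(sim$genome))) {
    id <- sim$genome$seq_id[i]
    if (id %in% hap_ids) next
    len <- sim$genome$length[i]
    cr <- sim$truth$cn_regions[sim$truth$cn_regions$seq_id == id, ]
    busy <- IRanges::IRanges(cr$start + 1, cr$end)
    clean <- IRanges::setdiff(IRanges::IRanges(1, len), busy)
    for (j in seq_along(clean)) {
      a <- IRanges::start(clean)[j] - 1
      b <- IRanges::end(clean)[j]
      n_genes <- (b - a) %/% gene_len
      if (n_genes < 1) next
      st <- a + (seq_len(n_genes) - 1) * gene_len
      rows[[length(rows) + 1]] <- tibble(
        seq_id = id, start = st, end = st + gene_len)
    }
  }
  out <- bind_rows(rows)
  out$busco_id <- sprintf("simbusco%04d", seq_len(nrow(out)))
  out$status <- "Complete"
  out$on_excluded_seq <- FALSE
  select(out, "busco_id", "status", "seq_id", "start", "end",
         "on_excluded_seq")
}

#' Simulate Poisson per-base depth with planted CN multipliers
#'
#' Depth at each base is an independent Poisson draw with rate
#' `lambda x CN(pos)`: 1 over plain sequence, the planted value over CN
#' regions, and 0.5 over haplotig scaffolds.
#'
#' @param sim Output of [simulate_genome()].
#' @param lambda Base depth rate (default from the config).
#' @param seed Seed (default `config$seed + 1`).
#' @return A list: `track` (a `depth_track`), `genome_mean`.
#' @export
simulate_depth <- function(sim, lambda = sim$config$base_depth,
                           seed = sim$config$seed + 1L) {
  set.seed(seed)
  depths <- list()
  hap_ids <- sim$truth$haplotigs$hap_id
  for (i in seq_len(nrow(sim$genome))) {
    id <- sim$genome$seq_id[i]
    n <- sim$genome$length[i]
    cn <- rep(if (id %in% hap_ids) 0.5 else 1, n)
    cr <- sim$truth$cn_regions[sim$truth$cn_regions$seq_id == id, ]
    for (j in seq_len(nrow(cr))) {
      cn[(cr$start[j] + 1):cr$end[j]] <- cr$cn[j]
    }
    depths[[id]] <- rpois(n, lambda * cn)
  }
  track <- depth_track(depths, sim$genome)
  list(track = track, genome_mean = genome_mean_depth(track))
}

#' Simulate uniformly placed read alignment intervals
#'
#' Fixed-length reads are placed uniformly on each scaffold (start uniform
#' on `[0, len - read_len]`), with per-scaffold counts set by the target
#' coverage, so spanning-read counts have a closed-form expectation (see
#' [expected_spanning()]).
#'
#' @param sim Output of [simulate_genome()].
#' @param read_len,coverage Read length and target coverage (defaults from
#'   the config).
#' @param seed Seed (default `config$seed + 2`).
#' @return Read alignment tibble: `read_id`, `read_len`, `seq_id`, `start`,
#'   `end`.
#' @export
simulate_reads <- function(sim, read_len = sim$config$read_len,
                           coverage = sim$config$read_coverage,
                           seed = sim$config$seed + 2L) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(sim$genome))) {
    id <- sim$genome$seq_id[i]
    n <- sim$genome$length[i]
    if (n < read_len) next
    n_reads <- round(coverage * n / read_len)
    starts <- sample.int(n - read_len + 1, n_reads, replace = TRUE) - 1L
    rows[[length(rows) + 1]] <- tibble(
      read_id = sprintf("%s_read%05d", id, seq_len(n_reads)),
      read_len = read_len, seq_id = id, start = starts,
      end = starts + read_len)
  }
  bind_rows(rows)
}

#' Closed-form expected spanning-read count
#'
#' For `n_reads` fixed-length reads placed uniformly on a scaffold, the
#' number spanning an interior feature of extended width `w` (feature +
#' both flanks) is Binomial(n, p) with
#' `p = max(0, read_len - w + 1) / (scaffold_len - read_len + 1)`.
#'
#' @param n_reads Reads on the scaffold.
#' @param scaffold_len,read_len Lengths in bp.
#' @param ext_width Feature width plus both flanks.
#' @return A list: `expected`, `sd`.
#' @export
expected_spanning <- function(n_reads, scaffold_len, read_len, ext_width) {
  p <- max(0, read_len - ext_width + 1) / (scaffold_len - read_len + 1)
  list(expected = n_reads * p, sd = sqrt(n_reads * p * (1 - p)))
}

#' Simulate two jittered platform SV call sets from one truth
#'
#' Plants non-overlapping SVs, then derives an ONT-like set A and an
#' SMRT-like set B: each platform drops each SV independently with
#' probability `fn_rate` and jitters retained breakpoints with independent
#' Gaussian noise of sd `jitter` (lengths jittered at `jitter / 4`).
#'
#' @param sim Output of [simulate_genome()].
#' @param jitter Breakpoint jitter sd in bp.
#' @param fn_rate Per-platform false-negative rate.
#' @param sv_n,sv_len_range Overrides of the config SV spec.
#' @param seed Seed (default `config$seed + 3`).
#' @return A list: `truth` (planted SVs with `in_a`, `in_b` flags), `a`,
#'   `b` (SV tibbles in the [read_sv_vcf()] schema).
#' @export
simulate_sv_sets <- function(sim, jitter = 20, fn_rate = 0,
                             sv_n = sim$config$sv_n,
                             sv_len_range = sim$config$sv_len_range,
                             seed = sim$config$seed + 3L) {
  stopifnot(jitter >= 0, fn_rate >= 0, fn_rate < 1)
  set.seed(seed)
  prim <- sim$genome$seq_id[!sim$genome$seq_id %in%
                              sim$truth$haplotigs$hap_id]
  n_tot <- sum(sv_n)
  types <- rep(names(sv_n), sv_n)
  lens <- sample_log_uniform(n_tot, sv_len_range)
  # non-overlapping placement: greedy accept over sorted random starts
  placed <- list()
  claimed <- setNames(vector("list", length(prim)), prim)
  for (i in seq_len(n_tot)) {
    for (try in 1:50) {
      sc <- sample(prim, 1)
      max0 <- sim$genome$length[sim$genome$seq_id == sc] - lens[i] - 1
      st <- sample.int(max0, 1)
      en <- st + lens[i]
      ok <- TRUE
      for (iv in claimed[[sc]]) {
        if (st < iv[2] + 500 && en > iv[1] - 500) { ok <- FALSE; break }
      }
      if (ok) {
        claimed[[sc]] <- c(claimed[[sc]], list(c(st, en)))
        placed[[i]] <- tibble(sv_id = sprintf("planted%04d", i),
                              sv_type = types[i], seq_id = sc,
                              start = st,
                              end = if (types[i] == "INS") st + 1 else en,
                              sv_len = lens[i])
        break
      }
    }
    if (length(placed) < i) abort("could not place SV; reduce sv_n")
  }
  truth <- bind_rows(placed)
  jig <- function(svs, platform, sample_id) {
    keep <- runif(nrow(truth)) >= fn_rate
    s <- truth[keep, , drop = FALSE]
    if (nrow(s) > 0) {
      dpos <- round(rnorm(nrow(s), 0, jitter))
      dlen <- round(rnorm(nrow(s), 0, jitter / 4))
      s$start <- pmax(0, s$start + dpos)
      s$sv_len <- pmax(30, s$sv_len + dlen)
      s$end <- ifelse(s$sv_type == "INS", s$start + 1, s$start + s$sv_len)
      s$sv_id <- sprintf("%s_%s", platform, s$sv_id)
    }
    s$sample_id <- rep(sample_id, nrow(s))
    s$platform <- rep(platform, nrow(s))
    list(svs = s, kept = keep)
  }
  a <- jig(truth, "ONT", "simdog")
  b <- jig(truth, "SMRT", "simdog")
  truth$in_a <- a$kept
  truth$in_b <- b$kept
  list(truth = truth, a = a$svs, b = b$svs)
}
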
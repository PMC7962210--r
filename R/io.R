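# Parsers and writers for the external formats the toolkit consumes.
# Internal convention: all coordinates are 0-based half-open; conversion from
# 1-based inclusive formats (blast6, BUSCO, VCF) happens here and only here.

IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Read a genome assembly or mtDNA FASTA
#'
#' Sequences are uppercased on ingestion and IUPAC ambiguity codes (R, Y, S,
#' W, K, M, B, D, H, V) are mapped to N; the number of converted bases is
#' reported per sequence in the `n_ambiguous` column and as a message.
#'
#' @param path Path to a FASTA file.
#' @param circular Character vector of sequence ids to flag as circular
#'   (e.g. the mitochondrial genome).
#' @return A tibble with one row per sequence: `seq_id`, `length`,
#'   `circular`, `n_ambiguous` and the full `residues` string.
#' @export
read_fasta <- function(path, circular = character()) {
  stopifnot(file.exists(path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) {
    abort(paste0("empty FASTA file: ", path))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate sequence id in ", path, ": ",
                 ids[duplicated(ids)][1]))
  }
  res <- unname(toupper(as.character(set)))
  n_ambig <- vapply(res, function(s) {
    sum(stringr::str_count(s, stringr::fixed(IUPAC_AMBIG)))
  }, integer(1), USE.NAMES = FALSE)
  if (sum(n_ambig) > 0) {
    res <- vapply(res, function(s) gsub("[RYSWKMBDHV]", "N", s), character(1),
                  USE.NAMES = FALSE)
    inform(sprintf("read_fasta: converted %d IUPAC ambiguity bases to N",
                   sum(n_ambig)))
  }
  tibble(
    seq_id = ids,
    length = nchar(res),
    circular = ids %in% circular,
    n_ambiguous = as.integer(n_ambig),
    residues = unname(res)
  )
}

#' Write sequences to FASTA
#'
#' @param genome Genome tibble from [read_fasta()] or [simulate_genome()].
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(setNames(genome$residues, genome$seq_id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

blast6_cols <- c("query_id", "s_id", "identity_pct", "aln_len", "mismatch",
                 "gapopen", "q_start", "q_end", "s_start", "s_end",
                 "evalue", "bitscore")

#' Read local homology hits (BLAST outfmt 6 or PAF)
#'
#' blast6 input must carry the 12 standard columns (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore); its
#' 1-based inclusive coordinates are converted to 0-based half-open, and hits
#' with `sstart > send` are stored on strand `-` with coordinates swapped.
#' PAF coordinates are used as-is (already 0-based half-open) and the strand
#' column is respected; PAF hits get `bitscore = alignment block length` and
#' `evalue = 0` since PAF carries neither.
#'
#' @param path Path to the hit table.
#' @param dialect `"blast6"` or `"paf"`.
#' @return A tibble of hits: `query_id`, `q_start`, `q_end`, `q_len` (PAF
#'   only, else NA), `s_id`, `s_start`, `s_end`, `strand`, `identity_pct`,
#'   `aln_len`, `evalue`, `bitscore`.
#' @export
read_hits <- function(path, dialect = c("blast6", "paf")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_hits())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  need <- if (dialect == "blast6") 12L else 12L
  bad <- which(ncols < need)
  if (length(bad) > 0) {
    abort(sprintf("%s line %d: expected >= %d columns, found %d",
                  dialect, bad[1], need, ncols[bad[1]]))
  }
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      abort(sprintf("%s: unparsable numeric in column '%s' (line %d)",
                    dialect, what, which(is.na(v))[1]))
    }
    v
  }
  col <- function(i) vapply(parts, `[[`, character(1), i)
  if (dialect == "blast6") {
    qs <- num(col(7), "qstart"); qe <- num(col(8), "qend")
    ss <- num(col(9), "sstart"); se <- num(col(10), "send")
    rev <- ss > se
    tib <- tibble(
      query_id = col(1),
      q_start = qs - 1, q_end = qe, q_len = NA_real_,
      s_id = col(2),
      s_start = ifelse(rev, se, ss) - 1,
      s_end = ifelse(rev, ss, se),
      strand = ifelse(rev, "-", "+"),
      identity_pct = num(col(3), "pident"),
      aln_len = num(col(4), "length"),
      evalue = num(col(11), "evalue"),
      bitscore = num(col(12), "bitscore")
    )
  } else {
    alnlen <- num(col(11), "alnlen")
    nmatch <- num(col(10), "nmatch")
    tib <- tibble(
      query_id = col(1),
      q_start = num(col(3), "qstart"), q_end = num(col(4), "qend"),
      q_len = num(col(2), "qlen"),
      s_id = col(6),
      s_start = num(col(8), "tstart"), s_end = num(col(9), "tend"),
      strand = col(5),
      identity_pct = 100 * nmatch / pmax(alnlen, 1),
      aln_len = alnlen,
      evalue = 0,
      bitscore = alnlen
    )
  }
  validate_hits(tib)
  tib
}

empty_hits <- function() {
  tibble(query_id = character(), q_start = numeric(), q_end = numeric(),
         q_len = numeric(), s_id = character(), s_start = numeric(),
         s_end = numeric(), strand = character(), identity_pct = numeric(),
         aln_len = numeric(), evalue = numeric(), bitscore = numeric())
}

validate_hits <- function(hits) {
  stopifnot(all(hits$q_end > hits$q_start), all(hits$s_end > hits$s_start),
            all(hits$evalue >= 0),
            all(hits$identity_pct >= 0 & hits$identity_pct <= 100))
  invisible(hits)
}

#' Write hits back to 12-column blast6
#'
#' Inverse of [read_hits()] for the blast6 dialect: internal 0-based
#' half-open coordinates are converted back to 1-based inclusive and `-`
#' strand hits re-emitted with subject coordinates swapped.
#'
#' @param hits Hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_blast6 <- function(hits, path) {
  neg <- hits$strand == "-"
  lines <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f",
                   hits$query_id, hits$s_id, hits$identity_pct,
                   as.integer(hits$aln_len), 0L, 0L,
                   as.integer(hits$q_start + 1), as.integer(hits$q_end),
                   as.integer(ifelse(neg, hits$s_end, hits$s_start + 1)),
                   as.integer(ifelse(neg, hits$s_start + 1, hits$s_end)),
                   hits$evalue, hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

# ---- depth tracks -----------------------------------------------------------

new_depth_track <- function(depth, gap, seq_lengths) {
  structure(list(depth = depth, gap = gap, seq_lengths = seq_lengths),
            class = "depth_track")
}

#' Build a depth track from per-scaffold depth vectors
#'
#' @param depths Named list of non-negative integer vectors, one per
#'   scaffold, `depths[[id]][i]` = read depth at 0-based position `i - 1`.
#' @param genome Genome tibble; gap positions (residue N) are masked.
#' @return A `depth_track` object.
#' @export
depth_track <- function(depths, genome) {
  stopifnot(all(names(depths) %in% genome$seq_id))
  lens <- setNames(genome$length, genome$seq_id)
  gap <- list()
  for (id in genome$seq_id) {
    if (is.null(depths[[id]])) depths[[id]] <- integer(lens[[id]])
    if (length(depths[[id]]) != lens[[id]]) {
      abort(sprintf("depth vector for %s has length %d, sequence is %d bp",
                    id, length(depths[[id]]), lens[[id]]))
    }
    if (any(depths[[id]] < 0)) abort("negative depth")
    res <- genome$residues[genome$seq_id == id]
    gap[[id]] <- as.integer(charToRaw(res)) == 78L  # 'N'
  }
  new_depth_track(depths[genome$seq_id], gap, lens)
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("<depth_track> %d sequences, %.0f bases, mean depth %.2f\n",
              length(x$depth), sum(x$seq_lengths),
              mean(unlist(x$depth, use.names = FALSE))))
  invisible(x)
}

#' Read a per-base depth file into a depth track
#'
#' Accepts either a 3-column per-base TSV (`seq pos depth`, 1-based
#' positions) or a 4-column bedGraph (`seq start end depth`, 0-based
#' half-open runs). Positions absent from the file get depth 0; the gap mask
#' is derived from N residues in `genome`.
#'
#' @param path Depth file.
#' @param genome Genome tibble covering every sequence in the file.
#' @return A `depth_track`.
#' @export
read_depth <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  lens <- setNames(genome$length, genome$seq_id)
  depths <- lapply(lens, integer)
  if (length(lines) > 0) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nc <- unique(lengths(parts))
    if (length(nc) != 1 || !nc %in% c(3L, 4L)) {
      abort("depth file must be uniformly 3-column TSV or 4-column bedGraph")
    }
    seqs <- vapply(parts, `[[`, character(1), 1)
    unknown <- setdiff(unique(seqs), names(lens))
    if (length(unknown) > 0) {
      abort(paste0("depth file references unknown sequence: ", unknown[1]))
    }
    if (nc == 3L) {
      pos <- as.integer(vapply(parts, `[[`, character(1), 2))
      dep <- as.integer(vapply(parts, `[[`, character(1), 3))
      if (any(is.na(pos)) || any(is.na(dep))) abort("unparsable depth line")
      if (any(dep < 0)) abort("negative depth")
      for (id in unique(seqs)) {
        sel <- seqs == id
        if (any(pos[sel] < 1 | pos[sel] > lens[[id]])) {
          abort(sprintf("position beyond length of %s", id))
        }
        depths[[id]][pos[sel]] <- dep[sel]
      }
    } else {
      s0 <- as.integer(vapply(parts, `[[`, character(1), 2))
      e0 <- as.integer(vapply(parts, `[[`, character(1), 3))
      dep <- as.integer(vapply(parts, `[[`, character(1), 4))
      if (any(is.na(s0)) || any(is.na(e0)) || any(is.na(dep))) {
        abort("unparsable bedGraph line")
      }
      if (any(dep < 0)) abort("negative depth")
      for (id in unique(seqs)) {
        sel <- which(seqs == id)
        if (any(e0[sel] > lens[[id]]) || any(s0[sel] < 0)) {
          abort(sprintf("position beyond length of %s", id))
        }
        covered <- logical(lens[[id]])
        for (i in sel) {
          idx <- (s0[i] + 1):e0[i]
          if (any(covered[idx])) abort("overlapping bedGraph runs")
          covered[idx] <- TRUE
          depths[[id]][idx] <- dep[i]
        }
      }
    }
  }
  depth_track(depths, genome)
}

#' Write a depth track as run-length-encoded bedGraph
#'
#' @param track A `depth_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(track$depth)) {
    r <- rle(track$depth[[id]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%d\t%d\t%d", id, starts[keep], ends[keep],
                         r$values[keep]), con)
    }
  }
  invisible(path)
}

#' Mean depth of a region, excluding assembly gaps
#'
#' @param track A `depth_track`.
#' @param seq_id,start,end Region, 0-based half-open.
#' @param exclude_gaps Drop gap-masked (N) bases from the mean.
#' @return Mean depth (double).
#' @export
region_mean_depth <- function(track, seq_id, start, end, exclude_gaps = TRUE) {
  stopifnot(seq_id %in% names(track$depth))
  stopifnot(start >= 0, end <= track$seq_lengths[[seq_id]], end > start)
  idx <- (start + 1):end
  d <- track$depth[[seq_id]][idx]
  if (exclude_gaps) {
    ok <- !track$gap[[seq_id]][idx]
    if (!any(ok)) abort("region is entirely assembly gap")
    d <- d[ok]
  }
  mean(d)
}

#' Genome-wide mean depth over non-gap bases
#'
#' @param track A `depth_track`.
#' @return Mean depth (double).
#' @export
genome_mean_depth <- function(track) {
  tot <- 0; nb <- 0
  for (id in names(track$depth)) {
    ok <- !track$gap[[id]]
    tot <- tot + sum(as.numeric(track$depth[[id]][ok]))
    nb <- nb + sum(ok)
  }
  tot / nb
}

#' Write read alignment intervals as minimal PAF
#'
#' Emits 12-column PAF lines for interval-only read alignments (exact
#' matches over the full alignment span), the inverse of reading such a
#' file with `read_hits(..., "paf")`.
#'
#' @param reads Tibble with `read_id`, `read_len`, `seq_id`, `start`,
#'   `end`.
#' @param seq_lengths Named vector of target sequence lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_paf <- function(reads, seq_lengths, path) {
  w <- reads$end - reads$start
  writeLines(sprintf("%s\t%d\t%d\t%d\t+\t%s\t%d\t%d\t%d\t%d\t%d\t60",
                     reads$read_id, as.integer(reads$read_len), 0L,
                     as.integer(w), reads$seq_id,
                     as.integer(seq_lengths[reads$seq_id]),
                     as.integer(reads$start), as.integer(reads$end),
                     as.integer(w), as.integer(w)), path)
  invisible(path)
}

# ---- BUSCO ------------------------------------------------------------------

#' Read a BUSCO v3 full table
#'
#' Parses the ragged tab-separated `full_table_*.tsv` ('#' comment lines;
#' columns id, status, sequence, start, end, ...). Coordinates are converted
#' from 1-based inclusive to 0-based half-open. Rows without coordinates
#' (Missing) are retained with NA intervals.
#'
#' @param path BUSCO full table path.
#' @param exclude_seqs Sequence ids whose genes are flagged
#'   `on_excluded_seq` (e.g. `"chrX"` for male samples, where X depth is
#'   haploid and would bias a single-copy model).
#' @return Tibble: `busco_id`, `status`, `seq_id`, `start`, `end`,
#'   `on_excluded_seq`.
#' @export
read_busco_table <- function(path, exclude_seqs = character()) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(parts, function(p) {
    status <- p[[2]]
    if (status %in% c("Complete", "Duplicated", "Fragmented")) {
      if (length(p) < 5) {
        abort(sprintf("BUSCO row for %s (%s) lacks coordinate columns",
                      p[[1]], status))
      }
      st <- suppressWarnings(as.numeric(p[[4]]))
      en <- suppressWarnings(as.numeric(p[[5]]))
      if (is.na(st) || is.na(en)) {
        abort(sprintf("BUSCO row for %s: unparsable coordinates", p[[1]]))
      }
      tibble(busco_id = p[[1]], status = status, seq_id = p[[3]],
             start = min(st, en) - 1, end = max(st, en))
    } else {
      tibble(busco_id = p[[1]], status = status, seq_id = NA_character_,
             start = NA_real_, end = NA_real_)
    }
  })
  out <- bind_rows(rows)
  out$on_excluded_seq <- !is.na(out$seq_id) & out$seq_id %in% exclude_seqs
  out
}

# ---- structural-variant VCF -------------------------------------------------

#' Read structural variants from a VCF
#'
#' Consumes the long-read caller dialect (SVTYPE/SVLEN/END INFO keys, as
#' written by sniffles and compatible callers). SVLEN magnitude is used; a
#' DEL/INV/DUP record missing END gets `END = POS + |SVLEN|`. Insertions are
#' stored as 1 bp breakpoints. Records with neither END nor SVLEN are
#' skipped with a warning giving the count. BND records are retained with
#' `sv_len = NA` and are dropped by [filter_sv_length()].
#'
#' @param path VCF path (plain text).
#' @param sample_id Label recorded in the `sample_id` column.
#' @param platform Sequencing platform label (`"ONT"`, `"SMRT"`, ...).
#' @return Tibble: `sv_id`, `sv_type`, `seq_id`, `start`, `end`, `sv_len`,
#'   `sample_id`, `platform` (0-based half-open intervals).
#' @export
read_sv_vcf <- function(path, sample_id = "sample", platform = "other") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- v@fix  # character matrix CHROM..INFO; stable for 0/1-row files
  fx <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fx) == 0) return(empty_svs())
  info <- fx$INFO
  grab <- function(key) {
    m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    m
  }
  svtype <- grab("SVTYPE")
  svlen <- suppressWarnings(as.numeric(grab("SVLEN")))
  endv <- suppressWarnings(as.numeric(grab("END")))
  pos <- as.numeric(fx$POS)
  n_skip <- 0L
  recs <- vector("list", nrow(fx))
  for (i in seq_len(nrow(fx))) {
    ty <- svtype[i]
    if (is.na(ty)) { n_skip <- n_skip + 1L; next }
    if (ty == "BND") {
      recs[[i]] <- tibble(sv_type = "BND", seq_id = fx$CHROM[i],
                          start = pos[i] - 1, end = pos[i],
                          sv_len = NA_real_)
      next
    }
    len <- abs(svlen[i])
    if (ty == "INS") {
      if (is.na(len)) { n_skip <- n_skip + 1L; next }
      recs[[i]] <- tibble(sv_type = "INS", seq_id = fx$CHROM[i],
                          start = pos[i] - 1, end = pos[i], sv_len = len)
    } else {
      en <- if (!is.na(endv[i])) endv[i] else if (!is.na(len)) pos[i] - 1 + len else NA_real_
      if (is.na(en)) { n_skip <- n_skip + 1L; next }
      if (is.na(len)) len <- en - (pos[i] - 1)
      recs[[i]] <- tibble(sv_type = ty, seq_id = fx$CHROM[i],
                          start = pos[i] - 1, end = en, sv_len = len)
    }
  }
  if (n_skip > 0) {
    warn(sprintf("read_sv_vcf: skipped %d records lacking both END and SVLEN",
                 n_skip))
  }
  out <- bind_rows(recs)
  if (nrow(out) == 0) return(empty_svs())
  out$sv_id <- sprintf("%s_%s_%05d", sample_id, platform, seq_len(nrow(out)))
  out$sample_id <- sample_id
  out$platform <- platform
  select(out, "sv_id", "sv_type", "seq_id", "start", "end", "sv_len",
         "sample_id", "platform")
}

empty_svs <- function() {
  tibble(sv_id = character(), sv_type = character(), seq_id = character(),
         start = numeric(), end = numeric(), sv_len = numeric(),
         sample_id = character(), platform = character())
}

#' Write structural variants to a minimal VCF 4.2
#'
#' @param svs SV tibble (as returned by [read_sv_vcf()]).
#' @param path Output path.
#' @param seq_lengths Optional named vector for contig header lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(svs, path, seq_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">")
  if (!is.null(seq_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(seq_lengths),
                          as.integer(seq_lengths)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(nrow(svs))
  for (i in seq_len(nrow(svs))) {
    ty <- svs$sv_type[i]
    info <- if (ty == "BND") {
      "SVTYPE=BND"
    } else if (ty == "INS") {
      sprintf("SVTYPE=INS;SVLEN=%d", as.integer(svs$sv_len[i]))
    } else {
      sprintf("SVTYPE=%s;SVLEN=%d;END=%d", ty,
              as.integer(if (ty == "DEL") -svs$sv_len[i] else svs$sv_len[i]),
              as.integer(svs$end[i]))
    }
    body[i] <- sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\t%s",
                       svs$seq_id[i], as.integer(svs$start[i] + 1),
                       svs$sv_id[i], ty, info)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- gene models ------------------------------------------------------------

#' Read gene models from GFF3 or BED6
#'
#' GFF3: `gene` features define spans; `exon` features are attached to their
#' gene via the Parent/ID attribute chain (exons parented by an mRNA are
#' resolved through it). BED6 rows each become a single-exon gene.
#'
#' @param path Annotation file.
#' @param format `"gff3"` or `"bed"`; guessed from the extension by default.
#' @return Tibble: `gene_id`, `seq_id`, `start`, `end`, `strand` with an
#'   `exons` list-column of `start`/`end` tibbles (0-based half-open).
#' @export
read_gene_models <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    return(bind_rows(lapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      st <- as.numeric(p[[2]]); en <- as.numeric(p[[3]])
      tibble(gene_id = if (length(p) >= 4) p[[4]] else paste0("gene", i),
             seq_id = p[[1]], start = st, end = en,
             strand = if (length(p) >= 6) p[[6]] else ".",
             exons = list(tibble(start = st, end = en)))
    })))
  }
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  ids <- as.character(gff$ID)
  parents <- vapply(as.list(gff$Parent), function(p) {
    if (length(p) == 0) NA_character_ else p[[1]]
  }, character(1))
  # resolve exon -> (mRNA ->) gene
  parent_of <- setNames(parents, ids)
  gene_ids <- ids[type == "gene"]
  resolve <- function(id) {
    seen <- character()
    while (!is.na(id) && !(id %in% gene_ids) && !(id %in% seen)) {
      seen <- c(seen, id)
      id <- parent_of[[id]] %||% NA_character_
    }
    id
  }
  gi <- which(type == "gene")
  genes <- tibble(
    gene_id = ids[gi],
    seq_id = as.character(GenomicRanges::seqnames(gff))[gi],
    start = GenomicRanges::start(gff)[gi] - 1,
    end = as.numeric(GenomicRanges::end(gff)[gi]),
    strand = as.character(GenomicRanges::strand(gff))[gi]
  )
  ei <- which(type == "exon")
  exon_gene <- vapply(parents[ei], resolve, character(1))
  exon_tbl <- tibble(
    gene_id = exon_gene,
    start = GenomicRanges::start(gff)[ei] - 1,
    end = as.numeric(GenomicRanges::end(gff)[ei])
  )
  genes$exons <- lapply(genes$gene_id, function(g) {
    e <- exon_tbl[exon_tbl$gene_id == g, c("start", "end")]
    if (nrow(e) == 0) {
      gr <- genes[genes$gene_id == g, ]
      e <- tibble(start = gr$start, end = gr$end)
    }
    arrange(e, .data$start)
  })
  genes
}

# ---- generic tab writers ----------------------------------------------------

#' Write a tibble as TSV with a single '#'-prefixed header line
#'
#' @param tbl Tibble (list-columns are not supported; flatten first).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_hash <- function(tbl, path) {
  stopifnot(!any(vapply(tbl, is.list, logical(1))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(tbl), collapse = "\t")), con)
  if (nrow(tbl) > 0) {
    body <- do.call(paste, c(lapply(tbl, function(x) {
      if (is.numeric(x)) format(x, trim = TRUE, scientific = FALSE, digits = 15)
      else as.character(x)
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a '#'-headed TSV written by [write_tsv_hash()]
#'
#' @param path Input path.
#' @return A tibble with types guessed by readr.
#' @export
read_tsv_hash <- function(path) {
  first <- readLines(path, n = 1)
  nms <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
  readr::read_tsv(path, comment = "", skip = 1, col_names = nms,
                  show_col_types = FALSE, progress = FALSE)
}

#' Write intervals as BED6
#'
#' @param tbl Tibble with `seq_id`, `start`, `end` and optionally `name`,
#'   `score`, `strand` columns (0-based half-open, BED-native).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(tbl, path) {
  nm <- if ("name" %in% names(tbl)) tbl$name else
    sprintf("feature%d", seq_len(nrow(tbl)))
  sc <- if ("score" %in% names(tbl)) tbl$score else rep(0, nrow(tbl))
  st <- if ("strand" %in% names(tbl)) tbl$strand else rep(".", nrow(tbl))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", tbl$seq_id,
                     as.integer(tbl$start), as.integer(tbl$end), nm,
                     format(sc, trim = TRUE), st), path)
  invisible(path)
}
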
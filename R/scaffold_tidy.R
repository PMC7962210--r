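# Assembly tidying: classify scaffolds from depth-bin fractions and
# self-mapping, in the PurgeHaplotigs/Diploidocus style, iterating removal
# rounds to a fixpoint.

#' Depth-bin thresholds from the single-copy depth
#'
#' Bins: low `[0, low)`, haploid `[low, mid)`, diploid `[mid, high)`, high
#' `[high, Inf)`. Default multipliers 0.23/0.71/1.94 of `X_SC` reproduce
#' the 8x/25x/68x cutoffs used for a 35x single-copy genome; explicit
#' cutoffs override them.
#'
#' @param X_SC Single-copy depth (reads).
#' @param low,mid,high Optional explicit cutoffs.
#' @return A `depth_thresholds` list: `low`, `mid`, `high`.
#' @export
default_thresholds <- function(X_SC, low = NULL, mid = NULL, high = NULL) {
  stopifnot(X_SC > 0)
  th <- list(low = low %||% round(0.23 * X_SC),
             mid = mid %||% round(0.71 * X_SC),
             high = high %||% round(1.94 * X_SC))
  if (!(th$low > 0 && th$low < th$mid && th$mid < th$high)) {
    abort("thresholds must satisfy 0 < low < mid < high")
  }
  structure(th, class = "depth_thresholds")
}

#' Depth-bin profile of every scaffold
#'
#' Fractions of non-gap bases falling in each depth bin, plus the median
#' non-gap depth. Self-mapping fractions are joined from `selfmap` (the
#' fraction of the scaffold's length aligned onto another scaffold; 0 when
#' absent).
#'
#' @param depth A `depth_track`.
#' @param thresholds A `depth_thresholds`.
#' @param selfmap Optional tibble `seq_id`, `selfmap_frac`.
#' @param seq_ids Scaffolds to profile (default: all in the track).
#' @return Tibble: `seq_id`, `n_bases` (non-gap), `frac_low`,
#'   `frac_haploid`, `frac_diploid`, `frac_high`, `median_cov`,
#'   `selfmap_frac`.
#' @export
profile_scaffolds <- function(depth, thresholds, selfmap = NULL,
                              seq_ids = names(depth$depth)) {
  rows <- lapply(seq_ids, function(id) {
    d <- depth$depth[[id]][!depth$gap[[id]]]
    if (length(d) == 0) abort(paste0("scaffold ", id, " is all gap"))
    tibble(
      seq_id = id, n_bases = length(d),
      frac_low = mean(d < thresholds$low),
      frac_haploid = mean(d >= thresholds$low & d < thresholds$mid),
      frac_diploid = mean(d >= thresholds$mid & d < thresholds$high),
      frac_high = mean(d >= thresholds$high),
      median_cov = median(d)
    )
  })
  out <- bind_rows(rows)
  if (is.null(selfmap)) {
    out$selfmap_frac <- 0
  } else {
    out <- left_join(out, selfmap[, c("seq_id", "selfmap_frac")],
                     by = "seq_id")
    out$selfmap_frac[is.na(out$selfmap_frac)] <- 0
  }
  out
}

#' Self-mapping fraction from PAF self-alignments
#'
#' For each query scaffold, the union of its intervals aligned onto *other*
#' scaffolds divided by its length.
#'
#' @param paf_hits Hit tibble from `read_hits(..., "paf")` of an
#'   assembly-vs-itself mapping.
#' @param seq_lengths Named vector of scaffold lengths.
#' @param targets Optional allow-list of target scaffolds (used during
#'   iterative tidying to ignore alignments onto already-removed scaffolds).
#' @return Tibble: `seq_id`, `selfmap_frac`.
#' @export
selfmap_from_paf <- function(paf_hits, seq_lengths, targets = NULL) {
  h <- paf_hits[paf_hits$query_id != paf_hits$s_id, , drop = FALSE]
  if (!is.null(targets)) h <- h[h$s_id %in% targets, , drop = FALSE]
  rows <- lapply(names(seq_lengths), function(id) {
    hh <- h[h$query_id == id, , drop = FALSE]
    frac <- if (nrow(hh) == 0) 0 else {
      cov <- IRanges::reduce(IRanges::IRanges(hh$q_start + 1, hh$q_end))
      sum(IRanges::width(cov)) / seq_lengths[[id]]
    }
    tibble(seq_id = id, selfmap_frac = frac)
  })
  bind_rows(rows)
}

#' Classify scaffolds from their depth/self-mapping profiles
#'
#' Rules, in fixed precedence order:
#' 1. `LOWCOV_FILTER`: median non-gap coverage below `min_median` (default
#'    3; i.e. less than half the scaffold covered by 3+ reads).
#' 2. `HAPLOTIG`: >= 80% of bases in the low+haploid bins and >= 95% of
#'    length mapped onto another scaffold.
#' 3. `LOWCOV_ARTEFACT`: >= 80% of bases in the low bin.
#' 4. `COLLAPSED_REPEAT`: < 20% diploid bases and >= 50% high bases.
#' 5. `REPEAT`: diploid is strictly the largest bin and > 50% self-mapped.
#' 6. `KEEP` otherwise.
#'
#' @param profiles Tibble from [profile_scaffolds()].
#' @param min_median Median-coverage floor for rule 1.
#' @return `profiles` with `rating` and `rule_id` columns.
#' @export
classify_scaffolds <- function(profiles, min_median = 3) {
  p <- profiles
  dip_dominant <- p$frac_diploid > p$frac_low &
    p$frac_diploid > p$frac_haploid & p$frac_diploid > p$frac_high
  rating <- dplyr::case_when(
    p$median_cov < min_median ~ "LOWCOV_FILTER",
    p$frac_low + p$frac_haploid >= 0.80 & p$selfmap_frac >= 0.95 ~ "HAPLOTIG",
    p$frac_low >= 0.80 ~ "LOWCOV_ARTEFACT",
    p$frac_diploid < 0.20 & p$frac_high >= 0.50 ~ "COLLAPSED_REPEAT",
    dip_dominant & p$selfmap_frac > 0.50 ~ "REPEAT",
    TRUE ~ "KEEP"
  )
  rule <- dplyr::recode(rating, LOWCOV_FILTER = "R1_median_cov",
                        HAPLOTIG = "R2_haplotig",
                        LOWCOV_ARTEFACT = "R3_lowcov",
                        COLLAPSED_REPEAT = "R4_collapsed",
                        REPEAT = "R5_repeat", KEEP = "R6_keep")
  mutate(p, rating = rating, rule_id = rule)
}

#' Iterative scaffold tidying to a fixpoint
#'
#' Each round profiles and classifies the surviving scaffolds, removes
#' those rated `LOWCOV_FILTER`, `HAPLOTIG` or `LOWCOV_ARTEFACT`, and
#' recomputes self-mapping against the survivors (a haplotig whose primary
#' partner was itself removed can lose its self-map support, so iteration
#' matters). `COLLAPSED_REPEAT` and `REPEAT` are annotations on retained
#' scaffolds, not removals. Stops when a round removes nothing or after
#' `max_rounds`.
#'
#' @param depth A `depth_track`.
#' @param thresholds A `depth_thresholds`.
#' @param selfmap_paf Optional PAF hit tibble of assembly self-alignments;
#'   alternatively pass a static `selfmap` tibble.
#' @param selfmap Optional static tibble `seq_id`, `selfmap_frac` (used
#'   when `selfmap_paf` is NULL; not recomputed between rounds).
#' @param max_rounds Maximum removal rounds (default 10).
#' @param min_median Median-coverage floor.
#' @return Tibble: one row per scaffold with its final profile, `rating`,
#'   `rule_id`, `round` (round of removal, or the final round for
#'   survivors) and `kept` flag.
#' @export
tidy_scaffolds <- function(depth, thresholds, selfmap_paf = NULL,
                           selfmap = NULL, max_rounds = 10, min_median = 3) {
  removal <- c("LOWCOV_FILTER", "HAPLOTIG", "LOWCOV_ARTEFACT")
  alive <- names(depth$depth)
  seq_lengths <- depth$seq_lengths
  done <- list()
  round <- 0L
  repeat {
    round <- round + 1L
    sm <- if (!is.null(selfmap_paf)) {
      selfmap_from_paf(selfmap_paf, seq_lengths[alive], targets = alive)
    } else selfmap
    prof <- profile_scaffolds(depth, thresholds, selfmap = sm,
                              seq_ids = alive)
    cls <- classify_scaffolds(prof, min_median = min_median)
    drop <- cls$seq_id[cls$rating %in% removal]
    if (length(drop) == 0 || round >= max_rounds) {
      done[[round]] <- mutate(cls, round = round,
                              kept = !.data$rating %in% removal)
      break
    }
    done[[round]] <- cls |>
      filter(.data$rating %in% removal) |>
      mutate(round = round, kept = FALSE)
    alive <- setdiff(alive, drop)
    if (length(alive) == 0) break
  }
  bind_rows(done) |> arrange(.data$seq_id)
}
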
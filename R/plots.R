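# ggplot2 views of the main result types.

#' @describeIn mtdna_coverage Per-base coverage of the mitochondrial unit
#'   by NUMT fragments.
#' @param object An `mt_coverage`.
#' @param ... Unused.
#' @export
autoplot.mt_coverage <- function(object, ...) {
  df <- tibble(pos = seq_along(object$coverage) - 1,
               coverage = object$coverage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$coverage)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "mtDNA position (bp)", y = "NUMT fragment coverage",
                  title = sprintf("%.1f mtDNA-copy equivalents",
                                  object$copies_equivalent)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_single_copy_model Histogram of per-gene copy numbers
#'   around the single-copy baseline.
#' @param object A `single_copy_model`.
#' @export
autoplot.single_copy_model <- function(object, ...) {
  ggplot2::ggplot(object$per_gene, ggplot2::aes(x = .data$cn)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "red") +
    ggplot2::labs(x = "predicted copy number (BUSCO Complete genes)",
                  y = "genes",
                  title = sprintf("X_SC = %dx, mean CN %.3f",
                                  object$X_SC, object$mean_cn)) +
    ggplot2::theme_minimal()
}

#' Bar chart of scaffold tidying ratings
#'
#' @param ratings Tibble from [tidy_scaffolds()] or [classify_scaffolds()].
#' @return A ggplot.
#' @export
plot_scaffold_ratings <- function(ratings) {
  ggplot2::ggplot(ratings, ggplot2::aes(x = .data$rating)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "scaffolds") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Paired-bar view of a cross-sample SV overlap summary
#'
#' @param summary Tibble from [overlap_samples()].
#' @return A ggplot.
#' @export
plot_sv_overlap <- function(summary) {
  long <- summary |>
    select("sv_type", "only_a", "shared", "only_b") |>
    tidyr::pivot_longer(-"sv_type", names_to = "set", values_to = "n") |>
    mutate(set = factor(.data$set, levels = c("only_a", "shared", "only_b")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sv_type, y = .data$n,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "SV type", y = "calls", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Relative mapping profile across references
#'
#' @param rel Tibble from [relative_mapping()].
#' @return A ggplot.
#' @export
plot_relative_mapping <- function(rel) {
  ggplot2::ggplot(rel, ggplot2::aes(x = .data$reference,
                                    y = .data$rel_mapped)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "reads mapped, deviation from sample mean (%)") +
    ggplot2::theme_minimal()
}
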
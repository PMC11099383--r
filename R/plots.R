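# ggplot2 presentations of the main result types.

#' Tidy a co-DE score matrix into long form
#'
#' @param x A `code_matrix`.
#' @param ... Unused.
#' @return Long tibble: `receptor`, `partner`, `partner_kind`, `affected`,
#'   `subtype`, `score`.
#' @method tidy code_matrix
#' @export
tidy.code_matrix <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), cols = all_of(code_matrix_subtypes(x)),
                      names_to = "subtype", values_to = "score")
}

#' @method glance code_matrix
#' @export
glance.code_matrix <- function(x, ...) {
  scores <- code_matrix_scores(x)
  tibble(n_pairs = nrow(x), n_subtypes = ncol(scores),
         n_affected = sum(x$affected),
         n_strong = sum(abs(scores) == 2))
}

#' Heatmap of co-DE scores across subtypes
#'
#' @param object A `code_matrix`.
#' @param affected_only Show only recurrently affected pairs; default TRUE.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot code_matrix
#' @export
autoplot.code_matrix <- function(object, affected_only = TRUE, ...) {
  long <- tidy(object)
  if (affected_only) long <- long[long$affected, , drop = FALSE]
  long$pair <- paste(long$receptor, long$partner, sep = "–")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subtype, y = .data$pair,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-2, 2)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "co-DE score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @method tidy axis_screen
#' @export
tidy.axis_screen <- function(x, ...) as_tibble(x)

#' @method glance axis_screen
#' @export
glance.axis_screen <- function(x, ...) {
  tibble(n_axes = nrow(x),
         n_tested = sum(!is.na(x$logrank_p_axis)),
         n_pass = sum(x$passes_filter))
}

#' Hazard-ratio overview of an axis survival screen
#'
#' Scatter of the combined-stratification hazard ratio against the axis
#' log-rank p-value, with passing axes highlighted.
#'
#' @param object An `axis_screen` table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot axis_screen
#' @export
autoplot.axis_screen <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$hr_axis) & !is.na(df$logrank_p_axis), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$hr_axis),
                                   y = -log10(.data$logrank_p_axis),
                                   colour = .data$passes_filter)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#B2182B")) +
    ggplot2::labs(x = "log2 HR (both-high vs both-low)",
                  y = "-log10 log-rank p", colour = "passes filter") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for a stratification
#'
#' Step curves from the KM table returned by [km_logrank()].
#'
#' @param km KM tibble (`group`, `time`, `survival`, ...).
#' @return A ggplot.
#' @export
plot_km <- function(km) {
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability",
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' Drug-activity scatter (correlation vs bimodality)
#'
#' @param calls An [activity_calls()] table.
#' @param corr_threshold,bc_threshold Thresholds drawn as dashed lines.
#' @return A ggplot.
#' @export
plot_activity <- function(calls, corr_threshold = 0.2, bc_threshold = 0.35) {
  df <- calls[!is.na(calls$active), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$correlation,
                                   y = .data$bimodality,
                                   colour = .data$active)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = corr_threshold, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = bc_threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#B2182B")) +
    ggplot2::labs(x = "replicate correlation", y = "bimodality coefficient",
                  colour = "active") +
    ggplot2::theme_minimal()
}

#' Receptor similarity scatter (ligand-wise vs tissue-wise)
#'
#' @param profiles A [similarity_profiles()] table.
#' @return A ggplot.
#' @export
plot_similarity <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$tissue_wise, y = .data$ligand_wise,
                               size = .data$n_ligands,
                               colour = .data$updown_balance)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_gradient2(low = "#2166AC", mid = "grey85",
                                    high = "#B2182B") +
    ggplot2::labs(x = "tissue-wise similarity", y = "ligand-wise similarity",
                  size = "# ligands", colour = "co-up minus co-down") +
    ggplot2::theme_minimal()
}
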
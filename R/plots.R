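# ggplot2 visualisations for the main result types.

#' Heatmap of an energy matrix
#'
#' @param object A `scp_energy`.
#' @param ... Unused.
#' @return A ggplot: 20x20 heatmap in canonical amino-acid order, favorable
#'   (negative) energies in blue.
#' @exportS3Method ggplot2::autoplot
autoplot.scp_energy <- function(object, ...) {
  df <- tidy.scp_energy(object)
  df$aa_i <- factor(df$aa_i, levels = aa_alphabet())
  df$aa_j <- factor(df$aa_j, levels = rev(aa_alphabet()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aa_i, y = .data$aa_j,
                                   fill = .data$energy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "amino acid at position i", y = "amino acid at position j",
                  fill = "energy") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param roc A [roc_auc()] result.
#' @return A ggplot of the ROC curve with the chance diagonal.
#' @export
plot_roc <- function(roc) {
  stopifnot(!is.null(roc$curve))
  ggplot2::ggplot(roc$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", roc$auc)) +
    ggplot2::theme_minimal()
}

#' Plot the binned r_E-versus-RMSD profile
#'
#' @param profile A [rmsd_re_profile()] result.
#' @return A ggplot of per-bin mean and median r_E with standard-error bars.
#' @export
plot_re_profile <- function(profile) {
  df <- profile[profile$n_pairs > 0, , drop = FALSE]
  df$mid <- (df$rmsd_lo + df$rmsd_hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_re - .data$se_re,
                                        ymax = .data$mean_re + .data$se_re),
                           width = 0.03, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_re), shape = 16) +
    ggplot2::geom_point(ggplot2::aes(y = .data$median_re), shape = 15,
                        colour = "#2166ac") +
    ggplot2::labs(x = "pairwise backbone RMSD (Å)",
                  y = expression(r[E])) +
    ggplot2::theme_minimal()
}

#' Compare member-to-medoid distance distributions across clusterings
#'
#' @param ... Named `scp_clusters` objects (e.g. `structure = , energy = ,
#'   random = `).
#' @return A ggplot of overlaid distance histograms with mean markers.
#' @export
plot_cluster_distances <- function(...) {
  objs <- list(...)
  stopifnot(length(objs) >= 1L, !is.null(names(objs)))
  df <- purrr::imap_dfr(objs, function(x, nm) {
    tibble::tibble(clustering = nm,
                   distance = unlist(lapply(x$clusters, `[[`, "distances")))
  })
  means <- df |>
    dplyr::group_by(.data$clustering) |>
    dplyr::summarise(m = mean(.data$distance))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, fill = .data$clustering)) +
    ggplot2::geom_histogram(alpha = 0.5, position = "identity", bins = 40) +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$m,
                                     colour = .data$clustering),
                        linetype = "dotted") +
    ggplot2::labs(x = "distance to medoid", y = "members") +
    ggplot2::theme_minimal()
}
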
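# ggplot2 views of the main result types.

#' @exportS3Method
autoplot.caskas_profile <- function(object, chrom = NULL, start = NULL,
                                    end = NULL, ...) {
  df <- tidy(object, drop_zero = FALSE)
  if (!is.null(chrom)) df <- df[df$chrom == chrom, ]
  if (!is.null(start)) df <- df[df$pos >= start, ]
  if (!is.null(end)) df <- df[df$pos < end, ]
  df$value <- ifelse(df$strand == "-", -df$value, df$value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$value,
                                   fill = .data$strand)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = sprintf("%s (RPM, minus strand negated)", object$kind),
                  fill = "strand") +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.saturation_result <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$mean_within)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_within - .data$sd_within,
                                      ymax = .data$mean_within + .data$sd_within),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "subsampling fraction",
                  y = sprintf("fraction of sites within %.0f%% of full depth",
                              100 * object$tolerance)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.mismatch_matrix <- function(object, ...) {
  n <- nrow(object$matrix)
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$frequency,
                                   fill = .data$region)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "distance from PAM (bp)",
                  y = sprintf("mismatch frequency (%d sites)", n),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
tidy.mismatch_matrix <- function(x, ...) {
  L <- ncol(x$matrix)
  tibble::tibble(
    offset = seq_len(L),
    frequency = unname(x$frequency),
    region = ifelse(seq_len(L) <= floor(L / 2), "seed", "distal"))
}

#' @exportS3Method
glance.mismatch_matrix <- function(x, ...) {
  tibble::tibble(n_sites = nrow(x$matrix), spacer_length = ncol(x$matrix),
                 seed_rate = x$seed_rate, distal_rate = x$distal_rate)
}

#' @exportS3Method
autoplot.replicate_agreement <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$replicate_a, y = .data$replicate_b)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "replicate A (RPM)", y = "replicate B (RPM)",
      title = sprintf("Pearson %.3f / Spearman %.3f",
                      object$pearson, object$spearman)) +
    ggplot2::theme_minimal()
}

#' Plot read 5'-end phasing around a predicted cut site
#'
#' Shows per-base plus- and minus-strand 5'-end RPM in a window around the
#' blunt-cut coordinate; phased spikes on both strands indicate cleavage,
#' a broad asymmetric distribution indicates binding without cutting.
#'
#' @param fiveprime A 5'-end `caskas_profile`.
#' @param site One-row site tibble (with `chrom`, `cut_site`).
#' @param window Half-width of the plotted window.
#' @return A ggplot object.
#' @export
plot_cut_profile <- function(fiveprime, site, window = 100L) {
  autoplot(fiveprime, chrom = site$chrom[1],
           start = site$cut_site[1] - window,
           end = site$cut_site[1] + window + 1L) +
    ggplot2::geom_vline(xintercept = site$cut_site[1], linetype = "dotted")
}

#' @exportS3Method
autoplot.indel_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$frequency)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "position (bp)", y = "fraction of reads with indel") +
    ggplot2::theme_minimal()
}
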
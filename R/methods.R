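#' @export
print.prefsel_sim <- function(x, ...) {
  h <- x$history
  cat(sprintf("<prefsel_sim> %d generations (%s)\n", x$generations, x$status))
  cat(sprintf("  L = %d, env_sd = %.2f, overlap = %s, fecundity selection = %s\n",
              x$config$loci$L, x$config$loci$env_sd, x$config$overlap,
              x$config$fecundity_selection))
  cat(sprintf("  mean size: %.2f -> %.2f; size variance: %.2f -> %.2f\n",
              h$size_mean[1L], h$size_mean[nrow(h)],
              h$size_var[1L], h$size_var[nrow(h)]))
  invisible(x)
}

#' Tidy the per-generation history of a run
#'
#' @param x A `prefsel_sim`.
#' @param ... Unused.
#' @return The history tibble without histogram list-columns.
#' @method tidy prefsel_sim
#' @export
tidy.prefsel_sim <- function(x, ...) {
  dplyr::select(x$history, -dplyr::any_of(c("size_hist", "pref_hist",
                                            "size_edges", "pref_edges")))
}

#' One-row summary of a run
#'
#' @param x A `prefsel_sim`.
#' @param ... Unused.
#' @return A one-row tibble with the run status, generation count, initial
#'   and final size mean/variance, and the variance ratio.
#' @method glance prefsel_sim
#' @export
glance.prefsel_sim <- function(x, ...) {
  h <- x$history
  n <- nrow(h)
  tibble::tibble(
    status = x$status,
    generations = x$generations,
    size_mean_initial = h$size_mean[1L],
    size_mean_final = h$size_mean[n],
    size_var_initial = h$size_var[1L],
    size_var_final = h$size_var[n],
    variance_ratio = h$size_var[n] / h$size_var[1L],
    pref_mean_final = h$pref_mean[n]
  )
}

#' Plot a simulation run
#'
#' `type = "trajectory"` draws the per-generation mean (ribbon: +/- 1 SD) of
#' size and preference genotype; `type = "histogram"` draws the pooled size
#' distribution of the trailing generations kept by the run.
#'
#' @param object A `prefsel_sim`.
#' @param type `"trajectory"` or `"histogram"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prefsel_sim
#' @export
autoplot.prefsel_sim <- function(object, type = c("trajectory", "histogram"),
                                 ...) {
  type <- match.arg(type)
  h <- object$history
  if (type == "trajectory") {
    d <- dplyr::bind_rows(
      tibble::tibble(generation = h$generation, trait = "size",
                     mean = h$size_mean, sd = sqrt(h$size_var)),
      tibble::tibble(generation = h$generation, trait = "preference genotype",
                     mean = h$pref_mean, sd = sqrt(h$pref_var))
    )
    ggplot2::ggplot(d, ggplot2::aes(x = .data$generation, y = .data$mean)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           alpha = 0.25) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~trait, scales = "free_y") +
      ggplot2::labs(x = "generation", y = "mean phenotype (±1 SD)") +
      ggplot2::theme_minimal()
  } else {
    d <- tibble::tibble(size = unlist(object$final_sizes, use.names = FALSE))
    ggplot2::ggplot(d, ggplot2::aes(x = .data$size)) +
      ggplot2::geom_histogram(bins = 40, fill = "grey35") +
      ggplot2::labs(x = "realized size (trailing generations pooled)",
                    y = "count") +
      ggplot2::theme_minimal()
  }
}
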
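# broom-style accessors and ggplot2 autoplot methods for the result types.

#' @method tidy ranked_list
#' @export
tidy.ranked_list <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @method glance ranked_list
#' @export
glance.ranked_list <- function(x, ...) {
  x |>
    tidy() |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(n_features = dplyr::n(),
                     top_feature = .data$feature[.data$rank == 1],
                     .groups = "drop")
}

#' @method tidy stability_profile
#' @export
tidy.stability_profile <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @method glance stability_profile
#' @export
glance.stability_profile <- function(x, ...) stability_summary(x)

#' @method tidy accuracy_curve
#' @export
tidy.accuracy_curve <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @method glance accuracy_curve
#' @export
glance.accuracy_curve <- function(x, ...) {
  x |>
    tidy() |>
    dplyr::group_by(.data$method, .data$classifier) |>
    dplyr::summarise(optimum_d = kneedle(.data$d, .data$accuracy),
                     accuracy_at_optimum =
                       .data$accuracy[match(kneedle(.data$d, .data$accuracy),
                                            .data$d)],
                     max_accuracy = max(.data$accuracy), .groups = "drop")
}

#' @method tidy similarity_matrix
#' @export
tidy.similarity_matrix <- function(x, ...) {
  as_tibble(as.data.frame(unclass(x)), rownames = "method_a") |>
    tidyr::pivot_longer(-"method_a", names_to = "method_b",
                        values_to = "similarity")
}

#' @method glance sleep_benchmark
#' @export
glance.sleep_benchmark <- function(x, ...) {
  tibble(n_epochs = nrow(x$features),
         n_subjects = length(unique(x$features$subject)),
         n_methods = length(unique(x$rankings$method)),
         seed = x$manifest$seed)
}

#' @method tidy sleep_benchmark
#' @export
tidy.sleep_benchmark <- function(x, ...) tidy(x$accuracy)

#' Plot a ranked list
#'
#' Bar chart of the criterion scores of the leading features, one facet
#' per method.
#' @param object A `ranked_list`.
#' @param n_top Features to show (default 15).
#' @param ... Unused.
#' @method autoplot ranked_list
#' @export
autoplot.ranked_list <- function(object, n_top = 15, ...) {
  df <- tidy(object) |> dplyr::filter(.data$rank <= n_top)
  ggplot2::ggplot(df, ggplot2::aes(
      x = stats::reorder(.data$feature, -.data$rank),
      y = .data$score)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~method, scales = "free") +
    ggplot2::labs(x = NULL, y = "criterion score")
}

#' Plot stability profiles
#'
#' Stability (mean pairwise Tanimoto of bootstrap top-d sets) against
#' subset size, one line per method.
#' @param object A `stability_profile`.
#' @param ... Unused.
#' @method autoplot stability_profile
#' @export
autoplot.stability_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
      x = .data$d, y = .data$stability, colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "number of selected features (d)",
                  y = "stability (Tanimoto)")
}

#' Plot accuracy curves
#'
#' Mean validation accuracy against feature count, one line per method,
#' faceted by classifier.
#' @param object An `accuracy_curve`.
#' @param ... Unused.
#' @method autoplot accuracy_curve
#' @export
autoplot.accuracy_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
      x = .data$d, y = .data$accuracy, colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~classifier) +
    ggplot2::labs(x = "number of selected features (d)",
                  y = "mean accuracy")
}

#' Plot a similarity matrix
#'
#' Heat map of the pairwise top-d Tanimoto overlap between methods.
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @method autoplot similarity_matrix
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
      x = .data$method_a, y = .data$method_b, fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$similarity)), size = 3) +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "white",
                                 high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Tanimoto")
}

#' @method print sleep_benchmark
#' @export
print.sleep_benchmark <- function(x, ...) {
  cat("<sleep_benchmark>\n")
  cat(sprintf("  %d epochs, %d subjects, %d ranking methods\n",
              nrow(x$features), length(unique(x$features$subject)),
              length(unique(x$rankings$method))))
  cat(sprintf("  analysis table: %d balanced epochs\n", nrow(x$analysis)))
  cat("  optima:\n")
  print(x$optima, n = Inf)
  invisible(x)
}

#' @method print wake_ar_model
#' @export
print.wake_ar_model <- function(x, ...) {
  cat(sprintf("<wake_ar_model> order %d, fitted on %d epochs\n",
              x$order, length(x$selected)))
  cat("  coefficients:", sprintf("%.4f", x$coefficients), "\n")
  invisible(x)
}
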
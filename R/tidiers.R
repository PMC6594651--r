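# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted interaction model
#'
#' One row per parameter tensor: component, tensor name, dimensions and
#' parameter count.
#'
#' @param x A `dti_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method tidy dti_fit
tidy.dti_fit <- function(x, ...) {
  leaves <- list()
  walk <- function(tree, path) {
    if (is.list(tree)) {
      for (nm in names(tree)) walk(tree[[nm]], c(path, nm))
    } else {
      leaves[[length(leaves) + 1]] <<- tibble::tibble(
        component = path[1],
        tensor = paste(path, collapse = "."),
        dims = paste(dim(tree) %||% length(tree), collapse = "x"),
        n = length(tree))
    }
  }
  walk(x$model$params, character(0))
  dplyr::bind_rows(leaves)
}

#' One-row summary of a fitted interaction model
#'
#' @param x A `dti_fit`.
#' @param ... Unused.
#' @return Tibble with `epochs`, `best_epoch`, `val_aupr`, `val_auc`,
#'   `threshold`, `n_params`.
#' @export
#' @method glance dti_fit
glance.dti_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    val_aupr = if (nrow(x$history) > 0) x$history$val_aupr[x$best_epoch] else NA_real_,
    val_auc = if (nrow(x$history) > 0) x$history$val_auc[x$best_epoch] else NA_real_,
    threshold = x$threshold,
    n_params = n_parameters(x))
}

#' Tidy a grid-search result
#' @param x A `dti_grid`.
#' @param ... Unused.
#' @return The per-cell results tibble.
#' @export
#' @method tidy dti_grid
tidy.dti_grid <- function(x, ...) x$results

#' One-row summary of a grid search
#' @param x A `dti_grid`.
#' @param ... Unused.
#' @return Tibble with the best cell's index, AUPR, and parameter count.
#' @export
#' @method glance dti_grid
glance.dti_grid <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$results),
                 best_cell = x$best_index,
                 best_val_aupr = x$results$val_aupr[x$best_index],
                 best_n_params = x$results$n_params[x$best_index])
}

#' Training-history curves
#'
#' Training loss and validation AUPR/AUC per epoch, best epoch marked.
#'
#' @param object A `dti_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot dti_fit
autoplot.dti_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training history (dashed: best-AUPR epoch)")
}

#' Bar chart of significant-entry fractions by level
#'
#' @param summary Tibble from [summarize_significance()].
#' @return A ggplot object.
#' @export
plot_significance <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = factor(.data$level), y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "significance level", y = "fraction of entries",
                  title = "Binding-site detection by significance level")
}

#' Residue coverage profile from top-k pooled windows
#'
#' @param coverage Tibble from [top_k_coverage()].
#' @param residues Optional annotated binding residues to highlight.
#' @return A ggplot object.
#' @export
plot_coverage <- function(coverage, residues = NULL) {
  p <- ggplot2::ggplot(coverage,
                       ggplot2::aes(x = .data$residue, y = .data$n_windows)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "residue (1-based)", y = "covering windows",
                  title = "Coverage by top-ranked pooled convolution windows")
  if (!is.null(residues)) {
    p <- p + ggplot2::geom_vline(xintercept = residues, alpha = 0.25,
                                 colour = "red")
  }
  p
}

#' @importFrom rlang .data
NULL
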
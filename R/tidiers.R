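#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an extraction result
#'
#' @param x an [extract_mcl()] result.
#' @param ... unused.
#' @return per-iteration sizes as a tibble.
#' @method tidy mcl_extraction
#' @export
tidy.mcl_extraction <- function(x, ...) x$history

#' @rdname tidy.mcl_extraction
#' @return for `glance`, a one-row run summary.
#' @method glance mcl_extraction
#' @export
glance.mcl_extraction <- function(x, ...) {
  tibble::tibble(n_iterations = x$n_iterations,
                 n_reactions = n_reactions(x$network),
                 n_metabolites = n_metabolites(x$network),
                 objective_score = x$objective_score,
                 n_columns = x$params$n_columns,
                 seed = x$params$seed)
}

#' @rdname tidy.mcl_extraction
#' @param object an [extract_mcl()] result.
#' @method autoplot mcl_extraction
#' @export
autoplot.mcl_extraction <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$n_reactions)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "outer iteration", y = "reactions in model",
                  title = "Model size trajectory during extraction") +
    ggplot2::theme_minimal()
}

#' Tidy a ROC result
#'
#' @param x,object an [roc()] result.
#' @param ... unused.
#' @return `tidy`: the (epsilon, FPR, TPR) points; `glance`: one row with the
#'   AUC.
#' @method tidy mcl_roc
#' @export
tidy.mcl_roc <- function(x, ...) x$points

#' @rdname tidy.mcl_roc
#' @method glance mcl_roc
#' @export
glance.mcl_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_points = nrow(x$points))
}

#' @rdname tidy.mcl_roc
#' @method autoplot mcl_roc
#' @export
autoplot.mcl_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("ROC (AUC = %.4f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Ranked subsystem t-score chart
#'
#' @param tscores a [subsystem_tscores()] table.
#' @param top show at most this many subsystems from each end.
#' @return a ggplot.
#' @export
plot_subsystem_tscores <- function(tscores, top = 20) {
  tab <- tscores |>
    dplyr::filter(!is.na(.data$t_score)) |>
    dplyr::arrange(.data$t_score)
  if (nrow(tab) > 2 * top)
    tab <- dplyr::bind_rows(utils::head(tab, top), utils::tail(tab, top))
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$t_score,
    y = stats::reorder(.data$subsystem, .data$t_score),
    fill = .data$t_score < 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "t-score vs random selector", y = NULL,
                  title = "Subsystem regulation (negative = downregulated)") +
    ggplot2::theme_minimal()
}
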
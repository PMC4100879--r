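direction_levels <- c("decreased", "unchanged", "increased")

#' Convert +/-/0 arrow codes to direction words and back
#'
#' @param x character vector of `+`, `-`, `0` (or direction words for
#'   [encode_arrows()]).
#' @return direction words (`increased`/`decreased`/`unchanged`) or arrow
#'   codes.
#' @export
decode_arrows <- function(x) {
  out <- dplyr::case_when(x == "+" ~ "increased",
                          x == "-" ~ "decreased",
                          x == "0" ~ "unchanged")
  if (anyNA(out)) stop("unknown arrow code(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' @rdname decode_arrows
#' @export
encode_arrows <- function(x) {
  out <- dplyr::case_when(x == "increased" ~ "+",
                          x == "decreased" ~ "-",
                          x == "unchanged" ~ "0")
  if (anyNA(out)) stop("unknown direction(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

align_calls <- function(truth, predicted) {
  as_tab <- function(x, what) {
    if (is.character(x) && !is.null(names(x)))
      x <- tibble::tibble(item = names(x), call = unname(x))
    if (!all(c("item", "call") %in% names(x)))
      stop(what, " needs columns item and call")
    bad <- setdiff(unique(x$call), direction_levels)
    if (length(bad)) stop(what, " has unknown call(s): ",
                          paste(bad, collapse = ", "))
    x[, c("item", "call")]
  }
  truth <- as_tab(truth, "truth")
  predicted <- as_tab(predicted, "predicted")
  only_t <- setdiff(truth$item, predicted$item)
  only_p <- setdiff(predicted$item, truth$item)
  if (length(only_t) || length(only_p))
    stop("alignment error: item sets differ",
         if (length(only_t)) paste0("; only in truth: ",
                                    paste(only_t, collapse = ", ")),
         if (length(only_p)) paste0("; only in predicted: ",
                                    paste(only_p, collapse = ", ")))
  dplyr::inner_join(dplyr::rename(truth, truth = "call"),
                    dplyr::rename(predicted, predicted = "call"),
                    by = "item")
}

#' Confusion counts for direction calls
#'
#' The convention, fixed by regenerating the published validation table from
#' its arrow panel:
#' \itemize{
#'   \item TP: predicted a change, truth has the same change;
#'   \item TN: both unchanged;
#'   \item FN: predicted unchanged, truth changed;
#'   \item FP: predicted a change when truth is unchanged — or the opposite
#'     change (a direction mismatch is a false positive, not also a false
#'     negative).
#' }
#'
#' @param truth,predicted tibbles with columns `item`, `call`, or named
#'   character vectors of calls; item sets must match exactly.
#' @return one-row tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(truth, predicted) {
  tab <- align_calls(truth, predicted)
  tibble::tibble(
    tp = sum(tab$predicted != "unchanged" & tab$predicted == tab$truth),
    fp = sum(tab$predicted != "unchanged" & tab$predicted != tab$truth),
    tn = sum(tab$predicted == "unchanged" & tab$truth == "unchanged"),
    fn = sum(tab$predicted == "unchanged" & tab$truth != "unchanged"))
}

#' Classification metrics from confusion counts
#'
#' Zero denominators give `NA` (undefined), never 0.  Recall and the true
#' positive rate are the same quantity; both names are emitted.
#'
#' @param counts one-row tibble or list with `tp`, `fp`, `tn`, `fn`.
#' @return one-row tibble with `precision`, `recall`, `tpr`, `tnr`, `fpr`,
#'   `accuracy`.
#' @export
metrics <- function(counts) {
  rate <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  with(counts, tibble::tibble(
    precision = rate(tp, tp + fp),
    recall = rate(tp, tp + fn),
    tpr = rate(tp, tp + fn),
    tnr = rate(tn, tn + fp),
    fpr = rate(fp, fp + tn),
    accuracy = rate(tp + tn, tp + fp + tn + fn)))
}

#' Threshold-swept ROC curve and AUC for direction deltas
#'
#' For every threshold in the grid, the deltas are thresholded into direction
#' calls ([call_directions()]), scored against the truth ([confusion()]), and
#' the (FPR, TPR) point recorded.  The anchor points (0,0) and (1,1) are
#' always appended, points are sorted by FPR, and the AUC is the trapezoid
#' area.  Points whose TPR or FPR is undefined (zero denominator) are
#' dropped.
#'
#' @param truth tibble with `item`, `call` (or named vector).
#' @param deltas tibble with `item`, `delta`.
#' @param epsilons threshold grid; `NULL` uses every observed |delta| (the
#'   exact sweep), [epsilon_grid()] is the 0-1000 log grid.
#' @return object of class `mcl_roc`: list with `points` (tibble `epsilon`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc <- function(truth, deltas, epsilons = NULL) {
  if (!all(c("item", "delta") %in% names(deltas)))
    stop("deltas needs columns item and delta")
  if (is.null(epsilons))
    epsilons <- sort(unique(c(0, abs(deltas$delta))))
  if (length(epsilons) < 2) stop("epsilon grid needs at least 2 values")
  pts <- purrr::map_dfr(epsilons, function(eps) {
    calls <- call_directions(deltas, eps)
    cc <- confusion(truth, tibble::tibble(item = calls$item,
                                          call = calls$call))
    m <- metrics(cc)
    tibble::tibble(epsilon = eps, fpr = m$fpr, tpr = m$tpr)
  })
  pts <- dplyr::filter(pts, !is.na(.data$fpr), !is.na(.data$tpr))
  curve <- dplyr::bind_rows(tibble::tibble(epsilon = NA_real_, fpr = 0, tpr = 0),
                            pts,
                            tibble::tibble(epsilon = NA_real_, fpr = 1, tpr = 1)) |>
    dplyr::arrange(.data$fpr, .data$tpr)
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "mcl_roc")
}

#' @export
print.mcl_roc <- function(x, ...) {
  cat("<mcl_roc> ", nrow(x$points), " points, AUC = ",
      format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Random direction selector
#'
#' Draws increased / decreased / unchanged uniformly per item — the chance
#' baseline for both the subsystem t-test and ROC comparisons.
#'
#' @param items character vector of item ids.
#' @param seed integer seed.
#' @return tibble with columns `item`, `call`.
#' @export
random_selector <- function(items, seed = 1) {
  set.seed(seed)
  tibble::tibble(item = items,
                 call = sample(direction_levels, length(items),
                               replace = TRUE))
}

#' The bundled amino-acid validation panel
#'
#' Twenty amino acids with the measured plasma direction in the Zucker
#' diabetic fatty rat versus healthy controls, alongside four model
#' prediction columns (exchange- and transport-based reads for the general
#' reconstruction and for the extracted multi-tissue model).
#'
#' @param as_calls translate the `+`/`-`/`0` codes into direction words.
#' @return tibble with columns `amino_acid`, `zucker`, `ex_recon1`, `ex_mcl`,
#'   `trans_recon1`, `trans_mcl`.
#' @export
table2_fixture <- function(as_calls = TRUE) {
  tab <- tibble::as_tibble(utils::read.delim(
    system.file("extdata", "table2_zucker.tsv", package = "mcltissue",
                mustWork = TRUE),
    stringsAsFactors = FALSE, colClasses = "character"))
  if (as_calls)
    tab <- dplyr::mutate(tab, dplyr::across(-"amino_acid", decode_arrows))
  tab
}

#' Score every prediction column of the validation panel
#'
#' Regenerates the summary confusion/metric table by scoring each prediction
#' column against the measured column.
#'
#' @param panel the validation tibble (default [table2_fixture()]).
#' @param truth_col name of the measured column.
#' @return tibble, one row per prediction column: counts plus metrics.
#' @export
score_panel <- function(panel = table2_fixture(), truth_col = "zucker") {
  pred_cols <- setdiff(names(panel), c("amino_acid", truth_col))
  truth <- tibble::tibble(item = panel$amino_acid,
                          call = panel[[truth_col]])
  purrr::map_dfr(pred_cols, function(pc) {
    cc <- confusion(truth, tibble::tibble(item = panel$amino_acid,
                                          call = panel[[pc]]))
    dplyr::bind_cols(tibble::tibble(model = pc), cc, metrics(cc))
  })
}
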
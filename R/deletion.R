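#' Map gene knockouts to disabled reactions
#'
#' Evaluates every reaction's GPR with the listed genes absent and all other
#' genes present; a reaction is returned when the full Boolean evaluation
#' comes out inactive (an isozyme `OR` rescues, a complex `AND` does not).
#' Reactions with no GPR are never gene-disabled.
#'
#' @param net a [metabolic_network()].
#' @param genes gene ids to delete.
#' @return character vector of disabled reaction ids; a warning (not an
#'   error) if none of the genes appears in any rule.
#' @export
genes_to_reactions <- function(net, genes) {
  genes <- unique(genes)
  values <- stats::setNames(rep(FALSE, length(genes)), genes)
  hit_any <- FALSE
  out <- character()
  for (i in seq_len(n_reactions(net))) {
    gpr <- net$reactions$gpr[i]
    if (!nzchar(gpr)) next
    tree <- parse_gpr(gpr)
    mentioned <- intersect(gpr_genes(tree), genes)
    if (!length(mentioned)) next
    hit_any <- TRUE
    if (!isTRUE(eval_gpr(tree, values, default = TRUE)))
      out <- c(out, net$reactions$id[i])
  }
  if (!hit_any && length(genes))
    warning("none of the deleted genes (",
            paste(genes, collapse = ", "), ") appears in any GPR")
  out
}

#' Normalized flux-bound change between two FVA bound sets
#'
#' For each reaction, `delta = ((diseaseMin + diseaseMax) - (refMin +
#' refMax)) / max(|mean of all four bounds|, tolerance)`; the denominator
#' guard protects against division by a near-zero mean.  Positive delta means
#' the attainable flux range shifted up in the perturbed state.
#'
#' @param ref,disease bound tables as returned by [fva()] (columns
#'   `reaction_id`, `min_flux`, `max_flux`); reactions absent from `disease`
#'   (e.g. deleted) contribute bounds (0, 0).
#' @param tolerance denominator floor.
#' @return tibble with columns `reaction_id`, `refMin`, `refMax`,
#'   `diseaseMin`, `diseaseMax`, `delta`.
#' @export
bound_deltas <- function(ref, disease, tolerance = 1e-6) {
  tab <- dplyr::left_join(
    dplyr::rename(ref, refMin = "min_flux", refMax = "max_flux"),
    dplyr::rename(disease, diseaseMin = "min_flux", diseaseMax = "max_flux"),
    by = "reaction_id") |>
    dplyr::mutate(diseaseMin = dplyr::coalesce(.data$diseaseMin, 0),
                  diseaseMax = dplyr::coalesce(.data$diseaseMax, 0))
  dplyr::mutate(
    tab,
    delta = ((.data$diseaseMin + .data$diseaseMax) -
               (.data$refMin + .data$refMax)) /
      pmax(abs((.data$refMin + .data$refMax +
                  .data$diseaseMin + .data$diseaseMax) / 4), tolerance))
}

#' Threshold deltas into direction calls
#'
#' @param deltas tibble with a `delta` column.
#' @param epsilon non-negative threshold: `delta > epsilon` is `increased`,
#'   `delta < -epsilon` `decreased`, otherwise `unchanged`.
#' @return the input with `epsilon` and `call` columns added.
#' @export
call_directions <- function(deltas, epsilon) {
  dplyr::mutate(
    deltas, epsilon = epsilon,
    call = dplyr::case_when(.data$delta > epsilon ~ "increased",
                            .data$delta < -epsilon ~ "decreased",
                            TRUE ~ "unchanged"))
}

#' Simulate one gene-deletion disorder
#'
#' Reference model: the affected reactions are forced on by setting their
#' lower bounds to 1 (zero flux through them is not permitted, giving maximal
#' contrast with their removal; on a reversible reaction this overrides the
#' negative lower bound).  Disease model: the affected reactions are removed.
#' FVA runs on the exchange reactions of both models, and the normalized
#' bound change of each exchange is thresholded into a concentration
#' direction call for its boundary metabolite.
#'
#' @param net a [metabolic_network()].
#' @param genes gene ids mutated in the disorder.
#' @param epsilon direction-call threshold.
#' @param disorder label recorded in the output.
#' @return tibble of direction calls over exchange reactions, with columns
#'   `disorder`, `reaction_id`, `metabolite`, bound columns, `delta`,
#'   `epsilon`, `call`.  If the reference model is infeasible after forcing,
#'   the disorder is not simulable: the result is an empty tibble with
#'   attribute `simulable = FALSE` and a message explains the exclusion.
#' @export
run_deletion <- function(net, genes, epsilon, disorder = "disorder") {
  exch <- net$reactions$id[net$reactions$is_exchange]
  exch_met <- net$stoichiometry |>
    dplyr::filter(.data$reaction_id %in% exch) |>
    dplyr::left_join(dplyr::select(net$metabolites, id, name),
                     by = c("metabolite_id" = "id")) |>
    dplyr::select("reaction_id", metabolite = "name")

  affected <- suppressWarnings(genes_to_reactions(net, genes))
  empty <- tibble::tibble(
    disorder = character(), reaction_id = character(),
    metabolite = character(), refMin = double(), refMax = double(),
    diseaseMin = double(), diseaseMax = double(), delta = double(),
    epsilon = double(), call = character())

  if (!length(affected)) {
    out <- tibble::tibble(disorder = disorder,
                          reaction_id = exch_met$reaction_id,
                          metabolite = exch_met$metabolite,
                          refMin = 0, refMax = 0, diseaseMin = 0,
                          diseaseMax = 0, delta = 0, epsilon = epsilon,
                          call = "unchanged")
    attr(out, "simulable") <- TRUE
    return(out)
  }

  ref_net <- net
  idx <- match(affected, ref_net$reactions$id)
  ref_net$reactions$lower_bound[idx] <- 1
  ref_net$reactions$upper_bound[idx] <-
    pmax(ref_net$reactions$upper_bound[idx], 1)
  dis_net <- subnetwork(net, setdiff(net$reactions$id, affected))

  ref_fva <- tryCatch(fva(ref_net, exch), error = function(e) e)
  if (inherits(ref_fva, "error")) {
    message("disorder '", disorder, "' not simulable: ",
            conditionMessage(ref_fva))
    attr(empty, "simulable") <- FALSE
    return(empty)
  }
  dis_exch <- intersect(exch, dis_net$reactions$id)
  dis_fva <- fva(dis_net, dis_exch)

  out <- bound_deltas(ref_fva, dis_fva) |>
    call_directions(epsilon) |>
    dplyr::left_join(exch_met, by = "reaction_id") |>
    dplyr::mutate(disorder = disorder) |>
    dplyr::select("disorder", "reaction_id", "metabolite", "refMin", "refMax",
                  "diseaseMin", "diseaseMax", "delta", "epsilon", "call")
  attr(out, "simulable") <- TRUE
  out
}

#' Simulate a panel of disorders
#'
#' @param net a [metabolic_network()].
#' @param disorders tibble with columns `disorder` and `genes` (list-column
#'   or comma-separated string), e.g. from [read_disorders()].
#' @param epsilon direction-call threshold.
#' @return combined calls tibble; non-simulable disorders are excluded and
#'   listed in the `not_simulable` attribute.
#' @export
run_deletion_panel <- function(net, disorders, epsilon) {
  gene_list <- if (is.list(disorders$genes)) disorders$genes else
    stringr::str_split(disorders$genes, ",\\s*")
  res <- purrr::map2(disorders$disorder, gene_list, function(d, g)
    run_deletion(net, g, epsilon, disorder = d))
  ok <- purrr::map_lgl(res, ~ isTRUE(attr(.x, "simulable")))
  out <- dplyr::bind_rows(res[ok])
  attr(out, "not_simulable") <- disorders$disorder[!ok]
  out
}

#' Read a disorder table
#'
#' Tab-separated with columns `disorder`, `genes` (comma-separated gene
#' symbols) and optionally `phenotype` (comma-separated
#' `metabolite=+|-|0` pairs for known boundary-metabolite changes).
#'
#' @param path file to read.
#' @return tibble with `disorder`, list-column `genes`, and, when present, a
#'   list-column `phenotype` of named direction vectors.
#' @export
read_disorders <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  out <- tibble::tibble(
    disorder = tab$disorder,
    genes = stringr::str_split(tab$genes, ",\\s*"))
  if ("phenotype" %in% names(tab)) {
    out$phenotype <- purrr::map(tab$phenotype, function(ph) {
      if (is.na(ph) || !nzchar(ph)) return(stats::setNames(character(), character()))
      kv <- stringr::str_split_fixed(
        stringr::str_split(ph, ",\\s*")[[1]], "=", 2)
      stats::setNames(decode_arrows(kv[, 2]), kv[, 1])
    })
  }
  out
}

#' The bundled amino-acid disorder panel
#'
#' Seventeen inborn errors of amino-acid metabolism with their causal genes,
#' for in-silico deletion studies.  Known phenotype directions are not
#' included (they are user-supplied).
#'
#' @return tibble with columns `disorder` and list-column `genes`.
#' @export
omim_disorders <- function() {
  read_disorders(system.file("extdata", "omim_disorders.tsv",
                             package = "mcltissue", mustWork = TRUE))
}

#' Log-spaced threshold grid for ROC sweeps
#'
#' 201 values: zero plus 200 log-spaced thresholds spanning 0.001 to 1000.
#'
#' @return numeric vector, increasing.
#' @export
epsilon_grid <- function() {
  c(0, 10^seq(-3, 3, length.out = 200))
}
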
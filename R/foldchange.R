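#' Read a differential-expression gene table
#'
#' Two tab-separated dialects: `gene_id`, `log2_fold_change`, `p_value`
#' (direction taken from the sign), or the pre-filtered two-column
#' `gene_id`, `direction` (`up`/`down`).
#'
#' @param path file to read.
#' @return tibble with columns `gene_id`, `direction`, and when available
#'   `log2_fold_change`, `p_value`.
#' @export
read_fold_changes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("direction" %in% names(tab)) {
    bad <- setdiff(unique(tab$direction), c("up", "down"))
    if (length(bad)) stop("unknown direction value(s): ",
                          paste(bad, collapse = ", "))
    return(tibble::as_tibble(tab))
  }
  if (!all(c("gene_id", "log2_fold_change", "p_value") %in% names(tab)))
    stop("fold-change table needs gene_id + direction, or gene_id + ",
         "log2_fold_change + p_value")
  dplyr::mutate(tibble::as_tibble(tab),
                direction = ifelse(.data$log2_fold_change >= 0, "up", "down"))
}

#' Apply the significance / fold-change filter
#'
#' Keeps records with `p_value < p_cutoff` and fold change above
#' `fc_cutoff` in magnitude (on the linear scale), the standard filter for
#' calling a gene differentially expressed.
#'
#' @param fold_changes tibble from [read_fold_changes()] or equivalent.
#' @param p_cutoff,fc_cutoff filter thresholds.
#' @return the filtered tibble.
#' @export
filter_fold_changes <- function(fold_changes, p_cutoff = 0.05,
                                fc_cutoff = 1.5) {
  if (!all(c("log2_fold_change", "p_value") %in% names(fold_changes)))
    return(fold_changes)  # pre-filtered dialect
  dplyr::filter(fold_changes,
                .data$p_value < p_cutoff,
                abs(.data$log2_fold_change) > log2(fc_cutoff))
}

# collapse multiple probe records per gene: majority of up vs down, tie ->
# unchanged (dropped)
gene_level_directions <- function(fold_changes) {
  wide <- fold_changes |>
    dplyr::count(.data$gene_id, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L)
  if (!"up" %in% names(wide)) wide$up <- 0L
  if (!"down" %in% names(wide)) wide$down <- 0L
  wide |>
    dplyr::mutate(code = dplyr::case_when(.data$up > .data$down ~ 1,
                                          .data$down > .data$up ~ -1,
                                          TRUE ~ 0)) |>
    dplyr::select("gene_id", "code")
}

#' Regulation status of each reaction from differential genes
#'
#' Probe records sharing one gene id are first collapsed by majority vote
#' (ties become unchanged).  Distinct genes then propagate through the GPR
#' logic with codes down = -1, unchanged = 0, up = +1: `AND` takes the
#' minimum (the most restricted complex subunit limits the enzyme), `OR` the
#' maximum (the least restricted isozyme rescues it).  Reactions whose rule
#' mentions no differential gene are unchanged.
#'
#' @param net a [metabolic_network()].
#' @param fold_changes filtered tibble with `gene_id` and `direction`.
#' @return tibble with columns `reaction_id`, `status`
#'   (`up`/`down`/`unchanged`) and `genes` (the differential genes the status
#'   traces to, comma-separated; `""` when defaulted).
#' @export
reaction_status <- function(net, fold_changes) {
  gl <- gene_level_directions(fold_changes)
  codes <- stats::setNames(gl$code, gl$gene_id)
  rows <- purrr::map(seq_len(n_reactions(net)), function(i) {
    gpr <- net$reactions$gpr[i]
    if (!nzchar(gpr))
      return(list(status = "unchanged", genes = ""))
    tree <- parse_gpr(gpr)
    hit <- intersect(gpr_genes(tree), names(codes))
    if (!length(hit))
      return(list(status = "unchanged", genes = ""))
    val <- eval_gpr(tree, codes, default = 0)
    list(status = c("down", "unchanged", "up")[val + 2],
         genes = paste(hit, collapse = ","))
  })
  tibble::tibble(reaction_id = net$reactions$id,
                 status = purrr::map_chr(rows, "status"),
                 genes = purrr::map_chr(rows, "genes"))
}

#' Apply the fold-change bound protocol
#'
#' Control model: reactions with an up or down status ("affected") get bounds
#' shrunk to magnitude 100 (lower bound -100 if reversible, else 0) so that a
#' later doubling can actually widen the attainable range in a steady-state
#' model; unaffected reactions keep the normal magnitude-1000 bounds;
#' exchange reactions are pinned to `[exchange_lb, 1000]`.  Disease model:
#' the control, with up-status bounds doubled and down-status bounds halved
#' (exchanges stay pinned).
#'
#' @param net a [metabolic_network()].
#' @param statuses tibble from [reaction_status()].
#' @param exchange_lb exchange lower bound; 1 forces every boundary exchange
#'   to carry flux (the study protocol).  Use 0 for exploratory runs when the
#'   forced-secretion model is infeasible.
#' @return list with `control` and `disease` networks.
#' @export
perturb_bounds <- function(net, statuses, exchange_lb = 1) {
  stat <- stats::setNames(statuses$status, statuses$reaction_id)
  ctrl <- net
  for (i in seq_len(n_reactions(ctrl))) {
    r <- ctrl$reactions[i, ]
    if (r$is_exchange) {
      ctrl$reactions$lower_bound[i] <- exchange_lb
      ctrl$reactions$upper_bound[i] <- 1000
      next
    }
    s <- if (r$id %in% names(stat)) stat[[r$id]] else "unchanged"
    mag <- if (s %in% c("up", "down")) 100 else 1000
    ctrl$reactions$upper_bound[i] <- mag
    ctrl$reactions$lower_bound[i] <- if (r$reversible) -mag else 0
  }
  dis <- ctrl
  for (i in seq_len(n_reactions(dis))) {
    r <- dis$reactions[i, ]
    if (r$is_exchange) next
    s <- if (r$id %in% names(stat)) stat[[r$id]] else "unchanged"
    f <- if (s == "up") 2 else if (s == "down") 0.5 else 1
    dis$reactions$lower_bound[i] <- dis$reactions$lower_bound[i] * f
    dis$reactions$upper_bound[i] <- dis$reactions$upper_bound[i] * f
  }
  list(control = ctrl, disease = dis)
}

#' Call flux directions between a control and a disease model
#'
#' Runs FVA over the scoped reactions in both models, computes the
#' normalized bound change ([bound_deltas()]) and thresholds it into
#' direction calls.  For the transport scope, calls can additionally be
#' aggregated per metabolite: the signed deltas of all cytosol/extracellular
#' transporters of one metabolite (across all tissues) are summed, giving a
#' fuller picture of net uptake or secretion than any single exchange.
#'
#' @param control,disease the two [metabolic_network()]s (same reaction ids;
#'   typically from [perturb_bounds()]).
#' @param scope `"exchange"`, `"transport"`, or `"all"`.
#' @param epsilon direction-call threshold.
#' @param per_metabolite aggregate transport deltas per metabolite name
#'   (default when `scope = "transport"`).
#' @return per-reaction calls tibble; with `per_metabolite = TRUE` a
#'   per-metabolite tibble with columns `metabolite`, `n_reactions`, `delta`,
#'   `epsilon`, `call`.
#' @export
call_flux_directions <- function(control, disease,
                                 scope = c("exchange", "transport", "all"),
                                 epsilon,
                                 per_metabolite = identical(scope, "transport")) {
  scope <- match.arg(scope)
  sel <- switch(scope,
                exchange = control$reactions$is_exchange,
                transport = control$reactions$is_transport,
                all = rep(TRUE, n_reactions(control)))
  ids <- control$reactions$id[sel]
  if (!length(ids)) stop("no reactions in scope '", scope, "'")
  ctrl_fva <- fva(control, ids)
  dis_fva <- tryCatch(fva(disease, intersect(ids, disease$reactions$id)),
                      error = function(e)
                        stop("disease model FVA failed (", conditionMessage(e),
                             "); check forced exchange lower bounds"))
  calls <- bound_deltas(ctrl_fva, dis_fva) |> call_directions(epsilon)
  if (!per_metabolite) return(calls)

  met_of <- control$stoichiometry |>
    dplyr::filter(.data$reaction_id %in% ids) |>
    dplyr::left_join(dplyr::select(control$metabolites, id, name, compartment),
                     by = c("metabolite_id" = "id")) |>
    dplyr::filter(.data$compartment == "e") |>
    dplyr::distinct(.data$reaction_id, metabolite = .data$name)
  calls |>
    dplyr::inner_join(met_of, by = "reaction_id") |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(n_reactions = dplyr::n(), delta = sum(.data$delta),
                     .groups = "drop") |>
    call_directions(epsilon)
}

#' Subsystem t-scores against a random selector
#'
#' Direction calls are coded down = -1, unchanged = 0, up = +1 and each
#' subsystem is compared by a Welch two-sample t-test against a same-size
#' random sample drawn uniformly from \{-1, 0, +1\} (a selector that picks
#' each category a third of the time).  The more negative the t-score, the
#' more coherently downregulated the subsystem; tiny subsystems cannot reach
#' large |t|, which is the point of the test — a 2-reaction subsystem that is
#' 100% down is matched by chance 1/9 of the time.
#'
#' @param calls per-reaction calls tibble (columns `reaction_id`, `call`).
#' @param net the network supplying the `subsystem` annotation.
#' @param seed integer seed for the random selector (one global stream; each
#'   subsystem draws its sample in order).
#' @return tibble with `subsystem`, `n_reactions`, `n_up`, `n_down`,
#'   `n_unchanged`, `t_score`, ordered from most negative t-score up;
#'   subsystems of size < 2 get `NA` (t undefined).
#' @export
subsystem_tscores <- function(calls, net, seed = 1) {
  tab <- calls |>
    dplyr::inner_join(dplyr::select(net$reactions, id, subsystem),
                      by = c("reaction_id" = "id")) |>
    dplyr::filter(nzchar(.data$subsystem))
  set.seed(seed)
  out <- tab |>
    dplyr::group_by(.data$subsystem) |>
    dplyr::summarise(
      n_reactions = dplyr::n(),
      n_up = sum(.data$call == "increased"),
      n_down = sum(.data$call == "decreased"),
      n_unchanged = sum(.data$call == "unchanged"),
      t_score = {
        x <- c(-1, 0, 1)[match(.data$call,
                               c("decreased", "unchanged", "increased"))]
        y <- sample(c(-1, 0, 1), length(x), replace = TRUE)
        if (length(x) < 2) NA_real_
        else tryCatch(unname(stats::t.test(x, y)$statistic),
                      error = function(e) NA_real_)
      },
      .groups = "drop") |>
    dplyr::arrange(.data$t_score)
  out
}
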
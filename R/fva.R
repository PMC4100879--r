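#' Solve a flux-balance linear program
#'
#' Optimizes a linear objective over the steady-state flux polytope
#' `{v : S v = 0, lb <= v <= ub}`.  Infeasibility and unboundedness are
#' reported as statuses, not errors, because model extraction routinely
#' probes infeasible configurations.
#'
#' @param net a [metabolic_network()].
#' @param objective named numeric vector of objective weights by reaction id
#'   (unnamed reactions get weight 0).
#' @param sense `"max"` or `"min"`.
#' @return a list with `status` (`"optimal"`, `"infeasible"`, ...),
#'   `objective_value`, and `fluxes`, a tibble with columns `reaction_id`,
#'   `flux` (all `NA` unless optimal).
#' @export
solve_lp <- function(net, objective, sense = c("max", "min")) {
  sense <- match.arg(sense)
  ids <- net$reactions$id
  if (length(objective)) {
    bad <- setdiff(names(objective), ids)
    if (length(bad))
      stop("objective references unknown reaction(s): ",
           paste(bad, collapse = ", "))
  }
  obj <- stats::setNames(numeric(length(ids)), ids)
  obj[names(objective)] <- objective
  S <- stoich_matrix(net)
  r <- lp_bounded(S, rep(0, nrow(S)), unname(obj),
                  net$reactions$lower_bound, net$reactions$upper_bound,
                  sense = sense)
  fluxes <- tibble::tibble(reaction_id = ids,
                           flux = if (r$status == "optimal") r$x
                                  else rep(NA_real_, length(ids)))
  list(status = r$status, objective_value = r$objective, fluxes = fluxes)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux over the
#' steady-state polytope, with no objective-optimality constraint (the plain
#' attainable range).  This costs two LP solves per reaction.
#'
#' @param net a [metabolic_network()].
#' @param reactions reaction ids to analyse (default: all).
#' @return a tibble with columns `reaction_id`, `min_flux`, `max_flux`.
#' @export
fva <- function(net, reactions = NULL) {
  ids <- reactions %||% net$reactions$id
  bad <- setdiff(ids, net$reactions$id)
  if (length(bad))
    stop("unknown reaction id(s): ", paste(bad, collapse = ", "))
  S <- stoich_matrix(net)
  lb <- net$reactions$lower_bound
  ub <- net$reactions$upper_bound
  base <- lp_bounded(S, rep(0, nrow(S)), numeric(ncol(S)), lb, ub)
  if (base$status != "optimal")
    stop("FVA aborted: base model is ", base$status)
  col <- match(ids, net$reactions$id)
  res <- purrr::map(col, function(j) {
    e <- numeric(ncol(S)); e[j] <- 1
    lo <- lp_bounded(S, rep(0, nrow(S)), e, lb, ub, sense = "min")
    hi <- lp_bounded(S, rep(0, nrow(S)), e, lb, ub, sense = "max")
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA solve failed for reaction ", ids[match(j, col)],
           " (", lo$status, "/", hi$status, ")")
    c(lo$objective, hi$objective)
  })
  tibble::tibble(reaction_id = ids,
                 min_flux = pmin(purrr::map_dbl(res, 1), purrr::map_dbl(res, 2)),
                 max_flux = pmax(purrr::map_dbl(res, 1), purrr::map_dbl(res, 2)))
}

#' Find blocked reactions
#'
#' A reaction is blocked when its whole FVA interval lies within
#' `[-tolerance, tolerance]`: no steady-state flux of meaningful magnitude
#' can pass through it.
#'
#' @param net a [metabolic_network()].
#' @param tolerance positive activity threshold in flux units.
#' @return character vector of blocked reaction ids.
#' @export
find_blocked <- function(net, tolerance = 1e-6) {
  if (tolerance <= 0) stop("tolerance must be > 0")
  bounds <- fva(net)
  bounds$reaction_id[bounds$min_flux >= -tolerance &
                       bounds$max_flux <= tolerance]
}

#' Remove blocked reactions, keeping a flux-consistent core
#'
#' @param net a [metabolic_network()].
#' @param tolerance activity threshold, see [find_blocked()].
#' @return the flux-consistent sub-network.
#' @export
remove_blocked <- function(net, tolerance = 1e-6) {
  blocked <- find_blocked(net, tolerance)
  if (!length(blocked)) return(net)
  subnetwork(net, setdiff(net$reactions$id, blocked))
}
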
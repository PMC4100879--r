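#' Draw a random extraction objective
#'
#' Samples `k` reactions uniformly without replacement from the union of the
#' high- and medium-confidence tiers (never the low tier) and gives them unit
#' weight.  Uses the current RNG state; seed management belongs to the
#' caller.
#'
#' @param net a [metabolic_network()].
#' @param tiers a [confidence_tiers()] object on `net`.
#' @param k number of reactions to maximize (capped at the pool size).
#' @return named numeric vector of unit weights.
#' @export
random_objective <- function(net, tiers, k = 3) {
  pool <- intersect(c(tiers$high, tiers$medium), net$reactions$id)
  if (!length(pool))
    stop("configuration error: no high- or medium-confidence reactions ",
         "available for the random objective")
  k <- max(1L, min(k, length(pool)))
  chosen <- if (length(pool) == 1L) pool else sample(pool, k)
  stats::setNames(rep(1, length(chosen)), chosen)
}

#' Build a randomized flux-distribution matrix (fdMatrix)
#'
#' Each column is the Boolean activity pattern (|flux| above the activity
#' tolerance) of one LP solution under one random objective over the high and
#' medium tiers.  Infeasible or degenerate solves leave an all-zero column;
#' their count is recorded, not raised.
#'
#' @param net a [metabolic_network()].
#' @param tiers a [confidence_tiers()] object on `net`.
#' @param n_columns number of randomized flux distributions (around
#'   10,000-20,000 at genome scale; a few hundred suffice on toy networks).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param k reactions per random objective, see [random_objective()].
#' @param activity_tol |flux| above this counts as active.
#' @return an object of class `fd_matrix`: list with the logical `activity`
#'   matrix (reactions x columns), the list of sampled `objectives`, `seed`,
#'   and `n_zero_columns`.
#' @export
build_fd_matrix <- function(net, tiers, n_columns = 10000, seed = NULL,
                            k = 3, activity_tol = 1e-6) {
  if (!is.numeric(n_columns) || n_columns < 1)
    stop("configuration error: n_columns must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ids <- net$reactions$id
  S <- stoich_matrix(net)
  lb <- net$reactions$lower_bound
  ub <- net$reactions$upper_bound
  activity <- matrix(FALSE, length(ids), n_columns,
                     dimnames = list(ids, NULL))
  objectives <- vector("list", n_columns)
  n_zero <- 0L
  for (jj in seq_len(n_columns)) {
    objv <- random_objective(net, tiers, k)
    objectives[[jj]] <- names(objv)
    cvec <- numeric(length(ids))
    cvec[match(names(objv), ids)] <- objv
    r <- lp_bounded(S, rep(0, nrow(S)), cvec, lb, ub, sense = "max")
    if (r$status == "optimal") {
      activity[, jj] <- abs(r$x) > activity_tol
      if (!any(activity[, jj])) n_zero <- n_zero + 1L
    } else n_zero <- n_zero + 1L
  }
  structure(list(activity = activity, objectives = objectives,
                 seed = seed, n_zero_columns = n_zero),
            class = "fd_matrix")
}

#' Score one flux-distribution column
#'
#' `score = |active & remaining medium| - w |active & remaining low|` with
#' `w = 0.5` by default: the weight at which the gain from one more
#' medium-confidence reaction exactly balances dropping two low-confidence
#' ones, i.e. equal preference for parsimony and medium-tier coverage.
#'
#' @param column logical activity vector named by reaction id (or a character
#'   vector of active reaction ids).
#' @param remaining_medium,remaining_low reaction ids not yet added.
#' @param low_weight penalty per active low-confidence reaction.
#' @return the numeric score.
#' @export
score_column <- function(column, remaining_medium, remaining_low,
                         low_weight = 0.5) {
  active <- if (is.logical(column)) names(column)[column] else column
  length(intersect(active, remaining_medium)) -
    low_weight * length(intersect(active, remaining_low))
}

score_all_columns <- function(activity, remaining_medium, remaining_low,
                              low_weight = 0.5) {
  med <- rownames(activity) %in% remaining_medium
  low <- rownames(activity) %in% remaining_low
  colSums(activity[med, , drop = FALSE]) -
    low_weight * colSums(activity[low, , drop = FALSE])
}

new_extraction_state <- function(tiers) {
  list(final_reactions = character(),
       remaining_high = tiers$high,
       remaining_medium = tiers$medium,
       remaining_low = tiers$low,
       log = tibble::tibble(step = character(), column = integer(),
                            score = double(), n_added = integer()))
}

add_column_to_state <- function(state, activity, j, step, low_weight = 0.5) {
  active <- rownames(activity)[activity[, j]]
  sc <- score_column(active, state$remaining_medium, state$remaining_low,
                     low_weight)
  state$final_reactions <- union(state$final_reactions, active)
  state$remaining_high <- setdiff(state$remaining_high, active)
  state$remaining_medium <- setdiff(state$remaining_medium, active)
  state$remaining_low <- setdiff(state$remaining_low, active)
  state$log <- dplyr::bind_rows(
    state$log, tibble::tibble(step = step, column = as.integer(j),
                              score = sc, n_added = length(active)))
  state
}

# targeted LP: activity pattern of maximizing (then, if reversible,
# minimizing) one reaction's flux; NULL when the reaction is blocked
targeted_activity_column <- function(net, reaction_id, activity_tol = 1e-6) {
  sol <- solve_lp(net, stats::setNames(1, reaction_id), "max")
  flux <- function(s) s$fluxes$flux[s$fluxes$reaction_id == reaction_id]
  if (sol$status != "optimal" || abs(flux(sol)) <= activity_tol) {
    lbound <- net$reactions$lower_bound[net$reactions$id == reaction_id]
    if (lbound < 0) {
      sol <- solve_lp(net, stats::setNames(1, reaction_id), "min")
      if (sol$status != "optimal" || abs(flux(sol)) <= activity_tol)
        return(NULL)
    } else return(NULL)
  }
  stats::setNames(abs(sol$fluxes$flux) > activity_tol, sol$fluxes$reaction_id)
}

#' Cover all high-confidence reactions
#'
#' Greedy loop: among columns with at least one still-uncovered
#' high-confidence reaction active, pick the best-scoring one (ties broken by
#' lowest column index), add all its active reactions, zero those rows, and
#' rescore, until no high-confidence reaction remains uncovered.  If some
#' high-confidence reaction is active in no sampled column, a targeted LP
#' maximizing that reaction's flux supplies an extra column; if it cannot
#' carry flux at all, a coverage failure lists the uncovered ids.
#'
#' @param state an extraction state as built internally by [extract_mcl()]
#'   (list with `final_reactions`, `remaining_high`, `remaining_medium`,
#'   `remaining_low`).
#' @param fdm an [build_fd_matrix()] result.
#' @param net the network the matrix was built on (for targeted rescue
#'   solves); `NULL` disables the rescue.
#' @param activity_tol activity threshold for rescue columns.
#' @return the updated state.
#' @export
cover_high_confidence <- function(state, fdm, net = NULL,
                                  activity_tol = 1e-6, low_weight = 0.5) {
  activity <- fdm$activity
  activity[rownames(activity) %in% state$final_reactions, ] <- FALSE
  while (length(state$remaining_high)) {
    scores <- score_all_columns(activity, state$remaining_medium,
                                state$remaining_low, low_weight)
    has_high <- colSums(activity[rownames(activity) %in%
                                   state$remaining_high, , drop = FALSE]) > 0
    if (!any(has_high)) {
      rescued <- FALSE
      if (!is.null(net)) {
        for (rid in state$remaining_high) {
          col <- targeted_activity_column(net, rid, activity_tol)
          if (!is.null(col)) {
            col[names(col) %in% state$final_reactions] <- FALSE
            newcol <- rep(FALSE, nrow(activity))
            names(newcol) <- rownames(activity)
            newcol[names(col)] <- col
            activity <- cbind(activity, newcol)
            rescued <- TRUE
          }
        }
      }
      if (!rescued)
        stop("coverage failure: high-confidence reaction(s) active in no ",
             "flux distribution: ",
             paste(state$remaining_high, collapse = ", "))
      next
    }
    cand <- which(has_high)
    j <- cand[which.max(scores[cand])]   # which.max returns first = lowest index
    state <- add_column_to_state(state, activity, j, "cover_high", low_weight)
    activity[rownames(activity) %in% state$final_reactions, ] <- FALSE
  }
  state
}

#' Grow the model by positive-score flux distributions
#'
#' After high-confidence coverage, repeatedly adds the best-scoring column
#' while that score is strictly positive, zeroing added rows and rescoring
#' after each addition.  Terminates when the best score is <= 0: the
#' extraction objective is at its maximum for this set of flux
#' distributions.
#'
#' @inheritParams cover_high_confidence
#' @return the updated state.
#' @export
grow_positive_score <- function(state, fdm, low_weight = 0.5) {
  activity <- fdm$activity
  activity[rownames(activity) %in% state$final_reactions, ] <- FALSE
  repeat {
    scores <- score_all_columns(activity, state$remaining_medium,
                                state$remaining_low, low_weight)
    j <- which.max(scores)
    if (!length(j) || scores[j] <= 0) break
    state <- add_column_to_state(state, activity, j, "grow", low_weight)
    activity[rownames(activity) %in% state$final_reactions, ] <- FALSE
  }
  state
}

#' Extract a multi-confidence-level (MCL) context-specific model
#'
#' The full extraction algorithm.  Outer loop: build a randomized
#' flux-distribution matrix on the current model scope, cover every
#' high-confidence reaction while maximizing the confidence-weighted score,
#' then keep adding positive-score distributions; the reactions collected
#' this way induce the next, smaller scope.  The loop stops when the model
#' size no longer changes between iterations.
#'
#' The extraction objective is
#' `|R_p  intersect C_m| - low_weight |R_p intersect C_x|` subject to full
#' inclusion of the high tier `C_h`, where `R_p` is the extracted reaction
#' set.
#'
#' @param net a flux-consistent [metabolic_network()] (run
#'   [remove_dead_ends()] / [remove_blocked()] first).
#' @param tiers a [confidence_tiers()] object on `net`.
#' @param n_columns flux distributions per outer iteration.
#' @param k reactions per random objective.
#' @param seed integer seed for the whole run (reproducible end to end).
#' @param low_weight penalty per low-confidence reaction in the score.
#' @param activity_tol |flux| above this counts as active.
#' @param max_outer_iterations hard cap on outer iterations.
#' @return an object of class `mcl_extraction`: list with `network` (the
#'   extracted sub-network), `history` (per-iteration sizes),
#'   `objective_score`, `reaction_ids`, `n_iterations`, `params`, and the
#'   per-iteration selection `log`.
#' @export
extract_mcl <- function(net, tiers, n_columns = 10000, k = 3, seed = 1,
                        low_weight = 0.5, activity_tol = 1e-6,
                        max_outer_iterations = 20) {
  set.seed(seed)
  current <- net
  history <- tibble::tibble(iteration = integer(), n_reactions = integer(),
                            n_metabolites = integer())
  logs <- list()
  prev_size <- NA_integer_
  final_state <- NULL
  for (iter in seq_len(max_outer_iterations)) {
    tiers_i <- restrict_tiers(tiers, current)
    fdm <- build_fd_matrix(current, tiers_i, n_columns = n_columns,
                           seed = NULL, k = k, activity_tol = activity_tol)
    state <- new_extraction_state(tiers_i)
    state$remaining_medium <- tiers_i$medium
    state$remaining_low <- tiers_i$low
    if (length(state$remaining_high))
      state <- cover_high_confidence(state, fdm, net = current,
                                     activity_tol = activity_tol,
                                     low_weight = low_weight)
    state <- grow_positive_score(state, fdm, low_weight = low_weight)
    extracted <- subnetwork(current, state$final_reactions)
    history <- dplyr::bind_rows(history, tibble::tibble(
      iteration = iter, n_reactions = n_reactions(extracted),
      n_metabolites = n_metabolites(extracted)))
    logs[[iter]] <- dplyr::mutate(state$log, iteration = iter)
    final_state <- state
    if (n_reactions(extracted) == 0L) {
      # nothing satisfies the objective: the empty model is the fixed point
      current <- extracted
      break
    }
    if (!is.na(prev_size) && n_reactions(extracted) == prev_size) {
      current <- extracted
      break
    }
    prev_size <- n_reactions(extracted)
    current <- extracted
    if (iter == max_outer_iterations)
      stop("extraction did not converge within ", max_outer_iterations,
           " iterations; size trajectory: ",
           paste(history$n_reactions, collapse = " -> "))
  }
  score <- length(intersect(current$reactions$id, tiers$medium)) -
    low_weight * length(intersect(current$reactions$id, tiers$low))
  structure(list(network = current,
                 reaction_ids = current$reactions$id,
                 history = history,
                 n_iterations = nrow(history),
                 objective_score = score,
                 log = dplyr::bind_rows(logs),
                 params = list(n_columns = n_columns, k = k, seed = seed,
                               low_weight = low_weight,
                               activity_tol = activity_tol)),
            class = "mcl_extraction")
}

#' @export
print.mcl_extraction <- function(x, ...) {
  cat("<mcl_extraction> ", n_reactions(x$network), " reactions, ",
      n_metabolites(x$network), " metabolites after ", x$n_iterations,
      " iteration(s); objective score ", x$objective_score, "\n", sep = "")
  invisible(x)
}
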
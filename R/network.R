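#' Construct a metabolic network
#'
#' The central container of the package: a stoichiometric model made of a
#' metabolite table, a reaction table and a long-format stoichiometry table.
#' All user-facing functions take and return this object or plain tibbles, so
#' pipelines compose with the pipe.
#'
#' Compartments follow the bracket convention of the native reaction-table
#' format: `"c"` is cytosol, `"e"` the (shared, blood-side) extracellular
#' compartment.  Two reaction roles are derived, not declared:
#' \describe{
#'   \item{exchange}{a boundary pseudo-reaction touching exactly one
#'     extracellular metabolite; its flux is the net secretion (positive) or
#'     uptake (negative, when the equation is written outbound) across the
#'     system boundary and proxies blood concentration change.}
#'   \item{transport}{a reaction moving one metabolite between the cytosol
#'     and the extracellular compartment (same metabolite name on both sides
#'     with opposite signs).}
#' }
#'
#' @param reactions tibble with columns `id`, `lower_bound`, `upper_bound`,
#'   and optionally `gpr` (Boolean gene rule, `""` for none), `subsystem`,
#'   `tissue_tag`, `reversible` (defaults to `lower_bound < 0`).
#' @param metabolites tibble with columns `id`, `name`, `compartment`, and
#'   optionally `tissue_tag` (`NA` for untagged / extracellular).
#' @param stoichiometry tibble with columns `reaction_id`, `metabolite_id`,
#'   `coefficient` (signed; negative = consumed).
#' @param name model name.
#'
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(reactions, metabolites, stoichiometry,
                              name = "network") {
  reactions <- tibble::as_tibble(reactions)
  metabolites <- tibble::as_tibble(metabolites)
  stoichiometry <- tibble::as_tibble(stoichiometry)

  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  if (!"tissue_tag" %in% names(reactions)) reactions$tissue_tag <- NA_character_
  if (!"reversible" %in% names(reactions))
    reactions$reversible <- reactions$lower_bound < 0
  if (!"tissue_tag" %in% names(metabolites))
    metabolites$tissue_tag <- NA_character_
  reactions$gpr[is.na(reactions$gpr)] <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""

  if (anyDuplicated(reactions$id))
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  if (anyDuplicated(metabolites$id))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  bad_met <- setdiff(stoichiometry$metabolite_id, metabolites$id)
  if (length(bad_met))
    stop("integrity error: stoichiometry references undeclared metabolite(s): ",
         paste(bad_met, collapse = ", "))
  bad_rxn <- setdiff(stoichiometry$reaction_id, reactions$id)
  if (length(bad_rxn))
    stop("integrity error: stoichiometry references undeclared reaction(s): ",
         paste(bad_rxn, collapse = ", "))
  if (any(reactions$lower_bound > reactions$upper_bound))
    stop("lower_bound > upper_bound for: ",
         paste(reactions$id[reactions$lower_bound > reactions$upper_bound],
               collapse = ", "))
  extr <- metabolites$compartment == "e" & !is.na(metabolites$tissue_tag)
  if (any(extr))
    stop("extracellular metabolites must not carry a tissue tag: ",
         paste(metabolites$id[extr], collapse = ", "))

  net <- structure(
    list(name = name, reactions = reactions, metabolites = metabolites,
         stoichiometry = stoichiometry),
    class = "metabolic_network")
  annotate_reaction_roles(net)
}

# derive is_exchange / is_transport from the stoichiometry
annotate_reaction_roles <- function(net) {
  met <- net$metabolites
  st <- dplyr::left_join(net$stoichiometry,
                         dplyr::select(met, id, name, compartment),
                         by = c("metabolite_id" = "id"))
  roles <- st |>
    dplyr::group_by(.data$reaction_id) |>
    dplyr::summarise(
      is_exchange = dplyr::n() == 1L && all(.data$compartment == "e"),
      is_transport = {
        ce <- .data$compartment %in% c("c", "e")
        any(vapply(unique(.data$name[ce]), function(nm) {
          sub <- .data$compartment[ce][.data$name[ce] == nm]
          co <- .data$coefficient[ce][.data$name[ce] == nm]
          any(sub == "c") && any(sub == "e") &&
            min(co) < 0 && max(co) > 0
        }, logical(1)))
      },
      .groups = "drop")
  net$reactions <- net$reactions |>
    dplyr::select(-dplyr::any_of(c("is_exchange", "is_transport"))) |>
    dplyr::left_join(roles, by = c("id" = "reaction_id")) |>
    dplyr::mutate(is_exchange = dplyr::coalesce(.data$is_exchange, FALSE),
                  is_transport = dplyr::coalesce(.data$is_transport, FALSE))
  net
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", x$name, "\n",
      "  reactions:   ", nrow(x$reactions),
      " (", sum(x$reactions$is_exchange), " exchange, ",
      sum(x$reactions$is_transport), " transport)\n",
      "  metabolites: ", nrow(x$metabolites), "\n", sep = "")
  invisible(x)
}

#' Network dimensions
#' @param net a [metabolic_network()].
#' @return integer count.
#' @export
n_reactions <- function(net) nrow(net$reactions)

#' @rdname n_reactions
#' @export
n_metabolites <- function(net) nrow(net$metabolites)

#' Dense stoichiometric matrix
#'
#' Rows are metabolites, columns reactions, in table order.
#'
#' @param net a [metabolic_network()].
#' @return numeric matrix with dimnames.
#' @export
stoich_matrix <- function(net) {
  S <- matrix(0, n_metabolites(net), n_reactions(net),
              dimnames = list(net$metabolites$id, net$reactions$id))
  S[cbind(net$stoichiometry$metabolite_id, net$stoichiometry$reaction_id)] <-
    net$stoichiometry$coefficient
  S
}

#' Restrict a network to a subset of reactions
#'
#' Keeps the given reactions and every metabolite they touch.
#'
#' @param net a [metabolic_network()].
#' @param reaction_ids character vector of reaction ids to keep.
#' @return the induced sub-network.
#' @export
subnetwork <- function(net, reaction_ids) {
  missing <- setdiff(reaction_ids, net$reactions$id)
  if (length(missing))
    stop("unknown reaction id(s): ", paste(missing, collapse = ", "))
  st <- dplyr::filter(net$stoichiometry, .data$reaction_id %in% reaction_ids)
  metabolic_network(
    reactions = dplyr::filter(net$reactions, .data$id %in% reaction_ids),
    metabolites = dplyr::filter(net$metabolites,
                                .data$id %in% unique(st$metabolite_id)),
    stoichiometry = st,
    name = net$name)
}

#' Iteratively remove dead-end metabolites and their reactions
#'
#' A dead-end metabolite can only ever be produced or only ever consumed
#' (reversible reactions count as both producer and consumer), so no
#' steady-state flux can pass through it.  All reactions touching a dead-end
#' metabolite are removed; removal can expose new dead ends, so the pruning
#' runs to a fixed point.  The result is always a sub-network of the input;
#' an empty network is a legal output.
#'
#' @param net a [metabolic_network()].
#' @param tolerance bounds within `[-tolerance, tolerance]` are treated as
#'   unable to carry flux in the producer/consumer test.
#' @return the pruned [metabolic_network()].
#' @export
remove_dead_ends <- function(net, tolerance = 1e-9) {
  repeat {
    if (n_metabolites(net) == 0L) return(net)
    st <- dplyr::left_join(
      net$stoichiometry,
      dplyr::select(net$reactions, id, lower_bound, upper_bound),
      by = c("reaction_id" = "id"))
    role <- st |>
      dplyr::group_by(.data$metabolite_id) |>
      dplyr::summarise(
        produced = any((.data$coefficient > 0 & .data$upper_bound > tolerance) |
                       (.data$coefficient < 0 & .data$lower_bound < -tolerance)),
        consumed = any((.data$coefficient < 0 & .data$upper_bound > tolerance) |
                       (.data$coefficient > 0 & .data$lower_bound < -tolerance)),
        .groups = "drop")
    dead <- c(role$metabolite_id[!(role$produced & role$consumed)],
              setdiff(net$metabolites$id, st$metabolite_id))
    if (!length(dead)) return(net)
    dead_rxn <- unique(net$stoichiometry$reaction_id[
      net$stoichiometry$metabolite_id %in% dead])
    keep <- setdiff(net$reactions$id, dead_rxn)
    st2 <- dplyr::filter(net$stoichiometry, .data$reaction_id %in% keep)
    net <- metabolic_network(
      reactions = dplyr::filter(net$reactions, .data$id %in% keep),
      metabolites = dplyr::filter(
        net$metabolites,
        .data$id %in% unique(st2$metabolite_id)),
      stoichiometry = st2,
      name = net$name)
  }
}

#' Expand a network into tissue copies sharing the extracellular compartment
#'
#' Every reaction that touches at least one non-extracellular metabolite is
#' replicated once per tissue; its id gains the tissue prefix
#' (e.g. `"A:"`) and its non-extracellular metabolites gain the tissue suffix
#' (e.g. `"[Adp]"`).  Reactions made of extracellular metabolites only —
#' which includes every exchange reaction — are kept exactly once, and
#' extracellular metabolites are shared across tissues and never suffixed.
#' The prefix/suffix are also recorded in the `tissue_tag` metadata columns
#' so downstream code never parses ids.
#'
#' @param net a [metabolic_network()].
#' @param tissues tibble with columns `prefix` and `suffix`, one row per
#'   tissue; the default is the adipocyte / hepatocyte / skeletal-muscle
#'   triple `A:/H:/M:` with suffixes `[Adp]/[Hep]/[Msc]`.
#' @return the expanded [metabolic_network()].
#' @export
expand_to_tissues <- function(net,
                              tissues = tibble::tibble(
                                prefix = c("A", "H", "M"),
                                suffix = c("Adp", "Hep", "Msc"))) {
  tissues <- tibble::as_tibble(tissues)
  if (!nrow(tissues)) stop("tissues must be non-empty")
  if (!all(c("prefix", "suffix") %in% names(tissues)))
    stop("tissues needs columns prefix and suffix")
  met <- net$metabolites
  if (!any(met$compartment == "e"))
    stop("network has no extracellular compartment to share")

  extr_ids <- met$id[met$compartment == "e"]
  rxn_mets <- split(net$stoichiometry$metabolite_id,
                    net$stoichiometry$reaction_id)
  extr_only <- vapply(net$reactions$id, function(r)
    all(rxn_mets[[r]] %in% extr_ids), logical(1))

  shared_rxn <- net$reactions[extr_only, , drop = FALSE]
  shared_st <- dplyr::filter(net$stoichiometry,
                             .data$reaction_id %in% shared_rxn$id)

  tissue_parts <- purrr::pmap(tissues, function(prefix, suffix) {
    rx <- net$reactions[!extr_only, , drop = FALSE]
    rx$id <- paste0(prefix, ":", rx$id)
    rx$tissue_tag <- prefix
    mt <- met[met$compartment != "e", , drop = FALSE]
    old_met <- mt$id
    mt$id <- paste0(mt$id, "[", suffix, "]")
    mt$tissue_tag <- suffix
    map <- stats::setNames(mt$id, old_met)
    st <- dplyr::filter(net$stoichiometry, !(.data$reaction_id %in% shared_rxn$id))
    st$reaction_id <- paste0(prefix, ":", st$reaction_id)
    inner <- st$metabolite_id %in% old_met
    st$metabolite_id[inner] <- map[st$metabolite_id[inner]]
    list(reactions = rx, metabolites = mt, stoichiometry = st)
  })

  reactions <- dplyr::bind_rows(shared_rxn,
                                purrr::map(tissue_parts, "reactions"))
  metabolites <- dplyr::bind_rows(met[met$compartment == "e", , drop = FALSE],
                                  purrr::map(tissue_parts, "metabolites"))
  stoich <- dplyr::bind_rows(shared_st,
                             purrr::map(tissue_parts, "stoichiometry"))
  if (anyDuplicated(reactions$id))
    stop("naming-collision error: duplicate reaction ids after expansion: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  if (anyDuplicated(metabolites$id))
    stop("naming-collision error: duplicate metabolite ids after expansion: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  metabolic_network(reactions, metabolites, stoich,
                    name = paste0(net$name, "_", nrow(tissues), "tissue"))
}

#' Set reaction bounds
#'
#' @param net a [metabolic_network()].
#' @param reaction_ids reactions to change.
#' @param lower,upper new bounds (recycled); `NULL` leaves a side untouched.
#' @return the modified network.
#' @export
set_bounds <- function(net, reaction_ids, lower = NULL, upper = NULL) {
  idx <- match(reaction_ids, net$reactions$id)
  if (anyNA(idx))
    stop("unknown reaction id(s): ",
         paste(reaction_ids[is.na(idx)], collapse = ", "))
  if (!is.null(lower)) net$reactions$lower_bound[idx] <- lower
  if (!is.null(upper)) net$reactions$upper_bound[idx] <- upper
  if (any(net$reactions$lower_bound[idx] > net$reactions$upper_bound[idx]))
    stop("lower_bound > upper_bound after update")
  net
}
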
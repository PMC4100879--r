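#' Read a metabolic network
#'
#' Two formats are supported: the package's native tab-separated reaction
#' table, and SBML (COBRA-style Level 2 with kinetic-law bound parameters, or
#' Level 3 with the `fbc` extension).
#'
#' The native format has one reaction per row with columns `reaction_id`,
#' `equation`, `lower_bound`, `upper_bound`, `gpr`, `subsystem`.  Equations
#' look like `1 A[c] + 1 B[c] -> 1 C[e]`; `<=>` marks a reversible reaction
#' and one side may be empty for boundary (exchange) reactions.  Metabolite
#' tokens carry the compartment as a bracketed suffix (`[c]`, `[e]`, ...) and
#' optionally a second bracketed tissue tag (`glc[c][Adp]`).
#'
#' @param path file to read.
#' @param format `"table"` (native) or `"sbml"`.
#' @param ... passed to the format-specific reader.
#' @return a [metabolic_network()].
#' @export
read_network <- function(path, format = c("table", "sbml"), ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         table = read_network_table(path, ...),
         sbml = read_sbml(path, ...))
}

parse_equation <- function(eq, reaction_id) {
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>" else
    if (grepl("->", eq, fixed = TRUE)) "->" else
      stop("parse error in reaction '", reaction_id,
           "': equation has no '->' or '<=>' arrow: ", eq)
  sides <- stringr::str_split_fixed(eq, stringr::fixed(arrow), 2)
  parse_side <- function(side, sign) {
    side <- stringr::str_trim(side)
    if (side == "") return(NULL)
    terms <- stringr::str_split(side, stringr::fixed(" + "))[[1]]
    m <- stringr::str_match(stringr::str_trim(terms),
                            "^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\s+(\\S.*)$")
    if (anyNA(m[, 1]))
      stop("parse error in reaction '", reaction_id, "': bad term(s): ",
           paste(terms[is.na(m[, 1])], collapse = ", "))
    tibble::tibble(metabolite_id = m[, 3],
                   coefficient = sign * as.numeric(m[, 2]))
  }
  list(reversible = arrow == "<=>",
       terms = dplyr::bind_rows(parse_side(sides[1], -1),
                                parse_side(sides[2], +1)))
}

parse_metabolite_token <- function(ids) {
  brackets <- stringr::str_match_all(ids, "\\[([^\\]]+)\\]")
  tibble::tibble(
    id = ids,
    name = stringr::str_replace(ids, "\\[.*$", ""),
    compartment = vapply(brackets, function(b)
      if (nrow(b)) b[1, 2] else "c", character(1)),
    tissue_tag = vapply(brackets, function(b)
      if (nrow(b) > 1) b[2, 2] else NA_character_, character(1)))
}

read_network_table <- function(path, name = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  needed <- c("reaction_id", "equation", "lower_bound", "upper_bound")
  if (!all(needed %in% names(tab)))
    stop("parse error: native table needs columns ",
         paste(needed, collapse = ", "))
  if (!"gpr" %in% names(tab)) tab$gpr <- ""
  if (!"subsystem" %in% names(tab)) tab$subsystem <- ""

  parsed <- purrr::map2(tab$equation, tab$reaction_id, parse_equation)
  stoich <- dplyr::bind_rows(purrr::map2(
    parsed, tab$reaction_id,
    function(p, id) dplyr::mutate(p$terms, reaction_id = id)))
  metabolites <- parse_metabolite_token(unique(stoich$metabolite_id))
  reactions <- tibble::tibble(
    id = tab$reaction_id,
    lower_bound = as.numeric(tab$lower_bound),
    upper_bound = as.numeric(tab$upper_bound),
    reversible = vapply(parsed, `[[`, logical(1), "reversible"),
    gpr = tab$gpr,
    subsystem = tab$subsystem)
  metabolic_network(reactions, metabolites, stoich, name = name)
}

format_num <- function(x) {
  out <- format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  out
}

#' Write a network in the native reaction-table format
#'
#' The output round-trips through [read_network()]: ids, bounds,
#' stoichiometry, GPR and subsystem are all preserved exactly.
#'
#' @param net a [metabolic_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  st <- split(net$stoichiometry, net$stoichiometry$reaction_id)
  eqs <- vapply(seq_len(n_reactions(net)), function(i) {
    r <- net$reactions[i, ]
    rows <- st[[r$id]]
    side <- function(sel) {
      if (is.null(rows) || !any(sel)) return("")
      paste(paste(format_num(abs(rows$coefficient[sel])),
                  rows$metabolite_id[sel]), collapse = " + ")
    }
    lhs <- side(!is.null(rows) & rows$coefficient < 0)
    rhs <- side(!is.null(rows) & rows$coefficient > 0)
    arrow <- if (r$reversible) "<=>" else "->"
    stringr::str_trim(paste(lhs, arrow, rhs))
  }, character(1))
  out <- data.frame(reaction_id = net$reactions$id,
                    equation = eqs,
                    lower_bound = format_num(net$reactions$lower_bound),
                    upper_bound = format_num(net$reactions$upper_bound),
                    gpr = net$reactions$gpr,
                    subsystem = net$reactions$subsystem)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Confidence tiers over a network's reactions
#'
#' Partitions the reaction set into the high (`C_h`), medium (`C_m`) and low
#' (`C_x`) evidence tiers that drive model extraction.  Any reaction not
#' listed as high or medium confidence falls into the low tier, so the three
#' sets are pairwise disjoint and jointly cover the network.
#'
#' @param net a [metabolic_network()].
#' @param high,medium character vectors of reaction ids.
#' @param low optional explicit low list (checked, then completed with every
#'   unlisted reaction).
#' @return an object of class `confidence_tiers`: a list with character
#'   vectors `high`, `medium`, `low`.
#' @export
confidence_tiers <- function(net, high = character(), medium = character(),
                             low = NULL) {
  all_ids <- net$reactions$id
  check <- function(x, what) {
    bad <- setdiff(x, all_ids)
    if (length(bad))
      stop(what, " tier lists unknown reaction(s): ",
           paste(bad, collapse = ", "))
    unique(x)
  }
  high <- check(high, "high")
  medium <- setdiff(check(medium, "medium"), high)
  if (length(intersect(high, medium)))
    stop("high and medium tiers overlap")
  rest <- setdiff(all_ids, c(high, medium))
  if (!is.null(low)) {
    low <- check(low, "low")
    overlap <- intersect(low, c(high, medium))
    if (length(overlap))
      stop("low tier overlaps high/medium: ", paste(overlap, collapse = ", "))
  }
  structure(list(high = high, medium = medium, low = rest),
            class = "confidence_tiers")
}

#' @export
print.confidence_tiers <- function(x, ...) {
  cat("<confidence_tiers> high:", length(x$high),
      " medium:", length(x$medium), " low:", length(x$low), "\n")
  invisible(x)
}

#' Read confidence tiers from one-id-per-line files
#'
#' @param net a [metabolic_network()].
#' @param high_path,medium_path,low_path text files with one reaction id per
#'   line; `low_path` may be `NULL` (the low tier is always completed as the
#'   complement of high and medium).
#' @return a [confidence_tiers()] object.
#' @export
read_tiers <- function(net, high_path, medium_path, low_path = NULL) {
  read_ids <- function(p) {
    if (is.null(p)) return(NULL)
    x <- readLines(p, warn = FALSE)
    x[nzchar(stringr::str_trim(x))]
  }
  confidence_tiers(net,
                   high = read_ids(high_path) %||% character(),
                   medium = read_ids(medium_path) %||% character(),
                   low = read_ids(low_path))
}

#' Restrict tiers to a sub-network
#' @param tiers a [confidence_tiers()] object.
#' @param net the (sub-)network defining the reaction universe.
#' @return a [confidence_tiers()] on `net`'s reactions.
#' @export
restrict_tiers <- function(tiers, net) {
  confidence_tiers(net,
                   high = intersect(tiers$high, net$reactions$id),
                   medium = intersect(tiers$medium, net$reactions$id))
}
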
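#' Specification for a toy parallel-pathway network
#'
#' The generator used throughout the test suite: `n_pathways` linear
#' pathways share one extracellular compartment, each running uptake
#' exchange -> uptake transport -> `length` cytosolic conversions ->
#' secretion transport -> secretion exchange (so each pathway has
#' `length + 4` reactions and is flux-consistent by construction).  Each
#' enzymatic reaction carries a single dedicated gene unless an AND/OR motif
#' is requested, so gene-level and reaction-level perturbations coincide.
#'
#' @param n_pathways number of parallel pathways.
#' @param lengths cytosolic chain length per pathway (recycled); `NULL`
#'   draws lengths 1-3 at random.
#' @param tiers confidence tier per pathway (`"high"`, `"medium"`, `"low"`,
#'   `"mixed"`, recycled); `NULL` draws medium/low/mixed at random.  The tier
#'   applies to all reactions of the pathway, exchanges included, except
#'   `"mixed"`: chain reactions are medium but transports and exchanges are
#'   low, so keeping the pathway is worth `length - 2` score points — a real
#'   trade-off for the extraction objective.
#' @param planted optional named vector pathway-index -> `"up"`/`"down"`:
#'   the chain genes of those pathways become differentially expressed.
#' @param motif `NULL`, `"or"` or `"and"`: give the first chain reaction of
#'   pathway 1 a two-gene isozyme/complex rule.
#' @param seed integer seed (drawn quantities only; structure is
#'   deterministic given the arguments).
#' @return a list of class `toy_spec`.
#' @export
toy_spec <- function(n_pathways = 2, lengths = 2, tiers = c("medium", "low"),
                     planted = NULL, motif = NULL, seed = 1) {
  if (n_pathways < 1) stop("validation error: need at least one pathway")
  set.seed(seed)
  if (is.null(lengths)) lengths <- sample(1:3, n_pathways, replace = TRUE)
  lengths <- rep_len(lengths, n_pathways)
  if (any(lengths < 1))
    stop("validation error: pathway length must be >= 1")
  if (is.null(tiers))
    tiers <- sample(c("medium", "low", "mixed"), n_pathways, replace = TRUE)
  tiers <- rep_len(tiers, n_pathways)
  bad <- setdiff(tiers, c("high", "medium", "low", "mixed"))
  if (length(bad)) stop("unknown tier(s): ", paste(bad, collapse = ", "))
  structure(list(n_pathways = n_pathways, lengths = lengths, tiers = tiers,
                 planted = planted, motif = motif, seed = seed),
            class = "toy_spec")
}

#' Generate a toy network bundle with planted ground truth
#'
#' @param spec a [toy_spec()].
#' @return list with `network` (a [metabolic_network()]), `tiers`
#'   (a [confidence_tiers()]), `gene_map` (tibble `reaction_id`, `gene`),
#'   and `truth`: the planted facts — `kept_pathways` / `kept_reactions` /
#'   `optimal_score` for extraction (high pathways are forced, a non-high
#'   pathway is kept iff its tier score is positive), `planted_directions`,
#'   and `accumulating_metabolites` (substrates of planted-down pathways,
#'   which a downregulated catabolic chain stops draining from the shared
#'   extracellular pool).
#' @export
make_toy_network <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  rx <- list(); st <- list(); gm <- list()
  add_rxn <- function(id, eq_terms, lb, ub, rev, gene, subsystem) {
    rx[[length(rx) + 1]] <<- tibble::tibble(
      id = id, lower_bound = lb, upper_bound = ub, reversible = rev,
      gpr = gene, subsystem = subsystem)
    st[[length(st) + 1]] <<- dplyr::mutate(eq_terms, reaction_id = id)
    if (nzchar(gene))
      gm[[length(gm) + 1]] <<- tibble::tibble(reaction_id = id, gene = gene)
  }
  term <- function(met, coef) tibble::tibble(metabolite_id = met,
                                             coefficient = coef)
  for (p in seq_len(spec$n_pathways)) {
    L <- spec$lengths[p]
    sub_e <- sprintf("sub%d[e]", p); sub_c <- sprintf("sub%d[c]", p)
    prod_e <- sprintf("prod%d[e]", p); prod_c <- sprintf("prod%d[c]", p)
    chain_mets <- c(sub_c,
                    if (L > 1) sprintf("int%d_%d[c]", p, seq_len(L - 1)),
                    prod_c)
    add_rxn(sprintf("EX_U%d", p), term(sub_e, 1), 0, 1000, FALSE, "",
            "exchange")
    add_rxn(sprintf("T_U%d", p),
            dplyr::bind_rows(term(sub_e, -1), term(sub_c, 1)),
            0, 1000, FALSE, sprintf("gT%d", p),
            sprintf("pathway%d", p))
    for (j in seq_len(L)) {
      gene <- sprintf("g%d_%d", p, j)
      if (p == 1 && j == 1 && !is.null(spec$motif))
        gene <- if (spec$motif == "or") "g1_1a or g1_1b" else
          "g1_1a and g1_1b"
      add_rxn(sprintf("C%d_%d", p, j),
              dplyr::bind_rows(term(chain_mets[j], -1),
                               term(chain_mets[j + 1], 1)),
              0, 1000, FALSE, gene, sprintf("pathway%d", p))
    }
    add_rxn(sprintf("T_S%d", p),
            dplyr::bind_rows(term(prod_c, -1), term(prod_e, 1)),
            0, 1000, FALSE, sprintf("gS%d", p), sprintf("pathway%d", p))
    add_rxn(sprintf("EX_S%d", p), term(prod_e, -1), 0, 1000, FALSE, "",
            "exchange")
  }
  stoich <- dplyr::bind_rows(st)
  metabolites <- parse_metabolite_token(unique(stoich$metabolite_id))
  reactions <- dplyr::bind_rows(rx)
  net <- metabolic_network(reactions, metabolites, stoich,
                           name = sprintf("toy_%dpw_seed%d",
                                          spec$n_pathways, spec$seed))
  gene_map <- dplyr::bind_rows(gm)

  pathway_of <- function(ids) as.integer(stringr::str_match(
    ids, "(?:EX_U|EX_S|T_U|T_S|C)(\\d+)")[, 2])
  pw <- pathway_of(net$reactions$id)
  is_chain <- grepl("^C\\d+_", net$reactions$id)
  tiers <- confidence_tiers(
    net,
    high = net$reactions$id[spec$tiers[pw] == "high"],
    medium = net$reactions$id[spec$tiers[pw] == "medium" |
                                (spec$tiers[pw] == "mixed" & is_chain)])

  sizes <- spec$lengths + 4L
  pw_score <- dplyr::case_when(spec$tiers == "medium" ~ as.numeric(sizes),
                               spec$tiers == "low" ~ -0.5 * sizes,
                               spec$tiers == "mixed" ~ spec$lengths - 2,
                               TRUE ~ 0)
  keep <- spec$tiers == "high" | pw_score > 0
  kept_reactions <- net$reactions$id[keep[pw]]
  planted_dirs <- NULL
  accumulating <- character()
  if (!is.null(spec$planted)) {
    pidx <- as.integer(names(spec$planted))
    planted_dirs <- unlist(lapply(seq_along(pidx), function(i) {
      genes <- gene_map$gene[pathway_of(gene_map$reaction_id) == pidx[i] &
                               grepl("^g\\d+_", gene_map$gene)]
      stats::setNames(rep(spec$planted[[i]], length(genes)), genes)
    }))
    accumulating <- sprintf("sub%d", pidx[spec$planted == "down"])
  }
  list(network = net, tiers = tiers, gene_map = gene_map,
       truth = list(kept_pathways = which(keep),
                    kept_reactions = kept_reactions,
                    optimal_score = sum(pw_score[keep]),
                    pathway_of = stats::setNames(pw, net$reactions$id),
                    planted_directions = planted_dirs,
                    accumulating_metabolites = accumulating))
}

#' Generate a synthetic differential-expression table with planted signal
#'
#' Planted genes get significant records (`p < 0.05`, |fold change| > 1.5)
#' with the planted sign; noise genes get sub-threshold records that
#' [filter_fold_changes()] removes, emulating the structure (not the
#' intensity distribution) of a filtered microarray DE table.
#'
#' @param gene_map tibble with a `gene` column (the model's gene universe).
#' @param planted named vector gene -> `"up"`/`"down"`.
#' @param n_noise_genes how many sub-threshold noise records to add.
#' @param seed integer seed.
#' @return tibble with `gene_id`, `log2_fold_change`, `p_value`, `direction`.
#' @export
synthetic_expression <- function(gene_map, planted, n_noise_genes = 0,
                                 seed = 1) {
  bad <- setdiff(names(planted), gene_map$gene)
  if (length(bad))
    stop("planted gene(s) not in the gene map: ", paste(bad, collapse = ", "))
  set.seed(seed)
  sign <- ifelse(planted == "up", 1, -1)
  planted_tab <- tibble::tibble(
    gene_id = names(planted),
    log2_fold_change = sign * (log2(1.5) + abs(stats::rnorm(length(planted),
                                                            0.5, 0.2))),
    p_value = stats::runif(length(planted), 0.001, 0.049))
  noise_tab <- if (n_noise_genes > 0) {
    weak_fc <- stats::runif(n_noise_genes, -0.9, 0.9) * log2(1.5)
    high_p <- stats::runif(n_noise_genes, 0.05, 0.99)
    tibble::tibble(
      gene_id = sprintf("noise%d", seq_len(n_noise_genes)),
      log2_fold_change = ifelse(seq_len(n_noise_genes) %% 2 == 0,
                                weak_fc,
                                stats::rnorm(n_noise_genes, 0, 2)),
      p_value = ifelse(seq_len(n_noise_genes) %% 2 == 0,
                       stats::runif(n_noise_genes, 0.001, 0.99),
                       high_p))
  } else NULL
  # even-index noise is insignificant by fold change, odd-index by p-value
  out <- dplyr::bind_rows(planted_tab, noise_tab)
  dplyr::mutate(out,
                direction = ifelse(.data$log2_fold_change >= 0, "up", "down"))
}

#' Write a complete runnable toy bundle to disk
#'
#' Emits the native network table, the three tier files, a gene fold-change
#' table for any planted perturbation, and the disorder panel, so every
#' command-line subcommand has ready inputs.
#'
#' @param spec a [toy_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
write_fixture_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- make_toy_network(spec)
  paths <- list(
    network = file.path(dir, "network.tsv"),
    high = file.path(dir, "tiers_high.txt"),
    medium = file.path(dir, "tiers_medium.txt"),
    low = file.path(dir, "tiers_low.txt"),
    expression = file.path(dir, "fold_changes.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_network(bundle$network, paths$network)
  writeLines(bundle$tiers$high, paths$high)
  writeLines(bundle$tiers$medium, paths$medium)
  writeLines(bundle$tiers$low, paths$low)
  expr <- if (!is.null(bundle$truth$planted_directions))
    synthetic_expression(bundle$gene_map, bundle$truth$planted_directions,
                         seed = spec$seed)
  else synthetic_expression(bundle$gene_map, character(), seed = spec$seed)
  utils::write.table(expr, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    tibble::tibble(kept_reaction = bundle$truth$kept_reactions),
    paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
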
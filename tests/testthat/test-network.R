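test_that("native table reader preserves counts, bounds, GPR and roles", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "reaction_id\tequation\tlower_bound\tupper_bound\tgpr\tsubsystem",
    "EX_A\t1 A[e] <=>\t-1000\t1000\t\texchange",
    "T_A\t1 A[e] -> 1 A[c]\t0\t1000\tg1\tuptake",
    "R1\t1 A[c] -> 2 B[c]\t0\t500\tg2 and g3\tcore",
    "EX_B\t-> 1 B[e]\t0\t10\t\texchange"), f)
  net <- read_network(f)
  expect_equal(n_reactions(net), 4)
  expect_equal(n_metabolites(net), 3 + 1)  # A[e], A[c], B[c], B[e]
  r1 <- net$reactions[net$reactions$id == "R1", ]
  expect_equal(r1$upper_bound, 500)
  expect_false(r1$reversible)
  expect_equal(r1$gpr, "g2 and g3")
  expect_true(net$reactions$reversible[net$reactions$id == "EX_A"])
  expect_true(net$reactions$is_exchange[net$reactions$id == "EX_A"])
  expect_true(net$reactions$is_exchange[net$reactions$id == "EX_B"])
  expect_true(net$reactions$is_transport[net$reactions$id == "T_A"])
  expect_false(net$reactions$is_transport[net$reactions$id == "R1"])
  S <- stoich_matrix(net)
  expect_equal(S["B[c]", "R1"], 2)
  expect_equal(S["A[c]", "R1"], -1)
})

test_that("undeclared metabolites and malformed equations raise parse errors", {
  expect_error(
    metabolic_network(
      reactions = tibble::tibble(id = "r", lower_bound = 0, upper_bound = 1),
      metabolites = tibble::tibble(id = "A[c]", name = "A",
                                   compartment = "c"),
      stoichiometry = tibble::tibble(reaction_id = "r",
                                     metabolite_id = "GHOST[c]",
                                     coefficient = 1)),
    "integrity error.*GHOST")
  f <- tempfile()
  writeLines(c("reaction_id\tequation\tlower_bound\tupper_bound",
               "r1\t1 A[c] 1 B[c]\t0\t1"), f)
  expect_error(read_network(f), "parse error")
  expect_error(read_network(tempfile()), "not found")
  expect_error(
    metabolic_network(
      reactions = tibble::tibble(id = "r", lower_bound = 2, upper_bound = 1),
      metabolites = tibble::tibble(id = "A[c]", name = "A",
                                   compartment = "c"),
      stoichiometry = tibble::tibble(reaction_id = "r",
                                     metabolite_id = "A[c]",
                                     coefficient = 1)),
    "lower_bound > upper_bound")
})

test_that("native write/read round trip is bit-identical", {
  bundle <- make_toy_network(toy_spec(n_pathways = 3, lengths = c(1, 2, 3),
                                      tiers = c("high", "medium", "low"),
                                      seed = 5))
  f1 <- tempfile(); f2 <- tempfile()
  write_network(bundle$network, f1)
  net2 <- read_network(f1)
  write_network(net2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(stoich_matrix(net2), stoich_matrix(bundle$network))
  expect_equal(net2$reactions$lower_bound, bundle$network$reactions$lower_bound)
})

test_that("SBML round trip preserves structure, bounds, GPR and subsystems", {
  bundle <- make_toy_network(toy_spec(n_pathways = 2, lengths = c(2, 1),
                                      motif = "or", seed = 3))
  f <- tempfile(fileext = ".xml")
  write_sbml(bundle$network, f)
  net2 <- read_network(f, format = "sbml")
  orig <- bundle$network
  expect_setequal(net2$reactions$id, orig$reactions$id)
  expect_setequal(net2$metabolites$id, orig$metabolites$id)
  m <- match(orig$reactions$id, net2$reactions$id)
  expect_equal(net2$reactions$lower_bound[m], orig$reactions$lower_bound)
  expect_equal(net2$reactions$upper_bound[m], orig$reactions$upper_bound)
  expect_equal(net2$reactions$gpr[m], orig$reactions$gpr)
  expect_equal(net2$reactions$subsystem[m], orig$reactions$subsystem)
  expect_equal(stoich_matrix(net2)[orig$metabolites$id, orig$reactions$id],
               stoich_matrix(orig))
})

test_that("dead-end pruning removes cascades, keeps consistent networks, and is idempotent", {
  # no dead ends: unchanged
  full <- make_toy_network(toy_spec(1, lengths = 2, tiers = "medium"))$network
  expect_equal(remove_dead_ends(full)$reactions$id, full$reactions$id)

  # A -> B -> C with no exit for C: C is dead, removal cascades to everything
  pruned <- remove_dead_ends(no_exit_chain())
  expect_equal(n_reactions(pruned), 0)

  # idempotence on a partially prunable network
  mixed <- metabolic_network(
    reactions = dplyr::bind_rows(
      full$reactions,
      tibble::tibble(id = "ORPHAN", lower_bound = 0, upper_bound = 10,
                     reversible = FALSE, gpr = "", subsystem = "")),
    metabolites = dplyr::bind_rows(
      full$metabolites,
      tibble::tibble(id = "X[c]", name = "X", compartment = "c",
                     tissue_tag = NA_character_)),
    stoichiometry = dplyr::bind_rows(
      full$stoichiometry,
      tibble::tibble(reaction_id = "ORPHAN", metabolite_id = "X[c]",
                     coefficient = 1)))
  once <- remove_dead_ends(mixed)
  twice <- remove_dead_ends(once)
  expect_false("ORPHAN" %in% once$reactions$id)
  expect_identical(once$reactions$id, twice$reactions$id)

  # a reversible sink counts as both producer and consumer
  rev_chain <- metabolic_network(
    reactions = tibble::tibble(id = c("EX_A", "R_AB", "EX_B"),
                               lower_bound = c(0, 0, -1000),
                               upper_bound = 1000),
    metabolites = tibble::tibble(id = c("A[e]", "B[e]"), name = c("A", "B"),
                                 compartment = "e"),
    stoichiometry = tibble::tibble(
      reaction_id = c("EX_A", "R_AB", "R_AB", "EX_B"),
      metabolite_id = c("A[e]", "A[e]", "B[e]", "B[e]"),
      coefficient = c(1, -1, 1, -1)))
  expect_equal(n_reactions(remove_dead_ends(rev_chain)), 3)
})

test_that("tissue expansion shares the extracellular compartment and counts add up", {
  bundle <- make_toy_network(toy_spec(1, lengths = 1, tiers = "medium"))
  net <- bundle$network  # 5 reactions: 2 exchange (extracellular-only) + 3
  ex <- expand_to_tissues(net)
  i <- sum(!vapply(split(net$stoichiometry$metabolite_id,
                         net$stoichiometry$reaction_id)[net$reactions$id],
                   function(m) all(grepl("\\[e\\]", m)), logical(1)))
  e <- n_reactions(net) - i
  expect_equal(n_reactions(ex), 3 * i + e)
  # extracellular metabolites shared, no tissue tag
  expect_true(all(is.na(ex$metabolites$tissue_tag[
    ex$metabolites$compartment == "e"])))
  expect_setequal(unique(stats::na.omit(ex$metabolites$tissue_tag)),
                  c("Adp", "Hep", "Msc"))
  expect_setequal(unique(stats::na.omit(ex$reactions$tissue_tag)),
                  c("A", "H", "M"))
  # exchange reactions appear exactly once
  expect_equal(sum(ex$reactions$is_exchange), sum(net$reactions$is_exchange))

  # single tissue: isomorphic to input up to renaming
  one <- expand_to_tissues(net, tibble::tibble(prefix = "A", suffix = "Adp"))
  expect_equal(n_reactions(one), n_reactions(net))
  expect_equal(n_metabolites(one), n_metabolites(net))

  # steady-state feasibility is preserved: the expanded model still carries
  # flux through every tissue copy
  expect_length(find_blocked(ex), 0)

  expect_error(expand_to_tissues(net, tibble::tibble(prefix = character(),
                                                     suffix = character())),
               "non-empty")
})

test_that("tier files load with low as the complement", {
  bundle <- make_toy_network(toy_spec(2, lengths = 1,
                                      tiers = c("high", "medium")))
  net <- bundle$network
  fh <- tempfile(); fm <- tempfile()
  writeLines(bundle$tiers$high, fh)
  writeLines(bundle$tiers$medium, fm)
  tiers <- read_tiers(net, fh, fm)
  expect_setequal(tiers$high, bundle$tiers$high)
  expect_setequal(tiers$medium, bundle$tiers$medium)
  expect_setequal(c(tiers$high, tiers$medium, tiers$low), net$reactions$id)
  expect_length(intersect(tiers$high, tiers$medium), 0)
  writeLines(c(bundle$tiers$high, "NOT_A_REACTION"), fh)
  expect_error(read_tiers(net, fh, fm), "unknown reaction")
})
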
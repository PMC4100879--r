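test_that("probe-level records collapse by majority and GPRs arbitrate distinct genes", {
  net <- branch_net()
  # 2 up + 1 down records on the same gene id: majority up
  fc <- tibble::tibble(gene_id = c("gCAT", "gCAT", "gCAT"),
                       direction = c("up", "up", "down"))
  st <- reaction_status(net, fc)
  expect_equal(st$status[st$reaction_id == "CAT"], "up")
  # tie -> unchanged
  fc2 <- tibble::tibble(gene_id = c("gCAT", "gCAT"),
                        direction = c("up", "down"))
  expect_equal(reaction_status(net, fc2)$status[st$reaction_id == "CAT"],
               "unchanged")
  # distinct genes through GPR logic: AND takes the restrictive branch
  net$reactions$gpr[net$reactions$id == "CAT"] <- "g_up and g_dn"
  net$reactions$gpr[net$reactions$id == "ALT"] <- "g_up or g_dn"
  fc3 <- tibble::tibble(gene_id = c("g_up", "g_dn"),
                        direction = c("up", "down"))
  st3 <- reaction_status(net, fc3)
  expect_equal(st3$status[st3$reaction_id == "CAT"], "down")
  expect_equal(st3$status[st3$reaction_id == "ALT"], "up")
  # no mapped differential gene -> unchanged
  expect_equal(st3$status[st3$reaction_id == "T_W"], "unchanged")
})

test_that("the bound protocol sets 100/1000 magnitudes, doubles up, halves down", {
  f <- tempfile()
  writeLines(c(
    "reaction_id\tequation\tlower_bound\tupper_bound\tgpr\tsubsystem",
    "EX_A\t-> 1 A[e]\t0\t1000\t\texchange",
    "T_A\t1 A[e] -> 1 A[c]\t0\t1000\tgt\ts",
    "UPREV\t1 A[c] <=> 1 B[c]\t-1000\t1000\tgu\ts",
    "DNIRR\t1 B[c] -> 1 C[e]\t0\t1000\tgd\ts",
    "OTHER\t1 B[c] -> 1 D[e]\t0\t1000\tgo\ts",
    "EX_C\t1 C[e] ->\t0\t1000\t\texchange",
    "EX_D\t1 D[e] ->\t0\t1000\t\texchange"), f)
  net <- read_network(f)
  st <- tibble::tibble(reaction_id = c("UPREV", "DNIRR"),
                       status = c("up", "down"))
  nets <- perturb_bounds(net, st)
  ctrl <- nets$control$reactions
  dis <- nets$disease$reactions
  bounds_of <- function(tab, id)
    c(tab$lower_bound[tab$id == id], tab$upper_bound[tab$id == id])
  expect_equal(bounds_of(ctrl, "UPREV"), c(-100, 100))
  expect_equal(bounds_of(dis, "UPREV"), c(-200, 200))
  expect_equal(bounds_of(ctrl, "DNIRR"), c(0, 100))
  expect_equal(bounds_of(dis, "DNIRR"), c(0, 50))
  expect_equal(bounds_of(ctrl, "OTHER"), c(0, 1000))
  expect_equal(bounds_of(dis, "OTHER"), c(0, 1000))
  for (ex in c("EX_A", "EX_C", "EX_D")) {
    expect_equal(bounds_of(ctrl, ex), c(1, 1000))
    expect_equal(bounds_of(dis, ex), c(1, 1000))
  }
  # exploratory switch relaxes the forced exchange secretion
  relaxed <- perturb_bounds(net, st, exchange_lb = 0)
  expect_equal(bounds_of(relaxed$control$reactions, "EX_A"), c(0, 1000))
})

test_that("direction calls flow from FVA differences; unchanged statuses give no calls", {
  bundle <- make_toy_network(toy_spec(2, lengths = c(3, 2),
                                      planted = c("1" = "down"), seed = 4))
  net <- bundle$network
  none <- reaction_status(net, tibble::tibble(gene_id = character(),
                                              direction = character()))
  nets0 <- perturb_bounds(net, none)
  calls0 <- call_flux_directions(nets0$control, nets0$disease, "all", 0.01,
                                 per_metabolite = FALSE)
  expect_true(all(calls0$call == "unchanged"))
  expect_true(all(abs(calls0$delta) < 1e-9))

  # planted downregulated catabolism: the substrate's transport flux drops
  # (less uptake from the shared extracellular pool = accumulation)
  fc <- synthetic_expression(bundle$gene_map,
                             bundle$truth$planted_directions, seed = 4)
  st <- reaction_status(net, filter_fold_changes(fc))
  nets <- perturb_bounds(net, st)
  tcalls <- call_flux_directions(nets$control, nets$disease, "transport", 0.1)
  v <- tcalls[tcalls$metabolite == "sub1", ]
  expect_lt(v$delta, 0)
  expect_equal(v$call, "decreased")
  # the untouched pathway's substrate stays unchanged
  expect_equal(tcalls$call[tcalls$metabolite == "sub2"], "unchanged")
})

test_that("scaling all bounds by a common factor leaves every call unchanged", {
  bundle <- make_toy_network(toy_spec(2, lengths = 2,
                                      planted = c("1" = "down"), seed = 6))
  net <- bundle$network
  fc <- synthetic_expression(bundle$gene_map,
                             bundle$truth$planted_directions, seed = 6)
  st <- reaction_status(net, fc)
  nets <- perturb_bounds(net, st)
  scale_net <- function(n, f) {
    n$reactions$lower_bound <- n$reactions$lower_bound * f
    n$reactions$upper_bound <- n$reactions$upper_bound * f
    n
  }
  c1 <- call_flux_directions(nets$control, nets$disease, "all", 0.1,
                             per_metabolite = FALSE)
  c2 <- call_flux_directions(scale_net(nets$control, 3),
                             scale_net(nets$disease, 3), "all", 0.1,
                             per_metabolite = FALSE)
  expect_equal(c2$delta, c1$delta, tolerance = 1e-8)
  expect_identical(c2$call, c1$call)
})

test_that("balanced regulation statuses still yield more down than up calls", {
  # every pathway holds two affected reactions; one down anywhere caps the
  # whole chain, while an increase needs both affected reactions up
  hits <- 0L
  for (seed in 1:50) {
    set.seed(seed)
    bundle <- make_toy_network(toy_spec(4, lengths = 2, seed = seed))
    net <- bundle$network
    chain_genes <- bundle$gene_map$gene[grepl("^g\\d", bundle$gene_map$gene)]
    dirs <- stats::setNames(sample(rep(c("up", "down"),
                                       length.out = length(chain_genes))),
                            chain_genes)
    st <- reaction_status(net, tibble::tibble(gene_id = names(dirs),
                                              direction = unname(dirs)))
    nets <- perturb_bounds(net, st)
    calls <- call_flux_directions(nets$control, nets$disease, "all", 0.05,
                                  per_metabolite = FALSE)
    if (sum(calls$call == "decreased") >= sum(calls$call == "increased"))
      hits <- hits + 1L
  }
  expect_gte(hits, 40L)
})

test_that("subsystem t-scores separate coherent regulation from chance", {
  net <- make_toy_network(toy_spec(1, lengths = 28, seed = 2))$network
  # 30 enzymatic reactions in the pathway subsystem, all down
  calls <- tibble::tibble(
    reaction_id = net$reactions$id,
    call = ifelse(net$reactions$subsystem == "pathway1", "decreased",
                  "unchanged"))
  ts <- subsystem_tscores(calls, net, seed = 3)
  big <- ts[ts$subsystem == "pathway1", ]
  expect_equal(big$n_reactions, 30)
  expect_equal(big$n_down, 30)
  expect_lt(big$t_score, -5)

  # a tiny all-down subsystem cannot reach a large |t|
  net2 <- make_toy_network(toy_spec(2, lengths = c(28, 1), seed = 2))$network
  calls2 <- tibble::tibble(
    reaction_id = net2$reactions$id,
    call = ifelse(net2$reactions$subsystem == "pathway2", "decreased",
                  "unchanged"))
  ts2 <- subsystem_tscores(calls2, net2, seed = 3)
  small <- ts2[ts2$subsystem == "pathway2", ]
  expect_equal(small$n_reactions, 3)
  expect_true(is.na(small$t_score) || abs(small$t_score) < 5)

  # symmetric coding: equal up/down counts sit near zero
  net3 <- make_toy_network(toy_spec(1, lengths = 28, seed = 2))$network
  idx <- net3$reactions$subsystem == "pathway1"
  calls3 <- tibble::tibble(
    reaction_id = net3$reactions$id,
    call = "unchanged")
  calls3$call[idx] <- rep(c("increased", "decreased"), length.out = sum(idx))
  ts3 <- subsystem_tscores(calls3, net3, seed = 3)
  expect_lt(abs(ts3$t_score[ts3$subsystem == "pathway1"]), 2)

  # t-score sign tracks the up/down balance for sizeable subsystems with no
  # unchanged calls (20 up vs 10 down across 5 selector draws)
  calls4 <- calls3
  calls4$call[idx] <- c(rep("increased", 20), rep("decreased", 10))
  agree <- sum(vapply(1:5, function(seed) {
    ts4 <- subsystem_tscores(dplyr::filter(calls4, idx), net3, seed = seed)
    sign(ts4$t_score[ts4$subsystem == "pathway1"]) == 1
  }, logical(1)))
  expect_gte(agree, 4)
})
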
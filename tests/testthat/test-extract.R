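test_that("random objectives stay on the high/medium tiers and are seed-deterministic", {
  bundle <- make_toy_network(toy_spec(3, lengths = 1,
                                      tiers = c("high", "medium", "low")))
  net <- bundle$network; tiers <- bundle$tiers
  set.seed(42)
  draws <- replicate(50, names(random_objective(net, tiers, k = 3)),
                     simplify = FALSE)
  expect_true(all(vapply(draws, function(d)
    length(intersect(d, tiers$low)) == 0, logical(1))))
  expect_true(all(vapply(draws, length, integer(1)) == 3))
  set.seed(7); a <- replicate(5, random_objective(net, tiers), simplify = FALSE)
  set.seed(7); b <- replicate(5, random_objective(net, tiers), simplify = FALSE)
  expect_identical(a, b)

  # the only possible draw with a 2-reaction pool
  t2 <- confidence_tiers(net, high = "C1_1", medium = "C2_1")
  expect_setequal(names(random_objective(net, t2, k = 2)), c("C1_1", "C2_1"))

  empty_pool <- confidence_tiers(net, high = character(), medium = character())
  expect_error(random_objective(net, empty_pool), "configuration error")
})

test_that("the flux-distribution matrix records LP activity patterns", {
  bundle <- make_toy_network(toy_spec(1, lengths = 1, tiers = "medium"))
  net <- bundle$network
  fdm <- build_fd_matrix(net, bundle$tiers, n_columns = 20, seed = 1)
  # a single linear pathway has one elementary mode: all-or-nothing activity
  expect_true(all(colSums(fdm$activity) %in% c(0L, n_reactions(net))))
  expect_equal(ncol(fdm$activity), 20)
  expect_setequal(rownames(fdm$activity), net$reactions$id)
  expect_error(build_fd_matrix(net, bundle$tiers, n_columns = 0),
               "configuration error")
  f1 <- build_fd_matrix(net, bundle$tiers, n_columns = 10, seed = 9)
  f2 <- build_fd_matrix(net, bundle$tiers, n_columns = 10, seed = 9)
  expect_identical(f1$activity, f2$activity)
})

test_that("column scoring applies the medium-minus-half-low formula", {
  col <- c(m1 = TRUE, m2 = TRUE, m3 = TRUE,
           l1 = TRUE, l2 = TRUE, l3 = TRUE, l4 = TRUE, x = FALSE)
  expect_equal(score_column(col, paste0("m", 1:3), paste0("l", 1:4)), 1.0)
  expect_equal(score_column(col[col == FALSE], paste0("m", 1:3),
                            paste0("l", 1:4)), 0)
  expect_equal(score_column(col, paste0("m", 1:3), paste0("l", 1:4),
                            low_weight = 1), -1)
})

test_that("high-confidence coverage picks best columns and zeroes added rows", {
  bundle <- make_toy_network(toy_spec(2, lengths = 1,
                                      tiers = c("high", "high")))
  net <- bundle$network; tiers <- bundle$tiers
  fdm <- build_fd_matrix(net, tiers, n_columns = 50, seed = 2)
  state <- mcltissue:::new_extraction_state(tiers)
  state <- cover_high_confidence(state, fdm, net = net)
  expect_length(state$remaining_high, 0)
  expect_setequal(state$final_reactions, net$reactions$id)

  # hand-built matrix with one column per disjoint pathway: both selected
  ids <- net$reactions$id
  pw1 <- grepl("1$", ids)
  act <- cbind(pw1, !pw1)
  rownames(act) <- ids
  fdm2 <- structure(list(activity = act), class = "fd_matrix")
  state2 <- mcltissue:::new_extraction_state(tiers)
  state2 <- cover_high_confidence(state2, fdm2)
  expect_setequal(state2$final_reactions, ids)
  expect_equal(nrow(state2$log), 2)

  # an uncoverable high reaction fails with its id in the message
  cut <- subnetwork(net, setdiff(net$reactions$id, "EX_S1"))
  tiers_cut <- restrict_tiers(tiers, cut)
  fdm_cut <- build_fd_matrix(cut, tiers_cut, n_columns = 20, seed = 2)
  state2 <- mcltissue:::new_extraction_state(tiers_cut)
  expect_error(cover_high_confidence(state2, fdm_cut, net = cut), "C1_1")
})

test_that("positive-score growth stops exactly at non-positive best score", {
  bundle <- make_toy_network(toy_spec(2, lengths = c(2, 1),
                                      tiers = c("medium", "low")))
  net <- bundle$network; tiers <- bundle$tiers
  fdm <- build_fd_matrix(net, tiers, n_columns = 100, seed = 3)
  state <- mcltissue:::new_extraction_state(tiers)
  grown <- grow_positive_score(state, fdm)
  # medium pathway (score 6) added; low pathway (score -2.5) never added
  expect_setequal(grown$final_reactions,
                  bundle$truth$kept_reactions)
  again <- grow_positive_score(grown, fdm)
  expect_identical(again$final_reactions, grown$final_reactions)
})

test_that("extraction returns the whole consistent network when all reactions are high", {
  bundle <- make_toy_network(toy_spec(2, lengths = 1, tiers = "high"))
  res <- extract_mcl(bundle$network, bundle$tiers, n_columns = 50, seed = 1)
  expect_setequal(res$reaction_ids, bundle$network$reactions$id)
})

test_that("extraction attains the brute-force optimum on crafted toy tiers", {
  # medium chain with low-confidence plumbing vs an all-low pathway:
  # keeping the mixed pathway is worth +1, the low pathway never pays
  for (seed in 1:3) {
    bundle <- make_toy_network(toy_spec(2, lengths = c(3, 2),
                                        tiers = c("mixed", "low"),
                                        seed = seed))
    res <- extract_mcl(bundle$network, bundle$tiers, n_columns = 300,
                       seed = seed)
    want <- oracle_extraction(bundle$network, bundle$tiers)
    expect_equal(res$objective_score, want$score, info = paste("seed", seed))
    expect_setequal(res$reaction_ids, want$reactions)
  }

  # boundary case: a zero-score pathway is not worth adding; the optimum is
  # the empty model and the greedy loop agrees
  b0 <- make_toy_network(toy_spec(2, lengths = c(2, 2),
                                  tiers = c("mixed", "low"), seed = 1))
  res0 <- extract_mcl(b0$network, b0$tiers, n_columns = 200, seed = 1)
  want0 <- oracle_extraction(b0$network, b0$tiers)
  expect_equal(want0$score, 0)
  expect_equal(res0$objective_score, 0)
  expect_length(res0$reaction_ids, 0)
})

test_that("extraction is seed-deterministic and robust across seeds", {
  bundle <- make_toy_network(toy_spec(3, lengths = c(1, 2, 1),
                                      tiers = c("high", "medium", "low")))
  a <- extract_mcl(bundle$network, bundle$tiers, n_columns = 150, seed = 11)
  b <- extract_mcl(bundle$network, bundle$tiers, n_columns = 150, seed = 11)
  expect_identical(sort(a$reaction_ids), sort(b$reaction_ids))

  sizes <- vapply(1:5, function(s)
    n_reactions(extract_mcl(bundle$network, bundle$tiers, n_columns = 150,
                            seed = s)$network), integer(1))
  expect_true(all(abs(sizes - mean(sizes)) <= 0.1 * mean(sizes) + 1e-9))

  # every high reaction present and able to carry flux in the output
  out <- extract_mcl(bundle$network, bundle$tiers, n_columns = 150,
                     seed = 2)$network
  expect_true(all(bundle$tiers$high %in% out$reactions$id))
  expect_length(intersect(find_blocked(out), bundle$tiers$high), 0)

  # per-iteration model sizes never grow across outer iterations
  hist <- extract_mcl(bundle$network, bundle$tiers, n_columns = 150,
                      seed = 4)$history
  expect_true(all(diff(hist$n_reactions) <= 0))
})

test_that("tidiers summarise extraction runs", {
  bundle <- make_toy_network(toy_spec(2, lengths = 1,
                                      tiers = c("high", "medium")))
  res <- extract_mcl(bundle$network, bundle$tiers, n_columns = 50, seed = 1)
  td <- tidy(res)
  expect_true(all(c("iteration", "n_reactions", "n_metabolites") %in%
                    names(td)))
  gl <- glance(res)
  expect_equal(gl$n_reactions, n_reactions(res$network))
  expect_s3_class(autoplot(res), "ggplot")
})
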
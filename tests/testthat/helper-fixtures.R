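# small networks built in code, shared across test files

# EX_in (0..10) -> R1 (0..5) -> EX_out (0..1000): bottleneck chain
chain_net <- function() {
  metabolic_network(
    reactions = tibble::tibble(id = c("EX_in", "R1", "EX_out"),
                               lower_bound = 0,
                               upper_bound = c(10, 5, 1000)),
    metabolites = tibble::tibble(id = c("A[c]", "B[c]"), name = c("A", "B"),
                                 compartment = "c"),
    stoichiometry = tibble::tibble(
      reaction_id = c("EX_in", "R1", "R1", "EX_out"),
      metabolite_id = c("A[c]", "A[c]", "B[c]", "B[c]"),
      coefficient = c(1, -1, 1, -1)))
}

# two-reaction reversible internal loop A <-> B, no exchange (type III cycle)
loop_net <- function() {
  metabolic_network(
    reactions = tibble::tibble(id = c("F1", "F2"),
                               lower_bound = -1000, upper_bound = 1000),
    metabolites = tibble::tibble(id = c("A[c]", "B[c]"), name = c("A", "B"),
                                 compartment = "c"),
    stoichiometry = tibble::tibble(
      reaction_id = c("F1", "F1", "F2", "F2"),
      metabolite_id = c("A[c]", "B[c]", "B[c]", "A[c]"),
      coefficient = c(-1, 1, -1, 1)))
}

# linear A -> B -> C with uptake for A but no exit for C
no_exit_chain <- function() {
  metabolic_network(
    reactions = tibble::tibble(id = c("EX_A", "R_AB", "R_BC"),
                               lower_bound = 0, upper_bound = 1000),
    metabolites = tibble::tibble(id = c("A[c]", "B[c]", "C[c]"),
                                 name = c("A", "B", "C"), compartment = "c"),
    stoichiometry = tibble::tibble(
      reaction_id = c("EX_A", "R_AB", "R_AB", "R_BC", "R_BC"),
      metabolite_id = c("A[c]", "A[c]", "B[c]", "B[c]", "C[c]"),
      coefficient = c(1, -1, 1, -1, 1)))
}

# random bounded flux network for oracle comparisons; always feasible (0 in box)
random_net <- function(n, m, seed) {
  set.seed(seed)
  repeat {
    S <- matrix(sample(c(-2, -1, 0, 0, 1, 2), m * n, replace = TRUE), m, n)
    if (all(colSums(abs(S)) > 0)) break
  }
  lb <- ifelse(stats::runif(n) < 0.5, -sample(1:5, n, TRUE), 0)
  ub <- sample(1:5, n, TRUE)
  ids <- sprintf("r%d", seq_len(n))
  mets <- sprintf("m%d[c]", seq_len(m))
  nz <- which(S != 0, arr.ind = TRUE)
  metabolic_network(
    reactions = tibble::tibble(id = ids, lower_bound = lb, upper_bound = ub),
    metabolites = tibble::tibble(id = mets,
                                 name = sub("\\[c\\]$", "", mets),
                                 compartment = "c"),
    stoichiometry = tibble::tibble(reaction_id = ids[nz[, 2]],
                                   metabolite_id = mets[nz[, 1]],
                                   coefficient = S[nz]),
    name = sprintf("random_%d", seed))
}

# one-gene-per-reaction 8-reaction net for deletion studies: substrate S is
# either secreted directly or catabolized to P first
branch_net <- function() {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "reaction_id\tequation\tlower_bound\tupper_bound\tgpr\tsubsystem",
    "EX_S\t-> 1 S[e]\t0\t1000\t\texchange",
    "T_S\t1 S[e] -> 1 S[c]\t0\t1000\tgT\tuptake",
    "CAT\t1 S[c] -> 1 P[c]\t0\t1000\tgCAT\tcatabolism",
    "T_P\t1 P[c] -> 1 P[e]\t0\t1000\tgP\tsecretion",
    "EX_P\t1 P[e] ->\t0\t1000\t\texchange",
    "ALT\t1 S[c] -> 1 W[c]\t0\t1000\tgALT\talternate",
    "T_W\t1 W[c] -> 1 W[e]\t0\t1000\tgW\talternate",
    "EX_W\t1 W[e] ->\t0\t1000\t\texchange"), f)
  read_network(f)
}

# presentation rounding: half away from zero, as printed summary tables use
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
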
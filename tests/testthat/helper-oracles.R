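# independent oracles: vertex enumeration for FVA, exhaustive subset search
# for extraction.  Deliberately brute-force — they must not share code paths
# with the implementation they check.

# FVA by vertex enumeration of {v : S v = 0, lb <= v <= ub}.
# Every vertex fixes at least n - rank(S) variables at a bound; enumerate all
# such fixings, solve for the rest, keep feasible points.
oracle_fva <- function(net, tol = 1e-6) {
  S <- stoich_matrix(net)
  n <- ncol(S)
  l <- net$reactions$lower_bound
  u <- net$reactions$upper_bound
  r <- qr(S)$rank
  k <- n - r
  verts <- list()
  if (k == 0) {
    verts[[1]] <- numeric(n)
  } else {
    for (fix in utils::combn(n, k, simplify = FALSE)) {
      B <- setdiff(seq_len(n), fix)
      SB <- S[, B, drop = FALSE]
      if (qr(SB)$rank < length(B)) next
      for (sides in 0:(2^k - 1)) {
        at_ub <- bitwAnd(sides, 2^(seq_len(k) - 1)) > 0
        xF <- ifelse(at_ub, u[fix], l[fix])
        xB <- qr.solve(SB, -S[, fix, drop = FALSE] %*% xF)
        x <- numeric(n); x[fix] <- xF; x[B] <- xB
        if (max(abs(S %*% x)) > tol) next
        if (all(x >= l - tol & x <= u + tol))
          verts[[length(verts) + 1]] <- x
      }
    }
  }
  stopifnot(length(verts) > 0)
  V <- do.call(rbind, verts)
  tibble::tibble(reaction_id = net$reactions$id,
                 min_flux = apply(V, 2, min),
                 max_flux = apply(V, 2, max))
}

# exhaustive extraction optimum: best confidence score over all
# flux-consistent reaction subsets containing the whole high tier
oracle_extraction <- function(net, tiers, low_weight = 0.5) {
  ids <- net$reactions$id
  free <- setdiff(ids, tiers$high)
  stopifnot(length(free) <= 14)
  st <- net$stoichiometry
  lbv <- stats::setNames(net$reactions$lower_bound, ids)
  ubv <- stats::setNames(net$reactions$upper_bound, ids)
  prod_row <- (st$coefficient > 0 & ubv[st$reaction_id] > 1e-9) |
    (st$coefficient < 0 & lbv[st$reaction_id] < -1e-9)
  cons_row <- (st$coefficient < 0 & ubv[st$reaction_id] > 1e-9) |
    (st$coefficient > 0 & lbv[st$reaction_id] < -1e-9)
  bits <- 2^(seq_along(free) - 1)
  # with no high tier the empty model (score 0) is always admissible
  best <- if (length(tiers$high)) -Inf else 0
  best_set <- if (length(tiers$high)) NULL else character()
  for (mask in 0:(2^length(free) - 1)) {
    sel <- c(tiers$high, free[bitwAnd(mask, bits) > 0])
    if (!length(sel)) next
    keep <- st$reaction_id %in% sel
    touched <- unique(st$metabolite_id[keep])
    ok <- all(touched %in% st$metabolite_id[keep & prod_row]) &&
      all(touched %in% st$metabolite_id[keep & cons_row])
    if (!ok) next  # a dead-end metabolite blocks the subset
    if (length(find_blocked(subnetwork(net, sel))) > 0) next
    sc <- length(intersect(sel, tiers$medium)) -
      low_weight * length(intersect(sel, tiers$low))
    if (sc > best) { best <- sc; best_set <- sel }
  }
  list(score = best, reactions = best_set)
}
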
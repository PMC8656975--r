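# shared fixtures and brute-force oracles, all built in code

# every permutation of a vector (used for exhaustive Moran enumeration, n <= 6)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

# path graph a-b-c-...
path_graph <- function(n) {
  ids <- letters[seq_len(n)]
  adjacency_graph(ids, cbind(ids[-n], ids[-1]))
}

# single-stratum population/count tables on a given graph (all strata except
# one empty), handy for hand-arithmetic standardization oracles
one_stratum_tables <- function(tract_ids, n_pop, n_obs,
                               sex = "male", age = "40-64") {
  full <- expand.grid(tract_id = tract_ids, sex = carmap::sexes,
                      age_group = carmap::age_groups,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full$value <- 0L
  pop <- full
  sel <- pop$sex == sex & pop$age_group == age
  pop$value[sel] <- n_pop[match(pop$tract_id[sel], tract_ids)]
  cnt <- full
  cnt$value[sel] <- n_obs[match(cnt$tract_id[sel], tract_ids)]
  list(pop = pop, counts = cnt)
}

# small BYM-style simulated dataset aligned to graph order
sim_dataset <- function(graph, seed, tau_u = 1, tau_v = 10, mean_E = 8,
                        null_risk = FALSE) {
  theta <- if (null_risk) rep(1, graph$n) else
    make_risk_surface(graph, tau_u = tau_u, tau_v = tau_v, seed = seed)$theta
  set.seed(seed + 500L)
  E <- stats::runif(graph$n, 0.5 * mean_E, 1.5 * mean_E)
  O <- stats::rpois(graph$n, E * as.numeric(theta))
  list(O = O, E = E, theta = as.numeric(theta))
}

quiet_fit <- function(...) suppressWarnings(fit_car(...))
quiet_joint <- function(...) suppressWarnings(fit_shared_component(...))
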
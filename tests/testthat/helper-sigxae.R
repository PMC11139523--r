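# Shared fixtures: all test data is generated in code at run time.

# small, fast training profile for unit tests
fast_ctrl <- function(units = c(32, 16, 8), batch = 32, lr = 2e-3,
                      max_epochs = 80, patience = 10, ...) {
  xae_control(units = units, batch = batch, lr = lr, max_epochs = max_epochs,
              patience = min(patience, max(max_epochs - 1, 1)), ...)
}

# one-subcohort cohort with all k signatures active in every sample
tiny_cohort <- function(k = 3, m = 60, burden = 1500, sdlog = 0.3,
                        sig_seed = 11, sim_seed = 1,
                        max_pairwise_cosine = 0.6) {
  truth <- random_signatures(k, max_pairwise_cosine = max_pairwise_cosine,
                             seed = sig_seed)
  spec <- scenario_spec(list(list(name = "a", n = m, signatures = seq_len(k),
                                  prevalence = rep(1, k),
                                  weights = rep(1, k))),
                        burden_meanlog = log(burden), burden_sdlog = sdlog)
  sim <- simulate_cohort(spec, truth, seed = sim_seed)
  sim
}

# brute-force minimum assignment cost by permutation enumeration
brute_force_assignment <- function(cost) {
  k <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf
  best_p <- NULL
  for (p in perms(seq_len(k))) {
    s <- sum(cost[cbind(seq_len(k), p)])
    if (s < best) { best <- s; best_p <- p }
  }
  list(cost = best, perm = best_p)
}
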
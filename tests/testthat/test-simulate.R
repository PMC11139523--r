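test_that("random signature generation honours its constraints", {
  s1 <- random_signatures(1, seed = 1)
  expect_equal(sum(s1), 1, tolerance = 1e-12)

  S <- random_signatures(5, max_pairwise_cosine = 0.6, seed = 2)
  cs <- crossprod(apply(S, 2, function(x) x / sqrt(sum(x^2))))
  expect_true(all(cs[upper.tri(cs)] <= 0.6 + 1e-12))
  expect_true(all(abs(colSums(S) - 1) < 1e-9))

  expect_identical(random_signatures(4, seed = 7), random_signatures(4, seed = 7))

  # an infeasible separation constraint fails loudly rather than hanging
  expect_error(random_signatures(20, max_pairwise_cosine = 0.01, sparsity = 0,
                                 max_tries = 50),
               "could not draw")
})

test_that("single-signature cohorts are multinomial draws of the profile", {
  truth <- random_signatures(1, seed = 5)
  spec <- scenario_spec(list(list(name = "a", n = 40, signatures = 1,
                                  prevalence = 1, weights = 1)),
                        burden_meanlog = log(100), burden_sdlog = 0)
  sim <- simulate_cohort(spec, truth, seed = 3)
  expect_true(all(rowSums(sim$catalogue) == 100))
  expect_true(all(sim$exposures == 100))
  expect_equal(sum(sim$exposures), 100 * 40)

  # aggregate frequencies converge to the profile (binomial-SE envelope,
  # 4 SE so that the simultaneous bound over 96 channels is comfortably rare)
  spec_big <- scenario_spec(list(list(name = "a", n = 100, signatures = 1,
                                      prevalence = 1, weights = 1)),
                            burden_meanlog = log(100), burden_sdlog = 0)
  sim_big <- simulate_cohort(spec_big, truth, seed = 8)
  n_draws <- sum(sim_big$catalogue) # 10,000 multinomial draws in total
  p <- as.vector(truth)
  se <- sqrt(p * (1 - p) / n_draws)
  freq <- colSums(sim_big$catalogue) / n_draws
  expect_true(all(abs(freq - p) <= 4 * se + 1e-12))
})

test_that("subcohorts with disjoint signatures have distinct mean spectra", {
  hits <- 0L
  for (s in 1:20) {
    S <- random_signatures(4, max_pairwise_cosine = 0.5, seed = 100 + s)
    spec <- scenario_spec(list(
      list(name = "g1", n = 50, signatures = 1:2, prevalence = c(1, 1),
           weights = c(1, 1)),
      list(name = "g2", n = 50, signatures = 3:4, prevalence = c(1, 1),
           weights = c(1, 1))),
      burden_meanlog = log(500), burden_sdlog = 0.2)
    sim <- simulate_cohort(spec, S, seed = s)
    m1 <- colMeans(sim$catalogue[sim$labels == "g1", ])
    m2 <- colMeans(sim$catalogue[sim$labels == "g2", ])
    mix1 <- rowMeans(S[, 1:2]); mix2 <- rowMeans(S[, 3:4])
    ok <- cosine_sim(m1, mix1) > cosine_sim(m1, mix2) &&
      cosine_sim(m2, mix2) > cosine_sim(m2, mix1)
    hits <- hits + ok
  }
  expect_identical(hits, 20L)
})

test_that("scenario templates reproduce the benchmark cohort layouts", {
  s4 <- scenario_template("scenario4")
  expect_equal(sum(vapply(s4$subcohorts, `[[`, 0, "n")), 1000)
  expect_length(s4$subcohorts, 2)
  expect_true(all(vapply(s4$subcohorts, `[[`, 0, "n") == 500))
  expect_length(unique(unlist(lapply(s4$subcohorts, `[[`, "signatures"))), 3)

  s1 <- scenario_template("scenario1", scale = 0.2)
  expect_equal(sum(vapply(s1$subcohorts, `[[`, 0, "n")), 200)
  expect_length(unique(unlist(lapply(s1$subcohorts, `[[`, "signatures"))), 11)

  s5 <- scenario_template("scenario5")
  expect_length(s5$subcohorts, 9)
  expect_true(all(vapply(s5$subcohorts, `[[`, 0, "n") == 300))
  expect_length(unique(unlist(lapply(s5$subcohorts, `[[`, "signatures"))), 21)

  expect_error(scenario_template("scenario9"))

  # ground-truth dimensionality follows the template
  truth <- random_signatures(3, seed = 2)
  sim <- simulate_cohort(scenario_template("scenario4", scale = 0.02), truth,
                         seed = 1)
  expect_equal(ncol(sim$signatures), 3)
  expect_equal(ncol(sim$exposures), 3)
})

test_that("catalogue factorizes as exposures x signatures in expectation", {
  sim <- tiny_cohort(k = 3, m = 80, burden = 10000, sdlog = 0.4, sig_seed = 4)
  pred <- sim$exposures %*% t(unclass(sim$signatures))
  rel <- sqrt(sum((unclass(sim$catalogue) - pred)^2)) / sqrt(sum(pred^2))
  expect_lt(rel, 0.05)

  # multinomial mode conserves burdens exactly
  expect_true(all(rowSums(sim$catalogue) == rowSums(sim$exposures)))
})

test_that("poisson noise mode matches the multinomial mean structure", {
  truth <- random_signatures(2, seed = 6)
  spec <- scenario_spec(list(list(name = "a", n = 300, signatures = 1:2,
                                  prevalence = c(1, 1), weights = c(1, 1))),
                        burden_meanlog = log(1000), burden_sdlog = 0,
                        noise = "poisson")
  sim <- simulate_cohort(spec, truth, seed = 2)
  # row sums fluctuate around the drawn exposures' totals
  expect_false(all(rowSums(sim$catalogue) == rowSums(sim$exposures)))
  expect_lt(abs(mean(rowSums(sim$catalogue)) - 1000), 10)
})
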
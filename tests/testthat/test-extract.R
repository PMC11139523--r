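test_that("bootstrap augmentation resamples each genome's multinomial", {
  # degenerate genome: all mass in one channel -> replicates are identical
  C <- matrix(0, 1, 96, dimnames = list("g", sbs_channels()))
  C[1, 5] <- 50
  B <- bootstrap_catalogue(as_sbs_catalogue(C), t = 6, seed = 1)
  expect_true(all(B[, 5] == 50) && all(B[, -5] == 0))

  set.seed(2)
  C10 <- as_sbs_catalogue(matrix(rpois(10 * 96, 8), 10, 96,
                                 dimnames = list(NULL, sbs_channels())))
  B10 <- bootstrap_catalogue(C10, t = 7, seed = 3)
  expect_equal(nrow(B10), 70)
  # every replicate conserves its source burden
  src <- rep(rowSums(C10), each = 7)
  expect_true(all(rowSums(B10) == src))
  expect_true(grepl("_r7$", rownames(B10)[7]))

  # replicate means match the analytic multinomial moments
  g <- as_sbs_catalogue(matrix(rpois(96, 30), 1, 96,
                               dimnames = list("x", sbs_channels())))
  R <- bootstrap_catalogue(g, t = 10000, seed = 4)
  N <- sum(g); p <- as.vector(g / N)
  # 4 SE: the bound is simultaneous over all 96 channels
  se <- sqrt(N * p * (1 - p) / 10000)
  dev <- abs(colMeans(R) - N * p)
  expect_true(all(dev <= 4 * se + 1e-9))

  # zero-mutation genomes pass through as zero rows
  z <- as_sbs_catalogue(matrix(0, 1, 96, dimnames = list("z", sbs_channels())))
  expect_true(all(bootstrap_catalogue(z, t = 3, seed = 1) == 0))
})

test_that("repeated training batches are deterministic and consistent", {
  sim <- tiny_cohort(k = 1, m = 40, burden = 1200, sdlog = 0, sig_seed = 21)
  Caug <- bootstrap_catalogue(sim$catalogue, 2, seed = 5)
  ctrl <- fast_ctrl(max_epochs = 60)
  r1 <- sigxae:::run_batch(Caug, sim$catalogue, k = 1, n = 3, ctrl, base_seed = 9)
  r2 <- sigxae:::run_batch(Caug, sim$catalogue, k = 1, n = 3, ctrl, base_seed = 9)
  expect_identical(vapply(r1, `[[`, 0, "erec"), vapply(r2, `[[`, 0, "erec"))

  # on rank-1 data every run finds the same signature direction
  ctrl_long <- fast_ctrl(max_epochs = 200, patience = 40)
  r4 <- sigxae:::run_batch(Caug, sim$catalogue, k = 1, n = 4, ctrl_long, base_seed = 1)
  W <- vapply(r4, function(r) r$W[, 1] / sqrt(sum(r$W[, 1]^2)), numeric(96))
  cs <- crossprod(W)
  expect_true(all(cs >= 0.99))

  # added capacity cannot increase the mean reconstruction error (majority,
  # with a convergence budget long enough for the comparison to be fair)
  ctrl2 <- fast_ctrl(batch = 16, max_epochs = 400, patience = 80)
  wins <- 0L
  for (s in 1:5) {
    e1 <- mean(vapply(sigxae:::run_batch(Caug, sim$catalogue, 1, 2, ctrl2, s),
                      `[[`, 0, "erec"))
    e2 <- mean(vapply(sigxae:::run_batch(Caug, sim$catalogue, 2, 2, ctrl2, s),
                      `[[`, 0, "erec"))
    wins <- wins + (e2 <= e1 * 1.02)
  }
  expect_gte(wins, 3)
})

test_that("matched consensus clustering recovers structure", {
  set.seed(31)
  W <- matrix(runif(96 * 3), 96, 3)

  # identical runs: centroids equal the columns, all silhouettes exactly 1
  runs <- lapply(1:5, function(i) list(k = 3, run = i, W = W, erec = i))
  cons <- consensus_cluster(runs)
  expect_equal(cons$silhouette_avg, 1)
  expect_equal(cons$silhouette_min, 1)
  expect_equal(unclass(cons$signatures), apply(W, 2, function(x) x / sum(x)),
               ignore_attr = TRUE, tolerance = 1e-12)

  # a permuted, slightly perturbed second run is re-aligned by matching
  perm <- c(3, 1, 2)
  W2 <- W[, perm] + matrix(runif(96 * 3, 0, 1e-4), 96, 3)
  cons2 <- consensus_cluster(list(list(k = 3, run = 1, W = W, erec = 1),
                                  list(k = 3, run = 2, W = W2, erec = 2)))
  memb <- cons2$membership
  c1 <- memb$cluster[memb$run == 1]
  c2 <- memb$cluster[memb$run == 2]
  # column j of run 2 holds run 1's column perm[j], so clusters must agree
  expect_identical(c2, c1[perm])
  # and the assignment equals the brute-force optimum over all 6 permutations
  cost <- 1 - crossprod(apply(W, 2, function(x) x / sqrt(sum(x^2))),
                        apply(W2, 2, function(x) x / sqrt(sum(x^2))))
  bf <- brute_force_assignment(cost)
  expect_identical(as.integer(solve_assignment(cost)), as.integer(bf$perm))
  expect_identical(as.integer(bf$perm), order(perm)) # the inverse permutation

  # equal-size clusters for arbitrary random inputs
  runs_r <- lapply(1:6, function(i)
    list(k = 4, run = i, W = matrix(runif(96 * 4), 96, 4), erec = i))
  cons_r <- consensus_cluster(runs_r)
  expect_true(all(table(cons_r$membership$cluster) == 6))
  expect_true(all(abs(colSums(cons_r$signatures) - 1) < 1e-9))
  expect_true(all(cons_r$silhouette >= -1 & cons_r$silhouette <= 1))

  expect_error(consensus_cluster(runs[1]), "at least 2")
})

test_that("optimal-k selection applies the silhouette filter then min error", {
  sol <- function(k, sa, sm, er)
    structure(list(k = k, signatures = NULL, silhouette_avg = sa,
                   silhouette_min = sm, mean_erec = er),
              class = "consensus_solution")
  s <- list(sol(2, 0.98, 0.95, 100), sol(3, 0.97, 0.92, 80),
            sol(4, 0.70, 0.40, 60))
  res <- select_k(s, th_avg = 0.8, th_min = 0.7)
  expect_identical(res$k_star, 3L)
  expect_false(res$flagged)

  # nothing passes: flag and fall back to the highest average silhouette
  low <- list(sol(2, 0.5, 0.2, 100), sol(3, 0.6, 0.1, 80))
  res2 <- select_k(low, th_avg = 0.8, th_min = 0.7)
  expect_true(res2$flagged)
  expect_identical(res2$k_star, 3L)

  # ties in error break toward the smaller k
  tie <- list(sol(4, 0.95, 0.9, 50), sol(3, 0.95, 0.9, 50))
  expect_identical(select_k(tie, 0.8, 0.7)$k_star, 3L)

  expect_error(select_k(list()), "no solutions")
})

test_that("assignment solver equals brute force on random cost matrices", {
  set.seed(99)
  for (i in 1:400) {
    k <- sample(2:5, 1)
    cost <- matrix(runif(k * k), k, k)
    a <- solve_assignment(cost)
    expect_equal(attr(a, "cost"), brute_force_assignment(cost)$cost,
                 tolerance = 1e-12)
  }
  # rectangular: 2 x 4 assigns each row a distinct column
  cost <- matrix(runif(8), 2, 4)
  a <- solve_assignment(cost)
  expect_length(unique(a), 2)
})

test_that("a planted single-signature cohort selects K* = 1", {
  sim <- tiny_cohort(k = 1, m = 100, burden = 2000, sdlog = 0.3, sig_seed = 17)
  fit <- sigxae(sim$catalogue, k = 1:4, augment = 5, runs = 5,
                seed = 2, control = fast_ctrl(max_epochs = 60), refit = FALSE)
  expect_identical(fit$k_selected, 1L)
  expect_gte(cosine_sim(coef(fit)[, 1], sim$signatures[, 1]), 0.99)
  expect_true(all(abs(colSums(coef(fit)) - 1) < 1e-9))

  # parametric bootstrap: simulated catalogues have the fitted burdens and
  # per-sample spectra close to the model mixture
  simc <- simulate(fit, nsim = 2, seed = 4)
  expect_length(simc, 2)
  Z <- predict(fit)
  expect_equal(rowSums(simc[[1]]), round(rowSums(Z %*% t(coef(fit)))),
               ignore_attr = TRUE, tolerance = 1e-12)
  cosr <- vapply(seq_len(nrow(Z)), function(i)
    cosine_sim(simc[[1]][i, ], coef(fit)[, 1]), 0)
  expect_gt(min(cosr), 0.9)
})
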
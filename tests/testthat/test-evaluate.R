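test_that("cosine similarity behaves on the canonical cases", {
  v <- runif(96)
  expect_equal(cosine_sim(v, v), 1)
  a <- c(1, 1, rep(0, 94)); b <- c(0, 0, 1, 1, rep(0, 92))
  expect_equal(cosine_sim(a, b), 0)
  expect_error(cosine_sim(rep(0, 96), v), "zero vector")
  expect_error(cosine_sim(1:3, 1:4), "length")
})

test_that("hungarian matching of signatures is optimal and well-shaped", {
  S <- random_signatures(4, seed = 40)
  m <- match_signatures(S, S)
  expect_equal(m$pairs$cosine, rep(1, 4), tolerance = 1e-12)
  expect_identical(sort(m$pairs$est), 1:4)
  expect_identical(m$pairs$true[order(m$pairs$est)], 1:4)

  # permuted columns: the pairing recovers the permutation (vs brute force)
  set.seed(41)
  for (k in 2:5) {
    Sk <- random_signatures(k, seed = 50 + k)
    perm <- sample(k)
    m2 <- match_signatures(Sk[, perm], Sk)
    got <- m2$pairs$true[order(m2$pairs$est)]
    expect_identical(got, perm)
    # total matched cosine equals the exhaustive-permutation maximum
    cs <- crossprod(apply(unclass(Sk[, perm]), 2, function(x) x / sqrt(sum(x^2))),
                    apply(unclass(Sk), 2, function(x) x / sqrt(sum(x^2))))
    bf <- brute_force_assignment(1 - cs)
    expect_equal(sum(m2$pairs$cosine), k - bf$cost, tolerance = 1e-12)
  }

  # unequal cardinalities pair min(k_est, k_true)
  m3 <- match_signatures(random_signatures(3, seed = 60),
                         random_signatures(2, seed = 61))
  expect_equal(nrow(m3$pairs), 2)
  expect_length(m3$unmatched_est, 1)
  expect_length(m3$unmatched_true, 0)
})

test_that("confusion counts follow the threshold rule and conservation", {
  S <- random_signatures(5, seed = 70)
  m <- match_signatures(S, S)
  expect_equal(confusion_at_threshold(m, 0.99), c(TP = 5, FP = 0, FN = 0))

  fake <- structure(list(pairs = data.frame(est = 1:3, true = 1:3,
                                            cosine = c(0.95, 0.85, 0.60)),
                         unmatched_est = integer(), unmatched_true = integer(),
                         k_est = 3, k_true = 3),
                    class = "signature_match")
  expect_equal(confusion_at_threshold(fake, 0.8), c(TP = 2, FP = 1, FN = 1))

  surplus <- structure(list(pairs = data.frame(est = 1:2, true = 1:2,
                                               cosine = c(0.99, 0.95)),
                            unmatched_est = 3:4, unmatched_true = integer(),
                            k_est = 4, k_true = 2),
                       class = "signature_match")
  expect_equal(confusion_at_threshold(surplus, 0.9), c(TP = 2, FP = 2, FN = 0))

  # conservation at every threshold for random matches
  set.seed(71)
  for (i in 1:10) {
    ke <- sample(2:6, 1); kt <- sample(2:6, 1)
    mm <- match_signatures(random_signatures(ke, seed = 80 + i),
                           random_signatures(kt, seed = 90 + i))
    for (th in seq(0, 1, by = 0.25)) {
      cf <- confusion_at_threshold(mm, th)
      expect_equal(unname(cf["TP"] + cf["FN"]), kt)
      expect_equal(unname(cf["TP"] + cf["FP"]), ke)
    }
  }
})

test_that("recovery curves match hand-computed values", {
  S <- random_signatures(3, seed = 100)
  perfect <- recovery_curve(S, S)
  expect_true(all(perfect$table$f1 == 1))
  expect_equal(unname(perfect$auc), c(1, 1, 1))

  fake_pair <- function(cosines, k) {
    # two signature sets whose matched cosines are known exactly
    base <- diag(96)[, 1:k]
    est <- sapply(seq_len(k), function(j) {
      v <- base[, j]
      v2 <- v
      v2[96] <- sqrt(1 / cosines[j]^2 - 1) # cos(v, v+tail) = cosines[j]
      v2
    })
    rownames(est) <- rownames(base) <- sbs_channels()
    list(est = est, true = base)
  }
  fp <- fake_pair(c(1.0, 0.9), 2)
  rc <- recovery_curve(fp$est, fp$true, thresholds = c(0.8, 0.85, 0.9, 0.95, 1))
  expect_equal(rc$table$f1, c(1, 1, 1, 0.5, 0.5))
  expect_equal(unname(rc$auc["f1"]), (0.05 * (1 + 1) / 2 + 0.05 * (1 + 1) / 2 +
                                        0.05 * (1 + 0.5) / 2 +
                                        0.05 * (0.5 + 0.5) / 2) / 0.2)

  # precision and sensitivity never increase with the threshold
  set.seed(101)
  for (i in 1:5) {
    r <- recovery_curve(random_signatures(4, seed = 110 + i),
                        random_signatures(3, seed = 120 + i))
    expect_true(all(diff(r$table$precision) <= 1e-12))
    expect_true(all(diff(r$table$sensitivity) <= 1e-12))
  }

  # disjoint signatures: nothing recovered anywhere on the grid
  d1 <- as_signature_matrix(diag(96)[, 1:2])
  d2 <- as_signature_matrix(diag(96)[, 3:4])
  r0 <- recovery_curve(d1, d2)
  expect_true(all(r0$table$f1 == 0))
  expect_equal(unname(r0$auc["f1"]), 0)
})

test_that("exposure-based classification separates distinct cohorts", {
  set.seed(130)
  Z <- rbind(cbind(runif(50, 500, 1500), runif(50, 0, 10)),
             cbind(runif(50, 0, 10), runif(50, 500, 1500)))
  labels <- rep(c("A", "B"), each = 50)
  rep_perfect <- classify_exposures(Z, labels, trees = 100, seed = 1)
  expect_equal(unname(rep_perfect$mean["mcc"]), 1)
  expect_equal(unname(rep_perfect$mean["kappa"]), 1)
  expect_equal(unname(rep_perfect$mean["balanced_accuracy"]), 1)

  # permuted labels give near-zero skill on average
  mccs <- vapply(1:10, function(i) {
    set.seed(200 + i)
    unname(classify_exposures(Z, sample(labels), trees = 60,
                              seed = i)$mean["mcc"])
  }, 0)
  expect_lt(abs(mean(mccs)), 0.15)

  # small classes are dropped and reported
  Z3 <- rbind(Z, cbind(runif(9, 200, 300), runif(9, 200, 300)))
  rep3 <- classify_exposures(Z3, c(labels, rep("C", 9)), trees = 60, seed = 2)
  expect_identical(names(rep3$dropped), "C")
  expect_error(classify_exposures(Z[1:50, ], labels[1:50]), "2 classes")
})

test_that("agreement metrics match an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(140)
  cm <- matrix(rpois(9, 20) + 1, 3, 3)
  ours <- sigxae:::kappa_from_confusion(cm)
  theirs <- e1071::classAgreement(cm)$kappa
  expect_equal(ours, theirs, tolerance = 1e-12)

  # binary MCC agrees with the Pearson correlation of the indicators
  cm2 <- matrix(c(40, 7, 5, 48), 2, 2)
  y <- rep(c(0, 0, 1, 1), times = c(40, 7, 5, 48))
  p <- rep(c(0, 1, 0, 1), times = c(40, 7, 5, 48))
  expect_equal(sigxae:::mcc_from_confusion(cm2), cor(y, p), tolerance = 1e-12)
})
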
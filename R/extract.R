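# De novo extraction: bootstrap augmentation -> n trainings per candidate k
# -> matched K-means consensus over decoder weight matrices -> silhouette
# stability filter -> select the stable k with the lowest reconstruction
# error on the original catalogue.

#' Solve the linear assignment problem
#'
#' Exact minimum-cost one-to-one assignment (Jonker--Volgenant style
#' shortest augmenting paths with dual potentials). For a cost matrix with
#' `nrow <= ncol`, returns the column assigned to each row.
#'
#' @param cost Numeric cost matrix, `nrow(cost) <= ncol(cost)`.
#' @return Integer vector `a` with `a[i]` the column matched to row `i`;
#'   the attribute `"cost"` holds the total assignment cost.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  a <- .cpp_lap(cost)
  structure(a, cost = sum(cost[cbind(seq_len(nrow(cost)), a)]))
}

derive_seed <- function(base, ...) {
  v <- c(base, ...)
  s <- 0
  for (x in v) s <- (s * 48271 + as.double(x) + 1) %% 2147483647
  as.integer(s)
}

#' Multinomial bootstrap augmentation of a catalogue
#'
#' Each genome with total burden N and channel frequencies p contributes
#' `t` independent Multinomial(N, p) replicates, enlarging the catalogue
#' `t`-fold so that the network sees resampled copies of every spectrum.
#' Replicate IDs are suffixed `_r1 .. _rt`. Zero-mutation genomes are
#' carried through as zero rows.
#'
#' @param C An `sbs_catalogue` (samples x 96).
#' @param t Augmentation factor (integer >= 1).
#' @param seed Integer seed.
#' @return An `sbs_catalogue` with `nrow(C) * t` samples.
#' @export
bootstrap_catalogue <- function(C, t = 100, seed = NULL) {
  C <- as_sbs_catalogue(C)
  stopifnot(t >= 1)
  t <- as.integer(t)
  m <- nrow(C)
  with_seed(seed, {
    out <- matrix(0, m * t, 96, dimnames = list(NULL, colnames(C)))
    ids <- character(m * t)
    for (g in seq_len(m)) {
      N <- sum(C[g, ])
      rows <- (g - 1L) * t + seq_len(t)
      if (N > 0) out[rows, ] <- t(stats::rmultinom(t, N, C[g, ] / N))
      ids[rows] <- sprintf("%s_r%d", rownames(C)[g], seq_len(t))
    }
    rownames(out) <- ids
    as_sbs_catalogue(out)
  })
}

# Train n models with distinct initializations on the augmented catalogue;
# reconstruction error is always measured on the original catalogue.
run_batch <- function(C_aug, C, k, n, control, base_seed, verbose = FALSE) {
  stopifnot(n >= 2)
  Xa <- unclass_matrix(C_aug)
  X <- unclass_matrix(C)
  runs <- vector("list", n)
  failed <- 0L
  for (i in seq_len(n)) {
    s <- derive_seed(base_seed, k, i)
    fit <- tryCatch(xae_train(Xa, k, control = control, seed = s),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      s2 <- derive_seed(base_seed, k, i, 777L)
      fit <- tryCatch(xae_train(Xa, k, control = control, seed = s2),
                      error = function(e) e)
    }
    if (inherits(fit, "error")) {
      failed <- failed + 1L
      runs[[i]] <- NULL
      next
    }
    W <- fit$model$Wd
    runs[[i]] <- list(k = k, run = i, seed = fit$seed, W = W,
                      erec = reconstruction_error(fit, X),
                      epochs = length(fit$model$history$val))
    if (verbose)
      message(sprintf("  k=%d run %d/%d: Erec %.1f (%d epochs)",
                      k, i, n, runs[[i]]$erec, runs[[i]]$epochs))
  }
  if (failed > 0.2 * n)
    stop(sprintf("%d of %d training runs failed for k = %d", failed, n, k),
         call. = FALSE)
  Filter(Negate(is.null), runs)
}

l2_normalize_cols <- function(M) {
  nrm <- sqrt(colSums(M^2))
  nrm[nrm == 0] <- 1
  sweep(M, 2, nrm, "/")
}

#' Consensus signatures from repeated trainings by matched clustering
#'
#' Clusters the `n` decoder weight matrices obtained for one candidate `k`
#' into `k` clusters of exactly `n` members: starting from the columns of
#' the lowest-error run as centroids, each run's columns are matched
#' one-to-one to the centroids by solving a k x k linear assignment on
#' `1 - cosine` cost, centroids are recomputed as the normalized mean of
#' their members, and the procedure repeats until the assignment is stable
#' (at most 100 iterations). Stability of the solution is summarized by
#' silhouette scores under `1 - cosine` distance: `silhouette_avg` is the
#' mean over all `n * k` columns, `silhouette_min` the minimum over
#' clusters of the per-cluster mean. For `k = 1` the single trivial cluster
#' is given silhouette 1.
#'
#' @param runs List of run results, each with elements `W` (96 x k) and
#'   `erec`, as produced internally by the extraction loop.
#' @return A list of class `"consensus_solution"`: `k`, `signatures`
#'   (96 x k, columns sum to 1), `silhouette_avg`, `silhouette_min`,
#'   `mean_erec`, `erec`, `membership`.
#' @export
consensus_cluster <- function(runs) {
  n <- length(runs)
  if (n < 2) stop("need at least 2 runs to form a consensus", call. = FALSE)
  k <- ncol(runs[[1]]$W)
  stopifnot(all(vapply(runs, function(r) ncol(r$W), 0L) == k))
  cols <- do.call(cbind, lapply(runs, function(r) l2_normalize_cols(r$W)))
  run_of <- rep(seq_len(n), each = k)
  best <- which.min(vapply(runs, `[[`, 0, "erec"))
  centroids <- l2_normalize_cols(runs[[best]]$W)
  assign_mat <- matrix(0L, n, k) # assign_mat[r, j] = cluster of run r's column j
  for (iter in seq_len(100)) {
    prev <- assign_mat
    for (r in seq_len(n)) {
      Wr <- cols[, run_of == r, drop = FALSE]
      cost <- 1 - crossprod(centroids, Wr)   # k clusters x k columns
      a <- .cpp_lap(t(cost))                 # column j -> cluster a[j]
      assign_mat[r, ] <- a
    }
    for (cl in seq_len(k)) {
      members <- cols[, as.vector(t(assign_mat)) == cl, drop = FALSE]
      cen <- rowMeans(members)
      centroids[, cl] <- cen / max(sqrt(sum(cen^2)), 1e-12)
    }
    if (identical(prev, assign_mat)) break
  }
  cluster <- as.vector(t(assign_mat)) # per column of `cols`
  # silhouettes with distance 1 - cosine
  if (k == 1) {
    sil <- rep(1, n)
  } else {
    D <- 1 - crossprod(cols)
    sil <- vapply(seq_len(n * k), function(i) {
      same <- cluster == cluster[i]
      a <- sum(D[i, same]) / (sum(same) - 1)
      b <- min(vapply(setdiff(seq_len(k), cluster[i]), function(cl)
        mean(D[i, cluster == cl]), 0))
      if (max(a, b) == 0) 1 else (b - a) / max(a, b)
    }, 0)
  }
  per_cluster <- vapply(seq_len(k), function(cl) mean(sil[cluster == cl]), 0)
  S <- apply(centroids, 2, function(x) x / sum(x))
  rownames(S) <- rownames(runs[[1]]$W) %||% sbs_channels()
  colnames(S) <- paste0("Sig", seq_len(k))
  structure(list(k = k, signatures = as_signature_matrix(S),
                 silhouette_avg = mean(sil),
                 silhouette_min = min(per_cluster),
                 silhouette = sil,
                 mean_erec = mean(vapply(runs, `[[`, 0, "erec")),
                 erec = vapply(runs, `[[`, 0, "erec"),
                 membership = data.frame(run = run_of,
                                         column = rep(seq_len(k), n),
                                         cluster = cluster),
                 n = n),
            class = "consensus_solution")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the optimal number of signatures
#'
#' Keeps candidate solutions whose average silhouette exceeds `th_avg` and
#' whose minimum silhouette exceeds `th_min`; among those, the selected
#' `k_star` is the one with the lowest mean reconstruction error, ties
#' broken toward the smaller (more parsimonious) `k`. If no candidate
#' passes, the `k` with the highest average silhouette is returned and the
#' result is flagged as having no stable solution.
#'
#' @param solutions List of [consensus_cluster()] solutions (one per k).
#' @param th_avg,th_min Silhouette thresholds.
#' @return List: `k_star`, `flagged`, `table` (per-k diagnostics),
#'   `solutions`.
#' @export
select_k <- function(solutions, th_avg = 0.9, th_min = 0.7) {
  if (length(solutions) == 0) stop("no solutions to select from", call. = FALSE)
  stopifnot(th_min <= th_avg)
  ks <- vapply(solutions, `[[`, 0, "k")
  tab <- data.frame(
    k = ks,
    silhouette_avg = vapply(solutions, `[[`, 0, "silhouette_avg"),
    silhouette_min = vapply(solutions, `[[`, 0, "silhouette_min"),
    mean_erec = vapply(solutions, `[[`, 0, "mean_erec"))
  tab$stable <- tab$silhouette_avg > th_avg & tab$silhouette_min > th_min
  tab <- tab[order(tab$k), ]
  rownames(tab) <- NULL
  if (any(tab$stable)) {
    cand <- tab[tab$stable, ]
    k_star <- cand$k[order(cand$mean_erec, cand$k)][1]
    flagged <- FALSE
  } else {
    k_star <- tab$k[which.max(tab$silhouette_avg)]
    flagged <- TRUE
  }
  list(k_star = as.integer(k_star), flagged = flagged, table = tab,
       solutions = solutions)
}

#' De novo mutational-signature extraction
#'
#' Fits the full extraction pipeline to an SBS-96 catalogue: (1) the
#' catalogue is enlarged `augment`-fold by multinomial bootstrap; (2) for
#' every candidate number of signatures `k` the autoencoder is trained
#' `runs` times from different random initializations on the augmented
#' catalogue, recording each run's decoder weights and its reconstruction
#' error on the original catalogue; (3) each candidate's runs are combined
#' into consensus signatures by matched clustering ([consensus_cluster()]);
#' (4) unstable candidates are filtered by silhouette thresholds and the
#' stable candidate with the lowest mean reconstruction error is selected
#' ([select_k()]); (5) exposures for the selected signatures are refitted
#' on the original catalogue with a frozen decoder ([refit_exposures()]).
#'
#' @param x Samples x 96 count matrix (an `sbs_catalogue` or coercible).
#' @param k Candidate numbers of signatures (integer vector).
#' @param augment Bootstrap augmentation factor `t`.
#' @param runs Trainings per candidate `k`.
#' @param th_avg,th_min Silhouette stability thresholds.
#' @param seed Base seed; every training and bootstrap draw derives its own
#'   seed from it deterministically.
#' @param control An [xae_control()]. The default (`NULL`) uses a profile
#'   sized to the candidate range: a narrow funnel whose bottleneck equals
#'   `max(8, max(k))` (widths about `3.2u / 1.6u / u`), minibatch 128,
#'   learning rate 4e-3, at most 150 epochs with patience 15 -- wide enough
#'   to represent the largest candidate while small enough that restarts
#'   converge reproducibly and a full consensus run stays tractable on one
#'   CPU.
#' @param refit Refit exposures for the selected signatures (default TRUE).
#' @param verbose Print per-k progress to stderr.
#' @return An object of class `"sigxae"`; see [coef.sigxae()],
#'   [predict.sigxae()], [plot.sigxae()].
#' @seealso [refit_exposures()], [match_signatures()], [simulate_cohort()]
#' @export
#' @examples
#' truth <- random_signatures(2, seed = 5)
#' spec <- scenario_spec(list(list(name = "a", n = 60, signatures = 1:2,
#'                                 prevalence = c(1, 1), weights = c(1, 1))),
#'                       burden_meanlog = log(800), burden_sdlog = 0.3)
#' sim <- simulate_cohort(spec, truth, seed = 1)
#' \donttest{
#' fit <- sigxae(sim$catalogue, k = 1:3, augment = 2, runs = 3,
#'               control = xae_control(units = c(32, 16, 8), max_epochs = 60,
#'                                     patience = 10), seed = 1)
#' fit
#' }
sigxae <- function(x, k = 1:8, augment = 100, runs = 100,
                   th_avg = 0.9, th_min = 0.7, seed = 1,
                   control = NULL, refit = TRUE,
                   verbose = FALSE) {
  C <- as_sbs_catalogue(x)
  k <- sort(unique(as.integer(k)))
  stopifnot(all(k >= 1), runs >= 2, augment >= 1)
  if (is.null(control)) {
    u3 <- max(8L, max(k))
    u1 <- max(32L, as.integer(round(3.2 * u3)))
    control <- xae_control(units = c(u1, u1 %/% 2L, u3), batch = 128,
                           lr = 4e-3, max_epochs = 150, patience = 15)
  }
  t0 <- proc.time()[["elapsed"]]
  C_aug <- bootstrap_catalogue(C, augment, seed = derive_seed(seed, 0L))
  solutions <- vector("list", length(k))
  for (ki in seq_along(k)) {
    if (verbose) message(sprintf("k = %d: training %d models ...", k[ki], runs))
    rb <- run_batch(C_aug, C, k[ki], runs, control, seed, verbose = FALSE)
    solutions[[ki]] <- consensus_cluster(rb)
    if (verbose)
      message(sprintf("k = %d: silhouette avg %.3f / min %.3f, mean Erec %.1f",
                      k[ki], solutions[[ki]]$silhouette_avg,
                      solutions[[ki]]$silhouette_min,
                      solutions[[ki]]$mean_erec))
  }
  sel <- select_k(solutions, th_avg = th_avg, th_min = th_min)
  best <- solutions[[match(sel$k_star, vapply(solutions, `[[`, 0, "k"))]]
  expo <- NULL
  if (refit)
    expo <- refit_exposures(C, best$signatures,
                            seed = derive_seed(seed, 999L))
  structure(list(
    k_selected = sel$k_star,
    signatures = best$signatures,
    exposures = expo,
    flagged = sel$flagged,
    selection = sel$table,
    solutions = solutions,
    thresholds = c(th_avg = th_avg, th_min = th_min),
    augment = as.integer(augment), runs = as.integer(runs),
    seed = as.integer(seed), control = control,
    catalogue = C,
    elapsed = proc.time()[["elapsed"]] - t0,
    call = match.call()),
    class = "sigxae")
}

#' @export
print.sigxae <- function(x, ...) {
  cat("De novo signature extraction (explainable autoencoder)\n")
  cat(sprintf("  %d samples, candidates k = %s, %dx augmentation, %d runs/k\n",
              nrow(x$catalogue), paste(range(x$selection$k), collapse = ".."),
              x$augment, x$runs))
  cat(sprintf("  selected K* = %d%s\n", x$k_selected,
              if (x$flagged) " (no stable solution; highest-silhouette k reported)"
              else ""))
  invisible(x)
}

#' @export
summary.sigxae <- function(object, ...) {
  structure(list(selection = object$selection, k_selected = object$k_selected,
                 flagged = object$flagged, thresholds = object$thresholds),
            class = "summary.sigxae")
}

#' @export
print.summary.sigxae <- function(x, ...) {
  cat("per-k consensus diagnostics (silhouette thresholds ",
      sprintf("avg > %.2f, min > %.2f):\n", x$thresholds[1], x$thresholds[2]),
      sep = "")
  tab <- x$selection
  tab$selected <- ifelse(tab$k == x$k_selected, "*", "")
  print(tab, digits = 4)
  if (x$flagged) cat("note: no k passed the stability filter\n")
  invisible(x)
}

#' Extracted consensus signatures
#'
#' @param object A fitted [sigxae()] object.
#' @param ... Unused.
#' @return The 96 x K* consensus signature matrix (columns sum to 1).
#' @export
coef.sigxae <- function(object, ...) object$signatures

#' Exposures for a new (or the training) catalogue
#'
#' Refits exposures against the selected consensus signatures with a frozen
#' decoder; with `newdata = NULL` returns the exposures computed at fit
#' time.
#'
#' @param object A fitted [sigxae()] object.
#' @param newdata Optional samples x 96 catalogue.
#' @param ... Passed to [refit_exposures()].
#' @return Samples x K* non-negative exposure matrix.
#' @export
predict.sigxae <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (!is.null(object$exposures)) return(object$exposures)
    newdata <- object$catalogue
  }
  refit_exposures(as_sbs_catalogue(newdata), object$signatures, ...)
}

#' @export
fitted.sigxae <- function(object, ...) {
  Z <- predict(object)
  Z %*% t(unclass(object$signatures))
}

#' @export
residuals.sigxae <- function(object, ...) {
  unclass(object$catalogue) - fitted(object)
}

#' Simulate catalogues from the fitted factorization
#'
#' Parametric bootstrap: each simulated catalogue draws, for every sample,
#' a multinomial of the sample's fitted exposures over its signature
#' mixture -- i.e. new data from the model `C ~ Z S'` with the trained
#' exposures and consensus signatures.
#'
#' @param object A fitted [sigxae()] object.
#' @param nsim Number of catalogues to simulate.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` `sbs_catalogue` objects.
#' @export
simulate.sigxae <- function(object, nsim = 1, seed = NULL, ...) {
  Z <- predict(object)
  S <- unclass(object$signatures)
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      counts <- matrix(0, nrow(Z), 96, dimnames = list(rownames(Z),
                                                       sbs_channels()))
      for (i in seq_len(nrow(Z))) {
        mix <- as.vector(S %*% Z[i, ])
        N <- round(sum(mix))
        if (N > 0) counts[i, ] <- stats::rmultinom(1, N, mix / sum(mix))
      }
      as_sbs_catalogue(counts)
    })
  })
}

#' Model-selection diagnostics plot
#'
#' Left panel: average and minimum silhouette per candidate k with the
#' stability thresholds; right panel: mean reconstruction error per k, the
#' selected K* marked.
#'
#' @param x A fitted [sigxae()] object.
#' @param ... Unused.
#' @export
plot.sigxae <- function(x, ...) {
  tab <- x$selection
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(tab$k, tab$silhouette_avg, type = "b", pch = 19,
                 ylim = c(min(0, min(tab$silhouette_min)), 1),
                 xlab = "candidate k", ylab = "silhouette",
                 main = "consensus stability")
  graphics::lines(tab$k, tab$silhouette_min, type = "b", pch = 1, lty = 2)
  graphics::abline(h = x$thresholds, col = "grey60", lty = 3)
  graphics::legend("bottomleft", c("average", "minimum"), pch = c(19, 1),
                   lty = c(1, 2), bty = "n")
  graphics::plot(tab$k, tab$mean_erec, type = "b", pch = 19,
                 xlab = "candidate k", ylab = "mean reconstruction error",
                 main = "reconstruction")
  graphics::abline(v = x$k_selected, col = "red3", lty = 2)
  invisible(x)
}
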
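# Synthetic SBS-96 cohorts with known ground truth. The generator follows
# the structure of the published benchmark designs: subcohorts with their own
# signature prevalences and activity weights, log-normal mutation burdens,
# and multinomial (or Poisson) channel noise.

# evaluate expr under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate random, well-separated signature profiles
#'
#' Draws `k` sparse Dirichlet profiles on the 96 channels by rejection
#' sampling: a fraction `sparsity` of channels is zeroed at random, the rest
#' receive a symmetric Dirichlet draw, and a candidate is accepted only if
#' its cosine similarity to every previously accepted profile does not
#' exceed `max_pairwise_cosine`. These profiles stand in for curated
#' reference signatures so that simulations need no external download; real
#' reference profiles can be supplied anywhere a signature matrix is
#' accepted (see [read_signatures()]).
#'
#' @param k Number of signatures (<= 96).
#' @param max_pairwise_cosine Upper bound on every off-diagonal pairwise
#'   cosine similarity, in \[0, 1).
#' @param sparsity Fraction of channels zeroed per profile, in \[0, 1).
#' @param concentration Dirichlet concentration on the active channels;
#'   values below 1 give spiky, signature-like profiles.
#' @param seed Integer seed; the same seed reproduces the same matrix.
#' @param max_tries Rejection attempts per signature before failing.
#' @return A normalized [as_signature_matrix()] (96 x k).
#' @export
random_signatures <- function(k, max_pairwise_cosine = 0.6, sparsity = 0.5,
                              concentration = 0.3, seed = NULL,
                              max_tries = 5000) {
  stopifnot(k >= 1, k <= 96, max_pairwise_cosine >= 0, max_pairwise_cosine < 1,
            sparsity >= 0, sparsity < 1)
  n_zero <- floor(96 * sparsity)
  with_seed(seed, {
    S <- matrix(0, 96, k)
    for (j in seq_len(k)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        p <- rdirichlet1(rep(concentration, 96))
        if (n_zero > 0) {
          p[sample.int(96, n_zero)] <- 0
          if (sum(p) == 0) next
          p <- p / sum(p)
        }
        if (j == 1 || all(pairwise_cosine(matrix(p, ncol = 1),
                                          S[, seq_len(j - 1), drop = FALSE]) <=
                          max_pairwise_cosine)) {
          S[, j] <- p
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf(paste0("could not draw signature %d with pairwise cosine <= %.2f ",
                            "after %d attempts; relax the constraint"),
                     j, max_pairwise_cosine, max_tries), call. = FALSE)
    }
    rownames(S) <- sbs_channels()
    colnames(S) <- paste0("True", seq_len(k))
    as_signature_matrix(S)
  })
}

#' Parametric description of a synthetic cohort
#'
#' A scenario is a list of subcohorts, each with a name, a sample count, the
#' indices of its active signatures, per-signature prevalence probabilities
#' (chance that a signature is switched on in a sample) and per-signature
#' activity weights (Dirichlet weights for how the mutation burden is split
#' among the signatures active in a sample), plus a log-normal burden model
#' and the channel noise model.
#'
#' @param subcohorts List of lists with fields `name`, `n`, `signatures`
#'   (integer indices), `prevalence` and `weights` (numeric, same length as
#'   `signatures`).
#' @param burden_meanlog,burden_sdlog Log-normal parameters of the total
#'   mutation burden per sample.
#' @param noise `"multinomial"` (burdens conserved exactly) or `"poisson"`.
#' @param seed Default seed used by [simulate_cohort()].
#' @return A list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(subcohorts, burden_meanlog = log(3000),
                          burden_sdlog = 1.0,
                          noise = c("multinomial", "poisson"), seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(length(subcohorts) >= 1, burden_sdlog >= 0)
  for (sc in subcohorts) {
    stopifnot(!is.null(sc$name), sc$n >= 1,
              length(sc$signatures) >= 1,
              length(sc$prevalence) == length(sc$signatures),
              length(sc$weights) == length(sc$signatures),
              all(sc$prevalence >= 0), all(sc$prevalence <= 1),
              all(sc$weights > 0))
  }
  structure(list(subcohorts = subcohorts, burden_meanlog = burden_meanlog,
                 burden_sdlog = burden_sdlog, noise = noise, seed = seed),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  ks <- sort(unique(unlist(lapply(x$subcohorts, `[[`, "signatures"))))
  cat(sprintf("scenario: %d subcohort(s), %d samples, %d signatures, %s noise\n",
              length(x$subcohorts), sum(vapply(x$subcohorts, `[[`, 0, "n")),
              length(ks), x$noise))
  for (sc in x$subcohorts)
    cat(sprintf("  %-12s n=%4d  signatures {%s}\n", sc$name, sc$n,
                paste(sc$signatures, collapse = ",")))
  invisible(x)
}

#' Benchmark scenario templates
#'
#' Cohort layouts mirroring the five published synthetic benchmark designs:
#' 1. one cohort of 1000 samples, 11 signatures;
#' 2. two subcohorts of 500 (renal-like, dominated by two flat signatures;
#'    ovarian-like, dominated by one), 11 signatures;
#' 3. two subcohorts of 500 with overlapping, near-duplicate dominant
#'    signatures, 11 signatures;
#' 4. two subcohorts of 500 with only 3 signatures in total;
#' 5. nine subcohorts of 300 samples each, 21 signatures.
#'
#' Templates fix the cohort structure only; the signature profiles
#' themselves are supplied separately ([random_signatures()] or a reference
#' file). Scenarios 2 and 3 are characterized by similar/overlapping
#' profiles, so the template carries a `suggested_max_cosine` attribute
#' (0.8 and 0.9) to be used when generating profiles for them.
#'
#' @param name `"scenario1"` .. `"scenario5"`.
#' @param scale Positive multiplier on every subcohort size.
#' @param seed Stored in the spec as the default simulation seed.
#' @return A [scenario_spec()].
#' @export
scenario_template <- function(name = sprintf("scenario%d", 1:5), scale = 1,
                              seed = NULL) {
  name <- match.arg(name)
  stopifnot(scale > 0)
  ns <- function(n) max(1L, as.integer(round(n * scale)))
  sub <- function(nm, n, sig, prev, w)
    list(name = nm, n = ns(n), signatures = sig, prevalence = prev, weights = w)
  spec <- switch(name,
    scenario1 = scenario_spec(list(
      sub("pancreas", 1000, 1:11,
          prev = seq(0.7, 0.3, length.out = 11),
          w = c(3, 2, rep(1, 9)))),
      burden_meanlog = log(3000), burden_sdlog = 0.8, seed = seed),
    scenario2 = scenario_spec(list(
      sub("renal", 500, 1:11, prev = c(1, 1, rep(0.25, 9)),
          w = c(4, 4, rep(1, 9))),
      sub("ovary", 500, 1:11, prev = c(0.25, 0.25, 1, rep(0.25, 8)),
          w = c(1, 1, 6, rep(1, 8)))),
      burden_meanlog = log(4000), burden_sdlog = 0.7, seed = seed),
    scenario3 = scenario_spec(list(
      sub("bladder", 500, 1:11, prev = c(1, rep(0.25, 10)),
          w = c(6, rep(1, 10))),
      sub("skin", 500, 1:11, prev = c(0.25, 1, 1, rep(0.25, 8)),
          w = c(1, 4, 4, rep(1, 8)))),
      burden_meanlog = log(5000), burden_sdlog = 0.8, seed = seed),
    scenario4 = scenario_spec(list(
      sub("renal", 500, 1:3, prev = c(1, 1, 0.25), w = c(3, 3, 1)),
      sub("ovary", 500, 1:3, prev = c(0.25, 0.25, 1), w = c(1, 1, 5))),
      burden_meanlog = log(3000), burden_sdlog = 0.7, seed = seed),
    scenario5 = {
      subs <- lapply(1:9, function(i) {
        specific <- 3 + c(2 * i - 1, 2 * i)
        sub(paste0("type", i), 300, c(1:3, specific),
            prev = c(0.6, 0.6, 0.6, 0.9, 0.9),
            w = c(1, 1, 1, 3, 3))
      })
      scenario_spec(subs, burden_meanlog = log(3500), burden_sdlog = 0.9,
                    seed = seed)
    })
  attr(spec, "suggested_max_cosine") <-
    switch(name, scenario2 = 0.8, scenario3 = 0.9, 0.6)
  attr(spec, "template") <- name
  spec
}

#' Simulate a cohort from a scenario and a signature matrix
#'
#' For each sample: the total burden N is log-normal (rounded, minimum 1);
#' each of the subcohort's signatures is switched on by an independent
#' Bernoulli draw of its prevalence (a sample left with no active signature
#' falls back to the subcohort's highest-prevalence one); the burden is
#' split across active signatures by a multinomial whose probabilities are a
#' Dirichlet draw weighted by the activity weights; and each signature's
#' exposure is scattered over the 96 channels by a multinomial draw of its
#' profile (or independent Poisson counts with the same mean under
#' `noise = "poisson"`). Exposures and labels are recorded exactly as drawn.
#'
#' @param spec A [scenario_spec()].
#' @param signatures 96 x k signature matrix; `spec` signature indices refer
#'   to its columns.
#' @param seed Overrides `spec$seed`.
#' @return List with elements `catalogue` (an `sbs_catalogue`), `signatures`
#'   (the k_true referenced columns, normalized), `exposures` (samples x
#'   k_true counts), `labels` (subcohort per sample).
#' @export
simulate_cohort <- function(spec, signatures, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  S <- as_signature_matrix(signatures)
  S <- sweep(S, 2, colSums(S), "/")
  used <- sort(unique(unlist(lapply(spec$subcohorts, `[[`, "signatures"))))
  if (max(used) > ncol(S))
    stop("scenario references signature index ", max(used),
         " but only ", ncol(S), " profiles were supplied", call. = FALSE)
  k_true <- length(used)
  seed <- if (is.null(seed)) spec$seed else seed
  with_seed(seed, {
    m <- sum(vapply(spec$subcohorts, `[[`, 0, "n"))
    counts <- matrix(0, m, 96, dimnames = list(NULL, sbs_channels()))
    expo <- matrix(0, m, k_true)
    labels <- character(m)
    ids <- character(m)
    row <- 0L
    n_fallback <- 0L
    for (sc in spec$subcohorts) {
      sig_pos <- match(sc$signatures, used)
      for (i in seq_len(sc$n)) {
        row <- row + 1L
        labels[row] <- sc$name
        ids[row] <- sprintf("%s_%d", sc$name, i)
        N <- max(1L, as.integer(round(stats::rlnorm(1, spec$burden_meanlog,
                                                    spec$burden_sdlog))))
        on <- stats::runif(length(sc$signatures)) < sc$prevalence
        if (!any(on)) {
          on[which.max(sc$prevalence)] <- TRUE
          n_fallback <- n_fallback + 1L
        }
        act <- which(on)
        share <- rdirichlet1(sc$weights[act])
        e <- if (length(act) == 1) N else
          as.vector(stats::rmultinom(1, N, share))
        for (a in seq_along(act)) {
          jg <- sig_pos[act[a]]         # column in the ground-truth set
          js <- sc$signatures[act[a]]   # column in the supplied matrix
          if (e[a] == 0) next
          ch <- if (spec$noise == "multinomial")
            as.vector(stats::rmultinom(1, e[a], S[, js]))
          else stats::rpois(96, e[a] * S[, js])
          counts[row, ] <- counts[row, ] + ch
          expo[row, jg] <- expo[row, jg] + e[a]
        }
      }
    }
    if (n_fallback > 0)
      message(n_fallback, " sample(s) had no active signature after the ",
              "prevalence draws; fell back to the most prevalent one")
    rownames(counts) <- ids
    rownames(expo) <- ids
    colnames(expo) <- colnames(S)[used]
    list(catalogue = as_sbs_catalogue(counts),
         signatures = as_signature_matrix(S[, used, drop = FALSE]),
         exposures = expo,
         labels = labels)
  })
}
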
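#' Training configuration for the explainable autoencoder
#'
#' The model couples a nonlinear encoder (three dense hidden layers, each
#' followed by batch normalization and a softplus activation) with a linear
#' decoder `xhat = z W'` whose 96 x k weight matrix `W` is constrained
#' elementwise non-negative and plays the role of the signature matrix. The
#' latent layer uses a scaled softplus so exposures are non-negative and live
#' at mutation-count scale. Training minimizes the unnormalized Poisson
#' negative log-likelihood plus a minimum-volume penalty
#' `beta * log det(W'W + I)` by minibatch Adam, with early stopping on a
#' held-out fraction of samples.
#'
#' @param units Widths of the three encoder hidden layers.
#' @param latent_dim Latent width k (number of signatures); usually supplied
#'   by the caller, kept here so a config can be self-contained.
#' @param lr Adam learning rate.
#' @param batch Minibatch size.
#' @param max_epochs Maximum training epochs (0 returns the initialized,
#'   untrained model).
#' @param patience Early-stopping patience in epochs; must be positive and
#'   less than `max_epochs` when `max_epochs > 0`.
#' @param val_frac Fraction of samples held out to monitor early stopping;
#'   0 monitors the training loss instead.
#' @param beta Minimum-volume regularization strength.
#' @param eps Small positive constant inside the log of the Poisson term.
#' @return A list of class `"xae_control"`.
#' @export
xae_control <- function(units = c(128, 64, 32), latent_dim = NULL,
                        lr = 1e-3, batch = 64, max_epochs = 1000,
                        patience = 30, val_frac = 0.1, beta = 1e-3,
                        eps = 1e-7) {
  stopifnot(length(units) == 3, all(units >= 1),
            lr > 0, batch >= 2, max_epochs >= 0, patience >= 1,
            val_frac >= 0, val_frac < 1, beta >= 0, eps > 0)
  if (max_epochs > 0 && patience >= max_epochs)
    stop("patience must be smaller than max_epochs", call. = FALSE)
  structure(list(units = as.integer(units), latent_dim = latent_dim,
                 lr = lr, batch = as.integer(batch),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), val_frac = val_frac,
                 beta = beta, eps = eps),
            class = "xae_control")
}

#' Unnormalized Poisson negative log-likelihood
#'
#' `sum(-x * log(xhat + eps) + xhat)` over all entries; the `log(x!)` term,
#' constant in `xhat`, is dropped. This is the data term of the training
#' loss and is minimized at `xhat = x`.
#'
#' @param x Non-negative observed counts (vector or matrix).
#' @param xhat Non-negative predicted means, same shape.
#' @param eps Stability constant added inside the log (default 0: `xhat`
#'   must then be strictly positive wherever evaluated).
#' @return Scalar loss.
#' @export
poisson_nll <- function(x, xhat, eps = 0) {
  x <- as.matrix(x); xhat <- as.matrix(xhat)
  if (!identical(dim(x), dim(xhat)))
    stop("x and xhat must have the same shape", call. = FALSE)
  if (any(x < 0)) stop("x must be non-negative", call. = FALSE)
  xq <- xhat + eps
  if (any(xq <= 0)) stop("xhat must be positive (after the eps shift)", call. = FALSE)
  sum(-x * log(xq) + xhat)
}

#' Minimum-volume penalty on a signature matrix
#'
#' `beta * log det(W'W + I_k)`, computed through the Cholesky factor of the
#' small k x k Gram matrix. By Sylvester's determinant identity this equals
#' the penalty written on the 96 x 96 form `det(WW' + I_96)`, so the choice
#' of identity dimension is immaterial.
#'
#' @param W 96 x k non-negative matrix.
#' @param beta Penalty strength.
#' @return Scalar penalty value.
#' @export
min_volume_penalty <- function(W, beta = 1) {
  W <- as.matrix(W)
  if (any(!is.finite(W))) stop("W must be finite", call. = FALSE)
  G <- crossprod(W)
  diag(G) <- diag(G) + 1
  ld <- 2 * sum(log(diag(chol(G))))
  out <- beta * ld
  if (!is.finite(out)) stop("non-finite minimum-volume penalty (exploding weights?)",
                            call. = FALSE)
  out
}

#' Train one autoencoder
#'
#' Low-level single-model fit. Most users call [sigxae()] (which trains many
#' models and builds a consensus) or [refit_exposures()] (which freezes the
#' decoder); this function exposes one training run.
#'
#' @param counts Samples x 96 count matrix (an `sbs_catalogue` or a plain
#'   matrix in canonical channel order).
#' @param k Latent dimension (number of signatures).
#' @param control An [xae_control()] object.
#' @param seed Integer seed for weight initialization, the validation split
#'   and minibatch shuffling.
#' @param decoder Optional 96 x k non-negative matrix used to initialize the
#'   decoder weights.
#' @param frozen If `TRUE` the decoder is excluded from optimization (used
#'   for exposure refitting); the minimum-volume penalty, constant in that
#'   case, is dropped.
#' @param l1_weights,l1_activity L1 penalties on the last encoder layer's
#'   weights and on the latent output (used by assignment).
#' @return An object of class `"xae_fit"`.
#' @export
xae_train <- function(counts, k, control = xae_control(), seed = 1,
                      decoder = NULL, frozen = FALSE,
                      l1_weights = 0, l1_activity = 0) {
  X <- unclass_matrix(counts)
  if (k > min(control$units))
    warning("latent dimension k exceeds the narrowest encoder layer",
            call. = FALSE)
  model <- .cpp_xae_train(X, as.integer(k), control$units,
                          control$lr, control$batch, control$max_epochs,
                          control$patience, control$val_frac,
                          if (frozen) 0 else control$beta, control$eps,
                          l1_weights, l1_activity, as.integer(seed),
                          decoder, isTRUE(frozen))
  structure(list(model = model, k = as.integer(k), control = control,
                 seed = as.integer(seed), frozen = isTRUE(frozen),
                 channels = colnames(X)),
            class = "xae_fit")
}

#' @export
print.xae_fit <- function(x, ...) {
  h <- x$model$history$val
  cat(sprintf("xae_fit: k = %d, encoder %s%s\n", x$k,
              paste(x$control$units, collapse = "/"),
              if (x$frozen) ", frozen decoder" else ""))
  cat(sprintf("epochs run %d (best %d), monitored loss %.4f\n",
              length(h), x$model$best_epoch,
              if (length(h)) min(h) else NA_real_))
  invisible(x)
}

#' Encode, reconstruct and score a catalogue with a trained model
#'
#' `xae_encode` returns the latent representation (the exposures),
#' `xae_reconstruct` the predicted catalogue `z W'`, and
#' `reconstruction_error` the Frobenius norm `||C - Chat||_F` on the given
#' (original, non-augmented) catalogue.
#'
#' @param fit An `xae_fit`.
#' @param counts Samples x 96 matrix aligned to the canonical channels.
#' @return `xae_encode`: samples x k non-negative matrix; `xae_reconstruct`:
#'   samples x 96 matrix; `reconstruction_error`: scalar.
#' @export
xae_encode <- function(fit, counts) {
  X <- unclass_matrix(counts)
  out <- .cpp_xae_forward(fit$model, X)
  z <- out$z
  rownames(z) <- rownames(X)
  colnames(z) <- paste0("Sig", seq_len(ncol(z)))
  z
}

#' @rdname xae_encode
#' @export
xae_reconstruct <- function(fit, counts) {
  X <- unclass_matrix(counts)
  out <- .cpp_xae_forward(fit$model, X)
  xhat <- out$xhat
  dimnames(xhat) <- dimnames(X)
  xhat
}

#' @rdname xae_encode
#' @export
reconstruction_error <- function(fit, counts) {
  X <- unclass_matrix(counts)
  sqrt(sum((X - xae_reconstruct(fit, X))^2))
}

# strip classes/dimnames checks; accepts sbs_catalogue or plain matrix with
# 96 columns (assumed canonical order when unnamed)
unclass_matrix <- function(x) {
  if (inherits(x, "sbs_catalogue")) return(unclass(x))
  x <- as.matrix(x)
  if (ncol(x) != 96)
    stop("expected 96 channel columns, got ", ncol(x), call. = FALSE)
  if (!is.null(colnames(x))) {
    chan <- sbs_channels()
    if (!all(chan %in% colnames(x)))
      stop("channel mismatch: columns do not cover the 96 SBS labels",
           call. = FALSE)
    x <- x[, chan, drop = FALSE]
  }
  storage.mode(x) <- "double"
  x
}
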
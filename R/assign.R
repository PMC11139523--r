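# Exposure assignment: with the signature profiles fixed, the decoder is
# initialized to the column-normalized signatures and frozen, and only the
# encoder is trained (Poisson likelihood; no volume penalty, which would be
# constant). Two L1 penalties promote sparse, non-inflated exposures: one on
# the last encoder layer's weights and one on the latent output after its
# non-negative activation.

#' Column-normalize a signature matrix
#'
#' Divides every column by its sum so that each signature is a probability
#' profile over the 96 channels. Idempotent; errors on an all-zero column.
#'
#' @param S 96 x k non-negative matrix.
#' @return Normalized [as_signature_matrix()].
#' @export
normalize_signatures <- function(S) {
  S <- as_signature_matrix(S)
  cs <- colSums(S)
  if (any(cs <= 0))
    stop("signature column(s) with zero sum: ",
         paste(colnames(S)[cs <= 0], collapse = ", "), call. = FALSE)
  as_signature_matrix(sweep(unclass(S), 2, cs, "/"))
}

#' Refitting configuration
#'
#' @param l1_weights L1 coefficient on the last encoder layer's weights.
#' @param l1_activity L1 coefficient on the latent output (the exposures).
#' @param lr,batch,max_epochs,patience Training hyperparameters; training
#'   runs until the training loss stops improving for `patience` epochs (no
#'   validation split and no augmentation are used when refitting).
#' @param units Encoder hidden widths.
#' @return List of class `"assign_control"`.
#' @export
assign_control <- function(l1_weights = 1e-4, l1_activity = 1e-3,
                           lr = 1e-3, batch = 64, max_epochs = 1000,
                           patience = 50, units = c(128, 64, 32)) {
  stopifnot(l1_weights >= 0, l1_activity >= 0)
  structure(list(l1_weights = l1_weights, l1_activity = l1_activity,
                 lr = lr, batch = as.integer(batch),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 units = as.integer(units)),
            class = "assign_control")
}

#' Assign exposures against a fixed signature set
#'
#' Trains the encoder of the autoencoder while the decoder weights are set
#' to the column-normalized signatures and frozen, so the latent
#' representation is forced to explain each genome as a non-negative
#' combination of the given profiles. The returned latent values are the
#' exposures (mutation counts attributed to each signature).
#'
#' @param C Samples x 96 catalogue.
#' @param S 96 x k signature matrix (normalized internally).
#' @param control An [assign_control()].
#' @param rescale Scale each sample's exposures so they sum to its observed
#'   total mutation count (default `FALSE`: the raw latent output is
#'   returned).
#' @param seed Integer seed.
#' @return Samples x k non-negative exposure matrix; the trained model is
#'   attached as attribute `"fit"`.
#' @export
refit_exposures <- function(C, S, control = assign_control(),
                            rescale = FALSE, seed = 1) {
  C <- as_sbs_catalogue(C)
  S_norm <- normalize_signatures(S)
  ctrl <- xae_control(units = control$units, lr = control$lr,
                      batch = control$batch, max_epochs = control$max_epochs,
                      patience = control$patience, val_frac = 0, beta = 0)
  fit <- xae_train(C, ncol(S_norm), control = ctrl, seed = seed,
                   decoder = unclass(S_norm), frozen = TRUE,
                   l1_weights = control$l1_weights,
                   l1_activity = control$l1_activity)
  Z <- xae_encode(fit, C)
  colnames(Z) <- colnames(S_norm)
  if (rescale) {
    rs <- rowSums(Z)
    rs[rs == 0] <- 1
    Z <- Z * (rowSums(C) / rs)
  }
  attr(Z, "fit") <- fit
  Z
}
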
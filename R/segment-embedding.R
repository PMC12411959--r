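#' Resample a segment waveform to a fixed length and normalise amplitude
#'
#' Linear-interpolation resampling to exactly `L_in` points, followed by
#' per-segment min-max normalisation to \[0, 1\]. A (numerically) constant
#' segment maps to all 0.5 by convention.
#'
#' @param samples Numeric vector, length >= 2.
#' @param L_in Target length.
#' @return Numeric vector of length `L_in` in \[0, 1\].
#' @export
resample_to_fixed <- function(samples, L_in = 64) {
  if (length(samples) < 2) stopf("segment must contain at least 2 samples")
  y <- if (length(samples) == L_in) samples else
    stats::approx(seq(0, 1, length.out = length(samples)), samples,
                  seq(0, 1, length.out = L_in))$y
  rng <- max(y) - min(y)
  if (rng < 1e-12) return(rep(0.5, L_in))
  (y - min(y)) / rng
}

# Extract raw waveforms of all segments of one type from a set of records.
extract_segments <- function(records, type) {
  out <- list()
  for (rec in records) {
    for (b in rec$beats) {
      sg <- b$segments[[type]]
      if (is.null(sg)) next
      out[[length(out) + 1]] <- rec$samples[(sg[1] + 1):sg[2]]
    }
  }
  out
}

# ---- fully connected autoencoder (64 -> 32 -> 16 -> 32 -> 64) ------------

ae_init <- function(L_in, hidden, latent) {
  glorot <- function(nin, nout)
    matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
  list(W1 = glorot(L_in, hidden), b1 = numeric(hidden),
       W2 = glorot(hidden, latent), b2 = numeric(latent),
       W3 = glorot(latent, hidden), b3 = numeric(hidden),
       W4 = glorot(hidden, L_in), b4 = numeric(L_in))
}

sigmoid_ <- function(z) 1 / (1 + exp(-z))

ae_forward <- function(p, S) {
  Z1 <- sweep(S %*% p$W1, 2, p$b1, "+"); H1 <- pmax(Z1, 0)
  Z2 <- sweep(H1 %*% p$W2, 2, p$b2, "+"); L <- sigmoid_(Z2)
  Z3 <- sweep(L %*% p$W3, 2, p$b3, "+"); H3 <- pmax(Z3, 0)
  Z4 <- sweep(H3 %*% p$W4, 2, p$b4, "+"); Y <- sigmoid_(Z4)
  list(H1 = H1, L = L, H3 = H3, Y = Y)
}

ae_backward <- function(p, S, fw) {
  n <- nrow(S)
  dY <- 2 * (fw$Y - S) / (n * ncol(S))          # d MSE
  dZ4 <- dY * fw$Y * (1 - fw$Y)
  g <- list()
  g$W4 <- crossprod(fw$H3, dZ4); g$b4 <- colSums(dZ4)
  dH3 <- dZ4 %*% t(p$W4); dZ3 <- dH3 * (fw$H3 > 0)
  g$W3 <- crossprod(fw$L, dZ3); g$b3 <- colSums(dZ3)
  dL <- dZ3 %*% t(p$W3); dZ2 <- dL * fw$L * (1 - fw$L)
  g$W2 <- crossprod(fw$H1, dZ2); g$b2 <- colSums(dZ2)
  dH1 <- dZ2 %*% t(p$W2); dZ1 <- dH1 * (fw$H1 > 0)
  g$W1 <- crossprod(S, dZ1); g$b1 <- colSums(dZ1)
  g
}

#' Fit a per-segment-type autoencoder for waveform embedding
#'
#' Trains a small fully connected autoencoder (default 64-32-16-32-64) on
#' min-max-normalised, fixed-length resampled segment waveforms by Adam
#' minimisation of the mean squared reconstruction error. The 16-dimensional
#' latent code passes through a logistic squashing, so every latent
#' coordinate lies strictly in (0, 1).
#'
#' @param segments List of numeric vectors, all of one segment type.
#' @param segment_type One of `"P"`, `"QRS"`, `"T"`.
#' @param L_in Resample length (encoder input size).
#' @param latent_dim Latent dimension.
#' @param hidden Hidden layer width.
#' @param epochs Number of full-batch Adam steps.
#' @param lr Adam learning rate.
#' @param seed Integer seed; training is deterministic given the seed.
#' @param max_fit_segments Training-set subsample cap (for speed; the fit is
#'   still deterministic).
#' @return An object of class `ae_model`.
#' @export
fit_autoencoder <- function(segments, segment_type, L_in = 64, latent_dim = 16,
                            hidden = 32, epochs = 150, lr = 2e-3, seed = 1,
                            max_fit_segments = 1500) {
  segment_type <- match.arg(segment_type, SEGMENT_TYPES)
  if (length(segments) < 50)
    stopf(paste("need >= 50 %s segments to fit an autoencoder (got %d);",
                "generate more synthetic records to enlarge the fitting set"),
          segment_type, length(segments))
  with_seed_(seed, {
    if (length(segments) > max_fit_segments)
      segments <- segments[sample.int(length(segments), max_fit_segments)]
    S <- t(vapply(segments, resample_to_fixed, numeric(L_in), L_in = L_in))
    p <- ae_init(L_in, hidden, latent_dim)
    st <- adam_init(p)
    loss0 <- mean((ae_forward(p, S)$Y - S)^2)
    for (e in seq_len(epochs)) {
      fw <- ae_forward(p, S)
      g <- ae_backward(p, S, fw)
      upd <- adam_step(p, g, st, lr)
      p <- upd$params; st <- upd$state
    }
    final <- mean((ae_forward(p, S)$Y - S)^2)
    structure(list(segment_type = segment_type, L_in = L_in,
                   latent_dim = latent_dim, params = p,
                   meta = list(epochs = epochs, seed = seed,
                               n_segments = length(segments),
                               initial_mse = loss0, final_mse = final)),
              class = "ae_model")
  })
}

#' Embed a segment waveform with a trained autoencoder
#'
#' @param ae An `ae_model`.
#' @param segment Numeric vector (raw waveform) or a matrix of already
#'   resampled rows of length `ae$L_in`.
#' @param segment_type Optional; if given, must match `ae$segment_type`.
#' @return Latent vector in (0,1)^latent_dim (or a matrix of such rows).
#' @export
embed_segment <- function(ae, segment, segment_type = NULL) {
  stopifnot(inherits(ae, "ae_model"))
  if (!is.null(segment_type) && !identical(segment_type, ae$segment_type))
    stopf("segment type '%s' does not match the model's type '%s'",
          segment_type, ae$segment_type)
  S <- if (is.matrix(segment)) segment else
    matrix(resample_to_fixed(segment, ae$L_in), 1)
  Z1 <- sweep(S %*% ae$params$W1, 2, ae$params$b1, "+")
  Z2 <- sweep(pmax(Z1, 0) %*% ae$params$W2, 2, ae$params$b2, "+")
  L <- sigmoid_(Z2)
  if (is.matrix(segment)) L else drop(L)
}

#' Fit the three per-type segment autoencoders on a set of records
#'
#' Convenience wrapper fitting `AE_P`, `AE_QRS` and `AE_T` on all segments of
#' the given records. In a cross-validation pipeline this must be called on
#' training-fold records only; embedding of held-out segments then uses the
#' frozen parameters.
#'
#' @param records List of `ecg_record`.
#' @param seed Integer seed (per-type child seeds are derived from it).
#' @param ... Passed to [fit_autoencoder()].
#' @return Named list with elements `P`, `QRS`, `T` of class `ae_set`.
#' @export
fit_segment_embeddings <- function(records, seed = 1, ...) {
  aes <- lapply(seq_along(SEGMENT_TYPES), function(i) {
    type <- SEGMENT_TYPES[i]
    fit_autoencoder(extract_segments(records, type), type,
                    seed = child_seed(seed, i), ...)
  })
  names(aes) <- SEGMENT_TYPES
  structure(aes, class = "ae_set")
}

#' Serialize / restore an autoencoder model as portable JSON
#'
#' One file per segment type; all parameters are written in full double
#' precision, so embeddings from a restored model match the original.
#'
#' @param ae An `ae_model`.
#' @param path File path.
#' @return `write_ae_model` returns `path` invisibly; `read_ae_model`
#'   returns the `ae_model`.
#' @export
write_ae_model <- function(ae, path) {
  stopifnot(inherits(ae, "ae_model"))
  obj <- list(segment_type = ae$segment_type, L_in = ae$L_in,
              latent_dim = ae$latent_dim, meta = ae$meta,
              params = lapply(ae$params, function(p)
                if (is.matrix(p)) list(dim = dim(p), x = as.numeric(p))
                else list(dim = NULL, x = as.numeric(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ae_model
#' @export
read_ae_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    x <- as.numeric(p$x)
    if (!is.null(p$dim) && length(p$dim)) matrix(x, p$dim[1], p$dim[2]) else x
  })
  structure(list(segment_type = obj$segment_type, L_in = obj$L_in,
                 latent_dim = obj$latent_dim, params = params,
                 meta = as.list(obj$meta)),
            class = "ae_model")
}

#' @export
print.ae_model <- function(x, ...) {
  cat(sprintf("<ae_model %s: %d -> %d, %d segments, mse %.2e -> %.2e>\n",
              x$segment_type, x$L_in, x$latent_dim, x$meta$n_segments,
              x$meta$initial_mse, x$meta$final_mse))
  invisible(x)
}
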
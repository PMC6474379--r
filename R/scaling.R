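#' Affine feature scaling onto the unit interval
#'
#' Training features are affinely mapped coordinate-wise onto `[0,1]`
#' (`(x - min) / (max - min)`); the same transform is later applied to
#' test features, which may therefore land outside `[0,1]` -- that is
#' fine, the saturating spline is constant there.  Constant training
#' columns (zero range) map to the constant 0.5; such coordinates can
#' never acquire knots because their hinge columns are constant.
#'
#' @param X_raw numeric matrix or data.frame (n x D), finite entries.
#' @return list of class `scaled_design` with `X_scaled` (n x D matrix in
#'   `[0,1]`), `transforms` (data.frame `shift`, `range`) and
#'   `feature_names`.
#' @export
scale_fit_transform <- function(X_raw) {
  X <- as.matrix(X_raw)
  storage.mode(X) <- "double"
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-finite feature value at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  }
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  transforms <- data.frame(shift = lo, range = hi - lo)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("x", seq_len(ncol(X)))
  structure(list(X_scaled = scale_apply(transforms, X),
                 transforms = transforms, feature_names = nm),
            class = "scaled_design")
}

#' Apply stored scaling transforms to new raw data
#'
#' Values outside the training range are preserved (not clipped) and may
#' fall outside `[0,1]`.
#'
#' @param transforms data.frame with columns `shift`, `range` as produced
#'   by [scale_fit_transform()] (also accepts a `spline_model` scaling).
#' @param X_new numeric matrix or data.frame with one column per transform.
#' @return numeric matrix of scaled values.
#' @export
scale_apply <- function(transforms, X_new) {
  transforms <- as.data.frame(transforms)
  X <- as.matrix(X_new)
  storage.mode(X) <- "double"
  if (ncol(X) != nrow(transforms)) {
    stop(sprintf("X has %d columns but %d transforms are stored",
                 ncol(X), nrow(transforms)))
  }
  out <- X
  for (d in seq_len(ncol(X))) {
    rg <- transforms$range[d]
    out[, d] <- if (rg == 0) 0.5 else (X[, d] - transforms$shift[d]) / rg
  }
  out
}
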
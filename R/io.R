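#' Read a CSV dataset with a named response column
#'
#' RFC-4180 CSV with a header row.  All non-response columns must be
#' numeric (categorical integer codes are treated as ordinary numeric
#' features); the response column is extracted by name.
#'
#' @param path CSV file path.
#' @param response_column name of the response column.
#' @return list with `X` (numeric matrix), `y` (numeric vector), `names`
#'   (feature names).
#' @export
read_dataset <- function(path, response_column) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (!response_column %in% names(df)) {
    stop(sprintf("response column '%s' not found in %s (columns: %s)",
                 response_column, path, paste(names(df), collapse = ", ")))
  }
  y <- df[[response_column]]
  Xdf <- df[setdiff(names(df), response_column)]
  if (ncol(Xdf) == 0L) stop("dataset has no feature columns")
  for (nm in names(Xdf)) {
    if (!is.numeric(Xdf[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(Xdf[[nm]])))))
      stop(sprintf("non-numeric cell in column '%s' (first at row %d)",
                   nm, if (length(bad)) bad[1] else 1L))
    }
  }
  if (!is.numeric(y)) stop(sprintf("response column '%s' is not numeric",
                                   response_column))
  X <- as.matrix(Xdf)
  storage.mode(X) <- "double"
  list(X = X, y = as.numeric(y), names = colnames(X))
}

#' Serialize a saturating-spline model to JSON
#'
#' Doubles are written with 17 significant digits, so write/read
#' round-trips reproduce every double bit-faithfully.  Coordinates are
#' 1-based (`coord_base` records this).
#'
#' @param model a [spline_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "spline_model"))
  a <- model$measure$atoms
  doc <- list(
    version = "1",
    coord_base = 1L,
    D = model$measure$D,
    intercept = model$intercept,
    scaling = list(shift = model$scaling$shift, range = model$scaling$range),
    atoms = list(coord = a$coord, t = a$t, w = a$w),
    tau = if (is.null(model$tau)) NULL else model$tau,
    loss = if (is.null(model$loss)) NULL else
      list(kind = model$loss$kind, delta = model$loss$delta),
    gap = if (is.null(model$gap) || is.na(model$gap)) NULL else model$gap
  )
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a saturating-spline model from JSON
#'
#' @param path file written by [write_model()].
#' @return a [spline_model()].
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  atoms <- data.frame(coord = as.integer(unlist(doc$atoms$coord)),
                      t = as.numeric(unlist(doc$atoms$t)),
                      w = as.numeric(unlist(doc$atoms$w)))
  if (nrow(atoms) == 0L) atoms <- empty_atoms()
  loss <- NULL
  if (!is.null(doc$loss) && !is.null(doc$loss$kind)) {
    loss <- if (identical(doc$loss$kind, "pseudo_huber")) {
      loss_spec("pseudo_huber", delta = doc$loss$delta)
    } else loss_spec(doc$loss$kind)
  }
  spline_model(
    atomic_measure(atoms, D = as.integer(doc$D)),
    intercept = as.numeric(doc$intercept),
    scaling = data.frame(shift = as.numeric(doc$scaling$shift),
                         range = as.numeric(doc$scaling$range)),
    tau = if (is.null(doc$tau)) NULL else as.numeric(doc$tau),
    loss = loss,
    gap = if (is.null(doc$gap)) NA_real_ else as.numeric(doc$gap)
  )
}
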
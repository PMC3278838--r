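#' Fit min-max normalization parameters
#'
#' Records the per-feature minimum and maximum of the given (training) data
#' together with the target range. The min-max map
#' \deqn{v' = \frac{v - \min_P}{\max_P - \min_P}
#'   (\mathit{new\_max}_P - \mathit{new\_min}_P) + \mathit{new\_min}_P}
#' rescales every feature into a common range so that features with large
#' numeric spans cannot dominate those with small ones. Parameters are
#' fitted on the training partition only and reused unchanged on validation
#' and test data, so out-of-range values are transformed by the same affine
#' map and may fall outside the target range.
#'
#' @param data Tibble with numeric feature columns (bookkeeping columns
#'   `sequence`, `label`, `seq_id`, `start` are ignored).
#' @param range Target range `c(new_min, new_max)`, default `c(0, 1)`.
#' @return A `minmax_params` tibble with columns `feature`, `min`, `max`,
#'   `new_min`, `new_max`, `degenerate` (constant feature: `min == max`).
#' @seealso [apply_minmax()], [invert_minmax()]
#' @export
fit_minmax <- function(data, range = c(0, 1)) {
  stopifnot(is.data.frame(data), nrow(data) > 0)
  if (range[2] <= range[1]) abort("`range` must satisfy new_min < new_max.")
  feats <- feature_columns(data)
  if (length(feats) == 0L) abort("No feature columns to normalize.")
  mins <- unname(map_dbl(data[feats], min))
  maxs <- unname(map_dbl(data[feats], max))
  params <- tibble(feature = feats, min = mins, max = maxs,
                   new_min = range[1], new_max = range[2],
                   degenerate = mins == maxs)
  class(params) <- c("minmax_params", class(params))
  params
}

#' Apply (or invert) fitted min-max normalization
#'
#' Degenerate features (`min == max` on the fitting data) map to `new_min`,
#' a deterministic, bounded convention. Every feature column of `data` must
#' appear in `params`.
#'
#' @param data Tibble with feature columns.
#' @param params Parameters from [fit_minmax()].
#' @return `data` with feature columns rescaled.
#' @export
apply_minmax <- function(data, params) {
  minmax_transform(data, params, inverse = FALSE)
}

#' @rdname apply_minmax
#' @export
invert_minmax <- function(data, params) {
  minmax_transform(data, params, inverse = TRUE)
}

minmax_transform <- function(data, params, inverse) {
  stopifnot(inherits(params, "minmax_params"))
  feats <- feature_columns(data)
  unknown <- setdiff(feats, params$feature)
  if (length(unknown)) {
    abort(sprintf("Features without normalization parameters: %s",
                  paste(unknown, collapse = ", ")))
  }
  out <- data
  for (f in feats) {
    p <- params[params$feature == f, ]
    if (p$degenerate) {
      out[[f]] <- if (inverse) rep(p$min, nrow(data)) else
        rep(p$new_min, nrow(data))
    } else if (inverse) {
      out[[f]] <- (data[[f]] - p$new_min) / (p$new_max - p$new_min) *
        (p$max - p$min) + p$min
    } else {
      out[[f]] <- (data[[f]] - p$min) / (p$max - p$min) *
        (p$new_max - p$new_min) + p$new_min
    }
  }
  attr(out, "feature_info") <- attr(data, "feature_info")
  attr(out, "normalization") <- if (inverse) NULL else params
  out
}

#' Serialize min-max parameters as JSON
#'
#' @param params A `minmax_params` tibble.
#' @param file Output (input) path.
#' @return [write_minmax()]: `file`, invisibly; [read_minmax()]: the
#'   parameter tibble.
#' @export
write_minmax <- function(params, file) {
  jsonlite::write_json(as.data.frame(params), file, digits = NA,
                       auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_minmax
#' @export
read_minmax <- function(file) {
  params <- as_tibble(jsonlite::read_json(file, simplifyVector = TRUE))
  class(params) <- c("minmax_params", class(params))
  params
}
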
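#' Z-score normalization of a feature table
#'
#' Centers and scales every feature column; constant columns are centered
#' only. The centers/scales are stored so the same transform can be applied
#' to held-out data ([apply_normalization()]), which is the leak-free way to
#' normalize inside resampling loops. Normalizing over the whole dataset
#' before any split reproduces the whole-dataset-normalization convention of
#' the original analysis and is available as `replication mode` in
#' [nested_evaluate()].
#'
#' @param features tibble with numeric feature columns (and optionally
#'   `patient_id`).
#' @return Tibble of the same shape with attribute `normalization`
#'   (list: center, scale) and `normalized = TRUE`.
#' @export
normalize_features <- function(features) {
  id <- if ("patient_id" %in% names(features)) features[["patient_id"]] else NULL
  X <- drop_id(features)
  ctr <- vapply(X, mean, numeric(1))
  scl <- vapply(X, sd, numeric(1))
  scl[!is.finite(scl) | scl == 0] <- 1
  out <- as.data.frame(Map(function(col, m, s) (col - m) / s, X, ctr, scl),
                       check.names = FALSE)
  out <- tibble::as_tibble(out)
  if (!is.null(id)) out <- tibble::add_column(out, patient_id = id, .before = 1)
  attr(out, "normalization") <- list(center = ctr, scale = scl)
  attr(out, "normalized") <- TRUE
  out
}

#' @rdname normalize_features
#' @param newdata tibble with the same feature columns.
#' @param norm the `normalization` attribute of a normalized table (or a
#'   normalized table itself).
#' @export
apply_normalization <- function(newdata, norm) {
  if (!is.null(attr(norm, "normalization"))) norm <- attr(norm, "normalization")
  id <- if ("patient_id" %in% names(newdata)) newdata[["patient_id"]] else NULL
  X <- drop_id(newdata)
  X <- X[, names(norm$center), drop = FALSE]
  out <- as.data.frame(Map(function(col, m, s) (col - m) / s,
                           X, norm$center, norm$scale), check.names = FALSE)
  out <- tibble::as_tibble(out)
  if (!is.null(id)) out <- tibble::add_column(out, patient_id = id, .before = 1)
  out
}
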
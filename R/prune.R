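#' Recursive correlation pruning
#'
#' While any pair of surviving features has `|Pearson r|` above the
#' threshold, the most correlated pair is resolved by dropping its member
#' with the weaker univariate score. Ties in correlation are resolved by
#' column order, ties in score by feature name order (the alphabetically
#' earlier name survives), so the result is deterministic.
#'
#' @param features tibble/data frame of numeric candidate columns.
#' @param scores named numeric vector of univariate scores (higher =
#'   stronger; e.g. `-log(p)` or `|CI - 0.5|`), covering all candidates.
#' @param threshold absolute Pearson correlation above which a pair is
#'   considered redundant.
#' @return Character vector of surviving feature names (input order).
#' @export
correlation_prune <- function(features, scores, threshold = 0.8) {
  X <- drop_id(features)
  nms <- names(X)
  if (!all(nms %in% names(scores)))
    stop("correlation_prune: scores missing for some candidates")
  if (ncol(X) < 2) return(nms)
  cm <- abs(suppressWarnings(cor(as.matrix(X))))
  cm[!is.finite(cm)] <- 0
  diag(cm) <- 0
  alive <- rep(TRUE, ncol(X))
  while (TRUE) {
    sub <- cm[alive, alive, drop = FALSE]
    mx <- max(sub)
    if (mx <= threshold) break
    hit <- which(sub == mx, arr.ind = TRUE)[1, ]   # first pair in column order
    pair <- which(alive)[c(hit[["row"]], hit[["col"]])]
    sc <- scores[nms[pair]]
    drop_ix <- if (sc[1] < sc[2]) pair[1]
      else if (sc[2] < sc[1]) pair[2]
      else pair[order(nms[pair])][2]               # score tie: keep earlier name
    alive[drop_ix] <- FALSE
  }
  nms[alive]
}
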
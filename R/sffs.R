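#' Sequential floating forward selection
#'
#' Classical SFFS: repeatedly add the candidate that maximizes the objective,
#' then conditionally exclude members while an exclusion improves on the
#' best known objective at the smaller size. Subset evaluations are memoized
#' and an objective failure scores the subset `-Inf`.
#'
#' @param candidates character vector of candidate feature names.
#' @param objective function taking a character subset and returning a
#'   scalar score (larger = better), e.g. a cross-validated CI or AUC.
#' @param max_size largest subset size explored.
#' @return The best subset found (character vector, in inclusion order),
#'   with attributes `score` and `trace` (tibble of the best score per size).
#' @export
sffs <- function(candidates, objective, max_size = 10) {
  candidates <- unique(candidates)
  max_size <- min(max_size, length(candidates))
  if (max_size == 0) return(character(0))
  cache <- new.env(parent = emptyenv())
  eval_set <- function(s) {
    key <- paste(sort(s), collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch(as.numeric(objective(s)), error = function(e) -Inf)
    if (!length(val) || !is.finite(val)) val <- -Inf
    cache[[key]] <- val
    val
  }
  best_score <- rep(-Inf, max_size)
  best_set <- vector("list", max_size)
  note <- function(s) {
    k <- length(s)
    if (k >= 1 && k <= max_size) {
      sc <- eval_set(s)
      if (sc > best_score[k]) { best_score[k] <<- sc; best_set[[k]] <<- s }
      sc
    } else -Inf
  }
  S <- character(0)
  while (length(S) < max_size) {
    rem <- setdiff(candidates, S)
    if (!length(rem)) break
    gains <- vapply(rem, function(f) eval_set(c(S, f)), numeric(1))
    S <- c(S, rem[[which.max(gains)]])
    note(S)
    # floating exclusion
    while (length(S) > 2) {
      drops <- vapply(S, function(f) eval_set(setdiff(S, f)), numeric(1))
      j <- which.max(drops)
      if (drops[j] > best_score[length(S) - 1]) {
        S <- setdiff(S, S[j])
        note(S)
      } else break
    }
  }
  k_best <- which(best_score == max(best_score))[1]   # ties: smallest size
  out <- best_set[[k_best]]
  attr(out, "score") <- best_score[k_best]
  attr(out, "trace") <- tibble::tibble(size = seq_len(max_size),
                                       score = best_score)
  out
}
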
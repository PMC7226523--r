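#' Two-way hierarchical clustering of a normalized feature matrix
#'
#' Agglomerative average-linkage (UPGMA) clustering with Euclidean distance
#' on both patients (rows) and features (columns); the patient dendrogram is
#' cut into `k_patients` clusters. Intended for z-scored feature tables
#' ([normalize_features()]).
#'
#' @param features normalized feature table (tibble; `patient_id` used as
#'   row labels when present). No missing values allowed.
#' @param k_patients number of patient clusters (>= 2).
#' @return Object of class `cluster_assignment`: `clusters` tibble
#'   (patient_id, cluster), `row_hclust`, `col_hclust`, `k`.
#' @export
two_way_cluster <- function(features, k_patients = 4) {
  ids <- if ("patient_id" %in% names(features)) features[["patient_id"]]
         else as.character(seq_len(nrow(features)))
  X <- as.matrix(drop_id(features))
  if (anyNA(X)) stop("two_way_cluster: matrix contains missing values")
  if (k_patients < 2) stop("two_way_cluster: k_patients must be >= 2")
  rh <- hclust(dist(X, method = "euclidean"), method = "average")
  ch <- hclust(dist(t(X), method = "euclidean"), method = "average")
  cl <- cutree(rh, k = k_patients)
  structure(list(clusters = tibble::tibble(patient_id = ids,
                                           cluster = as.integer(cl)),
                 row_hclust = rh, col_hclust = ch, k = as.integer(k_patients)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> k = ", x$k, "; sizes: ",
      paste(table(x$clusters$cluster), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Chi-square association of patient clusters with clinical parameters
#'
#' Pearson chi-square test of independence (no continuity correction) of the
#' cluster assignment against each clinical parameter. Parameters with a
#' degenerate contingency table (a zero margin) are skipped with a warning;
#' a note is attached when any expected cell count is below 5.
#'
#' @param assignment a `cluster_assignment`.
#' @param clinical tibble with `patient_id` and categorical columns.
#' @return Tibble: `parameter`, `chisq`, `df`, `p`, `low_expected`.
#' @export
cluster_association <- function(assignment, clinical) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  df <- dplyr::inner_join(assignment$clusters, clinical, by = "patient_id")
  params <- setdiff(names(clinical), "patient_id")
  rows <- list()
  for (p in params) {
    tab <- table(df$cluster, df[[p]])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      warning("cluster_association: degenerate table for ", p, ", skipped")
      next
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    rows[[p]] <- tibble::tibble(parameter = p,
                                chisq = unname(ct$statistic),
                                df = unname(ct$parameter),
                                p = unname(ct$p.value),
                                low_expected = any(ct$expected < 5))
  }
  dplyr::bind_rows(rows)
}

#' Export clustered heatmap data
#'
#' Writes the feature matrix reordered by both dendrograms plus the leaf
#' orders, for external heatmap rendering.
#'
#' @param assignment a `cluster_assignment`.
#' @param features the feature table that was clustered.
#' @param file CSV path for the reordered matrix.
#' @return The reordered matrix, invisibly.
#' @export
write_heatmap_data <- function(assignment, features, file) {
  X <- as.matrix(drop_id(features))
  M <- X[assignment$row_hclust$order, assignment$col_hclust$order, drop = FALSE]
  write.csv(M, file, row.names = FALSE)
  invisible(M)
}
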
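#' Homogeneous phenotype groups
#'
#' Partitions isolates into groups sharing exactly the same binary response
#' pattern over the four qualitative traits. Grouping is by exact pattern
#' identity (isolates with the same responses to all tests), not by a
#' distance threshold. Labels are assigned in descending lexicographic order
#' of the pattern string, so they are reproducible across runs and input
#' orders; the all-ones and all-zeros patterns are flagged.
#'
#' @param matrix Binary matrix from [build_matrix()].
#' @return Tibble with one row per distinct pattern: `label` (A, B, ...),
#'   `pattern` (e.g. `"1011"`, trait order as in [pgpb_traits()]),
#'   `n_members`, `members` (list column of isolate ids),
#'   `positive_to_all`, `negative_to_all`.
#' @export
pattern_groups <- function(matrix) {
  if (nrow(matrix) == 0) stop("empty binary matrix", call. = FALSE)
  pat <- apply(matrix, 1, paste, collapse = "")
  patterns <- sort(unique(pat), decreasing = TRUE)
  members <- lapply(patterns, function(p) sort(rownames(matrix)[pat == p]))
  tibble::tibble(
    label = LETTERS[seq_along(patterns)],
    pattern = patterns,
    n_members = lengths(members),
    members = members,
    positive_to_all = patterns == strrep("1", ncol(matrix)),
    negative_to_all = patterns == strrep("0", ncol(matrix))
  )
}

#' PCA diagnostic on the binary trait matrix
#'
#' Principal component analysis of the standardized (correlation-matrix)
#' binary trait matrix, used to expose the leading traits and the variance
#' they explain. This is a diagnostic only: selection never depends on PCA
#' coordinates. Loadings are reported as correlations between traits and
#' component scores; the sign of each component is fixed so that its
#' largest-magnitude loading is positive. Traits with zero variance carry no
#' information for a correlation PCA and are dropped with a warning.
#'
#' @param matrix Binary matrix from [build_matrix()] (or any numeric matrix).
#' @param n_components Number of components to retain (default: all).
#' @return Object of class `pgpb_pca`: list with `loadings` (trait x
#'   component correlation matrix), `variance_fraction` (per retained
#'   component; fractions over *all* components sum to 1), `scores`
#'   (isolate x component), `dropped_traits`.
#' @export
run_pca <- function(matrix, n_components = NULL) {
  if (nrow(matrix) < 2) stop("PCA needs at least 2 isolates", call. = FALSE)
  vars <- apply(matrix, 2, stats::var)
  dropped <- colnames(matrix)[vars == 0]
  if (length(dropped) > 0) {
    warning(
      "dropping zero-variance trait(s): ", paste(dropped, collapse = ", ")
    )
  }
  keep <- matrix[, vars > 0, drop = FALSE]
  if (ncol(keep) < 2) {
    stop("PCA needs at least 2 traits with nonzero variance", call. = FALSE)
  }
  fit <- prcomp(keep, center = TRUE, scale. = TRUE)
  all_fraction <- fit$sdev^2 / sum(fit$sdev^2)
  k <- if (is.null(n_components)) length(fit$sdev) else
    min(n_components, length(fit$sdev))
  # correlation loadings: eigenvector scaled by component sd (variables have
  # unit variance after standardization)
  loadings <- fit$rotation[, seq_len(k), drop = FALSE] %*%
    diag(fit$sdev[seq_len(k)], k, k)
  scores <- fit$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(
      loadings = loadings,
      variance_fraction = setNames(all_fraction[seq_len(k)],
        paste0("PC", seq_len(k))
      ),
      variance_fraction_all = all_fraction,
      scores = scores,
      dropped_traits = dropped
    ),
    class = "pgpb_pca"
  )
}

#' @export
print.pgpb_pca <- function(x, ...) {
  cat("<pgpb_pca>", ncol(x$scores), "components;",
    sprintf(
      "first two explain %.0f%% of total variance\n",
      100 * sum(x$variance_fraction_all[seq_len(min(
        2,
        length(x$variance_fraction_all)
      ))])
    )
  )
  print(round(x$loadings, 3))
  invisible(x)
}
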
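#' Binary code for a qualitative assay
#'
#' Collapses the per-replicate outcomes of one qualitative screening assay
#' (e.g. P-solubilization halo, CAS siderophore colour change) into a single
#' binary code: 1 only when every replicate is positive, 0 otherwise
#' (all-negative, a single positive, or any mixed outcome). The rule is
#' deliberately conservative: a trait counts for an isolate only when it is
#' reproducible across all replicates.
#'
#' @param outcomes Non-empty logical vector of per-replicate outcomes
#'   (`TRUE` = positive).
#' @return Integer 0 or 1.
#' @examples
#' encode_binary(c(TRUE, TRUE, TRUE)) # 1
#' encode_binary(c(TRUE, FALSE, FALSE)) # 0
#' @export
encode_binary <- function(outcomes) {
  outcomes <- as.logical(outcomes)
  if (length(outcomes) == 0) {
    stop("empty replicate list: an absent assay must be handled by the caller",
      call. = FALSE
    )
  }
  if (anyNA(outcomes)) stop("replicate outcomes must not be NA", call. = FALSE)
  as.integer(all(outcomes))
}

#' Isolate-by-trait binary matrix
#'
#' Applies [encode_binary()] to every isolate and qualitative trait of a
#' dataset. An assay absent for an isolate contributes 0 (it cannot support
#' selection), so the matrix has no missing cells.
#'
#' @param data A [pgpb_data] object.
#' @return Integer matrix with one row per isolate (rownames = isolate ids,
#'   in `data$isolates` order) and one column per trait in [pgpb_traits()]
#'   order; entries in \{0, 1\}.
#' @export
build_matrix <- function(data) {
  stopifnot(inherits(data, "pgpb_data"))
  ids <- data$isolates$isolate_id
  traits <- pgpb_traits()
  mat <- matrix(0L, nrow = length(ids), ncol = length(traits),
    dimnames = list(ids, traits)
  )
  if (nrow(data$qualitative) > 0) {
    coded <- data$qualitative |>
      dplyr::group_by(.data$isolate_id, .data$trait) |>
      dplyr::summarise(code = encode_binary(.data$outcome), .groups = "drop")
    mat[cbind(coded$isolate_id, coded$trait)] <- coded$code
  }
  mat
}

#' Per-group positivity summary
#'
#' Fraction of isolates coded positive (binary code 1) for each functional
#' group and trait, the per-group analogue of the screening bar charts used
#' to compare functional groups.
#'
#' @param matrix Binary matrix from [build_matrix()].
#' @param groups Named character vector mapping isolate id to functional
#'   group, or a data frame with columns `isolate_id` and `group`.
#' @return Tibble with columns `group`, `trait`, `n_isolates`, `n_positive`,
#'   `fraction_positive` (exact ratio in \[0, 1\]).
#' @export
summarize_positivity <- function(matrix, groups) {
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$isolate_id)
  }
  ids <- rownames(matrix)
  missing <- setdiff(ids, names(groups))
  if (length(missing) > 0) {
    stop("isolates without a group mapping: ",
      paste(head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  grp <- groups[ids]
  empty <- setdiff(unique(unname(groups)), unique(unname(grp)))
  if (length(empty) > 0) {
    stop("group(s) with zero isolates in the matrix: ",
      paste(empty, collapse = ", "),
      call. = FALSE
    )
  }
  long <- tibble::tibble(
    isolate_id = rep(ids, times = ncol(matrix)),
    group = rep(unname(grp), times = ncol(matrix)),
    trait = rep(colnames(matrix), each = nrow(matrix)),
    code = as.integer(matrix)
  )
  long |>
    dplyr::group_by(.data$group, .data$trait) |>
    dplyr::summarise(
      n_isolates = dplyr::n(),
      n_positive = sum(.data$code),
      fraction_positive = sum(.data$code) / dplyr::n(),
      .groups = "drop"
    )
}
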
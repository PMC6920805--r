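#' Quartile summary for one group x parameter
#'
#' Constructor for the per-(functional group, parameter) population summary
#' used as the coding cut-offs. By default a summary violating
#' q1 <= median <= q3 is rejected; `validate = FALSE` admits such a summary
#' (needed only when reproducing externally supplied cut-off tables that
#' contain a typographical inconsistency).
#'
#' @param group Functional group label.
#' @param parameter Quantitative parameter name.
#' @param q1,median,q3 First quartile, median, third quartile in assay units.
#' @param validate Enforce `q1 <= median <= q3` (default `TRUE`).
#' @return One-row tibble of class `pgpb_quartiles` with columns `group`,
#'   `parameter`, `q1`, `median`, `q3`.
#' @export
quartile_summary <- function(group, parameter, q1, median, q3,
                             validate = TRUE) {
  if (validate && !(q1 <= median && median <= q3)) {
    stop(sprintf(
      "invalid quartile summary for %s %s: q1 %g, median %g, q3 %g violates q1 <= median <= q3",
      group, parameter, q1, median, q3
    ), call. = FALSE)
  }
  out <- tibble::tibble(
    group = as.character(group), parameter = as.character(parameter),
    q1 = as.double(q1), median = as.double(median), q3 = as.double(q3)
  )
  class(out) <- c("pgpb_quartiles", class(out))
  out
}

#' Quartiles of pooled replicate values
#'
#' Median and quartiles over all replicates of all isolates of one functional
#' group for one parameter, by linear interpolation of order statistics
#' (`stats::quantile` type 7).
#'
#' @param values Numeric vector of at least 4 pooled replicate values.
#' @inheritParams quartile_summary
#' @return As [quartile_summary()].
#' @examples
#' compute_quartiles(1:8, "mesophilic", "iaa") # q1 2.75, median 4.5, q3 6.25
#' @export
compute_quartiles <- function(values, group = NA_character_,
                              parameter = NA_character_) {
  values <- as.double(values)
  if (length(values) < 4) {
    stop("quartiles need at least 4 pooled values", call. = FALSE)
  }
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE))
  quartile_summary(group, parameter, q[1], q[2], q[3])
}

#' All group x parameter quartile summaries of a dataset
#'
#' Pools the (QC-cleaned) replicate values of every isolate within each
#' functional group and computes the population quartiles per parameter.
#' Per the flow sheet, the pooled raw replicates define the cut-offs even
#' though the isolate-level value entering coding is a replicate mean.
#'
#' @param quantitative Quantitative tibble (`isolate_id`, `parameter`,
#'   `replicate`, `value`), typically `qc_dataset(...)$quantitative`.
#' @param isolates Isolate table (`isolate_id`, `group`) or a [pgpb_data]
#'   object.
#' @return Tibble with one row per (group, parameter) present: columns
#'   `group`, `parameter`, `q1`, `median`, `q3`.
#' @export
quartile_summaries <- function(quantitative, isolates) {
  if (inherits(isolates, "pgpb_data")) isolates <- isolates$isolates
  quant <- dplyr::inner_join(
    tibble::as_tibble(quantitative),
    isolates[, c("isolate_id", "group")],
    by = "isolate_id"
  )
  quant |>
    dplyr::group_by(.data$group, .data$parameter) |>
    dplyr::summarise(
      q1 = quantile(.data$value, 0.25, type = 7, names = FALSE),
      median = quantile(.data$value, 0.5, type = 7, names = FALSE),
      q3 = quantile(.data$value, 0.75, type = 7, names = FALSE),
      .groups = "drop"
    )
}

#' Ordinal 0-3 code for one assay value
#'
#' The population-quartile coding rule: code 0 for an absent assay or no
#' detectable activity (value <= 0); code 1 for a positive value below the
#' group median; code 2 for a value from the median up to (but excluding) the
#' third quartile; code 3 for a value at or above the third quartile.
#' Boundaries are closed on the upper side (a value exactly at the median
#' codes 2; exactly at q3 codes 3).
#'
#' @param value Assay value (isolate-level, typically a replicate mean), or
#'   `NA` for an assay that was not performed. Vectorized.
#' @param summary A [quartile_summary()] row (or any list with `median` and
#'   `q3`).
#' @return Integer code(s) in \{0, 1, 2, 3\}.
#' @examples
#' s <- quartile_summary("mesophilic", "p_mineralization", 1.12, 1.81, 2.61)
#' assign_code(4.90, s) # 3
#' assign_code(2.15, s) # 2
#' assign_code(NA, s) # 0
#' @export
assign_code <- function(value, summary) {
  med <- summary$median
  q3 <- summary$q3
  code <- integer(length(value))
  v <- as.double(value)
  pos <- !is.na(v) & v > 0
  code[pos & v < med] <- 1L
  code[pos & v >= med & v < q3] <- 2L
  code[pos & v >= q3] <- 3L
  code
}

#' Code every isolate x parameter of a dataset
#'
#' Computes the isolate-level value (mean of QC-kept replicates), looks up
#' the matching group x parameter quartile summary, and applies
#' [assign_code()]. Every isolate receives a code for every parameter in
#' [pgpb_parameters()]; an unperformed assay codes 0.
#'
#' @inheritParams quartile_summaries
#' @param summaries Quartile summary tibble (`group`, `parameter`, `q1`,
#'   `median`, `q3`), e.g. from [quartile_summaries()] or an externally
#'   supplied cut-off table.
#' @return Tibble with columns `isolate_id`, `group`, `parameter`, `value`
#'   (replicate mean; `NA` if absent), `code`.
#' @export
code_table <- function(quantitative, isolates, summaries) {
  if (inherits(isolates, "pgpb_data")) isolates <- isolates$isolates
  quant <- tibble::as_tibble(quantitative)
  summaries <- tibble::as_tibble(summaries)
  if (nrow(isolates) == 0) {
    return(tibble::tibble(
      isolate_id = character(), group = character(), parameter = character(),
      value = double(), code = integer()
    ))
  }
  grid <- tidyr::expand_grid(
    isolates[, c("isolate_id", "group")],
    parameter = pgpb_parameters()
  )
  means <- quant |>
    dplyr::group_by(.data$isolate_id, .data$parameter) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  tab <- dplyr::left_join(grid, means, by = c("isolate_id", "parameter"))
  performed <- !is.na(tab$value)
  need <- unique(tab[performed, c("group", "parameter")])
  have <- summaries[, c("group", "parameter")]
  miss <- dplyr::anti_join(need, have, by = c("group", "parameter"))
  if (nrow(miss) > 0) {
    stop(
      "missing quartile summaries for: ",
      paste(sprintf("%s/%s", miss$group, miss$parameter), collapse = ", "),
      call. = FALSE
    )
  }
  tab <- dplyr::left_join(tab, summaries, by = c("group", "parameter"))
  tab$code <- 0L
  idx <- which(performed)
  for (i in idx) {
    tab$code[i] <- assign_code(
      tab$value[i],
      list(median = tab$median[i], q3 = tab$q3[i])
    )
  }
  tab[, c("isolate_id", "group", "parameter", "value", "code")]
}
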
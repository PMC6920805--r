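new_selection_report <- function(first_round, second_round, excluded, final) {
  structure(
    list(
      first_round = tibble::as_tibble(first_round),
      second_round = tibble::as_tibble(second_round),
      excluded = tibble::as_tibble(excluded),
      final = as.character(final)
    ),
    class = "pgpb_selection"
  )
}

#' @export
print.pgpb_selection <- function(x, ...) {
  cat(
    "<pgpb_selection>", nrow(x$first_round), "first-round entries |",
    nrow(x$second_round), "second-round isolates |",
    nrow(x$excluded), "excluded |",
    length(x$final), "final\n"
  )
  invisible(x)
}

#' First-round selection: code 3 refined by Tukey homogeneous groups
#'
#' For every functional group and parameter, the candidates are the isolates
#' whose quartile code is 3 (value at or above the group's third quartile).
#' When two or more candidates compete, their replicate values are compared
#' by one-way ANOVA / Tukey HSD and only candidates carrying the top
#' homogeneous-group letter (the letter of the highest mean, `a`) are kept;
#' a lone candidate is selected without a test.
#'
#' @param codes Code table from [code_table()].
#' @param quantitative QC-cleaned quantitative tibble (replicate values used
#'   for the Tukey comparison).
#' @param alpha Significance level for Tukey HSD (default 0.05).
#' @param compare `"candidates"` (default) runs the Tukey comparison over the
#'   code-3 candidate set only; `"group"` compares over all assayed isolates
#'   of the functional group, keeping only code-3 isolates with the top
#'   letter.
#' @return Tibble `isolate_id`, `group`, `parameter`, `rule` (one row per
#'   isolate x parameter selected).
#' @export
first_round <- function(codes, quantitative, alpha = 0.05,
                        compare = c("candidates", "group")) {
  compare <- match.arg(compare)
  quant <- tibble::as_tibble(quantitative)
  out <- list()
  cells <- unique(codes[, c("group", "parameter")])
  for (i in seq_len(nrow(cells))) {
    g <- cells$group[i]
    p <- cells$parameter[i]
    cell <- codes[codes$group == g & codes$parameter == p, , drop = FALSE]
    cand <- cell$isolate_id[cell$code == 3L]
    if (length(cand) == 0) next
    rule <- sprintf("highest %s among %s (code 3)", p, g)
    if (length(cand) == 1) {
      out[[length(out) + 1]] <- tibble::tibble(
        isolate_id = cand, group = g, parameter = p,
        rule = paste0(rule, ", single candidate")
      )
      next
    }
    pool_ids <- if (compare == "candidates") cand else
      cell$isolate_id[cell$code > 0L]
    reps <- quant[
      quant$parameter == p & quant$isolate_id %in% pool_ids, ,
      drop = FALSE
    ]
    vals <- split(reps$value, reps$isolate_id)
    # Tukey needs >= 2 replicates everywhere; fall back to keeping all
    # candidates when the design cannot support the comparison
    if (length(vals) < 2 || any(lengths(vals) < 2)) {
      out[[length(out) + 1]] <- tibble::tibble(
        isolate_id = sort(cand), group = g, parameter = p,
        rule = paste0(rule, ", comparison not testable")
      )
      next
    }
    tk <- tukey_letters(vals, alpha = alpha)
    top_letter <- substr(tk$letters[1], 1, 1)
    keep <- tk$level[grepl(top_letter, tk$letters, fixed = TRUE)]
    keep <- intersect(keep, cand)
    out[[length(out) + 1]] <- tibble::tibble(
      isolate_id = sort(keep), group = g, parameter = p,
      rule = paste0(rule, ", top Tukey homogeneous group")
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      isolate_id = character(), group = character(),
      parameter = character(), rule = character()
    ))
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$group, .data$parameter, .data$isolate_id)
}

#' Second-round selection: breadth over multiple traits
#'
#' Adds isolates not already selected that show at least `min_traits`
#' parameters with any detectable level (code >= 1). This complements the
#' first round's depth criterion with a breadth criterion: an isolate good at
#' several things is worth keeping even if it tops no single parameter.
#'
#' @inheritParams first_round
#' @param already_selected Character vector of isolate ids selected in the
#'   first round.
#' @param min_traits Minimum number of parameters with code >= 1 (default 2).
#' @return Tibble `isolate_id`, `n_traits`, `rule`.
#' @export
second_round <- function(codes, already_selected, min_traits = 2) {
  counts <- codes |>
    dplyr::group_by(.data$isolate_id) |>
    dplyr::summarise(n_traits = sum(.data$code >= 1L), .groups = "drop")
  pick <- counts[
    !(counts$isolate_id %in% already_selected) &
      counts$n_traits >= min_traits, ,
    drop = FALSE
  ]
  tibble::tibble(
    isolate_id = sort(pick$isolate_id),
    n_traits = pick$n_traits[order(pick$isolate_id)],
    rule = sprintf(
      "%d parameters at code >= 1 (threshold %d)",
      pick$n_traits[order(pick$isolate_id)], min_traits
    )
  )
}

#' Viability exclusion and final report
#'
#' Removes selected isolates whose viability flag is `FALSE` (loss of
#' viability in cold storage) and assembles the full selection report.
#'
#' @param first Tibble from [first_round()].
#' @param second Tibble from [second_round()].
#' @param isolates Isolate table (`isolate_id`, `viability_ok`) or a
#'   [pgpb_data] object.
#' @return A `pgpb_selection` object: list with `first_round`,
#'   `second_round`, `excluded` (reason `"viability"`), and `final`
#'   (duplicate-free, sorted).
#' @export
viability_filter <- function(first, second, isolates) {
  if (inherits(isolates, "pgpb_data")) isolates <- isolates$isolates
  selected <- union(first$isolate_id, second$isolate_id)
  flags <- setNames(isolates$viability_ok, isolates$isolate_id)
  unknown <- setdiff(selected, names(flags))
  if (length(unknown) > 0) {
    stop("no viability flag for: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  out <- sort(selected[flags[selected]])
  excluded <- sort(selected[!flags[selected]])
  new_selection_report(
    first_round = first,
    second_round = second,
    excluded = tibble::tibble(
      isolate_id = excluded,
      reason = rep("viability", length(excluded))
    ),
    final = out
  )
}

#' Run the full quantitative selection stage
#'
#' Convenience wrapper chaining [qc_dataset()], [quartile_summaries()],
#' [code_table()], [first_round()], [second_round()] and
#' [viability_filter()] on a dataset.
#'
#' @param data A [pgpb_data] object with quantitative replicates.
#' @inheritParams qc_filter
#' @inheritParams first_round
#' @inheritParams second_round
#' @return A `pgpb_selection` report; the intermediate tables are attached as
#'   attributes `qc_log`, `summaries`, `codes`.
#' @export
select_isolates <- function(data, cv_threshold = 10, alpha = 0.05,
                            min_traits = 2,
                            compare = c("candidates", "group")) {
  stopifnot(inherits(data, "pgpb_data"))
  qc <- qc_dataset(data, cv_threshold = cv_threshold)
  summaries <- quartile_summaries(qc$quantitative, data)
  codes <- code_table(qc$quantitative, data, summaries)
  fr <- first_round(codes, qc$quantitative, alpha = alpha, compare = compare)
  sr <- second_round(codes, unique(fr$isolate_id), min_traits = min_traits)
  report <- viability_filter(fr, sr, data)
  attr(report, "qc_log") <- qc$log
  attr(report, "summaries") <- summaries
  attr(report, "codes") <- codes
  report
}
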
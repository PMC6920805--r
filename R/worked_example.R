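#' Worked example: 19 selected isolates from a durum wheat rhizosphere screen
#'
#' Published summary data of the isolates retained by the quantitative
#' selection stage of a durum wheat rhizosphere screening study: isolate-level
#' mean assay values, the per-group population cut-offs (median and
#' quartiles), the printed ordinal codes, and the round-by-round selection
#' membership (15 first-round entries, 4 second-round isolates, 3 viability
#' exclusions, 16 final). Useful for demonstrating [assign_code()] and the
#' selection accounting without raw replicate data.
#'
#' Two known internal inconsistencies of the source tables are preserved
#' as-is: the pseudomonad P-mineralization cut-off row violates
#' q1 <= median <= q3 (a typographical error; [quartile_summary()] accepts it
#' only with `validate = FALSE`), and a few printed codes (20P nitrification;
#' the whole 60M row, whose assay values are marked not-assessed yet carry
#' non-zero codes) cannot be reproduced from the printed values.
#'
#' @return List of tibbles: `isolates` (`isolate_id`, `group`,
#'   `viability_ok`), `values` (`isolate_id`, `parameter`, `value` -
#'   isolate-level means), `cutoffs` (`group`, `parameter`, `q1`, `median`,
#'   `q3`), `published_codes` (`isolate_id`, `parameter`, `code`), `rounds`
#'   (`isolate_id`, `round`, `group`, `parameter`).
#' @examples
#' ex <- worked_example()
#' s <- ex$cutoffs[ex$cutoffs$group == "mesophilic" &
#'   ex$cutoffs$parameter == "p_mineralization", ]
#' assign_code(4.90, s) # isolate 36M -> 3
#' @export
worked_example <- function() {
  path <- function(name) {
    system.file("extdata", name, package = "pgpbscreen", mustWork = TRUE)
  }
  read1 <- function(name, types) {
    readr::read_csv(path(name),
      show_col_types = FALSE, progress = FALSE,
      col_types = types
    )
  }
  list(
    isolates = read1("worked_example_isolates.csv", "ccl"),
    values = read1("worked_example_values.csv", "ccd"),
    cutoffs = read1("worked_example_cutoffs.csv", "ccddd"),
    published_codes = read1("worked_example_codes.csv", "cci"),
    rounds = read1("worked_example_rounds.csv", "cccc")
  )
}
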
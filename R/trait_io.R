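#' Assemble and validate a screening dataset
#'
#' Bundles the tidy (long-format) tables of a rhizosphere screening experiment
#' into a single validated object. One row of `qualitative` or `quantitative`
#' is one measurement on one replicate; an assay that was not performed for an
#' isolate is simply absent (never recorded as zero).
#'
#' @param isolates Data frame with columns `isolate_id`, `group`,
#'   `viability_ok`. Isolate ids are a numeric stem plus the group suffix
#'   letter (M mesophilic, B spore-forming, P pseudomonads, A actinobacteria),
#'   e.g. `"36M"`, `"19B"`.
#' @param qualitative Optional data frame with columns `isolate_id`, `trait`,
#'   `replicate`, `outcome`. `outcome` may be logical or the strings
#'   `"pos"`/`"neg"`.
#' @param quantitative Optional data frame with columns `isolate_id`,
#'   `parameter`, `replicate`, `value` (non-negative; units are uM for
#'   P-mineralization and nitrification, ug/mL for IAA).
#' @param growth Optional data frame with columns `pot_id`, `treatment`
#'   (an isolate id or `"control"`), `biomass_g`, `height_cm` (both strictly
#'   positive).
#'
#' @return An object of class `pgpb_data`: a list of validated tibbles
#'   `isolates`, `qualitative`, `quantitative`, `growth`.
#' @examples
#' d <- pgpb_data(
#'   isolates = data.frame(
#'     isolate_id = "36M", group = "mesophilic", viability_ok = TRUE
#'   ),
#'   quantitative = data.frame(
#'     isolate_id = "36M", parameter = "p_mineralization",
#'     replicate = 1:3, value = c(4.8, 4.9, 5.0)
#'   )
#' )
#' d$quantitative
#' @export
pgpb_data <- function(isolates, qualitative = NULL, quantitative = NULL,
                      growth = NULL) {
  isolates <- tibble::as_tibble(isolates)
  need <- c("isolate_id", "group", "viability_ok")
  if (!all(need %in% names(isolates))) {
    stop("`isolates` must have columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  isolates$isolate_id <- as.character(isolates$isolate_id)
  isolates$group <- as.character(isolates$group)
  isolates$viability_ok <- as.logical(isolates$viability_ok)

  dup <- isolates$isolate_id[duplicated(isolates$isolate_id)]
  if (length(dup) > 0) {
    stop("duplicate isolate ids: ", paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  bad_group <- setdiff(unique(isolates$group), pgpb_groups())
  if (length(bad_group) > 0) {
    stop("unknown functional group(s): ", paste(bad_group, collapse = ", "),
      call. = FALSE
    )
  }
  expected <- unname(pgpb_group_suffix()[isolates$group])
  suffix <- sub("^[0-9]+", "", isolates$isolate_id)
  mism <- which(suffix != expected)
  if (length(mism) > 0) {
    stop(
      "isolate id suffix inconsistent with functional group for: ",
      paste(sprintf(
        "%s (group %s, expected suffix %s)",
        isolates$isolate_id[mism], isolates$group[mism], expected[mism]
      ), collapse = "; "),
      call. = FALSE
    )
  }

  qualitative <- validate_qualitative(qualitative, isolates$isolate_id)
  quantitative <- validate_quantitative(quantitative, isolates$isolate_id)
  growth <- validate_growth_table(growth)

  structure(
    list(
      isolates = isolates, qualitative = qualitative,
      quantitative = quantitative, growth = growth
    ),
    class = "pgpb_data"
  )
}

validate_qualitative <- function(qualitative, ids) {
  if (is.null(qualitative)) {
    return(tibble::tibble(
      isolate_id = character(), trait = character(),
      replicate = integer(), outcome = logical()
    ))
  }
  qualitative <- tibble::as_tibble(qualitative)
  need <- c("isolate_id", "trait", "replicate", "outcome")
  if (!all(need %in% names(qualitative))) {
    stop("`qualitative` must have columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  qualitative$isolate_id <- as.character(qualitative$isolate_id)
  qualitative$trait <- as.character(qualitative$trait)
  qualitative$replicate <- as.integer(qualitative$replicate)
  if (is.character(qualitative$outcome)) {
    ok <- qualitative$outcome %in% c("pos", "neg")
    if (!all(ok)) {
      stop("qualitative outcomes must be 'pos' or 'neg'", call. = FALSE)
    }
    qualitative$outcome <- qualitative$outcome == "pos"
  }
  qualitative$outcome <- as.logical(qualitative$outcome)
  bad <- setdiff(unique(qualitative$trait), pgpb_traits())
  if (length(bad) > 0) {
    stop("unknown qualitative trait(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  orphan <- setdiff(unique(qualitative$isolate_id), ids)
  if (length(orphan) > 0) {
    stop("qualitative rows for unknown isolate(s): ",
      paste(orphan, collapse = ", "),
      call. = FALSE
    )
  }
  qualitative
}

validate_quantitative <- function(quantitative, ids) {
  if (is.null(quantitative)) {
    return(tibble::tibble(
      isolate_id = character(), parameter = character(),
      replicate = integer(), value = double()
    ))
  }
  quantitative <- tibble::as_tibble(quantitative)
  need <- c("isolate_id", "parameter", "replicate", "value")
  if (!all(need %in% names(quantitative))) {
    stop("`quantitative` must have columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  quantitative$isolate_id <- as.character(quantitative$isolate_id)
  quantitative$parameter <- as.character(quantitative$parameter)
  quantitative$replicate <- as.integer(quantitative$replicate)
  quantitative$value <- as.double(quantitative$value)
  bad <- setdiff(unique(quantitative$parameter), pgpb_parameters())
  if (length(bad) > 0) {
    stop("unknown quantitative parameter(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  neg <- which(!is.finite(quantitative$value) | quantitative$value < 0)
  if (length(neg) > 0) {
    stop(
      "negative or non-finite assay value(s), e.g. isolate ",
      quantitative$isolate_id[neg[1]], " ", quantitative$parameter[neg[1]],
      " = ", quantitative$value[neg[1]],
      call. = FALSE
    )
  }
  orphan <- setdiff(unique(quantitative$isolate_id), ids)
  if (length(orphan) > 0) {
    stop("quantitative rows for unknown isolate(s): ",
      paste(orphan, collapse = ", "),
      call. = FALSE
    )
  }
  quantitative
}

validate_growth_table <- function(growth) {
  if (is.null(growth)) {
    return(tibble::tibble(
      pot_id = character(), treatment = character(),
      biomass_g = double(), height_cm = double()
    ))
  }
  growth <- tibble::as_tibble(growth)
  need <- c("pot_id", "treatment", "biomass_g", "height_cm")
  if (!all(need %in% names(growth))) {
    stop("`growth` must have columns ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  growth$pot_id <- as.character(growth$pot_id)
  growth$treatment <- as.character(growth$treatment)
  growth$biomass_g <- as.double(growth$biomass_g)
  growth$height_cm <- as.double(growth$height_cm)
  if (any(growth$biomass_g <= 0) || any(growth$height_cm <= 0)) {
    stop("growth biomass and height must be strictly positive", call. = FALSE)
  }
  growth
}

#' @export
print.pgpb_data <- function(x, ...) {
  cat(
    "<pgpb_data>", nrow(x$isolates), "isolates |",
    nrow(x$qualitative), "qualitative rows |",
    nrow(x$quantitative), "quantitative rows |",
    nrow(x$growth), "growth pots\n"
  )
  invisible(x)
}

#' Read a screening dataset from delimited files
#'
#' Reads the four comma-delimited, headered tables of the pipeline
#' (`isolates.csv`, `qualitative.csv`, `quantitative.csv`, `growth.csv`) and
#' validates them into a [pgpb_data] object. Only `isolates` is mandatory.
#' Parsing is order-independent: permuting input rows yields the same dataset
#' up to row order, and replicate order within an isolate is preserved as
#' given by the `replicate` column.
#'
#' @param isolates,qualitative,quantitative,growth Paths to the respective
#'   CSV files; the latter three may be `NULL`.
#' @return A [pgpb_data] object.
#' @seealso [write_dataset()] for the inverse operation.
#' @export
read_dataset <- function(isolates, qualitative = NULL, quantitative = NULL,
                         growth = NULL) {
  read1 <- function(path) {
    if (is.null(path)) {
      return(NULL)
    }
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  pgpb_data(
    isolates = read1(isolates),
    qualitative = read1(qualitative),
    quantitative = read1(quantitative),
    growth = read1(growth)
  )
}

#' Write a screening dataset to delimited files
#'
#' Writes the four tables of a [pgpb_data] object as CSV files under `dir`
#' (`isolates.csv`, `qualitative.csv`, `quantitative.csv`, `growth.csv`).
#' Re-reading the files with [read_dataset()] reproduces the dataset.
#'
#' @param data A [pgpb_data] object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written (named character vector).
#' @export
write_dataset <- function(data, dir) {
  stopifnot(inherits(data, "pgpb_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    isolates = file.path(dir, "isolates.csv"),
    qualitative = file.path(dir, "qualitative.csv"),
    quantitative = file.path(dir, "quantitative.csv"),
    growth = file.path(dir, "growth.csv")
  )
  readr::write_csv(data$isolates, paths["isolates"], progress = FALSE)
  readr::write_csv(data$qualitative, paths["qualitative"], progress = FALSE)
  readr::write_csv(data$quantitative, paths["quantitative"], progress = FALSE)
  readr::write_csv(data$growth, paths["growth"], progress = FALSE)
  invisible(paths)
}

#' Serialize a selection report
#'
#' Writes a [pgpb_selection] report to a single long-format CSV with a
#' `section` column (`first_round`, `second_round`, `excluded`, `final`).
#' [read_report()] reproduces the report exactly.
#'
#' @param report A [pgpb_selection] object (see [viability_filter()]).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pgpb_selection"))
  blank <- NA_character_
  rows <- dplyr::bind_rows(
    tibble::tibble(
      section = rep("first_round", nrow(report$first_round)),
      isolate_id = report$first_round$isolate_id,
      group = report$first_round$group,
      parameter = report$first_round$parameter,
      rule = report$first_round$rule,
      reason = blank[rep(1, nrow(report$first_round))]
    ),
    tibble::tibble(
      section = rep("second_round", nrow(report$second_round)),
      isolate_id = report$second_round$isolate_id,
      group = blank[rep(1, nrow(report$second_round))],
      parameter = blank[rep(1, nrow(report$second_round))],
      rule = report$second_round$rule,
      reason = blank[rep(1, nrow(report$second_round))]
    ),
    tibble::tibble(
      section = rep("excluded", nrow(report$excluded)),
      isolate_id = report$excluded$isolate_id,
      group = blank[rep(1, nrow(report$excluded))],
      parameter = blank[rep(1, nrow(report$excluded))],
      rule = blank[rep(1, nrow(report$excluded))],
      reason = report$excluded$reason
    ),
    tibble::tibble(
      section = rep("final", length(report$final)),
      isolate_id = report$final,
      group = blank[rep(1, length(report$final))],
      parameter = blank[rep(1, length(report$final))],
      rule = blank[rep(1, length(report$final))],
      reason = blank[rep(1, length(report$final))]
    )
  )
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(
      section = character(), isolate_id = character(), group = character(),
      parameter = character(), rule = character(), reason = character()
    )
  }
  readr::write_csv(rows, path, progress = FALSE, na = "")
  invisible(path)
}

#' @rdname write_report
#' @return `read_report()` returns the reconstructed [pgpb_selection] object.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rows <- readr::read_csv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    na = character()
  )
  pick <- function(section) rows[rows$section == section, , drop = FALSE]
  fr <- pick("first_round")
  sr <- pick("second_round")
  ex <- pick("excluded")
  fin <- pick("final")
  new_selection_report(
    first_round = tibble::tibble(
      isolate_id = fr$isolate_id, group = fr$group,
      parameter = fr$parameter, rule = fr$rule
    ),
    second_round = tibble::tibble(
      isolate_id = sr$isolate_id, rule = sr$rule
    ),
    excluded = tibble::tibble(
      isolate_id = ex$isolate_id, reason = ex$reason
    ),
    final = fin$isolate_id
  )
}
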
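# Dixon's Q (r10) two-sided critical values, n = 3..10
.dixon_crit <- list(
  "0.05" = c(
    `3` = 0.970, `4` = 0.829, `5` = 0.710, `6` = 0.625,
    `7` = 0.568, `8` = 0.526, `9` = 0.493, `10` = 0.466
  ),
  "0.01" = c(
    `3` = 0.994, `4` = 0.926, `5` = 0.821, `6` = 0.740,
    `7` = 0.680, `8` = 0.634, `9` = 0.598, `10` = 0.568
  )
)

#' Coefficient of variation of replicate values
#'
#' Sample relative standard deviation in percent: 100 x sd / mean, with the
#' n-1 standard deviation. This is the replicate-consistency gate of the
#' quantitative stage.
#'
#' @param values Numeric vector of at least 2 replicate values with positive
#'   mean.
#' @return CV in percent (non-negative).
#' @examples
#' coefficient_of_variation(c(1, 2, 3)) # 50
#' @export
coefficient_of_variation <- function(values) {
  values <- as.double(values)
  if (length(values) < 2) {
    stop("CV needs at least 2 replicate values", call. = FALSE)
  }
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    stop("CV undefined for non-positive mean", call. = FALSE)
  }
  100 * sd(values) / m
}

#' Dixon's Q statistic
#'
#' Gap between the suspect extreme value and its nearest neighbour divided by
#' the range (the r10 statistic); the suspect extreme is whichever end has
#' the larger gap.
#'
#' @param values Numeric vector, 3 to 10 values.
#' @return List with `q` (statistic), `suspect` (index into `values` of the
#'   suspect replicate), `side` (`"low"` or `"high"`).
#' @export
dixon_q <- function(values) {
  n <- length(values)
  if (n < 3 || n > 10) {
    stop("Dixon's Q is tabulated for 3 to 10 values", call. = FALSE)
  }
  ord <- order(values)
  s <- values[ord]
  rng <- s[n] - s[1]
  if (rng == 0) {
    return(list(q = 0, suspect = ord[1], side = "low"))
  }
  q_low <- (s[2] - s[1]) / rng
  q_high <- (s[n] - s[n - 1]) / rng
  if (q_high >= q_low) {
    list(q = q_high, suspect = ord[n], side = "high")
  } else {
    list(q = q_low, suspect = ord[1], side = "low")
  }
}

#' CV gate with Dixon outlier removal
#'
#' Quality control for one isolate x parameter replicate set. If the CV is at
#' or below `cv_threshold` the replicates pass untouched. Otherwise Dixon's Q
#' test at `alpha` is applied: if the suspect extreme is significant it is
#' removed (never more than one value); if not, all values are kept and the
#' set is flagged unresolved. With `unconditional = TRUE` the suspect extreme
#' is removed whenever the CV exceeds the threshold, without a significance
#' gate.
#'
#' @param values Numeric replicate values (3 to 10; triplicates in the
#'   standard design).
#' @param cv_threshold CV threshold in percent (default 10; comparison is
#'   strict, CV must exceed it to trigger the test).
#' @param alpha Significance level of Dixon's test; 0.05 (default) or 0.01.
#' @param unconditional If `TRUE`, remove the suspect extreme unconditionally
#'   once the CV gate fires.
#' @return Object of class `pgpb_qc`: list with `kept`, `removed` (tibble
#'   `value`, `reason`), `cv_before`, `cv_after`, `flagged_unresolved`.
#' @examples
#' qc_filter(c(10.0, 10.2, 20.0)) # removes 20.0 (Q = 0.98 > 0.970)
#' qc_filter(c(10, 15, 20)) # keeps all, flagged (Q = 0.5)
#' @export
qc_filter <- function(values, cv_threshold = 10, alpha = 0.05,
                      unconditional = FALSE) {
  values <- as.double(values)
  cv0 <- coefficient_of_variation(values)
  no_removal <- function(flag) {
    structure(
      list(
        kept = values,
        removed = tibble::tibble(value = double(), reason = character()),
        cv_before = cv0, cv_after = cv0, flagged_unresolved = flag
      ),
      class = "pgpb_qc"
    )
  }
  if (cv0 <= cv_threshold) {
    return(no_removal(FALSE))
  }
  dx <- dixon_q(values)
  remove_it <- unconditional
  if (!unconditional) {
    key <- format(alpha, nsmall = 2)
    crit <- .dixon_crit[[key]]
    if (is.null(crit)) {
      stop("Dixon critical values tabulated for alpha 0.05 and 0.01 only",
        call. = FALSE
      )
    }
    remove_it <- dx$q > crit[[as.character(length(values))]]
  }
  if (!remove_it) {
    return(no_removal(TRUE))
  }
  kept <- values[-dx$suspect]
  structure(
    list(
      kept = kept,
      removed = tibble::tibble(
        value = values[dx$suspect],
        reason = sprintf(
          "dixon_q %.3f (%s extreme), cv %.1f%% > %g%%",
          dx$q, dx$side, cv0, cv_threshold
        )
      ),
      cv_before = cv0,
      cv_after = coefficient_of_variation(kept),
      flagged_unresolved = FALSE
    ),
    class = "pgpb_qc"
  )
}

#' @export
print.pgpb_qc <- function(x, ...) {
  cat(sprintf(
    "<pgpb_qc> kept %d, removed %d; CV %.2f%% -> %.2f%%%s\n",
    length(x$kept), nrow(x$removed), x$cv_before, x$cv_after,
    if (x$flagged_unresolved) " [unresolved]" else ""
  ))
  invisible(x)
}

#' Apply replicate QC across a quantitative table
#'
#' Runs [qc_filter()] on every isolate x parameter replicate set of a
#' dataset's quantitative table. Sets whose mean is zero (assay negative in
#' every replicate) are passed through untouched: they code 0 downstream and
#' a CV is undefined for them. Sets with fewer than 3 replicates are passed
#' through untouched as well (Dixon's test is not applicable).
#'
#' @param data A [pgpb_data] object or a quantitative tibble
#'   (`isolate_id`, `parameter`, `replicate`, `value`).
#' @inheritParams qc_filter
#' @return List with `quantitative` (cleaned tibble in input format) and
#'   `log` (tibble: `isolate_id`, `parameter`, `cv_before`, `cv_after`,
#'   `n_removed`, `removed_value`, `flagged_unresolved`).
#' @export
qc_dataset <- function(data, cv_threshold = 10, alpha = 0.05,
                       unconditional = FALSE) {
  quant <- if (inherits(data, "pgpb_data")) data$quantitative else
    tibble::as_tibble(data)
  if (nrow(quant) == 0) {
    return(list(quantitative = quant, log = tibble::tibble(
      isolate_id = character(), parameter = character(),
      cv_before = double(), cv_after = double(), n_removed = integer(),
      removed_value = double(), flagged_unresolved = logical()
    )))
  }
  key <- paste(quant$isolate_id, quant$parameter, sep = "\r")
  idx_by_key <- split(seq_len(nrow(quant)), key)
  n_keys <- length(idx_by_key)
  log_id <- character(n_keys)
  log_param <- character(n_keys)
  log_cv_before <- rep(NA_real_, n_keys)
  log_cv_after <- rep(NA_real_, n_keys)
  log_removed_n <- integer(n_keys)
  log_removed_val <- rep(NA_real_, n_keys)
  log_flagged <- logical(n_keys)
  keep <- rep(TRUE, nrow(quant))
  for (i in seq_len(n_keys)) {
    rows <- idx_by_key[[i]]
    vals <- quant$value[rows]
    log_id[i] <- quant$isolate_id[rows[1]]
    log_param[i] <- quant$parameter[rows[1]]
    if (length(vals) < 3 || mean(vals) == 0) next
    qc <- qc_filter(vals,
      cv_threshold = cv_threshold, alpha = alpha,
      unconditional = unconditional
    )
    log_cv_before[i] <- qc$cv_before
    log_cv_after[i] <- qc$cv_after
    log_flagged[i] <- qc$flagged_unresolved
    if (nrow(qc$removed) > 0) {
      log_removed_n[i] <- 1L
      log_removed_val[i] <- qc$removed$value[1]
      keep[rows[which(vals == qc$removed$value[1])[1]]] <- FALSE
    }
  }
  cleaned <- quant[keep, , drop = FALSE] |>
    dplyr::arrange(.data$isolate_id, .data$parameter, .data$replicate)
  list(
    quantitative = cleaned,
    log = tibble::tibble(
      isolate_id = log_id, parameter = log_param,
      cv_before = log_cv_before, cv_after = log_cv_after,
      n_removed = log_removed_n, removed_value = log_removed_val,
      flagged_unresolved = log_flagged
    )
  )
}
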
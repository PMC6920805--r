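#' Percent change versus control
#'
#' @param treatment_mean Treatment-level mean (biomass or height).
#' @param control_mean Control mean; must be strictly positive.
#' @return 100 x (treatment - control) / control.
#' @examples
#' percent_change(3.0, 2.0) # +50
#' @export
percent_change <- function(treatment_mean, control_mean) {
  if (!is.finite(control_mean) || control_mean <= 0) {
    stop("control mean must be strictly positive", call. = FALSE)
  }
  100 * (treatment_mean - control_mean) / control_mean
}

#' Growth-chamber validation statistics
#'
#' Per-treatment means of pot biomass dry matter and plant height, percent
#' change versus the uninoculated control, and Tukey HSD compact letters at
#' `alpha` for each response. Biomass and height are analysed as independent
#' responses (no multivariate correction), and percent changes are computed
#' from treatment means, not per-pot ratios.
#'
#' @param growth Growth tibble (`pot_id`, `treatment`, `biomass_g`,
#'   `height_cm`) or a [pgpb_data] object.
#' @param alpha Significance level for Tukey HSD (default 0.01).
#' @param control Label of the control treatment (default `"control"`).
#' @return Tibble with one row per treatment (control first, then by
#'   descending biomass mean): `treatment`, `n_pots`, `mean_biomass`,
#'   `pct_biomass_change`, `letters_biomass`, `mean_height`,
#'   `pct_height_change`, `letters_height`.
#' @export
validate_growth <- function(growth, alpha = 0.01, control = "control") {
  if (inherits(growth, "pgpb_data")) growth <- growth$growth
  growth <- tibble::as_tibble(growth)
  if (!control %in% growth$treatment) {
    stop("no '", control, "' treatment in the growth data", call. = FALSE)
  }
  n_pots <- table(growth$treatment)
  if (any(n_pots < 2)) {
    stop(
      "every treatment needs at least 2 pots; short: ",
      paste(names(n_pots)[n_pots < 2], collapse = ", "),
      call. = FALSE
    )
  }
  bio <- split(growth$biomass_g, growth$treatment)
  hei <- split(growth$height_cm, growth$treatment)
  tk_bio <- tukey_letters(bio, alpha = alpha)
  tk_hei <- tukey_letters(hei, alpha = alpha)
  mean_bio <- setNames(tk_bio$mean, tk_bio$level)
  mean_hei <- setNames(tk_hei$mean, tk_hei$level)
  let_bio <- setNames(tk_bio$letters, tk_bio$level)
  let_hei <- setNames(tk_hei$letters, tk_hei$level)
  treatments <- c(control, setdiff(tk_bio$level, control))
  tibble::tibble(
    treatment = treatments,
    n_pots = as.integer(n_pots[treatments]),
    mean_biomass = unname(mean_bio[treatments]),
    pct_biomass_change = vapply(
      treatments,
      function(t) percent_change(mean_bio[[t]], mean_bio[[control]]), 0,
      USE.NAMES = FALSE
    ),
    letters_biomass = unname(let_bio[treatments]),
    mean_height = unname(mean_hei[treatments]),
    pct_height_change = vapply(
      treatments,
      function(t) percent_change(mean_hei[[t]], mean_hei[[control]]), 0,
      USE.NAMES = FALSE
    ),
    letters_height = unname(let_hei[treatments])
  )
}
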
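#' Default per-group trait positivity probabilities
#'
#' Probabilities that an isolate of each functional group is latently
#' positive for each qualitative screening trait. Where the screening
#' literature for this system reports only a range for a group pair, a value
#' inside the range is fixed here (see the methods vignette).
#'
#' @return Tibble `group`, `trait`, `prob`.
#' @export
default_positivity <- function() {
  tibble::tibble(
    group = rep(pgpb_groups(), each = 4),
    trait = rep(pgpb_traits(), times = 4),
    prob = c(
      0.41, 0.49, 0.50, 0.25, # mesophilic
      0.54, 0.68, 0.68, 0.15, # spore_forming
      0.65, 0.82, 0.99, 0.22, # pseudomonads
      0.32, 0.30, 0.11, 0.13 # actinobacteria
    )
  )
}

#' Default quantitative calibration (median, third quartile)
#'
#' Per-group positive-part medians and upper quartiles of the three
#' quantitative parameters (uM for P-mineralization and nitrification, ug/mL
#' for IAA). The pseudomonad P-mineralization pair is omitted: its published
#' summary row is internally inconsistent (q3 below the median) and cannot
#' calibrate a distribution.
#'
#' @return Tibble `group`, `parameter`, `median`, `q3`.
#' @export
default_calibration <- function() {
  tibble::tibble(
    group = c(
      rep("mesophilic", 3), rep("spore_forming", 3),
      rep("pseudomonads", 2), rep("actinobacteria", 3)
    ),
    parameter = c(
      "p_mineralization", "iaa", "nitrification",
      "p_mineralization", "iaa", "nitrification",
      "iaa", "nitrification",
      "p_mineralization", "iaa", "nitrification"
    ),
    median = c(
      1.81, 18.86, 13.13,
      1.49, 5.33, 1.62,
      2.27, 15.83,
      0.49, 7.21, 2.44
    ),
    q3 = c(
      2.61, 38.91, 17.51,
      1.79, 9.09, 1.97,
      3.65, 17.32,
      1.61, 26.38, 8.16
    )
  )
}

#' Calibrate a lognormal positive part from (median, q3)
#'
#' Closed-form inversion of the lognormal quantile function: with
#' `log_location = ln(median)` and `log_scale = ln(q3/median) / z_0.75`
#' (z_0.75 = 0.6745), the distribution's median and upper quartile equal the
#' inputs exactly.
#'
#' @param median,q3 Positive-part median and third quartile; `q3 > median`.
#' @param zero_mass Probability of a structural zero (assay-negative
#'   isolate), default 0.
#' @return List of class `pgpb_calibration`: `zero_mass`, `log_location`,
#'   `log_scale`.
#' @examples
#' calibrate_lognormal(18.86, 38.91)$log_scale # ~= 1.074
#' @export
calibrate_lognormal <- function(median, q3, zero_mass = 0) {
  if (!is.finite(median) || !is.finite(q3) || median <= 0 || q3 <= median) {
    stop("calibration needs q3 > median > 0", call. = FALSE)
  }
  if (zero_mass < 0 || zero_mass >= 1) {
    stop("zero_mass must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      zero_mass = zero_mass,
      log_location = log(median),
      log_scale = log(q3 / median) / qnorm(0.75)
    ),
    class = "pgpb_calibration"
  )
}

#' Generator configuration
#'
#' Assembles and validates the parameters of the synthetic screening-data
#' generator. Defaults reproduce the statistical structure the pipeline
#' assumes: four functional groups at the study's cohort sizes, per-group
#' trait positivity, zero-inflated lognormal quantitative traits calibrated
#' to the per-group (median, q3) pairs, multiplicative triplicate noise with
#' occasional gross outliers, and growth-chamber effects of +50% biomass and
#' +25% height for treated elite strains.
#'
#' @param seed Integer seed; the single source of randomness. A hierarchical
#'   per-isolate stream is derived from it, so increasing `n_per_group` does
#'   not perturb earlier isolates.
#' @param n_per_group Named integer vector of isolate counts (defaults:
#'   mesophilic 133, spore_forming 96, pseudomonads 65, actinobacteria 180).
#' @param positivity Tibble as [default_positivity()].
#' @param calibration Tibble as [default_calibration()].
#' @param zero_mass Probability a performed quantitative assay is negative
#'   (structural zero), default 0.10.
#' @param replicate_cv Target within-isolate replicate CV (fraction, default
#'   0.05).
#' @param outlier_rate Probability a replicate set contains one gross
#'   outlier (one replicate multiplied by U(5, 10); at the default replicate
#'   CV a smaller multiplier would sit below Dixon's n = 3 critical value
#'   and the QC gate would never fire), default 0.05.
#' @param flip_rate Probability a qualitative replicate disagrees with the
#'   isolate's latent state, default 0.02.
#' @param n_replicates Replicates per assay (default 3).
#' @param viability_loss_rate Probability an isolate loses viability in cold
#'   storage, default 0.02.
#' @param elite_margin Planted elite strains take a positive value equal to
#'   `elite_margin` times the cohort maximum for their designated parameter
#'   (default 1.3), guaranteeing they occupy the extreme tail.
#' @param n_elites_per_group Number of elite strains per group, one per
#'   calibrated parameter in order (default 0 = no planting).
#' @param growth List of growth-chamber settings: `control_biomass` (g/pot),
#'   `control_height` (cm), `biomass_multiplier`, `height_multiplier`
#'   (treatment effects for elite strains), `pot_cv`, `pots_per_treatment`.
#' @return Validated list of class `pgpb_generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_per_group = c(
                               mesophilic = 133L, spore_forming = 96L,
                               pseudomonads = 65L, actinobacteria = 180L
                             ),
                             positivity = default_positivity(),
                             calibration = default_calibration(),
                             zero_mass = 0.10,
                             replicate_cv = 0.05,
                             outlier_rate = 0.05,
                             flip_rate = 0.02,
                             n_replicates = 3L,
                             viability_loss_rate = 0.02,
                             elite_margin = 1.3,
                             n_elites_per_group = 0L,
                             growth = list()) {
  growth_defaults <- list(
    control_biomass = 2.0, control_height = 25,
    biomass_multiplier = 1.5, height_multiplier = 1.25,
    pot_cv = 0.10, pots_per_treatment = 3L
  )
  growth <- utils::modifyList(growth_defaults, growth)
  if (!all(pgpb_groups() %in% names(n_per_group))) {
    stop("n_per_group must name all four functional groups", call. = FALSE)
  }
  n_per_group <- as.integer(n_per_group[pgpb_groups()])
  names(n_per_group) <- pgpb_groups()
  if (any(n_per_group < 0)) stop("negative group size", call. = FALSE)
  probs <- c(
    positivity$prob, zero_mass, outlier_rate, flip_rate,
    viability_loss_rate
  )
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (replicate_cv < 0 || elite_margin <= 1 || n_replicates < 2) {
    stop("invalid replicate_cv, elite_margin or n_replicates", call. = FALSE)
  }
  if (any(calibration$q3 <= calibration$median) ||
    any(calibration$median <= 0)) {
    stop("every calibration pair needs q3 > median > 0", call. = FALSE)
  }
  if (any(c(
    growth$control_biomass, growth$control_height,
    growth$biomass_multiplier, growth$height_multiplier
  ) <= 0)) {
    stop("growth means and multipliers must be positive", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed), n_per_group = n_per_group,
      positivity = tibble::as_tibble(positivity),
      calibration = tibble::as_tibble(calibration),
      zero_mass = zero_mass, replicate_cv = replicate_cv,
      outlier_rate = outlier_rate, flip_rate = flip_rate,
      n_replicates = as.integer(n_replicates),
      viability_loss_rate = viability_loss_rate,
      elite_margin = elite_margin,
      n_elites_per_group = as.integer(n_elites_per_group),
      growth = growth
    ),
    class = "pgpb_generator_config"
  )
}

# derived 32-bit substream seed; distinct per (stream id, unit index)
substream_seed <- function(seed, stream, index) {
  (as.double(seed %% 100000L) * 10007 + stream * 1e8 + index) %% 2147483647
}

#' Generate a synthetic screening + growth-chamber dataset
#'
#' Draws a full dataset with the structure the pipeline assumes:
#' \itemize{
#' \item qualitative outcomes: a latent per-isolate positivity per (group,
#'   trait) probability; replicates agree with the latent state except for a
#'   small flip rate;
#' \item quantitative values: IAA assayed for every isolate; P-mineralization
#'   and nitrification only for isolates latently positive to the matching
#'   qualitative screen (mirroring the screening reduction). A performed
#'   assay is a structural zero with probability `zero_mass`, otherwise
#'   lognormal per the group calibration, with multiplicative replicate noise
#'   at `replicate_cv` and gross outliers at `outlier_rate`;
#' \item elite strains (if requested): designated isolates planted at
#'   `elite_margin` times the cohort maximum of their parameter;
#' \item growth data: control pots at the configured means, treated pots
#'   (the elite strains) at the configured multiplicative effects, lognormal
#'   pot-level noise.
#' }
#' Output is deterministic given `config$seed`; the caller's RNG state is
#' left untouched.
#'
#' @param config A [generator_config()].
#' @return A [pgpb_data] object (growth table empty when there are no elite
#'   treatments) with attribute `elites`: tibble `isolate_id`, `group`,
#'   `parameter`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "pgpb_generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })

  groups <- pgpb_groups()
  n_rep <- config$n_replicates
  sigma_rep <- sqrt(log(1 + config$replicate_cv^2))
  pos_lookup <- setNames(
    config$positivity$prob,
    paste(config$positivity$group, config$positivity$trait)
  )
  cal_lookup <- setNames(
    lapply(
      seq_len(nrow(config$calibration)),
      function(i) {
        calibrate_lognormal(
          config$calibration$median[i], config$calibration$q3[i],
          zero_mass = config$zero_mass
        )
      }
    ),
    paste(config$calibration$group, config$calibration$parameter)
  )
  trait_for_param <- c(
    p_mineralization = "p_solubilization",
    nitrification = "nitrification_qual"
  )

  n_total <- sum(config$n_per_group)
  iso_id <- character(n_total)
  iso_group <- character(n_total)
  iso_viable <- logical(n_total)
  qual <- list()
  quant <- list()
  latent_value <- list() # per isolate: named latent positives

  row <- 0L
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    for (i in seq_len(config$n_per_group[[g]])) {
      row <- row + 1L
      set.seed(substream_seed(config$seed, gi, i))
      id <- paste0(i, pgpb_group_suffix()[[g]])
      iso_id[row] <- id
      iso_group[row] <- g
      iso_viable[row] <- runif(1) >= config$viability_loss_rate

      latent_pos <- logical(4)
      names(latent_pos) <- pgpb_traits()
      out_rows <- vector("list", 4)
      for (ti in seq_along(pgpb_traits())) {
        tr <- pgpb_traits()[ti]
        latent_pos[tr] <- runif(1) < pos_lookup[[paste(g, tr)]]
        flips <- runif(n_rep) < config$flip_rate
        out_rows[[ti]] <- xor(rep(latent_pos[tr], n_rep), flips)
      }
      qual[[row]] <- list(
        id = id, outcome = unlist(out_rows, use.names = FALSE)
      )

      lat <- c(
        p_mineralization = NA_real_, iaa = NA_real_,
        nitrification = NA_real_
      )
      vals <- vector("list", 3)
      names(vals) <- pgpb_parameters()
      for (p in pgpb_parameters()) {
        cal <- cal_lookup[[paste(g, p)]]
        performed <- !is.null(cal) &&
          (p == "iaa" || latent_pos[[trait_for_param[[p]]]])
        if (!performed) next
        if (runif(1) < cal$zero_mass) {
          lat[p] <- 0
          vals[[p]] <- rep(0, n_rep)
        } else {
          lat[p] <- rlnorm(1, cal$log_location, cal$log_scale)
          reps <- lat[p] * exp(rnorm(n_rep, 0, sigma_rep))
          if (runif(1) < config$outlier_rate) {
            hit <- sample.int(n_rep, 1)
            reps[hit] <- reps[hit] * runif(1, 5, 10)
          }
          vals[[p]] <- reps
        }
      }
      latent_value[[row]] <- lat
      quant[[row]] <- vals
    }
  }

  # plant elite strains: designated isolates take elite_margin x cohort max
  elites <- tibble::tibble(
    isolate_id = character(), group = character(), parameter = character()
  )
  if (config$n_elites_per_group > 0) {
    ek <- 0L
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      params_g <- config$calibration$parameter[config$calibration$group == g]
      n_elite <- min(
        config$n_elites_per_group, length(params_g),
        config$n_per_group[[g]]
      )
      rows_g <- which(iso_group == g)
      for (e in seq_len(n_elite)) {
        ek <- ek + 1L
        p <- params_g[e]
        r <- rows_g[e]
        lat_g <- vapply(latent_value[rows_g], function(x) x[[p]], 0)
        top <- max(c(lat_g, 0), na.rm = TRUE)
        base <- config$calibration$q3[
          config$calibration$group == g & config$calibration$parameter == p
        ]
        set.seed(substream_seed(config$seed, 9L, ek))
        lat_e <- config$elite_margin * max(top, base)
        latent_value[[r]][[p]] <- lat_e
        quant[[r]][[p]] <- lat_e * exp(rnorm(n_rep, 0, sigma_rep))
        iso_viable[r] <- TRUE
        elites <- dplyr::bind_rows(elites, tibble::tibble(
          isolate_id = iso_id[r], group = g, parameter = p
        ))
      }
    }
  }

  qualitative <- tibble::tibble(
    isolate_id = rep(iso_id, each = 4 * n_rep),
    trait = rep(rep(pgpb_traits(), each = n_rep), times = n_total),
    replicate = rep(rep(seq_len(n_rep), times = 4), times = n_total),
    outcome = unlist(lapply(qual, `[[`, "outcome"), use.names = FALSE)
  )
  done <- lapply(quant, function(vals) {
    names(vals)[!vapply(vals, is.null, TRUE)]
  })
  n_done <- lengths(done)
  quantitative <- NULL
  if (sum(n_done) > 0) {
    quantitative <- tibble::tibble(
      isolate_id = rep(iso_id, times = n_done * n_rep),
      parameter = unlist(
        lapply(done, function(d) rep(d, each = n_rep)),
        use.names = FALSE
      ),
      replicate = rep(seq_len(n_rep), times = sum(n_done)),
      value = unlist(
        lapply(seq_len(n_total), function(r) {
          unlist(quant[[r]][done[[r]]], use.names = FALSE)
        }),
        use.names = FALSE
      )
    )
  }

  growth <- NULL
  if (nrow(elites) > 0) {
    gcfg <- config$growth
    sigma_pot <- sqrt(log(1 + gcfg$pot_cv^2))
    treatments <- c("control", unique(elites$isolate_id))
    set.seed(substream_seed(config$seed, 17L, 1L))
    growth <- dplyr::bind_rows(lapply(
      seq_along(treatments),
      function(ti) {
        t <- treatments[ti]
        mult_b <- if (t == "control") 1 else gcfg$biomass_multiplier
        mult_h <- if (t == "control") 1 else gcfg$height_multiplier
        n_pot <- gcfg$pots_per_treatment
        tibble::tibble(
          pot_id = sprintf("%s_pot%d", t, seq_len(n_pot)),
          treatment = t,
          biomass_g = gcfg$control_biomass * mult_b *
            exp(rnorm(n_pot, 0, sigma_pot)),
          height_cm = gcfg$control_height * mult_h *
            exp(rnorm(n_pot, 0, sigma_pot))
        )
      }
    ))
  }

  data <- pgpb_data(
    isolates = tibble::tibble(
      isolate_id = iso_id, group = iso_group, viability_ok = iso_viable
    ),
    qualitative = qualitative,
    quantitative = quantitative,
    growth = growth
  )
  attr(data, "elites") <- elites
  data
}
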
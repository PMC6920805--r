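small_cfg <- function(seed = 1, ...) {
  generator_config(
    seed = seed,
    n_per_group = c(
      mesophilic = 8L, spore_forming = 6L,
      pseudomonads = 5L, actinobacteria = 7L
    ),
    ...
  )
}

test_that("lognormal calibration inverts (median, q3) in closed form", {
  cal <- calibrate_lognormal(18.86, 38.91)
  expect_equal(cal$log_location, log(18.86))
  expect_equal(cal$log_scale, log(38.91 / 18.86) / qnorm(0.75))
  expect_equal(cal$log_scale, 1.0737, tolerance = 1e-4)
  # symmetric check: inputs (1, e^z0.75) give log_scale exactly 1
  expect_equal(calibrate_lognormal(1, exp(qnorm(0.75)))$log_scale, 1)
  # the calibrated distribution's quantiles equal the inputs
  expect_equal(stats::qlnorm(0.5, cal$log_location, cal$log_scale), 18.86)
  expect_equal(stats::qlnorm(0.75, cal$log_location, cal$log_scale), 38.91)
  expect_error(calibrate_lognormal(2, 2), "q3 > median > 0")
  expect_error(calibrate_lognormal(2, 1), "q3 > median > 0")
})

test_that("generation is deterministic given the seed", {
  d1 <- generate_dataset(small_cfg(5, n_elites_per_group = 2L))
  d2 <- generate_dataset(small_cfg(5, n_elites_per_group = 2L))
  expect_identical(d1$isolates, d2$isolates)
  expect_identical(d1$qualitative, d2$qualitative)
  expect_identical(d1$quantitative, d2$quantitative)
  expect_identical(d1$growth, d2$growth)
  d3 <- generate_dataset(small_cfg(6, n_elites_per_group = 2L))
  expect_false(identical(d1$quantitative, d3$quantitative))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_dataset(small_cfg(1)))
  expect_identical(runif(1), before)
})

test_that("adding isolates does not perturb earlier draws", {
  cfg_a <- generator_config(
    seed = 3,
    n_per_group = c(
      mesophilic = 5L, spore_forming = 0L, pseudomonads = 0L,
      actinobacteria = 0L
    )
  )
  cfg_b <- generator_config(
    seed = 3,
    n_per_group = c(
      mesophilic = 9L, spore_forming = 0L, pseudomonads = 0L,
      actinobacteria = 0L
    )
  )
  d_a <- generate_dataset(cfg_a)
  d_b <- generate_dataset(cfg_b)
  ids <- d_a$isolates$isolate_id
  expect_identical(
    d_b$quantitative[d_b$quantitative$isolate_id %in% ids, ],
    d_a$quantitative
  )
  expect_identical(
    d_b$qualitative[d_b$qualitative$isolate_id %in% ids, ],
    d_a$qualitative
  )
})

test_that("generated datasets pass dataset validation and round-trip", {
  d <- generate_dataset(small_cfg(2, n_elites_per_group = 1L))
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  d2 <- read_dataset(
    isolates = file.path(dir, "isolates.csv"),
    qualitative = file.path(dir, "qualitative.csv"),
    quantitative = file.path(dir, "quantitative.csv"),
    growth = file.path(dir, "growth.csv")
  )
  expect_equal(d2$quantitative, d$quantitative)
  expect_true(all(d$quantitative$value >= 0))
})

test_that("positive-part quantiles are recovered at large n", {
  cfg <- generator_config(
    seed = 7,
    n_per_group = c(
      mesophilic = 2000L, spore_forming = 0L,
      pseudomonads = 0L, actinobacteria = 0L
    )
  )
  d <- generate_dataset(cfg)
  iaa <- d$quantitative$value[
    d$quantitative$parameter == "iaa" & d$quantitative$value > 0
  ]
  cal <- calibrate_lognormal(18.86, 38.91)
  n <- length(iaa)
  se_med <- 1 / (2 * stats::dlnorm(18.86, cal$log_location, cal$log_scale) *
    sqrt(n))
  expect_lt(abs(median(iaa) - 18.86), 3 * se_med)
  dq3 <- stats::dlnorm(38.91, cal$log_location, cal$log_scale)
  se_q3 <- sqrt(0.75 * 0.25 / n) / dq3
  expect_lt(
    abs(quantile(iaa, 0.75, names = FALSE) - 38.91),
    # replicate noise (CV 5%) widens the pooled q3 slightly; allow for it
    3 * se_q3 + 0.05 * 38.91
  )
})

test_that("observed positivity sits inside binomial 99% bounds", {
  cfg <- generator_config(
    seed = 12,
    n_per_group = c(
      mesophilic = 0L, spore_forming = 0L,
      pseudomonads = 600L, actinobacteria = 0L
    ),
    flip_rate = 0
  )
  d <- generate_dataset(cfg)
  m <- build_matrix(d)
  for (tr in pgpb_traits()) {
    p <- cfg$positivity$prob[
      cfg$positivity$group == "pseudomonads" & cfg$positivity$trait == tr
    ]
    lo <- stats::qbinom(0.005, 600, p)
    hi <- stats::qbinom(0.995, 600, p)
    expect_gte(sum(m[, tr]), lo)
    expect_lte(sum(m[, tr]), hi)
  }
})

test_that("config validation rejects impossible parameters", {
  expect_error(generator_config(zero_mass = 1.2), "probabilities")
  expect_error(generator_config(elite_margin = 0.9), "elite_margin")
  expect_error(
    generator_config(n_per_group = c(mesophilic = 5)),
    "all four functional groups"
  )
  bad_cal <- default_calibration()
  bad_cal$q3[1] <- bad_cal$median[1]
  expect_error(generator_config(calibration = bad_cal), "q3 > median")
})
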
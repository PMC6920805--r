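mk_codes <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      isolate_id = r[[1]], group = r[[2]],
      parameter = pgpb_parameters(),
      value = as.double(r[[3]]), code = as.integer(r[[3]])
    )
  }))
}

test_that("second round selects by trait breadth at code >= 1", {
  codes <- mk_codes(
    list("1P", "pseudomonads", c(0, 1, 2)), # two traits -> in
    list("2P", "pseudomonads", c(0, 0, 3)), # one trait -> out
    list("3P", "pseudomonads", c(1, 1, 0)), # two traits -> in
    list("4P", "pseudomonads", c(3, 3, 3)) # already selected -> skipped
  )
  sr <- second_round(codes, already_selected = "4P", min_traits = 2)
  expect_setequal(sr$isolate_id, c("1P", "3P"))
  expect_identical(sr$n_traits[sr$isolate_id == "1P"], 2L)
})

test_that("adding a trait measurement never drops a second-round isolate", {
  codes <- mk_codes(list("1A", "actinobacteria", c(0, 1, 1)))
  base <- second_round(codes, character(0))
  expect_identical(base$isolate_id, "1A")
  richer <- codes
  richer$code[richer$parameter == "p_mineralization"] <- 2L
  expect_identical(second_round(richer, character(0))$isolate_id, "1A")
})

test_that("first round handles empty and singleton candidate sets", {
  quant <- tibble::tibble(
    isolate_id = rep(c("1M", "2M"), each = 3), parameter = "iaa",
    replicate = rep(1:3, 2), value = c(30, 31, 29, 5, 5.2, 4.8)
  )
  none <- mk_codes(
    list("1M", "mesophilic", c(0, 2, 0)),
    list("2M", "mesophilic", c(0, 1, 0))
  )
  expect_identical(nrow(first_round(none, quant)), 0L)

  one <- mk_codes(
    list("1M", "mesophilic", c(0, 3, 0)),
    list("2M", "mesophilic", c(0, 1, 0))
  )
  fr <- first_round(one, quant)
  expect_identical(fr$isolate_id, "1M")
  expect_match(fr$rule, "single candidate")
})

test_that("first round keeps only the top Tukey homogeneous group", {
  # 1M and 2M both code 3 but 1M's replicates are far higher
  quant <- tibble::tibble(
    isolate_id = rep(c("1M", "2M", "3M"), each = 3), parameter = "iaa",
    replicate = rep(1:3, 3),
    value = c(100, 101, 99, 50, 51, 49, 5, 5.2, 4.8)
  )
  codes <- mk_codes(
    list("1M", "mesophilic", c(0, 3, 0)),
    list("2M", "mesophilic", c(0, 3, 0)),
    list("3M", "mesophilic", c(0, 1, 0))
  )
  fr <- first_round(codes, quant, alpha = 0.05)
  expect_identical(fr$isolate_id, "1M")
  expect_match(fr$rule, "top Tukey")
  # near-ties share the top letter and are both kept
  quant2 <- quant
  quant2$value[quant2$isolate_id == "2M"] <- c(99.5, 100.5, 100)
  fr2 <- first_round(codes, quant2, alpha = 0.05)
  expect_setequal(fr2$isolate_id, c("1M", "2M"))
})

test_that("viability exclusion assembles the final report", {
  fr <- tibble::tibble(
    isolate_id = c("1M", "2M"), group = "mesophilic", parameter = "iaa",
    rule = "r"
  )
  sr <- tibble::tibble(isolate_id = "1B", rule = "r")
  iso_ok <- tibble::tibble(
    isolate_id = c("1M", "2M", "1B"),
    group = c("mesophilic", "mesophilic", "spore_forming"),
    viability_ok = TRUE
  )
  rep1 <- viability_filter(fr, sr, iso_ok)
  expect_setequal(rep1$final, c("1M", "2M", "1B"))
  expect_identical(nrow(rep1$excluded), 0L)

  iso_none <- dplyr::mutate(iso_ok, viability_ok = FALSE)
  rep2 <- viability_filter(fr, sr, iso_none)
  expect_length(rep2$final, 0)
  expect_identical(rep2$excluded$reason, rep("viability", 3))
})

test_that("the worked-example accounting yields 15 + 4 - 3 = 16", {
  ex <- worked_example()
  first <- ex$rounds[ex$rounds$round == "first", ]
  second <- ex$rounds[ex$rounds$round == "second", ]
  expect_identical(nrow(first), 15L)
  report <- viability_filter(
    tibble::tibble(
      isolate_id = first$isolate_id, group = first$group,
      parameter = first$parameter, rule = "published"
    ),
    tibble::tibble(isolate_id = second$isolate_id, rule = "published"),
    ex$isolates
  )
  expect_setequal(report$excluded$isolate_id, c("114M", "45B", "89B"))
  expect_length(report$final, 16)
})

test_that("the final list does not depend on isolate input order", {
  cfg <- generator_config(
    seed = 4,
    n_per_group = c(
      mesophilic = 12L, spore_forming = 12L,
      pseudomonads = 12L, actinobacteria = 12L
    )
  )
  d <- generate_dataset(cfg)
  rep1 <- select_isolates(d)
  perm <- sample(nrow(d$isolates))
  d2 <- pgpb_data(
    isolates = d$isolates[perm, ],
    qualitative = d$qualitative[sample(nrow(d$qualitative)), ],
    quantitative = d$quantitative[sample(nrow(d$quantitative)), ]
  )
  rep2 <- select_isolates(d2)
  expect_identical(rep1$final, rep2$final)
})

test_that("planted elite isolates are always recovered in the first round", {
  for (seed in 1:20) {
    d <- generate_dataset(elite_cfg(seed))
    elites <- attr(d, "elites")
    qc <- qc_dataset(d)
    summaries <- quartile_summaries(qc$quantitative, d)
    codes <- code_table(qc$quantitative, d, summaries)
    fr <- first_round(codes, qc$quantitative)
    for (i in seq_len(nrow(elites))) {
      hit <- fr$isolate_id == elites$isolate_id[i] &
        fr$parameter == elites$parameter[i]
      expect_true(
        any(hit),
        label = sprintf(
          "seed %d: elite %s recovered for %s", seed,
          elites$isolate_id[i], elites$parameter[i]
        )
      )
    }
  }
})
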
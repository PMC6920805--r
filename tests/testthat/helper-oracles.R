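# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles, never by calling the code under test.

# pairwise Tukey-Kramer significance from the definition: studentized range
# of each pair against the pooled within-group mean square
oracle_pairwise_sig <- function(groups, alpha) {
  k <- length(groups)
  ns <- lengths(groups)
  means <- vapply(groups, mean, 0)
  df <- sum(ns) - k
  mse <- sum(vapply(
    groups,
    function(v) sum((v - mean(v))^2), 0
  )) / df
  sig <- matrix(FALSE, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      q <- abs(means[i] - means[j]) / se
      p <- stats::ptukey(q, k, df, lower.tail = FALSE)
      sig[i, j] <- sig[j, i] <- p < alpha
    }
  }
  sig
}

# one-way ANOVA from raw sums of squares
oracle_anova <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(all_v) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# eigendecomposition of the correlation matrix: correlation loadings and
# variance fractions
oracle_pca <- function(mat) {
  cr <- stats::cor(mat)
  eg <- eigen(cr, symmetric = TRUE)
  loadings <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  for (j in seq_len(ncol(loadings))) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
    }
  }
  rownames(loadings) <- colnames(mat)
  list(
    loadings = loadings,
    variance_fraction = eg$values / sum(eg$values)
  )
}

# configuration for elite-recovery tests: the quartile-coding rule needs a
# real assay population per group x parameter (the pooled q3 of one or two
# isolates' replicates falls inside the top isolate's own replicate spread,
# leaving no code-3 candidates), so the conditional assays get a positivity
# high enough that each cell has several performers
elite_cfg <- function(seed) {
  pos <- default_positivity()
  pos$prob[pos$trait %in% c("p_solubilization", "nitrification_qual")] <- 0.6
  generator_config(
    seed = seed,
    n_per_group = c(
      mesophilic = 15L, spore_forming = 15L,
      pseudomonads = 15L, actinobacteria = 15L
    ),
    positivity = pos,
    n_elites_per_group = 3L
  )
}

# a small fully populated dataset for IO and screening tests
make_tiny_data <- function() {
  pgpb_data(
    isolates = tibble::tibble(
      isolate_id = c("1M", "2M", "1B", "1P", "1A"),
      group = c(
        "mesophilic", "mesophilic", "spore_forming",
        "pseudomonads", "actinobacteria"
      ),
      viability_ok = c(TRUE, TRUE, TRUE, FALSE, TRUE)
    ),
    qualitative = tibble::tibble(
      isolate_id = rep(c("1M", "2M", "1B", "1P"), each = 6),
      trait = rep(rep(c("p_solubilization", "siderophores"), each = 3), 4),
      replicate = rep(1:3, 8),
      outcome = c(
        rep(TRUE, 6), # 1M positive to both
        rep(c(TRUE, TRUE, FALSE), 2), # 2M mixed -> 0
        rep(FALSE, 6), # 1B negative
        rep(TRUE, 3), rep(FALSE, 3) # 1P pos to P-sol only
      )
    ),
    quantitative = tibble::tibble(
      isolate_id = rep(c("1M", "2M", "1B"), each = 3),
      parameter = rep("iaa", 9),
      replicate = rep(1:3, 3),
      value = c(10, 10.5, 9.8, 4.1, 4.0, 4.2, 0, 0, 0)
    ),
    growth = tibble::tibble(
      pot_id = paste0("pot", 1:6),
      treatment = rep(c("control", "1M"), each = 3),
      biomass_g = c(2.0, 2.1, 1.9, 3.0, 3.1, 2.9),
      height_cm = c(25, 24, 26, 31, 30, 32)
    )
  )
}
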
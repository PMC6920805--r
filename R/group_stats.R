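check_groups <- function(groups) {
  if (length(groups) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (any(lengths(groups) < 2)) {
    stop("every group needs at least 2 replicate values", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "") ||
    anyDuplicated(names(groups))) {
    names(groups) <- make.unique(
      if (is.null(names(groups))) paste0("g", seq_along(groups)) else
        names(groups)
    )
  }
  groups
}

groups_to_df <- function(groups) {
  data.frame(
    value = unlist(groups, use.names = FALSE),
    level = factor(
      rep(names(groups), lengths(groups)),
      levels = names(groups)
    )
  )
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA over labelled replicate-value lists.
#'
#' @param groups Named list of numeric vectors, one per treatment/isolate,
#'   each with at least 2 values.
#' @return List with `f`, `p`, `df` (numerator, denominator).
#' @examples
#' oneway_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
oneway_anova <- function(groups) {
  groups <- check_groups(groups)
  df <- groups_to_df(groups)
  if (nrow(df) - length(groups) < 1) {
    stop("no residual degrees of freedom", call. = FALSE)
  }
  tab <- anova(aov(value ~ level, data = df))
  f <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (is.na(f)) { # zero residual variance with zero between variance
    f <- 0
    p <- 1
  }
  list(f = f, p = p, df = c(tab$Df[1], tab$Df[2]))
}

#' Tukey HSD homogeneous groups (compact letter display)
#'
#' All pairwise comparisons by Tukey's honestly-significant-difference test
#' (Tukey-Kramer adjustment for unequal replicate counts), summarised as a
#' compact letter display: two levels share a letter if and only if their
#' comparison is non-significant at `alpha`. Letters are assigned by the
#' insert-and-absorb algorithm over levels ordered by descending mean (ties
#' broken by label), so letter `a` always belongs to the highest mean.
#'
#' @inheritParams oneway_anova
#' @param alpha Significance level (0.05 for the selection stage, 0.01 for
#'   growth-chamber validation).
#' @return Tibble of class `pgpb_tukey`, ordered by descending mean:
#'   `level`, `n`, `mean`, `letters`; attributes `alpha` and `p_matrix`
#'   (pairwise adjusted p-values).
#' @examples
#' set.seed(1)
#' tukey_letters(list(hi = rnorm(5, 100), lo = rnorm(5, 0)), alpha = 0.05)
#' @export
tukey_letters <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups)
  df <- groups_to_df(groups)
  if (nrow(df) - length(groups) < 1) {
    stop("no residual degrees of freedom", call. = FALSE)
  }
  lev <- names(groups)
  k <- length(lev)
  pmat <- matrix(1, k, k, dimnames = list(lev, lev))
  fit <- aov(value ~ level, data = df)
  mse <- sum(fit$residuals^2) / fit$df.residual
  if (mse > 0) {
    hsd <- TukeyHSD(fit, conf.level = 1 - alpha)$level
    pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
    for (i in seq_along(pairs)) {
      a <- pairs[[i]][1]
      b <- pairs[[i]][2]
      pmat[a, b] <- pmat[b, a] <- hsd[i, "p adj"]
    }
  } else {
    # zero residual variance: any difference in means is significant
    means0 <- vapply(groups, mean, 0)
    for (a in lev) {
      for (b in lev) {
        if (a != b && means0[a] != means0[b]) pmat[a, b] <- 0
      }
    }
  }
  means <- vapply(groups, mean, 0)
  ord <- lev[order(-means, lev)]
  letters_by_level <- cld_insert_absorb(ord, pmat < alpha)
  out <- tibble::tibble(
    level = ord,
    n = lengths(groups)[ord],
    mean = unname(means[ord]),
    letters = unname(letters_by_level[ord])
  )
  attr(out, "alpha") <- alpha
  attr(out, "p_matrix") <- pmat
  class(out) <- c("pgpb_tukey", class(out))
  out
}

# Insert-and-absorb compact letter display. `ordered_levels` fixes letter
# order (first level gets "a"); `sig` is a logical matrix of significant
# pairs. Guarantees: significant pairs never share a letter; pairs never
# split share at least one.
cld_insert_absorb <- function(ordered_levels, sig) {
  cols <- list(ordered_levels)
  for (i in seq_along(ordered_levels)) {
    for (j in seq_along(ordered_levels)) {
      if (j <= i) next
      a <- ordered_levels[i]
      b <- ordered_levels[j]
      if (!sig[a, b]) next
      for (ci in rev(seq_along(cols))) {
        col <- cols[[ci]]
        if (a %in% col && b %in% col) {
          cols[[ci]] <- setdiff(col, a)
          cols[[length(cols) + 1]] <- setdiff(col, b)
        }
      }
      # absorb columns contained in another (duplicates: keep the earlier)
      drop <- rep(FALSE, length(cols))
      for (ci in seq_along(cols)) {
        for (cj in seq_along(cols)) {
          if (ci == cj || drop[ci] || drop[cj]) next
          if (all(cols[[ci]] %in% cols[[cj]]) &&
            (length(cols[[ci]]) < length(cols[[cj]]) || ci > cj)) {
            drop[ci] <- TRUE
          }
        }
      }
      cols <- cols[!drop]
    }
  }
  # order columns by the rank of their highest-ranked member, then assign a, b, ...
  first_rank <- vapply(
    cols,
    function(col) min(match(col, ordered_levels)), 0
  )
  cols <- cols[order(first_rank)]
  out <- setNames(rep("", length(ordered_levels)), ordered_levels)
  for (ci in seq_along(cols)) {
    for (lv in cols[[ci]]) {
      out[lv] <- paste0(out[lv], letters[ci])
    }
  }
  out
}

#' @export
print.pgpb_tukey <- function(x, ...) {
  cat("<pgpb_tukey> alpha =", attr(x, "alpha"), "\n")
  NextMethod()
}
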
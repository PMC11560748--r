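#' Summarize soil chemistry by treatment
#'
#' Per (treatment, indicator): sample mean, sample sd (n-1 denominator),
#' replicate count, and a Tukey HSD compact-letter group (treatments
#' sharing a letter are not significantly different at `alpha`).
#'
#' @param chem chemistry table (see [generate_chemistry()]).
#' @param indicators indicator columns to summarize.
#' @param alpha significance level for the letter display.
#' @param letters logical; compute Tukey letters (needs >= 2 replicates
#'   and >= 2 treatments).
#' @return data.frame with columns `treatment`, `indicator`, `mean`,
#'   `sd`, `n`, `tukey_letter`.
#' @export
summarize_chemistry <- function(chem, indicators = sq_indicators,
                                alpha = 0.05, letters = TRUE) {
  missing_ind <- setdiff(indicators, names(chem))
  if (length(missing_ind))
    stop("missing indicator column(s): ", paste(missing_ind, collapse = ", "))
  treatments <- unique(chem$treatment)
  out <- list()
  for (ind in indicators) {
    letts <- if (letters) tukey_letters(chem, ind, alpha = alpha)
             else stats::setNames(rep(NA_character_, length(treatments)), treatments)
    for (t in treatments) {
      x <- chem[[ind]][chem$treatment == t]
      if (length(x) < 2L)
        stop("treatment ", t, " has fewer than 2 replicates")
      out[[length(out) + 1L]] <- data.frame(
        treatment = t, indicator = ind,
        mean = mean(x), sd = stats::sd(x), n = length(x),
        tukey_letter = unname(letts[t])
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Core one-way ANOVA on a response vector and grouping factor; direct
# sums-of-squares arithmetic so the null-calibration simulations stay
# cheap. Cross-checked against stats::oneway.test in the test suite.
.anova_f <- function(x, g) {
  g <- as.factor(g)
  k <- nlevels(g)
  n <- length(x)
  if (k < 2L) stop("need >= 2 groups")
  if (any(tabulate(g) < 2L)) stop("need >= 2 replicates per group")
  gm <- tapply(x, g, mean)
  gn <- tabulate(g)
  ss_between <- sum(gn * (gm - mean(x))^2)
  ss_within <- sum((x - gm[g])^2)
  df1 <- k - 1L
  df2 <- n - k
  degenerate <- FALSE
  if (ss_within <= 0) {
    if (ss_between <= 0) {           # all values identical
      f <- 0; p <- 1; degenerate <- TRUE
    } else {                         # perfectly separated groups
      f <- Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    f <- (ss_between / df1) / (ss_within / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  list(f = f, p = p, df = c(df1, df2), degenerate = degenerate)
}

#' One-way ANOVA for a soil indicator across treatments
#'
#' Classical fixed-effects one-way ANOVA, `F = MS_between / MS_within`
#' on (k-1, N-k) degrees of freedom. Zero within-group variance is
#' reported as degenerate (`p = 0` if means differ, `F = 0, p = 1` if
#' all values are identical) rather than an error.
#'
#' @param chem chemistry table.
#' @param indicator indicator column name.
#' @return list with `f`, `p`, `df`, `degenerate`.
#' @export
anova_oneway <- function(chem, indicator) {
  if (!indicator %in% names(chem))
    stop("missing indicator column: ", indicator)
  .anova_f(chem[[indicator]], chem$treatment)
}

# Compact letter display: letter groups are the maximal cliques of the
# non-significance graph (vertices = treatments, edges = pairs with
# p >= alpha), ordered by their highest-mean member so "a" marks the
# largest mean. This realizes the letter semantics exactly: two
# treatments share a letter iff they are not significantly different.
.assign_letters <- function(means, pmat, alpha) {
  ord <- names(sort(means, decreasing = TRUE))
  adj <- (pmat >= alpha)[ord, ord, drop = FALSE]
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::max_cliques(g)
  groups <- lapply(cliques, function(cl) ord[as.integer(cl)])
  first <- vapply(groups, function(gr) min(match(gr, ord)), integer(1L))
  groups <- groups[order(first)]
  letts <- stats::setNames(rep("", length(means)), names(means))
  for (gi in seq_along(groups))
    for (t in groups[[gi]]) letts[t] <- paste0(letts[t], letters[gi])
  letts[ord][letts[ord] == ""] <- NA_character_  # unreachable; safety
  letts
}

#' Tukey HSD compact letter display for one indicator
#'
#' All pairwise comparisons via the studentized-range distribution
#' (Tukey HSD; Tukey-Kramer under unequal n, as provided by
#' [stats::TukeyHSD()]), then letters assigned highest-mean-first so
#' "a" marks the largest mean, as in field-trial tables.
#'
#' @param chem chemistry table.
#' @param indicator indicator column name.
#' @param alpha significance level.
#' @return named character vector of letter groups, one per treatment.
#' @export
tukey_letters <- function(chem, indicator, alpha = 0.05) {
  if (!indicator %in% names(chem))
    stop("missing indicator column: ", indicator)
  x <- chem[[indicator]]
  g <- factor(chem$treatment)
  means <- tapply(x, g, mean)
  tr <- levels(g)
  pmat <- matrix(1, length(tr), length(tr), dimnames = list(tr, tr))
  if (stats::var(x - means[g]) > 0 && length(tr) > 1L) {
    fit <- stats::aov(x ~ g, data = data.frame(x = x, g = g))
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    for (r in rownames(tk)) {
      pair <- strsplit(r, "-", fixed = TRUE)[[1L]]
      pmat[pair[1L], pair[2L]] <- pmat[pair[2L], pair[1L]] <- tk[r, "p adj"]
    }
  } else if (length(tr) > 1L) {
    # zero residual variance: identical means share a group, distinct split
    for (i in tr) for (j in tr)
      if (means[i] != means[j]) pmat[i, j] <- 0
  }
  .assign_letters(means, pmat, alpha)
}

#' Percent and fold change between two treatment means
#'
#' `percent_change = 100 (mean_num - mean_den) / mean_den` and
#' `fold_change = mean_num / mean_den`, computed from a
#' [summarize_chemistry()] table (or any table with `treatment`,
#' `indicator`, `mean` columns).
#'
#' @param summary summary table.
#' @param indicator indicator name.
#' @param num_treatment,den_treatment numerator / denominator treatments.
#' @return one-row data.frame with `indicator`, `num_treatment`,
#'   `den_treatment`, `percent_change`, `fold_change`.
#' @export
change_report <- function(summary, indicator, num_treatment, den_treatment) {
  pick <- function(t) {
    row <- summary[summary$treatment == t & summary$indicator == indicator, ]
    if (nrow(row) != 1L)
      stop("treatment ", t, " / indicator ", indicator, " not in summary")
    row$mean
  }
  mn <- pick(num_treatment)
  md <- pick(den_treatment)
  if (md <= 0) stop("denominator mean must be positive")
  data.frame(indicator = indicator,
             num_treatment = num_treatment, den_treatment = den_treatment,
             percent_change = 100 * (mn - md) / md,
             fold_change = mn / md)
}

#' Format a field-trial-style mean +/- sd + letter summary
#'
#' @param summary output of [summarize_chemistry()].
#' @param digits decimal places.
#' @return treatment x indicator character matrix like `"25.76 +/- 2.27ab"`.
#' @export
format_summary_table <- function(summary, digits = 2) {
  tr <- unique(summary$treatment)
  ind <- unique(summary$indicator)
  out <- matrix("", length(tr), length(ind), dimnames = list(tr, ind))
  for (i in seq_len(nrow(summary))) {
    s <- summary[i, ]
    out[s$treatment, s$indicator] <- paste0(
      formatC(s$mean, format = "f", digits = digits), " +/- ",
      formatC(s$sd, format = "f", digits = digits),
      if (!is.na(s$tukey_letter)) s$tukey_letter else "")
  }
  out
}
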
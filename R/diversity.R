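#' Alpha diversity per sample
#'
#' Observed richness, bias-corrected Chao1
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` (F1 singletons, F2 doubletons;
#' defined even when F2 = 0), Shannon entropy `-sum p log p` (natural
#' log by default), and Pielou evenness `H / log(S_obs)` (0 for a
#' single-OTU sample).
#'
#' @param cm a [community_matrix()] (or counts matrix, samples in rows).
#' @param base logarithm base for Shannon/Pielou.
#' @return data.frame with `sample_id`, `domain`, `observed_otus`,
#'   `chao1`, `shannon`, `pielou`.
#' @export
alpha_diversity <- function(cm, base = exp(1)) {
  counts <- if (inherits(cm, "community_matrix")) cm$counts else as.matrix(cm)
  domain <- if (inherits(cm, "community_matrix")) cm$domain else NA_character_
  tot <- rowSums(counts)
  if (any(tot == 0))
    stop("empty sample(s): ",
         paste(rownames(counts)[tot == 0], collapse = ", "))
  res <- lapply(seq_len(nrow(counts)), function(i) {
    x <- counts[i, ]
    x <- x[x > 0]
    s_obs <- length(x)
    f1 <- sum(x == 1)
    f2 <- sum(x == 2)
    chao1 <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    p <- x / sum(x)
    shannon <- -sum(p * log(p, base = base))
    pielou <- if (s_obs > 1L) shannon / log(s_obs, base = base) else 0
    data.frame(sample_id = rownames(counts)[i], domain = domain,
               observed_otus = s_obs, chao1 = chao1,
               shannon = shannon, pielou = pielou)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Relative-abundance composition collapsed to a taxonomic rank
#'
#' Counts are collapsed to the requested rank per sample and normalized;
#' if a treatment map is supplied, replicate means per treatment are
#' returned. OTUs lacking the rank are grouped as `"Unclassified"`.
#'
#' @param cm a [community_matrix()].
#' @param rank taxonomy column to collapse to (e.g. `"phylum"`,
#'   `"genus"`).
#' @param chem optional chemistry table supplying `treatment` per
#'   sample; if given, rows are treatments, else samples.
#' @return matrix of relative abundances; rows sum to 1.
#' @export
composition_by_rank <- function(cm, rank = "phylum", chem = NULL) {
  if (!rank %in% names(cm$taxonomy))
    stop("taxonomy has no rank column '", rank, "'")
  tax <- cm$taxonomy[[rank]]
  tax[is.na(tax) | tax == ""] <- "Unclassified"
  rel <- relative_abundance(cm)
  agg <- t(rowsum(t(rel), tax))           # samples x taxa
  if (!is.null(chem)) {
    tr <- chem$treatment[match(rownames(agg), chem$sample_id)]
    if (anyNA(tr)) stop("samples missing from chemistry table")
    agg <- rowsum(agg, tr)
    agg <- agg / as.vector(table(tr)[rownames(agg)])
  }
  agg
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum |x_k - y_k| / sum (x_k + y_k)`, computed on relative
#' abundances by default so library size does not masquerade as
#' community turnover.
#'
#' @param cm a [community_matrix()] or abundance matrix (samples in rows).
#' @param relative compute on row-normalized abundances (default) or on
#'   the raw values.
#' @return a `dist` object with attribute `metric = "bray_curtis"`.
#' @export
bray_curtis <- function(cm, relative = TRUE) {
  mat <- if (inherits(cm, "community_matrix")) cm$counts else as.matrix(cm)
  if (any(rowSums(mat) <= 0)) stop("per-sample totals must be positive")
  if (relative) mat <- sweep(mat, 1L, rowSums(mat), "/")
  d <- vegan::vegdist(mat, method = "bray")
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: eigendecomposition of the Gower-centered
#' `-d^2/2` matrix; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues; explained percentages are
#' relative to the sum of positive eigenvalues (negative eigenvalues are
#' excluded; no Lingoes/Cailliez correction).
#'
#' @param d a `dist` or symmetric matrix.
#' @param k maximum number of axes to return.
#' @return list of class `ordination` with `coordinates`,
#'   `eigenvalues`, `explained` (percent per axis), `method`.
#' @export
pcoa_ordination <- function(d, k = NULL) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (all(m == 0))
    return(structure(list(coordinates = matrix(0, n, 1, dimnames = list(rownames(m), "Axis1")),
                          eigenvalues = 0, explained = NA_real_,
                          method = "PCoA", degenerate = TRUE),
                     class = "ordination"))
  # cmdscale warns when fewer than k eigenvalues are positive; that is
  # the normal low-rank case and is handled below
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(m), k = n - 1L, eig = TRUE))
  ev <- fit$eig
  pos <- which(ev > sqrt(.Machine$double.eps) * max(abs(ev)))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  if (!is.null(k) && k < ncol(coords))
    coords <- coords[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = ev[pos],
                 explained = 100 * ev[pos] / sum(ev[pos]),
                 method = "PCoA", degenerate = FALSE),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(x$method, "ordination:", nrow(x$coordinates), "points,",
      ncol(x$coordinates), "axes; axis explained (%):",
      paste(round(x$explained[seq_len(min(4, length(x$explained)))], 2),
            collapse = ", "), "\n")
  invisible(x)
}

#' Redundancy analysis of community composition on soil chemistry
#'
#' Hellinger-transformed relative abundances regressed on standardized
#' indicators (vegan's RDA). The headline number is the total
#' constrained fraction: trace of the fitted covariance over the total,
#' in percent. Collinear (aliased) indicators are dropped with a
#' warning, in column order.
#'
#' @param cm a [community_matrix()] or abundance matrix.
#' @param chem chemistry table aligned to the samples.
#' @param indicators explanatory indicator columns.
#' @param transform `"hellinger"` (relative abundances,
#'   Hellinger-transformed; default) or `"none"` (the matrix is used
#'   as supplied, e.g. already transformed upstream).
#' @return list of class `ordination` with constrained-axis
#'   `coordinates`, `eigenvalues`, `explained` (percent of total
#'   inertia per constrained axis), `total_explained` (percent), and
#'   the underlying vegan fit as `fit`.
#' @export
rda_ordination <- function(cm, chem, indicators = sq_indicators,
                           transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  mat <- if (inherits(cm, "community_matrix")) cm$counts else as.matrix(cm)
  idx <- match(rownames(mat), chem$sample_id)
  if (anyNA(idx)) stop("samples missing from chemistry table")
  env_full <- chem[idx, indicators, drop = FALSE]
  keep <- vapply(env_full, function(x) stats::sd(x) > 0, logical(1L))
  if (any(!keep))
    warning("dropping zero-variance indicator(s): ",
            paste(indicators[!keep], collapse = ", "))
  env <- as.data.frame(scale(env_full[, keep, drop = FALSE]))
  if (nrow(mat) <= ncol(env) + 1L)
    warning("fewer samples than constraints + 1; RDA is saturated")
  hel <- if (transform == "hellinger")
    vegan::decostand(sweep(mat, 1L, rowSums(mat), "/"), method = "hellinger")
  else mat
  fit <- vegan::rda(hel ~ ., data = env)
  if (!is.null(fit$CCA$alias))
    warning("dropped aliased (collinear) indicator(s): ",
            paste(fit$CCA$alias, collapse = ", "))
  total <- fit$tot.chi
  constrained <- fit$CCA$tot.chi
  ev <- fit$CCA$eig
  coords <- vegan::scores(fit, display = "sites",
                          choices = seq_along(ev))
  structure(list(coordinates = coords,
                 eigenvalues = ev,
                 explained = 100 * ev / total,
                 total_explained = 100 * constrained / total,
                 method = "RDA", fit = fit),
            class = "ordination")
}

#' Mantel test between two distance matrices
#'
#' Statistic: Pearson correlation of the lower-triangle entries.
#' Significance: one-sided (positive association) permutation test over
#' simultaneous row/column relabelings of the second matrix,
#' `p = (1 + #[r_perm >= r_obs]) / (permutations + 1)`, seeded.
#'
#' @param d1,d2 `dist` objects or symmetric matrices over the same
#'   samples in the same order.
#' @param permutations number of label permutations.
#' @param seed integer seed for the permutation stream.
#' @return list with `r`, `p`, `permutations`.
#' @export
mantel_test <- function(d1, d2, permutations = 999, seed = 1L) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2)))
    stop("distance matrices must match in size")
  n <- nrow(m1)
  lower <- lower.tri(m1)
  v1 <- m1[lower]
  if (stats::sd(v1) == 0 || stats::sd(m2[lower]) == 0)
    return(list(r = NA_real_, p = NA_real_, permutations = permutations,
                degenerate = TRUE))
  r_obs <- stats::cor(v1, m2[lower])
  set.seed(seed)
  count <- 0L
  for (i in seq_len(permutations)) {
    perm <- sample.int(n)
    r_p <- stats::cor(v1, m2[perm, perm][lower])
    if (r_p >= r_obs) count <- count + 1L
  }
  list(r = r_obs, p = (1 + count) / (permutations + 1),
       permutations = permutations, degenerate = FALSE)
}

#' Spearman correlation panel of top taxa against soil indicators
#'
#' Taxa are collapsed at `rank`, ranked by mean relative abundance, and
#' the `top_n` correlated (Spearman, average ranks for ties) with every
#' indicator; two-tailed p from the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))`; stars at 0.05 / 0.01 / 0.001.
#' Constant vectors yield `NA` with a note.
#'
#' @param cm a [community_matrix()].
#' @param chem aligned chemistry table.
#' @param rank taxonomy rank to collapse to.
#' @param top_n number of taxa (by mean relative abundance).
#' @param indicators indicator columns.
#' @return data.frame with `taxon`, `indicator`, `rho`, `p`, `stars`.
#' @export
spearman_panel <- function(cm, chem, rank = "genus", top_n = 10,
                           indicators = sq_indicators) {
  comp <- composition_by_rank(cm, rank = rank)
  idx <- match(rownames(comp), chem$sample_id)
  if (anyNA(idx)) stop("samples missing from chemistry table")
  taxa <- names(sort(colMeans(comp), decreasing = TRUE))
  taxa <- taxa[seq_len(min(top_n, length(taxa)))]
  n <- nrow(comp)
  out <- list()
  for (tx in taxa) for (ind in indicators) {
    a <- comp[, tx]
    b <- chem[[ind]][idx]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      rho <- NA_real_; p <- NA_real_
    } else {
      rho <- stats::cor(rank(a), rank(b))
      if (abs(rho) >= 1) {
        p <- 0
      } else {
        tstat <- rho * sqrt((n - 2) / (1 - rho^2))
        p <- 2 * stats::pt(-abs(tstat), df = n - 2)
      }
    }
    stars <- if (is.na(p)) "" else if (p < 0.001) "***"
             else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
    out[[length(out) + 1L]] <- data.frame(taxon = tx, indicator = ind,
                                          rho = rho, p = p, stars = stars)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Regression of community distance on soil-quality contrast
#'
#' Ordinary least squares of pairwise community dissimilarity on the
#' pairwise absolute SQI difference. Because pairs share samples, the
#' p-value is a Mantel-style one-sided permutation test (positive
#' slope) over relabelings of the SQI vector, seeded. An alternative
#' reading regresses each sample's distance to the control centroid on
#' its own SQI (`mode = "to_control"`).
#'
#' @param d `dist` of community dissimilarities.
#' @param sqi named numeric vector of per-sample SQI values.
#' @param mode `"pairwise"` (default) or `"to_control"`.
#' @param control control treatment samples (names) for
#'   `mode = "to_control"`.
#' @param permutations,seed permutation test parameters.
#' @return list with `slope`, `intercept`, `r_squared`, `p`, `mode`.
#' @export
distance_vs_sqi_regression <- function(d, sqi, mode = c("pairwise", "to_control"),
                                       control = NULL,
                                       permutations = 999, seed = 1L) {
  mode <- match.arg(mode)
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 3L) stop("need >= 3 samples")
  sqi <- sqi[rownames(m)]
  if (anyNA(sqi)) stop("every sample needs an SQI value")
  if (stats::sd(sqi) == 0)
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, p = NA_real_, mode = mode,
                degenerate = TRUE))
  if (mode == "pairwise") {
    lower <- lower.tri(m)
    y <- m[lower]
    xfun <- function(s) abs(outer(s, s, "-"))[lower]
    x <- xfun(sqi)
    fit <- stats::lm(y ~ x)
    r_obs <- stats::cor(x, y)
    set.seed(seed)
    count <- 0L
    for (i in seq_len(permutations)) {
      r_p <- stats::cor(xfun(sqi[sample.int(n)]), y)
      if (r_p >= r_obs) count <- count + 1L
    }
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = summary(fit)$r.squared,
         p = (1 + count) / (permutations + 1), mode = mode,
         degenerate = FALSE)
  } else {
    if (is.null(control)) stop("mode 'to_control' needs control sample names")
    y <- rowMeans(m[, control, drop = FALSE])
    keep <- !(rownames(m) %in% control)
    y <- y[keep]; x <- sqi[keep]
    fit <- stats::lm(y ~ x)
    set.seed(seed)
    r_obs <- stats::cor(x, y)
    count <- 0L
    for (i in seq_len(permutations)) {
      r_p <- stats::cor(sample(x), y)
      if (abs(r_p) >= abs(r_obs)) count <- count + 1L
    }
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = summary(fit)$r.squared,
         p = (1 + count) / (permutations + 1), mode = mode,
         degenerate = FALSE)
  }
}
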
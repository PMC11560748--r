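#' Min-max membership functions
#'
#' Rescales each indicator column to \[0, 1\] over the entities of the
#' table. Ascending ("more is better", e.g. nutrients, diversity):
#' `F(x) = (x - min) / (max - min)`. Descending ("less is better",
#' e.g. pH, EC on saline-alkaline soil): `F(x) = (max - x) / (max - min)`.
#' A degenerate indicator (max = min) cannot rank entities; its
#' memberships are set to the neutral 0.5 with a warning, so it shifts
#' every entity's index equally.
#'
#' @param values entity x indicator numeric matrix (or data.frame) with
#'   row and column names.
#' @param directions named character vector, one of
#'   `"ascending"`/`"descending"` per indicator column.
#' @return entity x indicator matrix of memberships in \[0, 1\], class
#'   `membership_matrix`.
#' @export
membership <- function(values, directions) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("need >= 2 entities")
  miss <- setdiff(colnames(values), names(directions))
  if (length(miss))
    stop("no direction given for indicator(s): ", paste(miss, collapse = ", "))
  bad <- !directions[colnames(values)] %in% c("ascending", "descending")
  if (any(bad))
    stop("directions must be 'ascending' or 'descending'")
  memb <- values
  for (ind in colnames(values)) {
    x <- values[, ind]
    lo <- min(x); hi <- max(x)
    if (hi == lo) {
      warning("indicator '", ind, "' is constant across entities; ",
              "memberships set to 0.5")
      memb[, ind] <- 0.5
    } else if (directions[[ind]] == "ascending") {
      memb[, ind] <- (x - lo) / (hi - lo)
    } else {
      memb[, ind] <- (hi - x) / (hi - lo)
    }
  }
  class(memb) <- c("membership_matrix", class(memb))
  memb
}

#' Principal-component factor-loading weights
#'
#' Columns are standardized and PCA is taken as the eigendecomposition
#' of the correlation matrix. For component j with eigenvalue
#' `lambda_j`: the variance contribution rate is
#' `K_j = 100 lambda_j / sum(lambda)`; factor loadings are eigenvector
#' entries scaled by `sqrt(lambda_j)`; `C_ij` is the absolute loading
#' and the per-component indicator weights are `W_ij = C_ij / sum_i C_ij`.
#' `m` retained components are kept (clamped to the number of
#' indicators), or the smallest m whose cumulative K reaches
#' `cum_threshold`.
#'
#' @param values entity x indicator matrix.
#' @param m number of components to retain (default 4).
#' @param cum_threshold if given (percent), overrides `m` with the
#'   smallest count reaching this cumulative contribution.
#' @param loading_type `"factor"` (eigenvector x sqrt(lambda), default)
#'   or `"eigenvector"` for sensitivity analysis.
#' @return list of class `pca_weighting`: `m`, `contribution` (K, %,
#'   all components), `loadings`, `abs_loadings`, `weights` (indicator
#'   x component, columns summing to 1), `indicators`, `dropped`.
#' @export
pca_weighting <- function(values, m = 4L, cum_threshold = NULL,
                          loading_type = c("factor", "eigenvector")) {
  loading_type <- match.arg(loading_type)
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need >= 2 entities and >= 2 indicators")
  sds <- apply(values, 2L, stats::sd)
  dropped <- colnames(values)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance indicator(s): ",
            paste(dropped, collapse = ", "))
    values <- values[, sds > 0, drop = FALSE]
  }
  if (ncol(values) < 2L) stop("fewer than 2 indicators with variance")
  cormat <- stats::cor(values)
  eig <- eigen(cormat, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  vec <- eig$vectors
  # deterministic sign: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(ncol(vec))) {
    pivot <- which.max(abs(vec[, j]))
    if (vec[pivot, j] < 0) vec[, j] <- -vec[, j]
  }
  contribution <- 100 * lambda / sum(lambda)
  loadings <- sweep(vec, 2L, sqrt(lambda), "*")
  if (loading_type == "eigenvector") loadings <- vec
  dimnames(loadings) <- list(colnames(values),
                             paste0("PC", seq_len(ncol(vec))))
  absload <- abs(loadings)
  colsums <- colSums(absload)
  weights <- sweep(absload, 2L, ifelse(colsums > 0, colsums, 1), "/")
  # a null component (lambda = 0) has no loadings to weight; give it
  # uniform weights so every column sums to 1 (it carries K = 0 anyway)
  weights[, colsums == 0] <- 1 / nrow(weights)
  if (!is.null(cum_threshold)) {
    m <- which(cumsum(contribution) >= cum_threshold - 1e-9)[1L]
    if (is.na(m)) m <- length(contribution)
  }
  m <- min(as.integer(m), ncol(values))
  if (m < 1L) stop("m must be >= 1")
  structure(list(m = m, contribution = contribution,
                 loadings = loadings, abs_loadings = absload,
                 weights = weights, indicators = colnames(values),
                 dropped = dropped),
            class = "pca_weighting")
}

#' @export
print.pca_weighting <- function(x, ...) {
  cat("PCA weighting:", length(x$indicators), "indicators,", x$m,
      "retained components; contribution (%):",
      paste(round(x$contribution[seq_len(x$m)], 2), collapse = ", "),
      "(cumulative", round(sum(x$contribution[seq_len(x$m)]), 2), ")\n")
  invisible(x)
}

#' Composite soil quality index
#'
#' `SQI(e) = sum_j K_j * sum_i W_ij * F_ei` over the `m` retained
#' components, with `K_j` in percent, so with all memberships at 1 the
#' index attains `sum_j K_j` (at most 100). Entities are ranked by
#' descending SQI (rank 1 = best); exact ties share order by entity
#' label and are flagged.
#'
#' @param memberships entity x indicator [membership()] matrix.
#' @param weighting a [pca_weighting()].
#' @return data.frame of class `sqi_result` with `entity`, `sqi`,
#'   `rank`, `tied`.
#' @export
sqi_score <- function(memberships, weighting) {
  memb <- as.matrix(memberships)
  mismatch <- c(setdiff(colnames(memb), weighting$indicators),
                setdiff(weighting$indicators, colnames(memb)))
  if (length(mismatch))
    stop("indicator mismatch between memberships and weighting: ",
         paste(unique(mismatch), collapse = ", "))
  memb <- memb[, weighting$indicators, drop = FALSE]
  jj <- seq_len(weighting$m)
  inner <- memb %*% weighting$weights[, jj, drop = FALSE]   # entity x comp
  sqi <- as.vector(inner %*% weighting$contribution[jj])
  names(sqi) <- rownames(memb)
  ord <- order(-sqi, names(sqi))
  rk <- integer(length(sqi))
  rk[ord] <- seq_along(sqi)
  tied <- duplicated(sqi) | duplicated(sqi, fromLast = TRUE)
  out <- data.frame(entity = names(sqi), sqi = sqi, rank = rk, tied = tied)
  rownames(out) <- NULL
  class(out) <- c("sqi_result", class(out))
  out
}

#' Default indicator directions for the saline-alkaline index
#'
#' Nutrients and diversity ascend (more is better); pH and EC descend
#' (a saline-alkaline soil improves as they fall).
#' @param indicators indicator names.
#' @return named character vector of directions.
#' @export
default_directions <- function(indicators) {
  dirs <- stats::setNames(rep("ascending", length(indicators)), indicators)
  dirs[names(dirs) %in% c("pH", "EC")] <- "descending"
  dirs
}

#' Run the full soil-quality-index pipeline
#'
#' Assembles the entity x indicator table (soil chemistry plus, when
#' supplied, per-domain Chao1 and Shannon), applies [membership()],
#' [pca_weighting()] and [sqi_score()], and returns the result with all
#' intermediates for audit. Entities are treatment means by default;
#' `entity_mode = "sample"` scores every replicate sample instead (the
#' min/max of the membership functions are then taken over samples).
#'
#' @param chem chemistry table.
#' @param alpha_div optional named list of [alpha_diversity()] tables,
#'   one per domain, aligned to `chem$sample_id`.
#' @param indicators chemistry indicator columns to use.
#' @param alpha_metrics diversity metrics to append per domain.
#' @param entity_mode `"treatment"` (means; default) or `"sample"`.
#' @param directions indicator directions; defaults via
#'   [default_directions()].
#' @param m retained components (see [pca_weighting()]).
#' @param cum_threshold optional cumulative-contribution override.
#' @return list of class `sqi_pipeline`: `sqi` ([sqi_score()] result),
#'   `membership`, `weighting`, `table` (the entity x indicator input),
#'   `entity_mode`.
#' @export
run_sqi_pipeline <- function(chem, alpha_div = NULL,
                             indicators = sq_indicators,
                             alpha_metrics = c("chao1", "shannon"),
                             entity_mode = c("treatment", "sample"),
                             directions = NULL, m = 4L,
                             cum_threshold = NULL) {
  entity_mode <- match.arg(entity_mode)
  miss <- setdiff(indicators, names(chem))
  if (length(miss))
    stop("indicator(s) absent from chemistry table: ",
         paste(miss, collapse = ", "))
  tab <- as.matrix(chem[, indicators, drop = FALSE])
  rownames(tab) <- chem$sample_id
  for (dom in names(alpha_div)) {
    ad <- alpha_div[[dom]]
    idx <- match(chem$sample_id, ad$sample_id)
    if (anyNA(idx))
      stop("alpha diversity (", dom, ") missing sample(s): ",
           paste(chem$sample_id[is.na(idx)], collapse = ", "))
    add <- as.matrix(ad[idx, alpha_metrics, drop = FALSE])
    colnames(add) <- paste0(alpha_metrics, "_", dom)
    tab <- cbind(tab, add)
  }
  if (entity_mode == "treatment") {
    tab <- rowsum(tab, chem$treatment)
    tab <- tab / as.vector(table(chem$treatment)[rownames(tab)])
  }
  if (is.null(directions)) directions <- default_directions(colnames(tab))
  if (all(apply(tab, 2L, stats::sd) == 0)) {
    # fully degenerate table: every entity identical. All memberships sit
    # at the neutral 0.5, so whatever the weights, SQI = 50 for everyone.
    warning("all indicators constant across entities; SQI is uniform")
    sqi <- data.frame(entity = rownames(tab), sqi = 50,
                      rank = seq_len(nrow(tab)), tied = TRUE)
    class(sqi) <- c("sqi_result", class(sqi))
    return(structure(list(sqi = sqi, membership = NULL, weighting = NULL,
                          table = tab, entity_mode = entity_mode,
                          degenerate = TRUE),
                     class = "sqi_pipeline"))
  }
  memb <- membership(tab, directions)
  weighting <- pca_weighting(tab, m = m, cum_threshold = cum_threshold)
  if (length(weighting$dropped))
    memb <- memb[, weighting$indicators, drop = FALSE]
  res <- sqi_score(memb, weighting)
  structure(list(sqi = res, membership = memb, weighting = weighting,
                 table = tab, entity_mode = entity_mode),
            class = "sqi_pipeline")
}

#' @export
print.sqi_pipeline <- function(x, ...) {
  cat("SQI pipeline (", x$entity_mode, "-level, ",
      length(x$weighting$indicators), " indicators, m = ",
      x$weighting$m, ")\n", sep = "")
  print(x$sqi[order(x$sqi$rank), ], row.names = FALSE)
  invisible(x)
}
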
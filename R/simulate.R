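#' Generate a replicate-level soil chemistry table
#'
#' Draws each indicator independently per replicate from a normal law
#' with that treatment's (mean, sd). Draws outside the physical domain
#' (concentrations <= 0; pH outside (0, 14)) are resampled, not clipped,
#' so treatment means are preserved to first order. `sd = 0` yields
#' replicates identical to the mean.
#'
#' @param spec a [scenario_spec()].
#' @return data.frame with columns `sample_id`, `treatment`,
#'   `replicate`, and one column per indicator (SOM, AN, AP, AK, pH, EC).
#' @export
generate_chemistry <- function(spec) {
  validate_scenario_spec(spec)
  set.seed(.substream(spec$seed, 101))
  tr <- spec$treatments
  nrep <- spec$replicates_per_treatment
  rows <- vector("list", length(tr) * nrep)
  k <- 0L
  for (t in tr) {
    for (r in seq_len(nrep)) {
      vals <- vapply(sq_indicators, function(ind) {
        mu <- spec$chemistry_means[t, ind]
        sd <- spec$chemistry_sds[t, ind]
        if (sd == 0) return(mu)
        ok <- if (ind == "pH") function(x) x > 0 && x < 14 else function(x) x > 0
        repeat {
          x <- stats::rnorm(1L, mu, sd)
          if (ok(x)) return(x)
        }
      }, numeric(1L))
      k <- k + 1L
      rows[[k]] <- data.frame(
        sample_id = paste0(t, "_", r), treatment = t, replicate = r,
        as.list(vals), check.names = FALSE
      )
    }
  }
  chem <- do.call(rbind, rows)
  rownames(chem) <- NULL
  chem
}

#' Construct a community matrix object
#'
#' The container for a sample x OTU count table plus per-OTU taxonomy,
#' as produced by [generate_communities()] or read from disk.
#'
#' @param counts integer matrix, samples in rows, OTUs in columns, with
#'   dimnames.
#' @param taxonomy data.frame with columns `otu_id`, `domain`, `phylum`,
#'   `genus` (one row per OTU, matching `colnames(counts)`).
#' @param domain `"bacteria"` or `"fungi"`.
#' @param truth optional generator ground truth (planted blocks).
#' @return object of class `community_matrix`.
#' @export
community_matrix <- function(counts, taxonomy, domain, truth = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry sample and OTU dimnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0))
    stop("all-zero sample(s): ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  if (anyDuplicated(colnames(counts))) stop("otu ids must be unique")
  if (!identical(sort(taxonomy$otu_id), sort(colnames(counts))))
    stop("taxonomy must cover every OTU exactly once")
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$otu_id), , drop = FALSE]
  rownames(taxonomy) <- NULL
  structure(list(counts = counts, taxonomy = taxonomy,
                 domain = domain, truth = truth),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("community_matrix (", x$domain, "): ", nrow(x$counts), " samples x ",
      ncol(x$counts), " OTUs, median depth ",
      stats::median(rowSums(x$counts)), "\n", sep = "")
  invisible(x)
}

#' Per-sample relative abundances of a community matrix
#' @param cm a `community_matrix` (or a counts matrix).
#' @return matrix of row-normalized abundances.
#' @export
relative_abundance <- function(cm) {
  counts <- if (inherits(cm, "community_matrix")) cm$counts else as.matrix(cm)
  sweep(counts, 1L, rowSums(counts), "/")
}

# Round phylum target counts to integers that sum to n (largest remainder).
.apportion <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

# Dirichlet draw via normalized gammas; alpha == 0 entries stay 0.
.rdirichlet <- function(alpha) {
  g <- numeric(length(alpha))
  pos <- alpha > 0
  g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  g / sum(g)
}

.generate_domain <- function(spec, chem, domain, stream_offset) {
  set.seed(.substream(spec$seed, stream_offset))
  tr <- spec$treatments
  control <- tr[1L]
  mult <- spec$richness_multiplier[tr, domain]
  n_base <- as.integer(spec$n_otus_base[[domain]])
  n_active <- as.integer(round(n_base * mult))
  names(n_active) <- tr
  s_max <- max(n_active)
  libsize <- if (length(spec$library_size) > 1L)
    as.integer(spec$library_size[[domain]]) else as.integer(spec$library_size)
  if (libsize < 10L * n_base)
    warning("library_size < 10 x n_otus_base (", domain,
            "): undersampling will distort richness targets")

  profiles <- spec$phylum_profiles[[domain]][tr, , drop = FALSE]
  phyla <- colnames(profiles)
  # Fixed OTU -> phylum assignment from the across-treatment mean profile,
  # interleaved so every prefix of the pool keeps the phylum mix: richness
  # contrasts then add OTUs without skewing composition.
  n_phy <- .apportion(colMeans(profiles), s_max)
  assign_order <- order(unlist(lapply(seq_along(phyla), function(i) {
    if (n_phy[i] == 0) return(numeric(0))
    (seq_len(n_phy[i]) - 0.5) / n_phy[i]
  })))
  phylum_of <- rep(phyla, n_phy)[assign_order]
  prefix <- substr(domain, 1L, 1L)
  otu_ids <- sprintf("%s_OTU%04d", toupper(prefix), seq_len(s_max))
  genus_of <- paste0(substr(phylum_of, 1L, 4L), "_g",
                     ave(seq_len(s_max), phylum_of,
                         FUN = function(i) (seq_along(i) - 1L) %/% 3L + 1L))

  base_log <- stats::rnorm(s_max, 0, spec$lognormal_sd)

  # Planted blocks live among the first n_base OTUs (active under every
  # treatment) and get a +1 log-abundance boost so they are well sampled.
  blocks <- spec$correlated_blocks[[domain]]
  n_block_otus <- sum(vapply(blocks, function(b) b$size, integer(1L)))
  truth <- NULL
  block_idx <- list()
  if (n_block_otus > 0) {
    if (n_block_otus > n_base)
      stop("correlated blocks need more OTUs than n_otus_base (", domain, ")")
    pool <- sample(seq_len(n_base), n_block_otus)
    at <- 0L
    truth_rows <- list()
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      idx <- pool[(at + 1L):(at + b$size)]
      at <- at + b$size
      loading_sign <- if (b$sign == "positive") rep(1, b$size)
                      else rep_len(c(1, -1), b$size)
      block_idx[[bi]] <- list(idx = idx, sign = loading_sign, rho = b$rho)
      base_log[idx] <- abs(base_log[idx]) + 1  # keep block OTUs well sampled
      truth_rows[[bi]] <- data.frame(otu_id = otu_ids[idx], block = bi,
                                     loading_sign = loading_sign)
    }
    truth <- list(blocks = do.call(rbind, truth_rows))
  }

  # Per-sample log-abundance jitter outside blocks, and the residual
  # noise scale inside blocks. The block factor loading is
  # block_noise_sd * sqrt(rho / (1 - rho)), so rho sets the latent
  # correlation while the small absolute scale keeps abundances in the
  # near-linear regime of exp(), where the latent correlation survives
  # onto the abundance scale instead of being destroyed by lognormal
  # skew and compositional closure.
  sample_noise_sd <- 0.2
  block_noise_sd <- 0.1

  samples <- chem$sample_id
  counts <- matrix(0L, length(samples), s_max,
                   dimnames = list(samples, otu_ids))
  for (si in seq_along(samples)) {
    t <- chem$treatment[si]
    active <- seq_len(n_active[[t]])
    w <- exp(base_log)
    # rescale within phylum to hit the treatment's composition target
    for (pi in seq_along(phyla)) {
      members <- intersect(which(phylum_of == phyla[pi]), active)
      if (!length(members)) next
      w[members] <- w[members] * profiles[t, pi] / sum(w[members])
    }
    logw <- log(w)
    logw <- logw + stats::rnorm(s_max, 0, sample_noise_sd)
    for (b in block_idx) {
      f <- stats::rnorm(1L)
      lam <- block_noise_sd * sqrt(b$rho / (1 - b$rho))
      logw[b$idx] <- log(w[b$idx]) + b$sign * (lam * f) +
        stats::rnorm(length(b$idx), 0, block_noise_sd)
    }
    ew <- exp(logw)
    ew[-active] <- 0
    ew <- ew / sum(ew)
    alpha <- spec$concentration * length(active) * ew
    p <- .rdirichlet(alpha)
    counts[si, ] <- stats::rmultinom(1L, libsize, p)[, 1L]
  }
  taxonomy <- data.frame(otu_id = otu_ids, domain = domain,
                         phylum = phylum_of, genus = genus_of)
  community_matrix(counts, taxonomy, domain, truth = truth)
}

#' Generate OTU count tables coupled to a chemistry table
#'
#' Simulates one sample x OTU count table per domain (bacteria, fungi)
#' for the samples of `chem`. Counts are Dirichlet-multinomial around a
#' treatment-level expected composition that honors the scenario's
#' phylum profiles; the number of OTUs with nonzero mass scales with the
#' treatment's richness multiplier (so realized Chao1 fold-changes track
#' the targets); planted blocks of OTUs share a latent Gaussian factor
#' on the log-abundance scale, giving the co-occurrence network module
#' recoverable ground truth (stored in `$truth`).
#'
#' @param spec a [scenario_spec()].
#' @param chem chemistry table from [generate_chemistry()] (defines the
#'   samples and their treatments).
#' @return named list of [community_matrix()] objects, one per domain.
#' @export
generate_communities <- function(spec, chem) {
  validate_scenario_spec(spec)
  need <- c("sample_id", "treatment")
  if (!all(need %in% names(chem)))
    stop("chem must have sample_id and treatment columns")
  if (!all(chem$treatment %in% spec$treatments))
    stop("mismatched sample ids/treatments between spec and chemistry table")
  domains <- names(spec$n_otus_base)
  offsets <- 202L + 100L * (seq_along(domains) - 1L)
  out <- lapply(seq_along(domains), function(i)
    .generate_domain(spec, chem, domains[i], offsets[i]))
  names(out) <- domains
  out
}

#' Generate a full synthetic scenario
#'
#' Convenience wrapper running [generate_chemistry()] then
#' [generate_communities()].
#' @param spec a [scenario_spec()].
#' @return list with `chemistry` and `communities`.
#' @export
generate_scenario <- function(spec) {
  chem <- generate_chemistry(spec)
  list(chemistry = chem, communities = generate_communities(spec, chem))
}
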
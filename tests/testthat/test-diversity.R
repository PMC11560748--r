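mat_of <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  dimnames(m) <- list(paste0("s", seq_len(nrow(m))),
                      paste0("o", seq_len(ncol(m))))
  m
}

test_that("alpha diversity matches hand-computed formulas", {
  ad <- alpha_diversity(mat_of(c(1, 1, 2, 2, 5)))
  expect_equal(ad$observed_otus, 5L)
  expect_equal(ad$chao1, 5 + 2 * 1 / (2 * 3))
  # even two-species community: shannon = ln 2, evenness 1
  ad <- alpha_diversity(mat_of(c(10, 10)))
  expect_equal(ad$shannon, log(2))
  expect_equal(ad$pielou, 1)
  # no singletons: chao1 collapses to observed richness
  ad <- alpha_diversity(mat_of(c(5, 3, 2, 2)))
  expect_equal(ad$chao1, 4)
  # single-OTU sample: evenness defined as 0
  ad <- alpha_diversity(mat_of(c(7, 0)))
  expect_equal(ad$pielou, 0)
  expect_error(alpha_diversity(mat_of(c(0, 0), c(1, 1))), "s1")
})

test_that("Chao1 agrees with brute force and with vegan on random samples", {
  set.seed(17)
  brute_chao1 <- function(x) {
    # frequency-of-frequencies recomputation, independent of the
    # implementation's vectorized path
    ff <- table(x[x > 0])
    f1 <- if ("1" %in% names(ff)) as.numeric(ff[["1"]]) else 0
    f2 <- if ("2" %in% names(ff)) as.numeric(ff[["2"]]) else 0
    sum(x > 0) + f1 * (f1 - 1) / (2 * (f2 + 1))
  }
  counts <- matrix(rpois(200 * 40, lambda = rep(c(0.3, 1, 5), length.out = 40)),
                   200, 40, dimnames = list(paste0("s", 1:200), paste0("o", 1:40)))
  counts[rowSums(counts) == 0, 1] <- 1L
  ad <- alpha_diversity(counts)
  expect_equal(ad$chao1, unname(apply(counts, 1, brute_chao1)))
  # and against vegan's independent estimator
  veg <- t(suppressWarnings(vegan::estimateR(counts)))[, "S.chao1"]
  expect_equal(ad$chao1, unname(veg), tolerance = 1e-9)
})

test_that("composition collapses and normalizes by rank", {
  counts <- mat_of(c(30, 70, 100))
  tax <- data.frame(otu_id = colnames(counts), domain = "bacteria",
                    phylum = c("P1", "P1", "P2"), genus = c("g1", "g2", "g3"))
  cm <- community_matrix(counts, tax, "bacteria")
  comp <- composition_by_rank(cm, "phylum")
  expect_equal(unname(comp[1, c("P1", "P2")]), c(0.5, 0.5))
  # missing rank values group as Unclassified
  cm$taxonomy$phylum[3] <- NA
  comp <- composition_by_rank(cm, "phylum")
  expect_equal(unname(comp[1, "Unclassified"]), 0.5)
  expect_error(composition_by_rank(cm, "family"), "family")
})

test_that("Bray-Curtis matches hand cases and metric properties", {
  rel <- mat_of(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0.5, 0), c(1, 0, 0))
  d <- as.matrix(bray_curtis(rel, relative = FALSE))
  expect_equal(d["s1", "s2"], 0.5)
  expect_equal(d["s1", "s3"], 0)          # identical samples
  expect_equal(d["s2", "s4"], 1)          # disjoint support
  set.seed(3)
  counts <- matrix(rpois(200, 3), 10, 20)
  counts[, 1] <- counts[, 1] + 1
  dimnames(counts) <- list(paste0("s", 1:10), paste0("o", 1:20))
  dm <- as.matrix(bray_curtis(counts))
  expect_equal(dm, t(dm), tolerance = 1e-12)
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm >= 0 & dm <= 1))
})

test_that("PCoA embeds Euclidean configurations exactly", {
  # three collinear points: one axis carries everything
  pts <- cbind(c(0, 1, 2))
  rownames(pts) <- paste0("s", 1:3)
  ord <- pcoa_ordination(dist(pts))
  expect_equal(ord$explained[1], 100)
  # round trip from a known 2-D point set
  set.seed(9)
  pts <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  ord <- pcoa_ordination(dist(pts))
  expect_equal(as.matrix(dist(ord$coordinates)), as.matrix(dist(pts)),
               tolerance = 1e-9)
  expect_true(all(diff(ord$explained) <= 1e-9))
  # permutation invariance of the eigenvalues
  perm <- sample(10)
  ord2 <- pcoa_ordination(as.matrix(dist(pts))[perm, perm])
  expect_equal(ord2$eigenvalues, ord$eigenvalues, tolerance = 1e-9)
})

test_that("RDA explains everything for a noiseless linear response", {
  set.seed(12)
  chem <- generate_chemistry(tiny_spec(seed = 12))
  # response exactly linear in the standardized indicators
  env <- scale(as.matrix(chem[, sq_indicators]))
  resp <- env %*% matrix(rnorm(6 * 5), 6, 5)
  resp <- resp - min(resp) + 0.5    # make it a positive "abundance"
  rownames(resp) <- chem$sample_id
  colnames(resp) <- paste0("o", 1:5)
  # (vegan notes the model is saturated; that is the point of the case)
  ord <- suppressWarnings(rda_ordination(resp, chem, transform = "none"))
  expect_equal(ord$total_explained, 100, tolerance = 1e-6)
  # duplicated explanatory column changes nothing
  chem2 <- chem; chem2$SOM2 <- chem2$SOM
  ord2 <- suppressWarnings(
    rda_ordination(resp, chem2, indicators = c(sq_indicators, "SOM2"),
                   transform = "none"))
  expect_equal(ord2$total_explained, ord$total_explained, tolerance = 1e-9)
})

test_that("RDA on independent noise explains little at n = 40", {
  set.seed(13)
  n <- 40
  chem <- data.frame(sample_id = paste0("s", 1:n),
                     treatment = "A", replicate = 1:n,
                     SOM = rnorm(n), AN = rnorm(n), AP = rnorm(n),
                     AK = rnorm(n), pH = rnorm(n, 8, 0.2), EC = rnorm(n))
  counts <- matrix(rpois(n * 30, 20), n, 30,
                   dimnames = list(chem$sample_id, paste0("o", 1:30)))
  ord <- rda_ordination(counts, chem, indicators = sq_indicators[1:5])
  expect_lt(ord$total_explained, 20)
})

test_that("Mantel statistic and calibration behave", {
  set.seed(30)
  pts <- matrix(rnorm(16), 8, 2)
  d1 <- dist(pts)
  expect_equal(mantel_test(d1, d1, permutations = 99)$r, 1)
  expect_equal(mantel_test(d1, 2 * d1, permutations = 99)$r, 1)
  expect_true(mantel_test(d1, dist(rep(0, 8)) + 0, permutations = 9)$degenerate)
  # statistic agrees with vegan's Mantel r
  d2 <- dist(matrix(rnorm(16), 8, 2))
  expect_equal(mantel_test(d1, d2, permutations = 99)$r,
               unname(vegan::mantel(d1, d2, permutations = 9)$statistic),
               tolerance = 1e-12)
  # determinism under the seed
  expect_identical(mantel_test(d1, d2, permutations = 99, seed = 4),
                   mantel_test(d1, d2, permutations = 99, seed = 4))
})

test_that("Spearman panels handle monotone, anti-monotone and tied data", {
  # constant row totals (200) so relative abundances keep the raw ranks
  o1 <- c(10, 20, 30, 40, 50); o2 <- c(50, 40, 30, 20, 10)
  o3 <- c(10, 10, 30, 20, 50); o4 <- 200 - (o1 + o2 + o3)
  counts <- cbind(o1 = o1, o2 = o2, o3 = o3, o4 = o4)
  rownames(counts) <- paste0("s", 1:5)
  tax <- data.frame(otu_id = colnames(counts), domain = "bacteria",
                    phylum = "P", genus = c("gA", "gB", "gC", "gD"))
  cm <- community_matrix(counts, tax, "bacteria")
  chem <- data.frame(sample_id = paste0("s", 1:5), treatment = "A",
                     replicate = 1:5, SOM = c(1, 2, 3, 4, 5), AN = 1:5,
                     AP = 1:5, AK = 1:5, pH = rep(8, 5), EC = 5:1)
  panel <- spearman_panel(cm, chem, rank = "genus", top_n = 4)
  # relative abundance of gA rises with AN; gB falls
  g <- function(tx, ind) panel[panel$taxon == tx & panel$indicator == ind, ]
  expect_equal(g("gA", "AN")$rho, 1)
  expect_equal(g("gB", "AN")$rho, -1)
  expect_equal(g("gA", "EC")$rho, -1)
  # hand-rank check with an average-rank tie: gC rel abundance vs AN
  rel <- counts / rowSums(counts)
  expect_equal(g("gC", "AN")$rho, cor(rank(rel[, "o3"]), rank(1:5)))
  # constant indicator gives NA
  expect_true(all(is.na(g("gA", "pH")$rho)))
  # invariance under strictly monotone transforms
  chem2 <- chem; chem2$AN <- exp(chem2$AN)
  panel2 <- spearman_panel(cm, chem2, rank = "genus", top_n = 4)
  expect_equal(panel2$rho, panel$rho)
})

test_that("distance-vs-SQI regression recovers exact proportionality", {
  sqi <- c(s1 = 10, s2 = 20, s3 = 40, s4 = 70)
  d <- abs(outer(sqi, sqi, "-")) / 100
  rownames(d) <- colnames(d) <- names(sqi)
  # lm notes the fit is numerically perfect; that is what is asserted
  fit <- suppressWarnings(
    distance_vs_sqi_regression(as.dist(d), sqi, permutations = 99))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 1 / 100, tolerance = 1e-12)
  # constant SQI is degenerate
  fit <- distance_vs_sqi_regression(as.dist(d), setNames(rep(1, 4), names(sqi)),
                                    permutations = 9)
  expect_true(fit$degenerate)
  # the alternative distance-to-control reading runs
  fit <- suppressWarnings(
    distance_vs_sqi_regression(as.dist(d), sqi, mode = "to_control",
                               control = "s1", permutations = 99))
  expect_false(fit$degenerate)
})

test_that("chemistry-coupled communities link Bray-Curtis to SQI contrasts", {
  # in the default scenario both composition and SQI are treatment-driven,
  # so pairwise community distance should track |delta SQI|
  hits <- 0
  for (s in 1:15) {
    sc <- generate_scenario(tiny_spec(seed = 400 + s))
    ad <- lapply(sc$communities, alpha_diversity)
    sp <- run_sqi_pipeline(sc$chemistry, ad, entity_mode = "sample")
    sqi <- setNames(sp$sqi$sqi, sp$sqi$entity)
    d <- bray_curtis(sc$communities$bacteria)
    fit <- distance_vs_sqi_regression(d, sqi, permutations = 99,
                                      seed = s)
    if (fit$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 12)
})
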
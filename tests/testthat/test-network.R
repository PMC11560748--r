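cm_from_counts <- function(counts, domain = "bacteria") {
  tax <- data.frame(otu_id = colnames(counts), domain = domain,
                    phylum = "P", genus = paste0("g", seq_len(ncol(counts))))
  community_matrix(counts, tax, domain)
}

# orthonormal mean-zero basis for building vectors with exact correlations
.orthobasis <- function(n) qr.Q(qr(cbind(1, diag(n))))[, -1, drop = FALSE]

test_that("top-OTU selection ranks by mean relative abundance", {
  counts <- matrix(c(50, 30, 20,
                     50, 30, 20), 2, 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("oA", "oB", "oC")))
  cm <- cm_from_counts(counts)
  kept <- select_top_otus(list(cm), top_n = 2)
  expect_equal(colnames(kept), c("oA", "oB"))
  # top_n = total is the identity (with all columns retained)
  all3 <- select_top_otus(list(cm), top_n = 3)
  expect_equal(colnames(all3), c("oA", "oB", "oC"))
  # ties broken lexically by otu_id
  counts2 <- counts; counts2[, "oC"] <- counts2[, "oB"]
  tie <- select_top_otus(list(cm_from_counts(counts2)), top_n = 2)
  expect_equal(colnames(tie), c("oA", "oB"))
  expect_warning(select_top_otus(list(cm), top_n = 10), "keeping all")
})

test_that("edge thresholds are strict on both |r| and p", {
  b <- .orthobasis(12)
  x <- b[, 1]
  make <- function(r) r * x + sqrt(1 - r^2) * b[, 2]
  mat <- cbind(o1 = x, o2 = make(0.89), o3 = make(0.95), o4 = make(-0.95))
  rownames(mat) <- paste0("s", 1:12)
  expect_equal(cor(mat[, "o1"], mat[, "o2"]), 0.89, tolerance = 1e-12)
  net <- correlation_edges(mat, r_threshold = 0.9, p_threshold = 0.05)
  keys <- edge_key(net$edges$source, net$edges$target)
  expect_false(edge_key("o1", "o2") %in% keys)
  expect_true(edge_key("o1", "o3") %in% keys)
  expect_true(edge_key("o1", "o4") %in% keys)
  expect_equal(net$edges$sign[net$edges$r < 0], "negative")
  # identical OTUs: r = 1 exactly, p = 0, edge present
  dup <- cbind(mat, o5 = mat[, "o1"])
  net <- correlation_edges(dup)
  e <- net$edges[edge_key(net$edges$source, net$edges$target) ==
                   edge_key("o1", "o5"), ]
  expect_equal(e$r, 1)
  expect_equal(e$p, 0)
  # both thresholds are strict: at r_threshold = 1 even a perfect pair
  # (r = 1, p = 0) is excluded, at p_threshold = 0 nothing passes
  strict <- correlation_edges(dup, r_threshold = 1)
  expect_false(edge_key("o1", "o5") %in%
                 edge_key(strict$edges$source, strict$edges$target))
  expect_equal(nrow(correlation_edges(dup, p_threshold = 0)$edges), 0L)
  expect_error(correlation_edges(mat[1:2, ]), "3 samples")
  mat[, "o2"] <- 1
  expect_warning(correlation_edges(mat), "constant")
})

test_that("the edge set equals a brute-force all-pairs recomputation", {
  set.seed(55)
  n <- 12; p <- 50
  mat <- matrix(rlnorm(n * p), n, p,
                dimnames = list(paste0("s", 1:n), sprintf("o%02d", 1:p)))
  # plant a few strong pairs
  mat[, 2] <- mat[, 1] * exp(rnorm(n, 0, 0.05))
  mat[, 3] <- 1 / mat[, 1]
  net <- correlation_edges(mat, r_threshold = 0.6, p_threshold = 0.05)
  got <- sort(edge_key(net$edges$source, net$edges$target))
  want <- character()
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    ct <- cor.test(mat[, i], mat[, j])
    if (abs(ct$estimate) > 0.6 && ct$p.value < 0.05)
      want <- c(want, edge_key(colnames(mat)[i], colnames(mat)[j]))
  }
  expect_identical(got, sort(want))
})

test_that("topology metrics match hand enumeration on canonical graphs", {
  # triangle: complete graph on 3 nodes
  tri <- hand_net(data.frame(source = c("A", "B", "A"),
                             target = c("B", "C", "C"),
                             r = 0.99, p = 0, sign = "positive"))
  s <- summarize_network(tri)
  expect_equal(s$total_links, 3)
  expect_equal(s$density, 1)
  expect_equal(s$average_degree, 2)
  expect_equal(s$average_clustering_coefficient, 1)
  expect_equal(s$average_path_length, 1)
  # path A-B-C: ordered connected pairs (AB, BA, BC, CB, AC, CA)
  # have lengths 1,1,1,1,2,2 -> mean 4/3
  pathg <- hand_net(data.frame(source = c("A", "B"), target = c("B", "C"),
                               r = c(0.95, -0.95), p = 0,
                               sign = c("positive", "negative")))
  s <- summarize_network(pathg)
  expect_equal(s$total_links, 2)
  expect_equal(s$positive_links, 1)
  expect_equal(s$negative_links, 1)
  expect_equal(s$density, 2 / 3)
  expect_equal(s$average_clustering_coefficient, 0)
  expect_equal(s$average_path_length, 4 / 3)
  s10 <- summarize_network(pathg, seed = 10)
  expect_equal(s10$modularity, s$modularity)
})

test_that("star and disconnected graphs use the connected-pairs convention", {
  # star K_{1,10} built directly as a graph via a hand edge table
  star_edges <- data.frame(source = "hub", target = paste0("leaf", 1:10),
                           r = 0.99, p = 0, sign = "positive")
  g <- igraph::graph_from_data_frame(star_edges, directed = FALSE)
  net <- structure(list(edges = star_edges, nodes = NULL, graph = g,
                        params = list()), class = "occurrence_network")
  s <- summarize_network(net)
  expect_equal(s$average_degree, 20 / 11)
  expect_equal(s$average_clustering_coefficient, 0)
  # two disjoint edges: mean shortest path over connected pairs only
  e2 <- data.frame(source = c("a", "c"), target = c("b", "d"),
                   r = 0.99, p = 0, sign = "positive")
  g2 <- igraph::graph_from_data_frame(e2, directed = FALSE)
  net2 <- structure(list(edges = e2, nodes = NULL, graph = g2,
                         params = list()), class = "occurrence_network")
  s2 <- summarize_network(net2)
  expect_equal(s2$average_path_length, 1)
  # exhaustive BFS cross-check on a random sparse graph
  set.seed(8)
  g3 <- igraph::sample_gnp(20, 0.12)
  dmat <- igraph::distances(g3)
  finite <- dmat[is.finite(dmat) & dmat > 0]
  expect_equal(igraph::mean_distance(g3, unconnected = TRUE), mean(finite))
})

test_that("planted blocks are recovered from the generator ground truth", {
  blocks <- list(list(size = 8L, sign = "positive", rho = 0.99),
                 list(size = 6L, sign = "positive", rho = 0.99))
  sens <- c(); fpr <- c()
  for (s in 1:5) {
    sc <- generate_scenario(block_spec(blocks, seed = 500 + s))
    cm <- sc$communities$bacteria
    mat <- select_top_otus(list(cm), top_n = 100)
    net <- correlation_edges(mat)
    tp <- truth_pairs(cm$truth$blocks)
    got <- edge_key(net$edges$source, net$edges$target)
    sens <- c(sens, mean(tp$key %in% got))
    fpr <- c(fpr, sum(!(got %in% tp$key)) /
               (choose(ncol(mat), 2) - nrow(tp)))
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fpr), 0.05)
})

test_that("recovered edge signs match the planted loading pattern", {
  blocks <- list(list(size = 8L, sign = "positive", rho = 0.95),
                 list(size = 8L, sign = "negative", rho = 0.95))
  sc <- generate_scenario(block_spec(blocks, seed = 77))
  cm <- sc$communities$bacteria
  mat <- select_top_otus(list(cm), top_n = 100)
  # negative couplings of lognormal abundances cannot exceed |r| ~ 0.87
  # on the linear scale, so sign recovery is checked at a permissive
  # threshold where both signs are detectable
  net <- correlation_edges(mat, r_threshold = 0.6)
  tp <- truth_pairs(cm$truth$blocks)
  got <- data.frame(key = edge_key(net$edges$source, net$edges$target),
                    sign = net$edges$sign)
  hit <- merge(tp, got, by = "key", suffixes = c("_truth", "_got"))
  expect_gt(nrow(hit[hit$sign_truth == "negative", ]), 0)
  expect_gt(nrow(hit[hit$sign_truth == "positive", ]), 0)
  expect_true(all(hit$sign_truth == hit$sign_got))
})

test_that("per-treatment networks are deterministic and flag small n", {
  sc <- generate_scenario(tiny_spec(seed = 9))
  res1 <- suppressWarnings(
    per_treatment_networks(sc$communities, sc$chemistry, top_n = 40,
                           r_threshold = 0.95, seed = 3))
  res2 <- suppressWarnings(
    per_treatment_networks(sc$communities, sc$chemistry, top_n = 40,
                           r_threshold = 0.95, seed = 3))
  expect_identical(res1$summaries, res2$summaries)
  expect_equal(names(res1$networks), c("CK", "GF", "JA", "CP", "pooled"))
  # n = 3 treatments carry the instability caveat
  expect_true(any(grepl("n = 3", res1$caveats)))
  # closed-form invariants of the summary panel
  for (nm in names(res1$networks)) {
    s <- res1$summaries[[nm]]
    names(s) <- rownames(res1$summaries)
    expect_equal(s[["total_links"]],
                 s[["positive_links"]] + s[["negative_links"]])
    if (s[["total_links"]] > 0) {
      expect_equal(s[["average_degree"]],
                   2 * s[["total_links"]] / s[["node_count"]])
      expect_equal(s[["density"]],
                   2 * s[["total_links"]] /
                     (s[["node_count"]] * (s[["node_count"]] - 1)))
    }
  }
})
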
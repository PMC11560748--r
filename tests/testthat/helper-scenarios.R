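# Shared scenario builders for the test suite.

# Small, fast scenario keeping the default treatment structure.
tiny_spec <- function(seed = 1L, ...) {
  scenario_spec(n_otus_base = c(bacteria = 60L, fungi = 40L),
                library_size = 4000L,
                correlated_blocks = list(bacteria = list(), fungi = list()),
                seed = seed, ...)
}

# Uniform composition / equal richness scenario isolating planted blocks:
# no treatment-level community differences, so the only structure is the
# blocks' latent factors.
block_spec <- function(blocks, seed = 1L, n_otus = 300L) {
  uni <- matrix(1, 4, 1, dimnames = list(c("CK", "GF", "JA", "CP"), "PhylumA"))
  flat <- matrix(1, 4, 2, dimnames = list(c("CK", "GF", "JA", "CP"),
                                          c("bacteria", "fungi")))
  scenario_spec(
    richness_multiplier = flat,
    n_otus_base = c(bacteria = n_otus, fungi = 40L),
    phylum_profiles = list(bacteria = uni, fungi = uni),
    correlated_blocks = list(bacteria = blocks, fungi = list()),
    seed = seed)
}

# Wrap a hand-written edge table as an occurrence_network (for exact
# topology-metric checks on canonical graphs).
hand_net <- function(edges) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  structure(list(edges = edges, nodes = NULL, graph = g, params = list()),
            class = "occurrence_network")
}

# Undirected edge key for comparing edge sets.
edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# All within-block pairs of a generator truth table, with planted signs.
truth_pairs <- function(truth) {
  do.call(rbind, lapply(split(truth, truth$block), function(bl) {
    cmb <- utils::combn(seq_len(nrow(bl)), 2L)
    data.frame(key = edge_key(bl$otu_id[cmb[1L, ]], bl$otu_id[cmb[2L, ]]),
               sign = ifelse(bl$loading_sign[cmb[1L, ]] *
                               bl$loading_sign[cmb[2L, ]] > 0,
                             "positive", "negative"))
  }))
}
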
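#' Select top-abundance OTUs across domains
#'
#' Ranks OTUs by mean relative abundance over the selected samples and
#' keeps `top_n` per domain (ties broken lexically by otu_id, so the
#' selection is deterministic), then concatenates the domains' relative
#' abundance matrices over their shared samples.
#'
#' @param cms named list of [community_matrix()] objects.
#' @param top_n OTUs to keep per domain; if it exceeds the number of
#'   OTUs, all are kept with a warning.
#' @param samples optional subset of sample ids.
#' @return samples x OTUs relative-abundance matrix with an `otu_info`
#'   attribute (otu_id, domain, taxonomy, mean relative abundance).
#' @export
select_top_otus <- function(cms, top_n = 100, samples = NULL) {
  if (inherits(cms, "community_matrix")) cms <- list(cms)
  shared <- Reduce(intersect, lapply(cms, function(cm) rownames(cm$counts)))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  for (cm in cms)
    if (!setequal(rownames(cm$counts), rownames(cms[[1L]]$counts)))
      stop("sample mismatch between domains")
  if (!length(shared)) stop("no shared samples across domains")
  parts <- list(); info <- list()
  for (cm in cms) {
    rel <- relative_abundance(cm)[shared, , drop = FALSE]
    mu <- colMeans(rel)
    ord <- order(-mu, colnames(rel))
    keep_n <- min(top_n, ncol(rel))
    if (top_n > ncol(rel))
      warning("top_n exceeds OTU count for domain ", cm$domain,
              "; keeping all ", ncol(rel))
    keep <- ord[seq_len(keep_n)]
    parts[[cm$domain]] <- rel[, keep, drop = FALSE]
    info[[cm$domain]] <- data.frame(
      otu_id = colnames(rel)[keep], domain = cm$domain,
      phylum = cm$taxonomy$phylum[keep], genus = cm$taxonomy$genus[keep],
      mean_rel_abundance = mu[keep])
  }
  mat <- do.call(cbind, unname(parts))
  attr(mat, "otu_info") <- do.call(rbind, unname(info))
  mat
}

#' Thresholded Pearson co-occurrence network
#'
#' Pearson correlations between all OTU pairs across samples; two-tailed
#' p from `t = r sqrt(n-2) / sqrt(1-r^2)`; an edge is kept iff
#' `|r| > r_threshold` and `p < p_threshold` (both strict). Constant
#' OTUs are excluded from pairing with a warning. No multiple-testing
#' correction by default (set `fdr = TRUE` for BH-adjusted p).
#'
#' @param mat samples x OTUs abundance matrix (as from
#'   [select_top_otus()]).
#' @param r_threshold,p_threshold edge thresholds.
#' @param fdr apply Benjamini-Hochberg adjustment to the p-values
#'   before thresholding.
#' @return list of class `occurrence_network`: `edges` (data.frame
#'   `source`, `target`, `r`, `p`, `sign`), `nodes`, `graph`
#'   (igraph, all nodes incl. isolated), `params`.
#' @export
correlation_edges <- function(mat, r_threshold = 0.9, p_threshold = 0.05,
                              fdr = FALSE) {
  info <- attr(mat, "otu_info")
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 3L) stop("correlation p-value undefined: need >= 3 samples")
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant OTU(s): ",
            paste(colnames(mat)[sds == 0], collapse = ", "))
    mat <- mat[, sds > 0, drop = FALSE]
  }
  otus <- colnames(mat)
  cm <- stats::cor(mat)
  r <- cm[lower.tri(cm)]
  idx <- which(lower.tri(cm), arr.ind = TRUE)
  r_clamp <- pmin(pmax(r, -1), 1)
  tstat <- r_clamp * sqrt((n - 2) / pmax(1 - r_clamp^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r_clamp) >= 1] <- 0
  if (fdr) p <- stats::p.adjust(p, method = "BH")
  keep <- abs(r) > r_threshold & p < p_threshold
  edges <- data.frame(
    source = otus[idx[keep, 2L]], target = otus[idx[keep, 1L]],
    r = r[keep], p = p[keep],
    sign = ifelse(r[keep] > 0, "positive", "negative"))
  nodes <- if (!is.null(info)) info[info$otu_id %in% otus, , drop = FALSE]
           else data.frame(otu_id = otus)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = otus))
  structure(list(edges = edges, nodes = nodes, graph = g,
                 params = list(r_threshold = r_threshold,
                               p_threshold = p_threshold,
                               fdr = fdr, n_samples = n)),
            class = "occurrence_network")
}

#' @export
print.occurrence_network <- function(x, ...) {
  cat("occurrence_network:", igraph::vcount(x$graph), "nodes,",
      nrow(x$edges), "edges (|r| >", x$params$r_threshold, ", p <",
      x$params$p_threshold, ", n =", x$params$n_samples, "samples)\n")
  invisible(x)
}

#' Topology metric panel of a co-occurrence network
#'
#' Link counts by sign, average degree `2E/V`, density
#' `2E/(V(V-1))`, Louvain modularity of the unweighted unsigned graph
#' (seeded, hence reproducible), mean local clustering coefficient
#' (0 for nodes of degree < 2), and mean shortest-path length over
#' connected ordered pairs of the unweighted graph.
#'
#' @param net an [correlation_edges()] network.
#' @param seed seed for the Louvain partition.
#' @return one-row data.frame with `node_count`, `total_links`,
#'   `positive_links`, `negative_links`, `average_degree`, `density`,
#'   `modularity`, `average_clustering_coefficient`,
#'   `average_path_length`, `edgeless` flag.
#' @export
summarize_network <- function(net, seed = 1L) {
  g <- net$graph
  v <- igraph::vcount(g)
  if (v < 2L) stop("need >= 2 nodes")
  e <- igraph::ecount(g)
  pos <- sum(net$edges$sign == "positive")
  neg <- sum(net$edges$sign == "negative")
  if (e == 0L)
    return(data.frame(node_count = v, total_links = 0L,
                      positive_links = 0L, negative_links = 0L,
                      average_degree = 0, density = 0,
                      modularity = NA_real_,
                      average_clustering_coefficient = 0,
                      average_path_length = NA_real_, edgeless = TRUE))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  data.frame(node_count = v, total_links = e,
             positive_links = pos, negative_links = neg,
             average_degree = 2 * e / v,
             density = 2 * e / (v * (v - 1)),
             modularity = igraph::modularity(comm),
             average_clustering_coefficient = mean(cc),
             average_path_length = igraph::mean_distance(g, directed = FALSE,
                                                         unconnected = TRUE),
             edgeless = FALSE)
}

#' Per-treatment co-occurrence networks and comparison panel
#'
#' Builds one network per treatment from that treatment's samples
#' (bacteria and fungi concatenated after top-OTU filtering) plus the
#' pooled all-sample network, and assembles the topology panel in a
#' treatments-as-columns layout. With very few samples per treatment
#' the r/p threshold pair is close to vacuous (at n = 3, p < 0.05
#' requires |r| >= 0.997); such networks carry a `caveat`.
#'
#' @param cms named list of [community_matrix()] objects.
#' @param chem chemistry table with treatment labels.
#' @param top_n,r_threshold,p_threshold see [select_top_otus()] and
#'   [correlation_edges()].
#' @param pooled also build the pooled network (column `pooled`).
#' @param seed seed for Louvain partitions.
#' @return list with `networks` (per treatment), `summaries` (metric x
#'   treatment data.frame), `caveats`.
#' @export
per_treatment_networks <- function(cms, chem, top_n = 100,
                                   r_threshold = 0.9, p_threshold = 0.05,
                                   pooled = TRUE, seed = 1L) {
  treatments <- unique(chem$treatment)
  networks <- list(); summaries <- list(); caveats <- character()
  sets <- stats::setNames(lapply(treatments, function(t)
    chem$sample_id[chem$treatment == t]), treatments)
  if (pooled) sets$pooled <- chem$sample_id
  for (nm in names(sets)) {
    ids <- sets[[nm]]
    if (length(ids) < 3L)
      stop("treatment ", nm, " has fewer than 3 samples; ",
           "correlation p-values are undefined")
    if (length(ids) <= 4L) {
      r_need <- .r_crit(length(ids), p_threshold)
      caveats <- c(caveats, paste0(
        nm, ": n = ", length(ids), " samples makes p < ", p_threshold,
        " require |r| >= ", round(r_need, 3),
        "; edge counts are unstable at this size"))
    }
    mat <- select_top_otus(cms, top_n = top_n, samples = ids)
    net <- suppressWarnings(
      correlation_edges(mat, r_threshold, p_threshold))
    networks[[nm]] <- net
    summaries[[nm]] <- summarize_network(net, seed = seed)
  }
  panel <- t(do.call(rbind, summaries))
  colnames(panel) <- names(summaries)
  if (length(caveats)) for (cv in caveats) warning(cv, call. = FALSE)
  list(networks = networks, summaries = as.data.frame(panel),
       caveats = caveats)
}

# |r| needed for two-tailed p < alpha at n samples (t transform).
.r_crit <- function(n, alpha) {
  tcrit <- stats::qt(1 - alpha / 2, df = n - 2)
  sqrt(tcrit^2 / (tcrit^2 + n - 2))
}

#' Write a network as GraphML and an edge-list TSV
#'
#' @param net an [correlation_edges()] network.
#' @param graphml_path,edges_path output paths (either may be `NULL`).
#' @return invisibly, the edge data.frame.
#' @export
write_network <- function(net, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    utils::write.table(net$edges, edges_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(net$edges)
}
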
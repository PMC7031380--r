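# Spearman co-occurrence networks: correlation matrices with BH-FDR edge
# q-values, edge filtering by an RMT-derived threshold, and topology reports.

#' Pairwise Spearman correlation matrices for network construction
#'
#' Computes feature x feature Spearman rho and t-approximation p-values from
#' a profile restricted to one nutrient group, then BH-adjusts the upper
#' triangle into q-values. Features with zero variance across the group's
#' samples are dropped with a warning.
#'
#' @param profile Feature x sample matrix (samples of one nutrient group).
#' @return List (`correlation_matrices`): `features`, `rho`, `p`, `q`
#'   (all symmetric; diagonals rho = 1, p = 0, q = 0), `n_samples`.
#' @export
correlation_matrix <- function(profile) {
  m <- as.matrix(profile)
  abort_if(ncol(m) < 4, "correlation_matrix: need >= 4 samples in the group")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("correlation_matrix: dropping zero-variance feature(s): ",
            paste(rownames(m)[sds == 0], collapse = ", "), call. = FALSE)
    m <- m[sds > 0, , drop = FALSE]
  }
  nf <- nrow(m)
  abort_if(nf < 2, "correlation_matrix: fewer than 2 variable features")
  ranks <- t(apply(m, 1L, rank))
  rho <- stats::cor(t(ranks))
  n <- ncol(m)
  # two-sided p from the t-approximation, vectorized over the matrix
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(rho) <- 1
  diag(p) <- 0
  up <- upper.tri(rho)
  q <- matrix(0, nf, nf, dimnames = dimnames(rho))
  q[up] <- bh_fdr(p[up])
  q <- q + t(q)
  dimnames(p) <- dimnames(rho)
  structure(list(features = rownames(m), rho = rho, p = p, q = q,
                 n_samples = n),
            class = "correlation_matrices")
}

#' Build a co-occurrence network from filtered correlations
#'
#' An edge joins features i and j iff `|rho_ij| >= threshold` and
#' `q_ij < alpha`. Isolated nodes are retained (flagged by degree 0); signs
#' of the underlying correlations are kept on the edges.
#'
#' @param corr A `correlation_matrices` object.
#' @param threshold Absolute-correlation cutoff in \[0, 1\] (typically the
#'   RMT-derived value from [rmt_threshold()]).
#' @param alpha FDR level for edge eligibility (default 0.01).
#' @param catalog Optional `gene_catalog` used to attach category labels.
#' @param group Free-text label for the nutrient group (e.g. "plusN").
#' @return A `co_network`: list with `nodes` (feature, category, degree),
#'   `edges` (from, to, rho, q, sign), `threshold`, `alpha`, `group`.
#' @export
build_network <- function(corr, threshold, alpha = 0.01, catalog = NULL,
                          group = NA_character_) {
  abort_if(threshold < 0 || threshold > 1, "build_network: threshold outside [0, 1]")
  feats <- corr$features
  nf <- length(feats)
  idx <- upper_pairs(nf)
  keep <- abs(corr$rho[idx]) >= threshold & corr$q[idx] < alpha
  edges <- data.frame(from = feats[idx[keep, 1L]],
                      to = feats[idx[keep, 2L]],
                      rho = corr$rho[idx[keep, , drop = FALSE]],
                      q = corr$q[idx[keep, , drop = FALSE]],
                      stringsAsFactors = FALSE)
  edges$sign <- ifelse(edges$rho >= 0, "positive", "negative")
  degree <- stats::setNames(integer(nf), feats)
  if (nrow(edges) > 0) {
    tab <- table(c(edges$from, edges$to))
    degree[names(tab)] <- as.integer(tab)
  }
  category <- rep(NA_character_, nf)
  if (!is.null(catalog)) {
    mi <- match(feats, catalog$gene_symbol)
    category <- catalog$category[mi]
  }
  nodes <- data.frame(feature = feats, category = category,
                      degree = as.integer(degree), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 alpha = alpha, group = group),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat("co-occurrence network", if (!is.na(x$group)) paste0("[", x$group, "]"),
      ":", nrow(x$nodes), "nodes,", nrow(x$edges), "edges ( |rho| >=",
      format(x$threshold), ", q <", format(x$alpha), ")\n")
  invisible(x)
}

# unsigned adjacency matrix of a co_network
.adjacency <- function(net) {
  feats <- net$nodes$feature
  a <- matrix(0L, length(feats), length(feats), dimnames = list(feats, feats))
  if (nrow(net$edges) > 0) {
    i <- match(net$edges$from, feats)
    j <- match(net$edges$to, feats)
    a[cbind(i, j)] <- 1L
    a[cbind(j, i)] <- 1L
  }
  a
}

#' Topology report for a co-occurrence network
#'
#' Average degree 2E/N, graph density 2E/(N(N-1)), and average clustering
#' coefficient (mean over nodes of 2 x triangles / (k(k-1)), zero for
#' degree < 2), plus per-node degrees. Uses the unsigned skeleton.
#'
#' @param net A `co_network`.
#' @return List (`topology_report`): `average_degree`, `graph_density`,
#'   `average_clustering_coefficient`, `n_nodes`, `n_edges`, `node_degrees`.
#' @export
topology <- function(net) {
  a <- .adjacency(net)
  n <- nrow(a)
  abort_if(n == 0, "topology: empty network (no nodes)")
  deg <- rowSums(a)
  e <- sum(a) / 2
  density <- if (n > 1) 2 * e / (n * (n - 1)) else 0
  tri <- diag(a %*% a %*% a) / 2   # triangles through each node
  denom <- deg * (deg - 1)
  local_cc <- ifelse(deg >= 2, 2 * tri / denom, 0)
  structure(list(average_degree = 2 * e / n,
                 graph_density = density,
                 average_clustering_coefficient = mean(local_cc),
                 n_nodes = n, n_edges = e,
                 node_degrees = stats::setNames(as.integer(deg), rownames(a))),
            class = "topology_report")
}

#' Compare two networks' topology
#'
#' Elementwise differences (A minus B) of the three global parameters and
#' per-node degree differences over the union of node sets (absent nodes
#' count as degree 0).
#'
#' @param netA,netB `co_network` objects.
#' @return List with `delta_average_degree`, `delta_graph_density`,
#'   `delta_average_clustering_coefficient`, `node_degree_delta`.
#' @export
compare_networks <- function(netA, netB) {
  ta <- topology(netA)
  tb <- topology(netB)
  all_nodes <- union(names(ta$node_degrees), names(tb$node_degrees))
  da <- stats::setNames(rep(0L, length(all_nodes)), all_nodes)
  db <- da
  da[names(ta$node_degrees)] <- ta$node_degrees
  db[names(tb$node_degrees)] <- tb$node_degrees
  list(delta_average_degree = ta$average_degree - tb$average_degree,
       delta_graph_density = ta$graph_density - tb$graph_density,
       delta_average_clustering_coefficient =
         ta$average_clustering_coefficient - tb$average_clustering_coefficient,
       node_degree_delta = da - db)
}

#' Export a co-occurrence network to GraphML
#'
#' Cytoscape-importable GraphML with rho, q and sign edge attributes and
#' category/degree node attributes.
#'
#' @param net A `co_network`.
#' @param path Output file path.
#' @export
write_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    d = net$edges, directed = FALSE,
    vertices = net$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export network edges as TSV
#' @param net A `co_network`.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
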
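# Shared fixtures, all built in code.

# minimal valid catalog data.frame (strict checks off)
tiny_catalog_df <- function() {
  data.frame(
    gene_symbol = c("phoR", "phoD", "pstS"),
    ko_ids = c("K07636", "K01113", "K02040"),
    category = c("starvation_regulation", "solubilization_mineralization",
                 "uptake_transport"),
    product = c("sensor kinase", "alkaline phosphatase", "Pst substrate binder"),
    system_group = c("none", "none", "none"),
    stringsAsFactors = FALSE)
}

tiny_catalog <- function() as_gene_catalog(tiny_catalog_df(), strict = FALSE)

# KO table with explicit totals
tiny_ko_table <- function(counts, totals) {
  ko_count_table(counts, total_annotated = totals)
}

# two-group metadata: k samples per arm of one contrast, single site
contrast_meta <- function(k_minus, k_plus, contrast = "N", sites = "S1") {
  lv <- if (contrast == "N") c("minusN", "plusN") else c("minusP", "plusP")
  n <- k_minus + k_plus
  per_site <- split(seq_len(n), rep_len(sites, n))
  flag <- c(rep(lv[1], k_minus), rep(lv[2], k_plus))
  df <- data.frame(
    sample_id = paste0("s", seq_len(n)),
    site = rep_len(sites, n),
    treatment = flag,
    p_contrast = if (contrast == "P") flag else NA_character_,
    n_contrast = if (contrast == "N") flag else NA_character_,
    replicate = seq_len(n),
    stringsAsFactors = FALSE)
  as_sample_metadata(df)
}

# brute-force topology oracle: triple loop over all vertex triples
brute_topology <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  e <- sum(adj) / 2
  tri <- numeric(n)
  if (n >= 3) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        for (k in seq_len(n)) {
          if (i < j && j < k && adj[i, j] && adj[j, k] && adj[i, k]) {
            tri[c(i, j, k)] <- tri[c(i, j, k)] + 1
          }
        }
      }
    }
  }
  local_cc <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)
  list(average_degree = 2 * e / n,
       graph_density = if (n > 1) 2 * e / (n * (n - 1)) else 0,
       average_clustering_coefficient = mean(local_cc))
}

# wrap an adjacency (0/1 symmetric) as a co_network via a fake correlation set
network_from_adjacency <- function(adj) {
  rownames(adj) <- colnames(adj) <- paste0("g", seq_len(nrow(adj)))
  corr <- structure(list(features = rownames(adj), rho = adj, p = adj * 0,
                         q = adj * 0, n_samples = 10),
                    class = "correlation_matrices")
  build_network(corr, threshold = 1, alpha = 0.5)
}
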
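# Full-analysis orchestration: one call reads the KO table, metadata and
# catalog, and writes every stage's artifact plus a provenance manifest.

#' Configuration for a full analysis run
#'
#' @param ko_table Path to the KO count TSV.
#' @param metadata Path to the sample metadata TSV.
#' @param catalog Path to the catalog TSV (default: packaged catalog).
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed (mandatory: ordination and permutation tests are
#'   stochastic).
#' @param n_perm Permutations for ANOSIM / DistLM (default 999).
#' @param alpha Edge FDR level for networks (default 0.01).
#' @param network_threshold Fixed |rho| cutoff for network edges; `NULL`
#'   (default) asks [rmt_threshold()] for it per group.
#' @param strict_catalog Enforce the 40-gene scheme on the catalog.
#' @return A `run_config` list.
#' @export
run_config <- function(ko_table, metadata,
                       catalog = system.file("extdata", "p_gene_catalog.tsv",
                                             package = "psoilcycle"),
                       outdir = "psoilcycle_out", seed = 1, n_perm = 999,
                       alpha = 0.01, network_threshold = NULL,
                       strict_catalog = TRUE) {
  abort_if(is.null(seed), "run_config: seed is mandatory")
  abort_if(alpha <= 0 || alpha >= 1, "run_config: alpha must be in (0, 1)")
  structure(list(ko_table = ko_table, metadata = metadata, catalog = catalog,
                 outdir = outdir, seed = as.integer(seed),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 network_threshold = network_threshold,
                 strict_catalog = strict_catalog),
            class = "run_config")
}

#' Run the full P-cycling analysis
#'
#' Profiles the KO table against the catalog, then writes: the gene-level
#' profile (`profile.tsv`), per-contrast panel ANOVA tables (`anova_P.tsv`,
#' `anova_N.tsv`), shift statistics (`shifts.tsv`), ordination results with
#' ANOSIM and DistLM (`ordination.json`), one co-occurrence network per
#' nutrient group (`network_<group>.graphml` + edges TSV) with a pooled
#' topology report (`topology.json`), the default path-model fit
#' (`sem.json`), and a run manifest (`manifest.json`) from which every
#' stochastic result is reproducible. On any stage error, partial outputs
#' are removed and the error is re-raised with a stage tag.
#'
#' @param config A `run_config`.
#' @return Invisibly, the manifest list.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(path) {
    written <<- c(written, path)
    path
  }
  stage <- "validation"
  tryCatch({
    catalog <- load_catalog(config$catalog, strict = config$strict_catalog)
    tab <- read_ko_table(config$ko_table)
    meta <- read_sample_metadata(config$metadata)
    abort_if(!all(colnames(tab$counts) %in% meta$sample_id),
             "samples in KO table missing from metadata")

    stage <- "profile"
    norm <- median_normalize(tab)
    prof <- relative_abundance(norm, catalog)
    cats <- suppressWarnings(category_totals(prof, catalog))
    write_profile(prof, emit(file.path(config$outdir, "profile.tsv")))
    write_profile(cats, emit(file.path(config$outdir, "category_totals.tsv")))

    stage <- "compare"
    shifts <- do.call(rbind, lapply(c("P", "N"), function(ct) {
      data.frame(contrast = ct,
                 feature = rownames(cats),
                 shift_percent = shift_statistic(cats, meta, ct),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(shifts, emit(file.path(config$outdir, "shifts.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (ct in c("P", "N")) {
      an <- panel_anova(prof, meta, ct)
      utils::write.table(an,
                         emit(file.path(config$outdir,
                                        paste0("anova_", ct, ".tsv"))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "ordinate"
    d <- bray_curtis(prof)
    ord <- nmds(d, k = 2, seed = config$seed)
    ordination <- list(stress = ord$stress, converged = ord$converged,
                       seed = config$seed,
                       coordinates = as.data.frame(ord$points))
    for (ct in c("P", "N")) {
      col <- if (ct == "P") "p_contrast" else "n_contrast"
      keep <- meta$sample_id[!is.na(meta[[col]])]
      an <- anosim(d[keep, keep], meta[[col]][match(keep, meta$sample_id)],
                   n_perm = config$n_perm, seed = config$seed)
      ordination[[paste0("anosim_", ct)]] <- an[c("R", "p", "n_perm")]
    }
    covars <- intersect(c("pH", "np_ratio"), names(meta))
    if (length(covars) > 0) {
      dl <- distlm_marginal(d, meta[match(rownames(d), meta$sample_id),
                                    covars, drop = FALSE],
                            n_perm = config$n_perm, seed = config$seed)
      ordination$distlm <- dl
    }
    jsonlite::write_json(ordination,
                         emit(file.path(config$outdir, "ordination.json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")

    stage <- "network"
    topo <- list()
    for (grp in c("minusP", "plusP", "minusN", "plusN")) {
      col <- if (grepl("P$", grp)) "p_contrast" else "n_contrast"
      ids <- meta$sample_id[!is.na(meta[[col]]) & meta[[col]] == grp]
      sub <- prof[, ids, drop = FALSE]
      corr <- suppressWarnings(correlation_matrix(sub))
      thr <- config$network_threshold
      if (is.null(thr)) {
        thr <- tryCatch(rmt_threshold(corr$rho)$threshold, error = function(e) {
          warning("RMT threshold failed for group ", grp, " (", conditionMessage(e),
                  "); falling back to 0.8", call. = FALSE)
          0.8
        })
      }
      net <- build_network(corr, threshold = thr, alpha = config$alpha,
                           catalog = catalog, group = grp)
      write_graphml(net, emit(file.path(config$outdir,
                                        paste0("network_", grp, ".graphml"))))
      write_edge_list(net, emit(file.path(config$outdir,
                                          paste0("network_", grp, "_edges.tsv"))))
      tp <- topology(net)
      topo[[grp]] <- list(threshold = thr,
                          average_degree = tp$average_degree,
                          graph_density = tp$graph_density,
                          average_clustering_coefficient =
                            tp$average_clustering_coefficient,
                          n_nodes = tp$n_nodes, n_edges = tp$n_edges)
    }
    jsonlite::write_json(topo, emit(file.path(config$outdir, "topology.json")),
                         auto_unbox = TRUE, digits = NA)

    stage <- "sem"
    sem_data <- data.frame(
      N_input = as.numeric(!is.na(meta$n_contrast) & meta$n_contrast == "plusN"),
      P_input = as.numeric(!is.na(meta$p_contrast) & meta$p_contrast == "plusP"),
      pH = meta$pH, NP_ratio = meta$np_ratio,
      cat_regulation = cats["starvation_regulation", meta$sample_id],
      cat_solubilization = cats["solubilization_mineralization", meta$sample_id],
      cat_transport = cats["uptake_transport", meta$sample_id])
    fit <- fit_path_model(sem_data, nutrient_path_model())
    jsonlite::write_json(list(coefficients = fit$coefficients,
                              chi_square = fit$chi_square, df = fit$df,
                              chi_p = fit$chi_p, rmsea = fit$rmsea,
                              r2 = as.list(fit$r2), n = fit$n),
                         emit(file.path(config$outdir, "sem.json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")

    stage <- "manifest"
    manifest <- list(
      package = "psoilcycle",
      version = as.character(utils::packageVersion("psoilcycle")),
      inputs = list(ko_table = config$ko_table, metadata = config$metadata,
                    catalog = config$catalog),
      parameters = list(seed = config$seed, n_perm = config$n_perm,
                        alpha = config$alpha,
                        network_threshold = config$network_threshold),
      outputs = basename(written))
    jsonlite::write_json(manifest,
                         emit(file.path(config$outdir, "manifest.json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(manifest)
  }, error = function(e) {
    unlink(written)
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}
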
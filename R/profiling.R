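# From annotated KO read counts to relative-abundance profiles, system-group
# aggregates, category totals, treatment shift statistics and taxon deltas.

#' Median-normalize a KO count table
#'
#' Rescales every sample's counts by (median total annotated reads across
#' samples) / (that sample's total annotated reads), so all samples sit at a
#' common sequencing depth. Within-sample proportions are unchanged;
#' downstream relative abundances are invariant to this step, which exists
#' because taxon-level shift deltas operate on normalized absolute read
#' numbers.
#'
#' @param table A `ko_count_table` with strictly positive totals.
#' @return A `ko_count_table` with real-valued rescaled counts and totals.
#' @export
median_normalize <- function(table) {
  tot <- table$total_annotated
  abort_if(any(tot <= 0), "median_normalize: sample with zero annotated reads")
  f <- stats::median(tot) / tot
  out <- table
  out$counts <- sweep(table$counts, 2L, f, `*`)
  out$total_annotated <- tot * f
  out
}

#' Per-gene relative abundance (% of annotated reads)
#'
#' For each catalog gene, sums reads over the gene's KO IDs and divides by
#' the sample's total annotated reads, times 100. Scale-invariant per sample,
#' so raw and median-normalized tables give identical profiles. Genes with
#' no matching KO rows get 0 with a warning.
#'
#' @param table A `ko_count_table`.
#' @param catalog A `gene_catalog`.
#' @return A `profile_matrix`: numeric matrix, rows = gene symbols,
#'   columns = samples, values in percent.
#' @export
relative_abundance <- function(table, catalog) {
  abort_if(any(table$total_annotated <= 0),
           "relative_abundance: sample with zero annotated reads")
  komap <- catalog_ko_map(catalog)
  prof <- matrix(0, nrow = length(komap), ncol = ncol(table$counts),
                 dimnames = list(names(komap), colnames(table$counts)))
  missing_genes <- character(0)
  for (g in names(komap)) {
    hit <- intersect(komap[[g]], rownames(table$counts))
    if (length(hit) == 0) {
      missing_genes <- c(missing_genes, g)
      next
    }
    prof[g, ] <- colSums(table$counts[hit, , drop = FALSE])
  }
  if (length(missing_genes) > 0) {
    warning("no KO rows found for gene(s): ",
            paste(missing_genes, collapse = ", "), "; abundance set to 0",
            call. = FALSE)
  }
  prof <- sweep(prof, 2L, table$total_annotated, `/`) * 100
  class(prof) <- c("profile_matrix", class(prof))
  prof
}

#' Aggregate multi-subunit systems to their mean abundance
#'
#' Each system group (ugp transporter, phn transporter, pst transporter,
#' C-P lyase subunits) is replaced by one row holding the arithmetic mean of
#' its member genes' relative abundances; ungrouped genes pass through.
#'
#' @param profile Gene-level `profile_matrix`.
#' @param catalog A `gene_catalog`.
#' @return A `profile_matrix` with system-group rows.
#' @export
aggregate_systems <- function(profile, catalog) {
  groups <- aggregation_groups(catalog)
  for (g in names(groups)) {
    miss <- setdiff(groups[[g]], rownames(profile))
    abort_if(length(miss) > 0, "aggregate_systems: profile is missing member gene(s) ",
             paste(miss, collapse = ", "), " of group ", g)
  }
  grouped <- unlist(groups, use.names = FALSE)
  keep <- setdiff(rownames(profile), grouped)
  rows <- profile[keep, , drop = FALSE]
  agg <- do.call(rbind, lapply(groups, function(members) {
    colMeans(profile[members, , drop = FALSE])
  }))
  out <- rbind(rows, agg)
  class(out) <- c("profile_matrix", "matrix", "array")
  out
}

#' Total relative abundance per functional category
#'
#' Sums member-gene relative abundances within each of the three categories,
#' per sample. Genes absent from the profile contribute 0 with a warning.
#'
#' @param profile Gene-level `profile_matrix` (not system-aggregated).
#' @param catalog A `gene_catalog`.
#' @return Matrix, rows = the three categories, columns = samples (percent).
#' @export
category_totals <- function(profile, catalog) {
  cats <- p_gene_categories()
  out <- matrix(0, nrow = length(cats), ncol = ncol(profile),
                dimnames = list(cats, colnames(profile)))
  missing_all <- character(0)
  for (cc in cats) {
    members <- genes_in_category(catalog, cc)
    present <- intersect(members, rownames(profile))
    missing_all <- c(missing_all, setdiff(members, rownames(profile)))
    if (length(present) > 0) {
      out[cc, ] <- colSums(profile[present, , drop = FALSE])
    }
  }
  if (length(missing_all) > 0) {
    warning("category_totals: gene(s) absent from profile contribute 0: ",
            paste(missing_all, collapse = ", "), call. = FALSE)
  }
  out
}

#' Treatment shift statistic (percent change under nutrient input)
#'
#' The boxed figure statistic: 100 * (mean abundance in the +input group -
#' mean in the -input group) / (mean in the -input group). Group means pool
#' replicates across sites within the contrast by default; `by_site = TRUE`
#' returns one shift per site.
#'
#' @param values Named numeric vector (names = sample IDs) or a numeric
#'   matrix with sample columns (one shift per row).
#' @param meta A `sample_metadata` table covering the samples.
#' @param contrast `"P"` or `"N"`.
#' @param by_site Compute per-site shifts instead of the pooled shift.
#' @return Numeric shift(s) in percent.
#' @export
shift_statistic <- function(values, meta, contrast = c("P", "N"),
                            by_site = FALSE) {
  contrast <- match.arg(contrast)
  if (is.matrix(values)) {
    return(apply(values, 1L, shift_statistic, meta = meta, contrast = contrast,
                 by_site = by_site))
  }
  grp <- contrast_groups(meta, contrast)
  one_shift <- function(minus_ids, plus_ids) {
    m_minus <- mean(values[minus_ids])
    m_plus <- mean(values[plus_ids])
    abort_if(!is.finite(m_minus) || !is.finite(m_plus),
             "shift_statistic: values missing for some contrast samples")
    abort_if(m_minus == 0, "shift_statistic: -group mean is zero; shift undefined")
    100 * (m_plus - m_minus) / m_minus
  }
  if (!by_site) {
    return(one_shift(grp$minus, grp$plus))
  }
  sites <- unique(meta$site)
  out <- vapply(sites, function(s) {
    ids <- meta$sample_id[meta$site == s]
    one_shift(intersect(grp$minus, ids), intersect(grp$plus, ids))
  }, 0)
  stats::setNames(out, sites)
}

#' Taxon shift: difference of normalized read numbers under nutrient input
#'
#' Per taxon, mean normalized reads in the +input group minus the mean in the
#' -input group (the y-axis of the taxonomic-assignment comparison). Inputs
#' must already be median-normalized: this statistic is on the absolute
#' (depth-equalized) read scale, not relative abundance.
#'
#' @param normalized_reads Matrix, rows = taxa, columns = samples.
#' @param meta A `sample_metadata` table.
#' @param contrast `"P"` or `"N"`.
#' @param by_site Report per-site deltas (matrix taxa x sites) or pooled.
#' @return Numeric vector of deltas per taxon, or a matrix when `by_site`.
#' @export
taxon_shift <- function(normalized_reads, meta, contrast = c("P", "N"),
                        by_site = FALSE) {
  contrast <- match.arg(contrast)
  grp <- contrast_groups(meta, contrast)
  delta <- function(minus_ids, plus_ids) {
    abort_if(length(minus_ids) == 0 || length(plus_ids) == 0,
             "taxon_shift: empty contrast group")
    rowMeans(normalized_reads[, plus_ids, drop = FALSE]) -
      rowMeans(normalized_reads[, minus_ids, drop = FALSE])
  }
  if (!by_site) {
    return(delta(grp$minus, grp$plus))
  }
  sites <- unique(meta$site)
  out <- vapply(sites, function(s) {
    ids <- meta$sample_id[meta$site == s]
    delta(intersect(grp$minus, ids), intersect(grp$plus, ids))
  }, numeric(nrow(normalized_reads)))
  dimnames(out) <- list(rownames(normalized_reads), sites)
  out
}

#' Write a profile matrix to TSV
#' @param profile A `profile_matrix` (or any feature x sample matrix).
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(feature = rownames(profile), unclass(profile),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile matrix from TSV
#' @param path TSV written by [write_profile()].
#' @return A `profile_matrix`.
#' @export
read_profile <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  class(m) <- c("profile_matrix", class(m))
  m
}
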
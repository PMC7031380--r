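# The P-transformation gene catalog: 40 genes, three functional categories,
# four multi-subunit system groups used for figure-level aggregation.

#' Functional categories of the P-transformation catalog
#'
#' The three roles a P-cycling gene can play: regulation of the microbial
#' P-starvation response (the pho regulon), inorganic-P solubilization and
#' organic-P mineralization, and P uptake and transport (immobilization into
#' microbial biomass).
#' @export
p_gene_categories <- function() {
  c("starvation_regulation", "solubilization_mineralization", "uptake_transport")
}

# canonical multi-subunit system groups and their member genes
.system_group_members <- list(
  ugp_transporter  = c("ugpB", "ugpA", "ugpE", "ugpC"),
  phn_transporter  = c("phnC", "phnE", "phnD"),
  pst_transporter  = c("pstB", "pstC", "pstA", "pstS"),
  cp_lyase_subunit = c("phnF", "phnG", "phnH", "phnI", "phnJ", "phnK",
                       "phnL", "phnM", "phnN", "phnO", "phnP")
)

#' Load a P-gene catalog from a TSV file
#'
#' Reads a tab-separated catalog with columns `gene_symbol`, `ko_ids`
#' (comma-separated KEGG-orthology IDs), `category`, `product` and
#' `system_group`, and validates it. With `strict = TRUE` (the default for
#' the packaged catalog) the catalog must contain exactly 40 genes and the
#' four canonical system groups with their full memberships; structural
#' checks (unique symbols, known category labels, at least one KO per gene,
#' category-pure system groups) are always enforced.
#'
#' The packaged default catalog is a documented reconstruction: the gene
#' count, the three categories and all system-group memberships are fixed by
#' the published scheme, while KO assignments for a few accessory entries are
#' best-effort KEGG lookups.
#'
#' @param path Path to the catalog TSV. Defaults to the packaged catalog.
#' @param strict Enforce the full 40-gene scheme (count + group memberships).
#' @return A `gene_catalog`: a data.frame of catalog entries with class
#'   attribute and a `version` attribute.
#' @examples
#' cat40 <- load_catalog()
#' nrow(cat40)                       # 40
#' genes_in_category(cat40, "starvation_regulation")
#' @export
load_catalog <- function(path = system.file("extdata", "p_gene_catalog.tsv",
                                            package = "psoilcycle"),
                         strict = TRUE) {
  abort_if(!file.exists(path), "catalog file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  required <- c("gene_symbol", "ko_ids", "category", "product", "system_group")
  missing <- setdiff(required, names(df))
  abort_if(length(missing) > 0,
           "catalog format error: missing column(s) ",
           paste(missing, collapse = ", "))
  as_gene_catalog(df, strict = strict, version = basename(path))
}

#' Construct and validate a gene catalog from a data.frame
#'
#' @param df data.frame with the five catalog columns.
#' @param strict Enforce the 40-gene scheme.
#' @param version Free-text provenance label.
#' @return A validated `gene_catalog`.
#' @export
as_gene_catalog <- function(df, strict = TRUE, version = "user") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$system_group[is.na(df$system_group) | df$system_group == ""] <- "none"
  validate_catalog(df, strict = strict)
  class(df) <- c("gene_catalog", "data.frame")
  attr(df, "version") <- version
  df
}

validate_catalog <- function(df, strict = TRUE) {
  dup <- df$gene_symbol[duplicated(df$gene_symbol)]
  abort_if(length(dup) > 0, "catalog validation error: duplicate gene_symbol ",
           paste(unique(dup), collapse = ", "))
  bad_cat <- setdiff(unique(df$category), p_gene_categories())
  abort_if(length(bad_cat) > 0,
           "catalog validation error: unknown category label ",
           paste(bad_cat, collapse = ", "))
  n_ko <- vapply(strsplit(df$ko_ids, ","), function(k) sum(nzchar(trimws(k))), 1L)
  abort_if(any(n_ko < 1L), "catalog validation error: entry without KO ID: ",
           paste(df$gene_symbol[n_ko < 1L], collapse = ", "))
  bad_grp <- setdiff(unique(df$system_group),
                     c("none", names(.system_group_members)))
  abort_if(length(bad_grp) > 0,
           "catalog validation error: unknown system_group ",
           paste(bad_grp, collapse = ", "))
  # system groups must be category-pure
  for (g in setdiff(unique(df$system_group), "none")) {
    cats <- unique(df$category[df$system_group == g])
    abort_if(length(cats) > 1,
             "catalog validation error: system group ", g,
             " spans categories ", paste(cats, collapse = ", "))
  }
  if (strict) {
    abort_if(nrow(df) != 40L, "catalog validation error: expected 40 genes, got ",
             nrow(df))
    for (g in names(.system_group_members)) {
      members <- sort(df$gene_symbol[df$system_group == g])
      expected <- sort(.system_group_members[[g]])
      abort_if(!identical(members, expected),
               "catalog validation error: system group ", g,
               " members must be {", paste(expected, collapse = ", "), "}")
    }
  }
  invisible(df)
}

#' Write a gene catalog to TSV
#' @param catalog A `gene_catalog`.
#' @param path Output file path.
#' @export
write_catalog <- function(catalog, path) {
  cols <- c("gene_symbol", "ko_ids", "category", "product", "system_group")
  utils::write.table(as.data.frame(catalog)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene symbols belonging to one functional category
#'
#' @param catalog A `gene_catalog`.
#' @param category One of [p_gene_categories()].
#' @return Character vector of gene symbols, in catalog order.
#' @export
genes_in_category <- function(catalog, category) {
  abort_if(!(category %in% p_gene_categories()),
           "unknown category label: ", category)
  catalog$gene_symbol[catalog$category == category]
}

#' Multi-subunit system groups and their member genes
#'
#' Returns the aggregation groups present in the catalog (e.g. the pst
#' transporter system pstSCAB, or the 11 C-P lyase subunits) as a named list
#' of member gene symbols. Catalogs with no grouped genes yield an empty list.
#'
#' @param catalog A `gene_catalog`.
#' @return Named list, `system_group` -> character vector of members.
#' @export
aggregation_groups <- function(catalog) {
  groups <- setdiff(unique(catalog$system_group), "none")
  out <- lapply(groups, function(g) catalog$gene_symbol[catalog$system_group == g])
  names(out) <- groups
  out[order(names(out))]
}

#' KO IDs for each catalog gene
#' @param catalog A `gene_catalog`.
#' @return Named list, gene_symbol -> character vector of KO IDs.
#' @export
catalog_ko_map <- function(catalog) {
  out <- lapply(strsplit(catalog$ko_ids, ","), function(k) {
    k <- trimws(k)
    k[nzchar(k)]
  })
  names(out) <- catalog$gene_symbol
  out
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("P-transformation gene catalog (", nrow(x), " genes, version ",
      attr(x, "version") %||% "?", ")\n", sep = "")
  print(table(x$category))
  invisible(x)
}
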
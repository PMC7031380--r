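# KO read-count tables and sample metadata: containers plus TSV readers and
# writers. A KO table carries, besides the (possibly catalog-restricted)
# per-KO counts, each sample's total number of KEGG-annotated reads, which is
# the denominator for relative abundances.

TOTAL_ROW <- "__total_annotated__"

#' Construct a KO read-count table
#'
#' @param counts Numeric matrix, rows = KO IDs, columns = samples. Raw tables
#'   hold non-negative integers; median-normalized tables are real-valued.
#' @param total_annotated Optional named numeric vector of per-sample total
#'   annotated reads. When absent, column sums are used (with a warning),
#'   which is only correct if the table is not catalog-restricted.
#' @return A `ko_count_table` (list with `counts`, `total_annotated`).
#' @export
ko_count_table <- function(counts, total_annotated = NULL) {
  counts <- as.matrix(counts)
  abort_if(is.null(rownames(counts)), "KO table needs KO-ID row names")
  abort_if(is.null(colnames(counts)), "KO table needs sample-ID column names")
  abort_if(anyDuplicated(rownames(counts)) > 0, "duplicate KO row IDs")
  abort_if(anyDuplicated(colnames(counts)) > 0, "duplicate sample IDs")
  abort_if(any(!is.finite(counts)) || any(counts < 0),
           "counts must be finite and non-negative")
  if (is.null(total_annotated)) {
    warning("no total_annotated supplied; using column sums ",
            "(valid only for unrestricted tables)", call. = FALSE)
    total_annotated <- colSums(counts)
  }
  total_annotated <- total_annotated[colnames(counts)]
  abort_if(any(is.na(total_annotated)),
           "total_annotated missing for some samples")
  abort_if(any(total_annotated + 1e-8 < colSums(counts)),
           "total_annotated below column sum for some samples")
  structure(list(counts = counts,
                 total_annotated = stats::setNames(as.numeric(total_annotated),
                                                   colnames(counts))),
            class = "ko_count_table")
}

#' @export
print.ko_count_table <- function(x, ...) {
  cat("KO count table:", nrow(x$counts), "KOs x", ncol(x$counts), "samples\n")
  cat("total annotated reads per sample: ",
      paste(format(utils::head(x$total_annotated, 4), digits = 4), collapse = ", "),
      if (length(x$total_annotated) > 4) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a KO count table from TSV
#'
#' First column is the KO ID, remaining columns are per-sample counts. An
#' optional row `__total_annotated__` carries each sample's total annotated
#' reads; without it, column sums are used with a warning.
#'
#' @param path TSV file path.
#' @return A `ko_count_table`.
#' @export
read_ko_table <- function(path) {
  abort_if(!file.exists(path), "KO table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  abort_if(ncol(df) < 2, "KO table format error: need KO column + >=1 sample")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  abort_if(anyNA(m), "KO table format error: non-numeric or missing counts")
  abort_if(any(m < 0), "KO table error: negative count")
  rownames(m) <- ids
  tot <- NULL
  if (TOTAL_ROW %in% ids) {
    tot <- m[TOTAL_ROW, ]
    m <- m[setdiff(ids, TOTAL_ROW), , drop = FALSE]
  }
  abort_if(anyDuplicated(rownames(m)) > 0, "KO table error: duplicate KO row")
  ko_count_table(m, total_annotated = tot)
}

#' Write a KO count table to TSV (with the totals row)
#' @param table A `ko_count_table`.
#' @param path Output path.
#' @export
write_ko_table <- function(table, path) {
  m <- rbind(table$counts,
             matrix(table$total_annotated, nrow = 1,
                    dimnames = list(TOTAL_ROW, colnames(table$counts))))
  df <- data.frame(ko_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- sample metadata ----

CONTRAST_LEVELS <- list(P = c("minusP", "plusP"), N = c("minusN", "plusN"))

#' Construct and validate a sample metadata table
#'
#' Required columns: `sample_id`, `site`, `treatment`, `p_contrast`
#' (`minusP`/`plusP`/`NA`), `n_contrast` (`minusN`/`plusN`/`NA`) and
#' `replicate`. Any additional numeric columns are treated as soil
#' covariates (pH, N:P ratio, total N/P, available P, microbial biomass P,
#' P fractions, ...). Missing covariates stay missing; nothing is imputed.
#'
#' @param df data.frame of sample metadata.
#' @return A `sample_metadata` data.frame.
#' @export
as_sample_metadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("sample_id", "site", "treatment", "p_contrast", "n_contrast",
                "replicate")
  missing <- setdiff(required, names(df))
  abort_if(length(missing) > 0, "metadata format error: missing column(s) ",
           paste(missing, collapse = ", "))
  abort_if(anyDuplicated(df$sample_id) > 0, "metadata error: duplicate sample_id")
  for (cn in c("p_contrast", "n_contrast")) {
    lv <- CONTRAST_LEVELS[[if (cn == "p_contrast") "P" else "N"]]
    df[[cn]][df[[cn]] %in% c("", "NA")] <- NA
    bad <- setdiff(stats::na.omit(unique(df[[cn]])), lv)
    abort_if(length(bad) > 0, "metadata error: ", cn, " has invalid level(s) ",
             paste(bad, collapse = ", "))
  }
  covars <- setdiff(names(df), required)
  for (cn in covars) {
    if (is.numeric(df[[cn]])) {
      abort_if(any(is.infinite(df[[cn]])), "metadata error: non-finite covariate ", cn)
    }
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read sample metadata from TSV
#' @param path TSV file path.
#' @return A `sample_metadata` data.frame.
#' @export
read_sample_metadata <- function(path) {
  abort_if(!file.exists(path), "metadata file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  as_sample_metadata(df)
}

#' Write sample metadata to TSV
#' @param meta A `sample_metadata` data.frame.
#' @param path Output path.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Split sample IDs into the two arms of a nutrient contrast.
contrast_groups <- function(meta, contrast = c("P", "N")) {
  contrast <- match.arg(contrast)
  col <- if (contrast == "P") "p_contrast" else "n_contrast"
  lv <- CONTRAST_LEVELS[[contrast]]
  minus <- meta$sample_id[!is.na(meta[[col]]) & meta[[col]] == lv[1L]]
  plus <- meta$sample_id[!is.na(meta[[col]]) & meta[[col]] == lv[2L]]
  abort_if(length(minus) == 0 || length(plus) == 0,
           "contrast ", contrast, ": both groups must be non-empty")
  list(minus = minus, plus = plus)
}
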
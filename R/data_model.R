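# Input tables: reading/validation, relative-abundance normalisation, and the
# prevalence filter that splits genes into core / non-core / excluded.

#' Read a gene abundance table
#'
#' TSV with a header row of sample ids and the gene id in the first column.
#' Values must be non-negative with no missing cells; gene and sample ids
#' must be unique.
#'
#' @param path TSV file path.
#' @return genes x samples numeric matrix.
#' @export
read_abundance <- function(path) {
  m <- read_tsv_matrix(path)
  validate_abundance(m)
  m
}

#' @rdname read_abundance
#' @param m abundance matrix to validate.
#' @export
validate_abundance <- function(m) {
  if (anyDuplicated(rownames(m)))
    stopf("duplicate gene id(s): %s",
          paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stopf("duplicate sample id(s): %s",
          paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stopf("missing value at gene '%s', sample '%s'",
          rownames(m)[idx[1]], colnames(m)[idx[2]])
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stopf("negative abundance at gene '%s', sample '%s'",
          rownames(m)[idx[1]], colnames(m)[idx[2]])
  }
  invisible(m)
}

#' Read a gene metadata table
#'
#' TSV with columns `gene`, `category`, `is_duf`. DUF rows may carry an empty
#' category.
#'
#' @param path TSV file path.
#' @return data.frame with columns gene, category, is_duf.
#' @export
read_gene_metadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = c(gene = "character", category = "character"))
  need <- c("gene", "category", "is_duf")
  if (!all(need %in% names(df)))
    stopf("metadata must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$gene))
    stopf("duplicate gene id(s) in metadata: %s",
          paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  df$is_duf <- as.logical(df$is_duf)
  df$category[is.na(df$category)] <- ""
  df
}

#' Read an environmental factor table
#'
#' @param path TSV file path (factors as rows, samples as columns).
#' @param abundance optional abundance matrix whose sample ids the table must
#'   match.
#' @return factors x samples numeric matrix.
#' @export
read_env_table <- function(path, abundance = NULL) {
  m <- read_tsv_matrix(path)
  if (!is.null(abundance) && !identical(colnames(m), colnames(abundance)))
    stopf("environment sample ids do not match the abundance table")
  m
}

#' Normalise each sample to relative abundance
#'
#' Divides every sample column by its total so columns sum to 1; zeros are
#' preserved. Idempotent, and rank order within every sample is unchanged.
#'
#' @param m genes x samples non-negative matrix.
#' @return matrix of the same shape with unit column sums.
#' @export
relative_abundance <- function(m) {
  cs <- colSums(m)
  if (any(cs == 0))
    stopf("all-zero sample column(s): %s",
          paste(colnames(m)[cs == 0], collapse = ", "))
  sweep(m, 2, cs, "/")
}

#' Classify genes by prevalence
#'
#' Presence is the number of samples where a gene's abundance exceeds
#' `min_abundance` (default 0: any detection counts). A gene present in all
#' samples is `core`; present in at least `min_prevalence` but not all
#' samples, `noncore`; otherwise `excluded`. Excluded genes are dropped from
#' all downstream network stages.
#'
#' @param m genes x samples abundance matrix.
#' @param min_prevalence minimum presence count to enter the network.
#' @param min_abundance detection floor (strictly-greater-than).
#' @return data.frame with columns gene, presence, class.
#' @export
classify_prevalence <- function(m, min_prevalence = 25L, min_abundance = 0) {
  n <- ncol(m)
  if (min_prevalence > n)
    stopf("min_prevalence (%d) exceeds the number of samples (%d)",
          min_prevalence, n)
  presence <- rowSums(m > min_abundance)
  class <- ifelse(presence == n, "core",
           ifelse(presence >= min_prevalence, "noncore", "excluded"))
  data.frame(gene = rownames(m), presence = as.integer(presence),
             class = class, stringsAsFactors = FALSE)
}

#' Drop genes below the prevalence filter
#'
#' @param m abundance matrix.
#' @param prevalence result of [classify_prevalence()].
#' @return matrix restricted to core and non-core genes.
#' @export
filter_prevalence <- function(m, prevalence) {
  keep <- prevalence$gene[prevalence$class != "excluded"]
  m[rownames(m) %in% keep, , drop = FALSE]
}
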
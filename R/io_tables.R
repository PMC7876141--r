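# Tabular readers: genes x tumors matrices, gene/interval annotation,
# tumor metadata, fusion candidates, MAF-like mutation tables.

#' Read a genes x tumors matrix from TSV
#'
#' @param path TSV with gene identifiers in the first column and one column
#'   per tumor (header row).
#' @param kind One of `"expression"` (numeric, missing values tolerated but
#'   flagged), `"cna"` (thresholded integer calls in -2..2) or `"mutation"`
#'   (binary 0/1).
#' @return Numeric matrix with gene rownames and tumor colnames. For
#'   expression matrices containing missing cells, the affected genes are
#'   recorded in `attr(, "incomplete_genes")`.
#' @export
read_matrix <- function(path, kind = c("expression", "cna", "mutation")) {
  kind <- match.arg(kind)
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  genes <- as.character(d[[1]])
  dup <- genes[duplicated(genes)]
  .assert(length(dup) == 0L, "duplicate gene row(s): %s",
          paste(unique(dup), collapse = ", "))
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes

  if (kind == "cna") {
    bad <- which(!(m %in% c(-2, -1, 0, 1, 2)) | is.na(m))
    if (length(bad)) {
      i <- arrayInd(bad[1], dim(m))
      stop(sprintf("invalid CNA value %s for gene %s, tumor %s",
                   m[bad[1]], rownames(m)[i[1]], colnames(m)[i[2]]),
           call. = FALSE)
    }
  } else if (kind == "mutation") {
    .assert(all(m %in% c(0, 1)), "mutation matrix must be binary 0/1")
  } else if (anyNA(m)) {
    incomplete <- rownames(m)[rowSums(is.na(m)) > 0]
    warning(sprintf("%d gene(s) with missing expression values flagged",
                    length(incomplete)), call. = FALSE)
    attr(m, "incomplete_genes") <- incomplete
  }
  m
}

#' Quantile normalize an expression matrix
#'
#' Forces every tumor column onto a common distribution: the across-column
#' mean of order statistics. Ties within a column receive the average of the
#' target values over the tied ranks. Rows containing missing values are
#' left untouched (and excluded from the reference distribution).
#'
#' @param mat Numeric genes x tumors matrix.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  .assert(is.matrix(mat) && is.numeric(mat), "mat must be a numeric matrix")
  if (ncol(mat) < 2L) {
    warning("single-column matrix returned unchanged", call. = FALSE)
    return(mat)
  }
  complete <- rowSums(is.na(mat)) == 0
  out <- mat
  out[complete, ] <- limma::normalizeQuantiles(mat[complete, , drop = FALSE],
                                               ties = TRUE)
  out
}

#' Read gene annotation from a BED-derived table
#'
#' Expects BED6 (chrom, start, end, name, score, strand); coordinates are
#' kept 0-based half-open. The strand-aware transcription start (`tss`) is
#' the leftmost base for `+` genes and the rightmost for `-` genes.
#'
#' @param path BED6 file path.
#' @param drop_noncanonical Drop genes on non-canonical chromosomes.
#' @return `data.frame` with `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`.
#' @export
read_gene_bed <- function(path, drop_noncanonical = TRUE) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  .assert(ncol(d) >= 6L, "gene BED must have at least 6 columns")
  g <- data.frame(gene_id = as.character(d[[4]]), chrom = as.character(d[[1]]),
                  start = as.integer(d[[2]]), end = as.integer(d[[3]]),
                  strand = as.character(d[[6]]), stringsAsFactors = FALSE)
  if (drop_noncanonical) {
    keep <- .is_canonical(g$chrom)
    if (any(!keep)) {
      message(sprintf("dropped %d gene(s) on non-canonical chromosomes",
                      sum(!keep)))
      g <- g[keep, , drop = FALSE]
    }
  }
  .check_genes(g)
}

#' Read an interval set (TADs, enhancers) from BED3
#'
#' @param path BED3 file path (0-based half-open intervals).
#' @param name Label for the set.
#' @return `data.frame` with `chrom`, `start`, `end`, sorted by chromosome
#'   and start, carrying the label in `attr(, "name")`.
#' @export
read_intervals <- function(path, name = basename(path)) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  .assert(ncol(d) >= 3L, "BED must have at least 3 columns")
  iv <- data.frame(chrom = as.character(d[[1]]), start = as.integer(d[[2]]),
                   end = as.integer(d[[3]]), stringsAsFactors = FALSE)
  .assert(all(iv$start < iv$end), "interval start must be < end")
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  rownames(iv) <- NULL
  attr(iv, "name") <- name
  iv
}

#' Read tumor metadata
#'
#' @param path TSV with columns `tumor_id`, `patient_id`, `tumor_type`,
#'   `status` (one of initial, progressive, recurrent, second_malignancy).
#' @return Validated `data.frame`.
#' @export
read_tumor_meta <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("tumor_id", "patient_id", "tumor_type", "status")
  .assert(all(need %in% names(d)), "metadata is missing columns: %s",
          paste(setdiff(need, names(d)), collapse = ", "))
  .assert(!anyDuplicated(d$tumor_id), "duplicate tumor_id in metadata")
  ok <- c("initial", "progressive", "recurrent", "second_malignancy")
  .assert(all(d$status %in% ok), "invalid tumor status value(s)")
  d
}

#' Read fusion candidate calls
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `tumor_id`, `caller`.
#' @return `data.frame` of fusion candidates.
#' @export
read_fusion_calls <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "tumor_id", "caller")
  .assert(all(need %in% names(d)), "fusion table is missing columns: %s",
          paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' Read a MAF-like somatic mutation table
#'
#' @param path TSV with columns `gene`, `tumor_id`, `consequence` (e.g.
#'   missense, nonsense, nonstop, frameshift_indel, inframe_indel, promoter)
#'   and logical `hotspot`.
#' @return `data.frame` of mutation records.
#' @export
read_mutation_table <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene", "tumor_id", "consequence", "hotspot")
  .assert(all(need %in% names(d)), "mutation table is missing columns: %s",
          paste(setdiff(need, names(d)), collapse = ", "))
  d$hotspot <- as.logical(d$hotspot)
  d
}

#' Write a genes x tumors matrix as TSV
#'
#' @param mat Matrix with gene rownames and tumor colnames.
#' @param path Output path.
#' @param id_col Name of the leading identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "gene_id") {
  d <- data.frame(rownames(mat), mat, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- id_col
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
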
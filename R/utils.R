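# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' @noRd
.canonical_chroms <- function(prefix = TRUE) {
  base <- c(1:22, "X", "Y")
  if (prefix) paste0("chr", base) else as.character(base)
}

# Both "chr1" and "1" styles accepted.
.is_canonical <- function(chrom) {
  chrom %in% c(.canonical_chroms(TRUE), .canonical_chroms(FALSE))
}

.svclasses <- c("deletion", "duplication", "insertion", "inversion",
                "translocation")

.check_ssv_df <- function(ssvs) {
  need <- c("ssv_id", "svclass", "chrom1", "pos1", "orient1",
            "chrom2", "pos2", "orient2", "tumor_id", "pass_filter")
  .assert(all(need %in% names(ssvs)),
          "SSV table is missing columns: %s",
          paste(setdiff(need, names(ssvs)), collapse = ", "))
  .assert(all(ssvs$pos1 >= 0) && all(ssvs$pos2 >= 0),
          "SSV positions must be non-negative (0-based)")
  .assert(all(ssvs$svclass %in% .svclasses), "unknown svclass value")
  tra <- ssvs$svclass == "translocation"
  .assert(all((ssvs$chrom1 != ssvs$chrom2) == tra),
          "svclass must be 'translocation' exactly when chrom1 != chrom2")
  invisible(ssvs)
}

# Long-format breakend table: one row per breakend (two per SSV).
.breakends <- function(ssvs) {
  data.frame(
    ssv_id   = rep(ssvs$ssv_id, 2L),
    tumor_id = rep(ssvs$tumor_id, 2L),
    chrom    = c(ssvs$chrom1, ssvs$chrom2),
    pos      = c(ssvs$pos1, ssvs$pos2),
    orient   = c(ssvs$orient1, ssvs$orient2),
    stringsAsFactors = FALSE
  )
}

# 2x2 chi-squared (no continuity correction, matching the classical test on
# large tables); falls back to Fisher when any expected count is < 5.
.chisq_2x2 <- function(tab, warn_fallback = TRUE) {
  stopifnot(all(dim(tab) == c(2L, 2L)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    if (warn_fallback) {
      warning("expected cell count < 5; using Fisher's exact test",
              call. = FALSE)
    }
    ft <- stats::fisher.test(tab)
    return(list(statistic = NA_real_, p_value = ft$p.value,
                method = "fisher"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       method = "chisq")
}

# One-sided hypergeometric upper-tail probability of seeing >= x successes.
.hyper_upper <- function(x, m, n, k) {
  stats::phyper(x - 1L, m, n, k, lower.tail = FALSE)
}

# TSS under the strand-aware convention: leftmost base for '+', rightmost
# (end - 1, 0-based) for '-'.
.gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

.check_genes <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  .assert(all(need %in% names(genes)), "gene table is missing columns: %s",
          paste(setdiff(need, names(genes)), collapse = ", "))
  .assert(!anyDuplicated(genes$gene_id), "duplicate gene_id in annotation")
  .assert(all(genes$start < genes$end), "gene start must be < end")
  .assert(all(genes$strand %in% c("+", "-")), "gene strand must be + or -")
  if (is.null(genes$tss)) genes$tss <- .gene_tss(genes)
  genes
}
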
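# Gene x tumor breakpoint predictors. Both breakends of every SSV are
# treated as independent breakpoints. Windows are 0-based half-open and
# resolved strand-aware relative to the gene's transcription start (TSS).

#' Specify a genomic region window relative to genes
#'
#' @param region One of `"gene_body"`, `"upstream"`, `"downstream"`,
#'   `"symmetric"`. Upstream/downstream are strand-aware: upstream of a `-`
#'   strand gene extends to higher coordinates.
#' @param extent Window size in bp (ignored for `gene_body`); the symmetric
#'   window covers `tss - extent .. tss + extent`.
#' @param strand_aware Resolve upstream/downstream by gene strand
#'   (default TRUE).
#' @return A `window_spec` list.
#' @export
window_spec <- function(region = c("gene_body", "upstream", "downstream",
                                   "symmetric"),
                        extent = 100000L, strand_aware = TRUE) {
  region <- match.arg(region)
  if (region != "gene_body") {
    .assert(is.numeric(extent) && length(extent) == 1L && extent > 0,
            "window extent must be a single positive number")
  }
  structure(list(region = region, extent = as.integer(extent),
                 strand_aware = strand_aware),
            class = "window_spec")
}

# Per-gene window intervals (0-based half-open) for a window_spec.
.gene_windows <- function(genes, window) {
  tss <- genes$tss
  plus <- if (window$strand_aware) genes$strand == "+" else rep(TRUE, nrow(genes))
  e <- window$extent
  switch(window$region,
    gene_body = data.frame(start = genes$start, end = genes$end),
    upstream = data.frame(
      start = ifelse(plus, genes$start - e, genes$end),
      end   = ifelse(plus, genes$start, genes$end + e)),
    downstream = data.frame(
      start = ifelse(plus, genes$end, genes$start - e),
      end   = ifelse(plus, genes$end + e, genes$start)),
    symmetric = data.frame(start = tss - e, end = tss + e + 1L)
  )
}

#' Build a binary breakpoint-presence matrix
#'
#' Entry (gene, tumor) is 1 iff at least one breakend of any SSV from that
#' tumor falls inside the gene's window; both breakends of every SSV count.
#'
#' @param ssvs SSV table (mate-merged; see [read_sv_vcf()]).
#' @param genes Gene annotation (see [read_gene_bed()]).
#' @param window A [window_spec()].
#' @param tumors Character vector fixing the tumor columns (defaults to the
#'   tumors observed in `ssvs`).
#' @return Object of class `breakpoint_presence`: list with `values`
#'   (binary genes x tumors matrix) and `window`.
#' @export
build_presence_matrix <- function(ssvs, genes, window, tumors = NULL) {
  genes <- .check_genes(genes)
  .check_ssv_df(ssvs)
  .assert(inherits(window, "window_spec"), "window must be a window_spec")
  tumors <- tumors %||% sort(unique(ssvs$tumor_id))
  w <- .gene_windows(genes, window)
  values <- matrix(0L, nrow(genes), length(tumors),
                   dimnames = list(genes$gene_id, tumors))
  be <- .breakends(ssvs)
  be <- be[be$tumor_id %in% tumors, , drop = FALSE]
  if (nrow(be) > 0L && nrow(genes) > 0L) {
    wgr <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(start = w$start + 1L, end = w$end))
    bgr <- GenomicRanges::GRanges(
      be$chrom, IRanges::IRanges(start = be$pos + 1L, width = 1L))
    hits <- GenomicRanges::findOverlaps(wgr, bgr)
    if (length(hits) > 0L) {
      gi <- S4Vectors::queryHits(hits)
      ti <- match(be$tumor_id[S4Vectors::subjectHits(hits)], tumors)
      values[cbind(gi, ti)] <- 1L
    }
  }
  structure(list(values = values, window = window),
            class = "breakpoint_presence")
}

#' Build the log2 relative-distance matrix
#'
#' For each gene and tumor, the distance from the TSS to the nearest SSV
#' breakend within `max_dist`; tumors with no breakend in range are imputed
#' at `max_dist`. Values are log2 of the absolute distance, clipped below at
#' 1 bp (a breakend exactly at the TSS scores 0).
#'
#' @inheritParams build_presence_matrix
#' @param max_dist Search radius / imputation distance in bp (default 1 Mb).
#' @return Object of class `breakpoint_distance`: list with `values`
#'   (genes x tumors log2 distances), `imputed` (logical matrix) and
#'   `max_dist`.
#' @export
build_distance_matrix <- function(ssvs, genes, max_dist = 1e6, tumors = NULL) {
  genes <- .check_genes(genes)
  .check_ssv_df(ssvs)
  .assert(max_dist > 0, "max_dist must be positive")
  tumors <- tumors %||% sort(unique(ssvs$tumor_id))
  dist <- matrix(max_dist, nrow(genes), length(tumors),
                 dimnames = list(genes$gene_id, tumors))
  be <- .breakends(ssvs)
  be <- be[be$tumor_id %in% tumors, , drop = FALSE]
  if (nrow(be) > 0L && nrow(genes) > 0L) {
    for (ch in unique(genes$chrom)) {
      gi <- which(genes$chrom == ch)
      bch <- be[be$chrom == ch, , drop = FALSE]
      if (nrow(bch) == 0L) next
      for (tu in unique(bch$tumor_id)) {
        p <- sort(bch$pos[bch$tumor_id == tu])
        tss <- genes$tss[gi]
        idx <- findInterval(tss, p)
        left <- ifelse(idx >= 1L, tss - p[pmax(idx, 1L)], Inf)
        right <- ifelse(idx < length(p), p[pmin(idx + 1L, length(p))] - tss,
                        Inf)
        dist[gi, tu] <- pmin(left, right, max_dist)
      }
    }
  }
  imputed <- dist >= max_dist
  dist[imputed] <- max_dist
  structure(list(values = log2(pmax(dist, 1)), imputed = imputed,
                 max_dist = max_dist),
            class = "breakpoint_distance")
}

#' Count the SSV burden per tumor
#'
#' One count per mate-merged SSV record, so a translocation's two breakend
#' entries contribute a single event.
#'
#' @inheritParams build_presence_matrix
#' @param tumors Tumors to report (defaults to those observed); tumors with
#'   no SSVs are reported as 0.
#' @return Named integer vector of per-tumor SSV counts.
#' @export
count_ssv_burden <- function(ssvs, tumors = NULL) {
  .check_ssv_df(ssvs)
  tumors <- tumors %||% sort(unique(ssvs$tumor_id))
  counts <- table(factor(ssvs$tumor_id, levels = tumors))
  setNames(as.integer(counts), tumors)
}
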
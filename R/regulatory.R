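# Regulatory annotation of SSVs: TAD disruption and candidate enhancer
# translocation, plus the enrichment tests tying these annotations to
# expression-altered genes and to copy-number change.

# index of the containing interval (0-based half-open) or NA
.containing_interval <- function(chrom, pos, iv) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sub <- which(iv$chrom == ch)
    if (length(sub) == 0L) next
    i <- which(chrom == ch)
    idx <- findInterval(pos[i], iv$start[sub])
    hit <- idx >= 1L & pos[i] < iv$end[sub][pmax(idx, 1L)]
    out[i][hit] <- sub[idx[hit]]
  }
  out
}

.validate_tads <- function(tads) {
  tads <- tads[order(tads$chrom, tads$start), , drop = FALSE]
  by_chrom <- split(tads, tads$chrom)
  for (d in by_chrom) {
    if (nrow(d) > 1L) {
      .assert(all(d$start[-1] >= d$end[-nrow(d)]),
              "TAD intervals overlap within chromosome %s", d$chrom[1])
    }
  }
  tads
}

#' Classify SSVs by TAD disruption
#'
#' An SSV is `preserving` when both breakends fall inside the same TAD,
#' `disrupting` when they fall in different TADs (inter-chromosomal
#' translocations always disrupt), and `unresolved` when either breakend
#' lies outside the TAD annotation.
#'
#' @param ssvs SSV table (mate-merged).
#' @param tads TAD intervals (see [read_intervals()]); must be
#'   non-overlapping within each chromosome.
#' @return `data.frame` with `ssv_id` and `class`.
#' @export
classify_tad <- function(ssvs, tads) {
  .check_ssv_df(ssvs)
  tads <- .validate_tads(tads)
  i1 <- .containing_interval(ssvs$chrom1, ssvs$pos1, tads)
  i2 <- .containing_interval(ssvs$chrom2, ssvs$pos2, tads)
  cls <- ifelse(is.na(i1) | is.na(i2), "unresolved",
          ifelse(i1 == i2, "preserving", "disrupting"))
  # inter-chromosomal SSVs cannot share a TAD; the interval index already
  # guarantees this, stated here as a hard invariant
  stopifnot(!any(cls == "preserving" & ssvs$chrom1 != ssvs$chrom2))
  data.frame(ssv_id = ssvs$ssv_id, class = cls, stringsAsFactors = FALSE)
}

#' TAD-disruption enrichment among expression-altered SSVs
#'
#' 2x2 chi-squared test comparing the fraction of TAD-disrupting SSVs among
#' SSVs linked to altered gene expression versus the remaining SSVs;
#' `unresolved` SSVs are excluded. Falls back to Fisher's exact test with a
#' warning when an expected cell is below 5.
#'
#' @param tad_classes Output of [classify_tad()].
#' @param altered_ssv_ids SSV ids linked to altered expression (subset of
#'   the classified ids).
#' @return List with `statistic`, `p_value`, `method` and the 2x2 `table`.
#' @export
tad_enrichment <- function(tad_classes, altered_ssv_ids) {
  .assert(length(altered_ssv_ids) > 0, "altered SSV set is empty")
  .assert(all(altered_ssv_ids %in% tad_classes$ssv_id),
          "altered ids must be classified SSVs")
  d <- tad_classes[tad_classes$class != "unresolved", , drop = FALSE]
  altered <- d$ssv_id %in% altered_ssv_ids
  disrupting <- d$class == "disrupting"
  tab <- table(factor(altered, c(TRUE, FALSE)),
               factor(disrupting, c(TRUE, FALSE)))
  dimnames(tab) <- list(altered = c("yes", "no"),
                        disrupting = c("yes", "no"))
  res <- .chisq_2x2(tab)
  c(res, list(table = tab))
}

#' Detect a candidate enhancer translocation for one SSV and gene
#'
#' Tests whether an SSV breakend sitting up to `upstream_window` bp upstream
#' of a gene's TSS could replace the gene's native upstream neighborhood
#' with a fragment carrying an enhancer. The proximal breakend must retain
#' the gene-containing side of the junction: for a `+` strand gene the
#' downstream sequence of the breakpoint (negative orientation), for a `-`
#' strand gene the upstream sequence (positive orientation). The mate
#' breakend's retained side is then searched for the nearest enhancer
#' (interval midpoint) within `max_fused` bp. A call is emitted only when
#' the unaltered gene has no enhancer within `native_window` of the TSS, or
#' its nearest native enhancer is farther from the gene than the
#' translocated enhancer would be along the derivative chromosome
#' (TSS-to-breakend plus breakend-to-enhancer distance).
#'
#' @param ssv One-row SSV table.
#' @param gene One-row gene annotation.
#' @param enhancers Enhancer intervals (see [read_intervals()]).
#' @param max_fused Search radius on the fused side (default 500 kb).
#' @param native_window Native-enhancer search radius around the TSS
#'   (default 1 Mb).
#' @param upstream_window Size of the upstream region in which the proximal
#'   breakend must fall (default 500 kb).
#' @return One-row `data.frame`
#'   (`ssv_id`, `gene_id`, `tumor_id`, `enh_chrom`, `enh_start`, `enh_end`,
#'   `distance_to_breakend`, `native_enhancer_distance`) or NULL when no
#'   call is made.
#' @export
detect_enhancer_translocation <- function(ssv, gene, enhancers,
                                          max_fused = 5e5,
                                          native_window = 1e6,
                                          upstream_window = 5e5) {
  .assert(nrow(ssv) == 1L && nrow(gene) == 1L,
          "ssv and gene must be single rows")
  .assert(gene$strand %in% c("+", "-"), "gene without a valid strand")
  tss <- if (!is.null(gene$tss)) gene$tss else .gene_tss(gene)

  ends <- data.frame(chrom = c(ssv$chrom1, ssv$chrom2),
                     pos = c(ssv$pos1, ssv$pos2),
                     orient = c(ssv$orient1, ssv$orient2),
                     stringsAsFactors = FALSE)
  upstream_of <- function(pos) {
    if (gene$strand == "+") pos < tss & pos >= tss - upstream_window
    else pos > tss & pos <= tss + upstream_window
  }
  cand <- which(ends$chrom == gene$chrom & upstream_of(ends$pos))
  if (length(cand) == 0L) return(NULL)
  prox_i <- cand[which.min(abs(ends$pos[cand] - tss))]
  prox <- ends[prox_i, ]
  mate <- ends[3L - prox_i, ]

  required <- if (gene$strand == "+") "negative" else "positive"
  if (prox$orient != required) return(NULL)

  # nearest enhancer midpoint on the mate's retained side
  mid <- (enhancers$start + enhancers$end) / 2
  on_chrom <- enhancers$chrom == mate$chrom
  fused_side <- if (mate$orient == "positive") mid <= mate$pos else
    mid >= mate$pos
  hit <- which(on_chrom & fused_side & abs(mid - mate$pos) <= max_fused)
  if (length(hit) == 0L) return(NULL)
  j <- hit[which.min(abs(mid[hit] - mate$pos))]
  d_fused <- abs(mid[j] - mate$pos)
  d_derivative <- abs(tss - prox$pos) + d_fused

  native <- which(enhancers$chrom == gene$chrom &
                    abs(mid - tss) <= native_window)
  d_native <- if (length(native)) min(abs(mid[native] - tss)) else NA_real_
  if (!is.na(d_native) && d_native <= d_derivative) return(NULL)

  data.frame(ssv_id = ssv$ssv_id, gene_id = gene$gene_id,
             tumor_id = ssv$tumor_id,
             enh_chrom = enhancers$chrom[j], enh_start = enhancers$start[j],
             enh_end = enhancers$end[j],
             distance_to_breakend = d_fused,
             native_enhancer_distance = d_native,
             stringsAsFactors = FALSE)
}

#' Scan a cohort for candidate enhancer translocations
#'
#' Applies [detect_enhancer_translocation()] to every SSV whose breakend
#' lies in a gene's upstream window, keeping per (gene, tumor) only the SSV
#' whose proximal breakend is closest to the TSS, and deduplicating multiple
#' calls to the closest translocated enhancer.
#'
#' @param ssvs SSV table.
#' @param genes Gene annotation.
#' @inheritParams detect_enhancer_translocation
#' @return `data.frame` of calls (possibly empty).
#' @export
enhancer_translocations <- function(ssvs, genes, enhancers, max_fused = 5e5,
                                    native_window = 1e6,
                                    upstream_window = 5e5) {
  genes <- .check_genes(genes)
  .check_ssv_df(ssvs)
  calls <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    lo <- if (g$strand == "+") g$tss - upstream_window else g$tss + 1
    hi <- if (g$strand == "+") g$tss - 1 else g$tss + upstream_window
    near <- (ssvs$chrom1 == g$chrom & ssvs$pos1 >= lo & ssvs$pos1 <= hi) |
            (ssvs$chrom2 == g$chrom & ssvs$pos2 >= lo & ssvs$pos2 <= hi)
    if (!any(near)) next
    sub <- ssvs[near, , drop = FALSE]
    for (tu in unique(sub$tumor_id)) {
      st <- sub[sub$tumor_id == tu, , drop = FALSE]
      # only the breakend closest to the TSS is considered per tumor
      dmin <- pmin(ifelse(st$chrom1 == g$chrom, abs(st$pos1 - g$tss), Inf),
                   ifelse(st$chrom2 == g$chrom, abs(st$pos2 - g$tss), Inf))
      st <- st[which.min(dmin), , drop = FALSE]
      call <- detect_enhancer_translocation(st, g, enhancers, max_fused,
                                            native_window, upstream_window)
      if (!is.null(call)) calls[[length(calls) + 1L]] <- call
    }
  }
  if (length(calls) == 0L) {
    return(data.frame(ssv_id = character(), gene_id = character(),
                      tumor_id = character(), enh_chrom = character(),
                      enh_start = integer(), enh_end = integer(),
                      distance_to_breakend = numeric(),
                      native_enhancer_distance = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  key <- paste(out$gene_id, out$tumor_id)
  out <- out[order(key, out$distance_to_breakend), , drop = FALSE]
  out <- out[!duplicated(paste(out$gene_id, out$tumor_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment of breakpoint proximity among copy-number-altered gene/tumor
#' pairs
#'
#' Over all gene x tumor pairs, a 2x2 chi-squared test of (breakpoint
#' within the window) against (thresholded CNA at the stated level:
#' amplification +2 or deep deletion -2).
#'
#' @param presence A `breakpoint_presence` object (typically a symmetric
#'   1 Mb window).
#' @param cna Thresholded CNA matrix aligned on the same genes and tumors.
#' @param level `"amplification"` (+2) or `"deep_deletion"` (-2).
#' @return List with `statistic`, `p_value`, `method`, the 2x2 `table` and
#'   `n_cooccurring` (pairs with both breakpoint and CNA at level).
#' @export
cna_ssv_enrichment <- function(presence, cna,
                               level = c("amplification", "deep_deletion")) {
  level <- match.arg(level)
  stopifnot(inherits(presence, "breakpoint_presence"))
  genes <- intersect(rownames(presence$values), rownames(cna))
  tumors <- intersect(colnames(presence$values), colnames(cna))
  .assert(length(genes) > 0 && length(tumors) > 0,
          "presence and CNA matrices share no genes/tumors")
  bp <- presence$values[genes, tumors, drop = FALSE] == 1L
  cn <- cna[genes, tumors, drop = FALSE] ==
    if (level == "amplification") 2 else -2
  if (!any(cn)) {
    warning("no CNA calls at the requested level; association undefined",
            call. = FALSE)
    return(list(statistic = NA_real_, p_value = 1, method = "none",
                table = NULL, n_cooccurring = 0L))
  }
  tab <- table(factor(as.vector(bp), c(TRUE, FALSE)),
               factor(as.vector(cn), c(TRUE, FALSE)))
  dimnames(tab) <- list(breakpoint = c("yes", "no"), cna = c("yes", "no"))
  res <- .chisq_2x2(tab)
  c(res, list(table = tab, n_cooccurring = sum(bp & cn)))
}

#' Flag expression-altered gene/tumor pairs
#'
#' A (gene, tumor) pair is altered when the gene passes the FDR gate in the
#' supplied association table and the tumor's SD-from-median score exceeds
#' the threshold in the direction of the gene's association (score > 0.4
#' for positively associated genes, < -0.4 for negative).
#'
#' @param scores SD-from-median score matrix (see [sd_scores()]).
#' @param assoc Association table (see [run_association()]).
#' @param q_threshold FDR gate on `q_storey` (default 0.10).
#' @param sd_threshold Score threshold (default 0.4).
#' @return Logical genes x tumors matrix (only gated genes can be TRUE).
#' @export
expression_altered_flags <- function(scores, assoc, q_threshold = 0.1,
                                     sd_threshold = 0.4) {
  gated <- assoc[!is.na(assoc$q_storey) & assoc$q_storey < q_threshold, ]
  out <- matrix(FALSE, nrow(scores), ncol(scores), dimnames = dimnames(scores))
  for (i in seq_len(nrow(gated))) {
    g <- gated$gene_id[i]
    if (!g %in% rownames(scores)) next
    out[g, ] <- if (gated$direction[i] == "positive")
      !is.na(scores[g, ]) & scores[g, ] > sd_threshold
    else
      !is.na(scores[g, ]) & scores[g, ] < -sd_threshold
  }
  out
}
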
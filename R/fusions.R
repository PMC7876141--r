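# Refinement of RNA-seq fusion candidates with WGS SSV support and
# expression evidence.

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Filter fusion candidates against a banned list and same-gene artifacts
#'
#' Removes candidates whose unordered gene pair is on the banned list
#' (either order) and candidates whose two partners are the same gene.
#' Removal counts are reported via `message()`.
#'
#' @param calls Fusion candidate `data.frame` (`gene_a`, `gene_b`,
#'   `tumor_id`, `caller`).
#' @param banned_pairs `data.frame` with columns `gene_a`, `gene_b` of
#'   banned (unordered) pairs; may be empty.
#' @return Filtered candidate `data.frame`.
#' @export
filter_fusion_candidates <- function(calls, banned_pairs = NULL) {
  n0 <- nrow(calls)
  same <- calls$gene_a == calls$gene_b
  banned <- rep(FALSE, n0)
  if (!is.null(banned_pairs) && nrow(banned_pairs) > 0L) {
    banned <- .pair_key(calls$gene_a, calls$gene_b) %in%
      .pair_key(banned_pairs$gene_a, banned_pairs$gene_b)
  }
  message(sprintf(
    "fusion filtering: %d candidates, removed %d same-gene and %d banned",
    n0, sum(same), sum(banned & !same)))
  out <- calls[!(same | banned), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate fusion candidates with WGS breakpoint support
#'
#' A candidate is supported when at least one SSV breakend from the same
#' tumor falls within the annotated body (start to end, introns included)
#' of one (`one_gene`) or both (`both_genes`) partner genes.
#'
#' @param calls Fusion candidate `data.frame`.
#' @param ssvs SSV table.
#' @param genes Gene annotation.
#' @return `calls` with an added `ssv_support` column
#'   (`none`/`one_gene`/`both_genes`).
#' @export
annotate_ssv_support <- function(calls, ssvs, genes) {
  genes <- .check_genes(genes)
  be <- .breakends(ssvs)
  gidx <- match(c(calls$gene_a, calls$gene_b), genes$gene_id)
  unknown <- unique(c(calls$gene_a, calls$gene_b)[is.na(gidx)])
  if (length(unknown)) {
    warning(sprintf("%d fusion partner gene(s) missing from annotation",
                    length(unknown)), call. = FALSE)
  }
  in_body <- function(gene_id, tumor_id) {
    i <- match(gene_id, genes$gene_id)
    if (is.na(i)) return(FALSE)
    any(be$tumor_id == tumor_id & be$chrom == genes$chrom[i] &
          be$pos >= genes$start[i] & be$pos < genes$end[i])
  }
  hits_a <- mapply(in_body, calls$gene_a, calls$tumor_id)
  hits_b <- mapply(in_body, calls$gene_b, calls$tumor_id)
  calls$ssv_support <- ifelse(hits_a & hits_b, "both_genes",
                        ifelse(hits_a | hits_b, "one_gene", "none"))
  calls
}

#' Annotate fusion candidates with the high-expression criterion
#'
#' A candidate has a high expression association when either of two rules
#' holds: (1) for fusions recurring in at most two tumors, the
#' SD-from-median score of either partner exceeds `sd_threshold` in each
#' carrier tumor; or (2) either partner shows a significant positive
#' SSV-expression association (p below `p_threshold`) by the distance
#' metric or by the gene-body window.
#'
#' @param calls Fusion candidate `data.frame`.
#' @param scores SD-from-median score matrix (see [sd_scores()]).
#' @param assoc_body Gene-body window association table (or NULL).
#' @param assoc_dist Distance-metric association table (or NULL).
#' @param p_threshold Rule-2 p-value cutoff (default 0.01).
#' @param sd_threshold Rule-1 score cutoff (default 0.4).
#' @return `calls` with added `recurrence` and `high_expression` columns.
#' @export
annotate_high_expression <- function(calls, scores, assoc_body = NULL,
                                     assoc_dist = NULL, p_threshold = 0.01,
                                     sd_threshold = 0.4) {
  key <- .pair_key(calls$gene_a, calls$gene_b)
  rec <- vapply(split(calls$tumor_id, key), function(x) length(unique(x)),
                0L)
  calls$recurrence <- unname(rec[key])

  sig_genes <- function(assoc) {
    if (is.null(assoc) || nrow(assoc) == 0L) return(character(0))
    assoc$gene_id[!is.na(assoc$p_value) & assoc$p_value < p_threshold &
                    assoc$direction == "positive"]
  }
  assoc_pos <- union(sig_genes(assoc_body), sig_genes(assoc_dist))

  score_of <- function(gene_id, tumor_id) {
    if (!gene_id %in% rownames(scores) ||
        !tumor_id %in% colnames(scores)) return(NA_real_)
    scores[gene_id, tumor_id]
  }
  rule1 <- vapply(seq_len(nrow(calls)), function(i) {
    if (calls$recurrence[i] > 2L) return(FALSE)
    sa <- score_of(calls$gene_a[i], calls$tumor_id[i])
    sb <- score_of(calls$gene_b[i], calls$tumor_id[i])
    isTRUE(sa > sd_threshold) || isTRUE(sb > sd_threshold)
  }, TRUE)
  rule2 <- calls$gene_a %in% assoc_pos | calls$gene_b %in% assoc_pos
  calls$high_expression <- rule1 | rule2
  calls
}

#' Refine fusion candidates into support tiers
#'
#' Runs banned-list filtering, SSV-support annotation and the
#' high-expression criterion, then tiers each surviving candidate:
#' `ssv_supported_high_expr` (breakpoint support and high expression),
#' `ssv_supported` (support only), `rna_only` (neither).
#'
#' @inheritParams filter_fusion_candidates
#' @inheritParams annotate_ssv_support
#' @inheritParams annotate_high_expression
#' @return Refined fusion `data.frame` with `ssv_support`,
#'   `high_expression`, `recurrence` and `tier` columns.
#' @export
refine_fusions <- function(calls, banned_pairs, ssvs, genes, scores,
                           assoc_body = NULL, assoc_dist = NULL,
                           p_threshold = 0.01, sd_threshold = 0.4) {
  out <- filter_fusion_candidates(calls, banned_pairs)
  out <- annotate_ssv_support(out, ssvs, genes)
  out <- annotate_high_expression(out, scores, assoc_body, assoc_dist,
                                  p_threshold, sd_threshold)
  out$tier <- ifelse(out$ssv_support != "none" & out$high_expression,
                     "ssv_supported_high_expr",
               ifelse(out$ssv_support != "none", "ssv_supported",
                      "rna_only"))
  out
}
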
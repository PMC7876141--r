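# Correlates of the overall extent of genomic rearrangement: per-gene
# expression and inactivating-mutation associations with total SSV burden,
# alteration-group contrasts, the paired initial-vs-recurrent comparison,
# and a generic gene-set Fisher test.

#' Per-tumor burden profile
#'
#' @param counts Named per-tumor SSV counts (see [count_ssv_burden()]).
#' @return `data.frame` with `tumor_id`, `ssv_count` and
#'   `log_burden` = log10(count + 1).
#' @export
burden_profile <- function(counts) {
  .assert(all(counts >= 0), "SSV counts must be non-negative")
  data.frame(tumor_id = names(counts), ssv_count = as.integer(counts),
             log_burden = log10(counts + 1), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Genes whose expression tracks total SSV burden
#'
#' Per-gene OLS of log2 expression on log10(SSV count + 1) with tumor-type
#' and CNA covariates; Storey q attached.
#'
#' @param expr Raw-scale expression matrix.
#' @param burden Output of [burden_profile()].
#' @param meta Tumor metadata.
#' @param cna Thresholded CNA matrix (or NULL).
#' @param spec A [model_spec()].
#' @return Association `data.frame` (one row per gene) sorted by p-value.
#' @export
burden_expression_correlates <- function(expr, burden, meta, cna = NULL,
                                         spec = model_spec()) {
  tumors <- intersect(colnames(expr), burden$tumor_id)
  .assert(length(tumors) >= 3, "need at least 3 tumors with burden data")
  lb <- burden$log_burden[match(tumors, burden$tumor_id)]
  if (length(unique(lb)) < 2L) {
    warning("burden is constant across tumors; nothing to test",
            call. = FALSE)
    return(.empty_assoc_df("log_burden"))
  }
  types <- meta$tumor_type[match(tumors, meta$tumor_id)]
  expr <- expr[, tumors, drop = FALSE]
  if (!is.null(cna)) cna <- cna[, tumors, drop = FALSE]

  res <- lapply(rownames(expr), function(g) {
    cna_row <- if (!is.null(cna) && g %in% rownames(cna)) cna[g, ] else NULL
    fit_gene_model(expr[g, ], lb, types, cna_row, spec)
  })
  coef_ <- vapply(res, `[[`, 0, "coefficient")
  p <- vapply(res, `[[`, 0, "p_value")
  out <- data.frame(
    gene_id = rownames(expr), predictor_kind = "log_burden",
    coefficient = coef_,
    direction = ifelse(is.na(coef_), NA_character_,
                       ifelse(coef_ > 0, "positive", "negative")),
    p_value = p, q_storey = storey_fdr(p),
    n_ssv_tumors = NA_integer_,
    reason = vapply(res, `[[`, "", "reason"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Inactivating mutations associated with SSV burden
#'
#' Point-biserial (Pearson) correlation between per-gene binary mutation
#' indicators and log10-transformed SSV counts; only genes mutated in at
#' least `min_tumors` tumors are tested, and all-zero or all-one genes are
#' skipped.
#'
#' @param mut Binary genes x tumors mutation matrix.
#' @param burden Output of [burden_profile()].
#' @param min_tumors Minimum mutated tumors per tested gene (default 3).
#' @return `data.frame` with `gene_id`, `n_mutated`, `r`, `p_value`,
#'   `q_storey`, sorted by p-value.
#' @export
burden_mutation_correlates <- function(mut, burden, min_tumors = 3L) {
  tumors <- intersect(colnames(mut), burden$tumor_id)
  .assert(length(tumors) >= 3, "need at least 3 tumors")
  m <- mut[, tumors, drop = FALSE]
  .assert(all(m %in% c(0, 1)), "mutation matrix must be binary")
  lb <- burden$log_burden[match(tumors, burden$tumor_id)]
  n <- length(tumors)
  nm <- rowSums(m)
  tested <- rownames(m)[nm >= min_tumors & nm < n]
  if (length(tested) == 0L) {
    return(data.frame(gene_id = character(), n_mutated = integer(),
                      r = numeric(), p_value = numeric(),
                      q_storey = numeric(), stringsAsFactors = FALSE))
  }
  r <- as.vector(stats::cor(t(m[tested, , drop = FALSE]), lb))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  out <- data.frame(gene_id = tested, n_mutated = unname(nm[tested]),
                    r = r, p_value = p, q_storey = storey_fdr(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Burden contrasts between alteration groups
#'
#' OLS of log10(SSV count + 1) on alteration-group indicators plus
#' tumor-type dummies; each group is contrasted against the reference
#' group. Groups with fewer than two tumors are dropped with a warning.
#'
#' @param burden Output of [burden_profile()].
#' @param groups Named character vector mapping tumor_id to alteration
#'   class.
#' @param meta Tumor metadata.
#' @param reference Name of the reference group (must be present).
#' @return `data.frame` with `group`, `n`, `coefficient`, `p_value`.
#' @export
burden_group_test <- function(burden, groups, meta, reference) {
  tumors <- intersect(burden$tumor_id, names(groups))
  g <- groups[tumors]
  .assert(reference %in% g, "reference group '%s' not present", reference)
  tab <- table(g)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning(sprintf("dropping group(s) with < 2 tumors: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    keep <- !(g %in% small)
    tumors <- tumors[keep]; g <- g[keep]
  }
  .assert(reference %in% g, "reference group lost after size filtering")
  lb <- burden$log_burden[match(tumors, burden$tumor_id)]
  types <- meta$tumor_type[match(tumors, meta$tumor_id)]
  f <- stats::relevel(factor(g), ref = reference)
  other <- setdiff(levels(f), reference)

  df <- data.frame(lb = lb, f = f, type = factor(types))
  form <- if (nlevels(df$type) > 1L) lb ~ f + type else lb ~ f
  fit <- stats::lm(form, data = df)
  cf <- summary(fit)$coefficients
  rows <- paste0("f", other)
  data.frame(group = other, n = as.integer(table(f)[other]),
             coefficient = ifelse(rows %in% rownames(cf),
                                  cf[rows, "Estimate"], NA_real_),
             p_value = ifelse(rows %in% rownames(cf),
                              cf[rows, "Pr(>|t|)"], NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Paired initial vs progressive/recurrent burden test
#'
#' Paired t-test on log10(SSV count + 1) for patients with both an initial
#' tumor and a progressive or recurrent tumor. When a patient has several
#' tumors in an arm, the first by metadata row order is used.
#'
#' @param burden Output of [burden_profile()].
#' @param meta Tumor metadata (`patient_id`, `status`).
#' @return List with `t`, `p_value`, `n_pairs` and `mean_diff`
#'   (progressive/recurrent minus initial, log10 scale).
#' @export
paired_burden_test <- function(burden, meta) {
  meta <- meta[meta$tumor_id %in% burden$tumor_id, , drop = FALSE]
  initial <- meta[meta$status == "initial", , drop = FALSE]
  later <- meta[meta$status %in% c("progressive", "recurrent"), ,
                drop = FALSE]
  patients <- intersect(initial$patient_id, later$patient_id)
  .assert(length(patients) >= 2, "need at least 2 complete pairs")
  pick <- function(d, p) d$tumor_id[match(p, d$patient_id)]
  lb <- setNames(burden$log_burden, burden$tumor_id)
  x0 <- lb[pick(initial, patients)]
  x1 <- lb[pick(later, patients)]
  diffs <- x1 - x0
  if (all(diffs == 0)) {
    return(list(t = 0, p_value = 1, n_pairs = length(patients),
                mean_diff = 0))
  }
  tt <- stats::t.test(x1, x0, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       n_pairs = length(patients), mean_diff = mean(diffs))
}

#' One-sided gene-set enrichment by Fisher's exact test
#'
#' Hypergeometric upper-tail probability for the overlap between a selected
#' gene set and a category, within a stated universe.
#'
#' @param selected Character vector of selected genes (subset of
#'   `universe`).
#' @param universe Character vector of all eligible genes.
#' @param category Character vector of category member genes.
#' @return List with `overlap`, `expected` and `p_value`.
#' @export
gene_set_fisher <- function(selected, universe, category) {
  .assert(length(universe) > 0, "empty universe")
  universe <- unique(universe)
  selected <- unique(selected)
  .assert(all(selected %in% universe), "selected must be within universe")
  cat_u <- intersect(unique(category), universe)
  x <- length(intersect(selected, cat_u))
  m <- length(cat_u)
  p <- .hyper_upper(x, m, length(universe) - m, length(selected))
  list(overlap = x,
       expected = length(selected) * m / length(universe),
       p_value = unname(p))
}
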
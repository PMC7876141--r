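# Pathway-level somatic alteration tabulation. Per (tumor, gene) at most
# one alteration is recorded, chosen by the fixed precedence
# snv_indel > fusion > deep_deletion > amplification > ssv_cis.

.alteration_order <- c("snv_indel", "fusion", "deep_deletion",
                       "amplification", "ssv_cis")

.inactivating <- c("nonsense", "nonstop", "frameshift_indel",
                   "inframe_indel")

#' Built-in cancer pathway catalog
#'
#' Curated pathway membership with per-gene roles (oncogene vs tumor
#' suppressor), covering RTK, HIPPO, chromatin modification, SWI/SNF,
#' PI3K/AKT/mTOR, MYC family, TERT, Wnt/beta-catenin, p53/Rb and NRF2.
#' Role assignments for dual-role genes follow the convention that the SSV
#' rule applied should match the gene's canonical cancer role; the catalog
#' is a plain `data.frame` and can be edited or replaced
#' (see [read_pathway_config()]). The NRF2 pathway is included but
#' excluded from presentation-focused summaries by default
#' (`include_nrf2 = FALSE`).
#'
#' @param include_nrf2 Keep the small NRF2 pathway?
#' @return `data.frame` with columns `pathway`, `gene`, `role`.
#' @export
default_pathway_catalog <- function(include_nrf2 = FALSE) {
  onc <- function(p, g) data.frame(pathway = p, gene = g, role = "oncogene",
                                   stringsAsFactors = FALSE)
  tsg <- function(p, g) data.frame(pathway = p, gene = g,
                                   role = "tumor_suppressor",
                                   stringsAsFactors = FALSE)
  cat <- rbind(
    onc("RTK", c("BRAF", "EGFR", "ERBB2", "ERBB3", "ERBB4", "FGFR1",
                 "FGFR2", "FGFR3", "FGFR4", "HRAS", "KIT", "KRAS", "MET",
                 "NRAS")),
    tsg("RTK", "NF1"),
    tsg("HIPPO", c("NF2", "SAV1", "WWC1")),
    tsg("chromatin_modification",
        c("CREBBP", "EHMT1", "EHMT2", "EP300", "EZH1", "EZH2", "KAT2A",
          "KAT2B", "KDM1A", "KDM1B", "KDM4A", "KDM4B", "KDM5A", "KDM5B",
          "KDM5C", "KDM6A", "KDM6B", "KMT2A", "KMT2B", "KMT2C", "KMT2D",
          "KMT2E", "NSD1", "SETD2", "SMYD4", "SRCAP")),
    tsg("SWI_SNF",
        c("ACTB", "ACTL6A", "ACTL6B", "ARID1A", "ARID1B", "ARID2",
          "BCL11A", "BCL11B", "BCL6", "BCL6B", "BRD7", "BRD9", "DPF1",
          "DPF2", "DPF3", "PBRM1", "PHF10", "SMARCA2", "SMARCA4",
          "SMARCB1", "SMARCC1", "SMARCC2", "SMARCD1", "SMARCD2",
          "SMARCD3", "SMARCE1")),
    onc("PI3K_AKT_mTOR", c("AKT1", "AKT2", "AKT3", "MTOR", "PIK3CA",
                           "RHEB", "IDH1", "IDH2")),
    tsg("PI3K_AKT_mTOR", c("PIK3R1", "PTEN", "STK11", "TSC1", "TSC2",
                           "VHL")),
    onc("MYC_family", c("MYC", "MYCN", "MYB")),
    onc("TERT", "TERT"),
    onc("Wnt_beta_catenin", c("CTNNB1", "FGF19")),
    tsg("Wnt_beta_catenin", c("APC", "AXIN1", "NCOR1")),
    onc("p53_Rb", c("CCND1", "CCNE1", "CDK4", "E2F2", "E2F3", "MDM2")),
    tsg("p53_Rb", c("ATM", "CDKN1A", "CDKN2A", "FBXW7", "RB1", "TP53"))
  )
  if (include_nrf2) {
    cat <- rbind(cat, onc("NRF2", "NFE2L2"),
                 tsg("NRF2", c("KEAP1", "CUL3", "SIRT1", "FH")))
  }
  rownames(cat) <- NULL
  cat
}

#' Read a pathway configuration TSV
#'
#' @param path TSV with columns `pathway`, `gene`, `role`
#'   (oncogene/tumor_suppressor).
#' @return Validated pathway `data.frame`.
#' @export
read_pathway_config <- function(path) {
  d <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("pathway", "gene", "role")
  .assert(all(need %in% names(d)), "pathway config is missing columns: %s",
          paste(setdiff(need, names(d)), collapse = ", "))
  .assert(all(d$role %in% c("oncogene", "tumor_suppressor")),
          "role must be oncogene or tumor_suppressor")
  d
}

#' Tabulate per-gene somatic alterations with precedence
#'
#' For each (tumor, pathway gene) pair, records the highest-precedence
#' qualifying alteration among: SNV/indel (hotspot required for oncogenes;
#' hotspot or inactivating consequence for tumor suppressors; TERT-style
#' promoter events qualify for oncogenes), fusion (tier-1 refined calls),
#' deep deletion (CNA -2), high-level amplification (CNA +2), and
#' SSV-mediated cis effect. The SSV category applies only to genes passing
#' the FDR gate (`q_storey` below `q_threshold` for the gene-body window or
#' the 1 Mb distance metric); an oncogene qualifies with a breakpoint
#' within 1 Mb and expression score > `sd_threshold` in that tumor, a tumor
#' suppressor with a gene-body breakpoint and score < -`sd_threshold`.
#'
#' @param pathways Pathway catalog (see [default_pathway_catalog()]).
#' @param mutations MAF-like table (`gene`, `tumor_id`, `consequence`,
#'   `hotspot`).
#' @param fusions Refined fusion table (see [refine_fusions()]); rows at
#'   tier `ssv_supported_high_expr` qualify.
#' @param cna Thresholded CNA matrix.
#' @param presence_body,presence_1mb `breakpoint_presence` objects for the
#'   gene-body and symmetric 1 Mb windows.
#' @param scores SD-from-median score matrix.
#' @param assoc_body,assoc_dist Association tables used for the FDR gate.
#' @param tumors Tumor ids to tabulate.
#' @param q_threshold FDR gate (default 0.10).
#' @param sd_threshold Expression score threshold (default 0.4).
#' @return `data.frame` with `tumor_id`, `gene_id`, `alteration`,
#'   `evidence`.
#' @export
call_alterations <- function(pathways, mutations, fusions, cna,
                             presence_body, presence_1mb, scores,
                             assoc_body, assoc_dist, tumors,
                             q_threshold = 0.1, sd_threshold = 0.4) {
  genes <- unique(pathways[, c("gene", "role")])
  gated <- function(assoc) {
    if (is.null(assoc) || nrow(assoc) == 0L) return(character(0))
    assoc$gene_id[!is.na(assoc$q_storey) & assoc$q_storey < q_threshold]
  }
  fdr_ok <- union(gated(assoc_body), gated(assoc_dist))

  missing_genes <- genes$gene[!(genes$gene %in% rownames(cna) |
                                  genes$gene %in% mutations$gene |
                                  genes$gene %in% rownames(scores))]
  if (length(missing_genes)) {
    message(sprintf("%d pathway gene(s) absent from all inputs, skipped",
                    length(missing_genes)))
  }

  calls <- list()
  add <- function(tumor, gene, alt, evidence) {
    calls[[length(calls) + 1L]] <<- data.frame(
      tumor_id = tumor, gene_id = gene, alteration = alt,
      evidence = evidence, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(genes))) {
    g <- genes$gene[i]; role <- genes$role[i]
    for (tu in tumors) {
      # 1. SNV/indel
      mrows <- mutations[mutations$gene == g & mutations$tumor_id == tu, ,
                         drop = FALSE]
      qual_mut <- if (nrow(mrows) == 0L) FALSE else if (role == "oncogene") {
        any(mrows$hotspot | mrows$consequence == "promoter")
      } else {
        any(mrows$hotspot | mrows$consequence %in% .inactivating)
      }
      if (qual_mut) { add(tu, g, "snv_indel", "mutation table"); next }
      # 2. fusion
      if (!is.null(fusions) && nrow(fusions) > 0L) {
        frows <- fusions$tumor_id == tu &
          (fusions$gene_a == g | fusions$gene_b == g) &
          fusions$tier == "ssv_supported_high_expr"
        if (any(frows)) { add(tu, g, "fusion", "refined fusion"); next }
      }
      # 3/4. CNA
      cn <- if (g %in% rownames(cna) && tu %in% colnames(cna))
        cna[g, tu] else 0
      if (isTRUE(cn == -2)) { add(tu, g, "deep_deletion", "cna -2"); next }
      if (isTRUE(cn == 2)) { add(tu, g, "amplification", "cna +2"); next }
      # 5. SSV cis effect (FDR-gated)
      if (!(g %in% fdr_ok)) next
      sc <- if (g %in% rownames(scores) && tu %in% colnames(scores))
        scores[g, tu] else NA_real_
      if (is.na(sc)) next
      if (role == "oncogene") {
        bp <- g %in% rownames(presence_1mb$values) &&
          tu %in% colnames(presence_1mb$values) &&
          presence_1mb$values[g, tu] == 1L
        if (bp && sc > sd_threshold)
          add(tu, g, "ssv_cis", "1Mb breakpoint, overexpressed")
      } else {
        bp <- g %in% rownames(presence_body$values) &&
          tu %in% colnames(presence_body$values) &&
          presence_body$values[g, tu] == 1L
        if (bp && sc < -sd_threshold)
          add(tu, g, "ssv_cis", "gene-body breakpoint, underexpressed")
      }
    }
  }
  if (length(calls) == 0L) {
    return(data.frame(tumor_id = character(), gene_id = character(),
                      alteration = character(), evidence = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  out$alteration <- factor(out$alteration, levels = .alteration_order)
  out <- out[order(out$tumor_id, out$gene_id), , drop = FALSE]
  out$alteration <- as.character(out$alteration)
  rownames(out) <- NULL
  out
}

#' Pathway x tumor alteration matrix and per-pathway fractions
#'
#' A pathway is altered in a tumor when at least one member gene carries an
#' alteration call.
#'
#' @param alterations Output of [call_alterations()].
#' @param pathways Pathway catalog.
#' @param tumors Tumor ids defining the columns (and the fraction
#'   denominator).
#' @return List with `matrix` (logical pathways x tumors) and `fractions`
#'   (named numeric).
#' @export
pathway_matrix <- function(alterations, pathways, tumors) {
  pws <- unique(pathways$pathway)
  m <- matrix(FALSE, length(pws), length(tumors),
              dimnames = list(pws, tumors))
  for (pw in pws) {
    members <- pathways$gene[pathways$pathway == pw]
    hit <- alterations[alterations$gene_id %in% members, , drop = FALSE]
    m[pw, unique(hit$tumor_id[hit$tumor_id %in% tumors])] <- TRUE
  }
  list(matrix = m, fractions = rowMeans(m))
}

#' Tumor-type enrichment of pathway alterations
#'
#' One-sided Fisher's exact test per (pathway, tumor type): alteration
#' against membership in the type versus the rest of the cohort.
#'
#' @param pmat Output of [pathway_matrix()].
#' @param meta Tumor metadata.
#' @param focus_types Tumor types to test (defaults to all observed types);
#'   types with no tumors in the matrix are skipped.
#' @return `data.frame` with `pathway`, `tumor_type`, `altered_in_type`,
#'   `n_type`, `p_value`.
#' @export
pathway_type_enrichment <- function(pmat, meta, focus_types = NULL) {
  tumors <- colnames(pmat$matrix)
  types <- meta$tumor_type[match(tumors, meta$tumor_id)]
  focus_types <- focus_types %||% sort(unique(types))
  out <- list()
  for (pw in rownames(pmat$matrix)) {
    alt <- pmat$matrix[pw, ]
    for (ty in focus_types) {
      in_type <- types == ty
      n_type <- sum(in_type)
      if (n_type == 0L) next
      x <- sum(alt & in_type)
      p <- .hyper_upper(x, m = n_type, n = sum(!in_type), k = sum(alt))
      out[[length(out) + 1L]] <- data.frame(
        pathway = pw, tumor_type = ty, altered_in_type = x,
        n_type = n_type, p_value = unname(p), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
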
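# Seeded synthetic cohorts with the statistical structure the analysis
# assumes: multi-type tumors, heavy-tailed per-tumor SSV counts, optional
# SSV-CNA coupling, planted cis-effect genes, planted fusions, planted
# CNA-dosage-only genes (the confounder the CNA covariate must absorb),
# burden-linked inactivating mutations, and paired initial/progressive
# tumors. Every planted element is recorded in a ground-truth manifest.

#' Parameters for the synthetic cohort generator
#'
#' Defaults mirror the structure of a large pediatric brain tumor cohort:
#' the per-tumor SSV count is log-normal with median 47 and sdlog 1.19
#' (giving a heavy right tail with SD close to 167), the genome totals
#' 3 Gb (20 chromosomes of 150 Mb) so that the per-Mb breakpoint density
#' matches a whole-genome cohort -- window predictors are
#' density-sensitive, so genome size is not free to shrink -- expression
#' is generated on the log2 scale with unit residual noise, and
#' thresholded CNA adds 0.5 log2 units per step.
#'
#' @param n_tumors,n_types,n_genes,n_chromosomes,chrom_length Cohort and
#'   genome dimensions.
#' @param burden_median,burden_sdlog Log-normal per-tumor SSV count.
#' @param burden_patient_frac Fraction of the log-scale burden variance
#'   shared between tumors of the same patient (tumors from one patient
#'   have correlated genomic instability; the per-tumor marginal stays
#'   log-normal with `burden_sdlog`).
#' @param type_burden_mult Optional per-type burden multipliers (length
#'   `n_types`).
#' @param svclass_mix Named class mixture for background SSVs.
#' @param sv_size_meanlog,sv_size_sdlog Log-normal intra-chromosomal SSV
#'   size.
#' @param noise_sd Residual SD of log2 expression.
#' @param type_effect_sd SD of per-gene tumor-type baseline offsets.
#' @param cna_dosage_effect log2 expression shift per thresholded CNA step.
#' @param cna_background_rate Per-cell probability of a background CNA
#'   call.
#' @param cna_coupling Probability that a background duplication emits a
#'   +1/+2 CNA for genes it spans.
#' @param planted_cis_n,planted_cis_effect,planted_cis_carriers Planted
#'   cis-effect genes: count, effect size (in units of `noise_sd`, added to
#'   log2 expression of carrier tumors), carrier tumors per gene; carrier
#'   breakends land within 50 kb of the TSS.
#' @param planted_cna_n,planted_cna_carriers CNA-dosage-only genes: a
#'   spanning duplication (breakends within 100 kb) plus a +2 CNA call, no
#'   direct expression effect beyond dosage.
#' @param planted_fusion_n,fusion_expr_bump,fusion_carriers Planted
#'   fusions: translocations with breakends inside both partner bodies, a
#'   chimeric candidate row, and a log2 expression bump on the 5' partner.
#' @param decoy_banned_n,decoy_same_n,decoy_rna_n Decoy fusion candidates:
#'   banned-pair calls, same-gene calls, unsupported RNA-only calls.
#' @param burden_driver_n,burden_driver_intercept,burden_driver_slope
#'   Burden-linked driver genes: mutation probability
#'   `plogis(intercept + slope * log10(count + 1))`.
#' @param mut_background_genes,mut_background_rate Background mutation
#'   model.
#' @param burden_expr_n,burden_expr_slope Genes whose log2 expression gains
#'   `slope * log10(count + 1)`.
#' @param paired_patients Patients contributing an initial and a
#'   progressive tumor.
#' @param progressive_burden_mult Burden multiplier for progressive or
#'   recurrent tumors.
#' @param frac_progressive Fraction of unpaired tumors labeled progressive.
#' @param seed Mandatory integer seed.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_tumors = 150L, n_types = 3L, n_genes = 500L,
                          n_chromosomes = 20L, chrom_length = 1.5e8,
                          burden_median = 47, burden_sdlog = 1.19,
                          burden_patient_frac = 0.8,
                          type_burden_mult = NULL,
                          svclass_mix = c(deletion = 0.35,
                                          duplication = 0.25,
                                          inversion = 0.15,
                                          insertion = 0.05,
                                          translocation = 0.20),
                          sv_size_meanlog = log(5e4), sv_size_sdlog = 1.5,
                          noise_sd = 1, type_effect_sd = 0.5,
                          cna_dosage_effect = 0.5,
                          cna_background_rate = 0.01, cna_coupling = 0,
                          planted_cis_n = 0L, planted_cis_effect = 1.5,
                          planted_cis_carriers = 10L,
                          planted_cna_n = 0L, planted_cna_carriers = 15L,
                          planted_fusion_n = 0L, fusion_expr_bump = 3,
                          fusion_carriers = 1L,
                          decoy_banned_n = 5L, decoy_same_n = 5L,
                          decoy_rna_n = 10L,
                          burden_driver_n = 0L,
                          burden_driver_intercept = -2.5,
                          burden_driver_slope = 1.5,
                          mut_background_genes = 30L,
                          mut_background_rate = 0.03,
                          burden_expr_n = 0L, burden_expr_slope = 0.8,
                          paired_patients = 0L,
                          progressive_burden_mult = 1.5,
                          frac_progressive = 0.2, seed) {
  .assert(!missing(seed), "seed is mandatory")
  p <- as.list(environment())
  .assert(p$planted_cis_n + p$planted_cna_n + 2 * p$planted_fusion_n +
            p$burden_expr_n + p$burden_driver_n <= p$n_genes,
          "more planted genes requested than n_genes")
  .assert(abs(sum(p$svclass_mix) - 1) < 1e-8, "svclass_mix must sum to 1")
  .assert(2 * p$paired_patients <= p$n_tumors,
          "paired patients need two tumors each")
  p$type_burden_mult <- p$type_burden_mult %||% rep(1, p$n_types)
  .assert(length(p$type_burden_mult) == p$n_types,
          "type_burden_mult must have n_types entries")
  structure(p, class = "cohort_params")
}

#' Generate synthetic gene, TAD and enhancer annotation
#'
#' Genes are non-overlapping with random strands, placed on an even grid
#' with jitter; TADs tile each chromosome (width 0.8-1.2 Mb) with
#' occasional annotation gaps; enhancers sit near a third of gene TSSs and
#' in gene deserts.
#'
#' @param params A [cohort_params()] list.
#' @param seed Optional seed (defaults to `params$seed`); pass NA to use
#'   the current RNG stream.
#' @return List with `genes`, `tads`, `enhancers`.
#' @export
generate_annotation <- function(params, seed = params$seed) {
  if (!is.na(seed)) set.seed(seed)
  n_chr <- params$n_chromosomes
  chroms <- paste0("chr", seq_len(n_chr))
  L <- params$chrom_length

  per_chr <- diff(round(seq(0, params$n_genes, length.out = n_chr + 1)))
  genes <- list()
  for (ci in seq_len(n_chr)) {
    ng <- per_chr[ci]
    if (ng == 0L) next
    slot <- floor(L / ng)
    .assert(slot >= 60000, "genome too short for requested gene count")
    width <- round(runif(ng, 5e3, 5e4))
    offset <- round(runif(ng, 5e3, slot - width - 5e3))
    start <- (seq_len(ng) - 1L) * slot + offset
    genes[[ci]] <- data.frame(
      chrom = chroms[ci], start = as.integer(start),
      end = as.integer(start + width),
      strand = sample(c("+", "-"), ng, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  if (nrow(genes) > 0L) {
    genes$gene_id <- sprintf("G%04d", seq_len(nrow(genes)))
    genes <- .check_genes(genes)
    genes <- genes[, c("gene_id", "chrom", "start", "end", "strand", "tss")]
  }

  tads <- list()
  for (ci in seq_len(n_chr)) {
    pos <- 0
    while (pos < L - 2e5) {
      w <- round(runif(1, 8e5, 1.2e6))
      end <- min(pos + w, L)
      tads[[length(tads) + 1L]] <- data.frame(
        chrom = chroms[ci], start = as.integer(pos), end = as.integer(end),
        stringsAsFactors = FALSE)
      pos <- end
      if (runif(1) < 0.1) pos <- pos + round(runif(1, 2e4, 1e5))  # gap
    }
  }
  tads <- do.call(rbind, tads)

  enh <- list()
  if (nrow(genes) > 0L) {
    near <- which(runif(nrow(genes)) < 1 / 3)
    if (length(near)) {
      off <- round(runif(length(near), 5e3, 1e5)) *
        sample(c(-1, 1), length(near), replace = TRUE)
      s <- pmax(genes$tss[near] + off, 0)
      enh$near <- data.frame(chrom = genes$chrom[near],
                             start = as.integer(s),
                             end = as.integer(s + 1000),
                             stringsAsFactors = FALSE)
    }
  }
  n_desert <- max(1L, round(params$n_genes * 0.2))
  s <- round(runif(n_desert, 0, L - 1000))
  enh$desert <- data.frame(chrom = sample(chroms, n_desert, replace = TRUE),
                           start = as.integer(s), end = as.integer(s + 1000),
                           stringsAsFactors = FALSE)
  enhancers <- do.call(rbind, unname(enh))
  enhancers <- enhancers[order(enhancers$chrom, enhancers$start), ,
                         drop = FALSE]
  rownames(enhancers) <- NULL
  list(genes = genes, tads = tads, enhancers = enhancers)
}

.orients_for_class <- function(svclass, n) {
  switch(svclass,
    deletion = cbind(rep("positive", n), rep("negative", n)),
    duplication = cbind(rep("negative", n), rep("positive", n)),
    insertion = cbind(rep("positive", n), rep("negative", n)),
    inversion = {
      o <- sample(c("positive", "negative"), n, replace = TRUE)
      cbind(o, o)
    },
    translocation = cbind(sample(c("positive", "negative"), n, TRUE),
                          sample(c("positive", "negative"), n, TRUE))
  )
}

#' Generate a full synthetic cohort with ground truth
#'
#' @param params A [cohort_params()] list.
#' @return List with `ssvs`, `expr` (raw scale), `cna`, `meta`,
#'   `mutations`, `fusions` (candidate calls), `banned_pairs`, `genes`,
#'   `tads`, `enhancers`, and `truth` (the planted-element manifest,
#'   including per-tumor true burden).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  ann <- generate_annotation(params, seed = NA)
  genes <- ann$genes
  n_genes <- nrow(genes)
  chroms <- paste0("chr", seq_len(params$n_chromosomes))
  L <- params$chrom_length

  # --- tumors, patients, types, status -------------------------------------
  n_tumors <- params$n_tumors
  tumor_id <- sprintf("T%04d", seq_len(n_tumors))
  n_paired <- params$paired_patients
  n_single <- n_tumors - 2L * n_paired
  patient_id <- c(rep(sprintf("P%04d", seq_len(n_paired)), each = 2L),
                  sprintf("P%04d", n_paired + seq_len(n_single)))
  status <- c(rep(c("initial", "progressive"), n_paired),
              ifelse(runif(n_single) < params$frac_progressive,
                     "progressive", "initial"))
  type_pool <- paste0("Type", seq_len(params$n_types))
  patient_type <- setNames(sample(type_pool, n_paired + n_single,
                                  replace = TRUE),
                           unique(patient_id))
  meta <- data.frame(tumor_id = tumor_id, patient_id = patient_id,
                     tumor_type = unname(patient_type[patient_id]),
                     status = status, stringsAsFactors = FALSE)

  # --- per-tumor burden -----------------------------------------------------
  mult <- params$type_burden_mult[match(meta$tumor_type, type_pool)]
  mult <- mult * ifelse(meta$status %in% c("progressive", "recurrent"),
                        params$progressive_burden_mult, 1)
  # log-scale burden variance split into a patient-shared component and a
  # per-tumor component; the marginal is log-normal(burden_sdlog)
  sd_pat <- sqrt(params$burden_patient_frac) * params$burden_sdlog
  sd_tum <- sqrt(1 - params$burden_patient_frac) * params$burden_sdlog
  pat_ids <- unique(meta$patient_id)
  pat_eff <- setNames(stats::rnorm(length(pat_ids), 0, sd_pat), pat_ids)
  counts <- pmax(0L, round(exp(
    log(params$burden_median * mult) + pat_eff[meta$patient_id] +
      stats::rnorm(n_tumors, 0, sd_tum))))
  names(counts) <- tumor_id

  # --- background SSVs ------------------------------------------------------
  total <- sum(counts)
  cls <- sample(names(params$svclass_mix), total, replace = TRUE,
                prob = params$svclass_mix)
  chr1 <- sample(chroms, total, replace = TRUE)
  pos1 <- round(runif(total, 0, L - 2))
  size <- pmax(50, round(stats::rlnorm(total, params$sv_size_meanlog,
                                       params$sv_size_sdlog)))
  pos2 <- pmin(pos1 + size, L - 1)
  chr2 <- chr1
  tra <- cls == "translocation"
  if (any(tra)) {
    # a different chromosome, uniformly among the others
    shift <- sample.int(params$n_chromosomes - 1L, sum(tra), replace = TRUE)
    chr2[tra] <- chroms[1L + (match(chr1[tra], chroms) - 1L + shift) %%
                          params$n_chromosomes]
    pos2[tra] <- round(runif(sum(tra), 0, L - 2))
  }
  ins <- cls == "insertion"
  pos2[ins] <- pmin(pos1[ins] + pmax(50, round(size[ins] / 100)), L - 1)
  o <- matrix("", total, 2L)
  for (cl in unique(cls)) {
    i <- which(cls == cl)
    o[i, ] <- .orients_for_class(cl, length(i))
  }
  ssvs <- data.frame(
    ssv_id = sprintf("SSV%06d", seq_len(total)), svclass = cls,
    chrom1 = chr1, pos1 = as.integer(pos1), orient1 = o[, 1],
    chrom2 = chr2, pos2 = as.integer(pos2), orient2 = o[, 2],
    tumor_id = rep(tumor_id, times = counts), pass_filter = TRUE,
    stringsAsFactors = FALSE)

  next_id <- total
  new_ids <- function(n) {
    ids <- sprintf("SSV%06d", next_id + seq_len(n))
    next_id <<- next_id + n
    ids
  }
  extra <- list()

  # --- CNA ------------------------------------------------------------------
  cna <- matrix(0, n_genes, n_tumors, dimnames = list(genes$gene_id, tumor_id))
  nz <- which(runif(n_genes * n_tumors) < params$cna_background_rate)
  if (length(nz)) {
    cna[nz] <- sample(c(-1, 1, -2, 2), length(nz), replace = TRUE,
                      prob = c(0.45, 0.45, 0.05, 0.05))
  }
  if (params$cna_coupling > 0) {
    dup <- which(ssvs$svclass == "duplication" &
                   runif(nrow(ssvs)) < params$cna_coupling)
    for (i in dup) {
      gi <- which(genes$chrom == ssvs$chrom1[i] &
                    genes$start >= ssvs$pos1[i] & genes$end <= ssvs$pos2[i])
      if (length(gi)) {
        val <- if (runif(1) < 0.3) 2 else 1
        ti <- match(ssvs$tumor_id[i], tumor_id)
        cna[gi, ti] <- pmax(cna[gi, ti], val)
      }
    }
  }

  # --- reserve distinct genes for the planted channels ----------------------
  n_reserved <- params$planted_cis_n + params$planted_cna_n +
    2L * params$planted_fusion_n + params$burden_expr_n +
    params$burden_driver_n
  reserved <- if (n_reserved > 0L) sample(genes$gene_id, n_reserved) else
    character(0)
  take <- function(n) {
    out <- reserved[seq_len(n)]
    reserved <<- reserved[-seq_len(n)]
    out
  }

  # --- planted cis-effect genes --------------------------------------------
  cis_effect <- matrix(0, n_genes, n_tumors,
                       dimnames = list(genes$gene_id, tumor_id))
  cis_truth <- NULL
  if (params$planted_cis_n > 0L) {
    cis_genes <- take(params$planted_cis_n)
    carriers <- lapply(cis_genes, function(g)
      sample(tumor_id, params$planted_cis_carriers))
    for (k in seq_along(cis_genes)) {
      g <- cis_genes[k]
      gi <- match(g, genes$gene_id)
      for (tu in carriers[[k]]) {
        p1 <- genes$tss[gi] + round(runif(1, -5e4, 5e4))
        p1 <- max(0, min(p1, L - 2))
        p2 <- min(p1 + pmax(50, round(stats::rlnorm(
          1, params$sv_size_meanlog, params$sv_size_sdlog))), L - 1)
        extra[[length(extra) + 1L]] <- data.frame(
          ssv_id = new_ids(1L), svclass = "inversion",
          chrom1 = genes$chrom[gi], pos1 = as.integer(p1),
          orient1 = "positive", chrom2 = genes$chrom[gi],
          pos2 = as.integer(p2), orient2 = "positive",
          tumor_id = tu, pass_filter = TRUE, stringsAsFactors = FALSE)
        cis_effect[g, tu] <- cis_effect[g, tu] +
          params$planted_cis_effect * params$noise_sd
      }
    }
    cis_truth <- list(genes = cis_genes,
                      effect = params$planted_cis_effect,
                      carriers = setNames(carriers, cis_genes))
  }

  # --- planted CNA-dosage-only genes ---------------------------------------
  cna_truth <- NULL
  if (params$planted_cna_n > 0L) {
    cna_genes <- take(params$planted_cna_n)
    carriers <- lapply(cna_genes, function(g)
      sample(tumor_id, params$planted_cna_carriers))
    for (k in seq_along(cna_genes)) {
      g <- cna_genes[k]
      gi <- match(g, genes$gene_id)
      for (tu in carriers[[k]]) {
        p1 <- max(0, genes$start[gi] - round(runif(1, 1e3, 8e4)))
        p2 <- min(genes$end[gi] + round(runif(1, 1e3, 8e4)), L - 1)
        extra[[length(extra) + 1L]] <- data.frame(
          ssv_id = new_ids(1L), svclass = "duplication",
          chrom1 = genes$chrom[gi], pos1 = as.integer(p1),
          orient1 = "negative", chrom2 = genes$chrom[gi],
          pos2 = as.integer(p2), orient2 = "positive",
          tumor_id = tu, pass_filter = TRUE, stringsAsFactors = FALSE)
        cna[g, tu] <- 2
      }
    }
    cna_truth <- list(genes = cna_genes,
                      carriers = setNames(carriers, cna_genes))
  }

  # --- planted fusions ------------------------------------------------------
  fusion_rows <- list()
  fusion_truth <- NULL
  fusion_bump <- matrix(0, n_genes, n_tumors,
                        dimnames = list(genes$gene_id, tumor_id))
  if (params$planted_fusion_n > 0L) {
    fa <- take(params$planted_fusion_n)
    fb <- take(params$planted_fusion_n)
    # partners must sit on different chromosomes for a translocation
    for (k in seq_len(params$planted_fusion_n)) {
      if (genes$chrom[match(fa[k], genes$gene_id)] ==
          genes$chrom[match(fb[k], genes$gene_id)]) {
        alt <- which(genes$chrom != genes$chrom[match(fa[k], genes$gene_id)] &
                       !(genes$gene_id %in% c(fa, fb)))
        fb[k] <- genes$gene_id[alt[1L]]
      }
    }
    carriers <- replicate(params$planted_fusion_n,
                          sample(tumor_id, params$fusion_carriers),
                          simplify = FALSE)
    for (k in seq_len(params$planted_fusion_n)) {
      ia <- match(fa[k], genes$gene_id); ib <- match(fb[k], genes$gene_id)
      for (tu in carriers[[k]]) {
        p1 <- round(runif(1, genes$start[ia], genes$end[ia] - 1))
        p2 <- round(runif(1, genes$start[ib], genes$end[ib] - 1))
        extra[[length(extra) + 1L]] <- data.frame(
          ssv_id = new_ids(1L), svclass = "translocation",
          chrom1 = genes$chrom[ia], pos1 = as.integer(p1),
          orient1 = "positive", chrom2 = genes$chrom[ib],
          pos2 = as.integer(p2), orient2 = "negative",
          tumor_id = tu, pass_filter = TRUE, stringsAsFactors = FALSE)
        fusion_bump[fa[k], tu] <- params$fusion_expr_bump
        fusion_rows[[length(fusion_rows) + 1L]] <- data.frame(
          gene_a = fa[k], gene_b = fb[k], tumor_id = tu, caller = "both",
          stringsAsFactors = FALSE)
      }
    }
    fusion_truth <- list(gene_a = fa, gene_b = fb,
                         carriers = setNames(carriers,
                                             paste(fa, fb, sep = "|")))
  }

  # decoy candidates and the banned list
  banned_pairs <- data.frame(gene_a = character(), gene_b = character(),
                             stringsAsFactors = FALSE)
  if (params$decoy_banned_n > 0L && n_genes >= 4L) {
    ba <- sample(genes$gene_id, params$decoy_banned_n)
    bb <- sample(setdiff(genes$gene_id, ba), params$decoy_banned_n)
    banned_pairs <- data.frame(gene_a = ba, gene_b = bb,
                               stringsAsFactors = FALSE)
    fusion_rows[[length(fusion_rows) + 1L]] <- data.frame(
      gene_a = bb, gene_b = ba,  # reversed order: filter must catch both
      tumor_id = sample(tumor_id, params$decoy_banned_n, replace = TRUE),
      caller = "caller1", stringsAsFactors = FALSE)
  }
  if (params$decoy_same_n > 0L && n_genes > 0L) {
    sg <- sample(genes$gene_id, params$decoy_same_n, replace = TRUE)
    fusion_rows[[length(fusion_rows) + 1L]] <- data.frame(
      gene_a = sg, gene_b = sg,
      tumor_id = sample(tumor_id, params$decoy_same_n, replace = TRUE),
      caller = "caller2", stringsAsFactors = FALSE)
  }
  if (params$decoy_rna_n > 0L && n_genes >= 4L) {
    ra <- sample(genes$gene_id, params$decoy_rna_n, replace = TRUE)
    rb <- sample(genes$gene_id, params$decoy_rna_n, replace = TRUE)
    keep <- ra != rb
    fusion_rows[[length(fusion_rows) + 1L]] <- data.frame(
      gene_a = ra[keep], gene_b = rb[keep],
      tumor_id = sample(tumor_id, sum(keep), replace = TRUE),
      caller = "caller1", stringsAsFactors = FALSE)
  }
  fusions <- if (length(fusion_rows)) do.call(rbind, fusion_rows) else
    data.frame(gene_a = character(), gene_b = character(),
               tumor_id = character(), caller = character(),
               stringsAsFactors = FALSE)
  rownames(fusions) <- NULL

  # --- burden-linked expression and mutations -------------------------------
  log_burden <- log10(counts + 1)
  burden_expr_truth <- NULL
  burden_expr_term <- matrix(0, n_genes, n_tumors,
                             dimnames = list(genes$gene_id, tumor_id))
  if (params$burden_expr_n > 0L) {
    beg <- take(params$burden_expr_n)
    burden_expr_term[beg, ] <- matrix(
      rep(params$burden_expr_slope * log_burden, each = length(beg)),
      nrow = length(beg))
    burden_expr_truth <- list(genes = beg,
                              slope = params$burden_expr_slope)
  }

  mut_rows <- list()
  driver_truth <- NULL
  if (params$burden_driver_n > 0L) {
    drivers <- take(params$burden_driver_n)
    for (g in drivers) {
      pmut <- stats::plogis(params$burden_driver_intercept +
                              params$burden_driver_slope * log_burden)
      hit <- runif(n_tumors) < pmut
      if (any(hit)) {
        mut_rows[[length(mut_rows) + 1L]] <- data.frame(
          gene = g, tumor_id = tumor_id[hit], consequence = "nonsense",
          hotspot = FALSE, stringsAsFactors = FALSE)
      }
    }
    driver_truth <- list(genes = drivers,
                         intercept = params$burden_driver_intercept,
                         slope = params$burden_driver_slope)
  }
  if (params$mut_background_genes > 0L && n_genes > 0L) {
    bg <- sample(setdiff(genes$gene_id, unlist(driver_truth$genes)),
                 min(params$mut_background_genes, n_genes))
    for (g in bg) {
      hit <- runif(n_tumors) < params$mut_background_rate
      if (any(hit)) {
        cons <- sample(c("missense", "nonsense", "frameshift_indel"),
                       sum(hit), replace = TRUE)
        mut_rows[[length(mut_rows) + 1L]] <- data.frame(
          gene = g, tumor_id = tumor_id[hit], consequence = cons,
          hotspot = cons == "missense" & runif(sum(hit)) < 0.5,
          stringsAsFactors = FALSE)
      }
    }
  }
  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    data.frame(gene = character(), tumor_id = character(),
               consequence = character(), hotspot = logical(),
               stringsAsFactors = FALSE)
  rownames(mutations) <- NULL

  # --- expression -----------------------------------------------------------
  baseline <- runif(n_genes, 3, 8)
  type_off <- matrix(stats::rnorm(n_genes * params$n_types, 0,
                                  params$type_effect_sd),
                     n_genes, params$n_types,
                     dimnames = list(genes$gene_id, type_pool))
  E <- baseline + type_off[, meta$tumor_type, drop = FALSE] +
    params$cna_dosage_effect * cna + cis_effect + fusion_bump +
    burden_expr_term +
    matrix(stats::rnorm(n_genes * n_tumors, 0, params$noise_sd),
           n_genes, n_tumors)
  dimnames(E) <- list(genes$gene_id, tumor_id)
  expr <- pmax(2^E - 1, 0)

  if (length(extra)) ssvs <- rbind(ssvs, do.call(rbind, extra))
  rownames(ssvs) <- NULL
  # canonical breakend order (smaller chrom/pos first) so that VCF round
  # trips reproduce records exactly
  key1 <- paste(ssvs$chrom1, formatC(ssvs$pos1, width = 12, flag = "0"))
  key2 <- paste(ssvs$chrom2, formatC(ssvs$pos2, width = 12, flag = "0"))
  swap <- key2 < key1
  if (any(swap)) {
    tmp <- ssvs[swap, c("chrom1", "pos1", "orient1")]
    ssvs[swap, c("chrom1", "pos1", "orient1")] <-
      ssvs[swap, c("chrom2", "pos2", "orient2")]
    ssvs[swap, c("chrom2", "pos2", "orient2")] <- tmp
  }
  .check_ssv_df(ssvs)

  truth <- list(
    params_seed = params$seed,
    burden = as.list(setNames(as.integer(counts), tumor_id)),
    planted_cis = cis_truth, planted_cna_only = cna_truth,
    planted_fusions = fusion_truth, burden_expr = burden_expr_truth,
    burden_driver = driver_truth)

  list(ssvs = ssvs, expr = expr, cna = cna, meta = meta,
       mutations = mutations, fusions = fusions,
       banned_pairs = banned_pairs, genes = genes, tads = ann$tads,
       enhancers = ann$enhancers, truth = truth)
}

#' Write a synthetic cohort to disk
#'
#' Emits the full input bundle in the package's external formats: SV VCF
#' and BEDPE, expression/CNA TSV matrices, metadata/mutation/fusion TSVs,
#' gene BED6, TAD and enhancer BED3, and the ground-truth manifest as JSON.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_sv_vcf(cohort$ssvs, fp("sv.vcf"))
  write_sv_bedpe(cohort$ssvs, fp("sv.bedpe"))
  write_matrix_tsv(cohort$expr, fp("expression.tsv"))
  write_matrix_tsv(cohort$cna, fp("cna.tsv"))
  utils::write.table(cohort$meta, fp("meta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$mutations, fp("mutations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$fusions, fp("fusions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$banned_pairs, fp("banned_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  g <- cohort$genes
  utils::write.table(
    data.frame(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand),
    fp("genes.bed"), sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(cohort$tads, fp("tads.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cohort$enhancers, fp("enhancers.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(cohort$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Build a binary inactivating-mutation matrix from a MAF-like table
#'
#' @param mutations MAF-like table (`gene`, `tumor_id`, `consequence`).
#' @param tumors Tumor ids defining the columns.
#' @param inactivating_only Keep only nonsense/nonstop/indel consequences.
#' @return Binary genes x tumors matrix.
#' @export
mutation_matrix <- function(mutations, tumors, inactivating_only = TRUE) {
  d <- mutations
  if (inactivating_only) {
    d <- d[d$consequence %in% .inactivating, , drop = FALSE]
  }
  genes <- sort(unique(d$gene))
  m <- matrix(0L, length(genes), length(tumors),
              dimnames = list(genes, tumors))
  d <- d[d$tumor_id %in% tumors, , drop = FALSE]
  if (nrow(d)) m[cbind(match(d$gene, genes), match(d$tumor_id, tumors))] <- 1L
  m
}
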
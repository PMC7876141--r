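# Alteration precedence, SSV inclusion rules, pathway summaries.

pathway_fixture <- function() {
  pathways <- data.frame(
    pathway = c("PW1", "PW1", "PW2"),
    gene = c("ONC1", "TSG1", "ONC2"),
    role = c("oncogene", "tumor_suppressor", "oncogene"),
    stringsAsFactors = FALSE)
  tumors <- paste0("T", 1:4)
  genes <- c("ONC1", "TSG1", "ONC2")
  cna <- matrix(0, 3, 4, dimnames = list(genes, tumors))
  pv <- matrix(0L, 3, 4, dimnames = list(genes, tumors))
  presence_body <- structure(list(values = pv,
                                  window = window_spec("gene_body")),
                             class = "breakpoint_presence")
  presence_1mb <- structure(list(values = pv,
                                 window = window_spec("symmetric", 1e6)),
                            class = "breakpoint_presence")
  scores <- matrix(0, 3, 4, dimnames = list(genes, tumors))
  assoc <- data.frame(gene_id = genes, predictor_kind = "log_distance",
                      coefficient = 1, direction = "positive",
                      p_value = 1e-5, q_storey = 0.01, n_ssv_tumors = 5L,
                      reason = NA, stringsAsFactors = FALSE)
  list(pathways = pathways, tumors = tumors, cna = cna,
       presence_body = presence_body, presence_1mb = presence_1mb,
       scores = scores, assoc = assoc)
}

empty_mut <- data.frame(gene = character(), tumor_id = character(),
                        consequence = character(), hotspot = logical(),
                        stringsAsFactors = FALSE)

test_that("precedence: hotspot SNV outranks a qualifying cis SSV", {
  fx <- pathway_fixture()
  mut <- data.frame(gene = "ONC1", tumor_id = "T1",
                    consequence = "missense", hotspot = TRUE,
                    stringsAsFactors = FALSE)
  fx$presence_1mb$values["ONC1", "T1"] <- 1L
  fx$scores["ONC1", "T1"] <- 0.9
  calls <- suppressMessages(call_alterations(
    fx$pathways, mut, NULL, fx$cna, fx$presence_body, fx$presence_1mb,
    fx$scores, fx$assoc, NULL, fx$tumors))
  expect_equal(calls$alteration[calls$gene_id == "ONC1" &
                                  calls$tumor_id == "T1"], "snv_indel")
})

test_that("SSV inclusion rules: window, direction, threshold, FDR gate", {
  fx <- pathway_fixture()
  fx$presence_body$values["TSG1", "T2"] <- 1L
  fx$scores["TSG1", "T2"] <- -0.6
  fx$presence_1mb$values["ONC2", "T3"] <- 1L
  fx$scores["ONC2", "T3"] <- 0.2        # fails the > 0.4 SD rule
  fx$presence_1mb$values["ONC1", "T4"] <- 1L
  fx$scores["ONC1", "T4"] <- 0.9        # would qualify, but gate closed
  gated <- fx$assoc[fx$assoc$gene_id != "ONC1", ]
  calls <- suppressMessages(call_alterations(
    fx$pathways, empty_mut, NULL, fx$cna, fx$presence_body,
    fx$presence_1mb, fx$scores, gated, NULL, fx$tumors))
  expect_equal(calls$alteration[calls$gene_id == "TSG1"], "ssv_cis")
  expect_false(any(calls$gene_id == "ONC2"))
  expect_false(any(calls$gene_id == "ONC1"))
  # every ssv_cis call traces to an FDR-gated gene
  expect_true(all(calls$gene_id[calls$alteration == "ssv_cis"] %in%
                    gated$gene_id))
})

test_that("oncogene mutations need hotspot or promoter; suppressors accept
           inactivating", {
  fx <- pathway_fixture()
  mut <- data.frame(
    gene = c("ONC1", "ONC2", "TSG1"),
    tumor_id = c("T1", "T2", "T3"),
    consequence = c("missense", "promoter", "nonsense"),
    hotspot = c(FALSE, FALSE, FALSE), stringsAsFactors = FALSE)
  calls <- suppressMessages(call_alterations(
    fx$pathways, mut, NULL, fx$cna, fx$presence_body, fx$presence_1mb,
    fx$scores, fx$assoc, NULL, fx$tumors))
  # non-hotspot missense in an oncogene does not qualify
  expect_false(any(calls$gene_id == "ONC1"))
  expect_equal(calls$alteration[calls$gene_id == "ONC2"], "snv_indel")
  expect_equal(calls$alteration[calls$gene_id == "TSG1"], "snv_indel")
})

test_that("alteration output is invariant to input row order and CNA
           levels map correctly", {
  fx <- pathway_fixture()
  mut <- data.frame(
    gene = c("ONC1", "TSG1", "ONC2"),
    tumor_id = c("T1", "T2", "T3"),
    consequence = c("missense", "nonsense", "missense"),
    hotspot = c(TRUE, FALSE, TRUE), stringsAsFactors = FALSE)
  fx$cna["ONC2", "T1"] <- 2
  fx$cna["TSG1", "T4"] <- -2
  run <- function(m) suppressMessages(call_alterations(
    fx$pathways, m, NULL, fx$cna, fx$presence_body, fx$presence_1mb,
    fx$scores, fx$assoc, NULL, fx$tumors))
  a <- run(mut)
  b <- run(mut[c(3, 1, 2), ])
  expect_identical(a, b)
  expect_equal(a$alteration[a$gene_id == "ONC2" & a$tumor_id == "T1"],
               "amplification")
  expect_equal(a$alteration[a$gene_id == "TSG1" & a$tumor_id == "T4"],
               "deep_deletion")
})

test_that("pathway matrix uses OR semantics and fractions grow
           monotonically", {
  fx <- pathway_fixture()
  alt1 <- data.frame(tumor_id = "T1", gene_id = "ONC1",
                     alteration = "snv_indel", evidence = "x",
                     stringsAsFactors = FALSE)
  pm1 <- pathway_matrix(alt1, fx$pathways, fx$tumors)
  expect_true(pm1$matrix["PW1", "T1"])
  expect_equal(unname(pm1$fractions["PW1"]), 0.25)
  expect_equal(unname(pm1$fractions["PW2"]), 0)

  alt2 <- rbind(alt1, data.frame(tumor_id = "T2", gene_id = "TSG1",
                                 alteration = "ssv_cis", evidence = "y"))
  pm2 <- pathway_matrix(alt2, fx$pathways, fx$tumors)
  expect_true(all(pm2$fractions >= pm1$fractions))

  pm0 <- pathway_matrix(alt1[0, ], fx$pathways, fx$tumors)
  expect_true(all(pm0$fractions == 0))
})

test_that("pathway-type enrichment is a one-sided Fisher test", {
  pathways <- data.frame(pathway = "PW", gene = "G",
                         role = "oncogene", stringsAsFactors = FALSE)
  tumors <- sprintf("T%03d", 1:200)
  meta <- data.frame(tumor_id = tumors, patient_id = tumors,
                     tumor_type = rep(c("A", "B"), c(25, 175)),
                     status = "initial")
  m <- matrix(FALSE, 1, 200, dimnames = list("PW", tumors))
  m[1, c(1:20, 30:34)] <- TRUE  # 20/25 of type A, 5/175 of the rest
  res <- pathway_type_enrichment(list(matrix = m), meta,
                                 focus_types = c("A", "B"))
  pa <- res$p_value[res$tumor_type == "A"]
  expect_lt(pa, 1e-10)
  tab <- matrix(c(20, 5, 5, 170), 2, byrow = TRUE)
  expect_equal(pa, fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-10)
  # a never-altered pathway scores p = 1
  m0 <- matrix(FALSE, 1, 200, dimnames = list("PW", tumors))
  res0 <- pathway_type_enrichment(list(matrix = m0), meta)
  expect_true(all(res0$p_value == 1))
})

test_that("the built-in catalog is complete and role-consistent", {
  cat <- default_pathway_catalog(include_nrf2 = TRUE)
  expect_true(all(c("KRAS", "TP53", "SMARCB1", "NF2", "TERT", "MYCN",
                    "NFE2L2") %in% cat$gene))
  expect_true(all(cat$role %in% c("oncogene", "tumor_suppressor")))
  expect_false("NRF2" %in% default_pathway_catalog()$pathway)
  expect_false(anyDuplicated(cat[, c("pathway", "gene")]) > 0)
})
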
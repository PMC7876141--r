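# TAD classification, enhancer-translocation logic, enrichment tests.

simple_tads <- function() {
  data.frame(chrom = c("chr1", "chr1", "chr2"),
             start = c(0L, 1000000L, 0L),
             end = c(1000000L, 2000000L, 1500000L),
             stringsAsFactors = FALSE)
}

tad_ssv <- function(c1, p1, c2, p2, id = "S1") {
  data.frame(ssv_id = id,
             svclass = if (c1 == c2) "deletion" else "translocation",
             chrom1 = c1, pos1 = as.integer(p1), orient1 = "positive",
             chrom2 = c2, pos2 = as.integer(p2), orient2 = "negative",
             tumor_id = "TA", pass_filter = TRUE, stringsAsFactors = FALSE)
}

test_that("classify_tad covers preserving / disrupting / unresolved", {
  tads <- simple_tads()
  expect_equal(classify_tad(tad_ssv("chr1", 100, "chr1", 900000), tads)$class,
               "preserving")
  expect_equal(classify_tad(tad_ssv("chr1", 100, "chr2", 100), tads)$class,
               "disrupting")
  expect_equal(classify_tad(tad_ssv("chr1", 100, "chr1", 1500000),
                            tads)$class, "disrupting")
  # breakend in an annotation gap
  expect_equal(classify_tad(tad_ssv("chr1", 100, "chr1", 2500000),
                            tads)$class, "unresolved")
  # overlapping TADs rejected
  bad <- rbind(simple_tads(),
               data.frame(chrom = "chr1", start = 500000L, end = 1500000L))
  expect_error(classify_tad(tad_ssv("chr1", 1, "chr1", 2), bad), "overlap")
})

test_that("classify_tad agrees with brute-force containment on 1000 SSVs", {
  set.seed(31)
  tads <- data.frame(
    chrom = rep(c("chr1", "chr2"), each = 10),
    start = rep(seq(0L, 9000000L, by = 1000000L), 2) +
      rep(sample(c(0L, 50000L), 20, replace = TRUE)),
    end = rep(seq(0L, 9000000L, by = 1000000L), 2) + 950000L)
  ssvs <- make_ssvs(1000, seed = 32, L = 1.2e7)
  got <- classify_tad(ssvs, tads)
  contains <- function(ch, pos) {
    hit <- which(tads$chrom == ch & tads$start <= pos & pos < tads$end)
    if (length(hit)) hit else NA_integer_
  }
  expected <- vapply(seq_len(nrow(ssvs)), function(i) {
    a <- contains(ssvs$chrom1[i], ssvs$pos1[i])
    b <- contains(ssvs$chrom2[i], ssvs$pos2[i])
    if (is.na(a) || is.na(b)) "unresolved"
    else if (a == b) "preserving" else "disrupting"
  }, "")
  expect_identical(got$class, expected)
  tra <- ssvs$svclass == "translocation"
  expect_false(any(got$class[tra] == "preserving"))
})

test_that("tad_enrichment matches the closed-form chi-squared", {
  classes <- data.frame(
    ssv_id = sprintf("S%03d", 1:400),
    class = c(rep("disrupting", 180), rep("preserving", 20),   # altered set
              rep("disrupting", 100), rep("preserving", 100)),
    stringsAsFactors = FALSE)
  altered <- sprintf("S%03d", 1:200)
  res <- tad_enrichment(classes, altered)
  tab <- matrix(c(180, 20, 100, 100), 2, byrow = TRUE)
  expected <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(res$p_value, expected$p.value, tolerance = 1e-12)
  expect_equal(res$statistic, unname(expected$statistic), tolerance = 1e-12)
  expect_lt(res$p_value, 1e-6)

  # identical fractions -> p ~ 1
  cl2 <- data.frame(ssv_id = sprintf("S%03d", 1:200),
                    class = rep(c("disrupting", "preserving"), 100))
  res2 <- tad_enrichment(cl2, cl2$ssv_id[1:100])
  expect_gt(res2$p_value, 0.5)

  expect_error(tad_enrichment(cl2, character(0)), "empty")
})

# --- enhancer-translocation enumeration ------------------------------------
# full grid: strand x proximal orientation x fused-side enhancer placement
# x native enhancer placement. Geometry: TSS at 1,000,000; proximal
# breakend 100 kb upstream; mate at chr2:5,000,000 retaining its upstream
# (positive) side; candidate enhancer midpoints 200 kb (near) / 700 kb
# (out of reach) from the mate; native enhancer 50 kb (near) / 900 kb
# (far) from the TSS. Expected outcomes derived once by hand from the
# orientation rule and the derivative-distance comparison
# (d_deriv = 100 kb + 200 kb = 300 kb).
test_that("enhancer translocation matches the hand-derived fixture grid", {
  grid <- enhancer_grid()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    call <- enhancer_grid_case(g)
    if (g$expect_call) {
      expect_false(is.null(call),
                   label = paste("call expected for row", i))
      expect_equal(call$distance_to_breakend, 200000)
      if (g$native_enh == "far") {
        expect_equal(call$native_enhancer_distance, 900000)
      }
    } else {
      expect_null(call, label = paste("no call expected for row", i))
    }
  }
})

test_that("cohort-level enhancer scan dedups to the closest call", {
  gene <- make_genes(gene_id = "G1", chrom = "chr1", start = 1000000L,
                     end = 1020000L, strand = "+")
  mk <- function(id, prox, mate, morient) {
    data.frame(ssv_id = id, svclass = "translocation", chrom1 = "chr1",
               pos1 = prox, orient1 = "negative", chrom2 = "chr2",
               pos2 = mate, orient2 = morient, tumor_id = "TA",
               pass_filter = TRUE, stringsAsFactors = FALSE)
  }
  # two qualifying SSVs; only the one closest to the TSS is considered
  ssvs <- rbind(mk("S1", 900000L, 5000000L, "positive"),
                mk("S2", 950000L, 8000000L, "positive"))
  enh <- data.frame(chrom = "chr2", start = c(4899500L, 7989500L),
                    end = c(4900500L, 7990500L))
  calls <- enhancer_translocations(ssvs, gene, enh)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$ssv_id, "S2")
  expect_equal(calls$distance_to_breakend, 10000)
})

test_that("cna_ssv_enrichment detects planted coupling and degenerate
           input", {
  # large duplications (median 300 kb) so that spanning +1/+2 CNA calls
  # actually arise at whole-genome breakpoint density
  co <- cached("coupled_cohort", function() {
    generate_cohort(cohort_params(n_tumors = 150L, n_genes = 400L,
                                  cna_coupling = 0.9,
                                  sv_size_meanlog = log(3e5),
                                  sv_size_sdlog = 1, seed = 55L))
  })
  pres <- build_presence_matrix(co$ssvs, co$genes,
                                window_spec("symmetric", 1e6),
                                tumors = co$meta$tumor_id)
  res <- cna_ssv_enrichment(pres, co$cna, "amplification")
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$n_cooccurring, 0)
  # oracle identity with the generic 2x2 test actually used
  oracle <- if (res$method == "chisq") {
    suppressWarnings(chisq.test(res$table, correct = FALSE))$p.value
  } else {
    fisher.test(res$table)$p.value
  }
  expect_equal(res$p_value, oracle, tolerance = 1e-12)

  cna0 <- co$cna * 0
  expect_warning(res0 <- cna_ssv_enrichment(pres, cna0, "amplification"),
                 "undefined")
  expect_equal(res0$p_value, 1)
})
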
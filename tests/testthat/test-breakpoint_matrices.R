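# Presence / distance predictor matrices and burden counting, checked
# against brute-force oracles.

one_ssv <- function(chrom, pos, tumor = "TA", ssv_id = "S1",
                    mate_pos = pos + 500L) {
  data.frame(ssv_id = ssv_id, svclass = "deletion", chrom1 = chrom,
             pos1 = as.integer(pos), orient1 = "positive", chrom2 = chrom,
             pos2 = as.integer(mate_pos), orient2 = "negative",
             tumor_id = tumor, pass_filter = TRUE, stringsAsFactors = FALSE)
}

test_that("upstream windows are strand-aware", {
  genes <- make_genes(gene_id = c("Gp", "Gm"), chrom = "chr1",
                      start = c(1000000L, 1900000L),
                      end = c(1020000L, 2000001L), strand = c("+", "-"))
  w <- window_spec("upstream", 100000L)
  # + strand gene, tss = 1,000,000: breakend at 950,000 is upstream
  m1 <- build_presence_matrix(one_ssv("chr1", 950000L, mate_pos = 951000L),
                              genes, w)
  expect_equal(m1$values["Gp", "TA"], 1L)
  expect_equal(m1$values["Gm", "TA"], 0L)
  # - strand gene, tss = 2,000,000: upstream extends rightward
  m2 <- build_presence_matrix(one_ssv("chr1", 2050000L, mate_pos = 2051000L),
                              genes, w)
  expect_equal(m2$values["Gm", "TA"], 1L)
  expect_equal(m2$values["Gp", "TA"], 0L)
  # a tumor with no SSVs yields an all-zero column
  m3 <- build_presence_matrix(one_ssv("chr1", 950000L), genes, w,
                              tumors = c("TA", "TB"))
  expect_equal(unname(m3$values[, "TB"]), c(0L, 0L))
})

test_that("distance matrix imputes, clips and takes the nearest breakend", {
  genes <- make_genes(gene_id = "G1", chrom = "chr1", start = 5000000L,
                      end = 5050000L, strand = "+")
  # no breakend within 1 Mb
  far <- one_ssv("chr2", 100L)
  d1 <- build_distance_matrix(far, genes)
  expect_equal(unname(d1$values["G1", "TA"]), log2(1e6))
  expect_true(d1$imputed["G1", "TA"])
  # breakend exactly at the TSS: clipped to 1 bp, log2 -> 0
  d2 <- build_distance_matrix(one_ssv("chr1", 5000000L), genes)
  expect_equal(unname(d2$values["G1", "TA"]), 0)
  expect_false(d2$imputed["G1", "TA"])
  # nearest of several breakends wins: 1024 bp vs 500 kb -> log2 = 10
  ssvs <- rbind(one_ssv("chr1", 5001024L, ssv_id = "S1",
                        mate_pos = 5501024L),
                one_ssv("chr1", 5500000L, ssv_id = "S2",
                        mate_pos = 5900000L))
  d3 <- build_distance_matrix(ssvs, genes)
  expect_equal(unname(d3$values["G1", "TA"]), 10)
})

test_that("presence and distance matrices match a brute-force oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n_genes <- sample(5:20, 1)
    L <- 5e6
    start <- sort(sample.int(L - 60000L, n_genes))
    genes <- make_genes(
      gene_id = sprintf("G%02d", seq_len(n_genes)),
      chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
      start = start, end = start + sample(5000:30000, n_genes, TRUE),
      strand = sample(c("+", "-"), n_genes, TRUE))
    tumors <- paste0("T", 1:6)
    ssvs <- make_ssvs(n = sample(10:50, 1), seed = rep + 100,
                      L = L, tumors = tumors)
    w <- window_spec("upstream", 50000L)
    pres <- build_presence_matrix(ssvs, genes, w, tumors = tumors)
    dist <- build_distance_matrix(ssvs, genes, max_dist = 1e6,
                                  tumors = tumors)

    be <- data.frame(chrom = c(ssvs$chrom1, ssvs$chrom2),
                     pos = c(ssvs$pos1, ssvs$pos2),
                     tumor = rep(ssvs$tumor_id, 2))
    for (gi in seq_len(n_genes)) {
      tss <- genes$tss[gi]
      lo <- if (genes$strand[gi] == "+") genes$start[gi] - 50000L else
        genes$end[gi]
      hi <- lo + 50000L
      for (tu in tumors) {
        b <- be[be$tumor == tu & be$chrom == genes$chrom[gi], ]
        hitting <- sum(b$pos >= lo & b$pos < hi)
        expect_identical(pres$values[gi, tu], as.integer(hitting > 0))
        dmin <- if (nrow(b)) min(abs(b$pos - tss)) else Inf
        expected <- log2(max(min(dmin, 1e6), 1))
        expect_equal(unname(dist$values[gi, tu]), expected)
        expect_identical(unname(dist$imputed[gi, tu]), dmin >= 1e6)
      }
    }
  }
})

test_that("enlarging a window never turns presence off, distances bounded", {
  ssvs <- make_ssvs(n = 60, seed = 9)
  genes <- make_genes(gene_id = sprintf("G%02d", 1:10), chrom = "chr1",
                      start = seq(1e5, 5e6, length.out = 10),
                      end = seq(1e5, 5e6, length.out = 10) + 20000,
                      strand = rep(c("+", "-"), 5))
  small <- build_presence_matrix(ssvs, genes, window_spec("upstream", 2e4))
  big <- build_presence_matrix(ssvs, genes, window_spec("upstream", 2e5))
  expect_true(all(big$values >= small$values))

  dist <- build_distance_matrix(ssvs, genes)
  expect_true(all(dist$values <= log2(1e6)))
  expect_identical(dist$values == log2(1e6), dist$imputed)
})

test_that("burden counts mate-merged records once", {
  ssvs <- rbind(
    one_ssv("chr1", 100L, ssv_id = "S1"),
    one_ssv("chr1", 5000L, ssv_id = "S2"),
    one_ssv("chr1", 9000L, ssv_id = "S3"),
    data.frame(ssv_id = "S4", svclass = "translocation", chrom1 = "chr1",
               pos1 = 100L, orient1 = "positive", chrom2 = "chr2",
               pos2 = 200L, orient2 = "negative", tumor_id = "TA",
               pass_filter = TRUE, stringsAsFactors = FALSE))
  expect_equal(count_ssv_burden(ssvs), c(TA = 4L))
  expect_equal(count_ssv_burden(ssvs, tumors = c("TA", "TB")),
               c(TA = 4L, TB = 0L))
  expect_equal(count_ssv_burden(make_ssvs(100, seed = 2, tumors = "TX")),
               c(TX = 100L))
})
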
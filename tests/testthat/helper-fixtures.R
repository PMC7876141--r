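# Shared fixtures. Cohorts are generated once per test run and memoized;
# all randomness is seeded inside the generators.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, maker(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

make_genes <- function(...) {
  g <- data.frame(..., stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g
}

# a small mixed SSV table used by several modules
make_ssvs <- function(n = 10, seed = 1, chroms = c("chr1", "chr2"),
                      L = 1e7, tumors = c("TA", "TB")) {
  set.seed(seed)
  cls <- sample(c("deletion", "duplication", "inversion", "insertion",
                  "translocation"), n, replace = TRUE)
  c1 <- sample(chroms, n, replace = TRUE)
  p1 <- round(runif(n, 0, L - 1e5))
  p2 <- p1 + round(runif(n, 100, 5e4))
  c2 <- c1
  tra <- cls == "translocation"
  c2[tra] <- vapply(c1[tra], function(ch) sample(setdiff(chroms, ch), 1), "")
  p2[tra] <- round(runif(sum(tra), 0, L - 1))
  data.frame(
    ssv_id = sprintf("S%03d", seq_len(n)), svclass = cls,
    chrom1 = c1, pos1 = as.integer(p1),
    orient1 = sample(c("positive", "negative"), n, replace = TRUE),
    chrom2 = c2, pos2 = as.integer(p2),
    orient2 = sample(c("positive", "negative"), n, replace = TRUE),
    tumor_id = sample(tumors, n, replace = TRUE), pass_filter = TRUE,
    stringsAsFactors = FALSE
  )
}

# Hand-derived enhancer-translocation fixture grid: strand x proximal
# orientation x fused-side enhancer {near 200 kb, absent(700 kb)} x native
# enhancer {near 50 kb, far 900 kb, absent}. TSS at 1,000,000; proximal
# breakend 100 kb upstream; mate at chr2:5,000,000 retaining its upstream
# side. A call is expected iff the orientation rule holds (+ gene needs a
# negative-orientation breakend, - gene positive), the fused-side enhancer
# is within 500 kb, and the native enhancer is not closer than the
# derivative-chromosome distance (100 kb + 200 kb = 300 kb).
enhancer_grid <- function() {
  grid <- expand.grid(strand = c("+", "-"),
                      prox_orient = c("positive", "negative"),
                      fused_enh = c("near", "absent"),
                      native_enh = c("near", "far", "absent"),
                      stringsAsFactors = FALSE)
  orient_ok <- ifelse(grid$strand == "+", grid$prox_orient == "negative",
                      grid$prox_orient == "positive")
  grid$expect_call <- orient_ok & grid$fused_enh == "near" &
    grid$native_enh != "near"
  grid
}

enhancer_grid_case <- function(g) {
  gene <- make_genes(gene_id = "G1", chrom = "chr1",
                     start = if (g$strand == "+") 1000000L else 980000L,
                     end = if (g$strand == "+") 1020000L else 1000001L,
                     strand = g$strand)
  prox_pos <- if (g$strand == "+") 900000L else 1100000L
  ssv <- data.frame(ssv_id = "S1", svclass = "translocation",
                    chrom1 = "chr1", pos1 = prox_pos,
                    orient1 = g$prox_orient, chrom2 = "chr2",
                    pos2 = 5000000L, orient2 = "positive",
                    tumor_id = "TA", pass_filter = TRUE,
                    stringsAsFactors = FALSE)
  enh <- if (g$fused_enh == "near") {
    data.frame(chrom = "chr2", start = 4799500L, end = 4800500L)
  } else {
    data.frame(chrom = "chr2", start = 4299500L, end = 4300500L)
  }
  if (g$native_enh == "near") {
    enh <- rbind(enh, data.frame(chrom = "chr1", start = 1049500L,
                                 end = 1050500L))
  } else if (g$native_enh == "far") {
    enh <- rbind(enh, data.frame(chrom = "chr1", start = 99500L,
                                 end = 100500L))
  }
  detect_enhancer_translocation(ssv, gene, enh)
}

# small planted cohort reused across module tests (kept light; acceptance
# tests use the full-scale cohorts)
small_planted_cohort <- function() {
  cached("small_planted", function() {
    generate_cohort(cohort_params(
      n_tumors = 60L, n_types = 2L, n_genes = 120L, planted_cis_n = 4L,
      planted_fusion_n = 5L, planted_cna_n = 2L, burden_driver_n = 1L,
      burden_expr_n = 2L, paired_patients = 8L, seed = 101L))
  })
}
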
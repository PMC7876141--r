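# Per-gene OLS, Storey FDR, permutation FDR machinery, subgroup
# enrichment.

test_that("fit_gene_model recovers clean group differences and flags
           degenerate designs", {
  x <- rep(c(1, 0), each = 5)
  y_raw <- 2^(ifelse(x == 1, 6, 4)) - 1  # log2(y+1) = 6 vs 4, no noise
  fit <- fit_gene_model(y_raw, x, spec = model_spec(covariates = character(0)))
  expect_equal(fit$coefficient, 2, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-12)

  fit0 <- fit_gene_model(y_raw, rep(1, 10),
                         spec = model_spec(covariates = character(0)))
  expect_true(is.na(fit0$p_value))
  expect_equal(fit0$reason, "constant predictor")

  # predictor perfectly confounded with a tumor-type level
  types <- rep(c("A", "B"), each = 5)
  fit1 <- fit_gene_model(y_raw, x, types = types,
                         spec = model_spec(covariates = "tumor_type"))
  expect_true(is.na(fit1$p_value))
  expect_equal(fit1$reason, "rank deficient")
})

test_that("fit_gene_model agrees with a normal-equations oracle", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(20:60, 1)
    x <- rnorm(n)
    types <- sample(c("A", "B", "C"), n, replace = TRUE)
    cna <- sample(-2:2, n, replace = TRUE)
    y <- rnorm(n) + 0.3 * x + 0.5 * (types == "B") + 0.2 * cna
    fit <- fit_gene_model(y, x, types, cna, transform = FALSE)

    # independent oracle: explicit normal equations + t distribution
    X <- cbind(1, x, as.numeric(factor(types) == "B"),
               as.numeric(factor(types) == "C"), cna)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% beta
    df <- n - ncol(X)
    se <- sqrt(drop(crossprod(res)) / df * solve(t(X) %*% X)[2, 2])
    t_ <- beta[2] / se
    p <- 2 * pt(abs(t_), df, lower.tail = FALSE)
    expect_equal(fit$coefficient, beta[2], tolerance = 1e-8)
    expect_equal(fit$p_value, p, tolerance = 1e-8)
  }
})

test_that("storey_fdr evaluates the published formula exactly", {
  # 1000 genes, 50 with p <= 0.01, target gene at p = 0.01 -> q = 0.2
  p <- c(rep(0.005, 49), 0.01, seq(0.2, 1, length.out = 950))
  q <- storey_fdr(p)
  expect_equal(q[50], 0.01 * 1000 / 50)
  expect_equal(storey_fdr(rep(1, 7)), rep(1, 7))
  expect_equal(storey_fdr(0.5), 0.5)
  expect_equal(storey_fdr(numeric(0)), numeric(0))

  # property: direct per-element evaluation on random inputs
  set.seed(11)
  for (rep in 1:10) {
    p <- round(runif(sample(5:80, 1)), 3)  # rounding forces ties
    q <- storey_fdr(p)
    q_direct <- vapply(p, function(pi) min(1, pi * length(p) / sum(p <= pi)),
                       0)
    expect_equal(q, q_direct)
  }
})

test_that("a strongly planted gene is ranked first with positive
           direction", {
  co <- cached("single_planted", function() {
    generate_cohort(cohort_params(n_tumors = 100L, n_types = 2L,
                                  n_genes = 60L, planted_cis_n = 1L,
                                  planted_cis_carriers = 12L, seed = 303L))
  })
  res <- run_association(quantile_normalize(co$expr),
                         build_distance_matrix(co$ssvs, co$genes,
                                               tumors = co$meta$tumor_id),
                         co$meta, co$cna)
  expect_equal(res$gene_id[1], co$truth$planted_cis$genes)
  expect_equal(res$direction[1], "positive")
})

test_that("run_association recovers planted genes and respects
           min_tumors", {
  co <- small_planted_cohort()
  expr <- quantile_normalize(co$expr)
  dist <- build_distance_matrix(co$ssvs, co$genes,
                                tumors = co$meta$tumor_id)
  res <- run_association(expr, dist, co$meta, co$cna)
  planted <- co$truth$planted_cis$genes
  expect_true(all(planted %in% res$gene_id))
  prow <- res[match(planted, res$gene_id), ]
  expect_true(all(prow$direction == "positive"))
  expect_true(all(prow$p_value < 0.1))
  expect_gte(length(intersect(res$gene_id[1:5], planted)), 2L)
  expect_true(all(res$n_ssv_tumors >= 3))

  # permuting a significant gene's predictor destroys the association:
  # permuted p-values look null (the t-test is mildly anticonservative
  # for mixture-shaped expression, hence the slack above the nominal 5%)
  g <- res$gene_id[1]
  set.seed(12)
  types <- co$meta$tumor_type[match(colnames(dist$values),
                                    co$meta$tumor_id)]
  pv <- vapply(1:200, function(i) {
    xp <- sample(dist$values[g, ])
    fit_gene_model(expr[g, colnames(dist$values)], xp, types,
                   co$cna[g, colnames(dist$values)])$p_value
  }, 0)
  expect_gte(mean(pv > 0.05, na.rm = TRUE), 0.88)
  expect_lt(res$p_value[1], quantile(pv, 0.05, na.rm = TRUE))
})

test_that("run_association returns an empty table when nothing qualifies", {
  genes <- make_genes(gene_id = "G1", chrom = "chr1", start = 1000L,
                      end = 2000L, strand = "+")
  ssvs <- make_ssvs(2, seed = 1, tumors = c("T1", "T2"))
  ssvs$chrom1 <- ssvs$chrom2 <- "chr2"
  ssvs$svclass <- "deletion"
  dist <- build_distance_matrix(ssvs, genes, tumors = c("T1", "T2"))
  expr <- matrix(10, 1, 2, dimnames = list("G1", c("T1", "T2")))
  meta <- data.frame(tumor_id = c("T1", "T2"), patient_id = c("P1", "P2"),
                     tumor_type = "A", status = "initial")
  expect_warning(res <- run_association(expr, dist, meta),
                 "min_tumors")
  expect_equal(nrow(res), 0L)
})

test_that("the permutation fast path reproduces full-model p-values", {
  co <- small_planted_cohort()
  expr <- quantile_normalize(co$expr)
  dist <- build_distance_matrix(co$ssvs, co$genes,
                                tumors = co$meta$tumor_id)
  pf <- permutation_fdr(expr, dist, co$meta, co$cna, n_perm = 2,
                        seed = 5, diagnostics = TRUE)
  expect_equal(pf$fwl_observed_p, pf$observed$p_value, tolerance = 1e-10)
  expect_error(permutation_fdr(expr, dist, co$meta, co$cna, n_perm = 0),
               "n_perm")
})

test_that("subgroup enrichment matches fisher.test one-sided", {
  v <- matrix(0L, 3, 100,
              dimnames = list(c("G1", "G2", "G3"), sprintf("T%03d", 1:100)))
  A <- sprintf("T%03d", 1:10)
  B <- sprintf("T%03d", 11:100)
  v["G1", A[1:5]] <- 1L                      # strong enrichment in A
  v["G2", c(A[1:2], B[1:18])] <- 1L          # identical 20% frequency
  pres <- structure(list(values = v, window = window_spec("upstream")),
                    class = "breakpoint_presence")
  res <- subgroup_breakpoint_enrichment(pres, A, B)
  expect_lt(res$p_value[1], 1e-4)
  expect_gte(res$p_value[2], 0.5)
  expect_equal(res$p_value[3], 1)  # no breakpoints at all
  for (g in 1:3) {
    tab <- matrix(c(sum(v[g, A]), length(A) - sum(v[g, A]),
                    sum(v[g, B]), length(B) - sum(v[g, B])), 2)
    expect_equal(res$p_value[g],
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})
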
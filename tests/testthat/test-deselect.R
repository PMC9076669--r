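make_cm <- function(counts, condition) {
  rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  count_matrix(counts, condition)
}

test_that("low-count filter applies the CPM rule", {
  cm <- make_cm(rbind(c(0, 0), c(1, 0), c(50, 50)),
                c("non-stress", "stress"))
  # all-zero gene removed for any positive threshold
  f <- filter_low_counts(cm, min_cpm = 0.001, min_samples = 1)
  expect_false("g1" %in% rownames(f$counts))
  # vacuous filter keeps everything
  f0 <- filter_low_counts(cm, min_cpm = 0, min_samples = 0)
  expect_identical(rownames(f0$counts), rownames(cm$counts))
  # libraries (51, 50): gene2 has CPM 1/51*1e6 > 5000 in sample 1
  f2 <- filter_low_counts(cm, min_cpm = 5000, min_samples = 1)
  expect_true("g2" %in% rownames(f2$counts))
  expect_equal(ncol(f2$counts), 2)
})

test_that("log-CPM matches the direct formula", {
  cm <- make_cm(cbind(c(10, 90)), "stress")
  # library 100, prior 0: CPM 1e5 and 9e5
  lc <- log_cpm(cm, prior_count = 0)
  expect_equal(unname(lc[, 1]), c(log2(1e5), log2(9e5)))
  expect_equal(sum(2^lc[, 1]), 1e6)
  # prior 0.5, count 0, library 999
  cm2 <- make_cm(cbind(c(0, 999)), "stress")
  lc2 <- log_cpm(cm2, prior_count = 0.5)
  expect_equal(unname(lc2[1, 1]), log2(0.5 / 1000 * 1e6), tolerance = 1e-12)
})

test_that("moderated t reduces to the pooled two-sample t at d0 = 0", {
  cond <- rep(c("non-stress", "stress"), each = 4)
  set.seed(5)
  mat <- matrix(rnorm(800), nrow = 100,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:8)))
  st <- fit_moderated_t(mat, cond, prior_df = 0)
  ordinary <- apply(mat, 1, function(x) {
    t.test(x[cond == "stress"], x[cond == "non-stress"],
           var.equal = TRUE)$statistic
  })
  expect_equal(unname(st$t), unname(ordinary), tolerance = 1e-9)

  # hand-computed single-gene case: (1,2) vs (3,4)
  one <- matrix(c(1, 2, 3, 4), nrow = 1,
                dimnames = list("g1", paste0("s", 1:4)))
  st1 <- fit_moderated_t(one, c("non-stress", "non-stress", "stress", "stress"),
                         prior_df = 0)
  expect_equal(st1$log2fc, 2)
  expect_equal(st1$s2, 0.5)
  expect_equal(st1$t, 2.8284271, tolerance = 1e-6)

  # identical groups give t = 0
  flat <- matrix(c(1, 2, 1, 2), nrow = 1,
                 dimnames = list("g1", paste0("s", 1:4)))
  st2 <- fit_moderated_t(flat, c("non-stress", "non-stress",
                                 "stress", "stress"), prior_df = 0)
  expect_equal(st2$t, 0)
})

test_that("estimated-prior moderated t agrees with limma's eBayes", {
  cond <- rep(c("non-stress", "stress"), each = 5)
  set.seed(42)
  mat <- matrix(rnorm(2000, sd = rep(sqrt(rchisq(200, 4) / 4), 10)),
                nrow = 200,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:10)))
  st <- fit_moderated_t(mat, cond)
  design <- cbind(1, cond == "stress")
  eb <- limma::eBayes(limma::lmFit(mat, design))
  expect_equal(unname(st$t), unname(eb$t[, 2]), tolerance = 1e-6)
  expect_equal(unname(st$p), unname(eb$p.value[, 2]), tolerance = 1e-6)
  expect_equal(attr(st, "prior_df"), eb$df.prior, tolerance = 1e-6)
})

test_that("posterior variance lies between s2 and the prior variance", {
  cond <- rep(c("non-stress", "stress"), each = 4)
  set.seed(7)
  mat <- matrix(rnorm(1600, sd = rep(c(0.2, 3), each = 100)), nrow = 200,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:8)))
  st <- fit_moderated_t(mat, cond)
  s02 <- attr(st, "prior_var")
  lo <- pmin(st$s2, s02) - 1e-12
  hi <- pmax(st$s2, s02) + 1e-12
  expect_true(all(st$s2_post >= lo & st$s2_post <= hi))
})

test_that("constant genes keep a positive posterior variance", {
  cond <- rep(c("non-stress", "stress"), each = 3)
  set.seed(11)
  mat <- rbind(matrix(rnorm(594), nrow = 99), 0)
  dimnames(mat) <- list(paste0("g", 1:100), paste0("s", 1:6))
  st <- suppressWarnings(fit_moderated_t(mat, cond))
  expect_gt(st$s2_post[100], 0)
  expect_true(is.finite(st$t[100]))
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  # order invariance
  set.seed(3)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
})

test_that("top_genes orders by raw p and respects alpha and max_n", {
  st <- data.frame(gene = c("a", "b", "c", "d"),
                   p = c(0.04, 0.001, 0.5, 0.01),
                   adj_p = c(0.05, 0.004, 0.5, 0.02))
  expect_equal(top_genes(st, alpha = 1), c("b", "d", "a", "c"))
  expect_equal(top_genes(st, alpha = 0.05), c("b", "d", "a"))
  expect_equal(top_genes(st, alpha = 0.05, max_n = 2), c("b", "d"))
  expect_equal(top_genes(st, alpha = 0), character(0))
})

test_that("gene list intersection preserves first-list order", {
  expect_equal(intersect_gene_lists(c("A", "B", "C"), c("B", "C", "D")),
               c("B", "C"))
  expect_equal(intersect_gene_lists(c("C", "A"), c("A", "C")), c("C", "A"))
  expect_equal(intersect_gene_lists(c("A"), c("B")), character(0))
})

test_that("planted genes survive selection and intersection", {
  des <- two_study_design(400, c(25, 25), paste0("gene", 1:19),
                          log2_fold_change = 4, nb_dispersion = 0.05,
                          seed = 12)
  sim <- simulate_two_study_counts(des)
  lists <- lapply(list(sim$study1, sim$study2), function(cm) {
    f <- filter_low_counts(cm, 1, 2)
    top_genes(fit_moderated_t(log_cpm(f, 0.5), f$condition), alpha = 0.05)
  })
  shared <- intersect_gene_lists(lists[[1]], lists[[2]])
  tp <- length(intersect(shared, sim$truth))
  sens <- tp / length(sim$truth)
  fdp <- if (length(shared) > 0) 1 - tp / length(shared) else 0
  expect_gte(sens, 0.9)
  expect_lte(fdp, 0.1)
})
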
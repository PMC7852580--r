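test_that("BH adjustment matches brute-force step-up on short vectors", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(51)
  for (len in 1:8) {
    for (rep in 1:20) {
      p <- round(runif(len), 3)
      expect_equal(bh_adjust(p), bh_bruteforce(p))
    }
  }
  # order preservation: sorted(adjusted) respects sorted(p)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_identical(order(adj[order(p)]), seq_along(p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("identical phase profiles give zero fold change everywhere", {
  m <- matrix(rep(c(10, 20, 30, 40, 50), 4), ncol = 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  design <- data.frame(sample_id = paste0("s", 1:4),
                       phase = rep(c("A", "B"), each = 2))
  res <- de_test(m, design, "A", "B")
  expect_equal(res$log2_fold_change, rep(0, 5))
  expect_true(all(res$p_value == 1))
  expect_error(de_test(m[, 1:3], design[1:3, ], "A", "B"), "2 replicates")
  expect_error(de_test(m[0, ], design, "A", "B"), "empty")
})

test_that("planted strong fold changes are recovered at the decision thresholds", {
  ep <- expression_sim_params(n_genes = 1000,
                              phases = c("exponential", "stationary"),
                              replicates_per_phase = 3, de_fraction = 0.1,
                              log2fc_magnitude = 3, seed = 13)
  sim <- simulate_expression(ep)
  res <- de_classify(de_test(sim$counts, sim$design,
                             "exponential", "stationary"))
  planted <- sim$true_labels != "null"
  expect_gt(mean(res$direction[planted] != "not_de"), 0.9)
  # direction agrees with the planted sign for the recovered genes
  rec <- planted & res$direction != "not_de"
  expect_true(all(res$direction[rec & sim$true_labels == "up_first"] == "up_a"))
  expect_true(all(res$direction[rec & sim$true_labels == "up_last"] == "up_b"))
  # false positives at the stringent thresholds are rare
  expect_lt(mean(res$direction[!planted] != "not_de"), 0.01)
})

test_that("classification thresholds are strict and monotone", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2_fold_change = c(2, 3, -3, 1),
                    fdr = c(1e-4, 1e-4, 1e-4, 1e-4))
  cls <- de_classify(tab)
  expect_identical(cls$direction, c("not_de", "up_a", "up_b", "not_de"))
  expect_identical(unname(attr(cls, "counts")["total_de"]), 2L)
  # boundary FDR: fdr == threshold is not DE
  tab2 <- data.frame(gene_id = "x", log2_fold_change = 5, fdr = 1e-3)
  expect_identical(de_classify(tab2)$direction, "not_de")

  # monotonicity: relaxing thresholds never removes a call
  set.seed(61)
  rnd <- data.frame(gene_id = paste0("g", 1:200),
                    log2_fold_change = rnorm(200, sd = 3),
                    fdr = runif(200))
  strict <- de_classify(rnd, 2, 1e-3)
  loose <- de_classify(rnd, 1, 0.05)
  was_de <- strict$direction != "not_de"
  expect_true(all(loose$direction[was_de] != "not_de"))
})

test_that("phase means equal brute-force group means", {
  set.seed(71)
  m <- matrix(rexp(60, 1 / 100), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  design <- data.frame(sample_id = paste0("s", 1:6),
                       phase = rep(c("exp", "dil", "sta"), each = 2))
  pm <- phase_mean(m, design)
  for (ph in unique(design$phase)) {
    cols <- design$sample_id[design$phase == ph]
    expect_equal(pm[, ph], rowMeans(m[, cols]))
  }
  one <- phase_mean(m[, 1, drop = FALSE],
                    data.frame(sample_id = "s1", phase = "exp"))
  expect_equal(one[, "exp"], m[, 1])
  expect_error(phase_mean(m, design[-(1:2), ]), "without a phase")
})

test_that("high-expression selection uses a strict threshold on phase maxima", {
  pm <- rbind(border = c(499, 500, 500, 400, 300),
              onehigh = c(501, 1, 1, 1, 1),
              low = c(10, 20, 30, 40, 50))
  colnames(pm) <- paste0("ph", 1:5)
  expect_identical(highly_expressed_select(pm), "onehigh")
  set.seed(81)
  rnd <- matrix(runif(500, 0, 1000), nrow = 100,
                dimnames = list(paste0("g", 1:100), paste0("ph", 1:5)))
  sel <- highly_expressed_select(rnd, threshold = 600)
  expect_setequal(sel, rownames(rnd)[apply(rnd, 1, max) > 600])
})

test_that("highly expressed genes partition into three exhaustive classes", {
  cls <- data.frame(gene_id = paste0("g", 1:10),
                    direction = c(rep("up_a", 3), rep("up_b", 3),
                                  rep("not_de", 4)))
  part <- partition_heg(paste0("g", 1:10), cls)
  expect_identical(unname(part$sizes), c(3L, 3L, 4L))
  expect_identical(sum(part$sizes), 10L)
  expect_length(intersect(part$up_a, part$up_b), 0)
  empty <- partition_heg(character(0), cls)
  expect_identical(sum(empty$sizes), 0L)
  expect_error(partition_heg("missing", cls), "missing from the DE results")
})

test_that("functional aggregation sums member genes and normalizes to row maxima", {
  pm <- rbind(g1 = c(100, 50, 25), g2 = c(300, 150, 75), g3 = c(10, 20, 40))
  colnames(pm) <- c("exp", "dil", "sta")
  cmap <- data.frame(gene_id = c("g1", "g2", "g3"),
                     cellular_function = c("fA", "fA", "fB"))
  agg <- functional_aggregate(pm, cmap)
  a <- agg[agg$category == "fA", ]
  expect_equal(a$tpm_exp, 400)
  expect_equal(a$tpm_sta, 100)
  expect_equal(a$pct_exp, 100)
  expect_equal(a$pct_sta, 25)
  expect_equal(a$max_tpm, 400)
  b <- agg[agg$category == "fB", ]
  expect_equal(b$pct_sta, 100)  # single-gene category peaks where it peaks
  expect_equal(b$max_tpm, 40)
  # every row's maximum percentage is exactly 100
  pct <- as.matrix(agg[, grep("^pct_", names(agg))])
  expect_equal(unname(apply(pct, 1, max)), rep(100, nrow(agg)))
  expect_error(functional_aggregate(pm, cmap[-1, ]), "without a category")
})

test_that("sample correlations are symmetric with unit diagonal and honest NAs", {
  set.seed(91)
  m <- matrix(rnorm(300), nrow = 50)
  colnames(m) <- paste0("s", 1:6)
  m[, 2] <- m[, 1]                      # duplicated sample
  m[, 3] <- 2 * mean(m[, 1]) - m[, 1]   # negation about the mean
  r <- sample_correlation(m)
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 6))
  # brute-force covariance formula on one pair
  i <- m[, 4]; j <- m[, 5]
  expect_equal(r[4, 5],
               sum((i - mean(i)) * (j - mean(j))) /
                 sqrt(sum((i - mean(i))^2) * sum((j - mean(j))^2)))
  m[, 6] <- 7  # zero variance
  r2 <- sample_correlation(m)
  expect_true(all(is.na(r2[, 6])))
  expect_false(any(r2[, 6] %in% 0))
})
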
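test_that("longest isoform keeps one maximal-length record per gene", {
  tab <- make_curation_fixture()
  out <- longest_isoform(tab)
  expect_identical(nrow(out), length(unique(tab$gene_id)))
  expect_identical(out$transcript_id[out$gene_id == "g1"], "t1b")  # 500 > 300
  # equal-length tie: lexicographically smaller id wins
  expect_identical(out$transcript_id[out$gene_id == "g3"], "t3a")
  expect_identical(nrow(longest_isoform(longest_isoform(tab))), nrow(out))
})

test_that("longest isoform matches brute force on random tables", {
  set.seed(21)
  for (rep in 1:5) {
    n_genes <- 100L
    iso <- sample(1:4, n_genes, replace = TRUE)
    df <- data.frame(
      gene_id = rep(sprintf("g%03d", 1:n_genes), iso),
      stringsAsFactors = FALSE)
    df$transcript_id <- paste0(df$gene_id, "_t", unlist(lapply(iso, seq_len)))
    df$length <- sample(100:1000, nrow(df), replace = TRUE)
    tab <- transcript_table(df)
    out <- longest_isoform(tab)
    expect_identical(nrow(out), n_genes)
    # brute force: per gene, max length then min id
    for (g in sample(df$gene_id, 10)) {
      sub <- df[df$gene_id == g, ]
      best <- sub[sub$length == max(sub$length), ]
      expect_identical(out$transcript_id[out$gene_id == g],
                       min(best$transcript_id))
    }
  }
})

test_that("evidence filter keeps any positive evidence then drops contaminants", {
  df <- expand.grid(genome_hit = c(TRUE, FALSE),
                    transcriptome_hit = c(TRUE, FALSE),
                    eukaryote_annotation = c(TRUE, FALSE),
                    contaminant = c(TRUE, FALSE))
  df$transcript_id <- sprintf("t%02d", seq_len(nrow(df)))
  df$gene_id <- df$transcript_id
  df$length <- 100
  tab <- transcript_table(df)
  out <- evidence_filter(tab)
  expected <- with(df, (genome_hit | transcriptome_hit |
                          eukaryote_annotation) & !contaminant)
  expect_setequal(out$transcript_id, df$transcript_id[expected])
  # t01 is a contaminant with full positive evidence: the second pass drops it
  expect_false("t01" %in% out$transcript_id)
  expect_identical(nrow(evidence_filter(out)), nrow(out))  # idempotent
})

test_that("prevalence filter counts appearances and removed signal", {
  tab <- make_curation_fixture()
  res <- prevalence_filter(tab, min_samples = 3)
  # t2a appears in 1 sample, t3a in 1, t3b in 1: all dropped
  expect_false(any(c("t2a", "t3a", "t3b") %in% res$table$transcript_id))
  expect_true(all(c("t1a", "t1b", "t4a", "t5a") %in% res$table$transcript_id))
  counts <- as.matrix(as.data.frame(tab)[, attr(tab, "sample_cols")])
  dropped <- tab$transcript_id %in% c("t2a", "t3a", "t3b")
  expect_equal(res$removed_signal_fraction,
               sum(counts[dropped, ]) / sum(counts))

  all_kept <- prevalence_filter(tab, min_samples = 0)
  expect_identical(nrow(all_kept$table), nrow(tab))
  expect_equal(all_kept$removed_signal_fraction, 0)
  expect_error(prevalence_filter(tab, min_samples = 10), "exceeds")
  # idempotent
  again <- prevalence_filter(res$table, min_samples = 3)
  expect_identical(nrow(again$table), nrow(res$table))
  expect_equal(again$removed_signal_fraction, 0)
})

test_that("multi-ORF transcripts split only on discordant functions", {
  tab <- make_curation_fixture()
  out <- split_multi_orf(tab)
  # t2a has funcA;funcB -> split into two parts
  expect_true(all(c("t2a_p1", "t2a_p2") %in% out$transcript_id))
  expect_false("t2a" %in% out$transcript_id)
  # t3a has funcA;funcA -> not split
  expect_true("t3a" %in% out$transcript_id)
  # 0 or 1 ORF -> unchanged
  expect_true(all(c("t1a", "t1b", "t4a", "t5a") %in% out$transcript_id))
  expect_identical(nrow(out), nrow(tab) + 1L)
  # split parts inherit the parent counts
  parent <- as.data.frame(tab)[tab$transcript_id == "t2a", c("s1", "s2")]
  child <- as.data.frame(out)[out$transcript_id == "t2a_p1", c("s1", "s2")]
  expect_equal(unname(unlist(child)), unname(unlist(parent)))
  expect_identical(nrow(split_multi_orf(out)), nrow(out))  # idempotent
})

test_that("split accounting reproduces record expansion exactly", {
  expect_identical(split_accounting(15123, c("2" = 866, "3" = 92, "4" = 12)),
                   16209L)
  expect_identical(split_accounting(42), 42L)
  expect_error(split_accounting(10, c("1" = 5)), ">= 2")

  # oracle: expanding records one by one gives the same total
  set.seed(31)
  for (rep in 1:20) {
    n_base <- sample(50:500, 1)
    parts <- sample(2:5, sample(0:3, 1))
    hist <- vapply(parts, function(p) sample(1:20, 1), integer(1))
    names(hist) <- parts
    if (length(hist) == 0L || sum(hist) > n_base) {
      expect_identical(split_accounting(n_base), as.integer(n_base))
      next
    }
    # oracle: expand each split transcript into its parts, count records
    expanded <- n_base - sum(hist) +
      sum(rep(as.integer(names(hist)), hist))
    expect_identical(split_accounting(n_base, as.list(hist)),
                     as.integer(expanded))
  }
})

test_that("split accounting agrees with split_multi_orf on a fixture", {
  tab <- make_curation_fixture()
  orfs <- strsplit(tab$orf_functions, ";", fixed = TRUE)
  splitters <- lengths(orfs) >= 2 &
    vapply(orfs, function(x) length(unique(x)) > 1, logical(1))
  hist <- table(lengths(orfs)[splitters])
  expect_identical(split_accounting(nrow(tab), as.list(hist)),
                   nrow(split_multi_orf(tab)))
})

test_that("TPM normalizes each sample to one million with length correction", {
  expect_equal(unname(compute_tpm(cbind(s = c(5, 5)), c(100, 100))[, 1]),
               c(5e5, 5e5))
  expect_equal(unname(compute_tpm(cbind(s = c(10, 90)), c(1000, 3000))[, 1]),
               c(250000, 750000))
  set.seed(41)
  counts <- matrix(rpois(200, 50), nrow = 20,
                   dimnames = list(NULL, paste0("s", 1:10)))
  counts[, 3] <- 0
  tpm <- compute_tpm(counts, sample(500:5000, 20))
  sums <- colSums(tpm)
  expect_equal(unname(sums[-3]), rep(1e6, 9), tolerance = 1e-6)
  expect_equal(unname(sums[3]), 0)
  expect_identical(attr(tpm, "zero_samples"), "s3")
  expect_error(compute_tpm(counts, rep(0, 20)), "positive")
})

test_that("the curation chain reconciles counts at every stage", {
  tab <- make_curation_fixture()
  cur <- curate_transcripts(tab, min_samples = 3)
  r <- cur$report
  expect_identical(r$n_input, nrow(tab))
  expect_true(r$n_after_isoform <= r$n_input)
  expect_true(r$n_after_evidence <= r$n_after_isoform)
  expect_true(r$n_after_prevalence <= r$n_after_evidence)
  expect_true(r$n_after_contaminant <= r$n_after_prevalence)
  expect_true(r$n_after_split >= r$n_after_contaminant)
  expect_identical(r$n_after_split, nrow(cur$table))
  expect_true(r$removed_signal_fraction >= 0 &&
                r$removed_signal_fraction <= 1)
})
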
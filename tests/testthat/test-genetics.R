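toy_altmat <- function() {
  cna <- cna_matrix(matrix(
    c(2L, 0L, -1L,   # CDK4:  amp, none, het
      0L, -2L, 0L,   # RB1
      0L, 0L, 0L),   # BG
    nrow = 3, byrow = TRUE,
    dimnames = list(c("CDK4", "RB1", "BG"), c("s1", "s2", "s3"))))
  mut <- data.frame(sample_id = c("s1", "s3"), gene_id = c("CDK4", "RB1"),
                    variant_class = c("missense", "truncating"),
                    stringsAsFactors = FALSE)
  call_alterations(cna, mut)
}

test_that("alteration calling applies the event-class rules", {
  am <- toy_altmat()
  expect_equal(am$calls["CDK4", "s1"], "multiple")     # amp + missense
  expect_equal(am$calls["CDK4", "s3"], "het_loss")
  expect_equal(am$calls["RB1", "s2"], "deep_deletion")
  expect_equal(am$calls["RB1", "s3"], "mutation")
  expect_equal(am$calls["BG", "s1"], "none")
  # frequencies are exact column-count ratios
  expect_equal(am$freq$freq_amplification[am$freq$gene_id == "CDK4"], 1 / 3)
  expect_equal(am$freq$freq_mutation[am$freq$gene_id == "RB1"], 1 / 3)
  expect_equal(am$freq$freq_altered[am$freq$gene_id == "BG"], 0)
})

test_that("an all-diploid cohort calls none everywhere", {
  cna <- cna_matrix(matrix(0L, 2, 3, dimnames = list(c("A", "B"),
                                                     c("s1", "s2", "s3"))))
  mut <- data.frame(sample_id = character(0), gene_id = character(0),
                    variant_class = character(0), stringsAsFactors = FALSE)
  am <- call_alterations(cna, mut)
  expect_true(all(am$calls == "none"))
  expect_true(all(am$freq$freq_altered == 0))
  expect_error(pairwise_cooccurrence(am), "nonzero")
})

test_that("genes absent from both tables warn and produce all-none rows", {
  cna <- cna_matrix(matrix(0L, 1, 2, dimnames = list("A", c("s1", "s2"))))
  mut <- data.frame(sample_id = "s1", gene_id = "A",
                    variant_class = "missense", stringsAsFactors = FALSE)
  expect_warning(am <- call_alterations(cna, mut, c("A", "GHOST")), "GHOST")
  expect_true(all(am$calls["GHOST", ] == "none"))
})

test_that("co-occurrence grid is invariant to sample order and pair swap", {
  pc <- generate_pancancer(small_config(seed = 14))
  b <- pc$bundles[[1]]
  genes <- c("CCND1", "CDK4", "CDKN2A", "RB1")
  am <- call_alterations(b$cna, b$mutations, genes)
  grid <- pairwise_cooccurrence(am)
  perm <- sample(colnames(b$cna))
  am2 <- call_alterations(cna_matrix(b$cna[, perm]),
                          b$mutations, genes)
  grid2 <- pairwise_cooccurrence(am2)
  expect_equal(grid$or, grid2$or)
  expect_equal(grid$p, grid2$p)
  # swapping the pair leaves log OR unchanged (b/c swap transposes)
  swapped <- pairwise_cooccurrence(am, c("RB1", "CDKN2A"))
  orig <- grid[grid$gene_a == "CDKN2A" & grid$gene_b == "RB1", ]
  expect_equal(swapped$log_or, orig$log_or)
  expect_equal(swapped$p, orig$p)
})

test_that("planted mutual exclusivity is recovered at n=500", {
  cfg <- synthetic_config(n_cohorts = 1, n_samples = 500, seed = 1)
  b <- generate_pancancer(cfg)$bundles[[1]]
  am <- call_alterations(b$cna, b$mutations, c("CDKN2A", "RB1"))
  grid <- pairwise_cooccurrence(am)
  expect_lt(grid$or, 1)
  expect_lt(grid$p, 0.05)
  expect_equal(grid$call, "mutually_exclusive")
})

test_that("a never-altered gene yields an NA odds ratio entry", {
  cna <- cna_matrix(matrix(c(2L, 0L, 2L, 0L, 0L, 0L, 0L, 0L), 2,
                           byrow = TRUE,
                           dimnames = list(c("A", "B"),
                                           c("s1", "s2", "s3", "s4"))))
  mut <- data.frame(sample_id = "s2", gene_id = "A",
                    variant_class = "missense", stringsAsFactors = FALSE)
  am <- call_alterations(cna, mut)
  grid <- pairwise_cooccurrence(am)
  expect_true(is.na(grid$or))
  expect_true(is.finite(grid$p))
})

test_that("heterozygous loss can be included as altered by flag", {
  cna <- cna_matrix(matrix(c(-1L, 0L, -1L, 0L,
                             0L, -1L, 0L, 0L), 2, byrow = TRUE,
                           dimnames = list(c("A", "B"),
                                           c("s1", "s2", "s3", "s4"))))
  mut <- data.frame(sample_id = character(0), gene_id = character(0),
                    variant_class = character(0), stringsAsFactors = FALSE)
  am <- call_alterations(cna, mut)
  expect_error(pairwise_cooccurrence(am), "nonzero")
  grid <- pairwise_cooccurrence(am, classes = c("amplification",
                                                "deep_deletion", "het_loss",
                                                "mutation"))
  expect_equal(grid$a + grid$b, 2)  # A altered in two samples
})

test_that("cohort clustering on frequency profiles recovers separated cohorts", {
  freq <- rbind(c(80, 2, 1, 1), c(2, 81, 2, 1), c(1, 1, 79, 3),
                c(2, 1, 2, 82), c(40, 41, 2, 1))
  rownames(freq) <- paste0("C", 1:5)
  colnames(freq) <- c("CCND1", "CDK4", "RB1", "CDKN2A")
  fit <- cluster_cohorts(freq, k = 5, seed = 2)
  expect_equal(sort(unique(fit$labels)), 1:5)
  expect_false(fit$degenerate)
  refit <- cluster_cohorts(freq, k = 5, seed = 2)
  expect_identical(fit$labels, refit$labels)
  expect_error(cluster_cohorts(freq[1:3, ], k = 5), "fewer cohorts")
  ident <- freq[rep(1, 5), ]
  expect_warning(dfit <- cluster_cohorts(ident, k = 5, seed = 1),
                 "distinct")
  expect_true(dfit$degenerate)
})

test_that("CDKN2A-RB1 expression anti-correlation is planted and recovered", {
  cfg <- synthetic_config(n_cohorts = 1, n_samples = 300, seed = 4)
  b <- generate_pancancer(cfg)$bundles[[1]]
  res <- expression_pair_correlation(b$expr, "CDKN2A", "RB1")
  expect_lt(res$r, 0)
  expect_lt(res$p, 0.05)
  self <- expression_pair_correlation(b$expr, "RB1", "RB1")
  expect_equal(self$r, 1)
})
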
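test_that("CPM normalisation follows the definition and conserves totals", {
  m <- matrix(c(10L, 90L, 10L, 999990L), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- cpm_normalize(m)
  expect_equal(cpm["g1", "s1"], 1e5)
  expect_equal(cpm["g2", "s1"], 9e5)
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  expect_equal(attr(cpm, "unit"), "cpm")
  zero <- matrix(c(1L, 0L), 1, dimnames = list("g", c("a", "b")))
  expect_error(cpm_normalize(zero), "zero library")
})

test_that("repression filter keeps logFC <= -1 with p < 0.05", {
  # treated CPM 25 vs control 100, tight replicates -> logFC ~ -2
  cpm <- expression_matrix(
    matrix(c(25, 25.2, 24.8, 100, 100.5, 99.5,
             50, 50.1, 49.9, 50.2, 49.8, 50),
           nrow = 2, byrow = TRUE,
           dimnames = list(c("down", "flat"),
                           c("t1", "t2", "t3", "c1", "c2", "c3"))),
    unit = "cpm")
  hits <- repressed_genes(cpm, c("t1", "t2", "t3"), c("c1", "c2", "c3"),
                          pseudocount = 0.001)
  expect_equal(hits$gene_id, "down")
  expect_equal(hits$log2_fc, -2, tolerance = 0.01)
})

test_that("isogenic recovery of the planted repressed set is sensitive", {
  cfg <- synthetic_config(seed = 1)
  iso <- generate_isogenic_experiment(cfg)
  cpm <- cpm_normalize(iso$counts)
  gr <- iso$groups
  hits <- repressed_genes(cpm,
                          gr$column[gr$genotype == "parental" &
                                    gr$treatment == "drug"],
                          gr$column[gr$genotype == "parental" &
                                    gr$treatment == "vehicle"])
  planted <- c(iso$truth$rb_dependent, iso$truth$decoy,
               iso$truth$rb_independent)
  expect_gte(mean(planted %in% hits$gene_id), 0.9)
})

test_that("RB-dependency filter removes genes repressed in the knockout", {
  ko <- data.frame(gene_id = c("both", "par_only", "ko_weak"),
                   log2_fc = c(-2, 0.1, -0.4),
                   p = c(0.01, 0.8, 0.01), stringsAsFactors = FALSE)
  seed <- rb_dependency_filter(c("both", "par_only", "ko_weak"), ko)
  expect_setequal(seed, c("par_only", "ko_weak"))
  expect_warning(
    out <- rb_dependency_filter(c("both", "ghost"), ko), "ghost")
  expect_setequal(out, "ghost")
  # synthetic truth: no RB-independent gene survives the filter
  cfg <- synthetic_config(seed = 1)
  iso <- generate_isogenic_experiment(cfg)
  cpm <- cpm_normalize(iso$counts)
  gr <- iso$groups
  col_of <- function(g, t) gr$column[gr$genotype == g & gr$treatment == t]
  par_hits <- repressed_genes(cpm, col_of("parental", "drug"),
                              col_of("parental", "vehicle"))$gene_id
  ko_de <- de_table(cpm, col_of("rb1_null", "drug"),
                    col_of("rb1_null", "vehicle"))
  seed_genes <- rb_dependency_filter(par_hits, ko_de)
  expect_length(intersect(seed_genes, iso$truth$rb_independent), 0)
})

test_that("correlation pruning drops below-mean max-correlation genes", {
  # A and B perfectly correlated, C independent noise
  set.seed(30)
  a <- rnorm(60)
  m <- rbind(A = a, B = 2 * a + 5, C = rnorm(60))
  colnames(m) <- paste0("s", 1:60)
  expr <- expression_matrix(m, unit = "log2")
  model <- correlation_prune(c("A", "B", "C"), expr)
  expect_equal(unname(model$max_corr[c("A", "B")]), c(1, 1))
  expect_lt(model$max_corr[["C"]], 0.5)
  expect_equal(model$pruned_genes, "C")
  expect_setequal(model$genes, c("A", "B"))
})

test_that("equal mutual correlation prunes nothing (boundary tie rule)", {
  # three copies of one latent signal: all max correlations equal
  set.seed(31)
  z <- rnorm(80)
  m <- rbind(A = z, B = z + 1, C = 2 * z)
  colnames(m) <- paste0("s", 1:80)
  model <- correlation_prune(c("A", "B", "C"),
                             expression_matrix(m, unit = "log2"))
  expect_length(model$pruned_genes, 0)
  expect_setequal(model$genes, c("A", "B", "C"))
})

test_that("pruning removes planted decoys but no program gene", {
  cfg <- synthetic_config(seed = 1, program_cor = 0.6)
  clin <- generate_clinical_expression(cfg, n_samples = 2000)
  prog <- sprintf("PROG_%03d", 1:50)
  dec <- sprintf("DECOY_%03d", 1:20)
  model <- correlation_prune(c(prog, dec), clin)
  expect_setequal(model$pruned_genes, dec)
  expect_setequal(model$genes, prog)
  expect_message(correlation_prune(c(prog, "GHOST"), clin), "GHOST")
})

test_that("scores are z-score means with the documented invariances", {
  set.seed(33)
  m <- matrix(rnorm(5 * 40, 8), 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:40)))
  expr <- expression_matrix(m, unit = "log2")
  sc <- score_samples(expr, paste0("g", 1:5))
  # scores are exactly the per-sample means of gene z-scores
  zs <- t(scale(t(m)))
  expect_equal(sc$score, unname(colMeans(zs)))
  # affine rescaling of one gene leaves scores unchanged
  m3 <- m
  m3[2, ] <- 7 * m3[2, ] - 100
  sc3 <- score_samples(expression_matrix(m3, unit = "log2"),
                       paste0("g", 1:5))
  expect_equal(sc3$score, sc$score, tolerance = 1e-12)
  # duplicating the cohort rescales every z-score by the same sample-sd
  # factor sqrt(2(n-1)/(2n-1)); scores change only by that common scale
  m4 <- cbind(m, m)
  colnames(m4) <- c(colnames(m), paste0(colnames(m), "_dup"))
  sc4 <- score_samples(expression_matrix(m4, unit = "log2"),
                       paste0("g", 1:5))
  scale_fac <- sqrt(2 * (40 - 1) / (2 * 40 - 1))
  expect_equal(sc4$score[1:40], sc$score / scale_fac, tolerance = 1e-12)
})

test_that("score coverage below threshold is an error listing missing genes", {
  m <- matrix(rnorm(2 * 10, 8), 2,
              dimnames = list(c("g1", "g2"), paste0("s", 1:10)))
  expr <- expression_matrix(m, unit = "log2")
  expect_error(score_samples(expr, c("g1", "g2", "x1", "x2", "x3")),
               "x1")
  # at 50% coverage it proceeds
  sc <- score_samples(expr, c("g1", "g2", "x1", "x2"))
  expect_equal(attr(sc, "genes_missing"), c("x1", "x2"))
})

test_that("stratification is the 25/50/25 quantile cut with tie handling", {
  sc <- data.frame(sample_id = paste0("s", 1:8), score = 1:8)
  strat <- rbpath:::.stratify_scores(sc$score)
  expect_equal(as.character(strat),
               c("low25", "low25", "mid50", "mid50", "mid50", "mid50",
                 "high25", "high25"))
  expect_error(rbpath:::.stratify_scores(rep(1, 10)), "stratification failed")
  # sizes: |low| = floor(n/4) +- 1
  set.seed(40)
  for (n in c(17, 50, 203)) {
    s <- rnorm(n)
    st <- rbpath:::.stratify_scores(s)
    expect_lte(abs(sum(st == "low25") - floor(n * 0.25)), 1)
    expect_lte(abs(sum(st == "high25") - floor(n * 0.25)), 1)
  }
})

test_that("high signature scores mark program-active tumours and worse survival", {
  cfg <- synthetic_config(n_cohorts = 1, n_samples = 400, seed = 1)
  pc <- generate_pancancer(cfg)
  b <- pc$bundles[[1]]
  sc <- score_samples(b$expr, pc$truth$program_genes)
  active <- pc$truth$cohorts[[1]]$rb1_lost
  # AUC of score for active vs inactive
  r <- rank(sc$score)
  n1 <- sum(active)
  auc <- (sum(r[active]) - n1 * (n1 + 1) / 2) / (n1 * (sum(!active)))
  expect_gte(auc, 0.9)
  res <- stratify_and_compare(sc, b$clinical, "dfs")
  expect_lt(res$survival$p, 0.05)
})

test_that("derive_signature composes the full chain with provenance", {
  cfg <- synthetic_config(seed = 1)
  iso <- generate_isogenic_experiment(cfg)
  clin <- generate_clinical_expression(cfg, n_samples = 2000)
  model <- derive_signature(iso$counts, iso$groups, clin)
  expect_s3_class(model, "signature_model")
  jac <- length(intersect(model$genes, iso$truth$rb_dependent)) /
    length(union(model$genes, iso$truth$rb_dependent))
  expect_gte(jac, 0.8)
  expect_length(intersect(model$genes, iso$truth$rb_independent), 0)
  expect_true(model$provenance$n_seed >= length(model$genes))
  # predict() scores a cohort with the fitted model
  pc <- generate_pancancer(cfg)
  sc <- predict(model, pc$bundles[[1]]$expr)
  expect_s3_class(sc, "score_table")
  expect_equal(nrow(sc), ncol(pc$bundles[[1]]$expr))
})
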
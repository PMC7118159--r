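make_profile <- function(seed = 1) {
  cfg <- synthetic_config(n_cohorts = 1, n_samples = 300, seed = seed)
  pc <- generate_pancancer(cfg)
  b <- pc$bundles[[1]]
  sc <- score_samples(b$expr, pc$truth$program_genes)
  list(profile = genewise_correlation(b$expr, sc), truth = pc$truth,
       bundle = b, scores = sc)
}

test_that("gene-wise correlation behaves as planted", {
  pr <- make_profile(3)
  profile <- pr$profile
  prog_cc <- profile$cc[profile$gene_id %in% pr$truth$program_genes]
  other_cc <- profile$cc[grepl("^BG_", profile$gene_id)]
  expect_gt(min(prog_cc), 0.3)          # signature genes track their score
  expect_gt(mean(prog_cc), 0.5)
  expect_lt(mean(abs(other_cc)), 0.2)   # background genes do not
  # permuted sample labels centre the correlations on zero
  sc_perm <- pr$scores
  set.seed(9)
  sc_perm$score <- sample(sc_perm$score)
  prof_perm <- genewise_correlation(pr$bundle$expr, sc_perm)
  expect_lt(abs(mean(prof_perm$cc)), 0.05)
})

test_that("constant genes are excluded from the correlation profile", {
  m <- matrix(rnorm(40, 8), 4, dimnames = list(paste0("g", 1:4),
                                               paste0("s", 1:10)))
  m[2, ] <- 5
  expr <- expression_matrix(m, unit = "log2")
  sc <- data.frame(sample_id = paste0("s", 1:10), score = rnorm(10))
  expect_message(prof <- genewise_correlation(expr, sc), "constant")
  expect_false("g2" %in% prof$gene_id)
})

test_that("bootstrap cutoffs match an oracle resampler under the seed contract", {
  profile <- data.frame(gene_id = paste0("g", 1:10),
                        cc = c(-0.8, -0.3, -0.1, 0, 0.05, 0.1, 0.2, 0.4,
                               0.6, 0.9),
                        p = rep(0.01, 10))
  expect_warning(co <- bootstrap_cutoffs(profile, n_boot = 4, seed = 11),
                 "unstable")
  # oracle: same seeded generator contract (one sample() call of size
  # n * n_boot), quantiles computed independently
  set.seed(11)
  draws <- sample(profile$cc, 10 * 4, replace = TRUE)
  expect_equal(co$lower, unname(quantile(draws, 0.025)))
  expect_equal(co$upper, unname(quantile(draws, 0.975)))
  # degenerate profile: all CC equal -> lower = upper, nothing selected
  flat <- data.frame(gene_id = paste0("g", 1:12), cc = rep(0.3, 12),
                     p = rep(0.001, 12))
  co_flat <- suppressWarnings(bootstrap_cutoffs(flat, n_boot = 50, seed = 1))
  expect_equal(co_flat$lower, 0.3)
  expect_equal(co_flat$upper, 0.3)
  sel <- select_correlated(flat, co_flat)
  expect_true(all(sel$selected == "none"))
})

test_that("cutoffs from a symmetric profile are symmetric within Monte-Carlo error", {
  set.seed(21)
  cc <- c(rnorm(1000, 0, 0.3))
  cc <- c(cc, -cc)  # exactly symmetric
  profile <- data.frame(gene_id = paste0("g", seq_along(cc)), cc = cc,
                        p = rep(0.5, length(cc)))
  co <- bootstrap_cutoffs(profile, n_boot = 10000, seed = 2)
  # 3 SE of an empirical 2.5% quantile at this resample depth
  expect_lt(abs(co$lower + co$upper), 0.01)
  # convergence: pooled percentiles stabilise with n_boot
  co2 <- bootstrap_cutoffs(profile, n_boot = 20000, seed = 3)
  expect_lt(abs(co$lower - co2$lower), 0.01)
  expect_lt(abs(co$upper - co2$upper), 0.01)
})

test_that("selection requires both a cutoff exceedance and p < 0.05", {
  profile <- data.frame(gene_id = c("pos", "pos_ns", "neg", "mid"),
                        cc = c(0.8, 0.8, -0.9, 0.1),
                        p = c(0.001, 0.5, 0.001, 0.001))
  co <- structure(list(lower = -0.5, upper = 0.5), class = "bootstrap_cutoffs")
  sel <- select_correlated(profile, co)
  expect_equal(sel$selected, c("positive", "none", "negative", "none"))
})

test_that("GSEA weights follow W = CC * (-log10 p) with stable ordering", {
  profile <- data.frame(gene_id = c("a", "b", "c"),
                        cc = c(0.5, -0.4, 0.3),
                        p = c(0.01, 0.1, 1), stringsAsFactors = FALSE)
  rk <- gsea_weights(profile)
  expect_equal(rk$w[rk$gene_id == "a"], 1.0)
  expect_equal(rk$w[rk$gene_id == "b"], -0.4)
  expect_equal(rk$w[rk$gene_id == "c"], 0)
  expect_equal(rk$gene_id, c("a", "c", "b"))  # sorted by W descending
  # ordering invariant to input order; ties broken by gene id
  tied <- data.frame(gene_id = c("z", "y", "x"), cc = c(0.2, 0.2, 0.9),
                     p = c(0.1, 0.1, 0.001))
  rk1 <- gsea_weights(tied)
  rk2 <- gsea_weights(tied[c(3, 1, 2), ])
  expect_identical(rk1, rk2)
  expect_equal(rk1$gene_id, c("x", "y", "z"))
  # p = 0 floored and flagged
  z <- data.frame(gene_id = "g", cc = 0.5, p = 0)
  expect_warning(rkz <- gsea_weights(z), "floored")
  expect_true(rkz$p_floored)
  expect_equal(rkz$w, 0.5 * 300)
})

test_that("pre-ranked ES equals the brute-force running sum on small lists", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(10:12, 1)
    w <- sort(round(rnorm(n, 0, 2), 2), decreasing = TRUE)
    ranked <- data.frame(gene_id = sprintf("G%02d", 1:n), w = w,
                         stringsAsFactors = FALSE)
    members <- sample(ranked$gene_id, sample(2:(n - 1), 1))
    res <- preranked_gsea(ranked, list(S = members), n_perm = 10, seed = 1)
    expect_equal(res$es,
                 brute_force_es(w, ranked$gene_id %in% members),
                 tolerance = 1e-12)
  }
})

test_that("permutation p at full enumeration matches the sampled estimate", {
  # 10 genes, set size 2: only 45 distinct member placements
  w <- c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5)
  ranked <- data.frame(gene_id = letters[1:10], w = w,
                       stringsAsFactors = FALSE)
  obs <- preranked_gsea(ranked, list(S = c("a", "b")), n_perm = 4000,
                        seed = 7)
  combos <- combn(10, 2)
  enum_es <- apply(combos, 2, function(idx) {
    flag <- logical(10); flag[idx] <- TRUE
    brute_force_es(w, flag)
  })
  same <- enum_es[sign(enum_es) == sign(obs$es)]
  p_enum <- mean(abs(same) >= abs(obs$es))
  se <- sqrt(p_enum * (1 - p_enum) / 4000)
  expect_lt(abs(obs$p - p_enum), 3 * se + 2 / 4000)
})

test_that("degenerate sets are skipped and planted programs enrich", {
  pr <- make_profile(5)
  co <- bootstrap_cutoffs(pr$profile, n_boot = 2000, seed = 1)
  sel <- select_correlated(pr$profile, co)
  rk <- gsea_weights(sel)
  expect_gte(nrow(rk), 10)
  sets <- list(program = pr$truth$program_genes,
               whole_list = rk$gene_id,
               tiny = rk$gene_id[1])
  expect_message(res <- preranked_gsea(rk, sets, n_perm = 500, seed = 2),
                 "skipped")
  expect_equal(res$set_name, "program")
  expect_gt(res$es, 0)
  expect_lt(res$p, 0.05)
  expect_true(all(res$leading_edge[[1]] %in% pr$truth$program_genes))
  # byte-reproducible under the seed
  res2 <- preranked_gsea(rk, sets["program"], n_perm = 500, seed = 2)
  expect_identical(res$es, res2$es)
  expect_identical(res$p, res2$p)
})

test_that("ES agrees with fgsea on a moderate ranked list", {
  skip_if_not_installed("fgsea")
  pr <- make_profile(2)
  prof <- pr$profile
  rk <- gsea_weights(prof)  # full profile, no selection column
  stats <- setNames(rk$w, rk$gene_id)
  # fgsea requires distinct gene-level stats for exact ES agreement; add
  # deterministic jitter to break ties identically for both methods
  stats <- stats + seq_along(stats) * 1e-9
  ranked <- data.frame(gene_id = names(stats), w = unname(stats),
                       stringsAsFactors = FALSE)
  sets <- list(prog = pr$truth$program_genes[1:20],
               bg = sprintf("BG_%03d", 1:30))
  ours <- preranked_gsea(ranked, sets, n_perm = 10, seed = 1)
  ref <- suppressWarnings(
    fgsea::fgsea(sets, stats, nPermSimple = 10, scoreType = "std"))
  expect_equal(ours$es[match(ref$pathway, ours$set_name)], ref$ES,
               tolerance = 1e-6)
})

test_that("correlation-profile clustering separates anti-correlated programs", {
  set.seed(44)
  m <- rbind(matrix(rnorm(40 * 4, 0.7, 0.05), 40),
             matrix(rnorm(40 * 4, -0.6, 0.05), 40))
  rownames(m) <- paste0("g", 1:80)
  res <- cluster_correlation_matrix(m, k = 2)
  expect_equal(length(unique(res$labels[1:40])), 1)
  expect_equal(length(unique(res$labels[41:80])), 1)
  expect_true(res$labels[1] != res$labels[41])
  km <- cluster_correlation_matrix(m, k = 2, seed = 9, method = "kmeans")
  km2 <- cluster_correlation_matrix(m, k = 2, seed = 9, method = "kmeans")
  expect_identical(km$labels, km2$labels)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(res$labels,
                                         rep(1:2, each = 40)), 1)
  # NA imputation is recorded; identical rows flag degeneracy
  m[1, 2] <- NA
  res_na <- cluster_correlation_matrix(m, k = 2)
  expect_true(res_na$na_mask[1, 2])
  ident <- m[rep(1, 5), ]
  ident[is.na(ident)] <- 0
  expect_warning(dg <- cluster_correlation_matrix(ident, k = 2), "distinct")
  expect_true(dg$degenerate)
})
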
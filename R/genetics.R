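## Core-pathway genetics: alteration calling from discrete CNA + mutation
## tables, per-gene frequency summaries, pairwise co-occurrence /
## mutual-exclusivity odds-ratio testing, and k-means clustering of
## cohorts on pathway alteration frequencies.

#' Call per-gene somatic alterations for a cohort
#'
#' Default rules: amplification = CNA +2; deep deletion = CNA -2;
#' heterozygous loss = CNA -1 (tracked as its own class); mutation = any
#' non-silent mutation row. A gene/sample hit by two or more distinct
#' event classes is called `multiple`. Heterozygous loss is tracked but by
#' default excluded from the "altered" definition used in exclusivity
#' testing; see [pairwise_cooccurrence()].
#'
#' @param cna A [cna_matrix()].
#' @param mutations Mutation data frame (`sample_id`, `gene_id`,
#'   `variant_class`).
#' @param gene_list Genes to call (default: all genes in the CNA matrix).
#' @return An `alteration_matrix`: per-gene/sample categorical `calls`,
#'   component indicator matrices, and a per-gene frequency table.
#' @export
call_alterations <- function(cna, mutations, gene_list = rownames(cna)) {
  samples <- colnames(cna)
  n <- length(samples)
  comp <- list()
  for (g in gene_list) {
    if (!(g %in% rownames(cna)) &&
        !(g %in% mutations$gene_id)) {
      warning("gene '", g, "' absent from CNA and mutation tables; all-none row")
    }
  }
  getrow <- function(g) {
    if (g %in% rownames(cna)) cna[g, ] else rep(0L, n)
  }
  is_amp <- t(vapply(gene_list, function(g) getrow(g) == 2L, logical(n)))
  is_deep <- t(vapply(gene_list, function(g) getrow(g) == -2L, logical(n)))
  is_het <- t(vapply(gene_list, function(g) getrow(g) == -1L, logical(n)))
  is_mut <- t(vapply(gene_list, function(g) {
    samples %in% mutations$sample_id[mutations$gene_id == g]
  }, logical(n)))
  dimnames(is_amp) <- dimnames(is_deep) <- dimnames(is_het) <-
    dimnames(is_mut) <- list(gene_list, samples)

  n_classes <- is_amp + is_deep + is_het + is_mut
  calls <- matrix("none", nrow = length(gene_list), ncol = n,
                  dimnames = list(gene_list, samples))
  calls[is_amp] <- "amplification"
  calls[is_deep] <- "deep_deletion"
  calls[is_het] <- "het_loss"
  calls[is_mut] <- "mutation"
  calls[n_classes >= 2] <- "multiple"

  freq <- data.frame(
    gene_id = gene_list,
    freq_amplification = rowMeans(is_amp),
    freq_deep_deletion = rowMeans(is_deep),
    freq_het_loss = rowMeans(is_het),
    freq_mutation = rowMeans(is_mut),
    freq_altered = rowMeans(is_amp | is_deep | is_mut),
    stringsAsFactors = FALSE)
  rownames(freq) <- NULL

  structure(list(calls = calls, is_amp = is_amp, is_deep = is_deep,
                 is_het = is_het, is_mut = is_mut, freq = freq,
                 n_samples = n),
            class = "alteration_matrix")
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat(sprintf("Alteration matrix: %d genes x %d samples\n",
              nrow(x$calls), x$n_samples))
  print(utils::head(x$freq, 10))
  invisible(x)
}

#' Per-sample altered indicator under a chosen class regime
#'
#' @param altmat An `alteration_matrix`.
#' @param classes Event classes counting as "altered". The default follows
#'   the exclusivity-testing convention (heterozygous loss excluded);
#'   include `"het_loss"` to analyse shallow loss as altered.
#' @return Logical samples x genes matrix.
#' @export
altered_mask <- function(altmat,
                         classes = c("amplification", "deep_deletion",
                                     "mutation")) {
  ok <- c("amplification", "deep_deletion", "het_loss", "mutation")
  if (!all(classes %in% ok)) stop("unknown alteration class")
  m <- matrix(FALSE, nrow = altmat$n_samples, ncol = nrow(altmat$calls),
              dimnames = list(colnames(altmat$calls), rownames(altmat$calls)))
  if ("amplification" %in% classes) m <- m | t(altmat$is_amp)
  if ("deep_deletion" %in% classes) m <- m | t(altmat$is_deep)
  if ("het_loss" %in% classes) m <- m | t(altmat$is_het)
  if ("mutation" %in% classes) m <- m | t(altmat$is_mut)
  m
}

#' Pairwise co-occurrence / mutual-exclusivity grid
#'
#' For every gene pair, a 2x2 table over altered/unaltered samples is
#' tested with [odds_ratio_test()] (sample odds ratio + two-sided Fisher
#' exact). Supply a list of alteration matrices to pool cohorts by plain
#' sample concatenation.
#'
#' @param altmat An `alteration_matrix`, or a list of them to pool.
#' @param genes Genes to test (default: all called genes); at least two
#'   must have nonzero alteration counts.
#' @param classes Alteration classes counting as altered.
#' @return Data frame with one row per unordered pair: cells, `or`,
#'   `log_or`, `p`, `call`.
#' @export
pairwise_cooccurrence <- function(altmat, genes = NULL,
                                  classes = c("amplification",
                                              "deep_deletion", "mutation")) {
  if (inherits(altmat, "alteration_matrix")) altmat <- list(altmat)
  masks <- lapply(altmat, altered_mask, classes = classes)
  common <- Reduce(intersect, lapply(masks, colnames))
  if (is.null(genes)) genes <- common
  if (!all(genes %in% common)) {
    stop("genes not called in every cohort: ",
         paste(setdiff(genes, common), collapse = ", "))
  }
  mask <- do.call(rbind, lapply(masks, function(m) m[, genes, drop = FALSE]))
  if (length(genes) < 2 || all(colSums(mask) == 0)) {
    stop("need >= 2 genes with nonzero alteration counts")
  }
  pairs <- utils::combn(genes, 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    x <- mask[, pairs[1, i]]
    y <- mask[, pairs[2, i]]
    res <- odds_ratio_test(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))
    data.frame(gene_a = pairs[1, i], gene_b = pairs[2, i],
               a = res$a, b = res$b, c = res$c, d = res$d,
               or = res$or, log_or = res$log_or, p = res$p,
               call = if (is.null(res$call)) NA_character_ else res$call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Alteration-frequency table across cohorts
#'
#' Percentage of samples altered per gene per cohort, the input to
#' [cluster_cohorts()].
#'
#' @param bundles Named list of `cohort_bundle`s.
#' @param genes Pathway genes to summarise.
#' @param classes Alteration classes counting as altered.
#' @return Matrix cohorts x genes of alteration percentages (0-100).
#' @export
alteration_frequency_table <- function(bundles,
                                       genes = c("CCND1", "CDK4", "RB1",
                                                 "CDKN2A"),
                                       classes = c("amplification",
                                                   "deep_deletion",
                                                   "mutation")) {
  rows <- lapply(bundles, function(b) {
    am <- call_alterations(b$cna, b$mutations, gene_list = genes)
    100 * colMeans(altered_mask(am, classes = classes))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(bundles)
  out
}

#' Cluster cohorts on pathway alteration frequencies
#'
#' K-means over the per-cohort alteration-percentage matrix (default k=5),
#' with labels suitable for joining to clinical data for survival by
#' cluster.
#'
#' @param freq_table Cohorts x genes percentage matrix, e.g. from
#'   [alteration_frequency_table()].
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @return List with `labels` (per cohort), `centroids`, `wcss` and a
#'   `degenerate` flag (all cohorts identical).
#' @export
cluster_cohorts <- function(freq_table, k = 5L, seed = 1L) {
  freq_table <- as.matrix(freq_table)
  if (nrow(freq_table) < k) stop("fewer cohorts than clusters")
  degenerate <- nrow(unique(freq_table)) < k
  fit <- kmeans_partition(freq_table, k = k, seed = seed)
  fit$degenerate <- degenerate
  if (degenerate) warning("fewer distinct frequency profiles than clusters")
  fit
}

#' Expression correlation between two genes
#'
#' Pearson correlation (with t-based p) of two genes' per-sample
#' expression, the CDKN2A-RB1 panel of the pathway analysis.
#'
#' @param expr An [expression_matrix()].
#' @param gene_a,gene_b Gene identifiers present in `expr`.
#' @return A list `r`, `p`, `n` as from [pearson_correlation()].
#' @export
expression_pair_correlation <- function(expr, gene_a = "CDKN2A",
                                        gene_b = "RB1") {
  for (g in c(gene_a, gene_b)) {
    if (!(g %in% rownames(expr))) stop("gene not in expression matrix: ", g)
  }
  pearson_correlation(expr[gene_a, ], expr[gene_b, ])
}
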
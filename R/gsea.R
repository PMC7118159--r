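## Signature-correlation mining with bootstrap-derived cutoffs and
## weighted pre-ranked gene set enrichment.
##
## Each gene's expression is correlated with the per-sample signature
## score; cutoffs for calling a gene positively/negatively correlated are
## the 2.5th/97.5th percentiles of the pooled distribution of gene-level
## correlation coefficients resampled with replacement (10,000 resamples
## by default), and selection additionally requires p < 0.05. Selected
## genes are weighted W = CC * (-log10 p) and fed to a classic weighted
## Kolmogorov-Smirnov pre-ranked GSEA with gene-label permutation.

#' Gene-wise correlation to the signature score
#'
#' Pearson correlation (with t-based p) of every gene's expression against
#' the per-sample signature score. Constant genes are excluded with a
#' notice.
#'
#' @param expr An [expression_matrix()].
#' @param scores A `score_table` from [score_samples()] for the same
#'   samples.
#' @return Data frame: `gene_id`, `cc`, `p`, `n`.
#' @export
genewise_correlation <- function(expr, scores) {
  shared <- intersect(colnames(expr), scores$sample_id)
  if (length(shared) < 3) stop("need >= 3 shared samples")
  s <- scores$score[match(shared, scores$sample_id)]
  m <- expr[, shared, drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " constant gene(s) excluded from correlation")
    m <- m[sds > 0, , drop = FALSE]
  }
  cc <- as.numeric(stats::cor(t(m), s))
  n <- length(shared)
  tstat <- cc * sqrt((n - 2) / pmax(1 - cc^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(gene_id = rownames(m), cc = cc, p = p, n = n,
             stringsAsFactors = FALSE)
}

#' Bootstrap confidence cutoffs for correlation selection
#'
#' Resamples the vector of gene-level correlation coefficients with
#' replacement `n_boot` times (resample size = number of genes), pools all
#' resampled values and takes the central-interval percentiles (2.5/97.5
#' at the default level) as the lower/upper cutoffs. The alternative
#' reading — percentiles of the per-resample means — is available via
#' `method = "means"`.
#'
#' @param profile Data frame from [genewise_correlation()] (needs `cc`).
#' @param n_boot Number of bootstrap resamples (default 10000; < 100
#'   warns).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @param method `"pooled"` (default) or `"means"`.
#' @return A `bootstrap_cutoffs` list: `lower`, `upper`, `n_boot`, `seed`,
#'   `method`.
#' @export
bootstrap_cutoffs <- function(profile, n_boot = 10000L, level = 0.95,
                              seed = 1L, method = c("pooled", "means")) {
  method <- match.arg(method)
  cc <- profile$cc
  if (length(cc) < 10) stop("need >= 10 genes with defined correlation")
  if (n_boot < 100) warning("n_boot < 100 gives unstable cutoffs")
  alpha <- (1 - level) / 2
  set.seed(seed)
  n <- length(cc)
  draws <- matrix(sample(cc, n * n_boot, replace = TRUE), nrow = n)
  stat <- if (method == "pooled") as.numeric(draws) else colMeans(draws)
  q <- stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE)
  structure(list(lower = q[1], upper = q[2], n_boot = as.integer(n_boot),
                 level = level, seed = as.integer(seed), method = method),
            class = "bootstrap_cutoffs")
}

#' Select significantly correlated genes beyond the bootstrap cutoffs
#'
#' Positive selection requires `cc > upper` cutoff; negative requires
#' `cc < lower`; both additionally require `p < p_max` (default 0.05).
#' The two selections are disjoint by construction.
#'
#' @param profile Data frame from [genewise_correlation()].
#' @param cutoffs A `bootstrap_cutoffs`.
#' @param p_max Significance requirement on the correlation p-value.
#' @return The profile with a `selected` column
#'   (`positive`/`negative`/`none`).
#' @export
select_correlated <- function(profile, cutoffs, p_max = 0.05) {
  sel <- rep("none", nrow(profile))
  sel[profile$cc > cutoffs$upper & profile$p < p_max] <- "positive"
  sel[profile$cc < cutoffs$lower & profile$p < p_max] <- "negative"
  profile$selected <- sel
  profile
}

#' Rank selected genes by correlation-weighted significance
#'
#' Combines the positively and negatively selected genes and assigns each
#' the weight `W = CC * (-log10 p)`, sorted decreasing with ties broken
#' lexicographically by gene id. Zero p-values are floored at 1e-300 and
#' flagged.
#'
#' @param profile Profile with a `selected` column (from
#'   [select_correlated()]); rows with `selected == "none"` are dropped.
#'   A profile without the column is ranked in full.
#' @return Data frame `gene_id`, `cc`, `p`, `w`, `p_floored`, sorted by
#'   `w` descending.
#' @export
gsea_weights <- function(profile) {
  if ("selected" %in% colnames(profile)) {
    profile <- profile[profile$selected != "none", , drop = FALSE]
  }
  if (nrow(profile) == 0) stop("no selected genes to rank")
  floored <- profile$p == 0
  p <- pmax(profile$p, 1e-300)
  if (any(floored)) warning(sum(floored), " zero p-value(s) floored at 1e-300")
  w <- profile$cc * (-log10(p))
  out <- data.frame(gene_id = profile$gene_id, cc = profile$cc,
                    p = profile$p, w = w, p_floored = floored,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$w, out$gene_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## weighted KS running-sum enrichment score for one set
.gsea_es <- function(w, in_set) {
  n <- length(w)
  n_hit <- sum(in_set)
  aw <- abs(w)
  denom_hit <- sum(aw[in_set])
  p_hit <- if (denom_hit > 0) {
    cumsum(ifelse(in_set, aw, 0)) / denom_hit
  } else cumsum(ifelse(in_set, 1 / n_hit, 0))  # all-zero weights: unweighted
  p_miss <- cumsum(ifelse(in_set, 0, 1)) / (n - n_hit)
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

.gsea_leading_edge <- function(gene_ids, w, in_set) {
  n <- length(w)
  aw <- abs(w)
  denom_hit <- sum(aw[in_set])
  p_hit <- if (denom_hit > 0) {
    cumsum(ifelse(in_set, aw, 0)) / denom_hit
  } else cumsum(ifelse(in_set, 1 / sum(in_set), 0))
  p_miss <- cumsum(ifelse(in_set, 0, 1)) / (n - sum(in_set))
  dev <- p_hit - p_miss
  peak <- which.max(abs(dev))
  if (dev[peak] >= 0) {
    gene_ids[seq_len(peak)][in_set[seq_len(peak)]]
  } else {
    idx <- seq(peak, n)
    gene_ids[idx][in_set[idx]]
  }
}

#' Weighted pre-ranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running-sum enrichment over a
#' ranked, weighted gene list: hits advance by |W| (normalised within the
#' set), misses by 1/(N - set size); ES is the signed extremum. NES and p
#' come from gene-label permutation preserving set size:
#' `NES = ES / mean(|permutation ES| of matching sign)` and
#' `p = (1 + same-sign permutations at least as extreme) / (m + 1)`; a set
#' with no same-sign permutation ES gets `p = 1/(n_perm + 1)`. Sets with
#' fewer than 2 members in the list, or spanning the entire list, are
#' skipped with a notice.
#'
#' @param ranked Data frame from [gsea_weights()] (`gene_id`, `w`).
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Data frame: `set_name`, `size`, `es`, `nes`, `p`,
#'   `leading_edge` (list column).
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000L, seed = 1L) {
  if (nrow(ranked) < 10) stop("ranked list must have >= 10 genes")
  gene_ids <- ranked$gene_id
  w <- ranked$w
  n <- length(w)
  set.seed(seed)
  out <- list()
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], gene_ids)
    if (length(members) < 2) {
      message("set '", nm, "' skipped: fewer than 2 members in the ranked list")
      next
    }
    if (length(members) == n) {
      message("set '", nm, "' skipped: spans the entire ranked list")
      next
    }
    in_set <- gene_ids %in% members
    es <- .gsea_es(w, in_set)
    size <- length(members)
    perm_es <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, size)
      flag <- logical(n); flag[idx] <- TRUE
      .gsea_es(w, flag)
    }, numeric(1))
    same_sign <- perm_es[sign(perm_es) == sign(es)]
    if (length(same_sign) == 0) {
      nes <- NA_real_
      p <- 1 / (n_perm + 1)
    } else {
      nes <- es / mean(abs(same_sign))
      p <- (1 + sum(abs(same_sign) >= abs(es))) / (length(same_sign) + 1)
    }
    out[[nm]] <- data.frame(set_name = nm, size = size, es = es,
                            nes = nes, p = p, stringsAsFactors = FALSE)
    out[[nm]]$leading_edge <- list(.gsea_leading_edge(gene_ids, w, in_set))
  }
  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster genes on their cross-cohort correlation profiles
#'
#' Rows are genes (union of selected genes), columns cohorts, values the
#' correlation coefficient to the signature score; missing cohort values
#' are imputed as 0 with the mask recorded. Default is agglomerative
#' Ward clustering cut at k; `method = "kmeans"` uses
#' [kmeans_partition()].
#'
#' @param cc_matrix Numeric genes x cohorts matrix (may contain NA).
#' @param k Number of clusters (default 5).
#' @param seed Integer seed (k-means mode).
#' @param method `"ward"` (hierarchical, default) or `"kmeans"`.
#' @return List with `labels`, `na_mask`, `method` and a `degenerate`
#'   flag (identical rows).
#' @export
cluster_correlation_matrix <- function(cc_matrix, k = 5L, seed = 1L,
                                       method = c("ward", "kmeans")) {
  method <- match.arg(method)
  cc_matrix <- as.matrix(cc_matrix)
  if (k > nrow(cc_matrix)) stop("k exceeds the number of genes")
  na_mask <- is.na(cc_matrix)
  cc_matrix[na_mask] <- 0
  degenerate <- nrow(unique(cc_matrix)) < k
  if (degenerate) warning("fewer distinct correlation profiles than clusters")
  if (method == "ward") {
    hc <- stats::hclust(stats::dist(cc_matrix), method = "ward.D2")
    labels <- stats::cutree(hc, k = k)
  } else {
    labels <- kmeans_partition(cc_matrix, k = k, seed = seed)$labels
  }
  list(labels = labels, na_mask = na_mask, method = method,
       degenerate = degenerate)
}
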
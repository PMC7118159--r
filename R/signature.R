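## Derivation and application of the integrated CDK4/6-RB expression
## signature. The derivation chain is: CPM-normalise isogenic counts ->
## genes repressed by drug in the parental line (logFC <= -1, p < 0.05)
## -> drop genes equally repressed in the RB1-null line (RB-dependency
## filter) -> prune on a clinical cohort by max pairwise correlation ->
## signature. Scoring is the mean of per-gene z-scores; tumours are
## stratified 25/50/25 for survival comparison.

#' Counts-per-million normalisation
#'
#' `value = count / column sum * 1e6`; every library must be positive.
#'
#' @param counts Non-negative integer matrix (genes x samples).
#' @return An [expression_matrix()] with unit `"cpm"`.
#' @export
cpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  libs <- colSums(counts)
  if (any(libs == 0)) {
    stop("zero library size in column(s): ",
         paste(colnames(counts)[libs == 0], collapse = ", "))
  }
  cpm <- sweep(counts, 2, libs, "/") * 1e6
  expression_matrix(cpm, unit = "cpm")
}

#' Differential-expression table between two column groups
#'
#' log2 fold change and pooled-variance t-test on `log2(CPM + pseudocount)`
#' for every gene, treated relative to control.
#'
#' @param cpm CPM expression matrix.
#' @param treated_cols,control_cols Column names or indices (>= 2 each).
#' @param pseudocount Added before the log2 transform (default 1).
#' @return Data frame: `gene_id`, `log2_fc`, `p`, group means (log2 scale)
#'   and sizes, `degenerate` flag.
#' @export
de_table <- function(cpm, treated_cols, control_cols, pseudocount = 1) {
  tr <- log2(cpm[, treated_cols, drop = FALSE] + pseudocount)
  ct <- log2(cpm[, control_cols, drop = FALSE] + pseudocount)
  if (ncol(tr) < 2 || ncol(ct) < 2) stop("need >= 2 columns per group")
  out <- data.frame(gene_id = rownames(cpm),
                    log2_fc = rowMeans(tr) - rowMeans(ct),
                    p = NA_real_, mean_treated = rowMeans(tr),
                    mean_control = rowMeans(ct),
                    n_treated = ncol(tr), n_control = ncol(ct),
                    degenerate = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cpm))) {
    tt <- two_sample_t_test(tr[i, ], ct[i, ])
    out$p[i] <- tt$p
    out$degenerate[i] <- tt$degenerate
  }
  rownames(out) <- NULL
  out
}

#' Genes repressed by treatment
#'
#' Filters the DE table to genes with `log2_fc <= lfc_max` and
#' `p < p_max` (defaults: logFC <= -1, p < 0.05).
#'
#' @inheritParams de_table
#' @param lfc_max Maximum log2 fold change (inclusive).
#' @param p_max Exclusive p-value threshold.
#' @return The filtered DE data frame (rows = repressed genes).
#' @export
repressed_genes <- function(cpm, treated_cols, control_cols,
                            lfc_max = -1, p_max = 0.05, pseudocount = 1) {
  de <- de_table(cpm, treated_cols, control_cols, pseudocount = pseudocount)
  de[de$log2_fc <= lfc_max & de$p < p_max, , drop = FALSE]
}

#' RB-dependency filter
#'
#' Keeps the parental repressed genes that are NOT repressed (same
#' thresholds) in the identically treated RB1-null line; genes repressed
#' in both genotypes are RB-independent and removed. A parental hit absent
#' from the knockout results is retained with a warning (its dependency
#' loss cannot be demonstrated).
#'
#' @param parental_hits Character vector of parental repressed genes (or a
#'   data frame with a `gene_id` column).
#' @param ko_de Full DE table of the knockout contrast (from [de_table()]).
#' @param lfc_max,p_max Thresholds, identical to the parental analysis.
#' @return Character vector of RB-dependent seed genes.
#' @export
rb_dependency_filter <- function(parental_hits, ko_de,
                                 lfc_max = -1, p_max = 0.05) {
  if (is.data.frame(parental_hits)) parental_hits <- parental_hits$gene_id
  absent <- setdiff(parental_hits, ko_de$gene_id)
  if (length(absent)) {
    warning("genes absent from knockout results retained: ",
            paste(absent, collapse = ", "))
  }
  ko_hit <- ko_de$gene_id[ko_de$log2_fc <= lfc_max & ko_de$p < p_max]
  setdiff(parental_hits, ko_hit)
}

#' Prune seed genes by maximum clinical correlation
#'
#' For every seed gene, the Pearson correlation to each other seed gene is
#' computed across the clinical samples; a gene whose maximum correlation
#' falls strictly below the mean of all maximum correlations is pruned.
#' Signed correlation is used by default (the signature is a co-repressed
#' module); set `use_absolute = TRUE` for |r|. Genes exactly at the mean
#' survive (strict less-than, with a 1e-12 tolerance against
#' floating-point ties).
#'
#' @param seed_genes Character vector of candidate genes (>= 2 present in
#'   the clinical matrix; absent genes are dropped with a notice).
#' @param clinical_expr Clinical [expression_matrix()].
#' @param use_absolute Prune on |r| instead of signed r.
#' @return A `signature_model`: final `genes`, `seed_genes`,
#'   `pruned_genes`, per-gene `max_corr` and derivation parameters.
#' @export
correlation_prune <- function(seed_genes, clinical_expr,
                              use_absolute = FALSE) {
  seed_genes <- unique(seed_genes)
  missing <- setdiff(seed_genes, rownames(clinical_expr))
  if (length(missing)) {
    message(length(missing), " seed gene(s) missing from the clinical ",
            "matrix dropped: ", paste(missing, collapse = ", "))
  }
  present <- intersect(seed_genes, rownames(clinical_expr))
  if (length(present) < 2) stop("need >= 2 seed genes present in the clinical matrix")
  cc <- stats::cor(t(clinical_expr[present, , drop = FALSE]))
  if (use_absolute) cc <- abs(cc)
  diag(cc) <- -Inf
  max_corr <- apply(cc, 1, max)
  threshold <- mean(max_corr)
  pruned <- names(max_corr)[max_corr < threshold - 1e-12]
  genes <- setdiff(present, pruned)
  structure(list(genes = genes, seed_genes = present,
                 pruned_genes = pruned, max_corr = max_corr,
                 threshold = threshold,
                 params = list(use_absolute = use_absolute,
                               n_clinical_samples = ncol(clinical_expr))),
            class = "signature_model")
}

#' Derive the integrated signature from an isogenic experiment
#'
#' Convenience wrapper running the full chain: CPM normalisation, drug vs
#' vehicle repression in the parental line, RB-dependency filtering
#' against the knockout contrast, and clinical correlation pruning.
#'
#' @param counts Raw count matrix (genes x columns).
#' @param groups Column design with `column`, `genotype`
#'   (`parental`/`rb1_null`), `treatment` (`vehicle`/`drug`).
#' @param clinical_expr Clinical [expression_matrix()] for pruning.
#' @param lfc_max,p_max Repression thresholds (defaults -1, 0.05).
#' @param pseudocount Pseudocount for the log2 fold change.
#' @param use_absolute Pruning mode, see [correlation_prune()].
#' @return A `signature_model` with full provenance in `$provenance`.
#' @export
derive_signature <- function(counts, groups, clinical_expr,
                             lfc_max = -1, p_max = 0.05, pseudocount = 1,
                             use_absolute = FALSE) {
  cpm <- cpm_normalize(counts)
  col_of <- function(geno, treat) {
    groups$column[groups$genotype == geno & groups$treatment == treat]
  }
  par_de <- de_table(cpm, col_of("parental", "drug"),
                     col_of("parental", "vehicle"), pseudocount)
  par_hits <- par_de$gene_id[par_de$log2_fc <= lfc_max & par_de$p < p_max]
  ko_de <- de_table(cpm, col_of("rb1_null", "drug"),
                    col_of("rb1_null", "vehicle"), pseudocount)
  seed <- rb_dependency_filter(par_hits, ko_de, lfc_max, p_max)
  if (length(seed) < 2) stop("fewer than 2 RB-dependent seed genes")
  model <- correlation_prune(seed, clinical_expr, use_absolute)
  model$provenance <- list(n_parental_hits = length(par_hits),
                           n_seed = length(seed),
                           lfc_max = lfc_max, p_max = p_max,
                           pseudocount = pseudocount,
                           parental_de = par_de, ko_de = ko_de)
  model
}

#' @export
print.signature_model <- function(x, ...) {
  cat("Integrated CDK4/6-RB signature model\n")
  cat(sprintf("  %d signature genes (%d seed, %d pruned by max-correlation < %.4f)\n",
              length(x$genes), length(x$seed_genes),
              length(x$pruned_genes), x$threshold))
  invisible(x)
}

#' Score samples with a signature
#'
#' Each signature gene is z-scored across the cohort's samples; a sample's
#' score is the mean z across genes. At least `min_coverage` of the
#' signature genes must be present; missing genes are excluded and listed.
#' Strata are the lowest 25 percent, middle 50 percent and highest 25
#' percent of scores (quantile cut at the 25th/75th percentiles, boundary
#' ties going to the middle stratum).
#'
#' @param expr An [expression_matrix()].
#' @param signature A `signature_model` or character vector of genes.
#' @param min_coverage Minimum fraction of signature genes required.
#' @param stratify Also assign 25/50/25 strata (default TRUE).
#' @return A `score_table` data frame: `sample_id`, `score`, `stratum`;
#'   attributes record the genes used/missing.
#' @export
score_samples <- function(expr, signature, min_coverage = 0.5,
                          stratify = TRUE) {
  genes <- if (inherits(signature, "signature_model")) signature$genes else signature
  present <- intersect(genes, rownames(expr))
  if (length(present) < min_coverage * length(genes)) {
    stop("only ", length(present), "/", length(genes),
         " signature genes present; missing: ",
         paste(setdiff(genes, present), collapse = ", "))
  }
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    message("constant signature gene(s) excluded from scoring: ",
            paste(present[sds == 0], collapse = ", "))
    sub <- sub[sds > 0, , drop = FALSE]
  }
  z <- t(scale(t(sub)))
  score <- colMeans(z)
  out <- data.frame(sample_id = colnames(expr), score = unname(score),
                    stringsAsFactors = FALSE)
  if (stratify) out$stratum <- .stratify_scores(out$score)
  attr(out, "genes_used") <- rownames(sub)
  attr(out, "genes_missing") <- setdiff(genes, present)
  class(out) <- c("score_table", "data.frame")
  out
}

## 25/50/25 cut; boundary ties go to the middle stratum
.stratify_scores <- function(score) {
  q <- stats::quantile(score, c(0.25, 0.75), names = FALSE)
  stratum <- rep("mid50", length(score))
  stratum[score < q[1]] <- "low25"
  stratum[score > q[2]] <- "high25"
  if (!any(stratum == "low25") || !any(stratum == "high25")) {
    stop(sprintf(
      "stratification failed: tied scores collapse the %s quantile boundary (q25=%.6g, q75=%.6g)",
      if (!any(stratum == "low25")) "25th" else "75th", q[1], q[2]))
  }
  factor(stratum, levels = c("low25", "mid50", "high25"))
}

#' Score samples with a fitted signature model
#' @param object A `signature_model`.
#' @param expr An [expression_matrix()] of the cohort to score.
#' @param ... Passed to [score_samples()].
#' @export
predict.signature_model <- function(object, expr, ...) {
  score_samples(expr, object, ...)
}

#' Stratify scored samples and compare survival
#'
#' Joins scores to the clinical table, runs a Kaplan-Meier / log-rank
#' comparison across the three score strata, and optionally a two-group
#' t-test of scores between named sample groups (e.g. subtypes or
#' pre/on-treatment).
#'
#' @param scores A `score_table` from [score_samples()].
#' @param clinical Clinical data frame.
#' @param endpoint `"dfs"` or `"os"`.
#' @param group_a,group_b Optional character vectors of sample ids for the
#'   auxiliary score comparison.
#' @return List with `strata` (merged table), `survival` (a
#'   `survival_comparison`) and optional `group_test`.
#' @export
stratify_and_compare <- function(scores, clinical, endpoint = c("dfs", "os"),
                                 group_a = NULL, group_b = NULL) {
  endpoint <- match.arg(endpoint)
  if (nrow(scores) < 8) stop("need >= 8 scored samples")
  merged <- merge(scores, clinical, by = "sample_id")
  tm <- merged[[paste0(endpoint, "_months")]]
  ev <- merged[[paste0(endpoint, "_event")]]
  ok <- !is.na(tm) & !is.na(ev)
  surv <- km_logrank(tm[ok], ev[ok], merged$stratum[ok])
  group_test <- NULL
  if (!is.null(group_a) && !is.null(group_b)) {
    sa <- scores$score[scores$sample_id %in% group_a]
    sb <- scores$score[scores$sample_id %in% group_b]
    group_test <- two_sample_t_test(sa, sb)
  }
  list(strata = merged, survival = surv, group_test = group_test)
}
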
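## RB1-dosage differential expression across cohorts: per-cohort DE by
## dosage class, cross-cohort recurrence filtering with eligibility
## thresholds, cis/trans classification against the 13q annotation, and
## hypergeometric set-overlap testing.

#' Differential expression by copy-number dosage
#'
#' Per-gene log2 fold change (non-diploid class vs diploid) and
#' pooled-variance t-test on log-scale expression, split into up/down
#' significant sets at `|logFC| >= lfc_abs_min` and `p < p_max`. Also
#' records the cohort's het-loss and deep-deletion frequencies of the
#' dosage gene, used downstream for eligibility.
#'
#' @param expr An [expression_matrix()] on log2 (or z) scale.
#' @param cna A [cna_matrix()] sharing samples with `expr`.
#' @param gene Dosage gene (default `"RB1"`).
#' @param contrast `"diploid_vs_het"` or `"diploid_vs_deep"`.
#' @param lfc_abs_min Minimum absolute log2 fold change (default 1).
#' @param p_max Exclusive p threshold (default 0.05).
#' @return A `dosage_de_result`: full `table`, `up`/`down` gene sets,
#'   `eligible` flag (>= 2 samples per class), class sizes and the dosage
#'   gene's loss frequencies.
#' @export
dosage_de <- function(expr, cna, gene = "RB1",
                      contrast = c("diploid_vs_het", "diploid_vs_deep"),
                      lfc_abs_min = 1, p_max = 0.05) {
  contrast <- match.arg(contrast)
  shared <- intersect(colnames(expr), colnames(cna))
  cls <- .dosage_classes(cna[, shared, drop = FALSE], gene)
  target <- if (contrast == "diploid_vs_het") "het_loss" else "deep_deletion"
  ref_cols <- shared[!is.na(cls) & cls == "diploid"]
  alt_cols <- shared[!is.na(cls) & cls == target]
  freq_het <- mean(cna[gene, shared] == -1L)
  freq_deep <- mean(cna[gene, shared] == -2L)
  eligible <- length(ref_cols) >= 2 && length(alt_cols) >= 2
  tab <- NULL
  up <- character(0)
  down <- character(0)
  if (eligible) {
    a <- expr[, alt_cols, drop = FALSE]
    r <- expr[, ref_cols, drop = FALSE]
    tab <- data.frame(gene_id = rownames(expr),
                      log2_fc = rowMeans(a) - rowMeans(r),
                      p = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(expr))) {
      tab$p[i] <- two_sample_t_test(a[i, ], r[i, ])$p
    }
    sig <- abs(tab$log2_fc) >= lfc_abs_min & tab$p < p_max
    up <- tab$gene_id[sig & tab$log2_fc > 0]
    down <- tab$gene_id[sig & tab$log2_fc < 0]
  }
  structure(list(table = tab, up = up, down = down, contrast = contrast,
                 gene = gene, eligible = eligible,
                 n_diploid = length(ref_cols), n_alt = length(alt_cols),
                 freq_het = freq_het, freq_deep = freq_deep,
                 cohort = attr(expr, "cohort_label")),
            class = "dosage_de_result")
}

#' Cross-cohort recurrence filter of dosage-DE gene sets
#'
#' A cohort is eligible for the deep contrast when its deep-deletion
#' frequency exceeds `min_class_freq` (default > 5 percent) and for the
#' het contrast when its het-loss frequency exceeds 10 percent (and the
#' DE was computable). A gene is kept, per direction, when it is
#' significant in the same direction in strictly more than `min_fraction`
#' of eligible cohorts (defaults: > 0.33 for het, > 0.66 for deep).
#'
#' @param results List of `dosage_de_result`s of one contrast.
#' @param min_fraction Recurrence threshold; default by contrast.
#' @param min_class_freq Eligibility frequency threshold; default by
#'   contrast (0.05 deep, 0.10 het).
#' @return A `recurrent_gene_sets` list: `up`, `down`, per-gene recurrence
#'   `fraction_up`/`fraction_down`, `eligible_cohorts`.
#' @export
recurrence_filter <- function(results, min_fraction = NULL,
                              min_class_freq = NULL) {
  contrasts <- unique(vapply(results, `[[`, character(1), "contrast"))
  if (length(contrasts) != 1) stop("results mix contrasts")
  deep <- contrasts == "diploid_vs_deep"
  if (is.null(min_fraction)) min_fraction <- if (deep) 0.66 else 0.33
  if (is.null(min_class_freq)) min_class_freq <- if (deep) 0.05 else 0.10
  eligible <- vapply(results, function(r) {
    r$eligible && (if (deep) r$freq_deep else r$freq_het) > min_class_freq
  }, logical(1))
  if (sum(eligible) < 2) stop("fewer than 2 eligible cohorts")
  keep <- results[eligible]
  n_elig <- length(keep)
  genes <- sort(unique(unlist(lapply(keep, function(r) c(r$up, r$down)))))
  count_up <- vapply(genes, function(g) {
    sum(vapply(keep, function(r) g %in% r$up, logical(1)))
  }, numeric(1))
  count_down <- vapply(genes, function(g) {
    sum(vapply(keep, function(r) g %in% r$down, logical(1)))
  }, numeric(1))
  frac_up <- count_up / n_elig
  frac_down <- count_down / n_elig
  structure(list(up = genes[frac_up > min_fraction],
                 down = genes[frac_down > min_fraction],
                 fraction_up = stats::setNames(frac_up, genes),
                 fraction_down = stats::setNames(frac_down, genes),
                 eligible_cohorts = vapply(keep, function(r) {
                   if (is.null(r$cohort)) NA_character_ else r$cohort
                 }, character(1)),
                 contrast = contrasts, min_fraction = min_fraction,
                 min_class_freq = min_class_freq),
            class = "recurrent_gene_sets")
}

#' Fraction of a gene set located on a chromosome arm (cis)
#'
#' Fraction of set members annotated on the given arm; members without an
#' annotation record count as trans with a warning.
#'
#' @param gene_set Non-empty character vector.
#' @param annotation Annotation data frame.
#' @param chrom,arm Arm definition (default 13q).
#' @return List with `fraction` and per-gene `labels`
#'   (`cis`/`trans`/`unannotated`).
#' @export
cis_fraction <- function(gene_set, annotation, chrom = "13", arm = "q") {
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0) stop("cis fraction undefined for an empty set")
  ann <- annotation[!duplicated(annotation$gene_id), , drop = FALSE]
  idx <- match(gene_set, ann$gene_id)
  labels <- ifelse(is.na(idx), "unannotated",
                   ifelse(ann$chrom[idx] == chrom & ann$arm[idx] == arm,
                          "cis", "trans"))
  if (any(labels == "unannotated")) {
    warning(sum(labels == "unannotated"),
            " unannotated gene(s) counted as trans")
  }
  list(fraction = mean(labels == "cis"),
       labels = stats::setNames(labels, gene_set))
}

#' Pairwise hypergeometric overlap tests and Venn counts
#'
#' Upper-tail hypergeometric p for every pair of sets drawn from a common
#' universe, plus the full Venn region counts (including the three-way
#' intersection when three sets are given).
#'
#' @param sets Named list of character vectors, each a subset of
#'   `universe`.
#' @param universe Character vector (or its size) defining the sampling
#'   frame.
#' @return List with `pairwise` (data frame set_a, set_b, sizes, overlap,
#'   p) and `venn` counts.
#' @export
overlap_tests <- function(sets, universe) {
  if (is.numeric(universe) && length(universe) == 1) {
    n_universe <- as.integer(universe)
    sets <- lapply(sets, unique)
  } else {
    universe <- unique(universe)
    n_universe <- length(universe)
    sets <- lapply(sets, unique)
    viol <- lapply(sets, setdiff, y = universe)
    bad <- names(viol)[vapply(viol, length, integer(1)) > 0]
    if (length(bad)) {
      stop("sets not contained in universe: ", paste(bad, collapse = ", "),
           " (e.g. ", viol[[bad[1]]][1], ")")
    }
  }
  nm <- names(sets)
  pairs <- utils::combn(nm, 2)
  pairwise <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- sets[[pairs[1, i]]]; b <- sets[[pairs[2, i]]]
    k <- length(intersect(a, b))
    data.frame(set_a = pairs[1, i], set_b = pairs[2, i],
               n_a = length(a), n_b = length(b), overlap = k,
               p = hypergeometric_overlap(n_universe, length(a), length(b), k),
               stringsAsFactors = FALSE)
  })
  venn <- list(sizes = vapply(sets, length, integer(1)))
  if (length(sets) == 3) {
    venn$triple <- length(Reduce(intersect, sets))
  }
  list(pairwise = do.call(rbind, pairwise), venn = venn,
       n_universe = n_universe)
}
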
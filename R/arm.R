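## Chromosome-arm dosage analysis: positional loss-frequency profiles
## along an arm (13q by default), expression by gene dosage class, and
## survival stratified by dosage.

#' Positional loss-frequency profile along a chromosome arm
#'
#' Per-gene frequencies of heterozygous loss (CNA -1) and deep deletion
#' (CNA -2) across all cohort samples, for genes annotated on the given
#' arm, ordered by start coordinate. Denominators are the full cohort.
#'
#' @param cna A [cna_matrix()].
#' @param annotation Annotation data frame (see [read_annotation()]).
#' @param chrom Chromosome (default `"13"`).
#' @param arm Arm, `"p"` or `"q"` (default `"q"`).
#' @return An `arm_profile` data frame: `gene_id`, `start`, `freq_het`,
#'   `freq_deep`, ordered by position.
#' @export
arm_profile <- function(cna, annotation, chrom = "13", arm = "q") {
  ann <- annotation[annotation$chrom == chrom & annotation$arm == arm, ,
                    drop = FALSE]
  ann <- ann[!duplicated(ann$gene_id), , drop = FALSE]
  ann <- ann[ann$gene_id %in% rownames(cna), , drop = FALSE]
  if (nrow(ann) == 0) stop("no annotated genes with CNA data on ", chrom, arm)
  ann <- ann[order(ann$start), , drop = FALSE]
  sub <- cna[ann$gene_id, , drop = FALSE]
  out <- data.frame(gene_id = ann$gene_id, start = ann$start,
                    freq_het = rowMeans(sub == -1L),
                    freq_deep = rowMeans(sub == -2L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("arm_profile", "data.frame")
  out
}

#' @export
plot.arm_profile <- function(x, ...) {
  graphics::plot(x$start, x$freq_het, type = "l", col = "darkgreen",
                 xlab = "position (bp)", ylab = "loss frequency",
                 ylim = c(0, max(x$freq_het, x$freq_deep, 0.01)), ...)
  graphics::lines(x$start, x$freq_deep, col = "blue")
  graphics::legend("topright", legend = c("het loss", "deep deletion"),
                   col = c("darkgreen", "blue"), lty = 1, bty = "n")
  invisible(x)
}

.dosage_classes <- function(cna, gene) {
  if (!(gene %in% rownames(cna))) stop("gene not in CNA matrix: ", gene)
  code <- cna[gene, ]
  cls <- rep(NA_character_, length(code))
  cls[code == 0L] <- "diploid"
  cls[code == -1L] <- "het_loss"
  cls[code == -2L] <- "deep_deletion"
  stats::setNames(cls, colnames(cna))
}

#' Expression by copy-number dosage class
#'
#' Splits samples into diploid / heterozygous-loss / deep-deletion classes
#' of the given gene's discrete CNA code, summarises each class (median,
#' quartiles, min/max), and performs pooled-variance t-tests of diploid
#' vs. het and diploid vs. deep. Classes with fewer than 2 samples are
#' skipped with a notice.
#'
#' @param expr An [expression_matrix()] (log scale expected).
#' @param cna A [cna_matrix()] sharing samples with `expr`.
#' @param gene Gene whose dosage defines the classes and whose expression
#'   is compared (default `"RB1"`). Use `expr_gene` to look at another
#'   gene's expression across the same dosage classes.
#' @param expr_gene Gene whose expression is summarised (default `gene`).
#' @return List with per-class `values`, `summary` (box-plot statistics)
#'   and `tests` (one row per performed comparison).
#' @export
expression_by_dosage <- function(expr, cna, gene = "RB1", expr_gene = gene) {
  if (!(expr_gene %in% rownames(expr))) {
    stop("gene not in expression matrix: ", expr_gene)
  }
  shared <- intersect(colnames(expr), colnames(cna))
  cls <- .dosage_classes(cna[, shared, drop = FALSE], gene)
  vals <- split(expr[expr_gene, shared], cls)
  summ <- do.call(rbind, lapply(names(vals), function(k) {
    v <- vals[[k]]
    data.frame(class = k, n = length(v), median = stats::median(v),
               q1 = unname(stats::quantile(v, 0.25)),
               q3 = unname(stats::quantile(v, 0.75)),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  tests <- list()
  for (other in c("het_loss", "deep_deletion")) {
    if (is.null(vals[["diploid"]]) || length(vals[["diploid"]]) < 2 ||
        is.null(vals[[other]]) || length(vals[[other]]) < 2) {
      message("comparison diploid vs ", other,
              " skipped: fewer than 2 samples in a class")
      next
    }
    tt <- two_sample_t_test(vals[["diploid"]], vals[[other]])
    tests[[other]] <- data.frame(
      comparison = paste0("diploid_vs_", other),
      n_diploid = length(vals[["diploid"]]), n_other = length(vals[[other]]),
      mean_diploid = tt$mean_a, mean_other = tt$mean_b,
      t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  }
  list(values = vals, summary = summ,
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}

#' Survival stratified by gene dosage (diploid vs heterozygous loss)
#'
#' Kaplan-Meier curves and log-rank test comparing diploid against
#' heterozygous-loss samples of the given gene; deep deletions are
#' excluded from this comparison.
#'
#' @param clinical Clinical data frame (see [read_clinical_tsv()]).
#' @param cna A [cna_matrix()].
#' @param gene Gene defining the dosage classes (default `"RB1"`).
#' @param endpoint `"dfs"` or `"os"` (explicit, no guessing).
#' @return A `survival_comparison` (see [km_logrank()]).
#' @export
survival_by_dosage <- function(clinical, cna, gene = "RB1",
                               endpoint = c("dfs", "os")) {
  endpoint <- match.arg(endpoint)
  shared <- intersect(clinical$sample_id, colnames(cna))
  cls <- .dosage_classes(cna[, shared, drop = FALSE], gene)
  keep <- shared[cls[shared] %in% c("diploid", "het_loss")]
  cl <- clinical[match(keep, clinical$sample_id), , drop = FALSE]
  tm <- cl[[paste0(endpoint, "_months")]]
  ev <- cl[[paste0(endpoint, "_event")]]
  ok <- !is.na(tm) & !is.na(ev)
  grp <- cls[keep][ok]
  if (length(unique(grp)) < 2) {
    stop("both dosage classes needed for the survival comparison")
  }
  km_logrank(tm[ok], ev[ok], grp)
}
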
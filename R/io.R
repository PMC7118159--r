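## Readers/writers for the tabular dialects the pipeline consumes
## (expression TSV, cBioPortal discrete CNA, MAF-lite, clinical TSV,
## BED/TSV gene annotation, GMT gene sets) and the validated cohort bundle
## that ties them together. All gene/sample matching is exact string
## equality after whitespace trimming; gene coordinates are held 1-based
## inclusive internally (BED is converted on read).

trim <- function(x) gsub("^\\s+|\\s+$", "", x)

#' Construct a validated expression matrix
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names.
#' @param unit One of `"counts"`, `"cpm"`, `"log2"`, `"zscore"`. Counts must
#'   be non-negative.
#' @param cohort_label Free-text cohort identifier.
#' @return The matrix with attributes `unit` and `cohort_label`, class
#'   `expression_matrix`.
#' @export
expression_matrix <- function(values, unit, cohort_label = "") {
  unit <- match.arg(unit, c("counts", "cpm", "log2", "zscore"))
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")
  if (anyNA(values)) stop("missing expression values are not allowed")
  if (unit %in% c("counts", "cpm") && any(values < 0)) {
    stop(unit, " values must be non-negative")
  }
  structure(values, unit = unit, cohort_label = cohort_label,
            class = c("expression_matrix", "matrix", "array"))
}

#' Construct a validated discrete copy-number matrix
#'
#' Entries use the five-level GISTIC-style code: -2 deep deletion, -1
#' heterozygous (shallow) loss, 0 diploid, 1 gain, 2 amplification.
#'
#' @param values Integer matrix with unique gene rownames and sample
#'   colnames and entries in `{-2,...,2}`.
#' @export
cna_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("CNA matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers")
  bad_flag <- !(values %in% c(-2L, -1L, 0L, 1L, 2L))
  dim(bad_flag) <- dim(values)
  bad <- which(bad_flag, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "CNA value outside {-2..2} at gene '%s', sample '%s' (value %s)",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
      as.character(values[bad[1, , drop = FALSE]])))
  }
  storage.mode(values) <- "integer"
  structure(values, class = c("cna_matrix", "matrix", "array"))
}

#' Read an expression TSV (first column gene id, header of sample ids)
#' @param path File path.
#' @param unit Declared unit of the stored values.
#' @param cohort_label Cohort name attached to the matrix.
#' @export
read_expression_tsv <- function(path, unit = "log2", cohort_label = "") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file needs a gene column plus samples: ", path)
  genes <- trim(as.character(df[[1]]))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- genes
  colnames(m) <- trim(colnames(m))
  expression_matrix(m, unit = unit, cohort_label = cohort_label)
}

#' Read a cBioPortal-style discrete CNA TSV
#'
#' Expects a `Hugo_Symbol` column (or the gene ids in the first column) and
#' one integer column per sample with values in `{-2..2}`.
#' @param path File path.
#' @export
read_cna_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene_col <- if ("Hugo_Symbol" %in% colnames(df)) "Hugo_Symbol" else colnames(df)[1]
  genes <- trim(as.character(df[[gene_col]]))
  keep <- setdiff(colnames(df), c(gene_col, "Entrez_Gene_Id", "Cytoband"))
  m <- as.matrix(df[, keep, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "integer")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer CNA value at gene '%s', sample '%s' in %s",
                 genes[bad[1]], keep[bad[2]], path))
  }
  rownames(m) <- genes
  colnames(m) <- trim(colnames(m))
  cna_matrix(m)
}

.maf_class_map <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "truncating",
  Frame_Shift_Del = "truncating",
  Frame_Shift_Ins = "truncating",
  Nonstop_Mutation = "truncating",
  Translation_Start_Site = "truncating",
  In_Frame_Del = "inframe",
  In_Frame_Ins = "inframe",
  Splice_Site = "splice",
  Splice_Region = "splice"
)

#' Read a MAF-lite mutation table
#'
#' Needs columns `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`. Silent/synonymous rows are dropped (only
#' non-silent events feed alteration calling); everything not in the
#' standard MAF vocabulary maps to class `other`.
#' @param path File path.
#' @return Data frame with columns `sample_id`, `gene_id`, `variant_class`.
#' @export
read_maf_lite <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("MAF file missing columns: ", paste(miss, collapse = ", "))
  raw <- trim(df$Variant_Classification)
  silent <- raw %in% c("Silent", "silent", "Synonymous")
  df <- df[!silent, , drop = FALSE]
  raw <- raw[!silent]
  cls <- unname(.maf_class_map[raw])
  cls[is.na(cls)] <- "other"
  data.frame(sample_id = trim(df$Tumor_Sample_Barcode),
             gene_id = trim(df$Hugo_Symbol),
             variant_class = cls,
             stringsAsFactors = FALSE)
}

#' Read a clinical/survival TSV
#'
#' Columns: `sample`, `cohort`, `subtype`, `dfs_months`, `dfs_status`,
#' `os_months`, `os_status`. Missing values are encoded `NA`. An event flag
#' without a matching time is rejected.
#' @param path File path.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("sample", "cohort")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("clinical file missing columns: ", paste(miss, collapse = ", "))
  out <- data.frame(
    sample_id = trim(as.character(df$sample)),
    cohort = trim(as.character(df$cohort)),
    subtype = if ("subtype" %in% colnames(df)) as.character(df$subtype) else NA_character_,
    dfs_months = if ("dfs_months" %in% colnames(df)) as.numeric(df$dfs_months) else NA_real_,
    dfs_event = if ("dfs_status" %in% colnames(df)) as.integer(df$dfs_status) else NA_integer_,
    os_months = if ("os_months" %in% colnames(df)) as.numeric(df$os_months) else NA_real_,
    os_event = if ("os_status" %in% colnames(df)) as.integer(df$os_status) else NA_integer_,
    stringsAsFactors = FALSE)
  validate_clinical(out)
  out
}

validate_clinical <- function(cl) {
  for (ep in c("dfs", "os")) {
    tm <- cl[[paste0(ep, "_months")]]
    ev <- cl[[paste0(ep, "_event")]]
    if (any(!is.na(ev) & is.na(tm))) {
      stop(ep, " event flag present without a matching time")
    }
    if (any(!is.na(tm) & tm < 0)) stop(ep, " times must be non-negative")
    if (any(!is.na(ev) & !(ev %in% c(0L, 1L)))) stop(ep, " event flags must be 0/1")
  }
  invisible(cl)
}

#' Read gene annotation (TSV or BED)
#'
#' TSV columns: `gene`, `chrom`, `arm`, `start`, `end` with 1-based
#' inclusive coordinates. BED (0-based half-open, columns chrom/start/end/
#' name and optionally arm in column 5) is converted to the internal
#' 1-based convention on read.
#' @param path File path.
#' @param format `"tsv"` or `"bed"`.
#' @return Data frame `gene_id`, `chrom`, `arm`, `start`, `end`.
#' @export
read_annotation <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("gene", "chrom", "arm", "start", "end")
    miss <- setdiff(need, colnames(df))
    if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
    out <- data.frame(gene_id = trim(as.character(df$gene)),
                      chrom = trim(as.character(df$chrom)),
                      arm = trim(as.character(df$arm)),
                      start = as.integer(df$start), end = as.integer(df$end),
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4) stop("BED needs at least chrom/start/end/name columns")
    out <- data.frame(gene_id = trim(as.character(df[[4]])),
                      chrom = trim(as.character(df[[1]])),
                      arm = if (ncol(df) >= 5) trim(as.character(df[[5]])) else NA_character_,
                      start = as.integer(df[[2]]) + 1L,  # 0-based -> 1-based
                      end = as.integer(df[[3]]),
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$gene_id)) stop("duplicate gene in annotation")
  if (any(out$start >= out$end)) stop("annotation start must be < end")
  out
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, members. Member lists are
#' deduplicated preserving order; file order of sets is preserved.
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trim(lines))]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(structure(list(), names = character(0)))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    }
    members <- unique(trim(fields[-(1:2)]))
    members <- members[nzchar(members)]
    sets[[trim(fields[1])]] <- members
  }
  sets
}

#' Write a gene-set collection as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional descriptions (recycled `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table to TSV or JSON
#'
#' TSV serialises floats at full precision (round-trip faithful to 1e-12)
#' and writes `NA` for missing/NaN values; JSON uses jsonlite with
#' unrestricted digits.
#' @param table Data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_results <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- as.data.frame(table)
    for (j in seq_along(tab)) {
      if (is.double(tab[[j]])) {
        v <- sprintf("%.17g", tab[[j]])
        v[!is.finite(tab[[j]]) & !is.na(tab[[j]])] <-
          as.character(tab[[j]][!is.finite(tab[[j]]) & !is.na(tab[[j]])])
        v[is.na(tab[[j]])] <- NA_character_
        tab[[j]] <- v
      }
    }
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(table, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "columns")
  }
  invisible(path)
}

#' Read back a TSV written by [write_results()]
#' @param path File path.
#' @export
read_results_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = "NA")
}

#' Assemble and validate a cohort bundle
#'
#' Reads the five tables and intersects their sample identifiers
#' (expression, CNA, clinical; mutation rows outside the intersection are
#' dropped). Samples present in some tables but not others are reported in
#' `dropped_samples`. An empty intersection is fatal.
#'
#' @param expr_path,cna_path,mut_path,clinical_path,annotation_path File
#'   paths in the dialects described in the reader functions.
#' @param expr_unit Declared unit of the expression values.
#' @param cohort_label Cohort name.
#' @param annotation_format `"tsv"` or `"bed"`.
#' @return A `cohort_bundle` (see [cohort_bundle()]).
#' @export
load_cohort_bundle <- function(expr_path, cna_path, mut_path, clinical_path,
                               annotation_path, expr_unit = "log2",
                               cohort_label = "", annotation_format = "tsv") {
  expr <- read_expression_tsv(expr_path, unit = expr_unit,
                              cohort_label = cohort_label)
  cna <- read_cna_tsv(cna_path)
  mut <- read_maf_lite(mut_path)
  clinical <- read_clinical_tsv(clinical_path)
  annotation <- read_annotation(annotation_path, format = annotation_format)
  cohort_bundle(expr, cna, mut, clinical, annotation,
                cohort_label = cohort_label)
}

#' Build a validated cohort bundle from in-memory tables
#'
#' Canonicalises sample and gene order (lexicographic) so the bundle is
#' invariant to input row/column permutations, intersects sample ids across
#' expression, CNA and clinical tables, and records dropped samples.
#'
#' @param expr An [expression_matrix()].
#' @param cna A [cna_matrix()].
#' @param mutations Mutation data frame (`sample_id`, `gene_id`,
#'   `variant_class`).
#' @param clinical Clinical data frame (see [read_clinical_tsv()]).
#' @param annotation Annotation data frame (see [read_annotation()]).
#' @param cohort_label Cohort name.
#' @export
cohort_bundle <- function(expr, cna, mutations, clinical, annotation,
                          cohort_label = attr(expr, "cohort_label")) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(cna, "cna_matrix"))
  validate_clinical(clinical)
  shared <- Reduce(intersect, list(colnames(expr), colnames(cna),
                                   clinical$sample_id))
  if (length(shared) == 0) stop("no samples shared across expression, CNA and clinical tables")
  all_seen <- unique(c(colnames(expr), colnames(cna), clinical$sample_id))
  dropped <- sort(setdiff(all_seen, shared))
  shared <- sort(shared)

  unit <- attr(expr, "unit")
  expr_m <- expr[sort(rownames(expr)), shared, drop = FALSE]
  expr <- expression_matrix(unclass(expr_m)[, , drop = FALSE], unit = unit,
                            cohort_label = cohort_label)
  cna <- cna_matrix(cna[sort(rownames(cna)), shared, drop = FALSE])
  mutations <- mutations[mutations$sample_id %in% shared, , drop = FALSE]
  mutations <- mutations[order(mutations$sample_id, mutations$gene_id), ,
                         drop = FALSE]
  rownames(mutations) <- NULL
  clinical <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  annotation <- annotation[order(annotation$gene_id), , drop = FALSE]
  rownames(annotation) <- NULL

  structure(list(expr = expr, cna = cna, mutations = mutations,
                 clinical = clinical, annotation = annotation,
                 cohort_label = cohort_label,
                 sample_ids = shared, dropped_samples = dropped),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Cohort bundle:", x$cohort_label, "\n")
  cat(sprintf("  %d samples (%d dropped at intersection)\n",
              length(x$sample_ids), length(x$dropped_samples)))
  cat(sprintf("  expression: %d genes [%s]; CNA: %d genes; mutations: %d rows\n",
              nrow(x$expr), attr(x$expr, "unit"), nrow(x$cna),
              nrow(x$mutations)))
  invisible(x)
}
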
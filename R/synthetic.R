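## Synthetic pan-cancer generator with planted ground truth.
##
## Emulates the data model the real analyses consume: per-cohort somatic
## alteration calls with planted mutual exclusivity between RB1 loss and
## the CDK4/6-deregulating events (and co-occurrence of CCND1/CDK4
## amplification), segmental deletions along a synthetic chromosome 13q
## with cis dosage effects on expression, a co-regulated RB-dependent
## transcriptional program, isogenic parental/RB1-null x vehicle/drug
## count data, and survival with hazard tied to program activity.

.modes <- c("rb1_loss", "cdkn2a_del", "ccnd1_amp", "cdk4_amp", "none")

.default_mode_probs <- function(n_cohorts) {
  base <- rbind(
    c(0.40, 0.10, 0.05, 0.05, 0.40),  # RB1-loss dominated
    c(0.05, 0.40, 0.10, 0.05, 0.40),  # CDKN2A-deletion dominated
    c(0.05, 0.10, 0.30, 0.15, 0.40),  # cyclin/CDK4 amplification dominated
    c(0.05, 0.05, 0.05, 0.05, 0.80)   # quiet
  )
  colnames(base) <- .modes
  base[rep_len(seq_len(nrow(base)), n_cohorts), , drop = FALSE]
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a modest pan-cancer-like study: 4 cohorts of 200
#' tumours, a 60-gene synthetic 13q with RB1 in the middle, a 50-gene
#' RB-dependent transcriptional program, heterozygous/deep cis dosage
#' shifts of 0.5/3.0 log2 units, program activation of 1.0 on RB1 loss and
#' a survival log-hazard coefficient of 0.8 per SD of program activity.
#'
#' @param n_cohorts Number of cohorts.
#' @param n_samples Samples per cohort (scalar, recycled).
#' @param arm_genes Genes on the synthetic 13q arm.
#' @param rb1_index Position of RB1 along the arm.
#' @param brca2_index Position of the BRCA2 marker along the arm.
#' @param program_genes Number of RB-dependent program genes.
#' @param rb_independent_genes Genes repressed by drug regardless of RB1
#'   (isogenic experiment contrast class).
#' @param n_background Null background genes.
#' @param decoy_genes Uncorrelated decoy candidates in the clinical matrix.
#' @param mode_probs `n_cohorts x 5` matrix of per-cohort probabilities
#'   over `rb1_loss, cdkn2a_del, ccnd1_amp, cdk4_amp, none`; rows sum to 1.
#' @param co_amp_prob Probability that a CCND1 amplification is joined by a
#'   CDK4 amplification (and vice versa).
#' @param background_event_rate Independent per-gene per-sample alteration
#'   rate (epsilon).
#' @param deep_fraction Probability a 13q deletion segment is deep (-2).
#' @param focal_weight Probability a 13q deletion is focal rather than
#'   arm-level.
#' @param dosage_shift_het,dosage_shift_deep Cis expression shifts (log2
#'   units) inside het-loss / deep-deleted segments.
#' @param amp_shift Cis expression gain (log2) for amplified genes.
#' @param cdkn2a_comp_shift Compensatory CDKN2A upregulation (log2) in
#'   RB1-lost tumours (drives the planted CDKN2A-RB1 anti-correlation).
#' @param program_gain Program activation (latent units) when RB1 is lost.
#' @param activity_sd Standard deviation of the latent program activity
#'   around its mode-determined mean. 0.4 makes the signature score a
#'   strong classifier of program-active tumours (AUC about 0.9 at the
#'   default activation with comfortable margin).
#' @param hazard_coef Log-hazard per SD of standardized program activity.
#' @param baseline_hazard Baseline event rate per month.
#' @param censor_horizon Uniform censoring horizon (months), chosen so that
#'   roughly 60 percent of follow-up is censored at the defaults.
#' @param rb1_mut_prob Probability an RB1-loss tumour additionally carries
#'   a truncating RB1 mutation.
#' @param nb_dispersion Negative-binomial dispersion of isogenic counts
#'   (0 = Poisson).
#' @param isogenic_lfc Planted log2 fold change of repressed genes in the
#'   isogenic experiment.
#' @param replicates Biological replicates per isogenic arm.
#' @param program_cor Target pairwise correlation of program genes in the
#'   clinical expression matrix.
#' @param seed Integer seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_cohorts = 4L, n_samples = 200L,
                             arm_genes = 60L, rb1_index = 30L,
                             brca2_index = 8L, program_genes = 50L,
                             rb_independent_genes = 30L,
                             n_background = 100L, decoy_genes = 20L,
                             mode_probs = NULL, co_amp_prob = 0.3,
                             background_event_rate = 0.02,
                             deep_fraction = 0.3, focal_weight = 0.5,
                             dosage_shift_het = 0.5, dosage_shift_deep = 3.0,
                             amp_shift = 1.0, cdkn2a_comp_shift = 1.0,
                             program_gain = 1.0, activity_sd = 0.4,
                             hazard_coef = 0.8,
                             baseline_hazard = 0.02, censor_horizon = 80,
                             rb1_mut_prob = 0.2, nb_dispersion = 0.005,
                             isogenic_lfc = -2, replicates = 2L,
                             program_cor = 0.6, seed = 1L) {
  if (is.null(mode_probs)) mode_probs <- .default_mode_probs(n_cohorts)
  mode_probs <- as.matrix(mode_probs)
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              n_samples = as.integer(rep_len(n_samples, n_cohorts)),
              arm_genes = as.integer(arm_genes),
              rb1_index = as.integer(rb1_index),
              brca2_index = as.integer(brca2_index),
              program_genes = as.integer(program_genes),
              rb_independent_genes = as.integer(rb_independent_genes),
              n_background = as.integer(n_background),
              decoy_genes = as.integer(decoy_genes),
              mode_probs = mode_probs, co_amp_prob = co_amp_prob,
              background_event_rate = background_event_rate,
              deep_fraction = deep_fraction, focal_weight = focal_weight,
              dosage_shift_het = dosage_shift_het,
              dosage_shift_deep = dosage_shift_deep,
              amp_shift = amp_shift,
              cdkn2a_comp_shift = cdkn2a_comp_shift,
              program_gain = program_gain, activity_sd = activity_sd,
              hazard_coef = hazard_coef,
              baseline_hazard = baseline_hazard,
              censor_horizon = censor_horizon,
              rb1_mut_prob = rb1_mut_prob,
              nb_dispersion = nb_dispersion, isogenic_lfc = isogenic_lfc,
              replicates = as.integer(replicates),
              program_cor = program_cor, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  counts <- c(cfg$n_cohorts, cfg$n_samples, cfg$arm_genes,
              cfg$program_genes, cfg$n_background, cfg$replicates)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (cfg$rb1_index < 1 || cfg$rb1_index > cfg$arm_genes) {
    stop("rb1_index must lie on the arm")
  }
  probs <- c(cfg$co_amp_prob, cfg$background_event_rate, cfg$deep_fraction,
             cfg$focal_weight, cfg$rb1_mut_prob, cfg$mode_probs)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]")
  if (nrow(cfg$mode_probs) != cfg$n_cohorts || ncol(cfg$mode_probs) != 5) {
    stop("mode_probs must be n_cohorts x 5")
  }
  if (any(abs(rowSums(cfg$mode_probs) - 1) > 1e-8)) {
    stop("mode_probs rows must sum to 1")
  }
  if (cfg$program_cor < 0 || cfg$program_cor >= 1) {
    stop("program_cor must be in [0,1)")
  }
  if (cfg$activity_sd < 0) stop("activity_sd must be non-negative")
  invisible(cfg)
}

## gene universe shared by all generators
synthetic_genes <- function(cfg) {
  arm <- sprintf("CHR13Q_%03d", seq_len(cfg$arm_genes))
  arm[cfg$rb1_index] <- "RB1"
  if (cfg$brca2_index >= 1 && cfg$brca2_index <= cfg$arm_genes &&
      cfg$brca2_index != cfg$rb1_index) {
    arm[cfg$brca2_index] <- "BRCA2"
  }
  list(pathway = c("CCND1", "CDK4", "CDKN2A"),
       arm = arm,
       program = sprintf("PROG_%03d", seq_len(cfg$program_genes)),
       rb_independent = sprintf("RBI_%03d", seq_len(cfg$rb_independent_genes)),
       background = sprintf("BG_%03d", seq_len(cfg$n_background)),
       decoy = sprintf("DECOY_%03d", seq_len(cfg$decoy_genes)))
}

synthetic_annotation <- function(cfg) {
  g <- synthetic_genes(cfg)
  arm_start <- 2.0e7 + (seq_len(cfg$arm_genes) - 1L) * 5e5
  ann <- rbind(
    data.frame(gene_id = "CCND1", chrom = "11", arm = "q",
               start = 69455873L, end = 69469242L),
    data.frame(gene_id = "CDK4", chrom = "12", arm = "q",
               start = 58141510L, end = 58146230L),
    data.frame(gene_id = "CDKN2A", chrom = "9", arm = "p",
               start = 21967752L, end = 21995301L),
    data.frame(gene_id = g$arm, chrom = "13", arm = "q",
               start = as.integer(arm_start),
               end = as.integer(arm_start + 2e4)),
    data.frame(gene_id = g$program,
               chrom = as.character(rep_len(1:8, cfg$program_genes)),
               arm = "q",
               start = 1e6L + seq_len(cfg$program_genes) * 1000L,
               end = 1e6L + seq_len(cfg$program_genes) * 1000L + 500L),
    data.frame(gene_id = g$rb_independent, chrom = "3", arm = "p",
               start = 2e6L + seq_len(cfg$rb_independent_genes) * 1000L,
               end = 2e6L + seq_len(cfg$rb_independent_genes) * 1000L + 500L),
    data.frame(gene_id = g$background,
               chrom = as.character(rep_len(c(4:8, 10:12), cfg$n_background)),
               arm = rep_len(c("p", "q"), cfg$n_background),
               start = 5e6L + seq_len(cfg$n_background) * 1000L,
               end = 5e6L + seq_len(cfg$n_background) * 1000L + 500L),
    data.frame(gene_id = g$decoy, chrom = "2", arm = "q",
               start = 8e6L + seq_len(cfg$decoy_genes) * 1000L,
               end = 8e6L + seq_len(cfg$decoy_genes) * 1000L + 500L)
  )
  ann
}

## one cohort; assumes the RNG state is already positioned
.generate_cohort <- function(cfg, cohort_idx, label) {
  g <- synthetic_genes(cfg)
  n <- cfg$n_samples[cohort_idx]
  samples <- sprintf("%s_S%04d", label, seq_len(n))
  genes <- c(g$pathway, g$arm, g$program, g$background)
  arm_rows <- match(g$arm, genes)
  rb1_row <- match("RB1", genes)

  mode <- sample(.modes, n, replace = TRUE,
                 prob = cfg$mode_probs[cohort_idx, ])

  cna <- matrix(0L, nrow = length(genes), ncol = n,
                dimnames = list(genes, samples))
  seg_start <- rep(NA_integer_, n)
  seg_end <- rep(NA_integer_, n)
  seg_depth <- rep(NA_integer_, n)
  mut_sample <- character(0)
  mut_gene <- character(0)
  mut_class <- character(0)

  for (s in seq_len(n)) {
    m <- mode[s]
    if (m == "rb1_loss") {
      if (stats::runif(1) < cfg$focal_weight) {
        st <- sample.int(cfg$rb1_index, 1L)
        en <- cfg$rb1_index - 1L + sample.int(cfg$arm_genes - cfg$rb1_index + 1L, 1L)
      } else {
        st <- 1L; en <- cfg$arm_genes
      }
      depth <- if (stats::runif(1) < cfg$deep_fraction) -2L else -1L
      cna[arm_rows[st:en], s] <- depth
      seg_start[s] <- st; seg_end[s] <- en; seg_depth[s] <- depth
      if (stats::runif(1) < cfg$rb1_mut_prob) {
        mut_sample <- c(mut_sample, samples[s])
        mut_gene <- c(mut_gene, "RB1")
        mut_class <- c(mut_class, "truncating")
      }
    } else if (m == "cdkn2a_del") {
      cna["CDKN2A", s] <- -2L
    } else if (m == "ccnd1_amp") {
      cna["CCND1", s] <- 2L
      if (stats::runif(1) < cfg$co_amp_prob) cna["CDK4", s] <- 2L
    } else if (m == "cdk4_amp") {
      cna["CDK4", s] <- 2L
      if (stats::runif(1) < cfg$co_amp_prob) cna["CCND1", s] <- 2L
    }
  }

  # independent background events on every gene
  if (cfg$background_event_rate > 0) {
    hits <- which(matrix(stats::runif(length(genes) * n), length(genes)) <
                    cfg$background_event_rate, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      type <- sample(c("mutation", "amp", "deep_del"), nrow(hits),
                     replace = TRUE)
      is_mut <- type == "mutation"
      mut_sample <- c(mut_sample, samples[hits[is_mut, 2]])
      mut_gene <- c(mut_gene, genes[hits[is_mut, 1]])
      mut_class <- c(mut_class, rep("missense", sum(is_mut)))
      # copy-number background only lands on so-far diploid cells
      cn_hits <- hits[!is_mut, , drop = FALSE]
      cn_code <- ifelse(type[!is_mut] == "amp", 2L, -2L)
      free <- cna[cn_hits] == 0L
      cna[cn_hits[free, , drop = FALSE]] <- cn_code[free]
    }
  }

  rb1_lost <- cna[rb1_row, ] <= -1L | samples %in% mut_sample[mut_gene == "RB1"]

  # expression, log2 scale, baseline N(8, 1)
  expr <- matrix(stats::rnorm(length(genes) * n, mean = 8, sd = 1),
                 nrow = length(genes), dimnames = list(genes, samples))
  # cis dosage: shift genes inside deleted segments / amplified genes
  expr[cna == -1L] <- expr[cna == -1L] - cfg$dosage_shift_het
  expr[cna == -2L] <- expr[cna == -2L] - cfg$dosage_shift_deep
  expr[cna == 2L] <- expr[cna == 2L] + cfg$amp_shift
  # compensatory CDKN2A upregulation on RB1 loss (planted anti-correlation)
  expr["CDKN2A", rb1_lost] <- expr["CDKN2A", rb1_lost] + cfg$cdkn2a_comp_shift
  # shared program activity, raised when RB1 is lost
  activity <- cfg$program_gain * as.numeric(rb1_lost) +
    stats::rnorm(n, 0, cfg$activity_sd)
  prog_rows <- match(g$program, genes)
  expr[prog_rows, ] <- expr[prog_rows, ] +
    matrix(activity, nrow = length(prog_rows), ncol = n, byrow = TRUE)

  # survival: hazard proportional to exp(beta_surv * standardized activity)
  std_act <- if (stats::sd(activity) > 0) {
    (activity - mean(activity)) / stats::sd(activity)
  } else rep(0, n)
  dfs <- .draw_survival(std_act, cfg$hazard_coef, cfg$baseline_hazard,
                        cfg$censor_horizon)
  os <- .draw_survival(std_act, cfg$hazard_coef, cfg$baseline_hazard * 0.7,
                       cfg$censor_horizon * 1.5)

  clinical <- data.frame(sample_id = samples, cohort = label,
                         subtype = NA_character_,
                         dfs_months = dfs$time, dfs_event = dfs$event,
                         os_months = os$time, os_event = os$event,
                         stringsAsFactors = FALSE)
  mutations <- data.frame(sample_id = mut_sample, gene_id = mut_gene,
                          variant_class = mut_class,
                          stringsAsFactors = FALSE)

  bundle <- cohort_bundle(
    expression_matrix(expr, unit = "log2", cohort_label = label),
    cna_matrix(cna), mutations, clinical, synthetic_annotation(cfg),
    cohort_label = label)

  list(bundle = bundle,
       truth = list(mode = stats::setNames(mode, samples),
                    seg_start = seg_start, seg_end = seg_end,
                    seg_depth = seg_depth, rb1_lost = rb1_lost,
                    activity = activity,
                    censoring_rate = mean(dfs$event == 0)))
}

.draw_survival <- function(std_act, beta, base_rate, horizon) {
  n <- length(std_act)
  t_event <- stats::rexp(n, rate = base_rate * exp(beta * std_act))
  t_cens <- stats::runif(n, 0, horizon)
  list(time = pmin(t_event, t_cens),
       event = as.integer(t_event <= t_cens))
}

## realized 2x2 odds ratios over the pathway genes under the default
## altered = {amplification, deep deletion, mutation} regime
.realized_or <- function(bundle, genes = c("CCND1", "CDK4", "CDKN2A", "RB1")) {
  cna <- bundle$cna
  mut <- bundle$mutations
  altered <- sapply(genes, function(g) {
    hit <- abs(cna[g, ]) == 2L
    hit | colnames(cna) %in% mut$sample_id[mut$gene_id == g]
  })
  pairs <- utils::combn(genes, 2)
  out <- data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ],
                    or = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    x <- altered[, pairs[1, i]]; y <- altered[, pairs[2, i]]
    a <- sum(x & y); b <- sum(x & !y); c <- sum(!x & y); d <- sum(!x & !y)
    out$or[i] <- if (a * d == 0 && b * c == 0) NA_real_ else (a * d) / (b * c)
  }
  out
}

#' Generate synthetic pan-cancer cohort bundles with planted truth
#'
#' Draws one latent pathway mode per tumour (planting mutual exclusivity
#' between RB1 loss and the CDK4/6-deregulating modes and co-occurrence of
#' CCND1/CDK4 amplification), contiguous 13q deletion segments covering
#' RB1 for RB1-loss tumours, cis-shifted expression, a shared RB-dependent
#' program and survival tied to program activity.
#'
#' @param config A [synthetic_config()].
#' @return A list with `bundles` (named list of `cohort_bundle`) and
#'   `truth` (per-cohort modes, segments, realized pathway odds ratios,
#'   program gene list, config echo).
#' @export
generate_pancancer <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  g <- synthetic_genes(config)
  labels <- sprintf("SYN%02d", seq_len(config$n_cohorts))
  bundles <- list()
  truth_cohorts <- list()
  for (i in seq_len(config$n_cohorts)) {
    res <- .generate_cohort(config, i, labels[i])
    bundles[[labels[i]]] <- res$bundle
    res$truth$pairwise_or <- .realized_or(res$bundle)
    truth_cohorts[[labels[i]]] <- res$truth
  }
  list(bundles = bundles,
       truth = list(cohorts = truth_cohorts,
                    program_genes = g$program,
                    arm_genes = g$arm,
                    hazard_coef = config$hazard_coef,
                    config = config))
}

#' Generate an isogenic perturbation count experiment
#'
#' Negative-binomial counts for parental and RB1-null lines under vehicle
#' or drug, with the planted RB-dependent program repressed only in
#' parental+drug and the planted RB-independent genes repressed under drug
#' in both genotypes. The decoy genes are also repressed RB-dependently in
#' the cell line — they model cell-line-specific drug responses that do
#' not form a co-regulated module in tumours, which is what the clinical
#' correlation-pruning step exists to remove.
#'
#' @param config A [synthetic_config()].
#' @return List with `counts` (genes x columns), `groups` (column design)
#'   and `truth` (`rb_dependent`, `rb_independent`, `decoy` gene lists,
#'   pairwise disjoint).
#' @export
generate_isogenic_experiment <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  set.seed(config$seed + 1L)
  g <- synthetic_genes(config)
  genes <- c(g$program, g$decoy, g$rb_independent, g$background)
  reps <- config$replicates
  design <- expand.grid(replicate = seq_len(reps),
                        treatment = c("vehicle", "drug"),
                        genotype = c("parental", "rb1_null"),
                        stringsAsFactors = FALSE)
  cols <- sprintf("%s_%s_%d", toupper(substr(design$genotype, 1, 3)),
                  toupper(design$treatment), design$replicate)
  base_mu <- 2^stats::rnorm(length(genes), mean = 10, sd = 0.8)
  fold <- matrix(1, nrow = length(genes), ncol = nrow(design),
                 dimnames = list(genes, cols))
  repressed_fold <- 2^config$isogenic_lfc
  par_drug <- design$genotype == "parental" & design$treatment == "drug"
  any_drug <- design$treatment == "drug"
  fold[g$program, par_drug] <- repressed_fold
  fold[g$decoy, par_drug] <- repressed_fold
  fold[g$rb_independent, any_drug] <- repressed_fold
  mu <- base_mu * fold
  counts <- matrix(0L, nrow = length(genes), ncol = nrow(design),
                   dimnames = list(genes, cols))
  if (config$nb_dispersion > 0) {
    counts[] <- stats::rnbinom(length(mu), mu = mu,
                               size = 1 / config$nb_dispersion)
  } else {
    counts[] <- stats::rpois(length(mu), lambda = mu)
  }
  list(counts = counts,
       groups = data.frame(column = cols, genotype = design$genotype,
                           treatment = design$treatment,
                           replicate = design$replicate,
                           stringsAsFactors = FALSE),
       truth = list(rb_dependent = g$program,
                    rb_independent = g$rb_independent,
                    decoy = g$decoy))
}

#' Generate a clinical expression matrix with a co-regulated program
#'
#' Stand-in for a large breast-cancer expression cohort: the planted
#' program genes share a latent factor giving pairwise correlation
#' `program_cor`; decoy candidates and all other genes are uncorrelated.
#'
#' @param config A [synthetic_config()].
#' @param n_samples Number of clinical samples (default 2000).
#' @return An [expression_matrix()] (unit `log2`).
#' @export
generate_clinical_expression <- function(config = synthetic_config(),
                                         n_samples = 2000L) {
  validate_synthetic_config(config)
  set.seed(config$seed + 2L)
  g <- synthetic_genes(config)
  genes <- c(g$program, g$decoy, g$rb_independent, g$background)
  samples <- sprintf("CLIN_S%05d", seq_len(n_samples))
  expr <- matrix(stats::rnorm(length(genes) * n_samples, 8, 1),
                 nrow = length(genes), dimnames = list(genes, samples))
  rho <- config$program_cor
  if (rho > 0) {
    latent <- stats::rnorm(n_samples)
    prog <- match(g$program, genes)
    noise <- matrix(stats::rnorm(length(prog) * n_samples), length(prog))
    expr[prog, ] <- 8 + sqrt(rho) * matrix(latent, length(prog), n_samples,
                                           byrow = TRUE) +
      sqrt(1 - rho) * noise
  }
  expression_matrix(expr, unit = "log2", cohort_label = "SYNCLIN")
}
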
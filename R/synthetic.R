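#' Configuration for the synthetic multi-omic cohort generator
#'
#' Defaults emulate the discovery design the package targets: a 28-sample
#' core split into two latent groups, 2000 genes with 10% planted
#' differential features per layer at mean |log2 FC| 1.5, 2000 matched
#' transcript-protein pairs with weak global coupling (median pairwise
#' Pearson r 0.168), an opposite group-specific protein/mRNA log-ratio shift,
#' a group-uninformative methylation layer, immune cell-type mixing with
#' T-cell enrichment in group 1, and clinical covariates (mean ages 7 vs 12
#' years, group-dependent location probabilities and progression hazards).
#'
#' @param n_samples Cohort size (default 28).
#' @param group_proportions Length-2 proportions summing to 1 (default .5/.5).
#' @param n_genes Core genes in the mRNA layer (default 2000).
#' @param n_matched_pairs Genes also measured as proteins (default 2000;
#'   must be <= `n_genes`).
#' @param frac_de Fraction of core features planted differential per layer
#'   (default 0.1).
#' @param effect_size Mean |log2 fold change| of planted features (default 1.5).
#' @param noise_sd Residual sd of log2 expression within a group (default 0.7).
#' @param coupling_rho Target pooled transcript-protein Pearson correlation
#'   (default 0.168).
#' @param ratio_shift_delta Group-specific shift on log2 scale: added to
#'   group-1 mRNA and group-2 protein, creating opposite protein/mRNA ratio
#'   dominance (default 0.5).
#' @param methylation_informative When `FALSE` (default) the methylation
#'   layer carries no group signal.
#' @param n_methylation Methylation features (default 500).
#' @param celltype_fractions 2 x 4 matrix of per-group mean mixing fractions
#'   for tumor, tcell, microglia, macrophage; rows sum to 1.
#' @param mixing_concentration Dirichlet concentration of per-sample
#'   fractions around the group means (default 100).
#' @param mixture_noise_sd Lognormal sd of the linear-scale mixture noise
#'   (default 0.05, i.e. 5% multiplicative noise).
#' @param markers_per_type Marker genes per cell type appended to the mRNA
#'   layer as the mixture block (default 20).
#' @param age_means,age_sds Per-group normal age parameters in years
#'   (defaults 7/12 and 3/4), truncated at 0.
#' @param location_probs Per-group probability of infratentorial location
#'   (defaults 0.40/0.85).
#' @param braf_fusion_prob Probability of KIAA1549::BRAF fusion status, both
#'   groups (default 0.85).
#' @param pfs_hazards Per-group exponential progression hazards per month
#'   (defaults 0.025/0.008; group 1 progresses faster).
#' @param censor_rate Exponential censoring rate per month (default 0.01).
#' @param seed Global seed; all sub-generators derive child seeds from it.
#' @return A `cohort_config` list (validated).
#' @export
cohort_config <- function(n_samples = 28,
                          group_proportions = c(0.5, 0.5),
                          n_genes = 2000,
                          n_matched_pairs = 2000,
                          frac_de = 0.1,
                          effect_size = 1.5,
                          noise_sd = 0.7,
                          coupling_rho = 0.168,
                          ratio_shift_delta = 0.5,
                          methylation_informative = FALSE,
                          n_methylation = 500,
                          celltype_fractions = rbind(
                            g1 = c(tumor = 0.60, tcell = 0.20,
                                   microglia = 0.10, macrophage = 0.10),
                            g2 = c(tumor = 0.75, tcell = 0.05,
                                   microglia = 0.10, macrophage = 0.10)),
                          mixing_concentration = 100,
                          mixture_noise_sd = 0.05,
                          markers_per_type = 20,
                          age_means = c(7, 12),
                          age_sds = c(3, 4),
                          location_probs = c(0.40, 0.85),
                          braf_fusion_prob = 0.85,
                          pfs_hazards = c(0.025, 0.008),
                          censor_rate = 0.01,
                          seed = 1) {
  cfg <- list(n_samples = as.integer(n_samples),
              group_proportions = group_proportions, n_genes = as.integer(n_genes),
              n_matched_pairs = as.integer(n_matched_pairs), frac_de = frac_de,
              effect_size = effect_size, noise_sd = noise_sd,
              coupling_rho = coupling_rho, ratio_shift_delta = ratio_shift_delta,
              methylation_informative = isTRUE(methylation_informative),
              n_methylation = as.integer(n_methylation),
              celltype_fractions = as.matrix(celltype_fractions),
              mixing_concentration = mixing_concentration,
              mixture_noise_sd = mixture_noise_sd,
              markers_per_type = as.integer(markers_per_type),
              age_means = age_means, age_sds = age_sds,
              location_probs = location_probs,
              braf_fusion_prob = braf_fusion_prob,
              pfs_hazards = pfs_hazards, censor_rate = censor_rate,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_samples < 4) stop("n_samples must be >= 4")
    if (length(group_proportions) != 2 ||
        abs(sum(group_proportions) - 1) > 1e-8 || any(group_proportions <= 0))
      stop("group_proportions must be 2 positive values summing to 1")
    if (abs(coupling_rho) > 1) stop("|coupling_rho| must be <= 1")
    if (n_matched_pairs > n_genes) stop("n_matched_pairs must be <= n_genes")
    if (frac_de < 0 || frac_de > 1) stop("frac_de must lie in [0, 1]")
    if (noise_sd <= 0) stop("noise_sd must be positive")
    f <- celltype_fractions
    if (any(f < 0) || any(f > 1) || any(abs(rowSums(f) - 1) > 1e-8))
      stop("celltype_fractions rows must be in [0, 1] and sum to 1")
    if (any(pfs_hazards <= 0)) stop("pfs_hazards must be positive")
    if (any(location_probs < 0 | location_probs > 1))
      stop("location_probs must lie in [0, 1]")
  })
  invisible(cfg)
}

#' Closed-form coupling calibration
#'
#' For the construction `protein = rho * z + sqrt(1 - rho^2) * e` (z the
#' standardized transcript signal, e independent standard noise) the
#' population Pearson correlation equals `rho` exactly, so the calibrated
#' parameter is the target itself. The function exists to make that contract
#' explicit and validated.
#'
#' @param target_r Desired transcript-protein correlation, |r| <= 1.
#' @return The coupling parameter rho (= `target_r`).
#' @export
calibrate_coupling <- function(target_r) {
  if (!is.numeric(target_r) || length(target_r) != 1 || is.na(target_r))
    stop("target_r must be a single number")
  if (abs(target_r) > 1) stop("|target_r| must be <= 1")
  target_r
}

# Noise-coupling parameter compensated for the variance/covariance that the
# group-specific ratio shift adds to both layers, so the OBSERVED pooled
# correlation over balanced groups matches `target`. With shift delta on
# group-1 mRNA and group-2 protein (balanced groups), indicator covariance is
# -1/4, hence:
#   rho' = (target * (sigma^2 + delta^2/4) + delta^2/4) / sigma^2
.compensated_rho <- function(target, delta, sigma, p1 = 0.5) {
  v_ind <- p1 * (1 - p1)
  rho <- (target * (sigma^2 + delta^2 * v_ind) + delta^2 * v_ind) / sigma^2
  if (abs(rho) > 1)
    stop("requested coupling_rho unattainable given ratio_shift_delta and noise_sd")
  rho
}

#' Simulate progression-free survival
#'
#' Exponential event times with a per-group hazard and independent
#' exponential censoring.
#'
#' @param labels Group label per sample (2 levels, ordered by first
#'   occurrence; first level uses `hazards[1]`).
#' @param hazards Positive per-group event rates (per month).
#' @param censor_rate Censoring rate (0 = no censoring).
#' @param seed Random seed.
#' @return List with `pfs_time` (months) and `pfs_event` (1 = progression,
#'   0 = censored).
#' @export
simulate_survival <- function(labels, hazards, censor_rate = 0, seed = 1) {
  if (any(hazards <= 0)) stop("hazards must be positive")
  if (censor_rate < 0) stop("censor_rate must be >= 0")
  g <- two_groups(labels)
  n <- length(labels)
  set.seed(seed)
  rate <- ifelse(seq_len(n) %in% g$idx1, hazards[1], hazards[2])
  t_event <- stats::rexp(n, rate)
  t_cens <- if (censor_rate == 0) rep(Inf, n) else stats::rexp(n, censor_rate)
  list(pfs_time = pmin(t_event, t_cens),
       pfs_event = as.numeric(t_event <= t_cens))
}

#' Simulate a multi-omic cohort with planted ground truth
#'
#' Generates mRNA, protein and methylation layers plus a clinical table under
#' the structure described in [cohort_config()]: two latent groups with
#' planted differential features in the expression layers, matched
#' transcript-protein pairs whose noise components are coupled so the pooled
#' per-pair Pearson correlation matches `coupling_rho`, an opposite
#' group-specific log protein/mRNA shift, Beta-distributed group-independent
#' methylation, and a cell-type mixture block of immune marker genes in the
#' mRNA layer driven by per-sample Dirichlet fractions. Fully deterministic
#' given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort`: list with `mrna`, `protein`, `methylation`
#'   ([omic_matrix()]), `clinical` (`clinical_table`), `true_labels`,
#'   `true_de_features` (per layer, with direction), `true_fractions`
#'   (samples x cell types), `signature` ([signature_matrix()]) and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  cfg <- config
  seeds <- child_seeds(cfg$seed, 3)
  set.seed(seeds[1])

  n <- cfg$n_samples
  n1 <- round(n * cfg$group_proportions[1])
  if (n1 < 2 || n - n1 < 2) stop("each group needs >= 2 samples")
  labels <- rep(c("group1", "group2"), c(n1, n - n1))
  sample_ids <- sprintf("S%03d", seq_len(n))
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  g1 <- labels == "group1"

  ## --- core expression layers -------------------------------------------
  mu_m <- stats::rnorm(cfg$n_genes, 6, 1.5)
  mu_p <- stats::rnorm(cfg$n_genes, 4, 1.5)
  n_de <- round(cfg$frac_de * cfg$n_genes)
  de_m <- de_p <- integer(0)
  d_m <- d_p <- numeric(cfg$n_genes)
  if (n_de > 0) {
    de_m <- sort(sample.int(cfg$n_genes, n_de))
    de_p <- sort(sample.int(cfg$n_genes, n_de))
    d_m[de_m] <- cfg$effect_size * sample(c(-1, 1), n_de, replace = TRUE)
    d_p[de_p] <- cfg$effect_size * sample(c(-1, 1), n_de, replace = TRUE)
  }
  sig <- cfg$noise_sd
  z <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n)
  e <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n)
  rho <- .compensated_rho(cfg$coupling_rho, cfg$ratio_shift_delta, sig,
                          cfg$group_proportions[1])
  # Planted effects are the REALIZED between-group contrast: the global ratio
  # shift (group-1 mRNA / group-2 protein) is netted out of the per-feature
  # effect so a planted feature's log2 fold change equals d exactly.
  eff_m <- d_m
  eff_m[de_m] <- d_m[de_m] - cfg$ratio_shift_delta
  eff_p <- d_p
  eff_p[de_p] <- d_p[de_p] + cfg$ratio_shift_delta
  mrna <- mu_m + outer(eff_m, as.numeric(g1)) + sig * z +
    cfg$ratio_shift_delta * rep(as.numeric(g1), each = cfg$n_genes)
  prot_noise <- rho * z + sqrt(1 - rho^2) * e
  protein_all <- mu_p + outer(eff_p, as.numeric(g1)) + sig * prot_noise +
    cfg$ratio_shift_delta * rep(as.numeric(!g1), each = cfg$n_genes)
  pair_idx <- seq_len(cfg$n_matched_pairs)
  protein <- protein_all[pair_idx, , drop = FALSE]

  ## --- cell-type mixture block ------------------------------------------
  types <- colnames(cfg$celltype_fractions)
  n_types <- length(types)
  mk <- cfg$markers_per_type
  imm_ids <- sprintf("IMM_%s_%02d", rep(types, each = mk), rep(seq_len(mk), n_types))
  profiles <- matrix(stats::runif(mk * n_types * n_types, 1, 8),
                     mk * n_types, n_types, dimnames = list(imm_ids, types))
  for (j in seq_len(n_types)) {
    own <- (j - 1) * mk + seq_len(mk)
    profiles[own, j] <- stats::runif(mk, 80, 120)
  }
  fractions <- t(vapply(seq_len(n), function(i) {
    a <- cfg$celltype_fractions[if (g1[i]) 1 else 2, ] * cfg$mixing_concentration
    x <- stats::rgamma(n_types, shape = a)
    x / sum(x)
  }, numeric(n_types)))
  dimnames(fractions) <- list(sample_ids, types)
  bulk <- profiles %*% t(fractions)
  if (cfg$mixture_noise_sd > 0)
    bulk <- bulk * exp(matrix(stats::rnorm(length(bulk), 0, cfg$mixture_noise_sd),
                              nrow(bulk)))
  mrna_full <- rbind(mrna, log2(bulk))
  rownames(mrna_full) <- c(gene_ids, imm_ids)
  colnames(mrna_full) <- sample_ids
  rownames(protein) <- gene_ids[pair_idx]
  colnames(protein) <- sample_ids

  ## --- methylation layer -------------------------------------------------
  mm <- stats::runif(cfg$n_methylation, 0.1, 0.9)
  phi <- 20
  meth <- matrix(stats::rbeta(cfg$n_methylation * n, rep(mm * phi, n),
                              rep((1 - mm) * phi, n)),
                 cfg$n_methylation, n,
                 dimnames = list(sprintf("CPG%04d", seq_len(cfg$n_methylation)),
                                 sample_ids))
  if (cfg$methylation_informative) {
    n_dm <- max(1, round(cfg$frac_de * cfg$n_methylation))
    dm <- sample.int(cfg$n_methylation, n_dm)
    shift <- meth[dm, g1, drop = FALSE] + 0.2
    meth[dm, g1] <- pmin(shift, 0.999)
  }

  ## --- clinical table ----------------------------------------------------
  set.seed(seeds[2])
  age <- ifelse(g1, stats::rnorm(n, cfg$age_means[1], cfg$age_sds[1]),
                stats::rnorm(n, cfg$age_means[2], cfg$age_sds[2]))
  age <- pmax(age, 0.5)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  location <- ifelse(stats::runif(n) < ifelse(g1, cfg$location_probs[1],
                                              cfg$location_probs[2]),
                     "infratentorial", "supratentorial")
  braf <- ifelse(stats::runif(n) < cfg$braf_fusion_prob, "fusion", "wildtype")
  surv <- simulate_survival(labels, cfg$pfs_hazards, cfg$censor_rate,
                            seed = seeds[3])
  clinical <- clinical_table(data.frame(
    sample_id = sample_ids, age = age, sex = sex, location = location,
    braf_status = braf, pfs_time = surv$pfs_time, pfs_event = surv$pfs_event,
    group = labels, stringsAsFactors = FALSE))

  structure(list(
    mrna = omic_matrix(mrna_full, "mrna", is_log = TRUE),
    protein = omic_matrix(protein, "protein", is_log = TRUE),
    methylation = omic_matrix(meth, "methylation", is_log = FALSE),
    clinical = clinical,
    true_labels = stats::setNames(labels, sample_ids),
    true_de_features = list(
      mrna = data.frame(feature_id = gene_ids[de_m],
                        direction = ifelse(d_m[de_m] > 0, "up", "down"),
                        stringsAsFactors = FALSE),
      protein = data.frame(feature_id = gene_ids[intersect(de_p, pair_idx)],
                           direction = ifelse(d_p[intersect(de_p, pair_idx)] > 0,
                                              "up", "down"),
                           stringsAsFactors = FALSE)),
    true_fractions = fractions,
    # every mRNA feature with a real group contrast: planted DE genes plus the
    # marker genes of cell types whose group mixing fractions differ
    true_informative_features = list(
      mrna = c(gene_ids[de_m],
               imm_ids[rep(abs(cfg$celltype_fractions[1, ] -
                                 cfg$celltype_fractions[2, ]) > 1e-12,
                           each = mk)]),
      protein = gene_ids[intersect(de_p, pair_idx)]),
    signature = signature_matrix(profiles),
    config = cfg), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples (%s)\n", length(x$true_labels),
              paste(table(x$true_labels), collapse = " + ")))
  cat(sprintf("  mrna %d x %d, protein %d x %d, methylation %d x %d\n",
              nrow(x$mrna$values), ncol(x$mrna$values),
              nrow(x$protein$values), ncol(x$protein$values),
              nrow(x$methylation$values), ncol(x$methylation$values)))
  cat(sprintf("  planted DE: %d mrna, %d protein; coupling target %.3f\n",
              nrow(x$true_de_features$mrna), nrow(x$true_de_features$protein),
              x$config$coupling_rho))
  invisible(x)
}

#' Write all cohort layers and ground truth to a directory
#'
#' Emits the standard tabular formats of the I/O module plus a ground-truth
#' sidecar table (`truth_labels.tsv`, `truth_fractions.tsv`,
#' `truth_de_<layer>.tsv`).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_omic_matrix(cohort$mrna, file.path(dir, "mrna.tsv"))
  write_omic_matrix(cohort$protein, file.path(dir, "protein.tsv"))
  write_omic_matrix(cohort$methylation, file.path(dir, "methylation.tsv"))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_signature_matrix(cohort$signature, file.path(dir, "signature_matrix.tsv"))
  utils::write.table(data.frame(sample_id = names(cohort$true_labels),
                                group = cohort$true_labels),
                     file.path(dir, "truth_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(cohort$true_fractions),
                                cohort$true_fractions),
                     file.path(dir, "truth_fractions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (ly in names(cohort$true_de_features))
    utils::write.table(cohort$true_de_features[[ly]],
                       file.path(dir, sprintf("truth_de_%s.tsv", ly)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
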
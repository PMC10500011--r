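#' Configuration for an end-to-end pipeline run
#'
#' Bundles every stage's settings with one global seed and an output
#' directory. Input is either a synthetic [cohort_config()] (the default) or
#' a list of file paths to the tabular formats of the I/O module.
#'
#' @param out_dir Output directory for artifacts and the manifest.
#' @param cohort A [cohort_config()] (synthetic input), or a list with paths
#'   `mrna`, `protein`, `clinical` and optionally `methylation`,
#'   `signature_matrix`.
#' @param layers Which layers enter the fusion (subset of
#'   `c("mrna", "protein", "methylation")`).
#' @param snf [snf_params()].
#' @param k Number of clusters, or `"auto"` for eigengap selection.
#' @param k_max Largest candidate k for the eigengap rule.
#' @param p_thresh,fc_thresh Differential-expression thresholds.
#' @param n_per_direction Signature size per direction.
#' @param gene_sets Optional `gene_set_collection` or GMT path for
#'   enrichment; when `NULL`, synthetic sets are built from the cohort's
#'   cell-type markers plus random sets (synthetic input only).
#' @param validation Optional second cohort for submap: a `synthetic_cohort`
#'   or a list with `matrix` ([omic_matrix()]) and `labels`.
#' @param n_permutations Permutations for enrichment and submap.
#' @param seed Global seed; all stochastic stages derive child seeds from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            cohort = cohort_config(),
                            layers = c("mrna", "protein"),
                            snf = snf_params(),
                            k = "auto", k_max = 6,
                            p_thresh = 0.05, fc_thresh = 2,
                            n_per_direction = 50,
                            gene_sets = NULL,
                            validation = NULL,
                            n_permutations = 1000,
                            seed = 1) {
  layers <- match.arg(layers, c("mrna", "protein", "methylation"),
                      several.ok = TRUE)
  if (!identical(k, "auto") && (!is.numeric(k) || k < 2)) stop("k must be 'auto' or >= 2")
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  structure(list(out_dir = out_dir, cohort = cohort, layers = layers,
                 snf = snf, k = k, k_max = k_max, p_thresh = p_thresh,
                 fc_thresh = fc_thresh, n_per_direction = n_per_direction,
                 gene_sets = gene_sets, validation = validation,
                 n_permutations = n_permutations, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full discovery-to-validation pipeline
#'
#' Executes, in order: cohort acquisition, sample alignment, per-layer
#' affinity graphs, cross-network fusion, cluster-number selection and
#' spectral clustering, per-layer differential signatures, semi-supervised
#' group extension, matched-pair correlation and group-ratio analysis,
#' preranked gene-set enrichment and single-sample immune scoring, cell-type
#' deconvolution with group contrasts, clinical association and survival
#' tests, and (when a validation cohort is supplied) cross-cohort submap.
#' Every artifact is written under `config$out_dir` as tab-separated text and
#' recorded in `manifest.json` (inputs, parameters, seed, package version,
#' per-stage wall time), so any stage is re-runnable in isolation. A stage
#' error halts the run naming the stage, preserving earlier outputs.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly; the manifest is the run record.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- child_seeds(config$seed, 6)
  manifest <- list(package = "omicfuse",
                   version = as.character(utils::packageVersion("omicfuse")),
                   seed = config$seed,
                   parameters = list(K = config$snf$K, mu = config$snf$mu,
                                     T = config$snf$T, k = config$k,
                                     p_thresh = config$p_thresh,
                                     fc_thresh = config$fc_thresh,
                                     n_per_direction = config$n_per_direction,
                                     n_permutations = config$n_permutations,
                                     layers = config$layers),
                   stages = list())
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "error", message = conditionMessage(e))
      .write_manifest(manifest, config$out_dir)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "completed",
                                     wall_time_s = round(proc.time()[["elapsed"]] - t0, 3),
                                     outputs = attr(res, "outputs"))
    res
  }
  out <- function(...) file.path(config$out_dir, ...)
  with_outputs <- function(x, files) {
    if (is.null(x)) x <- list()
    attr(x, "outputs") <- files
    x
  }

  ## -- cohort -------------------------------------------------------------
  cohort <- stage("cohort", function() {
    if (inherits(config$cohort, "cohort_config")) {
      cc <- config$cohort
      cc$seed <- seeds[1]
      sim <- simulate_cohort(cc)
      write_cohort(sim, out("cohort"))
      with_outputs(sim, "cohort/")
    } else {
      paths <- config$cohort
      sim <- list(mrna = read_omic_matrix(paths$mrna, "mrna"),
                  protein = read_omic_matrix(paths$protein, "protein"),
                  methylation = if (!is.null(paths$methylation))
                    read_omic_matrix(paths$methylation, "methylation", is_log = FALSE),
                  clinical = read_clinical_table(paths$clinical),
                  signature = if (!is.null(paths$signature_matrix))
                    read_signature_matrix(paths$signature_matrix))
      with_outputs(sim, character())
    }
  })

  aligned <- stage("align", function() {
    mats <- Filter(Negate(is.null), cohort[config$layers])
    al <- align_cohort(mats, cohort$clinical)
    with_outputs(al, character())
  })

  affinities <- stage("affinity", function() {
    lapply(aligned$matrices, build_affinity, params = config$snf)
  })

  fusion <- stage("fuse", function() {
    fus <- fuse_networks(affinities, config$snf)
    write_omic_matrix(omic_matrix(fus$fused, "fused"), out("fused.tsv"))
    export_network(fus$fused, out("network_edges.tsv"))
    with_outputs(fus, c("fused.tsv", "network_edges.tsv"))
  })

  clustering <- stage("cluster", function() {
    eg <- estimate_num_clusters(fusion$fused, k_max = config$k_max)
    k <- if (identical(config$k, "auto")) eg$best_k else config$k
    labels <- spectral_cluster(fusion$fused, k, seed = seeds[2])
    lab <- paste0("group", labels)
    names(lab) <- names(labels)
    utils::write.table(data.frame(sample_id = names(lab), group = lab),
                       out("labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(k = seq_along(eg$eigengaps) + 1,
                                  eigengap = eg$eigengaps),
                       out("eigengaps.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    with_outputs(list(labels = lab, k = k, eigengaps = eg$eigengaps),
                 c("labels.tsv", "eigengaps.tsv"))
  })
  labels <- clustering$labels

  signatures <- stage("signatures", function() {
    res <- list()
    for (ly in intersect(config$layers, c("mrna", "protein"))) {
      de <- differential_features(aligned$matrices[[ly]], labels,
                                  config$p_thresh, config$fc_thresh)
      utils::write.table(de, out(sprintf("de_%s.tsv", ly)), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      sg <- suppressWarnings(build_signature(de, config$n_per_direction))
      write_signature(sg, out(sprintf("signature_%s.tsv", ly)))
      res[[ly]] <- list(de = de, signature = sg)
    }
    with_outputs(res, as.vector(outer(c("de_", "signature_"),
                                      names(res), paste0)))
  })

  extension <- stage("extend", function() {
    ly <- names(signatures)[1]
    full <- if (!is.null(cohort[[ly]])) cohort[[ly]] else aligned$matrices[[ly]]
    ext <- extend_groups_hcl(full, signatures[[ly]]$signature, labels)
    utils::write.table(data.frame(sample_id = names(ext), group = ext),
                       out("labels_extended.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    with_outputs(ext, "labels_extended.tsv")
  })

  stage("posttranscriptional", function() {
    if (!all(c("mrna", "protein") %in% names(aligned$matrices)))
      return(with_outputs(NULL, character()))
    pairs <- match_pairs(aligned$matrices$mrna, aligned$matrices$protein)
    pc <- pair_correlations(pairs)
    utils::write.table(pc$table, out("pair_correlations.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rt <- group_ratio(pairs, labels)
    utils::write.table(rt$per_pair, out("group_ratio_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(rt$per_sample, out("group_ratio_samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mw <- ratio_shift_test(rt$per_pair[[rt$groups[1]]], rt$per_pair[[rt$groups[2]]])
    summ <- data.frame(median_r = pc$median_r, mw_U = mw$U, mw_p = mw$p,
                       mw_method = mw$method)
    utils::write.table(summ, out("posttranscriptional_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    with_outputs(list(median_r = pc$median_r, mw = mw),
                 c("pair_correlations.tsv", "group_ratio_pairs.tsv",
                   "group_ratio_samples.tsv", "posttranscriptional_summary.tsv"))
  })

  stage("enrichment", function() {
    if (is.null(signatures$mrna) || is.null(aligned$matrices$mrna))
      return(with_outputs(NULL, character()))
    sets <- config$gene_sets
    if (is.null(sets) && !is.null(cohort$signature)) {
      # synthetic collection: the cohort's cell-type marker sets plus seeded
      # random sets over the core genes
      set.seed(seeds[3])
      marker_sets <- split(cohort$signature$feature_ids,
                           sub("^IMM_([a-z]+)_.*$", "\\1",
                               cohort$signature$feature_ids))
      core <- setdiff(aligned$matrices$mrna$feature_ids,
                      cohort$signature$feature_ids)
      rand_sets <- lapply(1:10, function(i) sample(core, 25))
      names(rand_sets) <- sprintf("random_set_%02d", 1:10)
      all_sets <- c(marker_sets, rand_sets)
      sets <- structure(list(sets = all_sets,
                             descriptions = stats::setNames(names(all_sets),
                                                            names(all_sets))),
                        class = "gene_set_collection")
      write_gmt(sets, out("synthetic_gene_sets.gmt"))
    }
    if (is.null(sets)) return(with_outputs(NULL, character()))
    de <- signatures$mrna$de
    ranked <- rank_features(stats::setNames(de$t, de$feature_id))
    gs <- preranked_gsea(ranked, sets, n_permutations = config$n_permutations,
                         seed = seeds[4], min_size = 5, filter = FALSE)
    utils::write.table(gs, out("gsea_mrna.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    edges <- enrichment_map_edges(gs, sets)
    utils::write.table(edges, out("enrichment_map_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    tcell <- grep("tcell", names(sets$sets), value = TRUE)
    scores <- NULL
    if (length(tcell)) {
      scores <- ssgsea_score(aligned$matrices$mrna, sets$sets[[tcell[1]]])
      utils::write.table(data.frame(sample_id = names(scores),
                                    immune_score = scores),
                         out("immune_scores.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    with_outputs(list(gsea = gs, scores = scores),
                 c("gsea_mrna.tsv", "enrichment_map_edges.tsv"))
  })

  stage("deconvolution", function() {
    if (is.null(cohort$signature) || is.null(aligned$matrices$mrna))
      return(with_outputs(NULL, character()))
    dec <- estimate_fractions(aligned$matrices$mrna, cohort$signature)
    utils::write.table(data.frame(sample_id = rownames(dec$fractions),
                                  dec$fractions, residual = dec$residuals),
                       out("fractions.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cmp <- compare_fractions(dec, labels)
    utils::write.table(cmp, out("fraction_contrasts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    with_outputs(list(fractions = dec, contrasts = cmp),
                 c("fractions.tsv", "fraction_contrasts.tsv"))
  })

  stage("clinical", function() {
    cl <- aligned$clinical
    if (is.null(cl)) return(with_outputs(NULL, character()))
    gl <- labels[cl$sample_id]
    age <- ratio_shift_test(cl$age[gl == "group1"], cl$age[gl != "group1"])
    loc <- categorical_association(table(gl, cl$location))
    lr <- logrank_test(cl$pfs_time, cl$pfs_event, gl)
    km <- km_curves(cl$pfs_time, cl$pfs_event, gl)
    utils::write.table(km, out("km_curves.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tests <- data.frame(
      test = c("age_mann_whitney", "location_association", "pfs_logrank"),
      statistic = c(age$U, loc$statistic, lr$chisq),
      p = c(age$p, loc$p, lr$p),
      method = c(age$method, loc$method, "logrank"))
    utils::write.table(tests, out("clinical_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    with_outputs(tests, c("km_curves.tsv", "clinical_tests.tsv"))
  })

  stage("submap", function() {
    if (is.null(config$validation))
      return(with_outputs(NULL, character()))
    val <- config$validation
    if (inherits(val, "synthetic_cohort"))
      val <- list(matrix = val$mrna, labels = unname(val$true_labels))
    disc <- if (!is.null(aligned$matrices$mrna)) aligned$matrices$mrna else aligned$matrices[[1]]
    sm <- submap(disc, labels, val$matrix, val$labels,
                 n_permutations = config$n_permutations, seed = seeds[5])
    utils::write.table(data.frame(group = rownames(sm$sa_matrix), sm$sa_matrix),
                       out("submap_sa.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    with_outputs(sm, "submap_sa.tsv")
  })

  manifest$wall_time_s <- round(proc.time()[["elapsed"]] - t_all, 3)
  .write_manifest(manifest, config$out_dir)
  invisible(config$out_dir)
}

.write_manifest <- function(manifest, dir) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
}
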
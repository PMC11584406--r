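# End-to-end orchestration: simulate -> stripes -> connectivity ->
# methylation -> two-phase model, with a YAML-style config, seeded
# determinism and a machine-readable run manifest.

#' Default pipeline configuration
#'
#' Every analysis threshold defaults to the protocol's quoted value
#' (long/short distance thresholds, window sizes, FDR cutoffs, consensus
#' minima, pairing distance, extraction resolution, methylation cutoffs,
#' fold thresholds); cohort size, sequencing depth and model widths are
#' artifact defaults sized for a desk-scale run.
#'
#' @param seed Integer seed governing every stochastic step.
#' @param out_dir Output directory for run artifacts.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(seed = 1, out_dir = tempfile("cisconn_run_")) {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    cohort = list(n_mucosa = 2, n_polyp = 2, n_adenocarcinoma = 2,
                  depth = 300000),
    genome = list(n_chrom = 2, chrom_size = 6e6, genes_per_mb = 10),
    stripes = list(long_min = 1500, short_max = 1000, local_window = 2000,
                   background_window = 50000, step = 100, fdr = 0.01,
                   min_samples = 3, min_size = 500),
    connectivity = list(max_dist = 200000, resolution = 1000,
                        peak_pad = 500, long_min = 1500),
    methylation = list(demethylated_max = 25, methylated_min = 40,
                       min_diff = 15, fdr = 0.1),
    loops = list(fold = 1.2, inner = 2, outer = 10),
    model = list(test_frac = 0.25, epochs = 25, hidden = c(64, 32, 16),
                 dropout = 0.2, batch = 64, lr = 1e-3)
  ), class = "run_config")
}

read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (k in names(cfg)) {
    if (is.list(cfg[[k]]) && is.list(base[[k]])) {
      for (k2 in names(cfg[[k]])) base[[k]][[k2]] <- cfg[[k]][[k2]]
    } else {
      base[[k]] <- cfg[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("config must carry a seed")
  if (cfg$cohort$depth <= 0) stop("depth must be positive")
  ns <- with(cfg$cohort, n_mucosa + n_polyp + n_adenocarcinoma)
  if (ns < 3) stop("cohort must contain at least three samples")
  if (min(cfg$cohort$n_mucosa, cfg$cohort$n_polyp,
          cfg$cohort$n_adenocarcinoma) < 1)
    stop("every stage needs at least one sample")
  invisible(cfg)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates a multi-stage cohort from planted truth, calls per-sample
#' stripes and cross-sample consensus anchors, computes per-gene
#' connectivity per sample, classifies promoter methylation and its change,
#' assembles the initial feature table and fits the two-phase predictive
#' model. All artifacts (anchors BED, connectivity and feature TSVs,
#' manifest JSON) are written to the configured output directory; the run is
#' deterministic given the seed.
#'
#' @param config A `run_config` (see [default_config()]) or the path to a
#'   YAML config file.
#' @return Invisibly, a list with the truth, manifest, anchors,
#'   connectivity tables, methylation summary, fitted model and output
#'   paths.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file '%s' not found",
                                           config))
    config <- read_run_config(config)
  }
  validate_config(config)
  seed <- config$seed
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  g <- config$genome
  cs <- stats::setNames(rep(as.integer(g$chrom_size), g$n_chrom),
                        paste0("chr", seq_len(g$n_chrom)))
  truth <- synthetic_truth(chrom_sizes = cs, genes_per_mb = g$genes_per_mb,
                           seed = seed)
  manifest <- cohort_manifest(config$cohort$n_mucosa, config$cohort$n_polyp,
                              config$cohort$n_adenocarcinoma)
  tracks <- simulate_tracks(truth, manifest, seed = seed)
  sp <- config$stripes
  params <- stripe_params(long_min = sp$long_min, short_max = sp$short_max,
                          local_window = sp$local_window,
                          background_window = sp$background_window,
                          step = sp$step, fdr = sp$fdr)

  genes <- gene_models(truth$genes)
  pairs <- pair_promoter_enhancers(
    genes, tracks$peaks[tracks$peaks$type != "promoter", ],
    max_dist = config$connectivity$max_dist)

  per_sample_stripes <- list()
  conn_tables <- list()
  for (s in manifest$sample_id) {
    rec <- simulate_contacts(truth, s, depth = config$cohort$depth,
                             seed = seed, manifest = manifest)
    st <- call_sample_stripes(rec, cs, params)
    per_sample_stripes[[s]] <- st
    conn_tables[[s]] <- connectivity(
      rec, genes, pairs,
      peak_fe = stats::setNames(tracks$peak_fe[, s],
                                rownames(tracks$peak_fe)),
      fe_track = tracks$fe_track[tracks$fe_track$sample == s, ],
      stripe_stats = st,
      methylation = tracks$methylation[tracks$methylation$sample == s, ],
      resolution = config$connectivity$resolution,
      peak_pad = config$connectivity$peak_pad,
      long_min = config$connectivity$long_min,
      params = params)
  }

  anchors <- consensus_anchors(per_sample_stripes, fdr = sp$fdr,
                               min_samples = min(sp$min_samples,
                                                 nrow(manifest)),
                               min_size = sp$min_size,
                               autosomes = names(cs))

  # Stage-mean tables for gene filtering and features.
  stage_means <- lapply(split(manifest$sample_id, manifest$stage), function(ss) {
    cols <- c("connectivity", "promoter_accessibility",
              "promoter_stripe_strength", "promoter_methylation",
              "enhancer_accessibility")
    m <- sapply(cols, function(cl)
      rowMeans(sapply(ss, function(s) conn_tables[[s]][[cl]]), na.rm = TRUE))
    df <- data.frame(gene_id = conn_tables[[1]]$gene_id, m,
                     stringsAsFactors = FALSE)
    df
  })
  stage_means <- stage_means[c("mucosa", "polyp", "adenocarcinoma")]
  filt <- filter_gene_set(stage_means)

  # Promoter methylation classification and mucosa->adenocarcinoma change.
  zones <- data.frame(region_id = genes$gene_id, chrom = genes$chrom,
                      start = genes$prom_start, end = genes$prom_end)
  meth <- tracks$methylation
  samp_stage <- stats::setNames(manifest$stage, manifest$sample_id)
  cpg_m <- meth[samp_stage[meth$sample] == "mucosa", ]
  cpg_a <- meth[samp_stage[meth$sample] == "adenocarcinoma", ]
  dm <- differential_methylation(zones, cpg_m, cpg_a,
                                 min_diff = config$methylation$min_diff,
                                 fdr = config$methylation$fdr)
  mucosa_meth <- stage_means$mucosa$promoter_methylation
  dm$state_mucosa <- classify_state(mucosa_meth)

  # Initial-model features on retained genes; target = polyp/mucosa
  # expression fold change from the simulated expression.
  keep <- filt$genes
  idx <- match(keep, genes$gene_id)
  expr <- tracks$expression
  stage_expr <- sapply(split(manifest$sample_id, manifest$stage),
                       function(ss) rowMeans(expr[, ss, drop = FALSE]))
  target <- log2((stage_expr[idx, "polyp"] + 1) /
                   (stage_expr[idx, "mucosa"] + 1))
  mucosa_feats <- filt$tables$mucosa[
    c("connectivity", "promoter_accessibility", "promoter_stripe_strength",
      "promoter_methylation", "enhancer_accessibility")]
  mucosa_feats$baseline_expression <- stage_expr[idx, "mucosa"]
  rownames(mucosa_feats) <- keep
  ft <- build_features("initial", mucosa_feats, target = target)
  md <- config$model
  model <- two_phase_fit(ft, test_n = max(10, round(md$test_frac * length(keep))),
                         epochs = md$epochs, hidden = md$hidden,
                         dropout = md$dropout, batch = md$batch, lr = md$lr,
                         seed = seed)

  # Artifacts.
  paths <- list(
    anchors = file.path(config$out_dir, "consensus_anchors.bed"),
    connectivity = file.path(config$out_dir, "connectivity.tsv"),
    methylation = file.path(config$out_dir, "promoter_methylation.tsv"),
    features = file.path(config$out_dir, "features_initial.tsv"),
    predictions = file.path(config$out_dir, "predictions.tsv"),
    manifest = file.path(config$out_dir, "run_manifest.json")
  )
  if (nrow(anchors)) {
    write_bed(data.frame(chrom = anchors$chrom, start = anchors$start,
                         end = anchors$end,
                         name = sprintf("anchor_%03d", seq_len(nrow(anchors)))),
              paths$anchors)
  } else {
    writeLines(character(), paths$anchors)
  }
  conn_long <- do.call(rbind, lapply(names(conn_tables), function(s) {
    df <- as.data.frame(conn_tables[[s]])
    df$sample <- s
    df$stage <- samp_stage[[s]]
    df
  }))
  write_tsv(conn_long, paths$connectivity)
  write_tsv(dm, paths$methylation)
  write_tsv(data.frame(gene_id = ft$gene_ids, ft$x, check.names = FALSE),
            paths$features)
  write_tsv(data.frame(gene_id = ft$gene_ids[model$test_idx],
                       observed = model$observed,
                       predicted = model$predictions),
            paths$predictions)

  run_manifest <- list(
    package_version = as.character(utils::packageVersion("cisconn")),
    r_version = R.version.string,
    seed = seed,
    config = unclass(config),
    n_samples = nrow(manifest),
    n_genes_retained = length(keep),
    n_anchors = nrow(anchors),
    model = list(selected_epoch = model$selected_epoch,
                 heldout_r = model$r),
    file_digests = as.list(tools::md5sum(unlist(paths[names(paths) !=
                                                        "manifest"])))
  )
  jsonlite::write_json(run_manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(truth = truth, manifest = manifest, tracks = tracks,
                 stripes = per_sample_stripes, anchors = anchors,
                 connectivity = conn_tables, stage_means = stage_means,
                 filtered = filt, methylation = dm, features = ft,
                 model = model, paths = paths, config = config))
}
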
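#' Simulate accessibility, methylation and expression tracks for a cohort
#'
#' Generates the non-contact data layers that accompany a simulated cohort:
#' accessible peaks (planted enhancers and promoters plus unpaired decoys)
#' with per-sample fold-enrichment signal, a per-bp fold-enrichment track
#' over promoter zones, a CpG-level methylation table drawn binomially around
#' each promoter's stage-specific mean, and a TPM expression matrix following
#' the saturating two-phase rule
#' \eqn{E = \beta \min(C_{true}, C_{sat}) + \epsilon}.
#'
#' @param truth A [synthetic_truth()] object.
#' @param manifest Sample manifest (see [cohort_manifest()]).
#' @param seed Integer seed.
#' @param expr_noise_frac Overrides the truth's expression noise fraction
#'   (s.d. of the additive noise as a fraction of the gene's saturated
#'   expression); set 0 for noise-free expression.
#' @return A list of class `synthetic_tracks` with elements `peaks`
#'   (data.frame peak_id/chrom/start/end/type/gene_id/base_fe), `peak_fe`
#'   (peaks x samples fold-enrichment matrix), `fe_track` (per-sample 100-bp
#'   promoter-zone fold-enrichment bins), `methylation` (long CpG table:
#'   chrom, pos, pct_meth, coverage, sample), `expression` (genes x samples
#'   TPM matrix) and `manifest`.
#' @export
simulate_tracks <- function(truth, manifest, seed,
                            expr_noise_frac = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!nrow(truth$genes)) stop("truth carries no genes")
  stopifnot_cols(manifest, c("sample_id", "stage"), "manifest")
  p <- truth$params
  noise_frac <- expr_noise_frac %||% p$expr_noise_frac
  genes <- truth$genes
  n_genes <- nrow(genes)
  acc_att <- p$accessibility_attenuation
  atten <- p$stage_attenuation

  with_seed(sub_seed(seed, "tracks"), {
    prom_peaks <- data.frame(
      gene_id = genes$gene_id, chrom = genes$chrom,
      start = as.integer(genes$tss - 300), end = as.integer(genes$tss + 300),
      fe = pmax(1, 3 * genes$c_base^0.6 * stats::rlnorm(n_genes, 0, 0.25)),
      stringsAsFactors = FALSE
    )
    prom_peaks$peak_id <- sprintf("p%04d", seq_len(n_genes))
    peaks <- rbind(
      cbind(truth$enhancers[c("peak_id", "gene_id", "chrom", "start", "end", "fe")],
            type = "enhancer"),
      cbind(prom_peaks[c("peak_id", "gene_id", "chrom", "start", "end", "fe")],
            type = "promoter"),
      if (nrow(truth$decoys))
        cbind(truth$decoys[c("peak_id", "gene_id", "chrom", "start", "end", "fe")],
              type = "decoy")
    )
    names(peaks)[names(peaks) == "fe"] <- "base_fe"
    rownames(peaks) <- NULL

    samples <- manifest$sample_id
    stage_of <- stats::setNames(manifest$stage, samples)

    peak_fe <- sapply(samples, function(s) {
      pmax(0.1, peaks$base_fe * acc_att[[stage_of[[s]]]] *
             stats::rlnorm(nrow(peaks), 0, 0.25))
    })
    rownames(peak_fe) <- peaks$peak_id

    # Per-bp (100-bp bin) fold enrichment over promoter zones, used by the
    # promoter-accessibility summary.
    zones <- promoter_zones(genes)
    fe_track <- do.call(rbind, lapply(samples, function(s) {
      do.call(rbind, lapply(seq_len(n_genes), function(i) {
        st <- seq(zones$start[i], zones$end[i] - 1L, by = 100L)
        data.frame(chrom = zones$chrom[i], start = st, end = st + 100L,
                   value = pmax(0.05, prom_peaks$fe[i] *
                                  acc_att[[stage_of[[s]]]] *
                                  stats::rlnorm(length(st), 0, 0.3)),
                   sample = s, stringsAsFactors = FALSE)
      }))
    }))

    # CpG methylation: ~16 CpGs per promoter, binomial draws around the
    # stage-specific mean.
    cpg_off <- seq(-1400L, 400L, by = 120L)
    meth <- do.call(rbind, lapply(samples, function(s) {
      m <- genes[[paste0("meth_", stage_of[[s]])]]
      do.call(rbind, lapply(seq_len(n_genes), function(i) {
        cov <- stats::rpois(length(cpg_off), 25) + 5L
        reads <- stats::rbinom(length(cpg_off), cov, m[i] / 100)
        data.frame(chrom = genes$chrom[i], pos = genes$tss[i] + cpg_off,
                   pct_meth = 100 * reads / cov, coverage = cov,
                   sample = s, stringsAsFactors = FALSE)
      }))
    }))

    expr <- sapply(samples, function(s) {
      c_true <- genes$c_base * atten[[stage_of[[s]]]]
      e <- genes$beta * pmin(c_true, p$c_sat)
      if (noise_frac > 0)
        e <- e + stats::rnorm(n_genes, 0, noise_frac * genes$beta * p$c_sat)
      pmax(0, e)
    })
    rownames(expr) <- genes$gene_id

    structure(list(peaks = peaks, peak_fe = peak_fe, fe_track = fe_track,
                   methylation = meth, expression = expr,
                   manifest = manifest),
              class = "synthetic_tracks")
  })
}

#' Simulate a gene-level feature cohort under the two-phase rule
#'
#' Generates a large per-gene feature table and matched expression outcomes
#' directly at the summary level (no contact simulation), sized for training
#' and evaluating the predictive models. Observed mucosa features are noisy
#' readouts of the latent connectivity \eqn{C} and enhancer-context strength
#' \eqn{\beta}; the regression target is the log2 expression fold change
#' implied by the saturating rule plus Gaussian noise whose s.d. is
#' `noise_frac` times the s.d. of the signal.
#'
#' Per-cancer-type outcomes are simulated as replicated TPM matrices with
#' type-specific attenuation, from which differential calls and directionality
#' scores can be derived with [de_calls()] and [directionality_score()].
#'
#' @param n_genes Number of genes.
#' @param n_tf Number of synthetic promoter TF-binding indicator columns.
#' @param n_types Number of simulated cancer types.
#' @param reps Replicate samples per group within each type.
#' @param c_sat Saturation point of the two-phase rule.
#' @param attenuation Named per-stage attenuation multipliers.
#' @param obs_noise Lognormal s.d. of feature observation noise.
#' @param noise_frac Target noise s.d. as a fraction of signal s.d.
#' @param seed Integer seed.
#' @return A list of class `feature_cohort`: `features` (data.frame of raw
#'   per-gene features), `target` (log2 fold change, polyp vs mucosa),
#'   `target_adenocarcinoma`, `signal` (noise-free target),
#'   `type_expr` (per-type list of TPM matrix + group factor),
#'   `conn_by_stage` and `expr_by_stage` (genes x stages matrices), and
#'   `truth` (latent parameters).
#' @export
simulate_feature_cohort <- function(n_genes = 10000, n_tf = 20, n_types = 8,
                                    reps = 4, c_sat = 1,
                                    attenuation = c(mucosa = 1, polyp = 0.6,
                                                    adenocarcinoma = 0.4),
                                    obs_noise = 0.2, noise_frac = 0.5,
                                    seed = 1) {
  with_seed(seed, {
    c_base <- stats::rlnorm(n_genes, log(2), 0.7)
    beta <- stats::rlnorm(n_genes, log(20), 0.8)
    meth <- ifelse(stats::runif(n_genes) < 0.7,
                   stats::runif(n_genes, 5, 18), stats::runif(n_genes, 45, 75))

    ln <- function(sd) stats::rlnorm(n_genes, 0, sd)
    features <- data.frame(
      connectivity = c_base * ln(obs_noise),
      promoter_stripe_strength = c_base * ln(obs_noise),
      promoter_accessibility = 3 * c_base^0.6 * ln(obs_noise),
      promoter_demethylation = pmin(100, pmax(0, 100 - meth +
                                                stats::rnorm(n_genes, 0, 3))),
      enhancer_accessibility = log10(pmax(1, 3 * beta * ln(obs_noise))),
      baseline_expression = pmax(0, beta * pmin(c_base, c_sat) *
                                   ln(obs_noise))
    )
    # Promoter TF indicators: half informative (logit tied to latent
    # connectivity), half pure noise; plus an enhancer-context TF sum.
    logit_c <- scale(log(c_base))[, 1]
    for (j in seq_len(n_tf)) {
      pr <- if (j <= n_tf / 2) stats::plogis(0.8 * logit_c) else 0.3
      features[[sprintf("tf%02d", j)]] <- stats::rbinom(n_genes, 1, pr)
    }
    features$enh_tf_sum <- stats::rpois(n_genes, pmax(0.5, 2 * log1p(beta)))

    fc_signal <- function(att, c_eff = c_base) {
      log2((beta * pmin(c_eff * att, c_sat) + 1) /
             (beta * pmin(c_base, c_sat) + 1))
    }
    sig_p <- fc_signal(attenuation[["polyp"]])
    sig_a <- fc_signal(attenuation[["adenocarcinoma"]])
    target <- sig_p + stats::rnorm(n_genes, 0, noise_frac * stats::sd(sig_p))
    target_a <- sig_a + stats::rnorm(n_genes, 0, noise_frac * stats::sd(sig_a))

    expr_noise <- function(e) pmax(0, e + stats::rnorm(length(e), 0, 2))
    type_expr <- lapply(seq_len(n_types), function(t) {
      att_t <- stats::runif(1, 0.35, 0.75)
      c_eff <- c_base * stats::rlnorm(n_genes, 0, 0.15)
      e_ref <- beta * pmin(c_base, c_sat)
      e_cond <- beta * pmin(c_eff * att_t, c_sat)
      tpm <- cbind(
        sapply(seq_len(reps), function(k) expr_noise(e_ref)),
        sapply(seq_len(reps), function(k) expr_noise(e_cond))
      )
      colnames(tpm) <- c(paste0("ref", seq_len(reps)),
                         paste0("cond", seq_len(reps)))
      list(tpm = tpm, group = rep(c("ref", "cond"), each = reps),
           attenuation = att_t)
    })
    names(type_expr) <- sprintf("type%02d", seq_len(n_types))

    stages <- names(attenuation)
    conn_by_stage <- sapply(stages, function(st)
      c_base * attenuation[[st]] * ln(obs_noise))
    expr_by_stage <- sapply(stages, function(st)
      pmax(0, beta * pmin(c_base * attenuation[[st]], c_sat) +
             stats::rnorm(n_genes, 0, 1)))
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    rownames(conn_by_stage) <- rownames(expr_by_stage) <- gene_ids
    rownames(features) <- gene_ids

    structure(list(
      features = features, target = target, target_adenocarcinoma = target_a,
      signal = sig_p, type_expr = type_expr,
      conn_by_stage = conn_by_stage, expr_by_stage = expr_by_stage,
      truth = list(c_base = c_base, beta = beta, c_sat = c_sat,
                   attenuation = attenuation)
    ), class = "feature_cohort")
  })
}

# Strand-oriented promoter zones [-1500, +500) around the TSS.
promoter_zones <- function(genes) {
  up <- 1500L; down <- 500L
  fw <- genes$strand != "-"
  data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = as.integer(ifelse(fw, genes$tss - up, genes$tss - down)),
    end = as.integer(ifelse(fw, genes$tss + down, genes$tss + up)),
    stringsAsFactors = FALSE
  )
}
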
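#' Ground-truth parameters for a synthetic cohort
#'
#' Defines the conditions a synthetic merged-microarray survival cohort is
#' generated under, and records them so recovery can be tested. Defaults are
#' calibrated to the clinical profile of large merged breast-cancer GEO
#' cohorts: roughly a third of patients relapse, mean age ~54 (SD 12.5),
#' ~70% ER-positive, ~23% HER2-positive, ~58% node-positive among patients
#' with known nodal status, and a protective high-signature effect of HR
#' 0.66.
#'
#' @param n_samples Number of base samples (duplicates are appended on top).
#' @param n_datasets Number of constituent datasets; each gets a
#'   multiplicative intensity scale factor.
#' @param dataset_scale_factors Per-dataset scale factors (> 0); default
#'   evenly spaced on `[0.5, 2]` so the scaling normalization is
#'   consequential.
#' @param n_probes Number of background (non-signature, non-receptor)
#'   probes.
#' @param n_signature_genes Signature size in genes; the first five genes
#'   get two probes each, the rest one.
#' @param effect_mode `"group"`: the hazard is multiplied by
#'   `exp(true_log_hr)` for samples whose signature score exceeds the
#'   `true_cutoff_quantile` quantile (the known true cutoff);
#'   `"linear"`: log-hazard is `true_log_hr` per SD of score.
#' @param true_log_hr True log hazard ratio (default `log(0.66)`,
#'   protective high expression).
#' @param true_cutoff_quantile Quantile of the score defining the true
#'   high/low split in group mode (default median).
#' @param baseline_hazard_rate Baseline exponential event rate per month;
#'   `NULL` (default) calibrates it by root-finding so the expected event
#'   fraction equals `target_event_fraction` given the censoring model.
#' @param weibull_shape Shape of the baseline event-time distribution
#'   (1 = exponential).
#' @param censor_rate Independent exponential censoring rate per month
#'   (default 1/60, i.e. ~60-month mean follow-up).
#' @param admin_cap_months Administrative censoring cap (default 120).
#' @param target_event_fraction Target fraction of samples with an event
#'   (default 0.33).
#' @param n_duplicates Number of exact-copy samples appended to the last
#'   dataset (at most `n_samples / 2`).
#' @param n_qc_outliers Number of samples given displaced QC metrics
#'   (>= 3 failing metrics each, so they are excluded under the default
#'   rule).
#' @param er_positive_fraction,her2_positive_fraction Fractions of samples
#'   drawn above the 500 / 4800 receptor-probe cutoffs.
#' @param node_positive_fraction Fraction node-positive among samples with
#'   known nodal status.
#' @param seed Integer seed; every random draw in [generate_cohort()] flows
#'   from it.
#' @return An object of class `synthetic_truth` (a validated list of the
#'   above).
#' @export
synthetic_truth <- function(n_samples = 600L, n_datasets = 3L,
                            dataset_scale_factors = NULL,
                            n_probes = 300L, n_signature_genes = 25L,
                            effect_mode = c("group", "linear"),
                            true_log_hr = log(0.66),
                            true_cutoff_quantile = 0.5,
                            baseline_hazard_rate = NULL,
                            weibull_shape = 1,
                            censor_rate = 1 / 60,
                            admin_cap_months = 120,
                            target_event_fraction = 0.33,
                            n_duplicates = 0L, n_qc_outliers = 0L,
                            er_positive_fraction = 0.70,
                            her2_positive_fraction = 0.23,
                            node_positive_fraction = 0.58,
                            seed = 1L) {
  effect_mode <- match.arg(effect_mode)
  if (n_samples < 2L) stop("need n_samples >= 2", call. = FALSE)
  if (is.null(dataset_scale_factors)) {
    dataset_scale_factors <- seq(0.5, 2, length.out = n_datasets)
  }
  if (length(dataset_scale_factors) != n_datasets ||
      any(dataset_scale_factors <= 0)) {
    stop("need one positive scale factor per dataset", call. = FALSE)
  }
  fracs <- c(er_positive_fraction, her2_positive_fraction,
             node_positive_fraction, target_event_fraction,
             true_cutoff_quantile)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0,1]", call. = FALSE)
  if (n_duplicates > n_samples / 2) {
    stop("n_duplicates may not exceed n_samples / 2", call. = FALSE)
  }
  if (n_qc_outliers > n_samples) stop("too many QC outliers", call. = FALSE)
  if (!is.null(baseline_hazard_rate) && baseline_hazard_rate <= 0) {
    stop("baseline_hazard_rate must be positive", call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples), n_datasets = as.integer(n_datasets),
         dataset_scale_factors = dataset_scale_factors,
         n_probes = as.integer(n_probes),
         n_signature_genes = as.integer(n_signature_genes),
         effect_mode = effect_mode, true_log_hr = true_log_hr,
         true_cutoff_quantile = true_cutoff_quantile,
         baseline_hazard_rate = baseline_hazard_rate,
         weibull_shape = weibull_shape, censor_rate = censor_rate,
         admin_cap_months = admin_cap_months,
         target_event_fraction = target_event_fraction,
         n_duplicates = as.integer(n_duplicates),
         n_qc_outliers = as.integer(n_qc_outliers),
         er_positive_fraction = er_positive_fraction,
         her2_positive_fraction = her2_positive_fraction,
         node_positive_fraction = node_positive_fraction,
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

# truncated log-normal via inverse-CDF, exactly on the requested side
rlnorm_trunc <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

# P(event observed) for event rate h under independent Exp(c) censoring
# with an administrative cap at tau months
event_prob <- function(h, c, tau) {
  if (c <= 0) return(1 - exp(-h * tau))
  h / (h + c) * (1 - exp(-(h + c) * tau))
}

calibrate_baseline_hazard <- function(eta, truth) {
  target <- truth$target_event_fraction
  f <- function(h0) {
    mean(event_prob(h0 * exp(eta), truth$censor_rate,
                    truth$admin_cap_months)) - target
  }
  stats::uniroot(f, c(1e-8, 10), tol = 1e-12)$root
}

#' Generate a synthetic merged-cohort dataset with known truth
#'
#' Produces the four pipeline inputs — expression matrix, clinical table, QC
#' table — plus the completed ground-truth record. Probe intensities are
#' log-normal on the linear MAS5-like scale with a heavy right tail;
#' signature probes additionally load on a latent per-sample senescence
#' factor; the two receptor probes are drawn from two-component truncated
#' mixtures placing the configured fractions above the 500 / 4800 cutoffs
#' (with a 10% guard band so per-sample normalization wobble cannot flip a
#' call). Each dataset's raw intensities are multiplied by its scale factor;
#' by construction the pre-scale shared-probe mean of every sample is
#' exactly 1000, so [scale_normalize()] recovers a common scale exactly and
#' injected duplicate samples (identical arrays deposited in a later
#' dataset at a different raw scale) become identical again after
#' normalization. Relapse-free survival times follow a proportional-hazards
#' model on the signature score (see [synthetic_truth()] `effect_mode`)
#' with independent exponential censoring and an administrative cap, and
#' are rounded to 0.1 month (realistic tied follow-up). QC outliers get
#' background, raw Q and 3':5' ratio displaced by 8 batch SDs and an
#' undetected bioB spike (4 failed metrics).
#'
#' @param truth A [synthetic_truth()].
#' @return List with `expression` ([expr_matrix()], raw scale), `clinical`
#'   (data.frame), `qc` (data.frame), `signature` ([signature_def()]) and
#'   `truth` — the input truth completed with the calibrated
#'   `baseline_hazard_rate`, the realized `true_cutoff` and per-sample
#'   `true_group` (group mode), `duplicate_pairs` (data.frame
#'   `copy_id`/`source_id`) and `qc_outlier_ids`.
#' @export
generate_cohort <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed)
  n <- truth$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  dataset <- sprintf("DS%02d", 1L + (seq_len(n) * truth$n_datasets - 1L) %/% n)
  names(truth$dataset_scale_factors) <- sprintf("DS%02d", seq_len(truth$n_datasets))

  # signature definition: first five genes carry two probes
  genes <- sprintf("SENG%02d", seq_len(truth$n_signature_genes))
  nprobe_per_gene <- ifelse(seq_along(genes) <= 5L, 2L, 1L)
  sig_gene <- rep(genes, nprobe_per_gene)
  sig_probe <- sprintf("%s_%d_at", sig_gene,
                       unlist(lapply(nprobe_per_gene, seq_len)))
  sig <- signature_def("synthetic_senescence", sig_gene, sig_probe)

  bg_probes <- sprintf("BG%04d_at", seq_len(truth$n_probes))
  er_probe <- "205225_at"; her2_probe <- "216836_s_at"
  all_probes <- c(bg_probes, sig_probe, er_probe, her2_probe)

  # latent per-sample senescence factor drives all signature probes
  z <- stats::rnorm(n)
  mu_bg <- stats::rnorm(truth$n_probes, log(500), 0.5)
  mu_sig <- stats::rnorm(length(sig_probe), log(500), 0.5)
  vals <- matrix(0, nrow = length(all_probes), ncol = n,
                 dimnames = list(all_probes, ids))
  vals[bg_probes, ] <- exp(mu_bg + matrix(stats::rnorm(truth$n_probes * n, 0, 0.8),
                                          truth$n_probes, n))
  vals[sig_probe, ] <- exp(mu_sig + outer(rep(0.3, length(sig_probe)), z) +
                             matrix(stats::rnorm(length(sig_probe) * n, 0, 0.4),
                                    length(sig_probe), n))
  er_pos <- stats::runif(n) < truth$er_positive_fraction
  her2_pos <- stats::runif(n) < truth$her2_positive_fraction
  # scanner saturation bounds the right tail of the receptor probes
  vals[er_probe, ] <- ifelse(er_pos,
                             rlnorm_trunc(n, log(1200), 0.8,
                                          lower = 550, upper = 4e4),
                             rlnorm_trunc(n, log(200), 0.8, upper = 450))
  vals[her2_probe, ] <- ifelse(her2_pos,
                               rlnorm_trunc(n, log(9000), 0.7,
                                            lower = 5280, upper = 6e4),
                               rlnorm_trunc(n, log(1500), 0.8, upper = 4350))

  # last tenth of background probes is platform-specific (not shared)
  n_specific <- max(1L, truth$n_probes %/% 10L)
  shared <- setdiff(all_probes, utils::tail(bg_probes, n_specific))

  # rescale every non-receptor probe per sample so the shared-probe mean is
  # exactly 1000 pre-scale; receptor intensities stay exactly as drawn
  rec <- c(er_probe, her2_probe)
  other_shared <- setdiff(shared, rec)
  fac <- (1000 * length(shared) - colSums(vals[rec, , drop = FALSE])) /
    colSums(vals[other_shared, , drop = FALSE])
  if (any(fac <= 0)) stop("infeasible shared-probe rescaling", call. = FALSE)
  nonrec <- setdiff(all_probes, rec)
  vals[nonrec, ] <- sweep(vals[nonrec, , drop = FALSE], 2L, fac, `*`)

  canonical <- expr_matrix(vals, dataset = dataset, shared_probes = shared)
  score <- score_signature(canonical, sig)

  # proportional-hazards survival on the score
  if (truth$effect_mode == "group") {
    cutoff <- stats::quantile(score, truth$true_cutoff_quantile, names = FALSE)
    true_group <- as.integer(score > cutoff)
    eta <- truth$true_log_hr * true_group
    truth$true_cutoff <- cutoff
    truth$true_group <- stats::setNames(true_group, ids)
  } else {
    eta <- truth$true_log_hr * as.numeric(scale(score))
    truth$true_cutoff <- NA_real_
    truth$true_group <- NULL
  }
  if (is.null(truth$baseline_hazard_rate)) {
    truth$baseline_hazard_rate <- calibrate_baseline_hazard(eta, truth)
  }
  rate <- truth$baseline_hazard_rate * exp(eta)
  t_event <- (stats::rexp(n) / rate)^(1 / truth$weibull_shape)
  t_cens <- pmin(stats::rexp(n, truth$censor_rate), truth$admin_cap_months)
  event <- as.integer(t_event <= t_cens)
  rfs <- pmax(round(pmin(t_event, t_cens), 1), 0.1)

  node_known <- stats::runif(n) < 0.69
  clinical <- data.frame(
    sample_id = ids, rfs_months = rfs, event = event,
    er_status = ifelse(er_pos, "positive", "negative"),
    her2_status = ifelse(her2_pos, "positive", "negative"),
    node_status = ifelse(node_known,
                         ifelse(stats::runif(n) < truth$node_positive_fraction,
                                "positive", "negative"),
                         NA_character_),
    size_cm = ifelse(stats::runif(n) < 0.8,
                     round(stats::rlnorm(n, log(2.2), 0.5), 1), NA_real_),
    age_years = ifelse(stats::runif(n) < 0.9,
                       round(pmax(stats::rnorm(n, 54.1, 12.5), 25), 1), NA_real_),
    subtype = NA_character_, stringsAsFactors = FALSE
  )

  qc <- data.frame(
    sample_id = ids,
    background_signal = stats::rnorm(n, 60, 8),
    raw_q = stats::rnorm(n, 2.2, 0.25),
    percent_present = pmin(pmax(stats::rnorm(n, 45, 4), 0), 100),
    biob_detected = TRUE,
    ratio_3to5 = pmax(stats::rnorm(n, 1.4, 0.15), 0.2),
    stringsAsFactors = FALSE
  )
  truth$qc_outlier_ids <- character(0)
  if (truth$n_qc_outliers > 0L) {
    out_ix <- sample.int(n, truth$n_qc_outliers)
    truth$qc_outlier_ids <- ids[out_ix]
    qc$background_signal[out_ix] <- qc$background_signal[out_ix] + 8 * 8
    qc$raw_q[out_ix] <- qc$raw_q[out_ix] + 8 * 0.25
    qc$ratio_3to5[out_ix] <- qc$ratio_3to5[out_ix] + 8 * 0.15
    qc$biob_detected[out_ix] <- FALSE
  }

  # duplicates: identical arrays re-deposited in the last dataset
  truth$duplicate_pairs <- data.frame(copy_id = character(0),
                                      source_id = character(0),
                                      stringsAsFactors = FALSE)
  if (truth$n_duplicates > 0L) {
    src_ix <- sample(which(dataset == "DS01"), truth$n_duplicates)
    copy_ids <- sprintf("DUP%03d", seq_len(truth$n_duplicates))
    last_ds <- sprintf("DS%02d", truth$n_datasets)
    dupvals <- canonical$values[, src_ix, drop = FALSE]
    colnames(dupvals) <- copy_ids
    canonical <- expr_matrix(cbind(canonical$values, dupvals),
                             dataset = c(dataset, rep(last_ds, truth$n_duplicates)),
                             shared_probes = shared)
    dup_clin <- clinical[src_ix, ]; dup_clin$sample_id <- copy_ids
    clinical <- rbind(clinical, dup_clin)
    dup_qc <- qc[src_ix, ]; dup_qc$sample_id <- copy_ids
    qc <- rbind(qc, dup_qc)
    rownames(clinical) <- rownames(qc) <- NULL
    truth$duplicate_pairs <- data.frame(copy_id = copy_ids,
                                        source_id = ids[src_ix],
                                        stringsAsFactors = FALSE)
  }

  # apply per-dataset raw scale factors last: the deliverable is raw data
  raw <- canonical
  raw$values <- sweep(raw$values, 2L,
                      truth$dataset_scale_factors[raw$dataset], `*`)
  list(expression = raw, clinical = clinical, qc = qc, signature = sig,
       truth = truth)
}

#' Recovery report: pipeline results against the generator's truth
#'
#' Summarizes how well the pipeline recovered the generator's known
#' parameters: hazard-ratio estimates at the selected and (group mode) true
#' cutoffs, duplicate-detection and QC-exclusion confusion counts with
#' precision/recall, and the realized event fraction.
#'
#' @param truth Completed truth from [generate_cohort()].
#' @param scan Optional [cutoff_scan()] result on the cohort.
#' @param removed Optional `removed` data.frame from [remove_duplicates()].
#' @param qc_result Optional [qc_filter()] result.
#' @param clinical Optional clinical table (for the realized event
#'   fraction).
#' @return List of recovery summaries (only those with inputs supplied).
#' @export
truth_report <- function(truth, scan = NULL, removed = NULL,
                         qc_result = NULL, clinical = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  out <- list(true_hr = exp(truth$true_log_hr),
              effect_mode = truth$effect_mode)
  if (!is.null(scan)) {
    out$selected_cutoff <- scan$selected_cutoff
    out$selected_hr <- unname(scan$selected$hr[1L])
    out$selected_p <- scan$p_at[scan$selected_index]
    out$log_hr_error <- log(out$selected_hr) - truth$true_log_hr
  }
  if (!is.null(removed)) {
    found <- removed$removed_id
    injected <- truth$duplicate_pairs$copy_id
    tp <- length(intersect(found, injected))
    out$duplicates <- list(
      n_injected = length(injected), n_found = length(found),
      true_positive = tp, false_positive = length(found) - tp,
      false_negative = length(injected) - tp,
      precision = if (length(found)) tp / length(found) else NA_real_,
      recall = if (length(injected)) tp / length(injected) else NA_real_)
  }
  if (!is.null(qc_result)) {
    found <- qc_result$excluded
    injected <- truth$qc_outlier_ids
    tp <- length(intersect(found, injected))
    out$qc_outliers <- list(
      n_injected = length(injected), n_excluded = length(found),
      true_positive = tp, false_positive = length(found) - tp,
      false_negative = length(injected) - tp,
      precision = if (length(found)) tp / length(found) else NA_real_,
      recall = if (length(injected)) tp / length(injected) else NA_real_)
  }
  if (!is.null(clinical)) {
    if (!is.null(truth$true_group) &&
        !any(clinical$sample_id %in% names(truth$true_group))) {
      stop("clinical table shares no samples with this truth record",
           call. = FALSE)
    }
    out$event_fraction <- mean(clinical$event)
    out$target_event_fraction <- truth$target_event_fraction
  }
  out
}
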
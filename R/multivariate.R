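#' Paired multivariate Cox model: signature group plus one covariate
#'
#' Clinical covariates in merged microarray cohorts are missing for
#' different, largely non-overlapping subsets of patients, so a single full
#' multivariate model would discard most of the cohort. Instead each
#' clinical covariate is paired with the signature group in its own
#' two-covariate Cox model, fitted on the cases complete for that covariate
#' (the count dropped is reported). Categorical covariates are
#' reference-coded: `"negative"` (receptor/node status) or the first level;
#' subtype uses `luminal_a` as reference.
#'
#' @param group Binary indicator (0/1 or logical) of the high-signature
#'   group at the selected cutoff, one per sample.
#' @param covariate One clinical covariate (numeric, or
#'   character/factor); `NA`s define the incomplete cases that are dropped.
#' @param times,events As in [km_estimate()].
#' @param covariate_name Label used in the output.
#' @param min_n Minimum complete cases; fewer refuses with a diagnostic
#'   (default 10).
#' @param ties Tie handling, see [cox_fit()].
#' @return A [cox_fit()] result (`cox_result`) with extra fields
#'   `n_dropped` (incomplete cases removed) and `covariate_name`.
#' @export
paired_cox <- function(group, covariate, times, events,
                       covariate_name = "covariate", min_n = 10L,
                       ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(length(group) == length(covariate),
            length(group) == length(times))
  group <- as.integer(as.logical(group))
  keep <- !is.na(covariate) & !is.na(group) & !is.na(times) & !is.na(events)
  n_dropped <- sum(!keep)
  if (sum(keep) < min_n) {
    stop("only ", sum(keep), " complete cases for ", covariate_name,
         " (< ", min_n, "); refusing to fit", call. = FALSE)
  }
  cov <- covariate[keep]
  if (is.character(cov) || is.factor(cov)) {
    lev <- unique(as.character(cov))
    ref <- if ("negative" %in% lev) "negative" else
      if ("luminal_a" %in% lev) "luminal_a" else sort(lev)[1L]
    cov <- factor(cov, levels = c(ref, sort(setdiff(lev, ref))))
  }
  df <- data.frame(signature_high = group[keep], cov, stringsAsFactors = FALSE)
  names(df)[2L] <- covariate_name
  fit <- cox_fit(df, times[keep], events[keep], ties = ties)
  fit$n_dropped <- n_dropped
  fit$covariate_name <- covariate_name
  fit
}

#' Run all paired signature-plus-covariate Cox models
#'
#' Convenience loop over [paired_cox()] for the standard clinical covariate
#' panel, returning one summary row per model.
#'
#' @param group Binary high-signature indicator, aligned with `clinical`.
#' @param clinical Clinical data.frame (see [read_clinical()]).
#' @param covariates Which clinical columns to pair with the signature.
#' @param min_n Passed to [paired_cox()].
#' @return Data.frame with one row per model: `covariate`, `n_used`,
#'   `n_dropped`, signature HR/CI/p and the (first) covariate term's
#'   HR/CI/p. Models that refuse (too few complete cases or degenerate
#'   design) appear with `NA` estimates and the diagnostic in `note`.
#' @export
paired_cox_panel <- function(group, clinical,
                             covariates = c("node_status", "er_status",
                                            "her2_status", "size_cm",
                                            "age_years", "subtype"),
                             min_n = 10L) {
  rows <- lapply(covariates, function(cv) {
    fit <- tryCatch(
      paired_cox(group, clinical[[cv]], clinical$rfs_months, clinical$event,
                 covariate_name = cv, min_n = min_n),
      error = function(e) conditionMessage(e)
    )
    if (is.character(fit)) {
      return(data.frame(covariate = cv, n_used = NA_integer_,
                        n_dropped = NA_integer_, hr_signature = NA_real_,
                        lo_signature = NA_real_, hi_signature = NA_real_,
                        p_signature = NA_real_, hr_covariate = NA_real_,
                        lo_covariate = NA_real_, hi_covariate = NA_real_,
                        p_covariate = NA_real_, note = fit,
                        stringsAsFactors = FALSE))
    }
    ix_cov <- which(fit$covariates != "signature_high")[1L]
    data.frame(covariate = cv, n_used = fit$n_used, n_dropped = fit$n_dropped,
               hr_signature = unname(fit$hr["signature_high"]),
               lo_signature = fit$ci95["signature_high", "lower"],
               hi_signature = fit$ci95["signature_high", "upper"],
               p_signature = unname(fit$p["signature_high"]),
               hr_covariate = unname(fit$hr[ix_cov]),
               lo_covariate = fit$ci95[ix_cov, "lower"],
               hi_covariate = fit$ci95[ix_cov, "upper"],
               p_covariate = unname(fit$p[ix_cov]), note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort-characteristics summary table
#'
#' Counts, percentages (one decimal) and mean +/- SD per clinical variable,
#' in the style of a clinical characteristics table. Denominator convention:
#' variables listed in `total_denominator` are expressed as a fraction of
#' the whole cohort (unknowns count against them), the rest as a fraction
#' of the patients with that variable observed — the mixed convention such
#' tables typically use when not all patients have all annotations.
#'
#' @param clinical Clinical data.frame (see [read_clinical()]).
#' @param total_denominator Variables whose percentages use total n.
#' @return Data.frame with columns `variable`, `level`, `n`, `denominator`,
#'   `percent` (one decimal; `NA` when the denominator is 0), `mean`, `sd`
#'   (continuous variables only).
#' @export
summarize_cohort <- function(clinical,
                             total_denominator = c("event", "er_status",
                                                   "her2_status")) {
  stopifnot(nrow(clinical) >= 1L)
  n_total <- nrow(clinical)
  pct <- function(n, d) if (d == 0L) NA_real_ else round(100 * n / d, 1)
  rows <- list()
  add <- function(variable, level, n, denom, mean = NA_real_, sd = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = level, n = n, denominator = denom,
      percent = pct(n, denom), mean = mean, sd = sd, stringsAsFactors = FALSE)
  }
  add("n_total", "", n_total, n_total)
  ev_denom <- if ("event" %in% total_denominator) n_total else
    sum(!is.na(clinical$event))
  add("event", "event", sum(clinical$event == 1L, na.rm = TRUE), ev_denom)
  for (v in c("er_status", "her2_status", "node_status", "subtype")) {
    obs <- clinical[[v]][!is.na(clinical[[v]])]
    denom <- if (v %in% total_denominator) n_total else length(obs)
    levels <- if (v == "subtype") {
      c("basal", "luminal_a", "luminal_b", "her2_enriched")
    } else c("positive", "negative")
    for (lv in levels) add(v, lv, sum(obs == lv), denom)
  }
  for (v in c("age_years", "size_cm")) {
    obs <- clinical[[v]][!is.na(clinical[[v]])]
    add(v, "", length(obs), n_total,
        mean = if (length(obs)) mean(obs) else NA_real_,
        sd = if (length(obs) > 1L) stats::sd(obs) else NA_real_)
  }
  do.call(rbind, rows)
}
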
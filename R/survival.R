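#' Kaplan-Meier (product-limit) survival curve
#'
#' Product-limit estimate over the distinct event times, with the number at
#' risk at each, and the median survival time defined as the smallest event
#' time at which the curve drops to 0.5 or below (undefined — `NA` — when
#' the curve never reaches 0.5).
#'
#' @param times Non-negative follow-up times (months).
#' @param events Binary event indicators (1 = relapse, 0 = censored).
#' @return An object of class `km_curve`: list with `event_times`, `surv`,
#'   `n_at_risk`, `n_events` (all aligned, at event times only),
#'   `median_months` and `n` (subjects).
#' @export
km_estimate <- function(times, events) {
  check_surv_input(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  has_event <- fit$n.event > 0
  surv <- fit$surv[has_event]
  event_times <- fit$time[has_event]
  med <- if (any(surv <= 0.5)) event_times[which(surv <= 0.5)[1L]] else NA_real_
  structure(
    list(event_times = event_times, surv = surv,
         n_at_risk = fit$n.risk[has_event], n_events = fit$n.event[has_event],
         median_months = med, n = length(times)),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event times, median = %s months\n",
              x$n, length(x$event_times),
              if (is.na(x$median_months)) "not reached" else
                format(x$median_months)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank comparison of two survival distributions,
#' with the chi-square statistic referred to 1 degree of freedom.
#'
#' @param times,events As in [km_estimate()].
#' @param group Two-level grouping (logical, or any vector with exactly two
#'   distinct values).
#' @return List with `chi_square` and `p`.
#' @export
logrank_test <- function(times, events, group) {
  check_surv_input(times, events)
  if (length(group) != length(times)) stop("`group` length mismatch", call. = FALSE)
  if (length(unique(group)) != 2L) {
    stop("log-rank test needs exactly two non-empty groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  list(chi_square = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Maximum partial-likelihood fit (Newton-Raphson, Efron tie handling by
#' default — month-resolution follow-up guarantees heavy ties) returning
#' per-covariate hazard ratios with Wald confidence intervals and p-values.
#' Non-convergence or separation (a covariate perfectly ordering the events,
#' driving its coefficient to infinity) raises a diagnostic error rather
#' than returning silent output.
#'
#' @param covariates Numeric vector, matrix, or data.frame of covariates
#'   (factors/character columns are reference-coded, first level as
#'   reference). No missing values; drop incomplete cases first.
#' @param times,events As in [km_estimate()].
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level Wald confidence level (default 0.95).
#' @param max_iter,eps Newton iteration cap and convergence tolerance.
#' @return An object of class `cox_result`: list with `covariates` (names),
#'   `beta`, `se`, `hr` (= exp(beta)), `ci95` (matrix, columns
#'   `lower`/`upper`), `p` (Wald), `score_chisq` (global score test at beta
#'   = 0), `n_used`, `n_events`, `ties`.
#' @export
cox_fit <- function(covariates, times, events, ties = c("efron", "breslow"),
                    conf_level = 0.95, max_iter = 25L, eps = 1e-9) {
  ties <- match.arg(ties)
  check_surv_input(times, events)
  if (sum(events) < 1L) stop("Cox fit needs at least one event", call. = FALSE)
  df <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (is.null(dim(covariates)) && is.atomic(covariates)) names(df) <- "x"
  if (nrow(df) != length(times)) stop("covariate length mismatch", call. = FALSE)
  for (nm in names(df)) {
    col <- df[[nm]]
    if (is.character(col) || is.logical(col)) df[[nm]] <- factor(col)
    if (is.numeric(col) && any(!is.finite(col))) {
      stop("covariate `", nm, "` has non-finite values", call. = FALSE)
    }
    if (anyNA(col)) stop("covariate `", nm, "` has missing values; drop incomplete cases first", call. = FALSE)
    if (length(unique(col)) < 2L) {
      stop("covariate `", nm, "` is constant", call. = FALSE)
    }
  }
  df$.time <- times
  df$.event <- events
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", setdiff(names(df), c(".time", ".event"))),
          collapse = " + ")))
  warned <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties,
                    control = survival::coxph.control(iter.max = max_iter,
                                                      eps = eps)),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  bad <- grepl("infinite|did not converge|out of iterations|singular",
               warned, ignore.case = TRUE)
  if (any(bad) || any(!is.finite(fit$coefficients))) {
    stop("Cox fit failed (separation or non-convergence): ",
         paste(unique(warned[bad]), collapse = "; "), call. = FALSE)
  }
  beta <- fit$coefficients
  se <- sqrt(diag(as.matrix(fit$var)))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- cbind(lower = exp(beta - zq * se), upper = exp(beta + zq * se))
  rownames(ci) <- names(beta)
  structure(
    list(covariates = names(beta), beta = beta, se = se, hr = exp(beta),
         ci95 = ci, p = 2 * stats::pnorm(-abs(beta / se)),
         score_chisq = unname(fit$score), n_used = fit$n,
         n_events = fit$nevent, ties = ties),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, digits = 3, ...) {
  cat(sprintf("Cox PH fit (%s ties): %d subjects, %d events\n",
              x$ties, x$n_used, x$n_events))
  tab <- data.frame(HR = x$hr, lower95 = x$ci95[, "lower"],
                    upper95 = x$ci95[, "upper"], p = x$p)
  print(format(tab, digits = digits))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, capped at 1 and monotone in p-value rank;
#' `q >= p` elementwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Quartile-bounded minimum-p survival cutoff scan
#'
#' The core statistic of the pipeline. Dichotomizes a continuous per-sample
#' score at every candidate threshold between the lower and upper quartiles
#' of its distribution (candidates are the distinct observed score values —
#' the only thresholds that change the partition), fits a Cox model on the
#' high-vs-low indicator at each (`score > cutoff` defines the high group),
#' and selects the cutoff with the smallest p-value. Identical minimum
#' p-values are broken by the strongest effect, formalized as the maximum
#' `|log HR|`; residual ties take the lower cutoff. Because the minimum over
#' many correlated tests inflates type-I error, Benjamini-Hochberg q-values
#' over the scanned family are attached; the selected-cutoff confidence
#' interval is the naive (unadjusted-for-selection) interval.
#'
#' @param scores Named numeric per-sample scores (see [score_signature()]).
#' @param times,events As in [km_estimate()].
#' @param p_source `"cox"` (Wald p from the same model that supplies the HR;
#'   default) or `"logrank"`.
#' @param ties Tie handling for the Cox fits.
#' @param quartile_probs Scan bounds as quantile probabilities (default
#'   `c(0.25, 0.75)`).
#' @return An object of class `scan_result`: list with `cutoffs`, `p_at`,
#'   `hr_at`, `q_at` (`NA` at skipped candidates), `n_low`/`n_high` per
#'   cutoff, `skipped` (logical; degenerate or failed candidates),
#'   `selected_index`, `selected_cutoff`, `selected` ([cox_fit()] result at
#'   the selected cutoff), `km_low`/`km_high` ([km_estimate()] per group at
#'   the selected cutoff), and `quartile_bounds`.
#' @export
cutoff_scan <- function(scores, times, events,
                        p_source = c("cox", "logrank"),
                        ties = c("efron", "breslow"),
                        quartile_probs = c(0.25, 0.75)) {
  p_source <- match.arg(p_source)
  ties <- match.arg(ties)
  check_surv_input(times, events)
  if (length(scores) != length(times)) stop("`scores` length mismatch", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (sum(events) < 1L) stop("scan needs at least one event", call. = FALSE)
  qb <- stats::quantile(scores, probs = quartile_probs, names = FALSE)
  cand <- sort(unique(scores[scores >= qb[1L] & scores <= qb[2L]]))
  if (length(cand) < 2L) {
    stop("fewer than 2 distinct score values between the quartile bounds; ",
         "no cutoff scan possible", call. = FALSE)
  }
  k <- length(cand)
  p_at <- hr_at <- rep(NA_real_, k)
  n_low <- n_high <- integer(k)
  skipped <- logical(k)
  for (i in seq_len(k)) {
    high <- scores > cand[i]
    n_high[i] <- sum(high); n_low[i] <- sum(!high)
    if (n_high[i] == 0L || n_low[i] == 0L) {
      skipped[i] <- TRUE
      next
    }
    fit <- tryCatch(cox_fit(as.numeric(high), times, events, ties = ties),
                    error = function(e) NULL)
    if (!is.null(fit)) hr_at[i] <- unname(fit$hr[1L])
    p_at[i] <- if (p_source == "cox") {
      if (is.null(fit)) NA_real_ else unname(fit$p[1L])
    } else {
      logrank_test(times, events, high)$p
    }
    skipped[i] <- is.na(p_at[i])
  }
  ok <- which(!skipped)
  if (length(ok) == 0L) stop("all candidate cutoffs are degenerate", call. = FALSE)
  # min p, ties -> max |log HR|, residual ties -> lower cutoff; equality is
  # taken up to a small relative tolerance so symmetric designs tie cleanly
  best_p <- min(p_at[ok])
  tol_p <- 1e-12 + 1e-10 * best_p
  tied <- ok[p_at[ok] <= best_p + tol_p]
  if (length(tied) > 1L) {
    alhr <- abs(log(hr_at[tied]))
    alhr[is.na(alhr)] <- -Inf   # candidates whose HR could not be estimated
    tied <- tied[alhr >= max(alhr) - 1e-10 * (1 + max(alhr))]
  }
  sel <- tied[1L]
  q_at <- rep(NA_real_, k)
  q_at[ok] <- bh_adjust(p_at[ok])
  high_sel <- scores > cand[sel]
  sel_fit <- tryCatch(cox_fit(as.numeric(high_sel), times, events, ties = ties),
                      error = function(e) {
                        warning("Cox fit at the selected cutoff failed: ",
                                conditionMessage(e), call. = FALSE)
                        NULL
                      })
  structure(
    list(cutoffs = cand, p_at = p_at, hr_at = hr_at, q_at = q_at,
         n_low = n_low, n_high = n_high, skipped = skipped,
         selected_index = sel, selected_cutoff = cand[sel],
         selected = sel_fit,
         km_low = km_estimate(times[!high_sel], events[!high_sel]),
         km_high = km_estimate(times[high_sel], events[high_sel]),
         quartile_bounds = qb, p_source = p_source),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  sel <- x$selected
  if (is.null(sel)) {
    cat(sprintf(
      "cutoff scan: %d candidates, selected cutoff %.6g (p = %.3g); Cox fit at the selected cutoff failed\n",
      length(x$cutoffs), x$selected_cutoff, x$p_at[x$selected_index]))
    return(invisible(x))
  }
  cat(sprintf(
    paste0("cutoff scan: %d candidates in [%.4g, %.4g] (%d skipped)\n",
           "selected cutoff %.6g: HR (high vs low) = %.3f ",
           "[%.3f, %.3f], p = %.3g, q = %.3g\n",
           "median RFS: low %s, high %s months\n"),
    length(x$cutoffs), x$quartile_bounds[1L], x$quartile_bounds[2L],
    sum(x$skipped), x$selected_cutoff, sel$hr[1L], sel$ci95[1L, "lower"],
    sel$ci95[1L, "upper"], x$p_at[x$selected_index], x$q_at[x$selected_index],
    if (is.na(x$km_low$median_months)) "not reached" else
      format(x$km_low$median_months),
    if (is.na(x$km_high$median_months)) "not reached" else
      format(x$km_high$median_months)))
  invisible(x)
}

#' Tabulate a cutoff scan for a significance-vs-cutoff plot
#'
#' One row per candidate cutoff with group sizes, HR, p and BH q — the
#' series behind a significance-vs-cutoff curve.
#'
#' @param scan A [cutoff_scan()] result.
#' @return Data.frame with columns `cutoff`, `n_low`, `n_high`, `hr`, `p`,
#'   `q`, `selected`.
#' @export
scan_table <- function(scan) {
  stopifnot(inherits(scan, "scan_result"))
  data.frame(cutoff = scan$cutoffs, n_low = scan$n_low, n_high = scan$n_high,
             hr = scan$hr_at, p = scan$p_at, q = scan$q_at,
             selected = seq_along(scan$cutoffs) == scan$selected_index)
}

#' Tabulate Kaplan-Meier curves of a scan's selected split
#'
#' @param scan A [cutoff_scan()] result.
#' @return Data.frame with columns `group` (`"low"`/`"high"`), `time`,
#'   `surv`, `n_at_risk`.
#' @export
km_table <- function(scan) {
  stopifnot(inherits(scan, "scan_result"))
  one <- function(km, lab) {
    data.frame(group = lab, time = km$event_times, surv = km$surv,
               n_at_risk = km$n_at_risk, stringsAsFactors = FALSE)
  }
  rbind(one(scan$km_low, "low"), one(scan$km_high, "high"))
}

check_surv_input <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input", call. = FALSE)
  if (length(times) != length(events)) stop("times/events length mismatch", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and non-negative", call. = FALSE)
  }
  if (!all(events %in% c(0, 1))) stop("events must be binary 0/1", call. = FALSE)
  invisible(TRUE)
}
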
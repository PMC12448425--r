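# Study-level report assembly: the univariable battery (one test per
# variable x shape-metric cell), the four multivariable fits, and the
# EOR-group summary that feeds the boxplot-style figure.

#' Run the univariable association battery
#'
#' One result per (variable, shape metric) cell: Spearman for age and EOR
#' against CSA and SI; Mann-Whitney for sex, histological subtype
#' (astrocytoma vs oligodendroglioma, unanalyzed excluded) and acquired
#' focal deficits; Kruskal-Wallis for lobar location. EOR and deficit rows
#' exclude biopsy-only patients. Significance is flagged at `alpha` with no
#' multiplicity correction.
#'
#' @param cohort Cohort data.frame.
#' @param alpha Two-sided significance level.
#' @return A data.frame of class `univariable_battery` with columns
#'   `variable`, `metric`, `test`, `statistic`, `estimate`, `p_value`,
#'   `significant`, `n`; per-group medians/quartiles are in
#'   `attr(, "group_summaries")`.
#' @export
run_univariable_battery <- function(cohort, alpha = 0.05) {
  cohort <- validate_cohort(cohort)
  rows <- list()
  summaries <- list()
  add <- function(variable, metric, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, metric = metric, test = res$test,
      statistic = unname(res$statistic), estimate = unname(res$estimate),
      p_value = res$p_value, significant = res$significant, n = res$n,
      stringsAsFactors = FALSE)
    if (!is.null(res$groups)) {
      g <- as.data.frame(res$groups)
      g$group <- rownames(res$groups)
      g$variable <- variable; g$metric <- metric
      summaries[[length(summaries) + 1L]] <<- g
    }
  }
  resected <- cohort[!cohort$biopsy_only, , drop = FALSE]

  for (metric in c("csa", "si")) {
    v <- if (metric == "csa") cohort$csa_cm2 else cohort$si
    vr <- if (metric == "csa") resected$csa_cm2 else resected$si

    add("age", metric, spearman_rank(cohort$age, v, alpha = alpha))
    add("eor", metric, spearman_rank(resected$eor, vr, alpha = alpha))

    m <- mann_whitney(v[cohort$sex == "male"], v[cohort$sex == "female"],
                      alpha = alpha)
    rownames(m$groups) <- c("male", "female")
    add("sex", metric, m)

    h <- mann_whitney(v[cohort$diagnosis == "astrocytoma"],
                      v[cohort$diagnosis == "oligodendroglioma"],
                      alpha = alpha)
    rownames(h$groups) <- c("astrocytoma", "oligodendroglioma")
    add("diagnosis", metric, h)

    fd <- mann_whitney(vr[resected$focal_deficit %in% TRUE],
                       vr[resected$focal_deficit %in% FALSE], alpha = alpha)
    rownames(fd$groups) <- c("deficit", "no_deficit")
    add("focal_deficit", metric, fd)

    by_loc <- split(v, cohort$location, drop = TRUE)
    add("location", metric, kruskal_wallis(by_loc, alpha = alpha))
  }
  out <- do.call(rbind, rows)
  attr(out, "group_summaries") <- do.call(rbind, summaries)
  class(out) <- c("univariable_battery", "data.frame")
  out
}

#' Fit the four multivariable models
#'
#' EOR is modelled by Huber-weight robust linear regression, once with CSA
#' and once with SI as the shape predictor (each adjusted for age,
#' preoperative volume, eloquence, and lobar location); focal deficits by
#' logistic regression with the same two shape predictors (adjusted for
#' age, preoperative volume and eloquence).
#'
#' @param cohort Cohort data.frame.
#' @param location_reference Reference lobar location for the dummies.
#' @param k Huber tuning constant.
#' @return List of class `multivariable_models` with elements `eor_csa`,
#'   `eor_si`, `deficit_csa`, `deficit_si`.
#' @export
run_multivariable_models <- function(cohort, location_reference = "central_deep",
                                     k = 1.345) {
  out <- list(
    eor_csa = huber_fit(model_spec("eor", "csa", location_reference), cohort, k = k),
    eor_si = huber_fit(model_spec("eor", "si", location_reference), cohort, k = k),
    deficit_csa = logistic_fit(model_spec("focal_deficit", "csa"), cohort),
    deficit_si = logistic_fit(model_spec("focal_deficit", "si"), cohort)
  )
  class(out) <- "multivariable_models"
  out
}

#' @export
print.multivariable_models <- function(x, ...) {
  cat("== Robust linear models on EOR ==\n")
  cat("-- CSA model --\n"); print(x$eor_csa)
  cat("-- SI model --\n"); print(x$eor_si)
  cat("== Logistic models on focal deficits ==\n")
  cat("-- CSA model --\n"); print(x$deficit_csa)
  cat("-- SI model --\n"); print(x$deficit_si)
  invisible(x)
}

#' Multivariable fits as one long data.frame
#' @param models A `multivariable_models` list.
#' @return data.frame with a `model` column and one row per coefficient.
#' @export
multivariable_table <- function(models) {
  do.call(rbind, lapply(names(models), function(nm) {
    cf <- models[[nm]]$coefficients
    cbind(model = nm, cf, n = models[[nm]]$n, stringsAsFactors = FALSE)
  }))
}

#' Summarize shape metrics by EOR group
#'
#' Groups resected patients into GTR plus three STR tertiles via
#' [group_eor()] and reports group sizes, EOR ranges, and medians/quartiles
#' of CSA and SI - the numbers behind the published boxplot figure.
#'
#' @param cohort Cohort data.frame.
#' @return data.frame with one row per EOR group.
#' @export
eor_group_summary <- function(cohort) {
  cohort <- validate_cohort(cohort)
  res <- cohort[!cohort$biopsy_only & !is.na(cohort$eor), , drop = FALSE]
  if (nrow(res) == 0L) ts_stats_error("no resected patients with EOR available")
  grp <- group_eor(res$eor)
  do.call(rbind, lapply(levels(grp), function(g) {
    sel <- grp == g
    if (!any(sel)) {
      return(data.frame(group = g, n = 0L, eor_min = NA_real_, eor_max = NA_real_,
                        csa_median = NA_real_, csa_q1 = NA_real_, csa_q3 = NA_real_,
                        si_median = NA_real_, si_q1 = NA_real_, si_q3 = NA_real_))
    }
    qc <- stats::quantile(res$csa_cm2[sel], c(0.25, 0.5, 0.75), names = FALSE)
    qs <- stats::quantile(res$si[sel], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = sum(sel),
               eor_min = min(res$eor[sel]), eor_max = max(res$eor[sel]),
               csa_median = qc[2], csa_q1 = qc[1], csa_q3 = qc[3],
               si_median = qs[2], si_q1 = qs[1], si_q3 = qs[3])
  }))
}
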
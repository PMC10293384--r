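# Shared preparation for the model layer: factor coding, ISCED
# dichotomization (>= 3), recording-system indicator.
.prep_model_table <- function(table) {
  stopifnot(is.data.frame(table))
  vis_levels <- intersect(c("BL", "FU1", "FU2"), unique(table$visit))
  table$visit <- factor(table$visit, levels = vis_levels)
  grp_levels <- intersect(c("HC", "de_novo", "treated"), unique(table$group))
  table$group <- factor(table$group, levels = grp_levels) # HC = reference
  table$sex <- factor(table$sex)
  table$isced_high <- factor(ifelse(table$ISCED >= 3, "high", "low"),
                             levels = c("low", "high"))
  if (is.null(table$recording_system))
    table$recording_system <- ifelse(table$visit == "FU2", "Elekta", "CTF")
  table$recording_system <- factor(table$recording_system,
                                   levels = intersect(c("CTF", "Elekta"),
                                                      unique(table$recording_system)))
  table
}

# drop covariates that are constant in the data at hand (single-level factor
# or zero-variance numeric); record what was dropped
.drop_constant_terms <- function(terms, data) {
  keep <- vapply(terms, function(tm) {
    if (!tm %in% names(data)) return(TRUE) # let the fit raise the error
    v <- data[[tm]]
    v <- v[!is.na(v)]
    if (is.factor(v) || is.character(v)) length(unique(v)) >= 2L
    else stats::var(as.numeric(v)) > 0
  }, logical(1))
  list(terms = terms[keep], dropped = terms[!keep])
}

# Wald CIs on the t scale (Satterthwaite df for mixed models), one tidy row
# per fixed-effect term.
.model_result <- function(fit, dependent, bonferroni = NULL, dropped = character()) {
  if (inherits(fit, "lmerMod")) {
    co <- stats::coef(summary(fit))
    df <- co[, "df"]
    se <- co[, "Std. Error"]
    p <- co[, "Pr(>|t|)"]
    n_obs <- stats::nobs(fit)
    n_subjects <- lme4::ngrps(fit)[["subject"]]
    singular <- lme4::isSingular(fit)
    random <- "(1 | subject)"
  } else {
    co <- stats::coef(summary(fit))
    df <- stats::df.residual(fit)
    se <- co[, "Std. Error"]
    p <- co[, "Pr(>|t|)"]
    n_obs <- stats::nobs(fit)
    n_subjects <- n_obs
    singular <- FALSE
    random <- "none"
  }
  est <- co[, "Estimate"]
  half <- stats::qt(0.975, df) * se
  out <- data.frame(term = rownames(co), estimate = est,
                    conf.low = est - half, conf.high = est + half,
                    p.value = p, row.names = NULL)
  if (!is.null(bonferroni)) {
    out$significant <- out$p.value < bonferroni
    attr(out, "threshold") <- bonferroni
  }
  if (singular)
    warning(sprintf(paste("random-intercept variance for '%s' was estimated at",
                          "the boundary (singular fit)"), dependent),
            call. = FALSE)
  attr(out, "dependent") <- dependent
  attr(out, "formula") <- deparse1(stats::formula(fit))
  attr(out, "n_obs") <- n_obs
  attr(out, "n_subjects") <- n_subjects
  attr(out, "random") <- random
  attr(out, "singular") <- singular
  attr(out, "dropped_terms") <- dropped
  class(out) <- c("model_result", "data.frame")
  out
}

#' @export
print.model_result <- function(x, digits = 3, ...) {
  cat(sprintf("<model_result> %s ~ ... [%s random effect], n = %d obs / %d subjects%s\n",
              attr(x, "dependent"), attr(x, "random"), attr(x, "n_obs"),
              attr(x, "n_subjects"),
              if (isTRUE(attr(x, "singular"))) " (singular fit)" else ""))
  if (length(attr(x, "dropped_terms")))
    cat("  dropped constant covariate(s): ",
        paste(attr(x, "dropped_terms"), collapse = ", "), "\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

.check_dependent <- function(table, dependent) {
  if (!dependent %in% names(table))
    stop(sprintf("dependent '%s' is not a column of the table", dependent),
         call. = FALSE)
  y <- stats::na.omit(table[[dependent]])
  if (length(unique(y)) < 2L)
    stop(sprintf("dependent '%s' is constant", dependent), call. = FALSE)
}

.lmer_formula <- function(dependent, fixed) {
  stats::as.formula(paste(dependent, "~", paste(fixed, collapse = " + "),
                          "+ (1 | subject)"))
}

#' Longitudinal progression model
#'
#' Linear mixed model of a neurophysiological measure over the three visits
#' in the patient group (controls excluded): visit enters as a categorical
#' variable via dummies (baseline reference), with baseline age, baseline
#' disease duration, sex, dichotomized ISCED and LEDD as covariates and a
#' subject random intercept. Missing visits are handled by likelihood (no
#' imputation, no listwise deletion across visits). Visit-dummy flags use the
#' Bonferroni threshold 0.05/6.
#'
#' @param table Analysis table (see [assemble_analysis_table()]), one row per
#'   subject-visit.
#' @param dependent Name of the measure column to model.
#' @return A `model_result` data frame (term, estimate, 95% CI, p, flag).
#' @export
fit_progression_model <- function(table, dependent) {
  table <- .prep_model_table(table)
  pat <- droplevels(table[table$group != "HC", , drop = FALSE])
  if (!nrow(pat)) stop("no patient rows in table", call. = FALSE)
  .check_dependent(pat, dependent)
  if (nlevels(pat$visit) < 2L)
    stop("progression model needs at least two visits", call. = FALSE)
  covs <- .drop_constant_terms(
    c("visit", "age", "disease_duration", "sex", "isced_high", "LEDD"), pat)
  fit <- lmerTest::lmer(.lmer_formula(dependent, covs$terms), data = pat,
                        REML = TRUE)
  .model_result(fit, dependent, bonferroni = 0.05 / 6, dropped = covs$dropped)
}

#' Baseline three-group comparison model
#'
#' Cross-sectional model of a measure at baseline across healthy controls,
#' de novo and treated patients: group dummies (controls as reference) plus
#' age, sex and dichotomized ISCED. With a single observation per subject the
#' random-intercept mixed model reduces exactly to ordinary least squares,
#' which is what is fitted. Group flags use the Bonferroni threshold 0.05/6.
#'
#' @param table Analysis table; only `visit == "BL"` rows are used.
#' @param dependent Name of the measure column to model.
#' @return A `model_result` data frame.
#' @export
fit_baseline_group_model <- function(table, dependent) {
  table <- .prep_model_table(table)
  bl <- droplevels(table[table$visit == "BL", , drop = FALSE])
  .check_dependent(bl, dependent)
  for (g in c("HC", "de_novo", "treated"))
    if (!g %in% bl$group)
      stop(sprintf("empty group at baseline: %s", g), call. = FALSE)
  covs <- .drop_constant_terms(c("group", "age", "sex", "isced_high"), bl)
  if (!"group" %in% covs$terms) stop("grouping variable is constant", call. = FALSE)
  fo <- stats::as.formula(paste(dependent, "~",
                                paste(covs$terms, collapse = " + ")))
  fit <- stats::lm(fo, data = bl)
  .model_result(fit, dependent, bonferroni = 0.05 / 6, dropped = covs$dropped)
}

#' Group-by-location interaction model
#'
#' Tests whether the de novo patients' deviation from controls differs
#' between cortical and subcortical regions: each baseline subject
#' contributes two rows (the cortical and the subcortical mean of the
#' measure), modelled with group, location, their interaction, the
#' covariates age, sex and dichotomized ISCED, and a subject random
#' intercept. The interaction coefficient is the quantity of interest.
#'
#' @param table Analysis table containing `<measure>_cortical` and
#'   `<measure>_subcortical` columns.
#' @param measure Base name of the measure (e.g. `"rp_alpha1"`).
#' @return A `model_result` data frame; the interaction term is
#'   `groupde_novo:locationsubcortical`.
#' @export
fit_interaction_model <- function(table, measure) {
  table <- .prep_model_table(table)
  bl <- droplevels(table[table$visit == "BL" &
                           table$group %in% c("HC", "de_novo"), , drop = FALSE])
  cols <- paste0(measure, c("_cortical", "_subcortical"))
  if (!all(cols %in% names(bl)))
    stop(sprintf("measure columns %s not found", paste(cols, collapse = ", ")),
         call. = FALSE)
  if (anyNA(bl[cols]))
    stop("missing location rows: cortical/subcortical values must both be present",
         call. = FALSE)
  long <- rbind(
    data.frame(bl[c("subject", "group", "age", "sex", "isced_high")],
               location = "cortical", value = bl[[cols[1L]]]),
    data.frame(bl[c("subject", "group", "age", "sex", "isced_high")],
               location = "subcortical", value = bl[[cols[2L]]]))
  long$location <- factor(long$location, levels = c("cortical", "subcortical"))
  covs <- .drop_constant_terms(c("group * location", "age", "sex", "isced_high"),
                               long)
  fit <- lmerTest::lmer(.lmer_formula("value", covs$terms), data = long,
                        REML = TRUE)
  .model_result(fit, paste0(measure, " (location-long)"), dropped = covs$dropped)
}

#' Longitudinal clinical-association model
#'
#' Association between the longitudinal course of a spectral measure and a
#' clinical score in the patient group: the clinical score (CAMCOG or
#' UPDRS-III) is the dependent variable, one spectral measure (cortical or
#' subcortical) the predictor — one predictor per model, since the spectral
#' measures are too collinear to combine — with baseline age, baseline
#' disease duration, sex, LEDD and the recording-system indicator as
#' covariates, dichotomized ISCED additionally only when the dependent is
#' CAMCOG, and a subject random intercept. Flags use the 0.05 level.
#'
#' @param table Analysis table.
#' @param dependent `"CAMCOG"` or `"UPDRS_III"`.
#' @param predictor Base name of the spectral measure (e.g. `"rp_delta"`,
#'   `"peak_frequency"`).
#' @param location `"cortical"` or `"subcortical"`.
#' @return A `model_result` data frame; the row for the predictor column
#'   carries the association of interest.
#' @export
fit_clinical_association <- function(table, dependent = c("CAMCOG", "UPDRS_III"),
                                     predictor, location = c("cortical",
                                                             "subcortical")) {
  dependent <- match.arg(dependent)
  location <- match.arg(location)
  table <- .prep_model_table(table)
  pat <- droplevels(table[table$group != "HC", , drop = FALSE])
  pcol <- paste0(predictor, "_", location)
  if (!pcol %in% names(pat))
    stop(sprintf("predictor column '%s' not found", pcol), call. = FALSE)
  .check_dependent(pat, dependent)
  fixed <- c(pcol, "age", "disease_duration", "sex", "LEDD", "recording_system")
  if (dependent == "CAMCOG") fixed <- c(fixed, "isced_high")
  covs <- .drop_constant_terms(fixed, pat)
  fit <- lmerTest::lmer(.lmer_formula(dependent, covs$terms), data = pat,
                        REML = TRUE)
  res <- .model_result(fit, dependent, bonferroni = 0.05, dropped = covs$dropped)
  attr(res, "predictor") <- pcol
  res
}

#' Write model results as tidy CSV
#'
#' One row per (model, term) with estimate, CI, p and flags; metadata columns
#' identify the model.
#'
#' @param results A `model_result` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_results_csv <- function(results, path) {
  if (inherits(results, "model_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(dependent = attr(r, "dependent"), as.data.frame(r),
               n_obs = attr(r, "n_obs"), n_subjects = attr(r, "n_subjects"),
               singular = attr(r, "singular"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
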
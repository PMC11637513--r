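# Regression analyses on matched individuals: linear models for term birth
# weight (grams), logistic models for low TBW / preterm / very preterm birth
# (odds ratios), with base and fully adjusted covariate sets, cluster-robust
# standard errors by matched set, and the distance-, covariate- and
# time-stratified variants plus the continuous-exposure sensitivity model.

#' Outcome definitions
#'
#' `tbw` (term birth weight, grams, linear) and `low_tbw` (< 2500 g) are
#' restricted to deliveries at 37-42 completed weeks; `ptb` (22 to < 37
#' weeks) and `vptb` (22 to < 32 weeks) use all analyzable records (22-42
#' weeks).
#'
#' @param name One of `"tbw"`, `"low_tbw"`, `"ptb"`, `"vptb"`.
#' @return List with `name`, `type` (`continuous`/`binary`) and the
#'   gestational-week restriction `weeks`.
#' @export
outcome_definition <- function(name = c("tbw", "low_tbw", "ptb", "vptb")) {
  name <- match.arg(name)
  switch(name,
    tbw = list(name = "tbw", type = "continuous", weeks = c(37L, 42L)),
    low_tbw = list(name = "low_tbw", type = "binary", weeks = c(37L, 42L)),
    ptb = list(name = "ptb", type = "binary", weeks = c(22L, 42L)),
    vptb = list(name = "vptb", type = "binary", weeks = c(22L, 42L)))
}

#' Restrict birth records to an outcome's analyzable cohort
#'
#' @param records Birth records with `gestational_weeks`.
#' @param outcome An [outcome_definition()] or its name.
#' @return The restricted records.
#' @export
restrict_records <- function(records, outcome) {
  if (is.character(outcome)) outcome <- outcome_definition(outcome)
  w <- records$gestational_weeks
  records[!is.na(w) & w >= outcome$weeks[1] & w <= outcome$weeks[2], ,
          drop = FALSE]
}

# Outcome vector for restricted records.
.outcome_values <- function(records, outcome) {
  switch(outcome$name,
    tbw = records$birth_weight,
    low_tbw = as.integer(records$birth_weight < 2500),
    ptb = as.integer(records$gestational_weeks < 37),
    vptb = as.integer(records$gestational_weeks < 32))
}

# Covariate lists. The base TBW model additionally adjusts for gestational
# week (categorical); the full set adds the sociodemographic covariates.
.covariate_set <- function(set, outcome) {
  base <- c("sex", "maternal_age", "birth_month", "birth_year",
            "nearest_dist", "county")
  if (outcome$name == "tbw") base <- c(base, "gest_weeks_cat")
  if (set == "base") return(base)
  c(base, "race_ethnicity", "foreign_born", "payment_source", "wic",
    "smoking", "weight_gain", "prenatal_care_month", "income_tertile")
}

#' Assemble the matched-individual analysis table
#'
#' One row per matched individual (exposed members once each, controls once
#' per use), with the downwind indicator, matched-set id (the exposed
#' residence id), outcome value and all available covariates. Matched sets
#' with any member missing a modelled value are dropped whole.
#'
#' @param matches Matched pairs from [build_matches()].
#' @param records Birth records (already restricted for the outcome).
#' @param exposure Cohort exposure table.
#' @param outcome An [outcome_definition()].
#' @return Data frame with `match_id`, `exposed`, `y` and covariates; the
#'   retained pair table is in `attr(, "pairs")`.
#' @export
build_analysis_data <- function(matches, records, exposure, outcome) {
  if (is.character(outcome)) outcome <- outcome_definition(outcome)
  keep <- matches$exposed_id %in% records$residence_id &
    matches$control_id %in% records$residence_id
  m <- matches[keep, , drop = FALSE]
  ex_ids <- unique(m$exposed_id)
  rows <- data.frame(
    residence_id = c(ex_ids, m$control_id),
    match_id = c(ex_ids, m$exposed_id),
    exposed = c(rep(1L, length(ex_ids)), rep(0L, nrow(m))),
    stringsAsFactors = FALSE)
  idx <- match(rows$residence_id, records$residence_id)
  rec <- records[idx, , drop = FALSE]
  rows$y <- .outcome_values(rec, outcome)
  copy_cols <- setdiff(names(rec), c("residence_id", "birth_record_id"))
  for (v in copy_cols) rows[[v]] <- rec[[v]]
  eidx <- match(rows$residence_id, exposure$residence_id)
  for (v in intersect(c("nearest_dist", "pct_downwind_max", "mean_pct_downwind",
                        "bldg_shield_max", "tree_shield_max"), names(exposure)))
    rows[[v]] <- exposure[[v]][eidx]
  if ("gestational_weeks" %in% names(rows))
    rows$gest_weeks_cat <- factor(rows$gestational_weeks)
  attr(rows, "pairs") <- m
  rows
}

# Reference level = most frequent category.
.relevel_by_freq <- function(f) {
  f <- droplevels(factor(f))
  stats::relevel(f, ref = names(sort(table(f), decreasing = TRUE))[1])
}

# Core fitting engine shared by all model variants. `exposure_var` is the
# column holding the exposure term (downwind indicator or continuous
# percent); reports on the grams scale for linear fits and the OR scale for
# logistic fits, with 95% CIs from cluster-robust (by matched set) or plain
# variance.
.fit_effect <- function(data, outcome, exposure_var, covars,
                        plain_se = FALSE, stratum = NA_character_,
                        model_label = "base") {
  est <- data.frame(outcome = outcome$name, model = model_label,
                    stratum = stratum,
                    scale = if (outcome$type == "continuous") "grams" else "odds-ratio",
                    point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    n_pairs = 0L, n_events = NA_integer_,
                    converged = FALSE, note = "", se_link = NA_real_,
                    stringsAsFactors = FALSE)
  pairs <- attr(data, "pairs")
  covars <- intersect(covars, names(data))
  use <- c("y", exposure_var, covars, "match_id")
  cc <- stats::complete.cases(data[, use, drop = FALSE])
  bad_sets <- unique(data$match_id[!cc])
  d <- data[!(data$match_id %in% bad_sets), , drop = FALSE]
  if (length(bad_sets))
    est$note <- sprintf("dropped %d matched sets with incomplete records", length(bad_sets))
  if (!is.null(pairs)) {
    pairs <- pairs[pairs$exposed_id %in% d$residence_id &
                     pairs$control_id %in% d$residence_id, , drop = FALSE]
    est$n_pairs <- nrow(pairs)
  }
  if (nrow(d) < 4 || length(unique(d[[exposure_var]])) < 2) return(est)
  if (outcome$type == "binary") {
    est$n_events <- sum(d$y)
    if (sum(d$y) == 0 || sum(d$y) == nrow(d)) return(est)
  }
  # keep only covariates that still vary; factors releveled to modal reference
  kept <- character(0)
  for (v in covars) {
    col <- d[[v]]
    if (is.numeric(col) && length(unique(col)) > 1) {
      kept <- c(kept, v)
    } else if (!is.numeric(col)) {
      f <- droplevels(factor(col))
      if (nlevels(f) > 1) {
        d[[v]] <- .relevel_by_freq(f)
        kept <- c(kept, v)
      }
    }
  }
  if (exposure_var == "exposed" && is.numeric(d$exposed) == FALSE)
    d$exposed <- as.numeric(d$exposed)
  form <- stats::reformulate(c(exposure_var, kept), response = "y")
  fit <- tryCatch({
    if (outcome$type == "continuous") stats::lm(form, data = d)
    else suppressWarnings(stats::glm(form, data = d, family = stats::binomial()))
  }, error = function(e) NULL)
  if (is.null(fit)) return(est)
  cf <- stats::coef(fit)
  xnm <- exposure_var
  if (is.na(cf[xnm])) {
    est$note <- paste(est$note, "exposure term aliased")
    return(est)
  }
  if (anyNA(cf)) {
    # drop fully aliased terms (e.g. a covariate collinear with exposure) and refit
    al <- names(cf)[is.na(cf)]
    drop_terms <- kept[vapply(kept, function(v) any(startsWith(al, v)), logical(1))]
    kept <- setdiff(kept, drop_terms)
    est$note <- paste(est$note, sprintf("dropped rank-deficient terms: %s",
                                        paste(drop_terms, collapse = ", ")))
    form <- stats::reformulate(c(exposure_var, kept), response = "y")
    fit <- if (outcome$type == "continuous") stats::lm(form, data = d)
           else suppressWarnings(stats::glm(form, data = d, family = stats::binomial()))
    cf <- stats::coef(fit)
  }
  V <- tryCatch({
    if (plain_se) stats::vcov(fit)
    else sandwich::vcovCL(fit, cluster = factor(d$match_id))
  }, error = function(e) NULL)
  if (is.null(V)) return(est)
  b <- cf[[xnm]]
  se <- sqrt(V[xnm, xnm])
  lo <- b - stats::qnorm(0.975) * se
  hi <- b + stats::qnorm(0.975) * se
  conv <- is.finite(b) && is.finite(se)
  if (outcome$type == "binary") {
    conv <- conv && isTRUE(fit$converged) && abs(b) < 15 && se < 50
    est$point <- exp(b); est$ci_low <- exp(lo); est$ci_high <- exp(hi)
  } else {
    est$point <- b; est$ci_low <- lo; est$ci_high <- hi
  }
  est$converged <- conv
  est$se_link <- se
  est$note <- trimws(est$note)
  est
}

#' Fit the downwind/upwind matched regression
#'
#' Linear (TBW, grams) or logistic (low TBW/PTB/vPTB, odds ratio) regression
#' of the outcome on the downwind indicator (upwind is the reference) over
#' matched individuals, adjusted by the base or full covariate set, with
#' 95% CIs from cluster-robust standard errors by matched set (or plain
#' model-based variance with `plain_se = TRUE`). Non-convergence (including
#' zero events and separation) is reported in the `converged` flag, not
#' raised.
#'
#' @param matches Matched pairs from [build_matches()].
#' @param records Birth records (restricted to the outcome's weeks window;
#'   [restrict_records()] is applied again as a guard).
#' @param exposure Cohort exposure table.
#' @param outcome Outcome name or [outcome_definition()].
#' @param covariate_set `"base"` or `"full"`.
#' @param plain_se Use model-based (unclustered) variance.
#' @param stratum Optional stratum label carried into the output.
#' @param extra_covars Additional covariate column names to adjust for.
#' @return One-row effect-estimate data frame: `outcome`, `model`,
#'   `stratum`, `scale`, `point`, `ci_low`, `ci_high`, `n_pairs`,
#'   `n_events`, `converged`, `note`, `se_link`.
#' @export
fit_downwind_model <- function(matches, records, exposure,
                               outcome = "tbw",
                               covariate_set = c("base", "full"),
                               plain_se = FALSE, stratum = NA_character_,
                               extra_covars = character(0)) {
  covariate_set <- match.arg(covariate_set)
  if (is.character(outcome)) outcome <- outcome_definition(outcome)
  records <- restrict_records(records, outcome)
  data <- build_analysis_data(matches, records, exposure, outcome)
  covars <- c(.covariate_set(covariate_set, outcome), extra_covars)
  .fit_effect(data, outcome, "exposed", covars, plain_se = plain_se,
              stratum = stratum, model_label = covariate_set)
}

# Assign each matched pair a stratum by a property of its exposed member,
# then fit within each stratum.
.fit_by_pair_stratum <- function(matches, records, exposure, outcome,
                                 covariate_set, strata_of_exposed, levels,
                                 drop_covar = NULL, plain_se = FALSE) {
  if (is.character(outcome)) outcome <- outcome_definition(outcome)
  out <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    sub <- matches[!is.na(strata_of_exposed) & strata_of_exposed == levels[i], ,
                   drop = FALSE]
    if (nrow(sub) == 0) {
      out[[i]] <- data.frame(outcome = outcome$name, model = covariate_set,
                             stratum = levels[i],
                             scale = if (outcome$type == "continuous") "grams" else "odds-ratio",
                             point = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                             n_pairs = 0L, n_events = NA_integer_,
                             converged = FALSE, note = "empty stratum",
                             se_link = NA_real_, stringsAsFactors = FALSE)
      next
    }
    rec <- restrict_records(records, outcome)
    data <- build_analysis_data(sub, rec, exposure, outcome)
    covars <- setdiff(.covariate_set(covariate_set, outcome), drop_covar)
    out[[i]] <- .fit_effect(data, outcome, "exposed", covars,
                            plain_se = plain_se, stratum = levels[i],
                            model_label = covariate_set)
  }
  do.call(rbind, out)
}

#' Distance-stratified models
#'
#' One estimate per nearest-road distance bin; a pair enters the bin of its
#' exposed member's own nearest-road distance. Empty or degenerate bins are
#' reported unconverged.
#'
#' @inheritParams fit_downwind_model
#' @param breaks Distance bin edges in meters
#'   (default `c(0, 50, 100, 300, 400, 500)`).
#' @return Effect-estimate data frame, one row per bin.
#' @export
fit_distance_strata <- function(matches, records, exposure, outcome = "tbw",
                                covariate_set = c("base", "full"),
                                breaks = c(0, 50, 100, 300, 400, 500),
                                plain_se = FALSE) {
  covariate_set <- match.arg(covariate_set)
  dist_e <- exposure$nearest_dist[match(matches$exposed_id, exposure$residence_id)]
  labs <- paste0(breaks[-length(breaks)] + c(0, rep(1, length(breaks) - 2)),
                 "-", breaks[-1])
  bin <- cut(dist_e, breaks = breaks, labels = labs, include.lowest = TRUE)
  .fit_by_pair_stratum(matches, records, exposure, outcome, covariate_set,
                       as.character(bin), labs, plain_se = plain_se)
}

#' Covariate-stratified models
#'
#' Subgroup estimates by a sociodemographic stratifier (pair assigned by the
#' exposed member's value); the stratifier is removed from the covariate
#' list inside its own strata.
#'
#' @inheritParams fit_downwind_model
#' @param stratum_var One of `"race_ethnicity"`, `"education_level"`,
#'   `"foreign_born"`, `"income_tertile"`.
#' @return Effect-estimate data frame, one row per stratum level.
#' @export
fit_covariate_strata <- function(matches, records, exposure, outcome = "tbw",
                                 covariate_set = c("base", "full"),
                                 stratum_var = "race_ethnicity",
                                 plain_se = FALSE) {
  covariate_set <- match.arg(covariate_set)
  vals <- records[[stratum_var]][match(matches$exposed_id, records$residence_id)]
  levels <- sort(unique(stats::na.omit(as.character(vals))))
  .fit_by_pair_stratum(matches, records, exposure, outcome, covariate_set,
                       as.character(vals), levels, drop_covar = stratum_var,
                       plain_se = plain_se)
}

#' Continuous-exposure sensitivity model
#'
#' Replaces the exposed/control indicator with percent of pregnancy downwind
#' of the max road, scaled so the coefficient reads per `per`-percent
#' increase (default per 10%).
#'
#' @inheritParams fit_downwind_model
#' @param per Percent-downwind unit for the reported coefficient (default 10).
#' @return One-row effect-estimate data frame.
#' @export
fit_continuous <- function(matches, records, exposure, outcome = "tbw",
                           covariate_set = c("base", "full"), per = 10,
                           plain_se = FALSE) {
  covariate_set <- match.arg(covariate_set)
  if (is.character(outcome)) outcome <- outcome_definition(outcome)
  records <- restrict_records(records, outcome)
  data <- build_analysis_data(matches, records, exposure, outcome)
  if (length(unique(stats::na.omit(data$pct_downwind_max))) < 2)
    stop("percent-downwind exposure is constant; continuous model undefined")
  data$pct_per_unit <- data$pct_downwind_max / per
  covars <- .covariate_set(covariate_set, outcome)
  est <- .fit_effect(data, outcome, "pct_per_unit", covars,
                     plain_se = plain_se, model_label = covariate_set)
  est$model <- paste0(covariate_set, "+continuous")
  est
}

#' Model with shielding adjustment
#'
#' Adds the max-road building and tree shielding percentages as linear
#' covariates (the sensitivity check that shielding does not alter the wind
#' estimate). Constant shielding columns are dropped as degenerate,
#' reproducing the unadjusted fit.
#'
#' @inheritParams fit_downwind_model
#' @return One-row effect-estimate data frame.
#' @export
fit_with_shielding <- function(matches, records, exposure, outcome = "tbw",
                               covariate_set = c("base", "full"),
                               plain_se = FALSE) {
  covariate_set <- match.arg(covariate_set)
  if (!all(c("bldg_shield_max", "tree_shield_max") %in% names(exposure)))
    stop("shielding metrics missing; run cohort_shielding() first")
  est <- fit_downwind_model(matches, records, exposure, outcome, covariate_set,
                            plain_se = plain_se,
                            extra_covars = c("bldg_shield_max", "tree_shield_max"))
  est$model <- paste0(covariate_set, "+shielding")
  est
}

#' Rolling birth-year window models
#'
#' One estimate per contiguous `window`-year span of birth years (stride 1);
#' pairs enter a window by the exposed member's birth year.
#'
#' @inheritParams fit_downwind_model
#' @param window Window width in years (default 3).
#' @return Effect-estimate data frame, one row per window.
#' @export
rolling_window_fits <- function(matches, records, exposure, outcome = "tbw",
                                covariate_set = c("base", "full"), window = 3,
                                plain_se = FALSE) {
  covariate_set <- match.arg(covariate_set)
  year_e <- records$birth_year[match(matches$exposed_id, records$residence_id)]
  yr <- range(year_e, na.rm = TRUE)
  starts <- seq(yr[1], max(yr[1], yr[2] - window + 1))
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    lab <- sprintf("%d-%d", starts[i], starts[i] + window - 1)
    inwin <- !is.na(year_e) & year_e >= starts[i] & year_e <= starts[i] + window - 1
    strata <- ifelse(inwin, lab, NA_character_)
    out[[i]] <- .fit_by_pair_stratum(matches, records, exposure, outcome,
                                     covariate_set, strata, lab,
                                     plain_se = plain_se)
  }
  do.call(rbind, out)
}
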
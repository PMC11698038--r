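# Variables normalized as ratios to the per-animal control mean; elevation
# is a polar quantity so it is normalized as a difference instead.
ratio_variables <- function() {
  c(rel_time_to_takeoff = "time_to_takeoff_s",
    rel_velocity = "velocity_m_s",
    rel_acceleration = "acceleration_m_s2",
    rel_kinetic_energy = "kinetic_energy_J",
    rel_kinetic_energy_density = "kinetic_energy_density_J_kg",
    rel_power = "power_W",
    rel_power_density = "power_density_W_kg")
}

difference_variables <- function() "elevation_deg"

#' Per-animal control means
#'
#' Arithmetic mean of each jump variable over one animal's control
#' (rigid-surface) jumps. These means are the normalization baseline for
#' that animal's experimental jumps; control means are never pooled across
#' animals.
#'
#' @param jump_table canonical jump table.
#' @param animal_id animal whose controls to average.
#' @return Named numeric vector of per-variable control means.
#' @export
control_means <- function(jump_table, animal_id) {
  ctrl <- jump_table[jump_table$platform_id == "control" &
                       jump_table$animal_id == animal_id, ]
  if (nrow(ctrl) == 0L)
    stop("animal ", animal_id, " has no control jumps")
  vars <- intersect(c(ratio_variables(), difference_variables()),
                    names(ctrl))
  vapply(ctrl[vars], mean, numeric(1))
}

#' Normalize experimental jumps to per-animal control means
#'
#' Every variable is expressed as a proportion of the same animal's control
#' mean, except elevation, which is expressed as a difference in degrees
#' (ratios of angles are not meaningful). Each normalized jump is labelled
#' with its stiffness regime: `compliant` where the platform stiffness is
#' below the across-animal mean effective stiffness `k_g_split`, `stiff`
#' where it is at or above it (ties, a measure-zero case, go to `stiff`).
#'
#' @param jump_table canonical jump table containing control and
#'   experimental rows.
#' @param k_g_split stiffness used for the regime split, N m^-1; defaults
#'   to the across-animal mean control k_g from [animal_stiffness()].
#' @return Data frame of normalized experimental jumps: identifiers, `k_p`,
#'   `regime`, and `rel_*` / `diff_*` columns.
#' @export
normalize_jumps <- function(jump_table, k_g_split = NULL) {
  if (is.null(k_g_split))
    k_g_split <- attr(animal_stiffness(jump_table), "mean_k_g")
  exper <- jump_table[jump_table$platform_id != "control", ]
  if (nrow(exper) == 0L) stop("no experimental jumps to normalize")
  if (any(is.na(exper$k_p_N_m)))
    stop("every experimental jump needs a platform stiffness k_p_N_m")
  out <- do.call(rbind, lapply(seq_len(nrow(exper)), function(i) {
    row <- exper[i, ]
    cm <- control_means(jump_table, row$animal_id)
    rv <- ratio_variables()
    rel <- lapply(rv, function(v) {
      if (cm[[v]] == 0)
        stop("zero control mean for ", v, " (animal ", row$animal_id,
             "): ratio undefined")
      row[[v]] / cm[[v]]
    })
    names(rel) <- names(rv)
    d <- data.frame(
      animal_id = row$animal_id,
      platform_id = row$platform_id,
      line_index = row$line_index,
      k_p_N_m = row$k_p_N_m,
      regime = if (row$k_p_N_m < k_g_split) "compliant" else "stiff",
      stringsAsFactors = FALSE
    )
    d <- cbind(d, as.data.frame(rel))
    d$diff_elevation_deg <- row$elevation_deg - cm[["elevation_deg"]]
    d
  }))
  attr(out, "k_g_split") <- k_g_split
  rownames(out) <- NULL
  out
}

#' One-sample location test against the normalization null
#'
#' Two-sided one-sample t-test of whether normalized values differ from the
#' null mean (1.0 for ratio variables, 0 for elevation differences). A
#' Shapiro-Wilk normality check at alpha = 0.05 is run first; when it
#' rejects, a Wilcoxon signed-rank test against the same null is reported
#' alongside the t-test.
#'
#' @param values numeric sample (n >= 2, non-zero variance).
#' @param null_mean null hypothesis mean, typically 1.0 or 0.
#' @param shapiro_alpha significance level of the normality check.
#' @return List: `statistic`, `p_value` (t-test), `normal` (logical),
#'   `shapiro_p`, and, when non-normal, `wilcoxon_statistic` /
#'   `wilcoxon_p`.
#' @export
one_sample_test <- function(values, null_mean, shapiro_alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least two values")
  if (stats::sd(values) == 0)
    stop("zero sample variance: test statistic undefined")
  tt <- stats::t.test(values, mu = null_mean)
  sh <- stats::shapiro.test(values)
  out <- list(
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    df = unname(tt$parameter),
    normal = sh$p.value >= shapiro_alpha,
    shapiro_p = sh$p.value
  )
  if (!out$normal) {
    wt <- stats::wilcox.test(values, mu = null_mean, exact = FALSE)
    out$wilcoxon_statistic <- unname(wt$statistic)
    out$wilcoxon_p <- wt$p.value
  }
  out
}

#' Per-line one-sample tests across all normalized variables
#'
#' Runs [one_sample_test()] for each normalized variable at each platform
#' stiffness (platform x line), against 1.0 for ratio variables and 0 for
#' the elevation difference.
#'
#' @param normalized output of [normalize_jumps()].
#' @return Long data frame: `platform_id`, `line_index`, `k_p_N_m`,
#'   `variable`, `n`, `mean`, `statistic`, `p`, `normal`.
#' @export
per_line_tests <- function(normalized) {
  vars <- c(grep("^rel_", names(normalized), value = TRUE),
            "diff_elevation_deg")
  groups <- split(normalized,
                  list(normalized$platform_id, normalized$line_index),
                  drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(vars, function(v) {
      null_mean <- if (startsWith(v, "rel_")) 1.0 else 0.0
      vals <- g[[v]]
      res <- tryCatch(one_sample_test(vals, null_mean),
                      error = function(e) NULL)
      data.frame(
        platform_id = g$platform_id[1],
        line_index = g$line_index[1],
        k_p_N_m = g$k_p_N_m[1],
        variable = v,
        n = length(vals),
        mean = mean(vals),
        statistic = if (is.null(res)) NA_real_ else res$statistic,
        p = if (is.null(res)) NA_real_ else res$p_value,
        normal = if (is.null(res)) NA else res$normal,
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Regime mixed models
#'
#' Fits the stiffness-regime models on normalized jumps, with a per-animal
#' random intercept throughout (animals are sampled repeatedly):
#' \itemize{
#'   \item compliant regime (k_p below the mean jumper stiffness): response
#'     ~ platform stiffness covariate;
#'   \item stiff regime: response ~ platform stiffness * platform type
#'     initially; if the interaction is non-significant (p >= 0.05 by the
#'     Satterthwaite F-test) it is dropped and the additive model refitted.
#' }
#'
#' @param normalized output of [normalize_jumps()].
#' @param variable name of the normalized response column (e.g.
#'   `"rel_velocity"`).
#' @param regime `"compliant"` or `"stiff"`.
#' @param interaction_alpha threshold for retaining the stiff-regime
#'   interaction term.
#' @return List with the fitted `model` (lmerMod), `anova` (Satterthwaite F
#'   table), `slope` (platform-stiffness coefficient), `slope_ci` (95%
#'   Wald interval), and `interaction_dropped`.
#' @export
regime_model <- function(normalized, variable,
                         regime = c("compliant", "stiff"),
                         interaction_alpha = 0.05) {
  regime <- match.arg(regime)
  d <- normalized[normalized$regime == regime, ]
  if (nrow(d) == 0L) stop("no jumps in the ", regime, " regime")
  if (length(unique(d$animal_id)) < 2L)
    stop("need at least two animals to estimate the per-animal random intercept")
  d$response <- d[[variable]]
  if (is.null(d$response)) stop("no such variable: ", variable)
  d$platform_id <- factor(d$platform_id)
  interaction_dropped <- FALSE
  if (regime == "stiff" && nlevels(d$platform_id) > 1L) {
    full <- lmerTest::lmer(
      response ~ k_p_N_m * platform_id + (1 | animal_id), data = d)
    an <- stats::anova(full)
    p_int <- an["k_p_N_m:platform_id", "Pr(>F)"]
    if (is.na(p_int) || p_int >= interaction_alpha) {
      interaction_dropped <- TRUE
      fit <- lmerTest::lmer(
        response ~ k_p_N_m + platform_id + (1 | animal_id), data = d)
    } else {
      fit <- full
    }
  } else {
    fit <- lmerTest::lmer(response ~ k_p_N_m + (1 | animal_id), data = d)
  }
  an <- stats::anova(fit)
  coefs <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  slope <- unname(coefs["k_p_N_m"])
  slope_se <- unname(se[names(coefs) == "k_p_N_m"])
  list(
    model = fit,
    anova = an,
    slope = slope,
    slope_se = slope_se,
    slope_ci = slope + c(-1, 1) * stats::qnorm(0.975) * slope_se,
    interaction_dropped = interaction_dropped
  )
}

#' Regime model battery over all normalized variables
#'
#' Fits [regime_model()] for every normalized variable in both regimes and
#' assembles a flat report: one row per model term with its estimate,
#' F statistic, Satterthwaite degrees of freedom and p-value.
#'
#' @param normalized output of [normalize_jumps()].
#' @param variables columns to model; defaults to all `rel_*` plus the
#'   elevation difference.
#' @return Data frame `regime`, `variable`, `term`, `estimate`, `F`,
#'   `df_num`, `df_den`, `p`, `interaction_dropped`.
#' @export
regime_model_report <- function(normalized, variables = NULL) {
  if (is.null(variables))
    variables <- c(grep("^rel_", names(normalized), value = TRUE),
                   "diff_elevation_deg")
  rows <- list()
  for (regime in intersect(c("compliant", "stiff"),
                           unique(normalized$regime))) {
    for (v in variables) {
      res <- tryCatch(regime_model(normalized, v, regime),
                      error = function(e) NULL)
      if (is.null(res)) next
      an <- res$anova
      coefs <- lme4::fixef(res$model)
      for (term in rownames(an)) {
        est <- if (term %in% names(coefs)) unname(coefs[term]) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          regime = regime, variable = v, term = term,
          estimate = est,
          F = an[term, "F value"],
          df_num = an[term, "NumDF"],
          df_den = an[term, "DenDF"],
          p = an[term, "Pr(>F)"],
          interaction_dropped = res$interaction_dropped,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
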
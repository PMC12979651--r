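#' Random-intercept screening LMM for one indicator
#'
#' Fits the screening linear mixed model for one behavioural or oculomotor
#' indicator: experimental conditions (group, congruency, SOA, cue type),
#' group-by-condition interactions and demographic/psychological
#' covariates as fixed effects, with a participant random intercept,
#' estimated by REML. Continuous predictors are z-transformed so
#' coefficients are comparable across scales. Fixed effects are reported
#' with Wald z statistics and normal-approximation p values; marginal and
#' conditional R-squared come from the variance-partition formulation
#' (fixed-effect variance over, respectively plus, the random-intercept
#' and residual variances).
#'
#' @param data Long table, one row per participant-by-condition cell,
#'   with a response column, condition columns, covariates and an `id`.
#' @param response Name of the response column.
#' @param condition_vars Condition factors; any with fewer than two levels
#'   in `data` (e.g. cue type for social-only indicators) are dropped.
#' @param covariates Covariate columns (z-scored when numeric).
#' @param group,id Column names of the group factor and participant id.
#' @return A `gc_lmm` object: `fixed` (tibble of term, estimate, z, p),
#'   `r2m`, `r2c`, `varcomp`, `singular`, and the underlying `lme4` fit.
#'   Has [tidy()] and [glance()] methods.
#' @export
fit_screening_lmm <- function(data, response = "value",
                              condition_vars = c("congruency", "soa",
                                                 "cue_type"),
                              covariates = c("age", "sex", "cars", "cdi",
                                             "staic_state", "staic_trait"),
                              group = "group", id = "id") {
  d <- tibble::as_tibble(data)
  d <- d[!is.na(d[[response]]), , drop = FALSE]
  condition_vars <- condition_vars[
    vapply(condition_vars, function(v)
      v %in% names(d) && dplyr::n_distinct(d[[v]]) > 1, TRUE)
  ]
  covariates <- intersect(covariates, names(d))
  for (v in covariates) {
    if (is.numeric(d[[v]])) d[[v]] <- as.numeric(scale(d[[v]]))
  }
  for (v in c(condition_vars, group)) d[[v]] <- factor(d[[v]])

  rhs <- c(
    group,
    condition_vars,
    paste(group, condition_vars, sep = ":"),
    covariates,
    paste0("(1|", id, ")")
  )
  fml <- as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  fit <- suppressMessages(lme4::lmer(fml, data = d, REML = TRUE))
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("screening LMM fit is singular (random-intercept variance ~ 0)",
            call. = FALSE)
  }

  co <- summary(fit)$coefficients
  fixed <- tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    z = unname(co[, "t value"]),
    p = 2 * pnorm(-abs(unname(co[, "t value"])))
  )

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_r <- sum(vc$vcov[vc$grp != "Residual"])
  var_e <- vc$vcov[vc$grp == "Residual"]
  var_f <- var(as.vector(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  tot <- var_f + var_r + var_e
  structure(
    list(
      fixed = fixed,
      r2m = var_f / tot,
      r2c = (var_f + var_r) / tot,
      varcomp = tibble::tibble(component = c("participant", "residual"),
                               variance = c(var_r, var_e)),
      singular = singular,
      response = response,
      model = fit
    ),
    class = "gc_lmm"
  )
}

#' Mann-Whitney U rank test
#'
#' Two-sided rank-sum comparison of two independent samples, with midranks
#' for ties: exact p by enumeration for small tie-free samples (both
#' groups of size 8 or fewer), normal approximation with tie correction
#' otherwise. Degenerate input with every value tied across both groups
#' returns p = 1.
#'
#' @param x,y Numeric samples (NAs dropped).
#' @return A one-row tibble with `U` (statistic for the first sample) and
#'   `p`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1L) {
    return(tibble::tibble(U = length(x) * length(y) / 2, p = 1))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && max(length(x), length(y)) <= 8
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact)
  )
  tibble::tibble(U = unname(ht$statistic), p = ht$p.value)
}

#' Cohen's d with pooled SD
#'
#' Standardised mean difference `(mean(x) - mean(y)) / s_pooled`, the
#' pooled SD weighting each group's variance by its degrees of freedom.
#'
#' @param x,y Numeric samples (NAs dropped); each needs at least two
#'   values.
#' @return The effect size `d` (`NA` if the pooled SD is zero).
#' @examples
#' cohens_d(rnorm(20, 1), rnorm(20, 0))
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (sp == 0) return(NA_real_)
  (mean(x) - mean(y)) / sp
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p values (monotone, capped at 1).
#'
#' @param p Vector of p values in `[0, 1]`.
#' @return Adjusted p values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

# map whole-session summary columns to their parent indicator
TOTAL_COLUMNS <- list(
  rt = "rt_sd",
  null_rate = c("null_rate_total", "sd_null_rate"),
  per_fix_dur = "per_fix_dur_social",
  acc = "acc_total",
  rja = "rja_rate_social",
  peripheral = "peripheral_rate_social"
)

#' Feature-screening funnel
#'
#' Implements the two-stage screen used before classification. Stage 1:
#' for each indicator, the screening LMM ([fit_screening_lmm()]) is fitted
#' on the participant-by-condition table; an indicator advances if any
#' fixed-effect or covariate term (intercept excluded) has p below
#' `alpha_screen`. Stage 2: every condition-level column of the advancing
#' indicators (including their gaze-cueing-effect and whole-session
#' columns) is compared between groups with the Mann-Whitney U test;
#' Benjamini-Hochberg correction is applied within this candidate set, and
#' columns with adjusted p below `alpha_final` are retained.
#'
#' @param cond_long Participant-by-condition long table
#'   ([aggregate_conditions()]) joined with the participant covariates.
#' @param participant_matrix Wide matrix from [aggregate_participants()].
#' @param indicators Indicator keys to screen (default: all present).
#' @param alpha_screen LMM screening threshold (default 0.15).
#' @param alpha_final Adjusted-p retention threshold (default 0.05).
#' @param covariates Covariates passed to the LMM.
#' @return A `gc_screen` list: `tests` (tibble of feature column,
#'   indicator, group summaries, `U`, `p_raw`, `p_adj`, `cohens_d`,
#'   `selected`), `indicators` (tibble of indicator, advanced, min LMM p),
#'   and `lmm` (named list of `gc_lmm` fits).
#' @export
screen_features <- function(cond_long, participant_matrix,
                            indicators = NULL, alpha_screen = 0.15,
                            alpha_final = 0.05,
                            covariates = c("age", "sex", "cars", "cdi",
                                           "staic_state", "staic_trait")) {
  indicators <- indicators %||% unique(cond_long$feature)
  lmms <- list()
  advanced <- logical(length(indicators))
  min_p <- rep(NA_real_, length(indicators))

  for (i in seq_along(indicators)) {
    ind <- indicators[i]
    d <- cond_long[cond_long$feature == ind, , drop = FALSE]
    if (sum(!is.na(d$value)) < 10 || dplyr::n_distinct(d$group) < 2) next
    fit <- tryCatch(
      suppressWarnings(fit_screening_lmm(d, covariates = covariates)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    lmms[[ind]] <- fit
    ps <- fit$fixed$p[fit$fixed$term != "(Intercept)"]
    min_p[i] <- suppressWarnings(min(ps, na.rm = TRUE))
    advanced[i] <- any(ps < alpha_screen, na.rm = TRUE)
  }

  candidate_cols <- function(ind) {
    cols <- grep(paste0("^", ind, "\\."), names(participant_matrix),
                 value = TRUE)
    cols <- c(cols, grep(paste0("^gce_", ind, "\\."),
                         names(participant_matrix), value = TRUE))
    c(cols, intersect(TOTAL_COLUMNS[[ind]] %||% character(0),
                      names(participant_matrix)))
  }
  cols <- unique(unlist(purrr::map(indicators[advanced], candidate_cols)))

  tests <- purrr::map(cols, function(cl) {
    v <- participant_matrix[[cl]]
    g <- participant_matrix$group
    x <- v[g == "ADHD"]; y <- v[g == "TD"]
    if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) return(NULL)
    mw <- mann_whitney(x, y)
    tibble::tibble(
      feature = cl,
      indicator = sub("^(gce_)?([a-z_]+?)\\..*$", "\\2", cl),
      mean_adhd = mean(x, na.rm = TRUE), sd_adhd = sd(x, na.rm = TRUE),
      mean_td = mean(y, na.rm = TRUE), sd_td = sd(y, na.rm = TRUE),
      U = mw$U, p_raw = mw$p,
      cohens_d = cohens_d(x, y)
    )
  }) |> dplyr::bind_rows()

  if (nrow(tests)) {
    tests$p_adj <- bh_adjust(tests$p_raw)
    tests$selected <- tests$p_adj < alpha_final
    tests <- dplyr::arrange(tests, .data$p_adj, .data$p_raw)
  } else {
    tests <- tibble::tibble(
      feature = character(), indicator = character(),
      mean_adhd = numeric(), sd_adhd = numeric(),
      mean_td = numeric(), sd_td = numeric(), U = numeric(),
      p_raw = numeric(), cohens_d = numeric(), p_adj = numeric(),
      selected = logical()
    )
  }

  structure(
    list(
      tests = tests,
      indicators = tibble::tibble(indicator = indicators,
                                  advanced = advanced, min_lmm_p = min_p),
      lmm = lmms,
      alpha_screen = alpha_screen, alpha_final = alpha_final
    ),
    class = "gc_screen"
  )
}

#' @export
print.gc_screen <- function(x, ...) {
  cat("<gc_screen> ", sum(x$indicators$advanced), "/",
      nrow(x$indicators), " indicators advanced; ",
      sum(x$tests$selected), "/", nrow(x$tests),
      " condition features retained (BH-adjusted p < ", x$alpha_final,
      ")\n", sep = "")
  invisible(x)
}
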
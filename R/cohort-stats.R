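#' Longitudinal cohort statistics
#'
#' Group summaries, percent changes of group means, two-way ANOVA with
#' Bonferroni-adjusted per-day group comparisons, Pearson correlation of
#' MR parameters against the regenerating liver volume, and binomial
#' logistic regression of fatal liver failure on early MR parameters.
#'
#' @name cohort-stats
NULL

#' Group summary of a long cohort table
#'
#' Sample mean and standard deviation (n - 1 denominator) per (group,
#' day, parameter) cell. Cells absent from the table (censored) are
#' absent from the summary — they are reported as n/a downstream, never
#' zero-filled. A cell with a single animal has an undefined SD; it is
#' reported as 0 with `sd_undefined = TRUE`.
#'
#' @param table long data.frame with columns `animal_id`, `group`, `day`,
#'   `parameter`, `value` (and optionally `units`)
#' @return data.frame with columns `group`, `day`, `parameter`, `n`,
#'   `mean`, `sd`, `sd_undefined`
#' @export
groupSummary <- function(table) {
  stopifnot(nrow(table) > 0,
            all(c("group", "day", "parameter", "value") %in% names(table)))
  key <- interaction(table$group, table$day, table$parameter, drop = TRUE)
  out <- do.call(rbind, lapply(split(table, key), function(d) {
    n <- nrow(d)
    data.frame(group = d$group[1], day = d$day[1], parameter = d$parameter[1],
               n = n, mean = mean(d$value),
               sd = if (n > 1L) stats::sd(d$value) else 0,
               sd_undefined = n == 1L)
  }))
  out <- out[order(out$parameter, out$group, out$day), ]
  rownames(out) <- NULL
  out
}

#' Percent change of a value from baseline
#'
#' Integer percent change of group means, rounded half away from zero to
#' match printed precision. `direction = "increase"` reports
#' \eqn{100 (v - b)/b}; `"decrease"` reports \eqn{100 (b - v)/b}, so a
#' drop prints as a positive percentage.
#'
#' @param baseline baseline (day-0) value, > 0
#' @param value value to compare
#' @param direction `"increase"` or `"decrease"`
#' @return integer percent
#' @examples
#' percentChange(997.0, 1180.0, "increase")  # 18
#' percentChange(68.5, 61.1, "decrease")     # 11
#' @export
percentChange <- function(baseline, value, direction = c("increase", "decrease")) {
  direction <- match.arg(direction)
  if (any(baseline <= 0)) stop("baseline must be positive")
  raw <- 100 * (value - baseline) / baseline
  if (direction == "decrease") raw <- -raw
  as.integer(roundHalfUp(raw))
}

#' Two-way ANOVA with Bonferroni-adjusted per-day group comparisons
#'
#' Fixed-effects two-factor (group x day) ANOVA on the available cells of
#' an unbalanced, censored cohort. Sums of squares are sequential with
#' day entered first, so the group effect is tested adjusted for day:
#' with censored groups (PLF animals never reach the late, high-mean
#' days) an unadjusted marginal group test would conflate missing days
#' with group differences and inflate the type-I error. The omnibus is
#' followed by pairwise group comparisons at each day using the
#' pooled residual mean square of the full model. Bonferroni adjustment
#' multiplies each raw p by the size of the comparison family — all
#' (group pair, day) comparisons for this parameter — capped at 1.
#'
#' @param table long cohort table (see [groupSummary()])
#' @param parameter parameter to analyse (e.g. `"T1"`)
#' @param alpha significance threshold carried into the output
#' @return list: `omnibus` (data.frame: effect, df, F, p), `pairwise`
#'   (data.frame: day, group1, group2, diff, t, df, p_raw, p_adj,
#'   significant), `family` (number of comparisons), `alpha`
#' @export
twoWayAnovaBonferroni <- function(table, parameter, alpha = 0.05) {
  d <- table[table$parameter == parameter, ]
  if (nrow(d) == 0) stop("no records for parameter ", parameter)
  # drop groups never measured on >= 2 animals
  keep <- vapply(split(d, d$group), function(g)
    max(table(g$day)) >= 2L, logical(1))
  if (any(!keep)) {
    warning("excluding group(s) with < 2 animals at every day: ",
            paste(names(keep)[!keep], collapse = ", "))
    d <- d[d$group %in% names(keep)[keep], ]
  }
  if (length(unique(d$group)) < 2L || length(unique(d$day)) < 2L)
    stop("two-way ANOVA needs >= 2 groups and >= 2 days with data")
  d$group <- factor(d$group)
  d$dayF <- factor(d$day)
  fit <- stats::lm(value ~ dayF * group, data = d)
  an <- stats::anova(fit)
  omnibus <- data.frame(
    effect = c("day", "group", "day:group"),
    df = an$Df[1:3], F = an$`F value`[1:3], p = an$`Pr(>F)`[1:3])

  mse <- an$`Mean Sq`[nrow(an)]
  dfRes <- an$Df[nrow(an)]
  cellN <- tapply(d$value, list(d$group, d$dayF), length)
  cellM <- tapply(d$value, list(d$group, d$dayF), mean)
  groups <- levels(d$group)
  days <- levels(d$dayF)
  rows <- list()
  for (day in days) for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j <= i) next
    n1 <- cellN[groups[i], day]; n2 <- cellN[groups[j], day]
    if (is.na(n1) || is.na(n2)) next
    diff <- cellM[groups[i], day] - cellM[groups[j], day]
    tval <- diff / sqrt(mse * (1 / n1 + 1 / n2))
    praw <- 2 * stats::pt(-abs(tval), dfRes)
    rows[[length(rows) + 1L]] <- data.frame(
      day = as.numeric(day), group1 = groups[i], group2 = groups[j],
      diff = diff, t = tval, df = dfRes, p_raw = praw)
  }
  pw <- do.call(rbind, rows)
  fam <- nrow(pw)
  pw$p_adj <- pmin(1, pw$p_raw * fam)
  pw$significant <- pw$p_adj < alpha
  list(omnibus = omnibus, pairwise = pw, family = fam, alpha = alpha)
}

#' Pearson correlation of an MR parameter with relative liver volume
#'
#' Pools all days on which an animal of the group has both the parameter
#' and a relative-volume record, and computes the sample Pearson r with a
#' two-sided t-test on n - 2 degrees of freedom.
#'
#' @param table long cohort table
#' @param group group to analyse
#' @param parameter MR parameter (e.g. `"T1"`)
#' @return list: `r`, `p`, `n`, `flag` (`"ok"` or `"degenerate"` when one
#'   variable has zero variance)
#' @export
pearsonVolumeCorrelation <- function(table, group, parameter) {
  d <- table[table$group == group, ]
  x <- d[d$parameter == parameter, c("animal_id", "day", "value")]
  v <- d[d$parameter == "volume_pct", c("animal_id", "day", "value")]
  m <- merge(x, v, by = c("animal_id", "day"), suffixes = c("_par", "_vol"))
  if (nrow(m) < 3L) stop("need >= 3 paired observations")
  if (stats::sd(m$value_par) == 0 || stats::sd(m$value_vol) == 0)
    return(list(r = NA_real_, p = NA_real_, n = nrow(m), flag = "degenerate"))
  ct <- stats::cor.test(m$value_par, m$value_vol, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(m), flag = "ok")
}

#' Nagelkerke pseudo R-squared from log-likelihoods
#'
#' \eqn{R^2 = \frac{1 - (L_0/L_1)^{2/n}}{1 - L_0^{2/n}}} — the Cox-Snell
#' ratio rescaled to a [0, 1] range; 0 for the intercept-only model.
#'
#' @param ll0 log-likelihood of the intercept-only model
#' @param ll1 log-likelihood of the fitted model
#' @param n number of observations
#' @return R-squared in [0, 1]
#' @export
nagelkerkeR2 <- function(ll0, ll1, n) {
  cs <- 1 - exp(2 * (ll0 - ll1) / n)
  denom <- 1 - exp(2 * ll0 / n)
  if (denom <= 0) return(0)
  max(0, min(1, cs / denom))
}

#' Binomial logistic regression of fatal liver failure on MR parameters
#'
#' Fits death by post-hepatectomy liver failure (the PLF group) against
#' the day-`day` MR parameters of all extended-hepatectomy animals
#' (ePH + PLF) by maximum likelihood, and reports coefficients, the
#' likelihood-ratio omnibus test against the intercept-only model, and
#' Nagelkerke R-squared. With few animals and several predictors the fit
#' may separate completely; this is flagged (and warned about), the
#' coefficients are still reported, and R-squared is computed from the
#' likelihoods.
#'
#' @param table long cohort table including an attribute-free `group`
#'   column with `"ePH"` and `"PLF"` animals
#' @param day measurement day providing the predictors
#' @param predictors MR parameters used as covariates
#' @return list: `coefficients`, `omnibus_chisq`, `omnibus_df`,
#'   `omnibus_p`, `nagelkerke_r2`, `n`, `separation`
#' @export
plfLogisticRegression <- function(table, day = 1,
                                  predictors = c("T1", "T2", "ADC", "MTR")) {
  d <- table[table$group %in% c("ePH", "PLF") & table$day == day &
               table$parameter %in% predictors, ]
  if (nrow(d) == 0) stop("no predictor records on day ", day)
  wide <- stats::reshape(d[, c("animal_id", "group", "parameter", "value")],
                         idvar = c("animal_id", "group"),
                         timevar = "parameter", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  pred <- intersect(predictors, names(wide))
  wide <- wide[stats::complete.cases(wide[, pred, drop = FALSE]), ]
  wide$died <- as.integer(wide$group == "PLF")
  if (length(unique(wide$died)) < 2L)
    stop("outcome must contain both classes")
  fml <- stats::as.formula(paste("died ~", paste(pred, collapse = " + ")))
  sepWarn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = wide),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })
  fit0 <- stats::glm(died ~ 1, family = stats::binomial(), data = wide)
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(fit0))
  n <- nrow(wide)
  sep <- sepWarn || any(abs(fit$fitted.values - 0.5) > 0.5 - 1e-8)
  if (sep)
    warning("complete or quasi-complete separation: coefficients unstable")
  chisq <- 2 * (ll1 - ll0)
  dfOmni <- length(stats::coef(fit)) - 1L
  list(coefficients = stats::coef(fit),
       omnibus_chisq = chisq, omnibus_df = dfOmni,
       omnibus_p = stats::pchisq(chisq, dfOmni, lower.tail = FALSE),
       nagelkerke_r2 = nagelkerkeR2(ll0, ll1, n),
       n = n, separation = sep)
}

#' Reproduce the headline percent-change figures
#'
#' Applies [percentChange()] to the group means for the nine headline
#' comparisons of the study (T1 days 1-2 and MTR day 1 for cPH and ePH,
#' T2 day 5 for cPH and ePH, ADC day 1 for cPH) and checks them against
#' the expected integers shipped in `extdata/expected_percent_changes.csv`.
#' The ADC ePH day-1 figure is excluded from the fixture: the published
#' integer is not reproducible from the published group means (see the
#' methods vignette).
#'
#' @param summary data.frame with columns `group`, `day`, `parameter`,
#'   `mean` ([groupSummary()] output or [referenceGroupValues()])
#' @return data.frame: parameter, day, group, direction, computed,
#'   expected, pass (NA when the needed cell is missing)
#' @export
reproduceAbstractChanges <- function(summary = referenceGroupValues()) {
  fix <- utils::read.csv(system.file("extdata",
                                     "expected_percent_changes.csv",
                                     package = "hepamri"))
  cell <- function(g, day, p) {
    m <- summary$mean[summary$group == g & summary$day == day &
                        summary$parameter == p]
    if (length(m) == 1L) m else NA_real_
  }
  fix$computed <- NA_integer_
  for (i in seq_len(nrow(fix))) {
    b <- cell(fix$group[i], 0, fix$parameter[i])
    v <- cell(fix$group[i], fix$day[i], fix$parameter[i])
    if (!is.na(b) && !is.na(v))
      fix$computed[i] <- percentChange(b, v, fix$direction[i])
  }
  fix$pass <- ifelse(is.na(fix$computed), NA, fix$computed == fix$expected)
  fix
}
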
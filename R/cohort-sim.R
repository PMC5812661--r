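#' Reference group-level trajectories
#'
#' Published group means and standard deviations of the longitudinal
#' mouse-hepatectomy study the simulator emulates: relative liver volume,
#' T1, T2, ADC and MTR for the four surgical groups (cPH = conventional
#' 70 percent hepatectomy, ePH = extended 86 percent hepatectomy, PLF =
#' ePH animals dying of post-hepatectomy liver failure, SHAM = sham
#' surgery) on postoperative days 0, 1, 2, 3, 5 and 7. PLF animals have
#' no entries after day 3 (all died by then); these cells are absent, not
#' zero-filled.
#'
#' @return long data.frame with columns `group`, `day`, `parameter`,
#'   `mean`, `sd`, `units` (ADC in 1e-3 mm^2/s, MTR and volume in percent,
#'   T1/T2 in ms)
#' @export
referenceGroupValues <- function() {
  days6 <- c(0, 1, 2, 3, 5, 7)
  days4 <- c(0, 1, 2, 3)
  row <- function(group, parameter, units, days, mean, sd)
    data.frame(group = group, day = days, parameter = parameter,
               mean = mean, sd = sd, units = units)
  rbind(
    row("cPH", "volume_pct", "percent", days6,
        c(100.0, 46.4, 54.0, 64.1, 77.0, 87.1),
        c(0.0, 7.3, 8.1, 8.3, 8.5, 6.8)),
    row("ePH", "volume_pct", "percent", days6,
        c(100.0, 27.7, 32.3, 39.3, 53.3, 68.7),
        c(0.0, 3.6, 3.6, 7.8, 11.6, 9.6)),
    row("PLF", "volume_pct", "percent", days4,
        c(100.0, 30.9, 33.5, 36.4), c(0.0, 1.3, 3.1, 0.9)),
    row("SHAM", "volume_pct", "percent", days6,
        c(100.0, 99.8, 99.4, 101.6, 99.8, 100.3),
        c(0.0, 2.0, 2.6, 1.6, 2.0, 1.5)),
    row("cPH", "T1", "ms", days6,
        c(997.0, 1180.0, 1232.2, 1084.8, 1069.8, 1053.1),
        c(104.8, 165.1, 182.1, 112.6, 26.1, 69.2)),
    row("ePH", "T1", "ms", days6,
        c(972.6, 1359.7, 1451.7, 1351.7, 1172.6, 1083.4),
        c(67.7, 152.6, 97.4, 144.8, 68.8, 76.7)),
    row("PLF", "T1", "ms", days4,
        c(991.7, 1310.4, 1304.2, 2060.6), c(38.0, 103.4, 180.0, 254.8)),
    row("SHAM", "T1", "ms", days6,
        c(1030.1, 1040.4, 1033.1, 996.9, 930.5, 934.1),
        c(46.0, 58.4, 60.8, 5.4, 92.5, 34.6)),
    row("cPH", "T2", "ms", days6,
        c(29.9, 30.9, 32.3, 34.5, 36.1, 32.6),
        c(3.0, 1.4, 2.7, 1.0, 2.9, 1.5)),
    row("ePH", "T2", "ms", days6,
        c(32.3, 31.7, 33.0, 35.1, 45.6, 38.9),
        c(3.4, 1.0, 2.6, 2.3, 8.3, 4.4)),
    row("PLF", "T2", "ms", days4,
        c(29.5, 34.1, 32.9, 35.2), c(6.1, 3.0, 1.6, 7.6)),
    row("SHAM", "T2", "ms", days6,
        c(32.3, 31.2, 29.8, 28.0, 30.4, 29.2),
        c(0.5, 1.0, 2.9, 0.9, 3.2, 1.2)),
    row("cPH", "ADC", "1e-3 mm^2/s", days6,
        c(1.54, 1.34, 1.24, 1.42, 1.42, 1.27),
        c(0.25, 0.24, 0.18, 0.19, 0.22, 0.09)),
    row("ePH", "ADC", "1e-3 mm^2/s", days6,
        c(1.52, 1.04, 1.21, 1.20, 1.35, 1.19),
        c(0.22, 0.27, 0.17, 0.11, 0.13, 0.13)),
    row("PLF", "ADC", "1e-3 mm^2/s", days4,
        c(1.53, 1.07, 0.93, 0.70), c(0.18, 0.23, 0.15, 0.13)),
    row("SHAM", "ADC", "1e-3 mm^2/s", days6,
        c(1.45, 1.40, 1.49, 1.48, 1.34, 1.48),
        c(0.14, 0.16, 0.18, 0.07, 0.09, 0.07)),
    row("cPH", "MTR", "percent", days6,
        c(68.5, 61.1, 64.3, 66.8, 67.5, 68.3),
        c(1.2, 2.7, 2.1, 2.3, 2.8, 3.3)),
    row("ePH", "MTR", "percent", days6,
        c(66.2, 56.4, 59.4, 62.2, 62.9, 63.7),
        c(3.2, 3.0, 3.3, 2.0, 1.9, 4.6)),
    row("PLF", "MTR", "percent", days4,
        c(67.2, 55.1, 57.4, 56.7), c(2.0, 2.3, 2.6, 1.6)),
    row("SHAM", "MTR", "percent", days6,
        c(66.5, 65.1, 67.2, 67.9, 66.2, 66.0),
        c(3.7, 2.4, 3.6, 3.5, 3.1, 2.0))
  )
}

#' Cohort simulation settings
#'
#' Defines the study conditions of the simulated longitudinal cohort:
#' group sizes (8 cPH, 7 ePH, 4 PLF, 3 SHAM animals), measurement days
#' (0, 1, 2, 3, 5, 7), per-cell mean/SD trajectories
#' ([referenceGroupValues()] by default), the baseline absolute liver
#' volume, and the two censoring rules — PLF animals have no records after
#' day 3 (fatal liver failure), and one ePH animal lacks T2 from day 5 on
#' (a failed acquisition).
#'
#' @param groupSizes named integer vector of animals per group
#' @param values long data.frame of per-cell mean/SD (see
#'   [referenceGroupValues()])
#' @param baselineVolume preoperative absolute liver volume in mm^3
#' @param t2DropoutEph number of ePH animals whose T2 records stop before
#'   day 5 (0 disables)
#' @return a list of class `cohortSpec`
#' @export
cohortSpec <- function(groupSizes = c(cPH = 8L, ePH = 7L, PLF = 4L, SHAM = 3L),
                       values = referenceGroupValues(),
                       baselineVolume = 1200,
                       t2DropoutEph = 1L) {
  stopifnot(all(groupSizes >= 1L),
            all(c("group", "day", "parameter", "mean", "sd") %in%
                  names(values)),
            all(values$sd >= 0), all(values$mean > 0),
            baselineVolume > 0)
  structure(list(groupSizes = groupSizes, values = values,
                 baselineVolume = baselineVolume,
                 t2DropoutEph = as.integer(t2DropoutEph)),
            class = "cohortSpec")
}

#' Simulate a longitudinal cohort table
#'
#' Draws one value per (animal, day, parameter) cell as the group mean
#' plus a Gaussian animal deviation with the per-cell SD. Deviations are
#' independent across days and parameters — the reference data report only
#' per-cell mean and SD, so no covariance structure is imposed (a
#' documented simplification). Censored cells (PLF after day 3, the ePH
#' T2 dropout) are absent from the table, never zero-filled. Relative
#' volume on day 0 is exactly 100 by construction.
#'
#' @param spec a [cohortSpec()] list
#' @param seed integer seed; identical seeds give identical tables
#' @param sdScale multiplier on all SDs (0 collapses every animal onto the
#'   group mean)
#' @return list with `table` (long data.frame: `animal_id`, `group`,
#'   `day`, `parameter`, `value`, `units`) and `animals` (data.frame:
#'   `animal_id`, `group`, `died`)
#' @export
simulateCohort <- function(spec = cohortSpec(), seed = 1L, sdScale = 1) {
  stopifnot(inherits(spec, "cohortSpec"), sdScale >= 0)
  vals <- spec$values
  groups <- names(spec$groupSizes)
  animals <- do.call(rbind, lapply(groups, function(g)
    data.frame(
      animal_id = sprintf("%s_%02d", g, seq_len(spec$groupSizes[[g]])),
      group = g, died = g == "PLF")))

  tab <- .withSeed(seed, {
    out <- vector("list", nrow(animals))
    for (a in seq_len(nrow(animals))) {
      g <- animals$group[a]
      cells <- vals[vals$group == g, ]
      dev <- stats::rnorm(nrow(cells), 0, cells$sd * sdScale)
      v <- cells$mean + dev
      # physical floor: parameters are strictly positive quantities
      v <- pmax(v, 0.05 * cells$mean)
      # day-0 relative volume is 100 by definition of the normalization
      v[cells$parameter == "volume_pct" & cells$day == 0] <- 100
      out[[a]] <- data.frame(animal_id = animals$animal_id[a], group = g,
                             day = cells$day, parameter = cells$parameter,
                             value = v, units = cells$units)
    }
    do.call(rbind, out)
  })

  if (spec$t2DropoutEph > 0L) {
    dropIds <- sprintf("ePH_%02d", seq_len(min(spec$t2DropoutEph,
                                               spec$groupSizes[["ePH"]])))
    drop <- tab$animal_id %in% dropIds & tab$parameter == "T2" & tab$day >= 5
    tab <- tab[!drop, ]
  }
  rownames(tab) <- NULL
  list(table = tab, animals = animals)
}

#' Null cohort settings for calibration studies
#'
#' Returns a [cohortSpec()] in which every group follows the same per-day
#' mean/SD trajectory (taken from the cPH group), keeping the group sizes
#' and censoring structure. Under this spec the group effect is truly
#' null, which makes it the reference for type-I-error calibration of the
#' ANOVA layer.
#'
#' @param parameter restrict the settings to one parameter (faster
#'   replicate simulation); `NULL` keeps all
#' @return a `cohortSpec`
#' @export
nullCohortSpec <- function(parameter = "T1") {
  vals <- referenceGroupValues()
  if (!is.null(parameter)) vals <- vals[vals$parameter %in% parameter, ]
  ref <- vals[vals$group == "cPH", ]
  out <- do.call(rbind, lapply(unique(vals$group), function(g) {
    d <- ref[ref$day %in% vals$day[vals$group == g], ]
    d$group <- g
    d
  }))
  cohortSpec(values = out, t2DropoutEph = 0L)
}
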
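makeLongTable <- function(...) {
  d <- data.frame(...)
  d$units <- ""
  d
}

test_that("group summary handles degenerate cells and censoring", {
  tab <- makeLongTable(
    animal_id = c("a1", "a2", "b1"),
    group = c("cPH", "cPH", "ePH"),
    day = c(0, 0, 0), parameter = "T1",
    value = c(990, 1010, 980))
  s <- groupSummary(tab)
  cphRow <- s[s$group == "cPH", ]
  expect_equal(cphRow$mean, 1000)
  expect_equal(cphRow$sd, sd(c(990, 1010)))
  ephRow <- s[s$group == "ePH", ]
  expect_identical(ephRow$n, 1L)
  expect_identical(ephRow$sd, 0)
  expect_true(ephRow$sd_undefined)
  # censored cells simply do not appear
  expect_identical(nrow(s), 2L)
})

test_that("percent change reproduces printed integers with half-up rounding", {
  expect_identical(percentChange(997.0, 1180.0, "increase"), 18L)
  expect_identical(percentChange(68.5, 61.1, "decrease"), 11L)
  expect_identical(percentChange(100, 100, "increase"), 0L)
  expect_identical(percentChange(100, 100, "decrease"), 0L)
  # half-up at the .5 boundary (base round() would give 0 here)
  expect_identical(percentChange(200, 201, "increase"), 1L)
  expect_identical(percentChange(200, 199, "decrease"), 1L)
  expect_error(percentChange(0, 10), "baseline")
  # sign symmetry of the unrounded change
  b <- 123.4; v <- 150.1
  expect_equal(100 * (v - b) / b, -(100 * (b - v) / b))
})

test_that("two identical groups yield no significant pairwise contrast", {
  base <- data.frame(
    animal_id = rep(paste0("x", 1:4), each = 3),
    group = "g1",
    day = rep(c(0, 1, 2), 4), parameter = "T1",
    value = rep(c(1000, 1100, 1050), 4) + rep(c(-20, -10, 10, 20), each = 3))
  mirror <- base
  mirror$group <- "g2"
  mirror$animal_id <- sub("x", "y", mirror$animal_id)
  res <- twoWayAnovaBonferroni(rbind(base, mirror), "T1")
  expect_true(all(res$pairwise$p_adj > 1 - 1e-9))
  expect_true(all(abs(res$pairwise$diff) < 1e-9))
})

test_that("groups with fewer than two animals are excluded with a warning", {
  co <- simulateCohort(cohortSpec(groupSizes = c(cPH = 4L, ePH = 4L,
                                                 PLF = 2L, SHAM = 1L)),
                       seed = 2)
  expect_warning(res <- twoWayAnovaBonferroni(co$table, "T1"), "SHAM")
  expect_false("SHAM" %in% c(res$pairwise$group1, res$pairwise$group2))
})

test_that("Bonferroni adjustment never drops below the raw p and caps at 1", {
  co <- simulateCohort(seed = 31)
  res <- twoWayAnovaBonferroni(co$table, "MTR")
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
  expect_true(all(res$pairwise$p_adj <= 1))
  expect_identical(res$family, nrow(res$pairwise))
  # censored unbalanced PLF group is handled without error
  expect_identical(sort(unique(res$pairwise$day[res$pairwise$group1 == "PLF" |
                                                  res$pairwise$group2 == "PLF"])),
                   c(0, 1, 2, 3))
})

test_that("a 3-SD group offset at one day is detected with high power", {
  detect <- logical(200)
  for (r in seq_len(200)) {
    set.seed(4000 + r)
    vals <- data.frame(
      animal_id = rep(sprintf("a%02d", 1:16), each = 3),
      group = rep(c("g1", "g2"), each = 24),
      day = rep(c(0, 1, 2), 16),
      parameter = "T1",
      value = rnorm(48, 1000, 50))
    # 3-SD offset for group g2 on day 1
    sel <- vals$group == "g2" & vals$day == 1
    vals$value[sel] <- vals$value[sel] + 150
    res <- twoWayAnovaBonferroni(vals, "T1")
    row <- res$pairwise[res$pairwise$day == 1, ]
    detect[r] <- row$p_adj < 0.05
  }
  expect_gte(mean(detect), 0.95)
})

test_that("Pearson r matches the covariance-formula oracle", {
  tab <- makeLongTable(
    animal_id = rep(c("a1", "a2", "a3"), 2),
    group = "ePH",
    day = rep(c(1, 2, 3), 2),
    parameter = rep(c("T1", "volume_pct"), each = 3),
    value = c(1, 2, 3, 2, 4, 5))
  res <- pearsonVolumeCorrelation(tab, "ePH", "T1")
  x <- c(1, 2, 3); y <- c(2, 4, 5)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 4), 0.982)
  expect_identical(res$n, 3L)
})

test_that("Pearson r is in [-1,1], affine invariant, and flags degeneracy", {
  tab <- makeLongTable(
    animal_id = rep(sprintf("a%d", 1:5), 2),
    group = "cPH", day = rep(1:5, 2),
    parameter = rep(c("T1", "volume_pct"), each = 5),
    value = c(5, 4, 3, 2, 1, 10, 20, 30, 40, 50))
  res <- pearsonVolumeCorrelation(tab, "cPH", "T1")
  expect_equal(res$r, -1)
  # affine rescaling of the parameter leaves r unchanged
  tab2 <- tab
  sel <- tab2$parameter == "T1"
  tab2$value[sel] <- 3.2 * tab2$value[sel] + 17
  expect_equal(pearsonVolumeCorrelation(tab2, "cPH", "T1")$r, res$r,
               tolerance = 1e-12)
  tab2$value[sel] <- 7
  expect_identical(pearsonVolumeCorrelation(tab2, "cPH", "T1")$flag,
                   "degenerate")
})

test_that("simulated trajectories induce the published correlation signs", {
  co <- simulateCohort(seed = 12)
  expect_lt(pearsonVolumeCorrelation(co$table, "ePH", "T1")$r, -0.5)
  expect_gt(pearsonVolumeCorrelation(co$table, "ePH", "MTR")$r, 0.3)
})

test_that("Nagelkerke R2 matches a brute-force likelihood oracle", {
  # binary predictor: x=0 -> 8 alive, 2 dead; x=1 -> 2 alive, 8 dead
  x <- c(rep(0, 10), rep(1, 10))
  died <- c(rep(0, 8), rep(1, 2), rep(0, 2), rep(1, 8))
  tab <- makeLongTable(
    animal_id = sprintf("m%02d", 1:20),
    group = ifelse(died == 1, "PLF", "ePH"),
    day = 1, parameter = "T1", value = x)
  res <- plfLogisticRegression(tab, day = 1, predictors = "T1")

  negll <- function(beta)
    -sum(died * (beta[1] + beta[2] * x) -
           log(1 + exp(beta[1] + beta[2] * x)))
  opt <- optim(c(0, 0), negll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 1000))
  ll1 <- -opt$value
  p0 <- mean(died)
  ll0 <- sum(died * log(p0) + (1 - died) * log(1 - p0))
  n <- 20
  oracle <- (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
  expect_equal(res$nagelkerke_r2, oracle, tolerance = 1e-8)
  expect_false(res$separation)
  expect_lt(res$omnibus_p, 0.05)
})

test_that("Nagelkerke R2 is 0 for the null and bounded in [0, 1]", {
  expect_identical(nagelkerkeR2(-10, -10, 30), 0)
  set.seed(9)
  y <- rbinom(500, 1, 0.3)
  x <- rnorm(500)
  fit <- glm(y ~ x, family = binomial())
  fit0 <- glm(y ~ 1, family = binomial())
  r2 <- nagelkerkeR2(as.numeric(logLik(fit0)), as.numeric(logLik(fit)), 500)
  expect_gte(r2, 0)
  expect_lt(r2, 0.05)   # outcome independent of the predictor
})

test_that("complete separation is flagged but still yields an R2", {
  x <- c(rep(0, 5), rep(1, 5))
  tab <- makeLongTable(
    animal_id = sprintf("m%02d", 1:10),
    group = c(rep("ePH", 5), rep("PLF", 5)),
    day = 1, parameter = "T1", value = x)
  expect_warning(res <- plfLogisticRegression(tab, day = 1,
                                              predictors = "T1"),
                 "separation")
  expect_true(res$separation)
  expect_gte(res$nagelkerke_r2, 0.99)
})

test_that("the nine headline percent changes reproduce from group means", {
  chk <- reproduceAbstractChanges()
  expect_identical(nrow(chk), 9L)
  expect_true(all(chk$pass))
  # a flat summary yields all-zero changes
  ref <- referenceGroupValues()
  flat <- ref
  for (i in seq_len(nrow(flat))) {
    b <- ref$mean[ref$group == flat$group[i] & ref$day == 0 &
                    ref$parameter == flat$parameter[i]]
    flat$mean[i] <- b
  }
  chk0 <- reproduceAbstractChanges(flat)
  expect_true(all(chk0$computed == 0))
  # a missing cell is reported as NA, not an error
  chkNA <- reproduceAbstractChanges(ref[ref$day != 5, ])
  expect_true(any(is.na(chkNA$computed)))
  expect_true(all(is.na(chkNA$pass[is.na(chkNA$computed)])))
})
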
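# Mixed-effects fitting, R-squared measures, selection, diagnostics.

strain_grid <- function() {
  data.frame(severity = rep(c("mild", "moderate"), each = 5),
             segment = rep(1:5, 2),
             strain = c(0.05, 0.10, 0.20, 0.18, 0.08,
                        0.10, 0.25, 0.45, 0.40, 0.15),
             strain_rate = c(0.2, 0.5, 1.0, 0.9, 0.4,
                             0.5, 1.2, 2.2, 2.0, 0.7))
}

# direct change-table builder (independent of gen_outcomes)
make_changes <- function(n_animals, beta = 2, sa = 0, ss = 0, se = 0,
                         beta_sev = 0, seed = 1) {
  set.seed(seed)
  g <- strain_grid()
  sev <- rep(c("mild", "moderate"), length.out = n_animals)
  a_int <- rnorm(n_animals, 0, sa)
  s_int <- rnorm(5, 0, ss)
  rows <- do.call(rbind, lapply(seq_len(n_animals), function(a) {
    gg <- g[g$severity == sev[a], ]
    data.frame(animal = a, severity = sev[a], segment = gg$segment,
               measure = "m",
               change = beta * gg$strain +
                 beta_sev * (sev[a] == "moderate") + a_int[a] +
                 s_int[gg$segment] + rnorm(5, 0, se),
               strain = gg$strain, strain_rate = gg$strain_rate)
  }))
  rows
}

test_that("noise-free data recover the exact slope with vanishing variance components", {
  ch <- make_changes(6, beta = 2)
  f <- fit_lme(ch, fixed = "strain")
  expect_equal(unname(f$coefficients["strain"]), 2, tolerance = 1e-6)
  expect_lt(f$sigma2$animal + f$sigma2$segment + f$sigma2$resid, 1e-8)
  expect_equal(marginal_r2(f), 1, tolerance = 1e-6)
})

test_that("REML variance components match closed-form ANOVA estimators on a balanced design", {
  set.seed(14)
  n_a <- 12; k <- 5
  a_int <- rnorm(n_a, 0, 0.7)
  ch <- do.call(rbind, lapply(seq_len(n_a), function(a) {
    data.frame(animal = a, severity = "mild", segment = 1:k, measure = "m",
               change = 1 + a_int[a] + rnorm(k, 0, 0.4),
               strain = 0, strain_rate = 0)
  }))
  f <- fit_lme(ch, fixed = character(0), random = "animal")
  # one-way random-effects ANOVA algebra
  gm <- mean(ch$change)
  am <- tapply(ch$change, ch$animal, mean)
  msb <- k * sum((am - gm)^2) / (n_a - 1)
  msw <- sum((ch$change - am[as.character(ch$animal)])^2) / (n_a * (k - 1))
  expect_equal(f$sigma2$resid, msw, tolerance = 1e-6)
  expect_equal(f$sigma2$animal, (msb - msw) / k, tolerance = 1e-6)
})

test_that("planted generator slopes are recovered within 2 SE", {
  tab <- gen_outcomes(strain_grid(),
                      list(effect_spec("m", beta_strain = 1.5,
                                       sigma_animal = 0.5,
                                       sigma_resid = 0.4)),
                      n_mild = 250, n_moderate = 250, seed = 31)
  ch <- ipsi_minus_reference(tab, "paired_contra")
  f <- fit_lme(ch, fixed = "strain")
  se <- sqrt(diag(as.matrix(vcov(f$fit))))["strain"]
  expect_lt(abs(unname(f$coefficients["strain"]) - 1.5), 2 * se)
})

test_that("joint strain and strain-rate models require an explicit override", {
  ch <- make_changes(6, beta = 1, se = 0.1)
  expect_error(fit_lme(ch, fixed = c("strain", "strain_rate")), "collinear")
  f <- fit_lme(ch, fixed = c("strain", "strain_rate"),
               collinearity_override = TRUE)
  expect_s3_class(f, "cci_lme")
})

test_that("marginal R2 follows its variance-ratio definition", {
  # hand-arithmetic check on planted components (1, 1, 0, 1.030)
  fake <- structure(list(fit = TRUE,
                         fitted_fixed = c(-sqrt(2), 0, sqrt(2)) + 5,
                         sigma2 = list(animal = 1, segment = 0,
                                       resid = 1.030)),
                    class = "cci_lme")
  # population variance of fitted_fixed is (2+0+2)/3 = 4/3; rescale to 1
  fake$fitted_fixed <- fake$fitted_fixed / sqrt(4 / 3)
  expect_equal(marginal_r2(fake), 1 / 3.030, tolerance = 1e-12)

  # intercept-only model has zero fixed-effect variance
  ch <- make_changes(6, beta = 0, sa = 0.5, se = 0.3, seed = 4)
  f0 <- fit_lme(ch, fixed = character(0))
  expect_equal(marginal_r2(f0), 0, tolerance = 1e-12)

  # invariant to rescaling the outcome
  ch2 <- make_changes(8, beta = 1, sa = 0.3, se = 0.4, seed = 5)
  f1 <- fit_lme(ch2, fixed = "strain")
  ch2s <- ch2; ch2s$change <- ch2s$change * 7.3
  f2 <- fit_lme(ch2s, fixed = "strain")
  expect_equal(marginal_r2(f1), marginal_r2(f2), tolerance = 1e-8)
})

test_that("REML estimates are invariant to adding a constant to the outcome", {
  ch <- make_changes(8, beta = 1, sa = 0.3, se = 0.4, seed = 6)
  f1 <- fit_lme(ch, fixed = "strain")
  ch$change <- ch$change + 100
  f2 <- fit_lme(ch, fixed = "strain")
  expect_equal(f1$sigma2$animal, f2$sigma2$animal, tolerance = 1e-8)
  expect_equal(f1$sigma2$resid, f2$sigma2$resid, tolerance = 1e-8)
})

test_that("LOO predictive R2 is exact on noise-free data and equals a brute-force loop", {
  ch <- make_changes(6, beta = 2)
  expect_equal(predictive_r2(ch, "strain")$value, 1, tolerance = 1e-6)

  chn <- make_changes(6, beta = 1.2, sa = 0.3, se = 0.5, seed = 8)
  got <- predictive_r2(chn, "strain")
  # independent naive loop straight over lme4
  press <- 0
  for (a in unique(chn$animal)) {
    tr <- chn[chn$animal != a, ]; te <- chn[chn$animal == a, ]
    m <- lme4::lmer(change ~ strain + (1 | animal) + (1 | segment),
                    data = tr, REML = TRUE)
    pred <- predict(m, newdata = te, re.form = NA, allow.new.levels = TRUE)
    press <- press + sum((te$change - pred)^2)
  }
  ref <- 1 - press / sum((chn$change - mean(chn$change))^2)
  expect_equal(got$value, ref, tolerance = 1e-10)
})

test_that("pure-noise outcomes show the overfitting signature (predictive below marginal)", {
  worse <- 0
  for (r in 1:20) {
    ch <- make_changes(12, beta = 0, sa = 0.3, se = 1, seed = 100 + r)
    f <- fit_lme(ch, fixed = "strain")
    pr <- predictive_r2(ch, "strain")$value
    if (pr <= marginal_r2(f)) worse <- worse + 1
  }
  expect_gte(worse, 17)
})

test_that("backward selection keeps planted effects and drops null ones", {
  # single candidate: that model is selected
  ch0 <- make_changes(8, beta = 1, se = 0.2, seed = 9)
  rep0 <- backward_select(ch0, full_fixed = "strain", tol = 0.01)
  expect_equal(rep0$selected_fixed, "strain")
  expect_equal(sum(rep0$candidates$selected), 1)

  # planted beta_severity = 0: severity dropped, strain retained
  ch1 <- make_changes(40, beta = 2, beta_sev = 0, sa = 0.1, se = 0.15,
                      seed = 10)
  rep1 <- backward_select(ch1, full_fixed = c("strain", "severity"),
                          tol = 0.01)
  expect_true("strain" %in% rep1$selected_fixed)
  expect_false("severity" %in% rep1$selected_fixed)

  # both effects large: both retained
  ch2 <- make_changes(40, beta = 2, beta_sev = 1.5, sa = 0.1, se = 0.15,
                      seed = 11)
  rep2 <- backward_select(ch2, full_fixed = c("strain", "severity"),
                          tol = 0.01)
  expect_setequal(rep2$selected_fixed, c("strain", "severity"))
})

test_that("diagnostics flag collinearity, non-normality, and recover after log", {
  ch <- make_changes(10, beta = 1, sa = 0.2, se = 0.4, seed = 12)
  f <- fit_lme(ch, fixed = "strain")
  d <- check_model(f)
  expect_true(d$normality_ok)
  expect_true(d$homoscedastic_ok)
  expect_true(d$collinearity_ok)

  # strain and strain rate are strongly correlated by construction here
  f2 <- fit_lme(ch, fixed = c("strain", "strain_rate"),
                collinearity_override = TRUE)
  d2 <- check_model(f2)
  expect_false(d2$collinearity_ok)
  expect_gt(d2$max_abs_cor, 0.9)

  # multiplicative noise fails normality, passes after the log transform
  set.seed(13)
  chl <- make_changes(12, beta = 0, seed = 13)
  chl$change <- exp(1 + rnorm(nrow(chl), 0, 0.8))
  fl <- fit_lme(chl, fixed = character(0))
  expect_false(check_model(fl)$normality_ok)
  fll <- fit_lme(apply_log(chl), fixed = character(0))
  expect_true(check_model(fll)$normality_ok)

  # explicit shift that leaves non-positive rows errors with row ids
  chb <- chl; chb$change[3] <- -5
  expect_error(apply_log(chb, shift = 1), "row")
})

test_that("pearson correlation matches the covariance formula and guards degeneracy", {
  expect_equal(pearson_r(1:10, 1:10), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  set.seed(15)
  x <- rnorm(40); y <- 0.3 * x + rnorm(40)
  brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), brute, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 2), c(3, 4)), "length")
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
})
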
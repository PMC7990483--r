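# Synthetic outcome generation, activation classification, reference modes.

toy_strains <- function() {
  data.frame(severity = rep(c("mild", "moderate"), each = 5),
             segment = rep(1:5, 2),
             strain = c(0.05, 0.10, 0.20, 0.18, 0.08,
                        0.10, 0.25, 0.45, 0.40, 0.15),
             strain_rate = c(0.2, 0.5, 1.0, 0.9, 0.4,
                             0.5, 1.2, 2.2, 2.0, 0.7))
}

test_that("noise-free generation is exactly linear in the strain covariate", {
  sp <- list(effect_spec("m", beta_strain = 2, baseline = 0.4))
  tab <- gen_outcomes(toy_strains(), sp, n_mild = 3, n_moderate = 3, seed = 7)
  ipsi <- tab[tab$hemisphere == "ipsi", ]
  expect_equal(ipsi$value, 0.4 + 2 * ipsi$strain, tolerance = 1e-12)
  # identical across animals within (severity, segment)
  spread <- tapply(ipsi$value, paste(ipsi$severity, ipsi$segment),
                   function(v) diff(range(v)))
  expect_true(all(spread == 0))
  # contralateral rows carry the baseline only
  expect_equal(tab$value[tab$hemisphere == "contra"],
               rep(0.4, 30), tolerance = 1e-12)
})

test_that("same seed reproduces the table bit for bit; seeds differ otherwise", {
  t1 <- gen_outcomes(toy_strains(), seed = 11)
  t2 <- gen_outcomes(toy_strains(), seed = 11)
  t3 <- gen_outcomes(toy_strains(), seed = 12)
  expect_identical(t1, t2)
  expect_false(identical(t1$value, t3$value))
})

test_that("default FA effect is negative: ipsilateral FA decreases with strain", {
  specs <- default_effect_specs()
  expect_lt(specs$FA$beta_strain, 0)
  tab <- gen_outcomes(toy_strains(), specs["FA"], n_mild = 30,
                      n_moderate = 30, seed = 3)
  ipsi <- tab[tab$hemisphere == "ipsi", ]
  expect_lt(cor(ipsi$strain, ipsi$value), 0)
})

test_that("animal-intercept variance is recovered from many animals", {
  sp <- list(effect_spec("m", beta_strain = 1, sigma_animal = 0.8,
                         sigma_resid = 0.5))
  tab <- gen_outcomes(toy_strains(), sp, n_mild = 1000, n_moderate = 1000,
                      seed = 21)
  ipsi <- tab[tab$hemisphere == "ipsi", ]
  resid <- ipsi$value - 1 * ipsi$strain
  a_hat <- tapply(resid, ipsi$animal, mean)
  # Var(animal mean) = sigma_a^2 + sigma_e^2 / 5
  est <- var(a_hat) - 0.5^2 / 5
  expect_lt(abs(est - 0.8^2) / 0.8^2, 0.05)
})

test_that("empirical variance decomposes into fixed + random + residual parts", {
  # segment SD zero here: only five segment draws ever exist, so the
  # realised variance of that component (df = 4) cannot meet a tight
  # tolerance at any n; animal and residual components have 4000 / 20000
  # independent draws and pin the accounting down
  sp <- list(effect_spec("m", beta_strain = 1.5, sigma_animal = 0.6,
                         sigma_resid = 0.8))
  tab <- gen_outcomes(toy_strains(), sp, n_mild = 2000, n_moderate = 2000,
                      seed = 22)
  ipsi <- tab[tab$hemisphere == "ipsi", ]
  var_fixed <- var(1.5 * ipsi$strain)
  expected <- var_fixed + 0.6^2 + 0.8^2
  expect_lt(abs(var(ipsi$value) - expected) / expected, 0.03)
})

test_that("group sizes of one are rejected", {
  expect_error(gen_outcomes(toy_strains(), n_mild = 1, n_moderate = 5),
               "more than one animal")
  expect_error(gen_outcomes(toy_strains()[-1, ]), "all 10")
})

test_that("activation classification uses a strict 2.7 um threshold", {
  cells <- data.frame(process_thickness = c(2.7, 1.0, 3.0, 2.8))
  out <- classify_activated(cells, area_mm2 = 2)
  expect_equal(nrow(out$activated), 2)        # 2.7 itself is NOT activated
  expect_equal(out$density_total, 2)
  expect_equal(out$density_activated, 1)
  expect_error(classify_activated(cells, area_mm2 = 0), "> 0")

  glia <- gen_glia_cells(n = 500, p_activated = 0.4, seed = 9)
  out2 <- classify_activated(glia, area_mm2 = 1.5)
  expect_equal(nrow(out2$activated),
               sum(glia$process_thickness > 2.7))   # brute-force filter
})

test_that("change tables implement both reference conventions", {
  sp <- list(effect_spec("m", beta_strain = 0, baseline = 1))
  tab <- gen_outcomes(toy_strains(), sp, n_mild = 4, n_moderate = 4, seed = 2)
  ch <- ipsi_minus_reference(tab, "paired_contra")
  expect_equal(ch$change, rep(0, nrow(ch)), tolerance = 1e-12)

  # shifting every contralateral value by -c moves all changes to +c
  tab2 <- tab
  tab2$value[tab2$hemisphere == "contra"] <-
    tab2$value[tab2$hemisphere == "contra"] - 0.25
  ch2 <- ipsi_minus_reference(tab2, "paired_contra")
  expect_equal(ch2$change, rep(0.25, nrow(ch2)), tolerance = 1e-12)

  # naive-mean mode matches a brute-force group-mean subtraction
  sp3 <- list(effect_spec("m", beta_strain = 1, sigma_resid = 0.3,
                          baseline = 2))
  tab3 <- gen_outcomes(toy_strains(), sp3, n_mild = 5, n_moderate = 5,
                       seed = 5)
  ch3 <- ipsi_minus_reference(tab3, "naive_mean")
  contra <- tab3[tab3$hemisphere == "contra", ]
  for (k in 1:5) {
    ref_k <- mean(contra$value[contra$segment == k])
    rows <- ch3$segment == k
    ipsi_k <- tab3$value[tab3$hemisphere == "ipsi" & tab3$segment == k]
    expect_equal(ch3$change[rows], ipsi_k - ref_k, tolerance = 1e-12)
  }
})

test_that("log link exponentiates the linear predictor", {
  sp <- list(effect_spec("m", beta_strain = 0.5, baseline = 1, link = "log"))
  tab <- gen_outcomes(toy_strains(), sp, n_mild = 2, n_moderate = 2, seed = 1)
  ipsi <- tab[tab$hemisphere == "ipsi", ]
  expect_equal(ipsi$value, exp(1 + 0.5 * ipsi$strain), tolerance = 1e-12)
})
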
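test_that("covariate screening has power against real effects and nominal type-I error", {
  set.seed(101)
  # strong sex effect: selected in essentially every replicate
  hits <- 0L
  for (r in 1:50) {
    sex <- rep(c("M", "F"), each = 100)
    ph <- make_pheno(data.frame(y = 3 * (sex == "M") + rnorm(200)), sex = sex,
                     subfamily = rep(sprintf("f%d", 1:20), 10),
                     litter_size = sample(3:9, 200, replace = TRUE))
    sel <- screen_covariates(ph)
    hits <- hits + (sel$selected[sel$covariate == "sex"])
  }
  expect_gte(hits, 49L)
  # independent litter size: selected at close to the nominal 5% rate
  false_sel <- 0L
  for (r in 1:400) {
    ph <- make_pheno(data.frame(y = rnorm(60)),
                     litter_size = sample(3:9, 60, replace = TRUE))
    sel <- suppressWarnings(screen_covariates(ph))
    false_sel <- false_sel + (sel$selected[sel$covariate == "litter_size"])
  }
  # binomial(400, 0.05): accept within 3 SD of the mean
  expect_lt(abs(false_sel - 20) , 3 * sqrt(400 * 0.05 * 0.95) + 1)
  # no subfamily variance: rarely selected
  sub_sel <- 0L
  for (r in 1:100) {
    ph <- make_pheno(data.frame(y = rnorm(150)),
                     subfamily = rep(sprintf("f%d", 1:15), each = 10),
                     litter_size = sample(3:9, 150, replace = TRUE))
    sub_sel <- sub_sel + (screen_covariates(ph)$selected[
      screen_covariates(ph)$covariate == "subfamily"])
  }
  expect_gte(100L - sub_sel, 90L)
})

test_that("constant covariates are reported unselected with a warning", {
  ph <- make_pheno(data.frame(y = rnorm(30)), sex = rep("F", 30))
  w <- capture_warnings(sel <- screen_covariates(ph))
  expect_true(any(grepl("constant", w)))  # sex and subfamily both constant
  expect_false(sel$selected[sel$covariate == "sex"])
  expect_true(is.na(sel$p_value[sel$covariate == "sex"]))
})

test_that("Spearman correlation is rank-exact and Bonferroni threshold matches 0.05/55", {
  set.seed(111)
  x <- rnorm(40)
  ph <- make_pheno(data.frame(x = x, y = exp(x), z = -x^3))
  cm <- spearman_matrix(ph)
  expect_equal(cm$rho["x", "y"], 1)     # monotone transform
  expect_equal(cm$rho["x", "z"], -1)    # antitone transform
  expect_equal(cm$rho, t(cm$rho))
  expect_true(all(abs(cm$rho) <= 1))
  expect_equal(diag(cm$rho), setNames(rep(1, 3), c("x", "y", "z")))
  # the printed family-wise threshold: 0.05 / 55 tests = 9.09e-4 ~ 9.10e-4
  cm55 <- spearman_matrix(ph, n_tests = 55)
  expect_equal(cm55$threshold, 0.05 / 55)
  expect_lt(abs(cm55$threshold - 9.10e-4), 1e-5)
  # invariance of rho under strictly monotone transforms (property)
  for (r in 1:10) {
    a <- rnorm(25); b <- rnorm(25) + 0.5 * a
    p2 <- make_pheno(data.frame(a = a, b = b, a2 = qnorm(rank(a) / 26),
                                b2 = 5 * b^3))
    cm2 <- spearman_matrix(p2)
    expect_equal(cm2$rho["a", "b"], cm2$rho["a2", "b2"], tolerance = 1e-12)
  }
  # constant trait: NA, flagged not significant
  p3 <- make_pheno(data.frame(a = rnorm(20), c = rep(1, 20)))
  cm3 <- spearman_matrix(p3)
  expect_true(is.na(cm3$rho["a", "c"]))
  expect_false(cm3$significant["a", "c"])
})

test_that("adjusted class means reduce to raw means without covariates and recover planted effects", {
  set.seed(121)
  g <- sample(0:2, 150, replace = TRUE)
  y <- c(`0` = -1, `1` = 0.4, `2` = 1)[as.character(g)] + rnorm(150, 0, 0.5)
  ph <- make_pheno(data.frame(y = y))
  m0 <- adjusted_class_means(ph, "y", g)
  raw <- tapply(y, g, mean)
  expect_equal(unname(m0["HOM1"]), unname(raw["2"]), tolerance = 1e-12)
  expect_equal(unname(m0["HET"]), unname(raw["1"]), tolerance = 1e-12)
  expect_equal(unname(m0["HOM2"]), unname(raw["0"]), tolerance = 1e-12)
  # planted additive + dominance pattern recovered within 3 SE
  se <- 0.5 / sqrt(min(table(g)))
  expect_lt(abs(m0["HOM1"] - 1), 3 * se)
  expect_lt(abs(m0["HET"] - 0.4), 3 * se)
  expect_lt(abs(m0["HOM2"] - (-1)), 3 * se)
  # absent class: NA for it, others equal the two-class fit
  g2 <- g; g2[g2 == 0L] <- 1L
  m2 <- adjusted_class_means(ph, "y", g2)
  expect_true(is.na(m2["HOM2"]))
  expect_false(anyNA(m2[c("HOM1", "HET")]))
})

test_that("covariate-adjusted means agree with emmeans under proportional weighting", {
  skip_if_not_installed("emmeans")
  set.seed(131)
  n <- 120
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.6, 0.4))
  litter <- sample(3:9, n, replace = TRUE)
  g <- sample(0:2, n, replace = TRUE)
  y <- 1 + 2 * (sex == "M") + 0.3 * litter + 0.8 * (g == 2) + rnorm(n)
  ph <- make_pheno(data.frame(y = y), sex = sex, litter_size = litter)
  ours <- adjusted_class_means(ph, "y", g,
                               covariates = c("sex", "litter_size"))
  d <- data.frame(y = y, sex = factor(sex), litter_size = litter,
                  G = factor(g, levels = c("2", "1", "0")))
  fit <- lm(y ~ sex + litter_size + G, data = d)
  em <- emmeans::emmeans(fit, "G", weights = "proportional")
  em <- as.data.frame(em)
  expect_equal(unname(ours["HOM1"]), em$emmean[em$G == "2"], tolerance = 1e-8)
  expect_equal(unname(ours["HET"]), em$emmean[em$G == "1"], tolerance = 1e-8)
  expect_equal(unname(ours["HOM2"]), em$emmean[em$G == "0"], tolerance = 1e-8)
})
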
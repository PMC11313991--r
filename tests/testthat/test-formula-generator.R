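test_that("enumeration matches the brute-force oracle in count and content", {
  # three sign-indefinite BPs: 192 numerators x 4 denominators = 768 ratio3
  bps <- basic_properties(c("A", "B", "C"))
  s3 <- enumerate_basic_features(bps, "ratio3")
  expect_equal(nrow(s3), 768L)
  expect_setequal(bf_set_keys(s3), oracle_enumerate(bps, "ratio3"))
  expect_equal(anyDuplicated(bf_set_keys(s3)), 0L)

  s4 <- enumerate_basic_features(bps, "ratio4")
  expect_setequal(bf_set_keys(s4), oracle_enumerate(bps, "ratio4"))
  expect_equal(anyDuplicated(bf_set_keys(s4)), 0L)

  # four BPs with a positive-definite member and an exclusivity group
  bps4 <- basic_properties(c("A", "B", "C", "P"),
                           positive_definite = c(FALSE, FALSE, FALSE, TRUE),
                           group = c("g", "g", NA, NA))
  s34 <- enumerate_basic_features(bps4, "ratio3")
  expect_setequal(bf_set_keys(s34), oracle_enumerate(bps4, "ratio3"))
})

test_that("enumeration degenerate inputs give empty sets", {
  expect_equal(nrow(enumerate_basic_features(basic_properties(c("A", "B")))), 0L)
  expect_equal(nrow(enumerate_basic_features(basic_properties("A"))), 0L)
})

test_that("positivity and exclusivity constraints shape the feature set", {
  bps <- basic_properties(c("A", "B", "C"),
                          positive_definite = c(TRUE, FALSE, FALSE))
  s <- enumerate_basic_features(bps, "ratio3")
  used_sqrt <- s$nf1 == "sqrt" & s$nbp1 != "A" |
    s$nf2 == "sqrt" & s$nbp2 != "A" | s$df1 == "sqrt" & s$dbp1 != "A"
  expect_false(any(used_sqrt))
  expect_true(any(s$nf1 == "sqrt" | s$nf2 == "sqrt" | s$df1 == "sqrt"))

  grouped <- basic_properties(c("A", "B", "C", "D"),
                              group = c("g", "g", NA, NA))
  sg <- enumerate_basic_features(grouped, c("ratio3", "ratio4"))
  both <- apply(sg[, c("nbp1", "nbp2", "dbp1", "dbp2")], 1, function(r)
    all(c("A", "B") %in% r[!is.na(r)]))
  expect_false(any(both))
})

test_that("evaluate_feature computes hand-checked values and flags invalids", {
  tab <- data.frame(A = 1, B = 1, C = 2)
  bf <- basic_feature(c("x", "x"), c("A", "B"), "add", "x", "C")
  expect_equal(evaluate_feature(bf, tab)$values, 1.0)

  # the published formula's unweighted core at the first hCA II ligand
  tab2 <- data.frame(logP = 0.92, HIE_E = -1.6, F2LE = -1.6)
  bf2 <- hca2_scoring_function()$feature
  ev <- evaluate_feature(bf2, tab2)
  expect_equal(ev$numerator, 0.92^3 - exp(-1.6), tolerance = 1e-12)
  expect_equal(ev$denominator, (-1.6)^3 - (-1.6)^5, tolerance = 1e-12)
  expect_equal(ev$values, 0.0903, tolerance = 1e-3)

  # zero denominator flags only that sample
  tab3 <- data.frame(A = c(1, 1), B = c(1, 1), C = c(2, 0))
  ev3 <- evaluate_feature(bf, tab3)
  expect_equal(ev3$invalid, c(FALSE, TRUE))
  expect_true(is.na(ev3$values[2]))

  # sqrt domain violation flags the offending sample
  bfs <- basic_feature(c("sqrt", "x"), c("A", "B"), "add", "x", "C")
  ev4 <- evaluate_feature(bfs, data.frame(A = c(4, -4), B = 1, C = 1))
  expect_equal(ev4$invalid, c(FALSE, TRUE))
})

test_that("fit_linear matches hand least squares and handles degeneracy", {
  f <- fit_linear(c(0, 1, 2), c(1, 3, 5))
  expect_equal(c(f$m, f$q, f$r2, f$rmse), c(2, 1, 1, 0))

  f2 <- fit_linear(c(0, 1, 2), c(0, 1, 1))
  expect_equal(f2$m, 0.5)
  expect_equal(f2$q, 1 / 6)
  expect_equal(f2$r2, 0.75)
  expect_equal(f2$rmse, sqrt(1 / 18))

  # cross-check against lm() on a larger random case
  set.seed(11)
  x <- rnorm(25); y <- 2 * x + rnorm(25)
  f3 <- fit_linear(x, y)
  lmfit <- lm(y ~ x)
  expect_equal(f3$m, unname(coef(lmfit)[2]))
  expect_equal(f3$q, unname(coef(lmfit)[1]))
  expect_equal(f3$r2, summary(lmfit)$r.squared)

  expect_warning(fc <- fit_linear(c(0, 1, 2), c(1, 1, 1)), "zero label variance")
  expect_equal(fc$r2, 0)
  expect_error(fit_linear(c(1, 2), c(1, 2)), "at least 3")
})

test_that("weight optimization recovers exact relations and beats the unweighted fit", {
  tab <- data.frame(A = c(1, 2, 3, 4, 5), B = c(2, 1, 4, 3, 6),
                    C = c(1, 2, 1, 2, 1))
  bf <- basic_feature(c("x", "x"), c("A", "B"), "add", "x", "C")
  ev <- evaluate_feature(bf, tab)
  tab$dG_exp <- 3 * ev$values - 2          # exact at weights (1,1,1)
  sf <- optimize_weights(bf, tab)
  expect_s3_class(sf, "scoring_function")
  expect_equal(sf$fit$r2, 1, tolerance = 1e-10)
  pred <- evaluate_scoring_function(sf, tab)
  expect_equal(pred, tab$dG_exp, tolerance = 1e-8)

  # the optimized r2 can never fall below the unweighted fit (tuple 1,1,1 scanned)
  set.seed(3)
  tab$dG_exp <- tab$dG_exp + rnorm(5, 0, 0.5)
  un <- fit_linear(evaluate_feature(bf, tab)$values, tab$dG_exp)
  sf2 <- optimize_weights(bf, tab)
  expect_gte(sf2$fit$r2, un$r2 - 1e-10)

  # weights come off the 0.1 grid
  expect_true(all(abs(sf2$weights * 10 - round(sf2$weights * 10)) < 1e-9))
})

test_that("numerator weight scaling is a pure slope degeneracy", {
  tab <- data.frame(A = c(1, 2, 3, 5), B = c(2, 1, 4, 2), C = c(1, 2, 1, 3),
                    dG_exp = c(0.5, 1.5, -1, 2))
  bf <- basic_feature(c("x", "x3"), c("A", "B"), "sub", "x", "C")
  for (lambda in c(0.5, 2)) {
    w1 <- c(0.6, 0.3, 0.5)
    w2 <- c(lambda * 0.6, lambda * 0.3, 0.5)
    v1 <- evaluate_feature(bf, tab, w1)$values
    v2 <- evaluate_feature(bf, tab, w2)$values
    f1 <- fit_linear(v1, tab$dG_exp)
    f2 <- fit_linear(v2, tab$dG_exp)
    expect_equal(v2, lambda * v1, tolerance = 1e-12)
    expect_equal(f2$m, f1$m / lambda, tolerance = 1e-10)
    expect_equal(f2$predictions, f1$predictions, tolerance = 1e-10)
    expect_equal(f2$r2, f1$r2, tolerance = 1e-12)
  }
  # a:b = 0.6:0.3 is recoverable at any grid tuple with a/b = 2
  ev <- evaluate_feature(bf, tab, c(0.6, 0.3, 1))
  tab$dG_exp <- 2 * ev$values + 1
  sf <- optimize_weights(bf, tab)
  expect_equal(sf$fit$r2, 1, tolerance = 1e-9)
  expect_equal(sf$weights[1] / sf$weights[2], 2, tolerance = 1e-9)
})

test_that("leave-one-out cross-validation matches the fold-by-fold oracle", {
  # exact linear relation: every fold predicts perfectly
  tab <- data.frame(A = c(1, 2, 3, 4), B = c(1, 1, 1, 1), C = c(1, 1, 1, 1))
  bf <- basic_feature(c("x", "x"), c("A", "B"), "mul", "x", "C")
  tab$dG_exp <- 2 * tab$A + 1
  sf <- scoring_function(bf, c(1, 1, 1), m = 2, q = 1)
  expect_equal(loocv(sf, tab)$loocv_rmse, 0, tolerance = 1e-12)

  # three-point hand case: feature (0,1,2), labels (0,1,1);
  # fold fits give held-out predictions (1, 0.5, 2), rmse = sqrt(0.75)
  tab2 <- data.frame(A = c(0, 1, 2), B = 1, C = 1, dG_exp = c(0, 1, 1))
  sf2 <- scoring_function(bf, c(1, 1, 1), m = 0.5, q = 1 / 6)
  cv <- loocv(sf2, tab2)
  expect_equal(cv$predictions, c(1, 0.5, 2), tolerance = 1e-12)
  expect_equal(cv$loocv_rmse, sqrt(0.75), tolerance = 1e-12)

  # oracle via lm() fold by fold on a noisy case
  set.seed(5)
  tab3 <- data.frame(A = runif(8, 1, 3), B = 1, C = 1)
  tab3$dG_exp <- 1.5 * tab3$A + rnorm(8, 0, 0.2)
  sf3 <- scoring_function(bf, c(1, 1, 1), m = 1, q = 0)
  got <- loocv(sf3, tab3)$loocv_rmse
  want <- sqrt(mean(vapply(1:8, function(i) {
    f <- lm(dG_exp ~ A, data = tab3[-i, ])
    (predict(f, tab3[i, ]) - tab3$dG_exp[i])^2
  }, 1)))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("the full search recovers a planted formula and is deterministic", {
  spec <- synthetic_spec(seed = 42, n_samples = 20, noise_sd = 0)
  tab <- make_feature_table(spec)
  bps <- basic_properties(c("logP", "HIE_E", "F2LE"))
  res <- run_search(tab, bps, top_n = 10)
  expect_gte(res$summary$r2[1], 0.99)
  res2 <- run_search(tab, bps, top_n = 10)
  expect_identical(res$summary, res2$summary)

  # search with a constant label: every fit has r2 = 0, order deterministic
  tabc <- tab
  tabc$dG_exp <- -10
  resc <- suppressWarnings(run_search(tabc, bps, top_n = 3, run_loocv = FALSE))
  expect_true(all(resc$summary$r2 == 0))
  resc2 <- suppressWarnings(run_search(tabc, bps, top_n = 3, run_loocv = FALSE))
  expect_identical(resc$summary, resc2$summary)
})

test_that("search on the hCA II descriptors honours the FMO exclusivity group", {
  # synthetic labels (the experimental ones are user-supplied); what is under
  # test is the constraint structure of the emitted formulas, not the fit
  d <- hca2_dataset()
  set.seed(9)
  d$dG_exp <- -12 + rnorm(9, 0, 0.5)
  res <- run_search(d, hca2_basic_properties(), top_n = 3, run_loocv = FALSE)
  fmo <- c("dE_FMO", "E_INT", "FE", "F2LE")
  for (r in res$results) {
    used <- unique(c(r$feature$num$bp, r$feature$den$bp))
    expect_lte(sum(used %in% fmo), 1)
  }
})

test_that("the generating formula's fit improves monotonically as noise shrinks", {
  r2_at <- function(sd) {
    spec <- synthetic_spec(seed = 4, n_samples = 20, noise_sd = sd)
    tab <- make_feature_table(spec)
    ev <- evaluate_feature(spec$formula, tab, spec$weights)
    fit_linear(ev$values, tab$dG_exp)$r2
  }
  r2 <- vapply(c(2.0, 1.0, 0.3, 0.1, 0), r2_at, 1)
  expect_true(all(diff(r2) > 0))
  expect_equal(r2[5], 1, tolerance = 1e-12)
})
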
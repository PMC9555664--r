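# small modelling frame with known structure, mirroring build_model_data output
make_model_frame <- function(n_years = 18, seed = 1, sp_effect = 2,
                             wnao_slope = -0.4, noise = 0.1) {
  set.seed(seed)
  yrs <- seq(2002, length.out = n_years)
  wnao <- rnorm(n_years)
  df <- expand.grid(year = yrs, species = c("shearwater", "gull"))
  df$species <- factor(df$species, levels = c("shearwater", "gull"))
  df$wnao <- wnao[match(df$year, yrs)]
  df$sync <- as.integer(df$year >= 2010 & df$year <= 2016)
  df$phase <- factor(ifelse(df$year < 2010, "before", "after"),
                     levels = c("before", "after"))
  df$year_c <- df$year - mean(df$year)
  df$response <- ifelse(df$species == "gull", sp_effect, 0) +
    wnao_slope * df$wnao + rnorm(nrow(df), 0, noise)
  df
}

test_that("AICc arithmetic follows the corrected formula", {
  expect_equal(aicc(0, 1, 100), 2 + 4 / 98)
  expect_equal(aicc(-10, 3, 20), 20 + 6 + 24 / 16)
  # correction vanishes as n grows: AICc -> AIC
  expect_equal(aicc(-50, 4, 1e7), -2 * -50 + 8, tolerance = 1e-4)
  expect_error(aicc(-10, 5, 6), class = "eggsync_undefined_correction")
})

test_that("significance is CI exclusion of zero, boundary counts as overlap", {
  expect_true(is_significant(0.16, 2.75))
  expect_false(is_significant(-0.1, 0.1))
  expect_false(is_significant(0, 0.5))
  expect_true(is_significant(-2, -0.3))
  expect_equal(is_significant(c(0.1, -1), c(0.2, 1)), c(TRUE, FALSE))
  expect_error(is_significant(1, 0), class = "eggsync_invalid_config")
})

test_that("a noiseless linear response is recovered exactly", {
  df <- make_model_frame(noise = 0, sp_effect = 0)
  # lm warns about the essentially perfect fit; that is the point here
  fit <- suppressWarnings(fit_volume_glm(df, "W_NAO"))
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "wnao"], -0.4, tolerance = 1e-10)
  expect_lt(cf$se[cf$term == "wnao"], 1e-10)
})

test_that("intercept-only maximum likelihood matches the closed form", {
  df <- data.frame(response = c(1, 2, 3))
  fit <- fit_volume_glm(df, character())
  expect_equal(fit$coefficients$estimate, 2)
  # ML residual variance RSS/n = 2/3 drives the log-likelihood
  n <- 3; sigma2 <- 2 / 3
  expect_equal(fit$loglik, -n / 2 * (log(2 * pi * sigma2) + 1))
  expect_equal(fit$k, 2)  # intercept + variance
})

test_that("parameter count includes intercept and residual variance", {
  df <- make_model_frame()
  fit <- fit_volume_glm(df, c("Sp", "Sync", "W_NAO", "Sp:Sync"))
  expect_equal(fit$k, 6)  # 4 slope terms + intercept + variance
  expect_equal(fit$n, 36)
  expect_equal(fit$aicc, aicc(fit$loglik, 6, 36), tolerance = 1e-6)
  expect_error(fit_volume_glm(df, c("Sp:Sync")),
               class = "eggsync_invalid_config")  # hierarchy violated
  expect_error(fit_volume_glm(df, "Elevation"),
               class = "eggsync_invalid_config")
})

test_that("fitted coefficients agree with normal-equation least squares", {
  df <- make_model_frame(seed = 4, noise = 0.5)
  fit <- fit_volume_glm(df, c("Sp", "Sync", "W_NAO", "Sp:Sync", "Sp:W_NAO"))
  X <- cbind(1, as.integer(df$species == "gull"), df$sync, df$wnao,
             as.integer(df$species == "gull") * df$sync,
             as.integer(df$species == "gull") * df$wnao)
  beta <- solve(t(X) %*% X, t(X) %*% df$response)
  expect_equal(unname(fit$coefficients$estimate), as.numeric(beta),
               tolerance = 1e-8)
})

test_that("collinear designs are reported as rank deficient", {
  df <- make_model_frame()
  df$sync <- 0L  # constant regressor
  expect_error(fit_volume_glm(df, c("Sync")), class = "eggsync_rank_deficient")
})

test_that("the default candidate set is the 18 hierarchical subsets", {
  specs <- candidate_specs()
  expect_length(specs, 18)
  labels <- names(specs)
  expect_true("1 (intercept only)" %in% labels)
  expect_true("Sp + Sync + W_NAO + Sp:Sync" %in% labels)
  # every interaction appears only with both mains
  for (s in specs) for (tm in s[grepl(":", s)])
    expect_true(all(strsplit(tm, ":")[[1]] %in% s))
  expect_length(candidate_specs(include_year = TRUE), 36)
})

test_that("model selection orders, weights and normalises", {
  df <- make_model_frame(seed = 2)
  single <- model_selection(df, candidate_specs()["Sp + Sync + W_NAO"])
  expect_equal(single$table$delta_aicc, 0)
  expect_equal(single$table$weight, 1)

  sel <- model_selection(df)
  expect_equal(sel$table$delta_aicc[1], 0)
  expect_false(is.unsorted(sel$table$aicc))
  expect_equal(sum(sel$table$weight), 1)
  # duplicated candidate: identical AICc, weights split evenly
  twin <- model_selection(df, list(a = "W_NAO", b = "W_NAO"))
  expect_equal(twin$table$weight, c(0.5, 0.5))
  expect_error(model_selection(df, list()), class = "eggsync_empty_input")
})

test_that("Akaike weights are invariant to a constant AICc shift", {
  df <- make_model_frame(seed = 3)
  sel <- model_selection(df)
  shifted <- exp(-(sel$table$aicc + 57.3 - min(sel$table$aicc + 57.3)) / 2)
  expect_equal(sel$table$weight, shifted / sum(shifted))
})

test_that("model averaging is full (zero-substitution) with renormalised weights", {
  df <- make_model_frame(seed = 5)
  sel <- model_selection(df, candidate_specs()["Sp + W_NAO"])
  avg <- model_average(sel)
  expect_equal(avg$estimate, sel$fits[[1]]$coefficients$estimate)
  expect_equal(avg$se, sel$fits[[1]]$coefficients$se)

  # hand-weighted check: equal-weight models, a term present in only one
  fake <- list(
    table = data.frame(model = c("m1", "m2"), delta_aicc = c(0, 0),
                       weight = c(0.5, 0.5)),
    fits = list(
      list(coefficients = data.frame(term = c("(Intercept)", "wnao"),
                                     estimate = c(1, 0.8), se = c(0.1, 0.2))),
      list(coefficients = data.frame(term = "(Intercept)",
                                     estimate = 1, se = 0.1))))
  avg2 <- model_average(fake)
  expect_equal(avg2$estimate[avg2$term == "wnao"], 0.4)
  # unconditional SE: 0.5*sqrt(0.2^2 + 0.4^2) + 0.5*sqrt(0 + 0.4^2)
  expect_equal(avg2$se[avg2$term == "wnao"],
               0.5 * sqrt(0.04 + 0.16) + 0.5 * 0.4)
})

test_that("nested truth wins the AICc race most of the time", {
  wins <- vapply(1:60, function(s) {
    df <- make_model_frame(seed = 100 + s, sp_effect = 0, wnao_slope = -0.4,
                           noise = 0.4)
    small <- fit_volume_glm(df, "W_NAO")
    big <- fit_volume_glm(df, c("Sp", "Sync", "W_NAO", "Sp:Sync", "Sp:W_NAO",
                                "Sync:W_NAO"))
    small$aicc <= big$aicc
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})

test_that("synchrony coding flags exactly the perfect-agreement years", {
  set.seed(12)
  x <- rnorm(12)
  res <- run_synchrony(x, x, n_sims = 100, seed = 1)
  code <- code_synchrony(res)
  expect_equal(code$sync, rep(1L, 10))
  # edge years outside the interior axis are coded 0 with a note
  expect_message(full <- code_synchrony(res, years = 1:12), "outside")
  expect_equal(full$sync, c(0L, rep(1L, 10), 0L))

  res$phi_t <- c(rep(1, 7), rep(0.2, 3))  # 7 perfectly synchronous years
  expect_equal(sum(code_synchrony(res)$sync), 7)

  a <- rep(c(1, 5), 6)
  anti <- run_synchrony(a, -a, n_sims = 100, seed = 2)
  expect_equal(code_synchrony(anti)$sync, rep(0L, 10))
})

test_that("phase slopes recover buffered-then-coupled structure", {
  df <- make_model_frame(seed = 6, noise = 0.05)
  # decouple the gull before closure: replace its pre-phase response
  pre_gull <- df$species == "gull" & df$phase == "before"
  set.seed(61)
  df$response[pre_gull] <- 2 + rnorm(sum(pre_gull), 0, 0.05)
  ps <- phase_slopes(df)
  sl <- ps$slopes
  g_pre <- sl[sl$species == "gull" & sl$phase == "before", ]
  g_post <- sl[sl$species == "gull" & sl$phase == "after", ]
  expect_true(g_pre$ci_lo <= 0 && g_pre$ci_hi >= 0)
  expect_true(g_post$ci_lo <= -0.4 && g_post$ci_hi >= -0.4)
  expect_equal(nrow(ps$gull_phase_contrast), 1)
  expect_true(is.finite(ps$buffering_pct[["before"]]))

  # identical slopes in both phases: the phase contrast covers 0
  df2 <- make_model_frame(seed = 7, noise = 0.3)
  ps2 <- phase_slopes(df2)
  expect_true(ps2$gull_phase_contrast$ci_lo <= 0 &&
                ps2$gull_phase_contrast$ci_hi >= 0)

  expect_error(phase_slopes(df[df$phase == "after", ]),
               class = "eggsync_insufficient_data")
})

test_that("model and coefficient tables serialise with their schemas", {
  tmp <- withr::local_tempdir()
  df <- make_model_frame(seed = 8)
  sel <- model_selection(df)
  p1 <- file.path(tmp, "models.csv")
  write_model_table_csv(sel, p1)
  expect_named(read.csv(p1),
               c("model", "k", "loglik", "aicc", "delta_aicc", "weight"))
  avg <- model_average(sel)
  p2 <- file.path(tmp, "avg.csv")
  write_averaged_csv(avg, p2)
  expect_named(read.csv(p2),
               c("term", "estimate", "ci_lo", "ci_hi", "significant"))
})
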
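#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1)`, where `k` counts every
#' estimated parameter including the intercept and the residual variance.
#'
#' @param loglik Maximised Gaussian log-likelihood.
#' @param k Number of estimated parameters (slopes + intercept + variance).
#' @param n Number of observations; must exceed `k + 1`.
#' @return The AICc value.
#' @export
#' @examples
#' aicc(-58.14, k = 6, n = 36)
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1))
    stop_eggsync("AICc correction undefined: need n > k + 1",
                 "eggsync_undefined_correction")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' CI-based significance
#'
#' An effect is significant when its confidence interval excludes zero; a
#' boundary at zero counts as overlapping.
#'
#' @param ci_lo,ci_hi Interval bounds, `ci_lo <= ci_hi` (vectorised).
#' @return Logical: `TRUE` iff 0 is outside `[ci_lo, ci_hi]`.
#' @export
is_significant <- function(ci_lo, ci_hi) {
  if (any(ci_lo > ci_hi))
    stop_eggsync("invalid interval: ci_lo > ci_hi", "eggsync_invalid_config")
  ci_lo > 0 | ci_hi < 0
}

#' Binary synchrony indicator per year
#'
#' Codes 1 for years with perfect synchrony (`Phi_t = 1`, i.e. both series
#' in the same state, within 1e-12) and 0 otherwise.  Years outside the
#' interior time axis of the synchrony analysis (the first and last year of
#' the series) get 0, with a message.
#'
#' @param sync_result A [run_synchrony()] result.
#' @param years Years to code; defaults to the result's own time axis.
#' @return Data frame with columns `year` and `sync` (0/1).
#' @export
code_synchrony <- function(sync_result, years = NULL) {
  if (is.null(years)) years <- sync_result$times
  sync <- integer(length(years))
  inside <- years %in% sync_result$times
  if (any(!inside))
    message(sprintf("year(s) %s are outside the synchrony time axis; coded 0",
                    paste(years[!inside], collapse = ", ")))
  idx <- match(years[inside], sync_result$times)
  sync[inside] <- as.integer(abs(sync_result$phi_t[idx] - 1) < 1e-12)
  data.frame(year = as.integer(years), sync = sync)
}

#' Assemble the egg-volume modelling data set
#'
#' One row per species x year with the response (annual mean egg volume,
#' globally z-scored by default so coefficients are comparable across
#' species), the binary synchrony indicator, the winter NAO value and the
#' before/after-closure phase.
#'
#' @param series An [annual_series()] data frame covering both species.
#' @param sync Data frame `year,sync` from [code_synchrony()].
#' @param env Data frame `year,wnao` with the winter NAO index.
#' @param closure_year Year of the regime change; that year belongs to the
#'   "after" phase.
#' @param standardize Z-score the response over all rows (default `TRUE`).
#' @return Data frame with columns `species` (factor, reference
#'   shearwater), `year`, `year_c` (centred), `response`, `sync`, `wnao`,
#'   `phase` (factor before/after).
#' @export
build_model_data <- function(series, sync, env, closure_year,
                             standardize = TRUE) {
  need <- c("species", "year", "mean_volume_cm3")
  if (!all(need %in% names(series)))
    stop_eggsync("series must have columns species, year, mean_volume_cm3",
                 "eggsync_schema_error")
  if (!all(c("year", "wnao") %in% names(env)))
    stop_eggsync("env must have columns year, wnao", "eggsync_schema_error")
  df <- merge(series[, need], env[, c("year", "wnao")], by = "year")
  df <- merge(df, sync, by = "year")
  if (anyNA(df$wnao))
    stop_eggsync("winter NAO values missing for some years", "eggsync_missing_values")
  df$species <- factor(df$species, levels = c("shearwater", "gull"))
  df$phase <- factor(ifelse(df$year < closure_year, "before", "after"),
                     levels = c("before", "after"))
  df$year_c <- df$year - mean(df$year)
  df$response <- if (standardize) {
    as.numeric(scale(df$mean_volume_cm3))
  } else {
    df$mean_volume_cm3
  }
  df[order(df$species, df$year),
     c("species", "year", "year_c", "response", "sync", "wnao", "phase")]
}

# term labels in the compact "+/:" notation -> model-frame variables
term_to_var <- c(Sp = "species", Sync = "sync", W_NAO = "wnao",
                 Year = "year_c", Closure = "phase",
                 "Sp:Sync" = "species:sync", "Sp:W_NAO" = "species:wnao",
                 "Sync:W_NAO" = "sync:wnao")

#' Candidate model specifications
#'
#' All hierarchical subsets of the main effects `{Sp, Sync, W_NAO}` together
#' with the two-way interactions `{Sp:Sync, Sp:W_NAO, Sync:W_NAO}` (an
#' interaction is only allowed when both its main effects are present),
#' including the intercept-only model: 18 candidates.  `Year` and `Closure`
#' main effects can optionally be added to the candidate pool (each model
#' then also appears with those mains appended).
#'
#' @param include_year,include_closure Add variants with a centred-year /
#'   before-after-closure main effect (default `FALSE`).
#' @return List of character vectors of term labels; names are the model
#'   labels in "+/:" notation.
#' @export
candidate_specs <- function(include_year = FALSE, include_closure = FALSE) {
  mains <- c("Sp", "Sync", "W_NAO")
  inters <- list("Sp:Sync" = c("Sp", "Sync"),
                 "Sp:W_NAO" = c("Sp", "W_NAO"),
                 "Sync:W_NAO" = c("Sync", "W_NAO"))
  specs <- list()
  for (i in 0:7) {
    m <- mains[bitwAnd(i, c(1L, 2L, 4L)) > 0]
    ok_inter <- names(inters)[vapply(inters, function(p) all(p %in% m), logical(1))]
    n_int <- length(ok_inter)
    for (j in seq_len(max(1, 2^n_int)) - 1) {
      ints <- if (n_int) ok_inter[bitwAnd(j, 2^(seq_len(n_int) - 1)) > 0] else character()
      specs[[length(specs) + 1]] <- c(m, ints)
    }
  }
  extras <- list(character())
  if (include_year) extras <- c(extras, lapply(extras, c, "Year"))
  if (include_closure) extras <- c(extras, lapply(extras, c, "Closure"))
  extras <- unique(extras)
  out <- list()
  for (e in extras) for (s in specs) out[[length(out) + 1]] <- c(s, e)
  out <- unique(out)
  names(out) <- vapply(out, model_label, character(1))
  out
}

model_label <- function(terms) {
  if (!length(terms)) "1 (intercept only)" else paste(terms, collapse = " + ")
}

#' Fit one Gaussian egg-volume model
#'
#' Identity-link Gaussian fit by maximum likelihood (ordinary least squares;
#' the residual variance entering the log-likelihood is RSS/n, so the
#' log-likelihood is the ML value the AICc arithmetic expects).  Wald 95%
#' confidence intervals (estimate +/- 1.96 SE) accompany each coefficient.
#'
#' @param data Modelling data from [build_model_data()].
#' @param terms Character vector of term labels (see [candidate_specs()]);
#'   empty for the intercept-only model.
#' @return A `volume_fit` list: `label`, `terms`, `fit` (the `lm` object),
#'   `coefficients` (data frame `term,estimate,se,ci_lo,ci_hi`), `loglik`,
#'   `k` (slopes + intercept + residual variance), `n`, `aicc`.
#' @export
fit_volume_glm <- function(data, terms = character()) {
  unknown <- setdiff(terms, names(term_to_var))
  if (length(unknown))
    stop_eggsync(sprintf("unknown model term(s): %s",
                         paste(unknown, collapse = ", ")),
                 "eggsync_invalid_config")
  for (tm in terms[grepl(":", terms)]) {
    mains <- strsplit(tm, ":")[[1]]
    if (!all(mains %in% terms))
      stop_eggsync(sprintf("interaction %s requires main effects %s",
                           tm, paste(mains, collapse = ", ")),
                   "eggsync_invalid_config")
  }
  rhs <- if (length(terms)) paste(term_to_var[terms], collapse = " + ") else "1"
  fit <- lm(as.formula(paste("response ~", rhs)), data = data)
  cf <- coef(fit)
  if (anyNA(cf))
    stop_eggsync(sprintf("rank-deficient design: collinear term(s) %s",
                         paste(names(cf)[is.na(cf)], collapse = ", ")),
                 "eggsync_rank_deficient")
  n <- nrow(data)
  k <- length(cf) + 1L  # + residual variance
  if (n <= length(cf))
    stop_eggsync("too few observations for this model",
                 "eggsync_insufficient_data")
  se <- sqrt(diag(vcov(fit)))
  coefs <- data.frame(term = names(cf), estimate = unname(cf),
                      se = unname(se),
                      ci_lo = unname(cf - 1.96 * se),
                      ci_hi = unname(cf + 1.96 * se))
  ll <- as.numeric(logLik(fit))  # Gaussian ML: sigma^2 = RSS/n
  out <- list(label = model_label(terms), terms = terms, fit = fit,
              coefficients = coefs, loglik = ll, k = k, n = n,
              aicc = if (n > k + 1) aicc(ll, k, n) else NA_real_)
  class(out) <- "volume_fit"
  out
}

#' @export
print.volume_fit <- function(x, ...) {
  cat(sprintf("Gaussian egg-volume model: %s\n", x$label))
  cat(sprintf("  logLik = %.2f, k = %d, n = %d, AICc = %.2f\n",
              x$loglik, x$k, x$n, x$aicc))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' AICc model selection over a candidate set
#'
#' Fits every candidate, sorts by AICc, and attaches AICc differences to the
#' best model and Akaike weights `w = exp(-delta/2) / sum exp(-delta/2)`.
#'
#' @param data Modelling data from [build_model_data()].
#' @param specs List of term vectors (default [candidate_specs()]).
#' @return A `model_table` list with `table` (data frame
#'   `model,k,loglik,aicc,delta_aicc,weight`, sorted ascending by AICc) and
#'   `fits` (the `volume_fit` objects in the same order).
#' @export
model_selection <- function(data, specs = candidate_specs()) {
  if (!length(specs))
    stop_eggsync("no candidate models", "eggsync_empty_input")
  fits <- lapply(specs, function(s) {
    tryCatch(fit_volume_glm(data, s), error = function(e) {
      stop_eggsync(sprintf("model '%s' failed: %s", model_label(s),
                           conditionMessage(e)),
                   "eggsync_fit_error")
    })
  })
  tab <- data.frame(model = vapply(fits, `[[`, character(1), "label"),
                    k = vapply(fits, `[[`, integer(1), "k"),
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    aicc = vapply(fits, `[[`, numeric(1), "aicc"))
  ord <- order(tab$aicc)
  tab <- tab[ord, ]
  fits <- fits[ord]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  w <- exp(-tab$delta_aicc / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  out <- list(table = tab, fits = fits)
  class(out) <- "model_table"
  out
}

#' @export
print.model_table <- function(x, ...) {
  cat("AICc model selection\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Multimodel averaging over the near-best set
#'
#' Full (zero-substitution) model averaging over the models within
#' `threshold` AICc points of the best: weights are renormalised within the
#' retained set, a coefficient absent from a model contributes 0 with
#' variance 0, and the unconditional standard error combines within-model
#' variance with between-model spread,
#' `SE = sum_i w_i sqrt(se_i^2 + (b_i - b_bar)^2)`.
#'
#' @param table A [model_selection()] result.
#' @param threshold AICc difference defining the averaging set (default 4).
#' @return Data frame `term,estimate,se,ci_lo,ci_hi,significant` with Wald
#'   95% intervals; attribute `n_models` gives the size of the retained
#'   set.
#' @export
model_average <- function(table, threshold = 4) {
  keep <- which(table$table$delta_aicc <= threshold)
  fits <- table$fits[keep]
  w <- table$table$weight[keep]
  w <- w / sum(w)
  terms <- unique(unlist(lapply(fits, function(f) f$coefficients$term)))
  rows <- lapply(terms, function(tm) {
    est <- se <- numeric(length(fits))
    for (i in seq_along(fits)) {
      cf <- fits[[i]]$coefficients
      j <- match(tm, cf$term)
      if (!is.na(j)) {
        est[i] <- cf$estimate[j]
        se[i] <- cf$se[j]
      }  # absent from model i: contributes 0 (full averaging)
    }
    b <- sum(w * est)
    se_u <- sum(w * sqrt(se^2 + (est - b)^2))
    data.frame(term = tm, estimate = b, se = se_u,
               ci_lo = b - 1.96 * se_u, ci_hi = b + 1.96 * se_u)
  })
  out <- do.call(rbind, rows)
  out$significant <- is_significant(out$ci_lo, out$ci_hi)
  attr(out, "n_models") <- length(fits)
  out
}

#' Per-species, per-phase environmental slopes
#'
#' Fits the full species x winter-NAO x phase interaction model and reports
#' each species' NAO slope in each phase (with 95% CI and p-value), the
#' before/after slope contrast for the gull, and a descriptive
#' buffering percentage, `100 * (1 - slope_gull / slope_shearwater)` per
#' phase: the share of the shearwater's environmental response that the
#' gull does not express.  The percentage is an interpretive summary (its
#' denominator is a fitted quantity), so read it alongside the slope
#' contrasts rather than as a test statistic.
#'
#' @param data Modelling data from [build_model_data()]; both phases must be
#'   represented for both species with at least 3 years each.
#' @return List with `slopes` (data frame `species,phase,slope,se,ci_lo,
#'   ci_hi,p`), `gull_phase_contrast` (one-row data frame), and
#'   `buffering_pct` (named numeric, one value per phase).
#' @export
phase_slopes <- function(data) {
  counts <- table(data$species, data$phase)
  if (any(counts < 3))
    stop_eggsync("each species needs >= 3 years in each phase",
                 "eggsync_insufficient_data")
  fit <- lm(response ~ species * wnao * phase, data = data)
  emt <- emmeans::emtrends(fit, ~ species * phase, var = "wnao")
  sl <- as.data.frame(summary(emt, infer = c(TRUE, TRUE)))
  slopes <- data.frame(species = sl$species, phase = sl$phase,
                       slope = sl$wnao.trend, se = sl$SE,
                       ci_lo = sl$lower.CL, ci_hi = sl$upper.CL,
                       p = sl$p.value)
  ph <- as.data.frame(summary(emmeans::contrast(emt, "revpairwise",
                                                by = "species"),
                              infer = c(TRUE, TRUE)))
  g <- ph[ph$species == "gull", ]
  gull_contrast <- data.frame(contrast = g$contrast, estimate = g$estimate,
                              se = g$SE, ci_lo = g$lower.CL, ci_hi = g$upper.CL,
                              p = g$p.value)
  buf <- vapply(levels(data$phase), function(p) {
    s <- slopes[slopes$phase == p, ]
    sg <- s$slope[s$species == "gull"]
    ss <- s$slope[s$species == "shearwater"]
    if (abs(ss) < .Machine$double.eps^0.5) NA_real_ else 100 * (1 - sg / ss)
  }, numeric(1))
  list(slopes = slopes, gull_phase_contrast = gull_contrast,
       buffering_pct = buf)
}

#' Write model-selection outputs
#'
#' `write_model_table_csv` writes `model,k,loglik,aicc,delta_aicc,weight`;
#' `write_averaged_csv` writes `term,estimate,ci_lo,ci_hi,significant`.
#'
#' @param table A [model_selection()] result.
#' @param averaged A [model_average()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_table_csv <- function(table, path) {
  write.csv(table$table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_model_table_csv
#' @export
write_averaged_csv <- function(averaged, path) {
  write.csv(averaged[, c("term", "estimate", "ci_lo", "ci_hi", "significant")],
            path, row.names = FALSE)
  invisible(path)
}
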
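# Directed dyad table assembly and crossed-random-effects grooming models.

#' Assemble the directed dyad model table
#'
#' One row per ordered pair (groomer, groomee) per season -- `N*(N-1)` rows
#' per season, e.g. 272 for 17 females -- carrying the response measures and
#' all model predictors: kinship (kin/non-kin from shared matriline),
#' relative rank of the groomer (dominant/subordinate), cardinal rank
#' distance `|NDS_groomer - NDS_groomee|`, friendship `F(groomer, groomee)`,
#' grooming received (the reverse-direction raw measure), co-provisioning
#' percentage, aggression received (rate of aggression from the groomee to
#' the groomer) and absolute age difference.
#'
#' @param measures directed grooming measures from [grooming_measures()].
#' @param aggression directed aggression rates from [aggression_rates()].
#' @param friendship named list by season of friendship matrices.
#' @param coprov named list by season of co-provisioning percentage
#'   matrices (symmetric).
#' @param nds named list by season of `davids_scores` data.frames (or one
#'   data.frame reused for all seasons).
#' @param roster roster data.frame (ages and matrilines).
#' @return data.frame of class `dyad_table`, ordered by (season, groomer,
#'   groomee).
#' @export
assemble_dyad_table <- function(measures, aggression, friendship, coprov,
                                nds, roster) {
  roster <- validate_roster(roster)
  ids <- sort(roster$individual_id)
  seasons <- sort(unique(measures$season))
  age <- stats::setNames(roster$age, roster$individual_id)
  mat <- stats::setNames(roster$matriline_id, roster$individual_id)

  if (is.data.frame(nds)) nds <- stats::setNames(
    rep(list(nds), length(seasons)), seasons)

  out <- list()
  for (s in seasons) {
    sc <- nds[[s]]
    if (is.null(sc))
      stop_with("dyadgroom_assembly_error", "no David's scores for season %s", s)
    missing_ids <- setdiff(ids, sc$individual_id)
    if (length(missing_ids))
      stop_with("dyadgroom_assembly_error",
                "season %s: no NDS for individual(s) %s", s,
                paste(missing_ids, collapse = ", "))
    f <- friendship[[s]]
    if (is.null(f) || !all(ids %in% rownames(f)))
      stop_with("dyadgroom_assembly_error",
                "season %s: friendship matrix missing or incomplete (ids: %s)",
                s, paste(setdiff(ids, rownames(f)), collapse = ", "))
    cp <- coprov[[s]]
    nds_v <- stats::setNames(sc$nds, sc$individual_id)
    pos <- rank_order(sc)
    pos_v <- stats::setNames(pos$position, pos$individual_id)

    m <- measures[measures$season == s, ]
    key_m <- paste(m$groomer_id, m$groomee_id)
    a <- aggression[aggression$season == s, ]
    key_a <- paste(a$actor_id, a$recipient_id)

    p <- ordered_pairs(ids)
    names(p) <- c("groomer_id", "groomee_id")
    fwd <- match(paste(p$groomer_id, p$groomee_id), key_m)
    rev <- match(paste(p$groomee_id, p$groomer_id), key_m)
    agg_rev <- match(paste(p$groomee_id, p$groomer_id), key_a)
    if (anyNA(fwd) || anyNA(rev))
      stop_with("dyadgroom_assembly_error",
                "season %s: grooming measures incomplete", s)
    row <- data.frame(
      season = s,
      p,
      grooming_rate = m$grooming_rate[fwd],
      grooming_time = m$grooming_time[fwd],
      kinship = factor(ifelse(mat[p$groomer_id] == mat[p$groomee_id],
                              "kin", "non-kin"),
                       levels = c("kin", "non-kin")),
      relative_rank = factor(ifelse(pos_v[p$groomer_id] < pos_v[p$groomee_id],
                                    "dominant", "subordinate"),
                             levels = c("dominant", "subordinate")),
      rank_distance = abs(nds_v[p$groomer_id] - nds_v[p$groomee_id]),
      friendship = f[cbind(p$groomer_id, p$groomee_id)],
      groom_rate_received = m$grooming_rate[rev],
      groom_time_received = m$grooming_time[rev],
      co_provisioning_pct = if (is.null(cp)) 0
        else cp[cbind(p$groomer_id, p$groomee_id)],
      aggression_received = if (nrow(a)) a$aggression_rate[agg_rev] else 0,
      age_difference = abs(age[p$groomer_id] - age[p$groomee_id]),
      stringsAsFactors = FALSE
    )
    out[[s]] <- row
  }
  out <- do.call(rbind, out)
  out$season <- factor(out$season, levels = seasons)
  out <- out[order(out$season, out$groomer_id, out$groomee_id), ]
  rownames(out) <- NULL
  class(out) <- c("dyad_table", "data.frame")
  out
}

#' Log transform with zero-handling offset
#'
#' `log(x + offset)`. The default offset is half the smallest positive
#' observed value of `x`, the conventional choice for rate/time measures
#' containing structural zeros; the offset actually used is recorded as an
#' attribute and in model metadata.
#'
#' @param x non-negative numeric vector.
#' @param offset positive offset, or NULL for the default rule.
#' @return numeric vector with attribute `offset`.
#' @export
log_offset_transform <- function(x, offset = NULL) {
  if (any(x < 0)) domain_error("log transform requires non-negative values")
  if (is.null(offset)) {
    pos <- x[x > 0]
    if (length(pos) == 0)
      config_error("cannot choose a log offset: no positive values")
    offset <- min(pos) / 2
  }
  if (offset <= 0 && any(x == 0))
    config_error("log offset must be > 0 when zeros are present")
  structure(log(x + offset), offset = offset)
}

#' Fit the crossed-random-effects grooming model
#'
#' Gaussian linear mixed model (fitted with `lme4::lmer`, REML) of the
#' log-transformed directed grooming rate or time on nine fixed effects --
#' age difference, kinship (reference kin), rank distance, relative rank
#' (reference dominant), friendship, grooming received (raw
#' reverse-direction measure), co-provisioning percentage, aggression
#' received and season (reference first season) -- with crossed random
#' intercepts for groomer and groomee identity. Confidence intervals are
#' Wald: `b +/- 1.96 SE`. Model significance is assessed by a likelihood
#' ratio test (ML refits) against the intercept-plus-random-effects null.
#'
#' @param table a `dyad_table`.
#' @param response `"rate"` or `"time"`.
#' @param offset log-transform offset (NULL for the default rule).
#' @param fixed_effects character vector of predictor columns; the default
#'   is the full nine-predictor set.
#' @return object of class `groom_lmm`: list with `fixed` (term, estimate,
#'   se, ci_low, ci_high, significant), `ranef_var`, `null_lrt`, `offset`,
#'   `model` (the fitted `lmerMod`), `response`, `n`.
#' @export
fit_grooming_lmm <- function(table, response = c("rate", "time"),
                             offset = NULL,
                             fixed_effects = c(
                               "age_difference", "kinship", "rank_distance",
                               "relative_rank", "friendship",
                               "groom_received", "co_provisioning_pct",
                               "aggression_received", "season")) {
  response <- match.arg(response)
  raw <- if (response == "rate") table$grooming_rate else table$grooming_time
  received <- if (response == "rate") table$groom_rate_received
              else table$groom_time_received
  y <- log_offset_transform(raw, offset)
  dat <- as.data.frame(table)
  dat$.y <- as.numeric(y)
  dat$groom_received <- received

  # a factor that is constant in this (sub)table -- e.g. season in a
  # single-season fit -- cannot enter the design
  for (fe in fixed_effects)
    if (is.factor(dat[[fe]])) dat[[fe]] <- droplevels(dat[[fe]])
  constant <- vapply(fixed_effects, function(fe)
    is.factor(dat[[fe]]) && nlevels(dat[[fe]]) < 2, logical(1))
  if (any(constant)) {
    message("dropping constant predictor(s): ",
            paste(fixed_effects[constant], collapse = ", "))
    fixed_effects <- fixed_effects[!constant]
  }

  rhs <- paste(c(fixed_effects, "(1 | groomer_id)", "(1 | groomee_id)"),
               collapse = " + ")
  form <- stats::as.formula(paste(".y ~", rhs))
  fit <- lme4::lmer(form, data = dat, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))

  fe <- lme4::fixef(fit)
  X_terms <- colnames(stats::model.matrix(fit))
  aliased <- setdiff(X_terms, names(fe))
  if (length(aliased))
    domain_error("rank-deficient design; aliased terms: %s",
                 paste(aliased, collapse = ", "))
  if (lme4::isSingular(fit))
    warning("singular fit: a random-effect variance was estimated at its floor (0)",
            call. = FALSE)

  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  fixed <- data.frame(term = names(fe), estimate = unname(fe),
                      se = unname(se),
                      ci_low = unname(fe - 1.96 * se),
                      ci_high = unname(fe + 1.96 * se),
                      stringsAsFactors = FALSE)
  fixed$significant <- fixed$ci_low > 0 | fixed$ci_high < 0
  fixed$significant[fixed$term == "(Intercept)"] <- NA

  vc <- as.data.frame(lme4::VarCorr(fit))
  ranef_var <- stats::setNames(vc$vcov, vc$grp)

  ml_full <- stats::update(fit, REML = FALSE)
  ml_null <- lme4::lmer(.y ~ 1 + (1 | groomer_id) + (1 | groomee_id),
                        data = dat, REML = FALSE,
                        control = lme4::lmerControl(check.conv.singular = "ignore"))
  chisq <- as.numeric(2 * (stats::logLik(ml_full) - stats::logLik(ml_null)))
  df <- attr(stats::logLik(ml_full), "df") - attr(stats::logLik(ml_null), "df")
  p <- stats::pchisq(chisq, df, lower.tail = FALSE)

  structure(list(
    response = paste0("grooming_", response),
    offset = attr(y, "offset"),
    fixed = fixed,
    ranef_var = ranef_var,
    logLik = as.numeric(stats::logLik(fit)),
    null_lrt = list(chisq = chisq, df = df, p = p),
    model = fit,
    n = nrow(dat)
  ), class = "groom_lmm")
}

#' @export
print.groom_lmm <- function(x, digits = 3, ...) {
  cat(sprintf("Crossed-random-effects LMM of log(%s + %.4g), n = %d rows\n",
              x$response, x$offset, x$n))
  f <- x$fixed
  f$estimate <- round(f$estimate, digits)
  f$se <- round(f$se, digits)
  f$ci_low <- round(f$ci_low, digits)
  f$ci_high <- round(f$ci_high, digits)
  print(f, row.names = FALSE)
  cat(sprintf("Random intercept variances: %s\n",
              paste(sprintf("%s = %.4g", names(x$ranef_var), x$ranef_var),
                    collapse = ", ")))
  cat(sprintf("Null-model LRT: chisq = %.2f, df = %d, p = %.3g\n",
              x$null_lrt$chisq, x$null_lrt$df, x$null_lrt$p))
  invisible(x)
}

#' Exp-scale interpretation of a log-response coefficient
#'
#' Because the response is log-transformed, a coefficient `b` means the
#' expected response is multiplied by `exp(b * delta)` when the predictor
#' increases by `delta` units (for two-level categorical predictors, the
#' non-reference level's mean is `exp(b)` times the reference mean). The
#' percent change `(exp(b * delta) - 1) * 100` is reported rounded to the
#' nearest integer, with negative values phrased as "lower".
#'
#' @param b coefficient (or CI endpoint); vectorized.
#' @param delta predictor increment, default 1.
#' @return data.frame with `b`, `delta`, `percent` (exact), `percent_rounded`
#'   and `label` (e.g. `"71% lower"`).
#' @export
effect_interpretation <- function(b, delta = 1) {
  if (any(!is.finite(b))) domain_error("coefficient must be finite")
  if (any(delta <= 0)) domain_error("delta must be > 0")
  percent <- (exp(b * delta) - 1) * 100
  rounded <- round(percent)
  data.frame(
    b = b, delta = delta, percent = percent, percent_rounded = rounded,
    label = sprintf("%d%% %s", abs(rounded),
                    ifelse(rounded < 0, "lower", "higher")),
    stringsAsFactors = FALSE
  )
}

#' Split the dyad table at the mean rank distance
#'
#' The threshold is the mean rank distance over the full pooled table; rows
#' strictly above it form the high-distance subset, rows at or below it the
#' low-distance subset. The two subsets partition the table.
#'
#' @param table a `dyad_table`.
#' @return list with `low`, `high` (dyad tables) and `threshold`.
#' @export
split_by_rank_distance <- function(table) {
  threshold <- mean(table$rank_distance)
  high <- table[table$rank_distance > threshold, , drop = FALSE]
  low <- table[table$rank_distance <= threshold, , drop = FALSE]
  if (nrow(high) == 0)
    domain_error("rank-distance split: high subset is empty (all distances <= mean)")
  if (nrow(low) == 0)
    domain_error("rank-distance split: low subset is empty")
  list(low = low, high = high, threshold = threshold)
}

#' Tabulate model fits with exp-scale interpretations
#'
#' Produces a results table in the conventional layout (estimate, SE, 95%
#' CI per predictor), flagging terms whose CI excludes zero, and attaching
#' exp-scale percent-change interpretations (computed from the estimate and
#' both CI endpoints) for each significant term.
#'
#' @param fits a named list of `groom_lmm` fits (or a single fit).
#' @param deltas optional named numeric vector of predictor increments used
#'   for interpretation (default 1 for every term); e.g.
#'   `c(groom_received = 0.1, aggression_received = 0.1)`.
#' @return data.frame of class `groom_report` with one row per model term.
#' @export
groom_report <- function(fits, deltas = NULL) {
  if (inherits(fits, "groom_lmm")) fits <- list(model = fits)
  out <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    f <- fit$fixed
    f <- f[f$term != "(Intercept)", , drop = FALSE]
    if (nrow(f) == 0) {
      out[[nm]] <- data.frame(model = character(), term = character(),
                              estimate = numeric(), se = numeric(),
                              ci_low = numeric(), ci_high = numeric(),
                              significant = logical(),
                              delta = numeric(), pct_change = character())
      next
    }
    delta <- rep(1, nrow(f))
    if (!is.null(deltas)) {
      hit <- match(f$term, names(deltas))
      # match on prefix too, so "groom_received" covers the raw column name
      for (i in seq_along(f$term))
        for (d in names(deltas))
          if (startsWith(f$term[i], d)) hit[i] <- match(d, names(deltas))
      delta[!is.na(hit)] <- deltas[hit[!is.na(hit)]]
    }
    pct <- vapply(seq_len(nrow(f)), function(i) {
      if (!isTRUE(f$significant[i])) return(NA_character_)
      lo <- effect_interpretation(f$ci_low[i], delta[i])
      hi <- effect_interpretation(f$ci_high[i], delta[i])
      sprintf("%d%% to %d%% %s (per %g)",
              min(abs(lo$percent_rounded), abs(hi$percent_rounded)),
              max(abs(lo$percent_rounded), abs(hi$percent_rounded)),
              if (f$estimate[i] < 0) "lower" else "higher", delta[i])
    }, character(1))
    out[[nm]] <- data.frame(model = nm, f, delta = delta, pct_change = pct,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("groom_report", "data.frame")
  res
}

#' Run the full analysis chain on a (simulated or read) study
#'
#' Convenience pipeline: displacement matrices and David's scores per
#' season, grooming/aggression measures, scan-time matrices, contact-based
#' friendship, dyad-table assembly and (optionally) the two LMM fits.
#'
#' @param events,scans,sessions,roster observation data.
#' @param scan_interval minutes between scans.
#' @param fit if TRUE, fit the rate and time models.
#' @param n_randomizations randomizations for the hierarchy tests (0 to
#'   skip the steepness/linearity tests and keep only scores).
#' @param seed seed for the randomization tests.
#' @return list with `obs_hours`, `dominance` (per season), `measures`,
#'   `aggression`, `scan_mats`, `friendship`, `table` and (if `fit`)
#'   `fit_rate`, `fit_time`.
#' @export
groom_pipeline <- function(events, scans, sessions, roster,
                           scan_interval = 2, fit = TRUE,
                           n_randomizations = 1000, seed = 1) {
  roster <- validate_roster(roster)
  ids <- sort(roster$individual_id)
  obs_hours <- observation_time(sessions, roster)
  seasons <- sort(unique(sessions$season))

  dominance <- list()
  nds <- list()
  for (s in seasons) {
    m <- displacement_matrix(events, season = s, ids = ids)
    if (n_randomizations > 0) {
      dominance[[s]] <- dominance_summary(m, n_randomizations, seed)
      nds[[s]] <- dominance[[s]]$scores
    } else {
      nds[[s]] <- davids_scores(m)
    }
  }

  bouts <- merge_grooming_bouts(events)
  measures <- grooming_measures(bouts, obs_hours, ids)
  aggression <- aggression_rates(events, obs_hours, ids)
  scan_mats <- scan_time_matrices(scans, sessions, scan_interval, ids)
  friendship <- lapply(scan_mats, function(x)
    friendship_index(x$contact_min, "contact"))
  coprov <- lapply(scan_mats, function(x) x$co_provisioning_pct)

  table <- assemble_dyad_table(measures, aggression, friendship, coprov,
                               nds, roster)
  out <- list(obs_hours = obs_hours, dominance = dominance, bouts = bouts,
              measures = measures, aggression = aggression,
              scan_mats = scan_mats, friendship = friendship,
              table = table)
  if (fit) {
    out$fit_rate <- fit_grooming_lmm(table, "rate")
    out$fit_time <- fit_grooming_lmm(table, "time")
  }
  out
}

#' Parameter-recovery experiment over simulation seeds
#'
#' Simulates a study per seed, runs the full chain (displacements ->
#' David's scores, scans -> friendship, dyad table -> crossed-random-effects
#' LMM) and extracts the fitted friendship and relative-rank coefficients
#' with their Wald 95% CIs, together with sign-recovery and CI-coverage
#' indicators against the generative values.
#'
#' @param n_seeds number of independent simulated troops.
#' @param config a [group_config()]; seed `config$seed + i` is used for
#'   troop i.
#' @param effects an [effect_config()] holding the generative coefficients.
#' @param response `"rate"` or `"time"`.
#' @return data.frame with one row per seed: estimates, CI bounds, and
#'   logical `sign_ok_*` / `covers_*` columns; generative values are
#'   attached as attributes `beta_friend` and `beta_sub`.
#' @export
recovery_experiment <- function(n_seeds = 20, config = group_config(),
                                effects = effect_config(),
                                response = "rate") {
  rows <- lapply(seq_len(n_seeds), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    g <- generate_group(cfg)
    st <- simulate_study(g$roster, g$truth, effects, cfg)
    pipe <- groom_pipeline(st$events, st$scans, st$sessions, g$roster,
                           scan_interval = cfg$scan_interval, fit = FALSE,
                           n_randomizations = 0)
    fit <- suppressWarnings(fit_grooming_lmm(pipe$table, response))
    f <- fit$fixed
    fr <- f[f$term == "friendship", ]
    rr <- f[grepl("^relative_rank", f$term), ]
    data.frame(seed = cfg$seed,
               friend_est = fr$estimate, friend_lo = fr$ci_low,
               friend_hi = fr$ci_high,
               rank_est = rr$estimate, rank_lo = rr$ci_low,
               rank_hi = rr$ci_high)
  })
  out <- do.call(rbind, rows)
  out$sign_ok_friend <- sign(out$friend_est) == sign(effects$beta_friend)
  out$sign_ok_rank <- sign(out$rank_est) == sign(effects$beta_sub)
  out$covers_friend <- out$friend_lo <= effects$beta_friend &
    effects$beta_friend <= out$friend_hi
  out$covers_rank <- out$rank_lo <= effects$beta_sub &
    effects$beta_sub <= out$rank_hi
  attr(out, "beta_friend") <- effects$beta_friend
  attr(out, "beta_sub") <- effects$beta_sub
  out
}
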
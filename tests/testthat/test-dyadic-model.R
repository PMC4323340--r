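test_that("the dyad table has N(N-1) rows per season with complement ranks", {
  pipe <- default_pipeline()
  tab <- pipe$table
  expect_equal(nrow(tab), 544) # 17 * 16 * 2 seasons
  expect_equal(sum(tab$season == "1"), 272)

  # relative rank of (A,B) is the complement of (B,A), in every season
  key <- paste(tab$season, tab$groomer_id, tab$groomee_id)
  rev <- match(paste(tab$season, tab$groomee_id, tab$groomer_id), key)
  expect_true(all(tab$relative_rank != tab$relative_rank[rev]))
  # rank distance is symmetric and cardinal (NDS based)
  expect_equal(tab$rank_distance, tab$rank_distance[rev])
  # grooming received is the reverse-direction raw measure
  expect_equal(tab$groom_rate_received, tab$grooming_rate[rev])

  small <- small_config(seed = 3)
  g <- generate_group(small)
  st <- simulate_study(g$roster, g$truth, effect_config(), small)
  p <- groom_pipeline(st$events, st$scans, st$sessions, g$roster,
                      fit = FALSE, n_randomizations = 0)
  expect_equal(nrow(p$table), 30) # 6 * 5, one season
})

test_that("assembly fails informatively when a component is missing", {
  pipe <- default_pipeline()
  fx <- default_study()
  expect_error(
    assemble_dyad_table(pipe$measures, pipe$aggression, pipe$friendship,
                        lapply(pipe$scan_mats, `[[`, "co_provisioning_pct"),
                        list(), fx$roster),
    "no David's scores")
})

test_that("log transform applies the half-minimum offset rule", {
  x <- c(0, 0.1, 0.4)
  y <- log_offset_transform(x)
  expect_equal(attr(y, "offset"), 0.05)
  expect_equal(as.numeric(y), log(x + 0.05))
  expect_equal(as.numeric(log_offset_transform(0, offset = 0.005)),
               log(0.005))
  expect_equal(as.numeric(log_offset_transform(c(2, 3), offset = 0)),
               log(c(2, 3)))
  expect_error(log_offset_transform(c(0, 1), offset = 0), "offset")
  expect_error(log_offset_transform(c(0, 0)), "no positive values")
  # monotonicity for any fixed offset
  withr::with_seed(2, {
    x <- sort(runif(50))
    expect_true(all(diff(log_offset_transform(x, 0.01)) > 0))
  })
})

test_that("exp-scale interpretation converts coefficients to percent change", {
  k <- effect_interpretation(-1.222)
  expect_equal(k$percent_rounded, -71)
  expect_equal(k$label, "71% lower")
  expect_equal(effect_interpretation(0)$percent_rounded, 0)
  g <- effect_interpretation(1.959, delta = 0.1)
  expect_equal(g$percent_rounded, 22)
  expect_equal(g$label, "22% higher")
  v <- effect_interpretation(c(0.148, 1.045))
  expect_equal(v$percent_rounded, c(16, 184))
  expect_error(effect_interpretation(0.5, delta = 0), "delta")
})

test_that("the rank-distance split partitions at the pooled mean", {
  tab <- data.frame(rank_distance = c(1, 2, 3, 6), x = 1:4)
  sp <- split_by_rank_distance(tab)
  expect_equal(sp$threshold, 3)
  expect_equal(sp$high$x, 4)
  expect_equal(sp$low$x, 1:3)

  expect_error(split_by_rank_distance(data.frame(rank_distance = rep(2, 4))),
               "high subset is empty")

  pipe <- default_pipeline()
  sp2 <- split_by_rank_distance(pipe$table)
  expect_equal(nrow(sp2$low) + nrow(sp2$high), nrow(pipe$table))
  expect_length(intersect(rownames(sp2$low), rownames(sp2$high)), 0)
  refit <- suppressWarnings(fit_grooming_lmm(sp2$low, "rate"))
  expect_s3_class(refit, "groom_lmm")
})

test_that("fitted models report Wald intervals of exact width", {
  pipe <- default_pipeline()
  f <- pipe$fit_rate$fixed
  expect_equal(f$ci_high - f$ci_low, 2 * 1.96 * f$se)
  expect_true(all(f$ci_low <= f$estimate & f$estimate <= f$ci_high))
  expect_true(all(pipe$fit_rate$ranef_var >= 0))
  expect_lt(pipe$fit_rate$null_lrt$p, 0.05)
})

test_that("with zero random-effect variance the LMM reduces to OLS", {
  cfg <- group_config(n_females = 8, matriline_sizes = c(3, 3, 2), seed = 18)
  g <- generate_group(cfg)
  st <- simulate_study(g$roster, g$truth,
                       effect_config(dyad_reciprocity_sd = 0, actor_sd = 0,
                                     receiver_sd = 0), cfg)
  pipe <- groom_pipeline(st$events, st$scans, st$sessions, g$roster,
                         fit = FALSE, n_randomizations = 0)
  fit <- suppressWarnings(fit_grooming_lmm(pipe$table, "rate"))
  expect_true(all(fit$ranef_var[c("groomer_id", "groomee_id")] < 1e-10))
  dat <- as.data.frame(pipe$table)
  dat$groom_received <- dat$groom_rate_received
  dat$.y <- log(dat$grooming_rate + fit$offset)
  ols <- lm(.y ~ age_difference + kinship + rank_distance + relative_rank +
              friendship + groom_received + co_provisioning_pct +
              aggression_received + season, data = dat)
  expect_equal(fit$fixed$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("under a null generator, fixed-effect CIs cover zero at rate", {
  # all behavioral effects zero: across 50 simulated troops, ~95% of the
  # nine fixed-effect Wald CIs should cover 0. The troop is large enough
  # (10 females, 2 seasons, 180 dyad rows) for the Wald normal
  # approximation to hold.
  eff <- effect_config(beta0 = -1.8, beta_kin = 0, beta_sub = 0,
                       beta_friend = 0, dyad_reciprocity_sd = 0,
                       actor_sd = 0, receiver_sd = 0,
                       aggression_affinity_coupling = 0)
  covered <- unlist(lapply(1:50, function(i) {
    cfg <- group_config(n_females = 10, matriline_sizes = c(4, 3, 3),
                        seasons = 2, focal_hours_per_female = 6,
                        seed = 7000 + i)
    g <- generate_group(cfg)
    st <- simulate_study(g$roster, g$truth, eff, cfg)
    pipe <- groom_pipeline(st$events, st$scans, st$sessions, g$roster,
                           fit = FALSE, n_randomizations = 0)
    fit <- suppressWarnings(fit_grooming_lmm(pipe$table, "rate"))
    f <- fit$fixed[fit$fixed$term != "(Intercept)", ]
    f$ci_low <= 0 & 0 <= f$ci_high
  }))
  expect_gte(mean(covered), 0.9)
})

test_that("the report flags terms whose CI excludes zero", {
  fake <- structure(list(
    response = "grooming_rate", offset = 0.01,
    fixed = data.frame(
      term = c("(Intercept)", "relative_ranksubordinate",
               "co_provisioning_pct", "groom_received"),
      estimate = c(-3, 0.587, 0.140, 1.229),
      se = c(0.2, 0.214, 0.141, 0.038),
      ci_low = c(-3.4, 0.148, -0.134, 0.496),
      ci_high = c(-2.6, 1.045, 0.415, 1.959),
      significant = c(NA, TRUE, FALSE, TRUE)),
    ranef_var = c(groomer_id = 0.1, groomee_id = 0.1, Residual = 1),
    null_lrt = list(chisq = 10, df = 9, p = 0.3), n = 544),
    class = "groom_lmm")
  rep <- groom_report(list(rate = fake),
                      deltas = c(groom_received = 0.1))
  expect_true(rep$significant[rep$term == "relative_ranksubordinate"])
  expect_false(rep$significant[rep$term == "co_provisioning_pct"])
  expect_match(rep$pct_change[rep$term == "relative_ranksubordinate"],
               "16% to 184% higher")
  expect_match(rep$pct_change[rep$term == "groom_received"],
               "5% to 22% higher")
  expect_true(is.na(rep$pct_change[rep$term == "co_provisioning_pct"]))

  empty <- fake
  empty$fixed <- fake$fixed[1, ]
  rep0 <- groom_report(list(rate = empty))
  expect_equal(nrow(rep0), 0)
  expect_true(all(c("term", "estimate", "ci_low", "ci_high") %in%
                    names(rep0)))
})

test_that("the full pipeline is reproducible end to end", {
  run <- function() {
    cfg <- small_config(seed = 77)
    g <- generate_group(cfg)
    st <- simulate_study(g$roster, g$truth, effect_config(), cfg)
    # small troops often estimate a variance at 0; the singular-fit warning
    # is expected and irrelevant to the reproducibility property
    pipe <- suppressWarnings(
      groom_pipeline(st$events, st$scans, st$sessions, g$roster,
                     fit = TRUE, n_randomizations = 200, seed = 5))
    list(fixed = pipe$fit_rate$fixed,
         h_prime = pipe$dominance[["1"]]$linearity$h_prime,
         p_steep = pipe$dominance[["1"]]$steepness$p_value)
  }
  expect_identical(run(), run())
})
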
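# Focal-sampling simulator with known ground-truth social structure.
#
# The generator emulates the observational design used for semi-free-ranging
# Barbary macaque females: a fixed roster of adult females structured into
# matrilines, a linear latent dominance hierarchy, focal continuous sampling
# in 30-minute sessions with instantaneous scans every 2 minutes, and
# directed grooming driven on the log scale by kinship, relative rank,
# friendship and shared dyadic (reciprocity) effects. Every downstream
# statistic in the package can therefore be checked against known truth.

#' Group and observation-design configuration
#'
#' Defaults describe a troop of 17 adult females in six matrilines observed
#' for 15.5 focal hours per female per season over two seasons, in 30-minute
#' focal sessions with scans at 2-minute intervals.
#'
#' @param n_females number of adult females (>= 3).
#' @param matriline_sizes integer vector summing to `n_females`; all
#'   within-matriline pairs (mother-daughter and sister-sister) are kin.
#' @param ages optional vector of ages in years (>= 3); drawn if NULL.
#' @param seasons number of observation seasons.
#' @param focal_hours_per_female focal observation hours per female per
#'   season.
#' @param session_length focal session length in minutes.
#' @param scan_interval minutes between instantaneous scans; must divide
#'   `session_length`.
#' @param affinity_kin,affinity_rank_decay,affinity_sd parameters of the
#'   latent dyadic affinity: log-affinity is `affinity_kin` for kin pairs,
#'   decays with scaled rank distance at `affinity_rank_decay`, plus
#'   symmetric normal noise with SD `affinity_sd`. The default SD (1.0)
#'   produces strongly differentiated relationships, matching the wide
#'   spread of contact-based friendship values seen in real groups.
#' @param seed master integer seed; every stage derives its own stream from
#'   it by a fixed offset.
#' @return list of class `group_config`.
#' @export
group_config <- function(n_females = 17,
                         matriline_sizes = c(4, 3, 3, 3, 2, 2),
                         ages = NULL,
                         seasons = 2,
                         focal_hours_per_female = 15.5,
                         session_length = 30,
                         scan_interval = 2,
                         affinity_kin = 0.7,
                         affinity_rank_decay = 1.5,
                         affinity_sd = 1.0,
                         seed = 1) {
  if (!is.numeric(n_females) || n_females < 3)
    config_error("group_config: n_females must be >= 3")
  if (sum(matriline_sizes) != n_females)
    config_error("group_config: matriline_sizes must sum to n_females")
  if (any(matriline_sizes < 1))
    config_error("group_config: matriline_sizes must all be >= 1")
  if (!is.null(ages)) {
    if (length(ages) != n_females)
      config_error("group_config: ages must have length n_females")
    if (any(ages < 3))
      config_error("group_config: ages must be >= 3 (adult females)")
  }
  if (focal_hours_per_female <= 0)
    config_error("group_config: focal_hours_per_female must be > 0")
  if (session_length <= 0)
    config_error("group_config: session_length must be > 0")
  if (scan_interval <= 0 || session_length %% scan_interval != 0)
    config_error("group_config: scan_interval must divide session_length")
  check_scalar_number(seed, "seed")
  structure(list(
    n_females = as.integer(n_females),
    matriline_sizes = as.integer(matriline_sizes),
    ages = ages, seasons = as.integer(seasons),
    focal_hours_per_female = focal_hours_per_female,
    session_length = session_length, scan_interval = scan_interval,
    affinity_kin = affinity_kin,
    affinity_rank_decay = affinity_rank_decay,
    affinity_sd = affinity_sd,
    seed = as.integer(seed)
  ), class = "group_config")
}

#' Behavioral effect configuration
#'
#' Log-scale effects driving directed grooming, plus rates for the other
#' recorded behaviors. Defaults are calibrated so that simulated troops
#' groom at roughly 0.17 acts and 0.8 minutes per focal hour per partner,
#' displace at rates yielding a few hundred interactions per season, and
#' direct displacements down the latent hierarchy with near-perfect
#' consistency, as observed in tolerant macaques.
#'
#' @param beta0 baseline log grooming rate (log acts per combined
#'   observation hour of the directed pair).
#' @param beta_kin log-scale increment for kin dyads.
#' @param beta_sub log-scale increment when the groomer is subordinate to
#'   the groomee.
#' @param beta_friend log-scale slope on the true friendship value.
#' @param dyad_reciprocity_sd SD of the shared (symmetric) dyadic random
#'   effect, which induces grooming reciprocity.
#' @param actor_sd,receiver_sd SDs of individual groomer/groomee random
#'   effects.
#' @param displacement_rate displacement events per dyad per combined
#'   observation hour.
#' @param consistency probability that a displacement is directed down the
#'   latent hierarchy; must lie in `[0.5, 1]`.
#' @param aggression_rate baseline aggression events per directed pair per
#'   combined observation hour.
#' @param aggression_affinity_coupling log-scale slope linking dyadic
#'   affinity to the aggression rate (spatially associated dyads fight
#'   more).
#' @param approach_rate baseline approaches per directed pair per combined
#'   observation hour (scaled by affinity).
#' @param mean_groom_bout_min mean grooming act duration in minutes
#'   (exponential).
#' @param scan_contact_p,scan_proximity_p,scan_coprovision_p expected
#'   fraction of scans in which the focal is recorded in each state with
#'   some partner; the partner is drawn proportional to affinity and the
#'   three states are mutually exclusive within a scan.
#' @return list of class `effect_config`.
#' @export
effect_config <- function(beta0 = -3.7,
                          beta_kin = 0.6,
                          beta_sub = 0.6,
                          beta_friend = 0.4,
                          dyad_reciprocity_sd = 0.3,
                          actor_sd = 0.3,
                          receiver_sd = 0.3,
                          displacement_rate = 0.12,
                          consistency = 0.985,
                          aggression_rate = 0.04,
                          aggression_affinity_coupling = 0.5,
                          approach_rate = 0.25,
                          mean_groom_bout_min = 4.6,
                          scan_contact_p = 0.10,
                          scan_proximity_p = 0.12,
                          scan_coprovision_p = 0.04) {
  if (consistency < 0.5 || consistency > 1)
    config_error("effect_config: consistency must lie in [0.5, 1]")
  for (nm in c("dyad_reciprocity_sd", "actor_sd", "receiver_sd"))
    if (get(nm) < 0) config_error("effect_config: %s must be >= 0", nm)
  for (nm in c("displacement_rate", "aggression_rate", "approach_rate",
               "mean_groom_bout_min"))
    if (get(nm) < 0) config_error("effect_config: %s must be >= 0", nm)
  p_total <- scan_contact_p + scan_proximity_p + scan_coprovision_p
  if (p_total >= 1 || min(scan_contact_p, scan_proximity_p,
                          scan_coprovision_p) < 0)
    config_error("effect_config: scan state fractions must be >= 0 and sum to < 1")
  structure(list(
    beta0 = beta0, beta_kin = beta_kin, beta_sub = beta_sub,
    beta_friend = beta_friend,
    dyad_reciprocity_sd = dyad_reciprocity_sd,
    actor_sd = actor_sd, receiver_sd = receiver_sd,
    displacement_rate = displacement_rate, consistency = consistency,
    aggression_rate = aggression_rate,
    aggression_affinity_coupling = aggression_affinity_coupling,
    approach_rate = approach_rate,
    mean_groom_bout_min = mean_groom_bout_min,
    scan_contact_p = scan_contact_p, scan_proximity_p = scan_proximity_p,
    scan_coprovision_p = scan_coprovision_p
  ), class = "effect_config")
}

#' Generate a roster and ground-truth social structure
#'
#' Builds a roster of adult females structured into matrilines (the oldest
#' member of each matriline is its founder and the mother of the others),
#' assigns a latent linear dominance hierarchy in which matrilines hold
#' contiguous rank blocks (nepotistic rank inheritance), and draws a
#' symmetric positive dyadic affinity matrix whose row-normalized form is
#' the true friendship structure.
#'
#' @param config a [group_config()].
#' @return list with `roster` (data.frame) and `truth`: a list of class
#'   `ground_truth` with `latent_rank` (named integer vector, 1 = top),
#'   `kin_pairs` (data.frame `id1`, `id2`), `affinity` (symmetric matrix),
#'   `f_true` (row-normalized affinity) and `true_betas` (filled in by
#'   [simulate_study()]).
#' @export
generate_group <- function(config = group_config()) {
  if (!inherits(config, "group_config"))
    config_error("generate_group: config must be a group_config object")
  N <- config$n_females
  ids <- sprintf("F%02d", seq_len(N))
  mat_id <- rep(sprintf("M%d", seq_along(config$matriline_sizes)),
                config$matriline_sizes)

  with_seed(config$seed + 101L, {
    ages <- config$ages
    if (is.null(ages)) {
      ages <- numeric(N)
      for (m in unique(mat_id)) {
        idx <- which(mat_id == m)
        founder_age <- stats::runif(1, 15, 26)
        ages[idx[1]] <- founder_age
        if (length(idx) > 1)
          ages[idx[-1]] <- stats::runif(length(idx) - 1, 3,
                                        max(4, founder_age - 4))
      }
    }
    mother <- rep(NA_character_, N)
    for (m in unique(mat_id)) {
      idx <- which(mat_id == m)
      founder <- idx[which.max(ages[idx])]
      mother[setdiff(idx, founder)] <- ids[founder]
    }
    roster <- data.frame(individual_id = ids, age = round(ages, 1),
                         matriline_id = mat_id, mother_id = mother,
                         stringsAsFactors = FALSE)

    # nepotistic latent hierarchy: matrilines hold contiguous rank blocks
    mat_order <- sample(unique(mat_id))
    ranked_ids <- unlist(lapply(mat_order, function(m)
      sample(ids[mat_id == m])))
    latent_rank <- stats::setNames(match(ids, ranked_ids), ids)

    kin <- matrix(FALSE, N, N, dimnames = list(ids, ids))
    for (m in unique(mat_id)) {
      idx <- which(mat_id == m)
      kin[idx, idx] <- TRUE
    }
    diag(kin) <- FALSE
    ut <- upper.tri(kin)
    kin_pairs <- data.frame(id1 = rownames(kin)[row(kin)[ut & kin]],
                            id2 = colnames(kin)[col(kin)[ut & kin]],
                            stringsAsFactors = FALSE)

    rank_dist <- abs(outer(latent_rank, latent_rank, `-`)) / N
    log_aff <- config$affinity_kin * kin -
      config$affinity_rank_decay * rank_dist
    noise <- matrix(0, N, N)
    noise[ut] <- stats::rnorm(sum(ut), 0, config$affinity_sd)
    noise <- noise + t(noise)
    affinity <- exp(log_aff + noise)
    diag(affinity) <- 0
    f_true <- affinity / (rowSums(affinity) / (N - 1))
    dimnames(f_true) <- dimnames(affinity)

    # feeding tolerance: shares the kin/rank structure of affinity at half
    # strength but has its own dyadic component -- tolerance at a food
    # source is related to, but not the same construct as, contact
    # affinity
    tol_noise <- matrix(0, N, N)
    tol_noise[ut] <- stats::rnorm(sum(ut), 0, config$affinity_sd)
    tol_noise <- tol_noise + t(tol_noise)
    tolerance <- exp(0.5 * log_aff + tol_noise)
    diag(tolerance) <- 0

    truth <- structure(list(latent_rank = latent_rank, kin_pairs = kin_pairs,
                            kin = kin, affinity = affinity, f_true = f_true,
                            tolerance = tolerance, true_betas = NULL),
                       class = "ground_truth")
    list(roster = roster, truth = truth)
  })
}

# place k acts with durations dur (seconds) in a session of sess_sec seconds,
# keeping >= 21 s between consecutive acts of the same directed pair so the
# 20-s termination rule keeps them distinct. Returns data.frame(start, end).
place_acts <- function(dur, sess_sec, min_gap = 21) {
  k <- length(dur)
  if (min_gap * (k - 1) + k > sess_sec)
    config_error("implausible grooming density: %d acts cannot fit one session", k)
  need <- sum(dur) + min_gap * (k - 1)
  if (need > 0.95 * sess_sec) dur <- dur * (0.95 * sess_sec - min_gap * (k - 1)) / sum(dur)
  dur <- pmax(dur, 1)
  free <- sess_sec - sum(dur) - min_gap * (k - 1)
  cuts <- sort(stats::runif(k, 0, 1))
  gaps <- c(cuts[1], diff(cuts)) * max(free, 0)
  start <- cumsum(gaps + c(0, dur[-k] + min_gap))
  data.frame(start = round(start, 1), end = round(start + dur, 1))
}

# assign n instantaneous events to uniformly chosen sessions/times of the
# two members' focal sessions
place_instants <- function(n, sess) {
  pick <- sample.int(nrow(sess), n, replace = TRUE)
  data.frame(session_id = sess$session_id[pick],
             focal_id = sess$focal_id[pick],
             start = round(stats::runif(n, 0, sess$duration_min[pick] * 60), 1))
}

#' Simulate a two-method focal observation study
#'
#' Generates focal continuous event logs (approach, displacement, groom,
#' aggression) and instantaneous scan logs (contact, proximity,
#' co-provisioning) for the group described by `roster`/`truth`, under the
#' behavioral effects in `effects`. Directed grooming acts per season follow
#' a Poisson count process whose log rate is
#' `beta0 + beta_kin*kin + beta_sub*subordinate + beta_friend*F_true +
#' dyad + actor + receiver`, with exposure the combined focal hours of the
#' pair; act durations are exponential. Displacements are directed down the
#' latent hierarchy with probability `consistency`. Scan states are
#' mutually exclusive within a scan and the partner is drawn proportional
#' to dyadic affinity. All streams derive from `config$seed`, so identical
#' inputs reproduce identical logs.
#'
#' @param roster roster data.frame from [generate_group()].
#' @param truth `ground_truth` from [generate_group()].
#' @param effects an [effect_config()].
#' @param config the [group_config()] used to generate the group.
#' @return list of class `focal_study` with `events`, `scans`, `sessions`
#'   and `truth` (with `true_betas` filled in).
#' @export
simulate_study <- function(roster, truth, effects = effect_config(),
                           config = group_config()) {
  roster <- validate_roster(roster)
  if (!inherits(truth, "ground_truth"))
    config_error("simulate_study: truth must come from generate_group()")
  ids <- roster$individual_id
  N <- length(ids)
  seasons <- as.character(seq_len(config$seasons))
  rank <- truth$latent_rank[ids]
  f_true <- truth$f_true
  kin <- truth$kin
  aff <- truth$affinity

  # session plan: tile session_length-minute sessions to reach the focal
  # budget exactly (a shorter remainder session if needed)
  total_min <- config$focal_hours_per_female * 60
  n_full <- floor(total_min / config$session_length)
  rem <- total_min - n_full * config$session_length
  durations <- c(rep(config$session_length, n_full), if (rem > 0) rem)
  sessions <- do.call(rbind, lapply(seasons, function(s) {
    do.call(rbind, lapply(ids, function(id) {
      data.frame(season = s,
                 session_id = sprintf("s%s_%s_%03d", s, id,
                                      seq_along(durations)),
                 focal_id = id, duration_min = durations,
                 stringsAsFactors = FALSE)
    }))
  }))

  hours <- stats::setNames(rep(config$focal_hours_per_female, N), ids)

  # log grooming rate per combined observation hour, directed pair
  pairs <- ordered_pairs(ids)
  sub <- as.numeric(rank[pairs$actor_id] > rank[pairs$recipient_id])
  kin_v <- kin[cbind(pairs$actor_id, pairs$recipient_id)]
  f_v <- f_true[cbind(pairs$actor_id, pairs$recipient_id)]

  re <- with_seed(config$seed + 211L, {
    a <- stats::setNames(stats::rnorm(N, 0, effects$actor_sd), ids)
    r <- stats::setNames(stats::rnorm(N, 0, effects$receiver_sd), ids)
    dm <- matrix(0, N, N, dimnames = list(ids, ids))
    ut <- upper.tri(dm)
    dm[ut] <- stats::rnorm(sum(ut), 0, effects$dyad_reciprocity_sd)
    dm <- dm + t(dm)
    list(actor = a, receiver = r, dyad = dm)
  })
  eta <- effects$beta0 + effects$beta_kin * kin_v + effects$beta_sub * sub +
    effects$beta_friend * f_v +
    re$dyad[cbind(pairs$actor_id, pairs$recipient_id)] +
    re$actor[pairs$actor_id] + re$receiver[pairs$recipient_id]
  if (any(exp(eta) > 3600))
    config_error(
      "simulate_study: implausible scale, expected grooming rate exceeds 1 event/second")

  events <- list()

  # --- grooming -------------------------------------------------------------
  events$groom <- with_seed(config$seed + 401L, {
    out <- list()
    for (s in seasons) {
      exposure <- hours[pairs$actor_id] + hours[pairs$recipient_id]
      n_acts <- stats::rpois(nrow(pairs), exp(eta) * exposure)
      for (p in which(n_acts > 0)) {
        A <- pairs$actor_id[p]; B <- pairs$recipient_id[p]
        sess <- sessions[sessions$season == s &
                           sessions$focal_id %in% c(A, B), ]
        pick <- sample.int(nrow(sess), n_acts[p], replace = TRUE)
        for (si in unique(pick)) {
          k <- sum(pick == si)
          dur <- stats::rexp(k, 1 / (effects$mean_groom_bout_min * 60))
          pl <- place_acts(dur, sess$duration_min[si] * 60)
          out[[length(out) + 1]] <- data.frame(
            season = s, session_id = sess$session_id[si],
            focal_id = sess$focal_id[si], actor_id = A, recipient_id = B,
            behavior = "groom", start = pl$start, end = pl$end,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  })

  # --- displacements --------------------------------------------------------
  ut_pairs <- pairs[pairs$actor_id < pairs$recipient_id, ]
  events$displacement <- with_seed(config$seed + 307L, {
    out <- list()
    for (s in seasons) {
      exposure <- hours[ut_pairs$actor_id] + hours[ut_pairs$recipient_id]
      n_ev <- stats::rpois(nrow(ut_pairs), effects$displacement_rate * exposure)
      for (p in which(n_ev > 0)) {
        A <- ut_pairs$actor_id[p]; B <- ut_pairs$recipient_id[p]
        dominant <- if (rank[A] < rank[B]) A else B
        subord <- setdiff(c(A, B), dominant)
        down <- stats::rbinom(n_ev[p], 1, effects$consistency) == 1
        sess <- sessions[sessions$season == s &
                           sessions$focal_id %in% c(A, B), ]
        pl <- place_instants(n_ev[p], sess)
        out[[length(out) + 1]] <- data.frame(
          season = s, session_id = pl$session_id, focal_id = pl$focal_id,
          actor_id = ifelse(down, dominant, subord),
          recipient_id = ifelse(down, subord, dominant),
          behavior = "displacement", start = pl$start, end = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })

  # --- aggression (rate increases with dyadic affinity) ---------------------
  f_sym <- (f_true + t(f_true)) / 2
  events$aggression <- with_seed(config$seed + 503L, {
    out <- list()
    lam <- effects$aggression_rate *
      exp(effects$aggression_affinity_coupling *
            (f_sym[cbind(pairs$actor_id, pairs$recipient_id)] - 1))
    for (s in seasons) {
      exposure <- hours[pairs$actor_id] + hours[pairs$recipient_id]
      n_ev <- stats::rpois(nrow(pairs), lam * exposure)
      for (p in which(n_ev > 0)) {
        A <- pairs$actor_id[p]; B <- pairs$recipient_id[p]
        sess <- sessions[sessions$season == s &
                           sessions$focal_id %in% c(A, B), ]
        pl <- place_instants(n_ev[p], sess)
        out[[length(out) + 1]] <- data.frame(
          season = s, session_id = pl$session_id, focal_id = pl$focal_id,
          actor_id = A, recipient_id = B, behavior = "aggression",
          start = pl$start, end = NA_real_, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })

  # --- approaches (affinity-driven) -----------------------------------------
  events$approach <- with_seed(config$seed + 601L, {
    out <- list()
    lam <- effects$approach_rate *
      f_sym[cbind(pairs$actor_id, pairs$recipient_id)]
    for (s in seasons) {
      exposure <- hours[pairs$actor_id] + hours[pairs$recipient_id]
      n_ev <- stats::rpois(nrow(pairs), lam * exposure)
      for (p in which(n_ev > 0)) {
        A <- pairs$actor_id[p]; B <- pairs$recipient_id[p]
        sess <- sessions[sessions$season == s &
                           sessions$focal_id %in% c(A, B), ]
        pl <- place_instants(n_ev[p], sess)
        out[[length(out) + 1]] <- data.frame(
          season = s, session_id = pl$session_id, focal_id = pl$focal_id,
          actor_id = A, recipient_id = B, behavior = "approach",
          start = pl$start, end = NA_real_, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })

  event_log <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  event_log <- event_log[order(event_log$season, event_log$session_id,
                               event_log$start, event_log$behavior,
                               event_log$actor_id, event_log$recipient_id), ]
  rownames(event_log) <- NULL
  event_log <- validate_event_log(event_log)

  # --- scans: one mutually exclusive state per scan, partner ~ affinity ----
  scans <- with_seed(config$seed + 701L, {
    out <- list()
    per_session <- config$session_length / config$scan_interval
    p_states <- c(contact = effects$scan_contact_p,
                  proximity = effects$scan_proximity_p,
                  `co-provisioning` = effects$scan_coprovision_p)
    for (s in seasons) {
      for (id in ids) {
        sess <- sessions[sessions$season == s & sessions$focal_id == id, ]
        n_per <- floor(sess$duration_min / config$scan_interval)
        n_scan <- sum(n_per)
        share <- aff[id, ids] / sum(aff[id, ids])
        share_tol <- truth$tolerance[id, ids] / sum(truth$tolerance[id, ids])
        # outcomes: 1 = none, then (partner x state); contact/proximity
        # partners follow affinity, co-provisioning partners feeding
        # tolerance
        prob <- c(1 - sum(p_states),
                  share * p_states[["contact"]],
                  share * p_states[["proximity"]],
                  share_tol * p_states[["co-provisioning"]])
        partner_of <- rep(ids, times = length(p_states))
        state_of <- rep(names(p_states), each = N)
        draw <- sample.int(length(prob), n_scan, replace = TRUE, prob = prob)
        hit <- which(draw > 1)
        if (length(hit)) {
          sess_idx <- rep(seq_len(nrow(sess)), n_per)
          within <- sequence(n_per)
          out[[length(out) + 1]] <- data.frame(
            season = s, session_id = sess$session_id[sess_idx[hit]],
            focal_id = id,
            partner_id = partner_of[draw[hit] - 1],
            state = state_of[draw[hit] - 1],
            scan_time = within[hit] * config$scan_interval * 60,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  })
  scans <- scans[order(scans$season, scans$session_id, scans$scan_time,
                       scans$partner_id), ]
  rownames(scans) <- NULL
  scans <- validate_scan_log(scans)

  truth$true_betas <- effects
  truth$random_effects <- re
  structure(list(events = event_log, scans = scans, sessions = sessions,
                 truth = truth, config = config, effects = effects),
            class = "focal_study")
}

#' @export
print.focal_study <- function(x, ...) {
  cat(sprintf(
    "Simulated focal study: %d individuals, %d seasons, %d events, %d scan records\n",
    length(unique(x$sessions$focal_id)), length(unique(x$sessions$season)),
    nrow(x$events), nrow(x$scans)))
  print(table(x$events$behavior))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Writes the event, scan and session CSVs plus a ground-truth JSON sidecar
#' (latent ranks, kin pairs, true effect sizes).
#'
#' @param study a `focal_study` from [simulate_study()].
#' @param roster the roster data.frame.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, roster, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_event_log(study$events, file.path(dir, "events.csv"))
  write_scan_log(study$scans, file.path(dir, "scans.csv"))
  write_session_table(study$sessions, file.path(dir, "sessions.csv"))
  write_roster(roster, file.path(dir, "roster.csv"))
  truth <- list(
    latent_rank = as.list(study$truth$latent_rank),
    kin_pairs = study$truth$kin_pairs,
    true_betas = unclass(study$truth$true_betas)
  )
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
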
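# Directed affiliation measures: grooming bouts and rates, aggression rates,
# scan-based contact/proximity/co-provisioning time, and the asymmetric
# friendship index.

#' Merge grooming segments into acts (20-second termination rule)
#'
#' A grooming act is considered terminated only when it stops for at least
#' 20 seconds: recorded segments of the same directed pair within the same
#' focal session whose gap is shorter than `gap` seconds belong to one act.
#' Act duration is the sum of segment lengths; within-act pauses are not
#' counted as grooming time.
#'
#' @param events an event log; only `groom` rows are used.
#' @param gap termination threshold in seconds (default 20; a pause of
#'   exactly `gap` seconds terminates the act).
#' @return data.frame with one row per act: `season`, `session_id`,
#'   `groomer_id`, `groomee_id`, `start`, `end`, `n_segments`,
#'   `duration` (seconds of active grooming).
#' @export
merge_grooming_bouts <- function(events, gap = 20) {
  events <- validate_event_log(events)
  g <- events[events$behavior == "groom", ]
  if (nrow(g) == 0)
    return(data.frame(season = character(), session_id = character(),
                      groomer_id = character(), groomee_id = character(),
                      start = numeric(), end = numeric(),
                      n_segments = integer(), duration = numeric()))
  key <- paste(g$season, g$session_id, g$actor_id, g$recipient_id, sep = "\r")
  parts <- split(g, key)
  acts <- lapply(parts, function(p) {
    p <- p[order(p$start), ]
    n <- nrow(p)
    if (n > 1) {
      overlap <- p$start[-1] < p$end[-n]
      if (any(overlap))
        data_error(
          "overlapping grooming segments for %s -> %s in session %s",
          p$actor_id[1], p$recipient_id[1], p$session_id[1])
    }
    new_act <- c(TRUE, if (n > 1) (p$start[-1] - p$end[-n]) >= gap)
    act_id <- cumsum(new_act)
    do.call(rbind, lapply(split(seq_len(n), act_id), function(idx) {
      data.frame(season = p$season[1], session_id = p$session_id[1],
                 groomer_id = p$actor_id[1], groomee_id = p$recipient_id[1],
                 start = p$start[idx[1]], end = p$end[idx[length(idx)]],
                 n_segments = length(idx),
                 duration = sum(p$end[idx] - p$start[idx]))
    }))
  })
  out <- do.call(rbind, acts)
  out <- out[order(out$season, out$session_id, out$groomer_id,
                   out$groomee_id, out$start), ]
  rownames(out) <- NULL
  out
}

# Fill a directed per-season frame with every ordered pair of ids.
directed_frame <- function(ids, seasons) {
  do.call(rbind, lapply(seasons, function(s) {
    p <- ordered_pairs(ids)
    data.frame(season = s, p, stringsAsFactors = FALSE)
  }))
}

#' Directed grooming rate and time
#'
#' Following the dyadic definition used for sociometric grooming analysis:
#' the grooming rate of the directed pair A -> B in a season is the number
#' of grooming acts A performed on B divided by the total observation time
#' of the two individuals (sum of both focal-hour totals), and grooming time
#' is the minutes A groomed B per combined observation hour. A directed
#' interaction A -> B is observable whenever either member is focal, hence
#' the combined denominator. Seasons are never pooled.
#'
#' @param bouts merged grooming acts from [merge_grooming_bouts()].
#' @param obs_hours observation-time table from [observation_time()].
#' @param ids character vector of subject ids (defines the directed pairs).
#' @return data.frame with `season`, `groomer_id`, `groomee_id`, `acts`,
#'   `minutes`, `grooming_rate` (acts/h), `grooming_time` (min/h).
#' @export
grooming_measures <- function(bouts, obs_hours, ids) {
  ids <- as.character(ids)
  seasons <- sort(unique(obs_hours$season))
  out <- directed_frame(ids, seasons)
  names(out)[2:3] <- c("groomer_id", "groomee_id")
  out$acts <- 0L
  out$minutes <- 0
  bouts <- bouts[bouts$groomer_id %in% ids & bouts$groomee_id %in% ids, ]
  if (nrow(bouts) > 0) {
    key_out <- paste(out$season, out$groomer_id, out$groomee_id)
    agg_n <- stats::aggregate(duration ~ season + groomer_id + groomee_id,
                              data = bouts,
                              FUN = length)
    agg_d <- stats::aggregate(duration ~ season + groomer_id + groomee_id,
                              data = bouts, FUN = sum)
    key_a <- paste(agg_n$season, agg_n$groomer_id, agg_n$groomee_id)
    idx <- match(key_a, key_out)
    if (anyNA(idx))
      key_error("grooming bouts involve individuals/seasons outside the table: %s",
                paste(key_a[is.na(idx)], collapse = "; "))
    out$acts[idx] <- agg_n$duration
    out$minutes[idx] <- agg_d$duration / 60
  }
  out$grooming_rate <- NA_real_
  out$grooming_time <- NA_real_
  for (s in seasons) {
    h <- hours_vector(obs_hours, s, ids)
    rows <- out$season == s
    comb <- h[out$groomer_id[rows]] + h[out$groomee_id[rows]]
    if (any(comb <= 0))
      domain_error("zero combined observation time in season %s", s)
    out$grooming_rate[rows] <- out$acts[rows] / comb
    out$grooming_time[rows] <- out$minutes[rows] / comb
  }
  out
}

#' Directed aggression rate
#'
#' Counts of aggression events actor -> recipient divided by the combined
#' observation hours of the pair, per season. The dyadic grooming model uses
#' these as "aggression received": the rate at which a groomer A receives
#' aggression from groomee B is `rate[B -> A]`.
#'
#' @inheritParams grooming_measures
#' @param events an event log; only `aggression` rows are used.
#' @return data.frame with `season`, `actor_id`, `recipient_id`, `acts`,
#'   `aggression_rate` (acts per combined observation hour).
#' @export
aggression_rates <- function(events, obs_hours, ids) {
  events <- validate_event_log(events)
  ids <- as.character(ids)
  seasons <- sort(unique(obs_hours$season))
  out <- directed_frame(ids, seasons)
  out$acts <- 0L
  a <- events[events$behavior == "aggression" &
                events$actor_id %in% ids & events$recipient_id %in% ids, ]
  if (nrow(a) > 0) {
    key_out <- paste(out$season, out$actor_id, out$recipient_id)
    tab <- stats::aggregate(behavior ~ season + actor_id + recipient_id,
                            data = a, FUN = length)
    idx <- match(paste(tab$season, tab$actor_id, tab$recipient_id), key_out)
    out$acts[idx[!is.na(idx)]] <- tab$behavior[!is.na(idx)]
  }
  out$aggression_rate <- NA_real_
  for (s in seasons) {
    h <- hours_vector(obs_hours, s, ids)
    rows <- out$season == s
    comb <- h[out$actor_id[rows]] + h[out$recipient_id[rows]]
    if (any(comb <= 0))
      domain_error("zero combined observation time in season %s", s)
    out$aggression_rate[rows] <- out$acts[rows] / comb
  }
  out
}

#' Scan-based dyadic time matrices
#'
#' Converts instantaneous scan records into per-season dyadic time
#' estimates: each scan in a state contributes `scan_interval` minutes, and
#' the two focal perspectives of a dyad are summed (focal A seen with B and
#' focal B seen with A), giving symmetric matrices. The co-provisioning
#' percentage is `100 * co-provisioning scans of the dyad / all scans in
#' which either member was the focal`, requiring a session table to count
#' total scans.
#'
#' @param scans a scan log.
#' @param sessions session table (to count total scans per focal).
#' @param scan_interval minutes between scans (default 2).
#' @param ids subject ids fixing the matrix order.
#' @return named list by season; each element a list with symmetric matrices
#'   `contact_min`, `proximity_min`, `co_provisioning_pct` and the vector
#'   `n_scans` of total scans per focal.
#' @export
scan_time_matrices <- function(scans, sessions, scan_interval = 2, ids) {
  if (!is.numeric(scan_interval) || scan_interval <= 0)
    config_error("scan_interval must be > 0")
  scans <- validate_scan_log(scans)
  sessions <- validate_session_table(sessions)
  ids <- as.character(ids)
  seasons <- sort(unique(sessions$season))
  out <- lapply(seasons, function(s) {
    sc <- scans[scans$season == s &
                  scans$focal_id %in% ids & scans$partner_id %in% ids, ]
    se <- sessions[sessions$season == s & sessions$focal_id %in% ids, ]
    n_scans <- stats::setNames(numeric(length(ids)), ids)
    per <- floor(se$duration_min / scan_interval)
    agg <- tapply(per, se$focal_id, sum)
    n_scans[names(agg)] <- agg
    count_state <- function(state) {
      x <- sc[sc$state == state, ]
      m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
      if (nrow(x) > 0) {
        tab <- table(factor(x$focal_id, levels = ids),
                     factor(x$partner_id, levels = ids))
        m <- m + unclass(tab)
      }
      dimnames(m) <- list(ids, ids)
      m
    }
    contact <- count_state("contact")
    prox <- count_state("proximity")
    coprov <- count_state("co-provisioning")
    sym <- function(m) m + t(m)
    denom <- outer(n_scans, n_scans, `+`)
    cp_pct <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    pos <- denom > 0
    cp_sym <- sym(coprov)
    cp_pct[pos] <- 100 * cp_sym[pos] / denom[pos]
    diag(cp_pct) <- 0
    list(contact_min = sym(contact) * scan_interval,
         proximity_min = sym(prox) * scan_interval,
         co_provisioning_pct = cp_pct,
         n_scans = n_scans)
  })
  stats::setNames(out, seasons)
}

#' Asymmetric friendship index
#'
#' The friendship of A towards B is the time A spends in contact with B
#' divided by the average time A spends in contact with all other females:
#' `F(A,B) = x[A,B] / mean(x[A,k], k != A)`. The index is asymmetric
#' (`F(A,B) != F(B,A)` in general, because the two row means differ) and
#' each row with positive contact has off-diagonal mean exactly 1. Partners
#' with zero contact are included in the denominator average. Rows with no
#' contact at all get `F = 0` with a warning.
#'
#' @param time_matrix square non-negative dyadic time (or count) matrix; the
#'   default basis is scan-based contact minutes, but any of the proximity,
#'   approach or grooming matrices may be used.
#' @param basis label recording which behavior the index is based on.
#' @return square matrix of friendship values with attribute `basis`.
#' @export
friendship_index <- function(time_matrix, basis = "contact") {
  m <- check_sociometric(time_matrix, "friendship basis matrix")
  if (nrow(m) < 2) domain_error("friendship index requires at least 2 ids")
  diag(m) <- 0
  denom <- rowSums(m) / (ncol(m) - 1)
  f <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  zero_rows <- denom == 0
  if (any(zero_rows))
    warning(sprintf("no contact recorded for: %s; friendship row set to 0",
                    paste(rownames(m)[zero_rows], collapse = ", ")),
            call. = FALSE)
  f[!zero_rows, ] <- m[!zero_rows, , drop = FALSE] / denom[!zero_rows]
  diag(f) <- 0
  attr(f, "basis") <- basis
  f
}

#' Correlations among the four friendship bases
#'
#' Computes friendship indices on four behavioral bases -- scan contact
#' time, scan proximity time, approach counts and grooming time -- and
#' returns the Spearman rank correlations between each pair of indices over
#' directed dyads, per season.
#'
#' @param events event log (for approaches and grooming).
#' @param scans scan log (for contact and proximity).
#' @param sessions session table.
#' @param ids subject ids.
#' @param scan_interval minutes between scans.
#' @return data.frame with `season`, `basis_a`, `basis_b`, `rho`. An
#'   undefined correlation (constant index) is returned as NA with a
#'   warning.
#' @export
friendship_correlations <- function(events, scans, sessions, ids,
                                    scan_interval = 2) {
  ids <- as.character(ids)
  scan_mats <- scan_time_matrices(scans, sessions, scan_interval, ids)
  bouts <- merge_grooming_bouts(events)
  seasons <- names(scan_mats)
  out <- list()
  for (s in seasons) {
    approach <- displacement_matrix(events, season = s, ids = ids,
                                    behavior = "approach")
    groom_min <- matrix(0, length(ids), length(ids),
                        dimnames = list(ids, ids))
    b <- bouts[bouts$season == s, ]
    if (nrow(b) > 0) {
      agg <- stats::aggregate(duration ~ groomer_id + groomee_id, data = b,
                              FUN = sum)
      groom_min[cbind(agg$groomer_id, agg$groomee_id)] <- agg$duration / 60
    }
    bases <- list(
      contact = friendship_index(scan_mats[[s]]$contact_min, "contact"),
      proximity = friendship_index(scan_mats[[s]]$proximity_min, "proximity"),
      approach = friendship_index(approach + t(approach), "approach"),
      grooming = friendship_index(groom_min + t(groom_min), "grooming")
    )
    off <- !diag(length(ids))
    nm <- names(bases)
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      if (i >= j) next
      x <- bases[[i]][off]
      y <- bases[[j]][off]
      rho <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning(sprintf(
          "season %s: friendship index constant for basis %s/%s; rho undefined",
          s, nm[i], nm[j]), call. = FALSE)
        NA_real_
      } else {
        stats::cor(x, y, method = "spearman")
      }
      out[[length(out) + 1]] <- data.frame(
        season = s, basis_a = nm[i], basis_b = nm[j], rho = rho)
    }
  }
  do.call(rbind, out)
}
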
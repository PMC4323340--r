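# Dominance-hierarchy statistics from a displacement matrix: dyadic dominance
# indices corrected for chance, David's scores, hierarchy steepness and
# linearity with randomization tests, and the directional consistency index.

#' Build a displacement matrix from an event log
#'
#' Entry (i, j) counts the displacement events in which i drove j away from a
#' resource. When `ids` is supplied (e.g. the adult-female roster), events
#' involving any other individual are excluded, which is how interactions
#' with non-subjects are filtered out.
#'
#' @param events an event log (see [validate_event_log()]).
#' @param season optional season label; only that season's events are counted.
#' @param ids optional character vector fixing the matrix id order.
#' @param behavior behavior to tabulate, default `"displacement"`.
#' @return a square count matrix with ids as dimnames.
#' @export
displacement_matrix <- function(events, season = NULL, ids = NULL,
                                behavior = "displacement") {
  events <- validate_event_log(events)
  events <- events[events$behavior == behavior, ]
  if (!is.null(season)) events <- events[events$season %in% season, ]
  if (is.null(ids)) {
    ids <- sort(unique(c(events$actor_id, events$recipient_id)))
    if (length(ids) == 0)
      domain_error("no %s events to tabulate and no ids supplied", behavior)
  } else {
    ids <- as.character(ids)
    events <- events[events$actor_id %in% ids & events$recipient_id %in% ids, ]
  }
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(events) > 0) {
    tab <- table(factor(events$actor_id, levels = ids),
                 factor(events$recipient_id, levels = ids))
    m <- m + unclass(tab)
    dimnames(m) <- list(ids, ids)
  }
  m
}

#' Dyadic dominance index corrected for chance (Dij)
#'
#' For each dyad with `n_ij = wins_ij + wins_ji > 0` interactions,
#' `Pij = wins_ij / n_ij` and `Dij = Pij - (Pij - 0.5) / (n_ij + 1)`, which
#' shrinks the raw win proportion towards 0.5 in small samples. Dyads that
#' were never observed interacting (unknown dyads) are set to the
#' no-information value `Dij = Dji = 0.5`, which keeps David's scores defined
#' in matrices with unknown relationships.
#'
#' @param m square sociometric count matrix (see [check_sociometric()]).
#' @return an object of class `dij_matrix`: list with `D` (the Dij matrix,
#'   zero diagonal), `n` (symmetric matrix of dyadic interaction counts) and
#'   `ids`.
#' @export
dyadic_dominance_index <- function(m) {
  m <- check_sociometric(m)
  diag(m) <- 0
  n <- m + t(m)
  D <- matrix(0.5, nrow(m), ncol(m), dimnames = dimnames(m))
  known <- n > 0
  P <- m[known] / n[known]
  D[known] <- P - (P - 0.5) / (n[known] + 1)
  diag(D) <- 0
  structure(list(D = D, n = n, ids = rownames(m)), class = "dij_matrix")
}

as_dij <- function(x) {
  if (inherits(x, "dij_matrix")) return(x)
  dyadic_dominance_index(x)
}

#' David's scores and normalized David's scores
#'
#' From a Dij matrix, `w = rowSums(D)`, `w2 = D %*% w`, `l = colSums(D)`,
#' `l2 = t(D) %*% l`, `DS = w + w2 - l - l2` and
#' `NDS = (DS + N(N-1)/2) / N`. DS sums to zero over individuals; NDS lies in
#' `[0, N-1]` with mean `(N-1)/2` and is the cardinal rank value used
#' downstream.
#'
#' @param x a `dij_matrix` or a raw sociometric count matrix.
#' @return data.frame of class `davids_scores` with columns `individual_id`,
#'   `w`, `w2`, `l`, `l2`, `ds`, `nds`.
#' @export
davids_scores <- function(x) {
  d <- as_dij(x)
  D <- d$D
  N <- nrow(D)
  if (N < 2) domain_error("David's scores require at least 2 individuals")
  w <- rowSums(D)
  w2 <- as.vector(D %*% w)
  l <- colSums(D)
  l2 <- as.vector(t(D) %*% l)
  ds <- w + w2 - l - l2
  nds <- (ds + N * (N - 1) / 2) / N
  structure(
    data.frame(individual_id = d$ids, w = w, w2 = w2, l = l, l2 = l2,
               ds = ds, nds = nds, row.names = NULL),
    class = c("davids_scores", "data.frame")
  )
}

#' Rank order from normalized David's scores
#'
#' Individuals are ranked by descending NDS; exact ties are broken
#' lexicographically by id and flagged.
#'
#' @param scores a `davids_scores` data.frame.
#' @return data.frame with `individual_id`, `nds`, `position` (1 = top) and
#'   `tied` (TRUE when the NDS is shared with another individual).
#' @export
rank_order <- function(scores) {
  o <- order(-scores$nds, scores$individual_id)
  out <- data.frame(individual_id = scores$individual_id[o],
                    nds = scores$nds[o],
                    position = seq_along(o))
  out$tied <- duplicated(out$nds) | duplicated(out$nds, fromLast = TRUE)
  out
}

# |OLS slope| of NDS against descending rank positions 1..N
steepness_value <- function(nds) {
  nds <- sort(nds, decreasing = TRUE)
  pos <- seq_along(nds)
  abs(sum((pos - mean(pos)) * (nds - mean(nds))) / sum((pos - mean(pos))^2))
}

check_randomizations <- function(n_randomizations) {
  if (!is.numeric(n_randomizations) || length(n_randomizations) != 1 ||
      n_randomizations < 1)
    config_error("n_randomizations must be a positive integer")
  if (n_randomizations < 100)
    warning("fewer than 100 randomizations gives a coarse p-value",
            call. = FALSE)
  as.integer(n_randomizations)
}

#' Hierarchy steepness with randomization test
#'
#' Steepness is the absolute slope of the ordinary least-squares regression
#' of NDS on the descending rank positions 1..N: a measure of the power
#' differential between adjacently ranked individuals (1 in a fully decided
#' linear hierarchy, 0 when all scores are equal). The null distribution is
#' obtained by redrawing the wins of each observed dyad as
#' `Binomial(n_ij, 0.5)` and recomputing Dij, NDS and steepness; the
#' one-tailed p-value is the proportion of randomized matrices whose
#' steepness is at least the observed one.
#'
#' @param m square displacement count matrix (or `dij_matrix`).
#' @param n_randomizations number of null matrices, default 10000.
#' @param seed integer seed for the randomization stream.
#' @return object of class `steepness_test`: list with `slope`, `steepness`,
#'   `p_value`, `n_randomizations`, `seed`, `scores`.
#' @export
steepness_test <- function(m, n_randomizations = 10000, seed = NULL) {
  d <- as_dij(m)
  N <- nrow(d$D)
  if (N < 3) domain_error("steepness requires at least 3 individuals")
  n_randomizations <- check_randomizations(n_randomizations)
  scores <- davids_scores(d)
  nds <- sort(scores$nds, decreasing = TRUE)
  pos <- seq_len(N)
  slope <- sum((pos - mean(pos)) * (nds - mean(nds))) /
    sum((pos - mean(pos))^2)
  observed <- abs(slope)

  ut <- upper.tri(d$n)
  dy_n <- d$n[ut]
  active <- which(dy_n > 0)
  null_steep <- with_seed(seed, {
    vapply(seq_len(n_randomizations), function(r) {
      upper_wins <- numeric(length(dy_n))
      upper_wins[active] <- stats::rbinom(length(active), dy_n[active], 0.5)
      wins <- matrix(0, N, N, dimnames = dimnames(d$D))
      lower_wins <- matrix(0, N, N)
      wins[ut] <- upper_wins
      lower_wins[ut] <- dy_n - upper_wins
      wins <- wins + t(lower_wins)
      steepness_value(davids_scores(dyadic_dominance_index(wins))$nds)
    }, numeric(1))
  })
  p <- mean(null_steep >= observed)
  structure(list(slope = slope, steepness = observed, p_value = p,
                 n_randomizations = n_randomizations, seed = seed,
                 scores = scores),
            class = "steepness_test")
}

# Landau's h from a dominance-relation vector V (number dominated per id)
landau_h <- function(V) {
  N <- length(V)
  12 / (N^3 - N) * sum((V - (N - 1) / 2)^2)
}

#' Hierarchy linearity: Landau's h and the improved index h'
#'
#' "i dominates j" means i won strictly more of the dyad's interactions than
#' j. Landau's `h = 12/(N^3 - N) * sum_i (V_i - (N-1)/2)^2`, where `V_i` is
#' the number of individuals i dominates, equals 1 for a perfect linear order
#' and 0 for maximal intransitivity. The improved index h' accounts for
#' unknown (never-interacting) and tied dyads by resolving each at random in
#' every replicate and averaging h over replicates; for the reported `h`,
#' unknown and tied dyads contribute 0.5 to each member's `V_i`, so that
#' `h' = h` exactly when there are none. The one-tailed p-value is the
#' proportion of fully random dominance matrices (every dyad's direction a
#' fair coin) with `h >= h'`.
#'
#' @inheritParams steepness_test
#' @return object of class `linearity_test`: list with `h`, `h_prime`, `u`
#'   (number of unknown dyads), `n_tied`, `p_value`, `n_randomizations`,
#'   `seed`.
#' @export
linearity_test <- function(m, n_randomizations = 10000, seed = NULL) {
  m <- check_sociometric(m)
  diag(m) <- 0
  N <- nrow(m)
  if (N < 3) domain_error("linearity requires at least 3 individuals")
  n_randomizations <- check_randomizations(n_randomizations)
  n <- m + t(m)
  ut <- upper.tri(m)
  i_idx <- row(m)[ut]
  j_idx <- col(m)[ut]
  wins_i <- m[ut]
  wins_j <- t(m)[ut]
  n_dy <- wins_i + wins_j
  unknown <- n_dy == 0
  tied <- !unknown & wins_i == wins_j
  random_dyads <- which(unknown | tied)
  u <- sum(unknown)

  # known contribution to V, with 0.5 credit for randomized dyads
  V_known <- numeric(N)
  dec_i <- !unknown & !tied & wins_i > wins_j
  dec_j <- !unknown & !tied & wins_j > wins_i
  V_known <- V_known +
    tabulate(i_idx[dec_i], N) + tabulate(j_idx[dec_j], N)
  V_half <- V_known + 0.5 * (tabulate(i_idx[random_dyads], N) +
                             tabulate(j_idx[random_dyads], N))
  h_base <- landau_h(V_half)

  res <- with_seed(seed, {
    if (length(random_dyads) == 0) {
      rep(landau_h(V_known), n_randomizations)
    } else {
      ri <- i_idx[random_dyads]
      rj <- j_idx[random_dyads]
      vapply(seq_len(n_randomizations), function(r) {
        bits <- stats::rbinom(length(random_dyads), 1, 0.5)
        V <- V_known + tabulate(ri[bits == 1], N) + tabulate(rj[bits == 0], N)
        landau_h(V)
      }, numeric(1))
    }
  })
  h_prime <- mean(res)

  null_seed <- if (is.null(seed)) NULL else seed + 1L
  all_i <- i_idx
  all_j <- j_idx
  null_h <- with_seed(null_seed, {
    vapply(seq_len(n_randomizations), function(r) {
      bits <- stats::rbinom(length(all_i), 1, 0.5)
      V <- tabulate(all_i[bits == 1], N) + tabulate(all_j[bits == 0], N)
      landau_h(V)
    }, numeric(1))
  })
  p <- mean(null_h >= h_prime)
  structure(list(h = h_base, h_prime = h_prime, u = u, n_tied = sum(tied),
                 p_value = p, n_randomizations = n_randomizations,
                 seed = seed),
            class = "linearity_test")
}

#' Directional consistency index
#'
#' `DCI = sum(H - L) / sum(H + L)` over observed dyads, where H and L are
#' the interaction counts in the dyad's more and less frequent direction.
#' 1 means all dyads interact in one direction only; 0 means every dyad is
#' exactly tied. Unknown dyads are excluded.
#'
#' @param m square sociometric count matrix.
#' @return the DCI, a number in `[0, 1]`.
#' @export
directional_consistency <- function(m) {
  m <- check_sociometric(m)
  diag(m) <- 0
  ut <- upper.tri(m)
  a <- m[ut]
  b <- t(m)[ut]
  known <- (a + b) > 0
  if (!any(known))
    domain_error("directional consistency undefined: all dyads unknown")
  H <- pmax(a, b)[known]
  L <- pmin(a, b)[known]
  sum(H - L) / sum(H + L)
}

#' Full dominance-hierarchy summary
#'
#' Convenience wrapper computing the Dij matrix, David's scores, rank order,
#' steepness and linearity randomization tests and the directional
#' consistency index from one displacement matrix.
#'
#' @inheritParams steepness_test
#' @return object of class `dominance_summary`.
#' @export
dominance_summary <- function(m, n_randomizations = 10000, seed = NULL) {
  m <- check_sociometric(m)
  d <- dyadic_dominance_index(m)
  scores <- davids_scores(d)
  ut <- upper.tri(d$n)
  n_unknown <- sum(d$n[ut] == 0)
  structure(list(
    matrix = m,
    dij = d,
    scores = scores,
    ranks = rank_order(scores),
    steepness = steepness_test(d, n_randomizations, seed),
    linearity = linearity_test(m, n_randomizations,
                               if (is.null(seed)) NULL else seed + 2L),
    dci = directional_consistency(m),
    n_dyads = sum(ut),
    n_unknown = n_unknown,
    n_interactions = sum(m)
  ), class = "dominance_summary")
}

#' @export
print.dominance_summary <- function(x, ...) {
  cat("Dominance hierarchy summary\n")
  cat(sprintf("  %d individuals, %d interactions, %d/%d unknown dyads\n",
              nrow(x$matrix), x$n_interactions, x$n_unknown, x$n_dyads))
  cat(sprintf("  linearity    h' = %.3f (h = %.3f, u = %d), p = %.4g\n",
              x$linearity$h_prime, x$linearity$h, x$linearity$u,
              x$linearity$p_value))
  cat(sprintf("  steepness    %.3f, p = %.4g\n",
              x$steepness$steepness, x$steepness$p_value))
  cat(sprintf("  directional consistency (DCI) = %.3f\n", x$dci))
  cat("  rank order: ",
      paste(x$ranks$individual_id, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' @export
print.steepness_test <- function(x, ...) {
  cat(sprintf("Hierarchy steepness: %.4f (slope %.4f), p = %.4g (%d randomizations)\n",
              x$steepness, x$slope, x$p_value, x$n_randomizations))
  invisible(x)
}

#' @export
print.linearity_test <- function(x, ...) {
  cat(sprintf("Linearity: h' = %.4f (h = %.4f, %d unknown, %d tied dyads), p = %.4g (%d randomizations)\n",
              x$h_prime, x$h, x$u, x$n_tied, x$p_value, x$n_randomizations))
  invisible(x)
}
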
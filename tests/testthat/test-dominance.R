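test_that("displacement matrix counts directed events and honors filters", {
  log <- rbind(
    event_row("displacement", "A", "B", 1),
    event_row("displacement", "A", "B", 2),
    event_row("displacement", "A", "B", 3),
    event_row("displacement", "B", "A", 4),
    event_row("displacement", "A", "C", 5, season = "2"),
    event_row("groom", "A", "B", 6, 30)
  )
  m <- displacement_matrix(log, season = "1", ids = c("A", "B"))
  expect_equal(m["A", "B"], 3)
  expect_equal(m["B", "A"], 1)
  expect_equal(sum(m), 4) # season-2 event and grooming excluded

  zero <- displacement_matrix(log[log$behavior == "groom", ],
                              ids = c("A", "B", "C"))
  expect_true(all(zero == 0))
})

test_that("Dij shrinks win proportions toward 0.5 and is antisymmetric", {
  m <- counts_matrix(c("A", "B"), list(list("A", "B", 8), list("B", "A", 2)))
  d <- dyadic_dominance_index(m)
  expect_equal(d$D["A", "B"], 0.8 - 0.3 / 11) # 0.772727...
  expect_equal(d$D["B", "A"], 1 - d$D["A", "B"])

  tie <- counts_matrix(c("A", "B"), list(list("A", "B", 1), list("B", "A", 1)))
  expect_equal(dyadic_dominance_index(tie)$D["A", "B"], 0.5)

  unknown <- counts_matrix(c("A", "B", "C"), list(list("A", "B", 2)))
  expect_equal(dyadic_dominance_index(unknown)$D["A", "C"], 0.5)
  expect_equal(dyadic_dominance_index(unknown)$D["C", "A"], 0.5)
})

test_that("David's scores match the hand-computed N=3 perfect hierarchy", {
  # fully decided Dij (every dominant's Dij = 1 exactly)
  ids <- c("A", "B", "C")
  D <- matrix(0, 3, 3, dimnames = list(ids, ids))
  D["A", "B"] <- D["A", "C"] <- D["B", "C"] <- 1
  dij <- structure(list(D = D, n = (D + t(D)) * 4, ids = ids),
                   class = "dij_matrix")
  sc <- davids_scores(dij)
  expect_equal(sc$ds, c(3, 0, -3))
  expect_equal(sc$nds, c(2, 1, 0))

  flat <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  sc0 <- davids_scores(flat)
  expect_equal(sc0$ds, rep(0, 3))
  expect_equal(sc0$nds, rep(1, 3))

  expect_error(davids_scores(matrix(0, 1, 1, dimnames = list("A", "A"))),
               "at least 2")
})

test_that("DS sums to zero and NDS stays in range on random matrices", {
  withr::with_seed(7, {
    for (i in 1:100) {
      N <- sample(3:9, 1)
      ids <- sprintf("I%02d", 1:N)
      m <- matrix(rpois(N * N, 2), N, N, dimnames = list(ids, ids))
      diag(m) <- 0
      sc <- davids_scores(m)
      expect_equal(sum(sc$ds), 0, tolerance = 1e-10)
      expect_true(all(sc$nds >= 0 & sc$nds <= N - 1))
      expect_equal(mean(sc$nds), (N - 1) / 2, tolerance = 1e-10)
    }
  })
})

test_that("outputs are equivariant to relabeling individuals", {
  withr::with_seed(11, {
    ids <- c("A", "B", "C", "D", "E")
    m <- matrix(rpois(25, 3), 5, 5, dimnames = list(ids, ids))
    diag(m) <- 0
    perm <- c("D", "A", "E", "C", "B")
    mp <- m[perm, perm]
    sc <- davids_scores(m)
    scp <- davids_scores(mp)
    expect_equal(scp$nds[match(ids, scp$individual_id)],
                 sc$nds[match(ids, sc$individual_id)])
    expect_equal(directional_consistency(m), directional_consistency(mp))
    expect_equal(rank_order(sc)$individual_id, rank_order(scp)$individual_id)
  })
})

test_that("rank order sorts by descending NDS, breaking ties by id", {
  sc <- structure(data.frame(individual_id = c("A", "B", "C"),
                             nds = c(2, 1, 0)),
                  class = c("davids_scores", "data.frame"))
  expect_equal(rank_order(sc)$individual_id, c("A", "B", "C"))
  expect_false(any(rank_order(sc)$tied))

  sc$nds <- c(1, 2, 2)
  ro <- rank_order(sc)
  expect_equal(ro$individual_id, c("B", "C", "A"))
  expect_equal(ro$tied, c(TRUE, TRUE, FALSE))
})

test_that("steepness is 1 on the perfect N=3 hierarchy and 0 when flat", {
  expect_warning(
    res <- steepness_test(
      counts_matrix(c("A", "B", "C"),
                    list(list("A", "B", 50), list("A", "C", 50),
                         list("B", "C", 50))),
      n_randomizations = 50, seed = 1),
    "coarse")
  # Dij with n=50: 1 - 0.5/51; NDS slope slightly below 1
  expect_equal(res$steepness, 1, tolerance = 0.05)
  # with exactly decided Dij the slope of NDS (2,1,0) on positions (1,2,3)
  # is exactly -1
  expect_equal(steepness_value(c(2, 1, 0)), 1)

  flat <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(steepness_value(davids_scores(flat)$nds), 0)
  expect_error(steepness_test(perfect3(), n_randomizations = 0), "positive")
})

test_that("steepness randomization p is reproducible for a given seed", {
  m <- default_study()
  m1 <- displacement_matrix(m$study$events, season = "1",
                            ids = m$roster$individual_id)
  a <- steepness_test(m1, n_randomizations = 200, seed = 99)
  b <- steepness_test(m1, n_randomizations = 200, seed = 99)
  expect_identical(a$p_value, b$p_value)
  l1 <- linearity_test(m1, n_randomizations = 200, seed = 99)
  l2 <- linearity_test(m1, n_randomizations = 200, seed = 99)
  expect_identical(l1$h_prime, l2$h_prime)
  expect_identical(l1$p_value, l2$p_value)
})

test_that("Landau's h is 1 for a perfect order and 0 for a cycle", {
  res <- linearity_test(perfect3(), n_randomizations = 100, seed = 1)
  expect_equal(res$h, 1)
  expect_equal(res$h_prime, 1) # no unknown or tied dyads
  expect_equal(res$u, 0)

  cycle <- counts_matrix(c("A", "B", "C"),
                         list(list("A", "B", 2), list("B", "C", 2),
                              list("C", "A", 2)))
  res2 <- linearity_test(cycle, n_randomizations = 100, seed = 1)
  expect_equal(res2$h, 0)
  expect_equal(res2$h_prime, 0)
})

test_that("h' matches exhaustive enumeration over unknown-dyad resolutions", {
  # N = 5 with 4 unknown dyads; enumerate all 2^4 equally likely resolutions
  ids <- LETTERS[1:5]
  m <- counts_matrix(ids, list(
    list("A", "B", 3), list("A", "C", 2), list("B", "C", 4),
    list("C", "D", 1), list("D", "E", 2), list("A", "D", 1)
  ))
  # unknown dyads: A-E, B-D, B-E, C-E
  unknown <- list(c("A", "E"), c("B", "D"), c("B", "E"), c("C", "E"))
  base_V <- c(A = 3, B = 1, C = 1, D = 1, E = 0)
  landau <- function(V) 12 / (5^3 - 5) * sum((V - 2)^2)
  h_all <- numeric(0)
  for (bits in 0:(2^4 - 1)) {
    V <- base_V
    for (k in 1:4) {
      pair <- unknown[[k]]
      winner <- if (bitwAnd(bits, bitwShiftL(1L, k - 1L)) > 0) pair[1] else pair[2]
      V[winner] <- V[winner] + 1
    }
    h_all <- c(h_all, landau(V))
  }
  exact <- mean(h_all)

  # closed-form expectation: h (0.5 credit for random dyads) + 6u/(N^3 - N)
  res <- linearity_test(m, n_randomizations = 4000, seed = 3)
  expect_equal(res$u, 4)
  expect_equal(res$h + 6 * res$u / (5^3 - 5), exact, tolerance = 1e-12)
  mc_se <- sd(h_all) / sqrt(4000)
  expect_lt(abs(res$h_prime - exact), 3 * mc_se + 1e-12)
})

test_that("directional consistency follows its definition", {
  uni <- counts_matrix(c("A", "B", "C"),
                       list(list("A", "B", 4), list("B", "C", 2)))
  expect_equal(directional_consistency(uni), 1)

  two <- counts_matrix(c("A", "B", "C", "D"),
                       list(list("A", "B", 5), list("C", "D", 3),
                            list("D", "C", 1)))
  expect_equal(directional_consistency(two), 7 / 9)

  tied <- counts_matrix(c("A", "B"), list(list("A", "B", 2), list("B", "A", 2)))
  expect_equal(directional_consistency(tied), 0)

  none <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(directional_consistency(none), "all dyads unknown")
})

test_that("dense observation with perfect consistency recovers the latent order", {
  cfg <- small_config(seed = 5, hours = 8)
  g <- generate_group(cfg)
  st <- simulate_study(g$roster, g$truth,
                       effect_config(consistency = 1, displacement_rate = 0.5),
                       cfg)
  m <- displacement_matrix(st$events, season = "1",
                           ids = g$roster$individual_id)
  expect_equal(directional_consistency(m), 1)
  recovered <- rank_order(davids_scores(m))$individual_id
  expect_equal(recovered, names(sort(g$truth$latent_rank)))
})
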
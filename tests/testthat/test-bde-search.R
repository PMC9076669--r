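test_that("BDeu score matches the Beta-Binomial closed form", {
  ds <- discrete_dataset("A", 2, matrix(c(0L, 1L), nrow = 1))
  # ln[(G(1)/G(3)) * (G(1.5)/G(0.5))^2] = ln(1/8)
  expect_equal(bde_score(dag("A"), ds, ess = 1), log(1 / 8),
               tolerance = 1e-9)
})

test_that("empty dataset scores 0 and unknown nodes error", {
  ds0 <- discrete_dataset(c("A", "B"), c(2, 2),
                          matrix(integer(0), nrow = 2, ncol = 0))
  expect_equal(bde_score(dag(c("A", "B")), ds0), 0)
  ds <- discrete_dataset(c("A", "B"), c(2, 2),
                         matrix(c(0L, 1L, 1L, 0L), nrow = 2))
  expect_error(bde_score(dag(c("A", "Z")), ds), "absent")
})

test_that("Markov-equivalent DAGs score identically", {
  set.seed(14)
  dags3 <- enumerate_all_dags(3, c("A", "B", "C"))
  for (rep in 1:5) {
    ds <- discrete_dataset(c("A", "B", "C"), c(3, 3, 3),
                           matrix(sample(0:2, 3 * 60, TRUE), nrow = 3))
    scores <- vapply(dags3, bde_score, numeric(1), data = ds)
    classes <- vapply(dags3, equivalence_class_key, character(1))
    for (cl in unique(classes)) {
      s <- scores[classes == cl]
      expect_lt(diff(range(s)) / max(abs(s)), 1e-6)
    }
    # two-node equivalence at tight tolerance
    s_ab <- bde_score(dag(c("A", "B"), rbind(c("A", "B"))), ds)
    s_ba <- bde_score(dag(c("A", "B"), rbind(c("B", "A"))), ds)
    expect_equal(s_ab, s_ba, tolerance = 1e-9)
  }
})

test_that("the score decomposes over node families", {
  set.seed(15)
  ds <- discrete_dataset(c("A", "B", "C", "D"), rep(2, 4),
                         matrix(sample(0:1, 4 * 80, TRUE), nrow = 4))
  g1 <- dag(c("A", "B", "C", "D"), rbind(c("A", "B"), c("C", "D")))
  g2 <- dag(c("A", "B", "C", "D"), rbind(c("A", "B"), c("A", "D"), c("C", "D")))
  # changing D's parent set must shift the total by D's family terms only
  fam_d1 <- bde_score(dag(c("C", "D"), rbind(c("C", "D"))), ds) -
    bde_score(dag("C"), ds)
  fam_d2 <- bde_score(dag(c("A", "C", "D"), rbind(c("A", "D"), c("C", "D"))), ds) -
    bde_score(dag(c("A", "C")), ds)
  expect_equal(bde_score(g2, ds) - bde_score(g1, ds), fam_d2 - fam_d1,
               tolerance = 1e-9)
})

test_that("true edges raise the score, spurious edges lower it", {
  wins_true <- 0
  wins_null <- 0
  for (seed in 1:20) {
    g <- dag(c("A", "B", "C"), rbind(c("A", "B")))
    bn <- strong_dependence_bn(g, c(A = 3, B = 3, C = 3), noise = 0.1)
    ds <- sample_discrete(bn, 1000, seed = seed)
    empty <- dag(c("A", "B", "C"))
    s0 <- bde_score(empty, ds)
    if (bde_score(dag(c("A", "B", "C"), rbind(c("A", "B"))), ds) > s0) {
      wins_true <- wins_true + 1
    }
    if (bde_score(dag(c("A", "B", "C"), rbind(c("A", "C"))), ds) < s0) {
      wins_null <- wins_null + 1
    }
  }
  expect_gte(wins_true, 18)
  expect_gte(wins_null, 18)
})

test_that("compiled search scores agree with the R reference scorer", {
  g <- recovery_truth()
  bn <- strong_dependence_bn(g, setNames(rep(3, 6), g$nodes), noise = 0.1)
  ds <- sample_discrete(bn, 200, seed = 3)
  top <- simulated_annealing_search(ds, search_config(n_proposals = 5000,
                                                      seed = 2))
  for (net in top[seq_len(min(20, length(top)))]) {
    expect_equal(net$log_score, bde_score(net$dag, ds), tolerance = 1e-9)
  }
})

test_that("zero-temperature search is a hill climb", {
  g <- dag(c("A", "B", "C"), rbind(c("A", "B")))
  bn <- strong_dependence_bn(g, c(A = 3, B = 3, C = 3), noise = 0.1)
  ds <- sample_discrete(bn, 500, seed = 6)
  cfg <- search_config(n_proposals = 2000, t0 = 0, seed = 7)
  top <- simulated_annealing_search(ds, cfg, track_trajectory = TRUE)
  traj <- attr(top, "trajectory")
  expect_true(all(diff(traj) >= 0))
})

test_that("search is deterministic and handles a zero budget", {
  g <- dag(c("A", "B", "C"), rbind(c("A", "B")))
  bn <- strong_dependence_bn(g, c(A = 3, B = 3, C = 3), noise = 0.1)
  ds <- sample_discrete(bn, 300, seed = 8)
  cfg <- search_config(n_proposals = 20000, seed = 99)
  t1 <- simulated_annealing_search(ds, cfg)
  t2 <- simulated_annealing_search(ds, cfg)
  expect_identical(lapply(t1, function(x) x$dag$edges),
                   lapply(t2, function(x) x$dag$edges))
  expect_equal(vapply(t1, `[[`, numeric(1), "log_score"),
               vapply(t2, `[[`, numeric(1), "log_score"))

  t0 <- simulated_annealing_search(ds, search_config(n_proposals = 0, seed = 1))
  expect_length(t0, 1)
  expect_equal(nrow(t0[[1]]$dag$edges), 0)
})

test_that("search output is a subset of the exhaustive score landscape", {
  g <- dag(c("A", "B", "C"), rbind(c("A", "B")))
  bn <- strong_dependence_bn(g, c(A = 3, B = 3, C = 3), noise = 0.1)
  ds <- sample_discrete(bn, 400, seed = 13)
  all_scores <- sort(vapply(enumerate_all_dags(3, c("A", "B", "C")),
                            bde_score, numeric(1), data = ds))
  top <- simulated_annealing_search(ds, search_config(n_proposals = 3e4,
                                                      seed = 5))
  for (net in top) {
    expect_true(any(abs(all_scores - net$log_score) < 1e-6))
  }
  # and the best found is the global optimum here
  expect_equal(top[[1]]$log_score, max(all_scores), tolerance = 1e-9)
})

test_that("run-level consensus applies the strict majority rule", {
  nodes <- c("A", "B", "C")
  net <- function(edges) list(dag = dag(nodes, edges), log_score = 0)
  # arc B->C in 51 of 100 networks, A->B in all 100
  tops <- c(replicate(51, net(rbind(c("A", "B"), c("B", "C"))), simplify = FALSE),
            replicate(49, net(rbind(c("A", "B"))), simplify = FALSE))
  cons <- consensus_of_top(tops, 0.5)
  keys <- paste(cons$edges[, 1], cons$edges[, 2])
  expect_setequal(keys, c("A B", "B C"))
  expect_equal(cons$confidence[match("A B", keys)], 1.0)
  expect_equal(cons$confidence[match("B C", keys)], 0.51)
  # an arc in exactly half the networks is excluded (strict majority)
  half <- c(replicate(50, net(rbind(c("A", "B"))), simplify = FALSE),
            replicate(50, list(dag = dag(nodes), log_score = 0),
                      simplify = FALSE))
  cons2 <- consensus_of_top(half, 0.5)
  expect_equal(nrow(cons2$edges), 0)
})
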
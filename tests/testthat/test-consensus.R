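fixed_net <- function(nodes, edges) digraph(nodes, edges)

test_that("grouped arc counting is exact", {
  nodes <- c("A", "B", "C")
  same <- replicate(100, fixed_net(nodes, rbind(c("A", "B"))), simplify = FALSE)
  w <- group_and_weight(same, 100)
  expect_length(w, 1)
  expect_equal(w[[1]]$arcs$weight, 100L)

  mixed <- c(replicate(73, fixed_net(nodes, rbind(c("A", "B"))),
                       simplify = FALSE),
             replicate(27, fixed_net(nodes, NULL), simplify = FALSE))
  w2 <- group_and_weight(mixed, 100)
  expect_equal(w2[[1]]$arcs$weight, 73L)
  # an arc absent from a group is simply not listed
  expect_false("B" %in% w2[[1]]$arcs$parent)
  expect_error(group_and_weight(mixed[1:99], 100), "divisible")
})

test_that("arc selection is inclusive at the threshold boundary", {
  nodes <- c("A", "B", "C")
  aw <- function(group, df) structure(list(group = group, group_size = 100,
                                           arcs = df),
                                      class = "arc_weights")
  mats <- list(aw(1, data.frame(parent = c("A", "B"), child = c("B", "C"),
                                weight = c(50L, 49L))),
               aw(2, data.frame(parent = c("A", "B"), child = c("B", "C"),
                                weight = c(50L, 49L))))
  fn <- select_arcs(mats, 50, nodes = nodes)
  expect_equal(nrow(fn$arcs), 1)                 # mean 50 selected
  expect_equal(fn$arcs$parent, "A")
  expect_equal(fn$arcs$mean_weight, 50)
  expect_setequal(fn$isolated, "C")              # B linked via A->B
  fn49 <- select_arcs(mats, 49, nodes = nodes)   # mean 49 passes at 49
  expect_equal(nrow(fn49$arcs), 2)
  # mean weight across ALL groups, absent arcs count 0
  mats2 <- list(mats[[1]], aw(2, data.frame(parent = character(0),
                                            child = character(0),
                                            weight = integer(0))))
  fn2 <- select_arcs(mats2, 50, nodes = nodes)
  expect_equal(nrow(fn2$arcs), 0)                # mean 25 < 50
  expect_setequal(fn2$isolated, nodes)
})

test_that("raising the threshold never adds arcs", {
  set.seed(44)
  nodes <- paste0("V", 1:5)
  nets <- replicate(40, {
    e <- NULL
    for (i in 1:4) if (runif(1) < 0.6) e <- rbind(e, c(nodes[i], nodes[i + 1]))
    fixed_net(nodes, e)
  }, simplify = FALSE)
  w <- group_and_weight(nets, 10)
  prev <- NULL
  for (th in c(2, 4, 6, 8, 10)) {
    sel <- select_arcs(w, th, nodes = nodes)
    keys <- paste(sel$arcs$parent, sel$arcs$child)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
})

test_that("single-group selection is invariant to run order", {
  set.seed(45)
  nodes <- c("A", "B", "C")
  nets <- replicate(20, {
    e <- NULL
    if (runif(1) < 0.5) e <- rbind(e, c("A", "B"))
    if (runif(1) < 0.5) e <- rbind(e, c("B", "C"))
    fixed_net(nodes, e)
  }, simplify = FALSE)
  w1 <- group_and_weight(nets, 20)
  w2 <- group_and_weight(nets[sample(20)], 20)
  s1 <- select_arcs(w1, 8, nodes = nodes)
  s2 <- select_arcs(w2, 8, nodes = nodes)
  expect_equal(s1$arcs, s2$arcs)
})

test_that("bidirectional conflicts keep the heavier direction", {
  aw <- structure(list(group = 1, group_size = 10,
                       arcs = data.frame(parent = c("A", "B", "C", "D"),
                                         child = c("B", "A", "D", "C"),
                                         weight = c(9L, 7L, 6L, 6L))),
                  class = "arc_weights")
  fn <- suppressMessages(select_arcs(list(aw), 5, nodes = c("A", "B", "C", "D")))
  keys <- paste(fn$arcs$parent, fn$arcs$child)
  expect_true("A B" %in% keys)      # 9 beats 7
  expect_false("B A" %in% keys)
  expect_true("C D" %in% keys)      # tie -> lexicographically smaller parent
  expect_false("D C" %in% keys)
  expect_message(select_arcs(list(aw), 5, nodes = c("A", "B", "C", "D")),
                 "tie")
})

test_that("ensemble runs are reproducible and composable", {
  g <- dag(c("A", "B", "C"), rbind(c("A", "B")))
  bn <- strong_dependence_bn(g, c(A = 3, B = 3, C = 3), noise = 0.05)
  ds <- sample_discrete(bn, 300, seed = 2)
  cfg <- search_config(n_proposals = 2e4)
  e1 <- run_ensemble(ds, cfg, n_runs = 4, master_seed = 7)
  e2 <- run_ensemble(ds, cfg, n_runs = 4, master_seed = 7)
  expect_identical(lapply(e1, `[[`, "edges"), lapply(e2, `[[`, "edges"))

  # a 1-run ensemble equals a direct search + consensus with the sub-seed
  single <- run_ensemble(ds, cfg, n_runs = 1, master_seed = 7)
  cfg1 <- cfg
  cfg1$seed <- derive_seed(7, 1)
  direct <- consensus_of_top(simulated_annealing_search(ds, cfg1), 0.5)
  expect_identical(single[[1]]$edges, direct$edges)
})

test_that("ensemble members recover a strong 2-variable dependence", {
  g <- dag(c("A", "B", "C"), rbind(c("A", "B")))
  bn <- strong_dependence_bn(g, c(A = 3, B = 3, C = 3), noise = 0.05)
  ds <- sample_discrete(bn, 500, seed = 4)
  # within-run fraction 0.3: score equivalence splits a reversible arc's
  # directions near 50/50, so a strict-majority cut can drop the adjacency
  ens <- run_ensemble(ds, search_config(n_proposals = 2e4), n_runs = 20,
                      master_seed = 31, majority_fraction = 0.3)
  with_ab <- vapply(ens, function(net) {
    any(undirected_key(net$edges[, 1], net$edges[, 2]) == "A|B")
  }, logical(1))
  expect_gte(mean(with_ab), 0.95)
})

test_that("the scaled ensemble recovers the planted skeleton", {
  g <- recovery_truth()
  bn <- strong_dependence_bn(g, setNames(rep(3, 6), g$nodes), noise = 0.05)
  ds <- sample_discrete(bn, 500, seed = 22)
  cfg <- search_config(n_proposals = 1e5)
  f1 <- vapply(1:3, function(ms) {
    ens <- run_ensemble(ds, cfg, n_runs = 20, master_seed = ms)
    w <- group_and_weight(ens, 5)
    fn <- select_arcs(w, 2.5, nodes = ds$variables)
    skeleton_f1(g, fn$arcs)
  }, numeric(1))
  expect_gte(median(f1), 0.8)
})
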
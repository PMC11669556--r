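# MAP queries, interventions, scenarios, pathway strengths.

test_that("single-node MAP is the posterior mode; ties go lexicographic", {
  g <- unroll(rand_net(6, seed = 201))
  ev <- list(`V05@0` = g$states[["V05@0"]][1L])
  m <- map_query(g, ev, "V03@0")
  post <- posterior(g, ev, "V03@0")$marginals[["V03@0"]]
  expect_equal(unname(m$assignment["V03@0"]), names(post)[which.max(post)])
  expect_equal(m$prob, max(post), tolerance = 1e-10)

  # two symmetric equally likely configurations
  v <- dbn_variable("X", c("a", "b"), temporal = FALSE)
  gu <- unroll(network_from_structure(dbn_structure(list(v), NULL, 1L)))
  mu <- map_query(gu, list(), "X@0", k = 2L)
  expect_equal(unname(mu$assignment["X@0"]), "a")
  expect_equal(mu$top$prob, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("marginal MAP matches exhaustive argmax on random networks", {
  for (seed in 1:8) {
    set.seed(400 + seed)
    g <- unroll(rand_net(sample(5:8, 1L), seed = 400 + seed))
    en <- enum_all(g)
    ev <- rand_evidence(g, n_hard = 1L, n_soft = 1L)
    q <- setdiff(g$nodes$id, names(ev))
    m <- map_query(g, ev, q)
    o <- enum_map(g, ev, sort(q), en)
    expect_equal(m$prob, o$prob, tolerance = 1e-9)
    expect_identical(unname(m$assignment[sort(q)]), unname(o$assignment))
  }
})

test_that("top-k enumerates the full joint with probabilities summing to 1", {
  g <- unroll(rand_net(4, seed = 210))
  q <- g$nodes$id
  kfull <- prod(vapply(g$states[q], length, 0L))
  m <- map_query(g, list(), q, k = kfull)
  expect_equal(nrow(m$top), kfull)
  expect_equal(sum(m$top$prob), 1, tolerance = 1e-6)
  expect_true(all(diff(m$top$prob) <= 1e-12))
})

test_that("do-operator surgery gives interventional, not observational, answers", {
  # confounded triple U -> X, U -> Y, X -> Y with hand-built tables
  s2 <- c("s0", "s1")
  vs <- lapply(c("U", "X", "Y"), function(n) dbn_variable(n, s2, temporal = FALSE))
  st <- dbn_structure(vs, data.frame(parent = c("U", "U", "X"),
                                     child = c("X", "Y", "Y"), lag = 0L), 1L)
  pu <- c(0.3, 0.7)
  px <- matrix(c(0.9, 0.1, 0.2, 0.8), 2L, byrow = TRUE)
  py <- matrix(c(0.85, 0.15, 0.4, 0.6, 0.5, 0.5, 0.05, 0.95), 4L, byrow = TRUE)
  net <- dbn_network(st, list(
    U = list(transition = dbn_cpt("U", s2, NULL, list(), matrix(pu, 1L))),
    X = list(transition = dbn_cpt("X", s2, data.frame(parent = "U", lag = 0L),
                                  list(s2), px)),
    Y = list(transition = dbn_cpt("Y", s2,
                                  data.frame(parent = c("U", "X"), lag = c(0L, 0L)),
                                  list(s2, s2), py))))
  # hand: P(Y | do(X = s1)) = sum_u P(u) P(Y | u, X = s1); rows of py are
  # (U, X) configurations with U varying fastest
  hand <- pu[1L] * py[3L, ] + pu[2L] * py[4L, ]
  do_y <- counterfactual_query(net, list(`X@0` = "s1"), "Y@0")
  expect_equal(unname(do_y), hand, tolerance = 1e-10)
  obs <- posterior(unroll(net), list(`X@0` = "s1"), "Y@0")$marginals[["Y@0"]]
  expect_gt(abs(obs[["s1"]] - do_y[["s1"]]), 0.05)

  # intervened node becomes a point mass; surgery is idempotent
  g1 <- intervene(net, list(`X@0` = "s1"))
  expect_equal(unname(posterior(g1, list(), "X@0")$marginals[["X@0"]]), c(0, 1))
  g2 <- intervene(g1, list(`X@0` = "s1"))
  expect_identical(g1$factors, g2$factors)

  # intervening on a childless, parentless node changes nothing else
  iso <- dbn_structure(c(vs, list(dbn_variable("Z", s2, temporal = FALSE))),
                       st$arcs, 1L)
  net_iso <- dbn_network(iso, c(net$tables, list(
    Z = list(transition = dbn_cpt("Z", s2, NULL, list(), matrix(c(0.6, 0.4), 1L))))))
  before <- posterior(unroll(net_iso), list(), c("U@0", "X@0", "Y@0"))
  after <- posterior(intervene(net_iso, list(`Z@0` = "s1")), list(),
                     c("U@0", "X@0", "Y@0"))
  for (id in c("U@0", "X@0", "Y@0"))
    expect_equal(before$marginals[[id]], after$marginals[[id]], tolerance = 1e-12)

  expect_error(intervene(default_truth("weak"), list(`PS@0` = "C")),
               "structurally absent")
})

test_that("interventional distributions match truncated-factorisation enumeration", {
  for (seed in 1:6) {
    set.seed(500 + seed)
    net <- rand_net(sample(5:8, 1L), seed = 500 + seed)
    g <- unroll(net)
    ids <- g$nodes$id
    xid <- sample(ids, 1L)
    yid <- sample(setdiff(ids, xid), 1L)
    xstate <- sample(g$states[[xid]], 1L)
    got <- counterfactual_query(net, stats::setNames(list(xstate), xid), yid)
    # oracle: drop X's factor, clamp X, renormalise
    en <- enum_all(g, skip = xid)
    keep <- en$grid[, xid] == match(xstate, g$states[[xid]])
    agg <- rowsum(en$p[keep], en$grid[keep, yid])
    expect_equal(unname(got), as.vector(agg / sum(agg)), tolerance = 1e-9)
  }
})

test_that("no unblocked back door means do equals conditioning", {
  chain <- motif_net("chain")
  got_do <- counterfactual_query(chain, list(`B@0` = "s1"), "C@0")
  got_obs <- posterior(unroll(chain), list(`B@0` = "s1"), "C@0")$marginals[["C@0"]]
  expect_equal(got_do, got_obs, tolerance = 1e-9)
})

test_that("do on a node with no path to the outcome returns the prior", {
  coll <- motif_net("collider")
  prior_b <- posterior(unroll(coll), list(), "B@0")$marginals[["B@0"]]
  do_b <- counterfactual_query(coll, list(`A@0` = "s0"), "B@0")
  expect_equal(do_b, prior_b, tolerance = 1e-12)
})

test_that("scenario analysis reports coherent deltas and flags", {
  net <- default_truth("strong")
  # clamping the target to its own baseline marginal is a no-op: the custom
  # clamp specifies the post-clamp distribution, so matching the baseline
  # leaves every delta at zero. The CNS baseline marginal is wave-dependent,
  # so check the identity wave by wave via the uniform-likelihood route it
  # reduces to (clamp / baseline = constant when clamp = baseline).
  g <- unroll(net)
  baselines <- lapply(0:4, function(t)
    unname(posterior(g, list(), paste0("CNS@", t))$marginals[[paste0("CNS@", t)]]))
  sc0 <- scenario_analysis(net, "CNS", "custom", c("WQ", "HS"), clamp = baselines)
  noop <- sc0$table[sc0$table$node %in% c("WQ", "HS"), ]
  expect_true(all(abs(noop$delta) < 1e-9))
  expect_true(all(noop$flag == "0"))

  sb <- scenario_analysis(net, "CNS", "best", c("HS", "FS"))
  sw <- scenario_analysis(net, "CNS", "worst", c("HS", "FS"))
  # small households raise food security which raises normal nutrition, so
  # the best case pulls P(HS = "<=6") up and the worst case down
  hb <- sb$table[sb$table$node == "HS" & sb$table$state == "<=6" & sb$table$wave >= 2, ]
  hw <- sw$table[sw$table$node == "HS" & sw$table$state == "<=6" & sw$table$wave >= 2, ]
  expect_true(all(hb$delta > 0))
  expect_true(all(hw$delta < 0))
  expect_true(all(hb$flag == "+"))
  expect_true(all(hw$flag == "-"))

  expect_error(scenario_analysis(net, "CNS", "custom", "HS", clamp = rep(0, 8)),
               "likelihood")
})

test_that("pathway strength follows the declared max-conditional convention", {
  s2 <- c("s0", "s1")
  vs <- lapply(c("A", "B", "C"), function(n) dbn_variable(n, s2, temporal = FALSE))
  st <- dbn_structure(vs, data.frame(parent = c("A", "B"), child = c("B", "C"),
                                     lag = 0L), 1L)
  pb <- matrix(c(1, 0, 0, 1), 2L, byrow = TRUE)        # B copies A
  pc_ <- matrix(c(0.5, 0.5, 0.5, 0.5), 2L, byrow = TRUE)  # C independent of B
  net <- dbn_network(st, list(
    A = list(transition = dbn_cpt("A", s2, NULL, list(), matrix(c(0.7, 0.3), 1L))),
    B = list(transition = dbn_cpt("B", s2, data.frame(parent = "A", lag = 0L),
                                  list(s2), pb)),
    C = list(transition = dbn_cpt("C", s2, data.frame(parent = "B", lag = 0L),
                                  list(s2), pc_))))
  pw <- pathway_strength(net, c("A", "B", "C"))
  expect_equal(pw$strength[pw$parent == "A"], 1)        # deterministic copy
  expect_equal(pw$strength[pw$parent == "B"], 0.5)      # uniform child
  expect_equal(pw$parent_map_state[pw$parent == "A"], "s0")
  # hand-computed conditional on a non-degenerate chain
  chain <- motif_net("chain")
  pw2 <- pathway_strength(chain, c("A", "B"))
  # A's MAP state is s1 (p = 0.55); max_b P(B | A = s1) = 0.8
  expect_equal(pw2$parent_map_state, "s1")
  expect_equal(pw2$strength, 0.8, tolerance = 1e-10)
  expect_error(pathway_strength(chain, c("A", "C")), "not in the network")
})
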
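# Structure learning: G-squared CI tests, PC skeleton/orientation,
# constraints, BIC, search-space counting.

test_that("G2 detects perfect association and respects independence", {
  set.seed(101)
  x <- sample(c("a", "b"), 1000, TRUE)
  df <- data.frame(X = x, Y = x)
  ct <- ci_test_g2(df, "X", "Y", alpha = 0.01)
  expect_false(ct$independent)
  expect_lt(ct$p_value, 1e-10)

  # unreliable tests (too few complete cases) default to independence
  df2 <- data.frame(X = c("a", "b"), Y = c("a", "b"))
  ct2 <- ci_test_g2(df2, "X", "Y")
  expect_false(ct2$reliable)
  expect_true(ct2$independent)
})

test_that("G2 type-I error rate stays near the nominal level", {
  set.seed(103)
  alpha <- 0.05
  rejections <- vapply(1:200, function(i) {
    df <- data.frame(X = sample(c("a", "b"), 10000, TRUE),
                     Y = sample(c("a", "b"), 10000, TRUE))
    !ci_test_g2(df, "X", "Y", alpha = alpha)$independent
  }, logical(1))
  expect_lte(mean(rejections), 2 * alpha)
})

test_that("a collider makes marginally independent causes dependent", {
  net <- motif_net("collider")
  d <- motif_data(net, 20000, seed = 9)
  sp <- stacked_panel(d, net$structure, max_lag = 0L)
  expect_true(ci_test_g2(sp, "A", "B", alpha = 0.01)$independent)
  expect_false(ci_test_g2(sp, "A", "B", S = "C", alpha = 0.01)$independent)
})

test_that("PC recovers motif skeletons and collider orientation from data", {
  chain <- motif_net("chain")
  p1 <- pc_learn(motif_data(chain, 8000, seed = 3), chain$structure,
                 max_lag = 0L, alpha = 0.01)
  expect_setequal(paste(p1$skeleton$a, p1$skeleton$b), c("A B", "B C"))
  expect_true("B" %in% p1$sepsets[["A\rC"]])

  coll <- motif_net("collider")
  p2 <- pc_learn(motif_data(coll, 8000, seed = 4), coll$structure,
                 max_lag = 0L, alpha = 0.01)
  vstr <- p2$arcs[p2$arcs$origin == "vstructure", ]
  expect_setequal(paste(vstr$from, vstr$to), c("A C", "B C"))
})

test_that("PC with an independence oracle recovers motif CPDAGs exactly", {
  for (kind in c("chain", "fork", "collider")) {
    net <- motif_net(kind)
    orac <- dsep_oracle(net$structure$arcs)
    p <- pc_learn(NULL, net$structure, max_lag = 0L,
                  ci_oracle = function(x, y, S) orac(x, y, S))
    if (kind == "collider") {
      expect_setequal(paste(p$skeleton$a, p$skeleton$b), c("A C", "B C"))
      directed <- p$arcs[p$arcs$origin != "fallback", ]
      expect_setequal(paste(directed$from, directed$to), c("A C", "B C"))
    } else {
      expect_setequal(paste(p$skeleton$a, p$skeleton$b), c("A B", "B C"))
      # chain and fork are Markov-equivalent: CPDAG fully undirected
      expect_equal(nrow(p$arcs[p$arcs$origin != "fallback", ]), 0L)
    }
  }
})

test_that("constraints are honoured and conflicts reported", {
  chain <- motif_net("chain")
  d <- motif_data(chain, 4000, seed = 6)
  # forbid the direction the fallback would otherwise take
  cons <- dbn_constraints(forbidden = data.frame(parent = "A", child = "B", lag = 0L))
  p <- pc_learn(d, chain$structure, max_lag = 0L, constraints = cons)
  expect_false(any(p$dag$parent == "A" & p$dag$child == "B" & p$dag$lag == 0L))
  # both directions forbidden: edge cannot appear at all
  cons2 <- dbn_constraints(forbidden = data.frame(parent = c("A", "B"),
                                                  child = c("B", "A"), lag = 0L))
  p2 <- pc_learn(d, chain$structure, max_lag = 0L, constraints = cons2)
  expect_false(any(apply(p2$skeleton, 1L, function(r) setequal(r, c("A", "B")))))
  # a required arc between marginally independent nodes survives the test
  # verdict, with a logged conflict
  coll <- motif_net("collider")
  dc <- motif_data(coll, 4000, seed = 16)
  cons3 <- dbn_constraints(required = data.frame(parent = "A", child = "B", lag = 0L))
  p3 <- pc_learn(dc, coll$structure, max_lag = 0L, constraints = cons3)
  expect_true(any(p3$dag$parent == "A" & p3$dag$child == "B"))
  expect_true(any(grepl("required edge", p3$conflicts)))
  # contradictory constraint sets are rejected outright
  expect_error(dbn_constraints(forbidden = data.frame(parent = "A", child = "B", lag = 0L),
                               required = data.frame(parent = "A", child = "B", lag = 0L)),
               "contradictory")
})

test_that("PC is deterministic and never violates temporal tiering", {
  b <- sample_cohort(cohort_config(n_subjects = 800, seed = 41, missing_rate = 0))
  st <- b$network$structure
  p1 <- pc_learn(b$complete, st, max_lag = 2L, alpha = 0.01, max_cond = 1L)
  p2 <- pc_learn(b$complete, st, max_lag = 2L, alpha = 0.01, max_cond = 1L)
  expect_identical(p1$arcs, p2$arcs)
  expect_identical(p1$tests, p2$tests)
  # inter-slice arcs always point past -> present: every lagged endpoint in
  # the final DAG appears as a parent, and the unrolled result is acyclic
  lagged <- p1$dag[p1$dag$lag > 0L, ]
  expect_true(all(lagged$lag %in% 1:2))
  learned <- pdag_to_structure(p1, st)
  expect_true(dbnpanel:::lag0_acyclic(learned))
  expect_s3_class(unroll(network_from_structure(learned)), "dbn_ground")
})

test_that("constraint files round-trip", {
  cons <- dbn_constraints(
    forbidden = data.frame(parent = c("DA", "MSW", "ME", "CS", "CA"),
                           child = c("HHS", "CS", "CS", "WQ", "MA"), lag = 0L),
    required = data.frame(parent = "PS", child = "WQ", lag = 0L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_constraints(cons, path)
  cons2 <- read_constraints(path)
  expect_equal(cons$forbidden, cons2$forbidden, ignore_attr = TRUE)
  expect_equal(cons$required, cons2$required, ignore_attr = TRUE)
})

test_that("BIC prefers the generating chain and penalises extra arcs", {
  chain <- motif_net("chain")
  d <- motif_data(chain, 20000, seed = 7)
  vars <- unname(chain$structure$variables)
  empty <- dbn_structure(vars, NULL, 1L)
  true_s <- chain$structure
  extra <- dbn_structure(vars, rbind(true_s$arcs,
                                     data.frame(parent = "A", child = "C", lag = 0L)), 1L)
  s_true <- bic_score(true_s, d)
  expect_gt(s_true, bic_score(empty, d))
  # a superfluous arc gains less than its parameter penalty
  gain <- bic_score(extra, d) - s_true
  expect_lt(gain, 0.5 * 2 * log(20000))
  # identical structures up to arc-row ordering score identically
  perm <- dbn_structure(vars, true_s$arcs[rev(seq_len(nrow(true_s$arcs))), ], 1L)
  expect_equal(bic_score(perm, d), s_true, tolerance = 1e-9)
})

test_that("graph search space counts are exact", {
  expect_equal(count_graph_structures(1), list(exponent = 0L, count = 1,
                                               count_str = "1"))
  c4 <- count_graph_structures(4)
  expect_equal(c4$exponent, 6L)
  expect_equal(c4$count, 64)
  expect_equal(c4$count_str, "64")
  # exact decimal doubling agrees with double arithmetic while it is exact
  c10 <- count_graph_structures(10)  # 2^45 < 2^53
  expect_equal(c10$count_str, sprintf("%.0f", 2^45))
})
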
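# Exact inference: posteriors vs enumeration, smoothing, soft evidence,
# record log-likelihood and anomaly scoring.

test_that("posteriors match exhaustive enumeration on random networks", {
  for (seed in 1:10) {
    set.seed(300 + seed)
    g <- unroll(rand_net(sample(5:10, 1L), seed = 300 + seed))
    en <- enum_all(g)
    ev <- rand_evidence(g)
    q <- setdiff(sample(g$nodes$id, 3L), names(ev))
    if (length(q) == 0L) q <- setdiff(g$nodes$id, names(ev))[1L]
    post <- posterior(g, ev, q)
    for (id in q) {
      expect_equal(post$marginals[[id]], enum_posterior(g, ev, id, en),
                   tolerance = 1e-10)
    }
    expect_equal(post$log_evidence, enum_log_evidence(g, ev, en),
                 tolerance = 1e-9)
    # marginalisation consistency
    for (id in q) expect_equal(sum(post$marginals[[id]]), 1, tolerance = 1e-9)
  }
})

test_that("no evidence returns prior marginals; hard evidence a point mass", {
  g <- unroll(rand_net(6, seed = 42))
  en <- enum_all(g)
  pr <- posterior(g, list(), "V03@0")
  expect_equal(pr$marginals[["V03@0"]], enum_posterior(g, list(), "V03@0", en),
               tolerance = 1e-10)
  expect_equal(pr$log_evidence, 0)
  st <- g$states[["V02@0"]][1L]
  pm <- posterior(g, stats::setNames(list(st), "V02@0"), "V02@0")$marginals[["V02@0"]]
  expect_equal(unname(pm[st]), 1)
})

test_that("conditioning on a common effect's sibling follows Bayes' rule", {
  # confounder triple A -> B, A -> C with hand-computable 2-state tables
  vs <- lapply(c("A", "B", "C"), function(n)
    dbn_variable(n, c("s0", "s1"), temporal = FALSE))
  st <- dbn_structure(vs, data.frame(parent = c("A", "A"), child = c("B", "C"),
                                     lag = 0L), 1L)
  pa <- c(0.4, 0.6)
  pb <- matrix(c(0.9, 0.1, 0.3, 0.7), 2L, byrow = TRUE)   # P(B | A)
  pc_ <- matrix(c(0.8, 0.2, 0.25, 0.75), 2L, byrow = TRUE)  # P(C | A)
  s2 <- c("s0", "s1")
  net <- dbn_network(st, list(
    A = list(transition = dbn_cpt("A", s2, NULL, list(), matrix(pa, 1L))),
    B = list(transition = dbn_cpt("B", s2, data.frame(parent = "A", lag = 0L),
                                  list(s2), pb)),
    C = list(transition = dbn_cpt("C", s2, data.frame(parent = "A", lag = 0L),
                                  list(s2), pc_))))
  g <- unroll(net)
  # hand: P(A | C = s1) = pa * pc[,2] / sum; P(B = s1 | C = s1) = sum_a P(a|c) pb[a,2]
  pa_c <- pa * pc_[, 2L]; pa_c <- pa_c / sum(pa_c)
  hand <- sum(pa_c * pb[, 2L])
  got <- posterior(g, list(`C@0` = "s1"), "B@0")$marginals[["B@0"]]
  expect_equal(unname(got["s1"]), hand, tolerance = 1e-12)
  prior_b <- sum(pa * pb[, 2L])
  expect_gt(abs(hand - prior_b), 0.01)  # dependence flows through the confounder
})

test_that("evidence chaining adds log-probabilities", {
  g <- unroll(rand_net(8, seed = 55))
  set.seed(56)
  ev1 <- rand_evidence(g, n_hard = 2L, n_soft = 0L)
  repeat {
    ev2 <- rand_evidence(g, n_hard = 2L, n_soft = 0L)
    if (!any(names(ev2) %in% names(ev1))) break
  }
  l12 <- posterior(g, c(ev1, ev2), character(0))$log_evidence
  l1 <- posterior(g, ev1, character(0))$log_evidence
  # log P(E2 | E1) computed independently by enumeration on the
  # E1-conditioned distribution
  en <- enum_all(g)
  w1 <- en$p * enum_weights(en, g, ev1)
  l2_given_1 <- log(sum(w1 / sum(w1) * enum_weights(en, g, ev2)))
  expect_equal(l12, l1 + l2_given_1, tolerance = 1e-9)
  expect_equal(l12, enum_log_evidence(g, c(ev1, ev2), en), tolerance = 1e-9)
})

test_that("uniform soft evidence is a no-op", {
  g <- unroll(rand_net(7, seed = 60))
  q <- c("V04@0", "V06@0")
  base <- posterior(g, list(), q)
  unif <- stats::setNames(
    lapply(c("V02@0", "V05@0"), function(id) rep(1, length(g$states[[id]]))),
    c("V02@0", "V05@0"))
  with_soft <- posterior(g, unif, q)
  for (id in q)
    expect_equal(base$marginals[[id]], with_soft$marginals[[id]], tolerance = 1e-10)
})

test_that("contradictory evidence signals impossible-evidence", {
  vs <- lapply(c("X", "Y"), function(n) dbn_variable(n, c("a", "b"), temporal = FALSE))
  st <- dbn_structure(vs, data.frame(parent = "X", child = "Y", lag = 0L), 1L)
  net <- dbn_network(st, list(
    X = list(transition = dbn_cpt("X", c("a", "b"), NULL, list(), matrix(c(1, 0), 1L))),
    Y = list(transition = dbn_cpt("Y", c("a", "b"), data.frame(parent = "X", lag = 0L),
                                  list(c("a", "b")), diag(2)))))
  g <- unroll(net)
  expect_error(posterior(g, list(`X@0` = "a", `Y@0` = "b"), character(0)),
               class = "dbn_impossible_evidence")
})

test_that("impute returns posteriors for missing cells only", {
  g <- unroll(rand_net(6, seed = 70))
  ids <- g$nodes$id
  full <- stats::setNames(
    vapply(ids, function(id) g$states[[id]][1L], ""), ids)
  expect_identical(impute(g, full), list())

  rec <- full
  rec[c("V02@0", "V05@0")] <- NA
  im <- impute(g, rec)
  expect_setequal(names(im), c("V02@0", "V05@0"))
  en <- enum_all(g)
  ev <- as.list(rec[!is.na(rec)])
  for (id in names(im))
    expect_equal(im[[id]], enum_posterior(g, ev, id, en), tolerance = 1e-10)
})

test_that("a deterministic copy arc imputes the copied state", {
  vs <- lapply(c("X", "Y"), function(n) dbn_variable(n, c("a", "b"), temporal = FALSE))
  st <- dbn_structure(vs, data.frame(parent = "X", child = "Y", lag = 0L), 1L)
  net <- dbn_network(st, list(
    X = list(transition = dbn_cpt("X", c("a", "b"), NULL, list(), matrix(c(.5, .5), 1L))),
    Y = list(transition = dbn_cpt("Y", c("a", "b"), data.frame(parent = "X", lag = 0L),
                                  list(c("a", "b")), diag(2)))))
  g <- unroll(net)
  im <- impute(g, c(`X@0` = "b", `Y@0` = NA))
  expect_equal(unname(im[["Y@0"]]["b"]), 1)
})

test_that("record_loglik marginalises missing cells", {
  g <- unroll(rand_net(6, seed = 80))
  ids <- g$nodes$id
  en <- enum_all(g)
  r <- which.max(en$p)
  full <- stats::setNames(vapply(seq_along(ids), function(j)
    g$states[[ids[j]]][en$grid[r, j]], ""), ids)
  expect_equal(record_loglik(g, full),
               joint_probability(g, as.list(full), log = TRUE), tolerance = 1e-10)
  expect_equal(record_loglik(g, stats::setNames(rep(NA_character_, length(ids)), ids)), 0)
  part <- full
  part[c(2L, 4L)] <- NA
  expect_equal(record_loglik(g, part),
               enum_log_evidence(g, as.list(part[!is.na(part)]), en), tolerance = 1e-9)
})

test_that("anomaly scoring flags the adversarial record", {
  net <- rand_net(6, seed = 91, alpha = 0.6)
  g <- unroll(net)
  b <- sample_cohort(cohort_config(n_subjects = 200, seed = 92, missing_rate = 0),
                     truth = net)
  df <- as.data.frame(b$complete)
  # adversarial subject: the minimum-prior-probability state at every cell
  for (id in g$nodes$id) {
    v <- parse_var <- dbnpanel:::parse_node_id(id)
    pr <- posterior(g, list(), id)$marginals[[id]]
    df[df$subject_id == "S00001" & df$wave == v$wave, v$var] <- names(pr)[which.min(pr)]
  }
  data <- panel_dataset(df, net$structure, waves = 1L)
  sc <- anomaly_scores(g, data, flag_quantile = 0.05)
  expect_equal(sc$subject_id[which.max(sc$score)], "S00001")
  expect_true(sc$flagged[sc$subject_id == "S00001"])
  expect_lte(sum(sc$flagged), ceiling(200 * 0.05))

  # identical subjects: constant scores, no flags
  df2 <- df
  for (v in setdiff(names(df2), c("subject_id", "wave"))) df2[[v]] <- df2[[v]][1L]
  sc2 <- anomaly_scores(g, panel_dataset(df2, net$structure, waves = 1L), 0.05)
  expect_equal(sum(sc2$flagged), 0L)

  expect_error(anomaly_scores(g, data, flag_quantile = 0.6))
})
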
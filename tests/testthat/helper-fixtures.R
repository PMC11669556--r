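# Fixtures and independent oracles shared across the suite. The enumeration
# oracles work directly on the conditional tables with vectorised index
# arithmetic; they never call the variable-elimination path they check.

# ---- random single-wave networks ------------------------------------------

# random DAG over `n_nodes` variables with 2-3 states and random tables
rand_net <- function(n_nodes, seed, max_parents = 2L, states_max = 3L,
                     alpha = 1) {
  set.seed(seed)
  nm <- sprintf("V%02d", seq_len(n_nodes))
  vars <- lapply(nm, function(v)
    dbn_variable(v, paste0("s", seq_len(sample(2:states_max, 1L))),
                 temporal = FALSE))
  arcs <- NULL
  for (j in seq_len(n_nodes)) {
    if (j == 1L) next
    np <- sample(0:min(max_parents, j - 1L), 1L)
    if (np > 0L) {
      ps <- sample(nm[seq_len(j - 1L)], np)
      arcs <- rbind(arcs, data.frame(parent = ps, child = nm[j], lag = 0L))
    }
  }
  st <- dbn_structure(vars, arcs, horizon = 1L)
  network_from_structure(st, "random", alpha = alpha)
}

# ---- enumeration oracle ----------------------------------------------------

# all joint configurations of a ground network as an integer matrix
# (columns in ground$nodes$id order) plus their probabilities computed by
# direct table lookups; `skip` excludes a node's factor from the product
# (truncated factorisation for do-operator oracles)
enum_all <- function(ground, skip = character(0)) {
  ids <- ground$nodes$id
  card <- vapply(ground$states[ids], length, 0L)
  n <- prod(card)
  stopifnot(n <= 2e6)
  base <- 0:(n - 1L)
  stride <- cumprod(c(1L, card[-length(card)]))
  grid <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) grid[, j] <- 1L + (base %/% stride[j]) %% card[j]
  p <- rep(1, n)
  for (id in setdiff(ids, skip)) {
    f <- ground$factors[[id]]
    fst <- cumprod(c(1L, f$card[-length(f$card)]))
    idx <- rep(1, n)
    for (j in seq_along(f$vars)) idx <- idx + (grid[, f$vars[j]] - 1L) * fst[j]
    p <- p * f$val[idx]
  }
  list(grid = grid, p = p, ids = ids, card = card)
}

# evidence weights per configuration (hard and soft entries)
enum_weights <- function(enum, ground, evidence) {
  w <- rep(1, length(enum$p))
  for (id in names(evidence)) {
    e <- evidence[[id]]
    if (is.character(e)) {
      w <- w * (enum$grid[, id] == match(e, ground$states[[id]]))
    } else {
      w <- w * e[enum$grid[, id]]
    }
  }
  w
}

enum_posterior <- function(ground, evidence, query_id, enum = NULL) {
  if (is.null(enum)) enum <- enum_all(ground)
  w <- enum$p * enum_weights(enum, ground, evidence)
  agg <- as.vector(rowsum(w, enum$grid[, query_id]))
  stats::setNames(agg / sum(w), ground$states[[query_id]])
}

enum_log_evidence <- function(ground, evidence, enum = NULL) {
  if (is.null(enum)) enum <- enum_all(ground)
  log(sum(enum$p * enum_weights(enum, ground, evidence)))
}

# exhaustive MAP over `query` (marginalising everything else)
enum_map <- function(ground, evidence, query, enum = NULL) {
  if (is.null(enum)) enum <- enum_all(ground)
  w <- enum$p * enum_weights(enum, ground, evidence)
  key <- apply(enum$grid[, query, drop = FALSE], 1L, paste, collapse = ",")
  agg <- rowsum(w, key)
  best <- rownames(agg)[which.max(agg)]
  idx <- as.integer(strsplit(best, ",", fixed = TRUE)[[1L]])
  list(assignment = stats::setNames(
         vapply(seq_along(query), function(j) ground$states[[query[j]]][idx[j]], ""),
         query),
       prob = max(agg) / sum(w))
}

# ---- three-node motif fixtures --------------------------------------------

# chain A -> B -> C, fork A <- B -> C (B the common cause), collider
# A -> C <- B, with fixed high-contrast binary tables
motif_net <- function(kind = c("chain", "fork", "collider")) {
  kind <- match.arg(kind)
  arcs <- switch(kind,
    chain = data.frame(parent = c("A", "B"), child = c("B", "C"), lag = 0L),
    fork = data.frame(parent = c("B", "B"), child = c("A", "C"), lag = 0L),
    collider = data.frame(parent = c("A", "B"), child = c("C", "C"), lag = 0L))
  vars <- lapply(c("A", "B", "C"), function(n)
    dbn_variable(n, c("s0", "s1"), temporal = FALSE))
  st <- dbn_structure(vars, arcs, horizon = 1L)
  s2 <- c("s0", "s1")
  root <- function(v, p1) dbn_cpt(v, s2, NULL, list(), matrix(c(p1, 1 - p1), 1L))
  cond1 <- function(v, p) dbn_cpt(v, s2, data.frame(parent = p, lag = 0L), list(s2),
                                  matrix(c(0.85, 0.15, 0.2, 0.8), 2L, byrow = TRUE))
  tabs <- switch(kind,
    chain = list(A = list(transition = root("A", 0.45)),
                 B = list(transition = cond1("B", "A")),
                 C = list(transition = cond1("C", "B"))),
    fork = list(B = list(transition = root("B", 0.5)),
                A = list(transition = cond1("A", "B")),
                C = list(transition = cond1("C", "B"))),
    collider = list(A = list(transition = root("A", 0.55)),
                    B = list(transition = root("B", 0.4)),
                    C = list(transition = dbn_cpt("C", s2,
                      data.frame(parent = c("A", "B"), lag = 0L), list(s2, s2),
                      matrix(c(0.9, 0.1, 0.5, 0.5, 0.4, 0.6, 0.05, 0.95),
                             4L, byrow = TRUE)))))
  dbn_network(st, tabs)
}

motif_data <- function(net, n, seed) {
  sample_cohort(cohort_config(n_subjects = n, seed = seed, missing_rate = 0),
                truth = net)$complete
}

# d-separation oracle on a single-wave DAG for CPDAG recovery studies
dsep_oracle <- function(arcs) {
  parents_of <- function(v) arcs$parent[arcs$child == v]
  children_of <- function(v) arcs$child[arcs$parent == v]
  function(x, y, S) {
    # moralised ancestral graph reachability
    anc <- unique(c(x, y, S))
    repeat {
      more <- unique(unlist(lapply(anc, parents_of)))
      if (all(more %in% anc)) break
      anc <- unique(c(anc, more))
    }
    edges <- arcs[arcs$parent %in% anc & arcs$child %in% anc, , drop = FALSE]
    und <- rbind(edges[, c("parent", "child")],
                 stats::setNames(edges[, c("child", "parent")], c("parent", "child")))
    # marry co-parents
    for (v in anc) {
      ps <- intersect(parents_of(v), anc)
      if (length(ps) >= 2L) {
        pr <- t(utils::combn(ps, 2L))
        und <- rbind(und, data.frame(parent = c(pr[, 1L], pr[, 2L]),
                                     child = c(pr[, 2L], pr[, 1L])))
      }
    }
    und <- und[!(und$parent %in% S) & !(und$child %in% S), , drop = FALSE]
    seen <- x
    repeat {
      nxt <- setdiff(und$child[und$parent %in% seen], seen)
      if (length(nxt) == 0L) break
      seen <- c(seen, nxt)
    }
    !(y %in% seen)
  }
}

# ---- parameter-recovery fixture -------------------------------------------

# known 5-variable, 2-wave binary network with moderate random tables
recovery_net <- function(seed = 99) {
  vs <- lapply(c("A", "B", "C", "D", "E"), function(n) dbn_variable(n, c("s0", "s1")))
  arcs <- rbind(data.frame(parent = c("A", "B", "D"), child = c("B", "C", "E"), lag = 0L),
                data.frame(parent = c("A", "C"), child = c("A", "C"), lag = 1L))
  st <- dbn_structure(vs, arcs, horizon = 2L)
  set.seed(seed)
  network_from_structure(st, "random", alpha = 2)
}

# flat list of all table probability matrices, keyed by schema
net_probs <- function(net) {
  sch <- dbnpanel:::table_schemas(net$structure)
  out <- list()
  for (k in names(sch)) {
    s <- sch[[k]]
    tl <- net$tables[[s$var]]
    cpt <- if (s$kind == "transition") tl$transition
           else tl$initial[[as.character(s$waves[1L])]]
    out[[k]] <- cpt$prob
  }
  out
}

max_table_diff <- function(net1, net2) {
  p1 <- net_probs(net1); p2 <- net_probs(net2)
  max(mapply(function(a, b) max(abs(a - b)), p1, p2[names(p1)]))
}

# random evidence over a ground network: a few hard states and soft vectors
rand_evidence <- function(ground, n_hard = 2L, n_soft = 1L) {
  ids <- sample(ground$nodes$id, min(n_hard + n_soft, nrow(ground$nodes)))
  ev <- list()
  for (i in seq_along(ids)) {
    st <- ground$states[[ids[i]]]
    ev[[ids[i]]] <- if (i <= n_hard) sample(st, 1L) else stats::runif(length(st), 0.1, 1)
  }
  ev
}
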
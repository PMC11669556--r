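# MAP queries by max-sum-product elimination with traceback, do-operator
# graph surgery, best-/worst-case scenario analysis and a declared
# max-conditional convention for per-arc pathway strengths.

# one constrained-order max run: sum out nuisance (min-fill), then max out
# the free query vars in reverse lexicographic order so the traceback picks
# the lexicographically smallest maximiser under ties
.map_solve <- function(ground, ev, qfree, extra_hard = list(), excl = list()) {
  factors <- evidence_factors(ground, ev)
  for (id in names(extra_hard)) {
    s <- state_index(ground, id, extra_hard[[id]])
    for (k in seq_along(factors)) {
      if (id %in% factors[[k]]$vars) factors[[k]] <- f_restrict(factors[[k]], id, s)
    }
  }
  for (id in setdiff(names(excl), names(extra_hard))) {
    # exclusions on fixed vars are already honoured by the fixed value
    w <- rep(1, length(ground$states[[id]]))
    w[excl[[id]]] <- 0
    factors[[id]] <- f_weight(factors[[id]], id, w)
  }
  qv <- setdiff(qfree, names(extra_hard))
  all_vars <- unique(unlist(lapply(factors, `[[`, "vars"), use.names = FALSE))
  nuis <- setdiff(all_vars, qv)
  res1 <- ve_eliminate(factors, min_fill_order(lapply(factors, `[[`, "vars"), nuis),
                       mode = "sum")$factors
  res2 <- ve_eliminate(res1, sort(qv, decreasing = TRUE), mode = "max")
  score <- sum(vapply(res2$factors, function(f) {
    if (length(f$val) != 1L) stop("internal: non-scalar factor after MAP elimination")
    if (f$val <= 0) -Inf else f$lg + log(f$val)
  }, 0))
  assign_idx <- integer(0)
  if (is.finite(score)) {
    for (v in sort(qv)) {  # reverse elimination order
      af <- res2$trace[[v]]
      if (is.null(af)) { assign_idx[v] <- 1L; next }
      pos <- 1L
      if (length(af$vars) > 0L) {
        stride <- cumprod(c(1L, af$card[-length(af$card)]))
        pos <- 1L + sum((assign_idx[af$vars] - 1L) * stride)
      }
      assign_idx[v] <- as.integer(af$val[pos])
    }
  }
  states <- vapply(names(assign_idx), function(v) ground$states[[v]][assign_idx[v]], "")
  list(score = score, idx = assign_idx,
       assignment = c(stats::setNames(as.character(unlist(extra_hard)), names(extra_hard)),
                      states))
}

#' Marginal MAP query with optional top-k enumeration
#'
#' Finds the joint configuration of the query nodes with the highest
#' posterior probability given the evidence, marginalising all other nodes
#' (marginal MAP; set `query` to every non-evidence node for full MPE).
#' Ties are broken toward the lexicographically first assignment in state
#' order. `k > 1` returns the k best configurations via systematic
#' re-solving with exclusion constraints (Lawler partitioning).
#'
#' @inheritParams posterior
#' @param query Nonempty set of ground node ids, disjoint from hard evidence.
#' @param k Number of top assignments to return.
#' @return An object of class `dbn_map`: `assignment`, `prob`,
#'   `log_evidence` and `top` (data frame of the k best with probabilities).
#' @export
map_query <- function(ground, evidence = list(), query, k = 1L) {
  ev <- check_evidence(ground, evidence)
  if (length(query) == 0L) stop("query must be nonempty")
  if (any(query %in% names(ev$hard)))
    stop("query nodes must be disjoint from hard-evidenced nodes")
  unknown <- setdiff(query, ground$nodes$id)
  if (length(unknown) > 0L) stop("unknown query nodes: ", paste(unknown, collapse = ", "))
  log_z <- posterior(ground, evidence, character(0))$log_evidence
  qv <- sort(query)

  best <- .map_solve(ground, ev, qv)
  if (!is.finite(best$score)) impossible_evidence(best$score)
  results <- list(best)
  if (k > 1L) {
    # Lawler partitioning: each expansion fixes a prefix of the incumbent and
    # excludes the incumbent's state at the branch variable
    queue <- list()
    expand <- function(sol, fixed, excl) {
      free <- setdiff(qv, names(fixed))
      for (i in seq_along(free)) {
        v <- free[i]
        fx <- fixed
        if (i > 1L) for (u in free[seq_len(i - 1L)]) fx[[u]] <- sol$assignment[[u]]
        ex <- excl
        ex[[v]] <- union(ex[[v]], match(sol$assignment[[v]], ground$states[[v]]))
        if (length(ex[[v]]) >= length(ground$states[[v]])) next
        cand <- .map_solve(ground, ev, qv, extra_hard = fx, excl = ex)
        if (is.finite(cand$score))
          queue[[length(queue) + 1L]] <<- list(sol = cand, fixed = fx, excl = ex)
      }
    }
    expand(best, stats::setNames(list(), character(0)), list())
    while (length(results) < k && length(queue) > 0L) {
      scores <- vapply(queue, function(q) q$sol$score, 0)
      j <- which.max(scores)
      nxt <- queue[[j]]
      queue[[j]] <- NULL
      results[[length(results) + 1L]] <- nxt$sol
      expand(nxt$sol, nxt$fixed, nxt$excl)
    }
  }
  top <- do.call(rbind, lapply(results, function(r) {
    df <- as.data.frame(as.list(r$assignment[qv]), check.names = FALSE)
    df$prob <- exp(r$score - log_z)
    df
  }))
  structure(list(assignment = results[[1L]]$assignment[qv],
                 prob = exp(best$score - log_z),
                 log_score = best$score, log_evidence = log_z, top = top),
            class = "dbn_map")
}

#' @export
print.dbn_map <- function(x, ...) {
  cat("MAP assignment (p =", format(x$prob), "):\n")
  print(x$assignment)
  invisible(x)
}

#' Apply do-operator interventions (graph surgery)
#'
#' For each intervened ground node the incoming arcs are severed and its
#' table replaced by a point mass on the forced state (truncated
#' factorisation); everything else is untouched and the input network is
#' not modified.
#'
#' @param net A [dbn_network()] or an already [unroll()]ed ground network.
#' @param spec Named list/vector mapping `"VAR@wave"` to the forced state.
#' @return A mutilated `dbn_ground` network.
#' @export
intervene <- function(net, spec) {
  ground <- if (inherits(net, "dbn_ground")) net else unroll(net)
  spec <- unlist(spec)
  unknown <- setdiff(names(spec), ground$nodes$id)
  if (length(unknown) > 0L)
    stop("cannot intervene on structurally absent node(s): ",
         paste(unknown, collapse = ", "))
  for (id in names(spec)) {
    s <- state_index(ground, id, spec[[id]])
    val <- rep(0, length(ground$states[[id]]))
    val[s] <- 1
    ground$factors[[id]] <- new_factor(id, length(val), val)
    ground$parents[[id]] <- character(0)
  }
  ground$interventions <- c(ground$interventions, as.list(spec))
  ground
}

#' Interventional (counterfactual) outcome distribution
#'
#' `P(outcome | do(spec))`: the posterior of the outcome node on the
#' mutilated network, optionally conditioned on additional evidence.
#'
#' @inheritParams intervene
#' @param outcome A ground node id.
#' @param evidence Extra evidence applied after surgery.
#' @return Named probability vector over the outcome's states.
#' @export
counterfactual_query <- function(net, spec, outcome, evidence = list()) {
  g <- intervene(net, spec)
  posterior(g, evidence, outcome)$marginals[[outcome]]
}

#' Best-/worst-case scenario analysis
#'
#' Clamps the target variable at every wave where it exists and reports how
#' the posterior of each requested node moves against the evidence-free
#' baseline. `best` clamps the target to its designated normal state (hard
#' evidence); `worst` applies soft evidence with zero likelihood on the
#' normal state and uniform likelihood over the remaining states (the
#' pooled "undernourished" reading); `custom` clamps the target to the
#' distribution(s) in `clamp`, realised as per-wave likelihood
#' `clamp / baseline` so that clamping a wave to its own baseline marginal
#' is an exact no-op. `mode = "do"` replaces evidential clamping by
#' do-interventions (only meaningful for hard clamps).
#'
#' @param net A [dbn_network()].
#' @param target Target variable name.
#' @param scenario `"best"`, `"worst"` or `"custom"`.
#' @param report_nodes Character vector of variable names to report.
#' @param normal_state The target's designated normal state.
#' @param clamp For `scenario = "custom"`: the desired target distribution,
#'   either one vector over target states (applied at every wave) or a list
#'   with one vector per target wave.
#' @param mode `"evidence"` (default) or `"do"`.
#' @return An object of class `dbn_scenario` whose `table` has one row per
#'   (node, wave, state): baseline, predicted, delta and a direction flag.
#' @export
scenario_analysis <- function(net, target, scenario = c("best", "worst", "custom"),
                              report_nodes, normal_state = "N", clamp = NULL,
                              mode = c("evidence", "do")) {
  scenario <- match.arg(scenario)
  mode <- match.arg(mode)
  ground <- unroll(net)
  struct <- net$structure
  tv <- struct$variables[[target]]
  if (is.null(tv)) stop("unknown target variable: ", target)
  if (!(normal_state %in% tv$states))
    stop("target has no state '", normal_state, "'")
  tw <- tv$first_wave:(struct$horizon - 1L)
  tids <- node_id(target, tw)
  ev <- switch(scenario,
    best = stats::setNames(as.list(rep(normal_state, length(tids))), tids),
    worst = {
      w <- as.numeric(tv$states != normal_state)
      stats::setNames(rep(list(w), length(tids)), tids)
    },
    custom = {
      # the clamp specifies the desired target distribution per wave; it is
      # realised as per-wave likelihood clamp / baseline so that clamping a
      # wave to its own baseline marginal is an exact no-op
      if (is.null(clamp)) stop("scenario 'custom' needs a clamp")
      if (!is.list(clamp)) clamp <- rep(list(clamp), length(tids))
      if (length(clamp) != length(tids))
        stop("per-wave clamp list must have one entry per target wave")
      ev_c <- list()
      for (j in seq_along(tids)) {
        cl <- as.numeric(clamp[[j]])
        if (length(cl) != length(tv$states) || any(cl < 0) || all(cl == 0))
          stop("clamp must be a non-negative, not-all-zero likelihood over target states")
        cl <- cl / sum(cl)
        base_t <- posterior(ground, list(), tids[j])$marginals[[tids[j]]]
        if (any(cl > 0 & base_t <= 0))
          stop("custom clamp puts mass on a state with zero baseline support at ", tids[j])
        ev_c[[tids[j]]] <- unname(ifelse(base_t > 0, cl / base_t, 0))
      }
      ev_c
    })
  rids <- unlist(lapply(report_nodes, function(v) {
    vr <- struct$variables[[v]]
    if (is.null(vr)) stop("unknown report variable: ", v)
    node_id(v, vr$first_wave:(struct$horizon - 1L))
  }))
  base <- posterior(ground, list(), c(rids, tids))
  pred <- if (mode == "evidence") {
    posterior(ground, ev, c(rids, tids))
  } else {
    if (scenario != "best") stop("mode 'do' requires a hard clamp (scenario 'best')")
    posterior(intervene(net, ev), list(), c(rids, tids))
  }
  rows <- list()
  for (id in c(rids, tids)) {
    pw <- parse_node_id(id)
    b <- base$marginals[[id]]
    p <- pred$marginals[[id]]
    d <- p - b
    rows[[id]] <- data.frame(node = pw$var, wave = pw$wave, state = names(b),
                             baseline = as.numeric(b), predicted = as.numeric(p),
                             delta = as.numeric(d),
                             flag = ifelse(d > 1e-12, "+", ifelse(d < -1e-12, "-", "0")),
                             stringsAsFactors = FALSE)
  }
  structure(list(scenario = scenario, target = target, normal_state = normal_state,
                 mode = mode,
                 table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 log_evidence = pred$log_evidence),
            class = "dbn_scenario")
}

#' @export
print.dbn_scenario <- function(x, ...) {
  cat("Scenario '", x$scenario, "' on target ", x$target,
      " (", x$mode, " mode)\n", sep = "")
  print(utils::head(x$table, 20L))
  invisible(x)
}

#' Per-arc pathway strength along a causal chain
#'
#' For each consecutive arc `A -> B` of the path and each wave where both
#' endpoints exist, reports `max_b P(B = b | A = a*, evidence)` with `a*`
#' the MAP state of `A` under the evidence. This max-conditional convention
#' is a declared stand-in for proprietary "edge probability" outputs and is
#' labelled as such in reports.
#'
#' @param net A [dbn_network()].
#' @param path Character vector of variable names along the chain.
#' @param evidence Optional evidence (named list as in [posterior()]).
#' @return Data frame: parent, child, lag, wave, MAP parent state, strength.
#' @export
pathway_strength <- function(net, path, evidence = list()) {
  stopifnot(length(path) >= 2L)
  struct <- net$structure
  ground <- unroll(net)
  rows <- list()
  for (i in seq_len(length(path) - 1L)) {
    a <- path[i]; b <- path[i + 1L]
    arcs <- struct$arcs[struct$arcs$parent == a & struct$arcs$child == b, , drop = FALSE]
    if (nrow(arcs) == 0L)
      stop("arc ", a, " -> ", b, " is not in the network structure")
    lag <- min(arcs$lag)
    for (t in 0:(struct$horizon - 1L)) {
      aid <- node_id(a, t - lag); bid <- node_id(b, t)
      if (!(aid %in% ground$nodes$id) || !(bid %in% ground$nodes$id)) next
      pa <- posterior(ground, evidence, aid)$marginals[[aid]]
      a_star <- names(pa)[which.max(pa)]
      ev2 <- evidence
      ev2[[aid]] <- a_star
      pb <- posterior(ground, ev2, bid)$marginals[[bid]]
      rows[[length(rows) + 1L]] <- data.frame(
        parent = a, child = b, lag = lag, wave = t, parent_map_state = a_star,
        strength = max(pb), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "convention") <- "max-conditional given MAP parent state"
  out
}
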
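#' Declare a categorical panel variable
#'
#' A variable in a dynamic network is a named categorical quantity observed
#' (in principle) at every survey wave from `first_wave` onward. Variables
#' carrying a temporal dependency (a lagged arc onto themselves or others)
#' are flagged `temporal`; a non-temporal variable such as child sex may
#' only take part in within-wave (lag-0) arcs.
#'
#' @param name Short identifier, e.g. `"CNS"`.
#' @param states Ordered character vector of at least two distinct state labels.
#' @param temporal Logical; does the variable have lagged dependencies?
#' @param first_wave 0-based index of the first wave at which the variable is
#'   observable. Variables absent from early waves (late-entering programme
#'   indicators, say) are modelled by structural absence, not placeholder states.
#' @return An object of class `dbn_variable`.
#' @export
dbn_variable <- function(name, states, temporal = TRUE, first_wave = 0L) {
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0L)
  states <- as.character(states)
  if (length(states) < 2L) stop("variable '", name, "' needs at least 2 states")
  if (anyDuplicated(states)) stop("variable '", name, "' has duplicated state labels")
  if (grepl("@", name, fixed = TRUE)) stop("variable names must not contain '@'")
  structure(list(name = name, states = states, temporal = isTRUE(temporal),
                 first_wave = as.integer(first_wave)),
            class = "dbn_variable")
}

node_id <- function(var, wave) paste0(var, "@", wave)

parse_node_id <- function(id) {
  m <- regmatches(id, regexec("^(.*)@([0-9]+)$", id))
  data.frame(var = vapply(m, `[`, "", 2L),
             wave = as.integer(vapply(m, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Define a temporal network structure
#'
#' The structure is a template graph over `(variable, lag)` pairs: lag-0 arcs
#' act within a wave, lag-1/lag-2 arcs connect a parent at wave `t - lag` to
#' a child at wave `t`. Unrolled over `horizon` waves it must form an acyclic
#' ground graph, which holds exactly when the lag-0 subgraph is acyclic.
#'
#' @param variables List of [dbn_variable()] objects.
#' @param arcs Data frame with columns `parent`, `child`, `lag` (lag in 0..2).
#' @param horizon Number of waves the template spans.
#' @return An object of class `dbn_structure`.
#' @export
dbn_structure <- function(variables, arcs = NULL, horizon = 5L) {
  if (inherits(variables, "dbn_variable")) variables <- list(variables)
  nm <- vapply(variables, function(v) v$name, "")
  if (anyDuplicated(nm)) stop("duplicated variable names")
  names(variables) <- nm
  if (is.null(arcs) || nrow(arcs) == 0L) {
    arcs <- data.frame(parent = character(0), child = character(0), lag = integer(0),
                       stringsAsFactors = FALSE)
  } else {
    arcs <- data.frame(parent = as.character(arcs$parent),
                       child = as.character(arcs$child),
                       lag = as.integer(arcs$lag), stringsAsFactors = FALSE)
    bad <- !(arcs$parent %in% nm) | !(arcs$child %in% nm)
    if (any(bad)) stop("arcs reference undeclared variables: ",
                       paste(unique(c(arcs$parent[bad], arcs$child[bad])), collapse = ", "))
    if (anyDuplicated(arcs)) stop("duplicated arcs")
    arcs <- arcs[order(arcs$child, arcs$lag, arcs$parent), , drop = FALSE]
    rownames(arcs) <- NULL
  }
  structure(list(variables = variables, arcs = arcs, horizon = as.integer(horizon)),
            class = "dbn_structure")
}

# parent slots of a variable, deterministically ordered by (lag, parent name)
parent_slots <- function(struct, v) {
  a <- struct$arcs[struct$arcs$child == v, , drop = FALSE]
  a <- a[order(a$lag, a$parent), , drop = FALSE]
  a[, c("parent", "lag")]
}

# which of v's slots exist at wave t (parent observable at wave t - lag)
available_slots <- function(struct, v, t) {
  sl <- parent_slots(struct, v)
  if (nrow(sl) == 0L) return(sl)
  fw <- vapply(sl$parent, function(p) struct$variables[[p]]$first_wave, 0L)
  sl[t - sl$lag >= fw, , drop = FALSE]
}

lag0_acyclic <- function(struct) {
  a <- struct$arcs[struct$arcs$lag == 0L, , drop = FALSE]
  nm <- names(struct$variables)
  topo_order_edges(nm, a$parent, a$child, quiet = TRUE)$acyclic
}

# Kahn topological sort; returns list(order, acyclic)
topo_order_edges <- function(nodes, from, to, quiet = FALSE) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  adj <- split(to, factor(from, levels = nodes))
  tb <- table(factor(to, levels = nodes))
  indeg[names(tb)] <- as.integer(tb)
  avail <- sort(nodes[indeg == 0L])
  out <- character(0)
  while (length(avail) > 0L) {
    n <- avail[1L]; avail <- avail[-1L]
    out <- c(out, n)
    for (m in adj[[n]]) {
      indeg[m] <- indeg[m] - 1L
      if (indeg[m] == 0L) avail <- sort(c(avail, m))
    }
  }
  ok <- length(out) == length(nodes)
  if (!ok && !quiet) stop("graph is cyclic")
  list(order = out, acyclic = ok)
}

#' Construct a conditional probability table
#'
#' Rows enumerate the Cartesian product of the parent state spaces with the
#' first parent slot varying fastest (the `expand.grid` convention); columns
#' are the child states. Rows off unit mass by no more than `1e-6` are
#' renormalised with a warning; larger deviations are rejected.
#'
#' @param child Child variable name.
#' @param child_states Character vector of child states.
#' @param slots Data frame with columns `parent`, `lag` (possibly 0 rows).
#' @param parent_states List of state vectors parallel to `slots` rows.
#' @param prob Numeric matrix, `prod(lengths(parent_states))` rows.
#' @return An object of class `dbn_cpt`.
#' @export
dbn_cpt <- function(child, child_states, slots, parent_states, prob) {
  if (is.null(slots)) slots <- data.frame(parent = character(0), lag = integer(0))
  prob <- as.matrix(prob)
  nconf <- prod(vapply(parent_states, length, 0L))
  if (length(parent_states) == 0L) nconf <- 1L
  if (nrow(prob) != nconf || ncol(prob) != length(child_states))
    stop("cpt for '", child, "': prob must be ", nconf, " x ", length(child_states))
  if (any(prob < 0)) stop("cpt for '", child, "': negative probabilities")
  rs <- rowSums(prob)
  off <- abs(rs - 1)
  if (any(off > 1e-6)) stop("cpt for '", child, "': rows do not sum to 1 (max off ",
                            signif(max(off), 3), ")")
  if (any(off > 1e-9)) {
    warning("cpt for '", child, "': renormalising rows off unit mass by <= 1e-6")
    prob <- prob / rs
  }
  structure(list(child = child, states = as.character(child_states),
                 slots = data.frame(parent = as.character(slots$parent),
                                    lag = as.integer(slots$lag)),
                 parent_states = parent_states, prob = unname(prob)),
            class = "dbn_cpt")
}

# linear row index for given parent state indices (first slot fastest)
cpt_row_index <- function(cards, idx_matrix) {
  if (length(cards) == 0L) return(rep(1L, nrow(idx_matrix)))
  stride <- cumprod(c(1L, cards[-length(cards)]))
  1L + as.integer(as.matrix(idx_matrix - 1L) %*% stride)
}

#' Assemble a dynamic network from a structure and tables
#'
#' Every variable needs one time-homogeneous `transition` table (used at all
#' waves where each of its lagged/early parents is available) and an
#' `initial` table for every earlier wave at/after its `first_wave`, whose
#' parent slots must be exactly the available subset of the template slots.
#'
#' @param struct A [dbn_structure()].
#' @param tables Named list (per variable) of `list(transition = , initial = )`,
#'   with `initial` a list keyed by wave as character.
#' @return An object of class `dbn_network`.
#' @export
dbn_network <- function(struct, tables) {
  stopifnot(inherits(struct, "dbn_structure"))
  for (v in names(struct$variables)) {
    vr <- struct$variables[[v]]
    full <- parent_slots(struct, v)
    for (t in vr$first_wave:(struct$horizon - 1L)) {
      avail <- available_slots(struct, v, t)
      cpt <- governing_table(tables, v, t, full, avail)
      if (is.null(cpt))
        stop("no table governs variable '", v, "' at wave ", t)
      if (!identical(paste(cpt$slots$parent, cpt$slots$lag),
                     paste(avail$parent, avail$lag)))
        stop("table for '", v, "' at wave ", t, " has wrong parent slots")
      if (!identical(cpt$states, vr$states))
        stop("table for '", v, "' has wrong child states")
      for (j in seq_len(nrow(avail))) {
        if (!identical(cpt$parent_states[[j]],
                       struct$variables[[avail$parent[j]]]$states))
          stop("table for '", v, "' wave ", t, ": slot ", j, " state mismatch")
      }
    }
  }
  structure(list(structure = struct, tables = tables), class = "dbn_network")
}

# the table that governs variable v at wave t (transition if all template
# slots are available there, else the wave-specific initial table)
governing_table <- function(tables, v, t, full, avail) {
  tl <- tables[[v]]
  if (is.null(tl)) return(NULL)
  if (nrow(avail) == nrow(full)) tl$transition else tl$initial[[as.character(t)]]
}

governing_key <- function(struct, v, t) {
  full <- parent_slots(struct, v)
  avail <- available_slots(struct, v, t)
  if (nrow(avail) == nrow(full)) paste0(v, "/transition") else paste0(v, "/initial@", t)
}

#' Unroll a dynamic network over a horizon
#'
#' Instantiates the temporal template into an ordinary acyclic ground
#' network with one node per `(variable, wave)` pair from the variable's
#' `first_wave` on, and one fully specified conditional distribution per
#' ground node. Arcs from `(parent, t - lag)` to `(child, t)` exist exactly
#' when the template declares them and the parent is observable at `t - lag`.
#'
#' @param net A [dbn_network()].
#' @param horizon Number of waves; defaults to the structure's horizon.
#' @return An object of class `dbn_ground` with fields `nodes`, `states`,
#'   `parents`, `factors`, `cpt_ref`, `topo`.
#' @export
unroll <- function(net, horizon = NULL) {
  struct <- net$structure
  if (is.null(horizon)) horizon <- struct$horizon
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("horizon must be >= 1")
  if (nrow(struct$arcs) > 0L && any(struct$arcs$lag >= horizon))
    stop("arc lag exceeds horizon")
  if (!lag0_acyclic(struct)) stop("lag-0 subgraph is cyclic")

  nodes <- do.call(rbind, lapply(names(struct$variables), function(v) {
    fw <- struct$variables[[v]]$first_wave
    if (fw > horizon - 1L) return(NULL)
    data.frame(var = v, wave = fw:(horizon - 1L), stringsAsFactors = FALSE)
  }))
  nodes$id <- node_id(nodes$var, nodes$wave)

  states <- parents <- factors <- cpt_ref <- vector("list", nrow(nodes))
  names(states) <- names(parents) <- names(factors) <- names(cpt_ref) <- nodes$id
  for (k in seq_len(nrow(nodes))) {
    v <- nodes$var[k]; t <- nodes$wave[k]
    vr <- struct$variables[[v]]
    full <- parent_slots(struct, v)
    avail <- available_slots(struct, v, t)
    cpt <- governing_table(net$tables, v, t, full, avail)
    if (is.null(cpt)) stop("no table for ", nodes$id[k])
    pids <- if (nrow(avail) > 0L) node_id(avail$parent, t - avail$lag) else character(0)
    cards <- c(vapply(cpt$parent_states, length, 0L), length(cpt$states))
    states[[k]] <- cpt$states
    parents[[k]] <- pids
    # factor dims: (slot1, ..., slotk, child); as.vector(prob) matches because
    # rows enumerate slot configs first-slot-fastest and columns are child states
    factors[[k]] <- new_factor(c(pids, nodes$id[k]), cards, as.vector(cpt$prob))
    cpt_ref[[k]] <- list(key = governing_key(struct, v, t), var = v, wave = t)
  }
  topo <- topo_order_edges(nodes$id,
                           from = unlist(parents, use.names = FALSE),
                           to = rep(nodes$id, lengths(parents)))
  if (!topo$acyclic) stop("unrolled ground graph is cyclic")
  structure(list(nodes = nodes, states = states, parents = parents,
                 factors = factors, cpt_ref = cpt_ref, topo = topo$order,
                 network = net),
            class = "dbn_ground")
}

ground_arcs <- function(ground) {
  data.frame(from = unlist(ground$parents, use.names = FALSE),
             to = rep(ground$nodes$id, lengths(ground$parents)),
             stringsAsFactors = FALSE)
}

state_index <- function(ground, id, state) {
  i <- match(state, ground$states[[id]])
  if (is.na(i)) stop("state '", state, "' is not a state of ", id)
  i
}

#' Joint probability of a complete ground assignment
#'
#' Multiplies, over every ground node, the conditional-table entry selected
#' by the assignment. The log variant sums logs and does not underflow.
#'
#' @param ground A [unroll()]ed network.
#' @param assignment Named character vector or list mapping every ground node
#'   id (`"VAR@wave"`) to a state label.
#' @param log Return the log probability?
#' @return A probability in `[0, 1]`, or its log.
#' @export
joint_probability <- function(ground, assignment, log = FALSE) {
  assignment <- unlist(assignment)
  missing_ids <- setdiff(ground$nodes$id, names(assignment))
  if (length(missing_ids) > 0L)
    stop("assignment incomplete; missing: ", paste(utils::head(missing_ids, 5L), collapse = ", "))
  lp <- 0
  for (id in ground$nodes$id) {
    f <- ground$factors[[id]]
    idx <- vapply(seq_along(f$vars), function(j) {
      state_index(ground, f$vars[j], assignment[[f$vars[j]]])
    }, 0L)
    stride <- cumprod(c(1L, f$card[-length(f$card)]))
    p <- f$val[1L + sum((idx - 1L) * stride)]
    lp <- lp + (if (p > 0) base::log(p) else -Inf)
  }
  if (log) lp else exp(lp)
}

#' Validate a dynamic network
#'
#' Checks every representation invariant (state uniqueness, first-wave
#' ranges, lag bounds, temporality of lagged arcs, lag-0 and ground
#' acyclicity, table normalisation and coverage) and reports violations
#' rather than raising.
#'
#' @param net A [dbn_network()] (tolerates partially malformed contents).
#' @return Character vector of human-readable violations; empty if valid.
#' @export
dbn_validate <- function(net) {
  v_out <- character(0)
  struct <- net$structure
  H <- struct$horizon
  nm <- names(struct$variables)
  for (v in nm) {
    vr <- struct$variables[[v]]
    if (anyDuplicated(vr$states))
      v_out <- c(v_out, paste0("variable ", v, ": duplicated state labels"))
    if (vr$first_wave < 0L || vr$first_wave > H - 1L)
      v_out <- c(v_out, paste0("variable ", v, ": first_wave outside [0, ", H - 1L, "]"))
  }
  a <- struct$arcs
  if (nrow(a) > 0L) {
    bad <- !(a$lag %in% 0:2)
    for (i in which(bad))
      v_out <- c(v_out, paste0("arc ", a$parent[i], "->", a$child[i],
                               ": lag ", a$lag[i], " outside {0,1,2}"))
    for (i in which(a$lag >= 1L)) {
      for (side in c("parent", "child")) {
        vv <- a[[side]][i]
        if (!is.null(struct$variables[[vv]]) && !struct$variables[[vv]]$temporal)
          v_out <- c(v_out, paste0("arc ", a$parent[i], "->", a$child[i], " lag ", a$lag[i],
                                   ": non-temporal variable ", vv, " in a lagged arc"))
      }
    }
  }
  if (!lag0_acyclic(struct))
    v_out <- c(v_out, "lag-0 subgraph is cyclic")
  # table checks (each distinct governing table checked once)
  seen <- character(0)
  for (v in nm) {
    vr <- struct$variables[[v]]
    full <- parent_slots(struct, v)
    for (t in vr$first_wave:(H - 1L)) {
      avail <- available_slots(struct, v, t)
      cpt <- governing_table(net$tables, v, t, full, avail)
      if (is.null(cpt)) {
        v_out <- c(v_out, paste0("no table governs ", node_id(v, t)))
        next
      }
      key <- governing_key(struct, v, t)
      if (key %in% seen) next
      seen <- c(seen, key)
      rs <- rowSums(cpt$prob)
      for (r in which(abs(rs - 1) > 1e-9))
        v_out <- c(v_out, paste0("table ", governing_key(struct, v, t), " row ", r,
                                 " sums to ", signif(rs[r], 6)))
      if (any(cpt$prob < 0))
        v_out <- c(v_out, paste0("table ", governing_key(struct, v, t),
                                 " has negative entries"))
    }
  }
  if (length(v_out) == 0L) {
    gr <- try(unroll(net), silent = TRUE)
    if (inherits(gr, "try-error"))
      v_out <- c(v_out, paste0("unroll failed: ", attr(gr, "condition")$message))
  }
  v_out
}

#' @export
print.dbn_structure <- function(x, ...) {
  cat("Temporal structure:", length(x$variables), "variables,",
      nrow(x$arcs), "arcs, horizon", x$horizon, "\n")
  invisible(x)
}

#' @export
print.dbn_network <- function(x, ...) {
  cat("Dynamic network over", length(x$structure$variables),
      "variables, horizon", x$structure$horizon, "\n")
  invisible(x)
}

#' @export
print.dbn_ground <- function(x, ...) {
  cat("Ground network:", nrow(x$nodes), "nodes,", nrow(ground_arcs(x)), "arcs\n")
  invisible(x)
}
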
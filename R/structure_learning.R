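# Constraint-based structure learning with the PC algorithm under temporal
# tiering. Nodes are (variable, lag) pairs; lag-0 edges are learned among
# contemporaneous variables, inter-slice candidates default to self-lags and
# are always oriented past -> present. Expert knowledge enters as forbidden /
# required arcs. Everything is deterministic: edges are visited and
# conditioning sets enumerated in lexicographic order.

lag_label <- function(var, lag) ifelse(lag == 0L, var, paste0(var, ".l", lag))

parse_lag_label <- function(lab) {
  m <- regexec("^(.*)\\.l([0-9]+)$", lab)
  r <- regmatches(lab, m)
  data.frame(var = ifelse(lengths(r) > 0L, vapply(r, function(x) if (length(x)) x[2L] else NA_character_, ""), lab),
             lag = ifelse(lengths(r) > 0L, as.integer(vapply(r, function(x) if (length(x)) x[3L] else NA_character_, "")), 0L),
             stringsAsFactors = FALSE)
}

#' Stack a panel into a lagged cross-section
#'
#' One row per subject-wave with `wave >= max_lag`; columns are the lag-0
#' variables plus `VAR.l1`, `VAR.l2` copies holding the subject's value
#' `lag` waves earlier. This is the working table for conditional
#' independence testing in a time-homogeneous dynamic network.
#'
#' @param data A [panel_dataset()].
#' @param struct A [dbn_structure()] (declares the variable roster).
#' @param max_lag Largest lag to materialise.
#' @return Data frame of characters with attribute `levels` (state spaces).
#' @export
stacked_panel <- function(data, struct, max_lag = 2L) {
  vars <- struct$variables
  waves <- struct$horizon
  stopifnot(max_lag >= 0L, waves >= max_lag + 1L)
  keep <- data$wave >= max_lag & data$wave <= waves - 1L
  out <- data.frame(subject_id = data$subject_id[keep], wave = data$wave[keep],
                    stringsAsFactors = FALSE)
  levels_out <- list()
  for (v in names(vars)) {
    out[[v]] <- data[[v]][keep]
    levels_out[[v]] <- vars[[v]]$states
    if (vars[[v]]$temporal && max_lag >= 1L) {
      for (l in seq_len(max_lag)) {
        lab <- lag_label(v, l)
        # grid-completed and ordered by subject/wave, so shifting within the
        # full panel by l rows lands on the same subject's earlier wave
        shifted <- data[[v]][match(paste(data$subject_id, data$wave - l),
                                   paste(data$subject_id, data$wave))]
        out[[lab]] <- shifted[keep]
        levels_out[[lab]] <- vars[[v]]$states
      }
    }
  }
  attr(out, "levels") <- levels_out
  out
}

#' G-squared conditional independence test
#'
#' Likelihood-ratio test of `X` independent of `Y` given the conditioning set
#' `S` on complete cases, with the chi-square reference distribution.
#' Degrees of freedom are `(|X| - 1)(|Y| - 1)` per non-empty stratum of `S`
#' (degenerate strata dropped). A test with fewer than `min_ratio * df`
#' complete cases is marked unreliable and treated as independent.
#'
#' @param data Data frame (typically [stacked_panel()] output).
#' @param x,y Column names.
#' @param S Character vector of conditioning column names (possibly empty).
#' @param alpha Significance level.
#' @param levels Optional named list of state spaces (defaults to the
#'   `levels` attribute of `data`, else observed values).
#' @param min_ratio Reliability threshold on complete cases per df.
#' @return An object of class `dbn_citest`.
#' @export
ci_test_g2 <- function(data, x, y, S = character(0), alpha = 0.01,
                       levels = NULL, min_ratio = 5) {
  if (is.null(levels)) levels <- attr(data, "levels")
  lv <- function(col) {
    if (!is.null(levels) && !is.null(levels[[col]])) levels[[col]]
    else sort(unique(stats::na.omit(data[[col]])))
  }
  cols <- c(x, y, S)
  cc <- stats::complete.cases(data[, cols, drop = FALSE])
  n <- sum(cc)
  fx <- factor(data[[x]][cc], levels = lv(x))
  fy <- factor(data[[y]][cc], levels = lv(y))
  cx <- nlevels(fx); cy <- nlevels(fy)
  if (length(S) > 0L) {
    fs <- do.call(interaction,
                  c(lapply(S, function(s) factor(data[[s]][cc], levels = lv(s))),
                    list(drop = FALSE, lex.order = TRUE)))
    tab <- table(fx, fy, fs)
  } else {
    tab <- array(table(fx, fy), dim = c(cx, cy, 1L))
  }
  g2 <- 0
  nonempty <- 0L
  for (k in seq_len(dim(tab)[3L])) {
    o <- tab[, , k]
    tot <- sum(o)
    if (tot == 0L) next
    nonempty <- nonempty + 1L
    e <- outer(rowSums(o), colSums(o)) / tot
    pos <- o > 0
    g2 <- g2 + 2 * sum(o[pos] * log(o[pos] / e[pos]))
  }
  df <- max(1L, (cx - 1L) * (cy - 1L) * max(nonempty, 1L))
  p <- stats::pchisq(g2, df = df, lower.tail = FALSE)
  reliable <- n >= min_ratio * df && nonempty > 0L
  independent <- !reliable || p > alpha
  structure(list(x = x, y = y, S = S, statistic = g2, df = df, p_value = p,
                 n = n, alpha = alpha, reliable = reliable,
                 independent = independent),
            class = "dbn_citest")
}

#' @export
print.dbn_citest <- function(x, ...) {
  cat(sprintf("G2 test %s _||_ %s | {%s}: G2=%.3f df=%d p=%.3g -> %s%s\n",
              x$x, x$y, paste(x$S, collapse = ","), x$statistic, x$df, x$p_value,
              if (x$independent) "independent" else "dependent",
              if (!x$reliable) " (unreliable)" else ""))
  invisible(x)
}

#' Expert constraints for structure learning
#'
#' @param forbidden,required Data frames with columns `parent`, `child`,
#'   `lag` (arcs, directed). A lag-0 edge is removed from the candidate set
#'   only if both directions are forbidden; a single forbidden direction
#'   constrains orientation.
#' @return An object of class `dbn_constraints`.
#' @export
dbn_constraints <- function(forbidden = NULL, required = NULL) {
  canon <- function(x) {
    if (is.null(x) || nrow(x) == 0L)
      return(data.frame(parent = character(0), child = character(0), lag = integer(0)))
    data.frame(parent = as.character(x$parent), child = as.character(x$child),
               lag = as.integer(x$lag), stringsAsFactors = FALSE)
  }
  forbidden <- canon(forbidden); required <- canon(required)
  both <- merge(forbidden, required)
  if (nrow(both) > 0L)
    stop("contradictory constraints: arc(s) both forbidden and required: ",
         paste(sprintf("%s->%s lag %d", both$parent, both$child, both$lag), collapse = "; "))
  structure(list(forbidden = forbidden, required = required), class = "dbn_constraints")
}

#' Read / write a constraint file
#'
#' Delimited text with columns `type` (`forbid`/`require`), `parent`,
#' `child`, `lag`.
#' @param path File path.
#' @return A [dbn_constraints()] object.
#' @export
read_constraints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("type", "parent", "child", "lag")
  if (!all(need %in% names(df))) stop("constraint file needs columns: ",
                                      paste(need, collapse = ", "))
  dbn_constraints(forbidden = df[df$type == "forbid", ],
                  required = df[df$type == "require", ])
}

#' @param x A [dbn_constraints()] object.
#' @rdname read_constraints
#' @export
write_constraints <- function(x, path) {
  df <- rbind(cbind(type = rep("forbid", nrow(x$forbidden)), x$forbidden),
              cbind(type = rep("require", nrow(x$required)), x$required))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

arc_key <- function(parent, child, lag) paste(parent, child, lag, sep = "\r")

# would adding from -> to close a directed cycle?
creates_cycle <- function(arcs_env, from, to) {
  # BFS from `to` along directed arcs; cycle iff we can reach `from`
  seen <- to
  frontier <- to
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(lapply(frontier, function(nd) arcs_env$out[[nd]]), use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    if (from %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

#' Learn a temporal structure with the PC algorithm
#'
#' Starts from the complete constraint-respecting graph over (variable, lag)
#' pairs, removes edges by conditional-independence tests with conditioning
#' sets of growing size drawn from current adjacencies, orients v-structures
#' and applies Meek propagation rules, then orients any residual undirected
#' lag-0 edges by a deterministic tier/lexicographic fallback. Inter-slice
#' edges are always oriented past to present; required arcs are never
#' removed and forbidden arcs never appear.
#'
#' @param data A [panel_dataset()].
#' @param struct A [dbn_structure()] declaring the roster (its arcs are
#'   ignored; only variables and horizon are used).
#' @param max_lag Largest lag considered (inter-slice candidates are
#'   self-lags `V[t-l] -> V[t]` unless `cross_lags` adds more).
#' @param constraints A [dbn_constraints()] or `NULL`.
#' @param alpha Significance level for the G-squared tests.
#' @param max_cond Largest conditioning-set size.
#' @param cross_lags Optional data frame `parent`, `child`, `lag` of extra
#'   inter-slice candidates.
#' @param tiers Optional named integer vector of causal tiers; the fallback
#'   orients residual undirected edges from the higher tier (more upstream,
#'   e.g. intervention) to the lower (child-level outcomes).
#' @param ci_oracle Optional `function(x, y, S)` returning `TRUE` when
#'   independent; replaces the data-driven test (used for oracle studies).
#' @return An object of class `dbn_pdag`: `skeleton`, `arcs` (with origin
#'   tags), `sepsets`, `tests`, `conflicts`, and `dag` (final arc set as
#'   parent/child/lag rows).
#' @export
pc_learn <- function(data, struct, max_lag = 2L, constraints = NULL,
                     alpha = 0.01, max_cond = 3L, cross_lags = NULL,
                     tiers = NULL, ci_oracle = NULL) {
  stopifnot(alpha > 0, alpha < 0.5)
  if (is.null(constraints)) constraints <- dbn_constraints()
  vars <- names(struct$variables)
  sp <- if (is.null(ci_oracle)) stacked_panel(data, struct, max_lag) else NULL

  # candidate edges (undirected, endpoints as lag labels)
  cand <- list()
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (i < j) cand[[length(cand) + 1L]] <- c(vars[i], vars[j])
    }
  }
  for (v in vars) {
    if (struct$variables[[v]]$temporal && max_lag >= 1L) {
      for (l in seq_len(min(max_lag, struct$horizon - 1L)))
        cand[[length(cand) + 1L]] <- c(lag_label(v, l), v)
    }
  }
  if (!is.null(cross_lags)) {
    for (i in seq_len(nrow(cross_lags)))
      cand[[length(cand) + 1L]] <- c(lag_label(cross_lags$parent[i], cross_lags$lag[i]),
                                     cross_lags$child[i])
  }
  edge_id <- function(a, b) paste(sort(c(a, b)), collapse = "\r")
  edges <- unique(vapply(cand, function(e) edge_id(e[1L], e[2L]), ""))

  forb <- constraints$forbidden
  req <- constraints$required
  forb_dir <- paste(lag_label(forb$parent, forb$lag), forb$child, sep = "\r")
  is_forbidden <- function(from, to) paste(from, to, sep = "\r") %in% forb_dir
  req_edges <- if (nrow(req) > 0L)
    vapply(seq_len(nrow(req)), function(i)
      edge_id(lag_label(req$parent[i], req$lag[i]), req$child[i]), "") else character(0)

  # drop candidates forbidden in both directions (lagged: single direction)
  keep <- vapply(edges, function(eid) {
    ab <- strsplit(eid, "\r", fixed = TRUE)[[1L]]
    la <- parse_lag_label(ab[1L]); lb <- parse_lag_label(ab[2L])
    if (la$lag > 0L || lb$lag > 0L) {
      from <- if (la$lag > 0L) ab[1L] else ab[2L]
      to <- if (la$lag > 0L) ab[2L] else ab[1L]
      return(!is_forbidden(from, to) || eid %in% req_edges)
    }
    !(is_forbidden(ab[1L], ab[2L]) && is_forbidden(ab[2L], ab[1L])) || eid %in% req_edges
  }, logical(1))
  edges <- sort(edges[keep])

  adj <- new.env(parent = emptyenv())
  add_adj <- function(a, b) {
    assign(a, union(mget(a, envir = adj, ifnotfound = list(character(0)))[[1L]], b), envir = adj)
    assign(b, union(mget(b, envir = adj, ifnotfound = list(character(0)))[[1L]], a), envir = adj)
  }
  rm_adj <- function(a, b) {
    assign(a, setdiff(get(a, envir = adj), b), envir = adj)
    assign(b, setdiff(get(b, envir = adj), a), envir = adj)
  }
  for (eid in edges) { ab <- strsplit(eid, "\r", fixed = TRUE)[[1L]]; add_adj(ab[1L], ab[2L]) }

  sepsets <- list()
  conflicts <- character(0)
  tests <- list()
  run_test <- function(a, b, S) {
    if (!is.null(ci_oracle)) {
      ind <- isTRUE(ci_oracle(a, b, S))
      tests[[length(tests) + 1L]] <<- data.frame(
        x = a, y = b, S = paste(S, collapse = "|"), statistic = NA_real_,
        df = NA_integer_, p_value = NA_real_, n = NA_integer_,
        reliable = TRUE, independent = ind, stringsAsFactors = FALSE)
      return(ind)
    }
    ct <- ci_test_g2(sp, a, b, S, alpha = alpha)
    tests[[length(tests) + 1L]] <<- data.frame(
      x = a, y = b, S = paste(S, collapse = "|"), statistic = ct$statistic,
      df = ct$df, p_value = ct$p_value, n = ct$n, reliable = ct$reliable,
      independent = ct$independent, stringsAsFactors = FALSE)
    ct$independent
  }

  # ---- skeleton phase ----
  live <- edges
  for (ell in 0:max_cond) {
    changed <- FALSE
    snapshot <- live
    for (eid in snapshot) {
      if (!(eid %in% live)) next
      ab <- strsplit(eid, "\r", fixed = TRUE)[[1L]]
      a <- ab[1L]; b <- ab[2L]
      if (eid %in% req_edges) {
        # constraints win: test once for the log, keep the edge regardless
        if (ell == 0L && run_test(a, b, character(0)))
          conflicts <- c(conflicts,
                         paste0("required edge ", a, "-", b,
                                " tests independent; kept by constraint"))
        next
      }
      nbrs <- sort(union(setdiff(get(a, envir = adj), b), setdiff(get(b, envir = adj), a)))
      if (length(nbrs) < ell) next
      subsets <- if (ell == 0L) list(character(0)) else
        utils::combn(nbrs, ell, simplify = FALSE)
      removed <- FALSE
      for (S in subsets) {
        if (run_test(a, b, S)) {
          rm_adj(a, b)
          sepsets[[eid]] <- S
          live <- setdiff(live, eid)
          removed <- TRUE
          changed <- TRUE
          break
        }
      }
      if (removed) next
    }
    degs <- vapply(unique(unlist(strsplit(live, "\r", fixed = TRUE))),
                   function(nd) length(get(nd, envir = adj)), 0L)
    if (length(degs) == 0L || max(degs) - 1L < ell + 1L) break
  }
  skeleton <- do.call(rbind, lapply(live, function(eid) {
    ab <- strsplit(eid, "\r", fixed = TRUE)[[1L]]
    data.frame(a = ab[1L], b = ab[2L], stringsAsFactors = FALSE)
  }))
  if (is.null(skeleton)) skeleton <- data.frame(a = character(0), b = character(0))

  # ---- orientation ----
  arcs_env <- new.env(parent = emptyenv())
  arcs_env$out <- list()
  directed <- data.frame(from = character(0), to = character(0), origin = character(0),
                         stringsAsFactors = FALSE)
  undirected <- character(0)  # edge ids still undirected
  orient <- function(from, to, origin, force = FALSE) {
    if (to %in% arcs_env$out[[from]]) return(TRUE)
    if (is_forbidden(from, to) && !force) {
      conflicts <<- c(conflicts, paste0("orientation ", from, "->", to,
                                        " (", origin, ") forbidden; skipped"))
      return(FALSE)
    }
    if (creates_cycle(arcs_env, from, to)) {
      conflicts <<- c(conflicts, paste0("orientation ", from, "->", to,
                                        " (", origin, ") would create a cycle; skipped"))
      return(FALSE)
    }
    arcs_env$out[[from]] <- union(arcs_env$out[[from]], to)
    directed <<- rbind(directed, data.frame(from = from, to = to, origin = origin,
                                            stringsAsFactors = FALSE))
    undirected <<- setdiff(undirected, edge_id(from, to))
    TRUE
  }
  for (i in seq_len(nrow(skeleton))) {
    a <- skeleton$a[i]; b <- skeleton$b[i]
    la <- parse_lag_label(a); lb <- parse_lag_label(b)
    if (la$lag > 0L) orient(a, b, "lag", force = TRUE)
    else if (lb$lag > 0L) orient(b, a, "lag", force = TRUE)
    else undirected <- c(undirected, edge_id(a, b))
  }
  for (i in seq_len(nrow(req))) {
    from <- lag_label(req$parent[i], req$lag[i]); to <- req$child[i]
    if (req$lag[i] == 0L) orient(from, to, "required", force = TRUE)
  }

  has_arc <- function(from, to) to %in% arcs_env$out[[from]]
  is_und <- function(a, b) edge_id(a, b) %in% undirected
  adjacent <- function(a, b) is_und(a, b) || has_arc(a, b) || has_arc(b, a)
  all_nodes <- sort(unique(c(skeleton$a, skeleton$b)))

  # v-structures: a -> z <- b for nonadjacent a, b with z outside sepset(a, b)
  for (z in all_nodes) {
    if (parse_lag_label(z)$lag > 0L) next
    nb <- sort(get(z, envir = adj))
    if (length(nb) < 2L) next
    for (i in seq_len(length(nb) - 1L)) {
      for (j in (i + 1L):length(nb)) {
        a <- nb[i]; b <- nb[j]
        if (adjacent(a, b)) next
        eid <- edge_id(a, b)
        if (is.null(sepsets[[eid]])) next
        if (z %in% sepsets[[eid]]) next
        if (is_und(a, z)) orient(a, z, "vstructure")
        if (is_und(b, z)) orient(b, z, "vstructure")
      }
    }
  }

  # Meek propagation rules to a fixpoint
  repeat {
    progressed <- FALSE
    for (eid in sort(undirected)) {
      ab <- strsplit(eid, "\r", fixed = TRUE)[[1L]]
      for (k in 1:2) {
        a <- ab[k]; b <- ab[3L - k]
        # R1: c -> a, c not adjacent to b  =>  a -> b
        cands <- setdiff(all_nodes, c(a, b))
        r1 <- any(vapply(cands, function(cc) has_arc(cc, a) && !adjacent(cc, b), logical(1)))
        # R2: a -> c -> b  =>  a -> b
        r2 <- any(vapply(cands, function(cc) has_arc(a, cc) && has_arc(cc, b), logical(1)))
        # R3: a - c1 -> b, a - c2 -> b, c1 c2 nonadjacent  =>  a -> b
        cs <- cands[vapply(cands, function(cc) is_und(a, cc) && has_arc(cc, b), logical(1))]
        r3 <- length(cs) >= 2L &&
          any(utils::combn(cs, 2L, function(p) !adjacent(p[1L], p[2L])))
        if (r1 || r2 || r3) {
          origin <- paste0("meek:", if (r1) "R1" else if (r2) "R2" else "R3")
          if (orient(a, b, origin)) { progressed <- TRUE; break }
        }
      }
      if (progressed) break
    }
    if (!progressed) break
  }

  # deterministic fallback for residual undirected lag-0 edges
  tier_of <- function(v) if (!is.null(tiers) && !is.na(tiers[v])) unname(tiers[v]) else 0L
  for (eid in sort(undirected)) {
    ab <- sort(strsplit(eid, "\r", fixed = TRUE)[[1L]])
    ta <- tier_of(ab[1L]); tb <- tier_of(ab[2L])
    if (ta > tb) { from <- ab[1L]; to <- ab[2L] }
    else if (tb > ta) { from <- ab[2L]; to <- ab[1L] }
    else { from <- ab[1L]; to <- ab[2L] }  # equal tier: earlier name -> later
    if (is_forbidden(from, to) || creates_cycle(arcs_env, from, to)) {
      tmp <- from; from <- to; to <- tmp
    }
    orient(from, to, "fallback", force = TRUE)
  }

  dag <- if (nrow(directed) > 0L) {
    pf <- parse_lag_label(directed$from)
    data.frame(parent = pf$var, child = directed$to, lag = pf$lag,
               origin = directed$origin, stringsAsFactors = FALSE)
  } else data.frame(parent = character(0), child = character(0), lag = integer(0),
                    origin = character(0))
  tests_df <- if (length(tests) > 0L) do.call(rbind, tests) else
    data.frame(x = character(0), y = character(0), S = character(0))
  structure(list(skeleton = skeleton, arcs = directed, dag = dag,
                 sepsets = sepsets, tests = tests_df, conflicts = conflicts,
                 alpha = alpha, max_lag = max_lag),
            class = "dbn_pdag")
}

#' @export
print.dbn_pdag <- function(x, ...) {
  cat("PC result:", nrow(x$skeleton), "skeleton edges,", nrow(x$arcs),
      "oriented arcs,", nrow(x$tests), "CI tests,",
      length(x$conflicts), "conflicts\n")
  invisible(x)
}

#' Convert a PC result to a temporal structure
#'
#' @param pdag A [pc_learn()] result.
#' @param struct The roster structure the PC run used.
#' @return A [dbn_structure()] whose arcs are the final oriented DAG.
#' @export
pdag_to_structure <- function(pdag, struct) {
  dbn_structure(unname(struct$variables),
                pdag$dag[, c("parent", "child", "lag")],
                horizon = struct$horizon)
}

#' Write the CI-test log as delimited text
#' @param pdag A [pc_learn()] result.
#' @param path File path.
#' @export
write_ci_log <- function(pdag, path) {
  utils::write.csv(pdag$tests, path, row.names = FALSE)
  invisible(path)
}

#' BIC score of a temporal structure on complete data
#'
#' Maximised log-likelihood (pseudocount 0; unseen parent configurations
#' contribute 0) minus `0.5 * k * log(n)` per table, with `k` the table's
#' free parameters and `n` its pooled observation count. Higher is better.
#'
#' @param struct A [dbn_structure()].
#' @param data A complete [panel_dataset()].
#' @return Numeric score.
#' @export
bic_score <- function(struct, data) {
  pm <- panel_matrix(data, struct)
  if (anyNA(pm)) stop("bic_score requires complete data")
  pa <- phase_a(struct, pm, rep(1, nrow(pm)))
  score <- 0
  for (key in names(pa$dims)) {
    d <- pa$dims[[key]]
    cm <- matrix(pa$counts[[key]], d[1L], d[2L])
    tot <- rowSums(cm)
    pos <- cm > 0
    ll <- sum(cm[pos] * log((cm / tot)[pos]))
    n_tab <- sum(cm)
    if (n_tab > 0) score <- score + ll - 0.5 * d[1L] * (d[2L] - 1L) * log(n_tab)
  }
  score
}

#' Size of the directed-graph search space
#'
#' For `n` nodes there are `2 ^ (n (n - 1) / 2)` possible undirected
#' skeletons over which structure search ranges; the count is returned both
#' as a double (exact for powers of two) and as an exact decimal string.
#'
#' @param n Number of nodes (>= 1).
#' @return List with `exponent`, `count` (double) and `count_str` (exact
#'   decimal string).
#' @export
count_graph_structures <- function(n) {
  stopifnot(n >= 1)
  e <- as.integer(n * (n - 1) / 2)
  # exact decimal doubling, least-significant digit first
  digits <- 1L
  for (i in seq_len(e)) {
    digits <- digits * 2L
    carry <- 0L
    for (j in seq_along(digits)) {
      x <- digits[j] + carry
      digits[j] <- x %% 10L
      carry <- x %/% 10L
    }
    while (carry > 0L) {
      digits <- c(digits, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  list(exponent = e, count = 2^e,
       count_str = paste(rev(digits), collapse = ""))
}
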
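# Maximum-likelihood and EM estimation of the conditional tables implied by
# a temporal structure. Counts for the shared transition table of a variable
# are pooled across all waves it governs; early waves with reduced parent
# sets get their own initial tables.
#
# EM works on deduplicated records. For each unique record the missing cells
# are split into connected components given the observed cells; a component's
# joint posterior is an exact renormalised product of the reduced family
# tables, evaluated from precomputed index plans so that each EM iteration is
# a handful of vectorised gathers per component. Components whose joint state
# space would be large fall back to generic variable elimination.

# ---- family metadata -------------------------------------------------------

# one entry per ground node: governing table key, member columns in the
# panel matrix (slot order then child), member cardinalities and strides
family_layout <- function(struct, col_ids) {
  schemas <- table_schemas(struct)
  fams <- list()
  for (key in names(schemas)) {
    sch <- schemas[[key]]
    for (t in sch$waves) {
      pids <- if (nrow(sch$slots) > 0L) node_id(sch$slots$parent, t - sch$slots$lag)
              else character(0)
      cid <- node_id(sch$var, t)
      members <- c(pids, cid)
      card <- c(vapply(sch$parent_states, length, 0L), length(sch$child_states))
      fams[[cid]] <- list(key = key, cols = match(members, col_ids),
                          card = as.integer(card),
                          stride = cumprod(c(1L, card[-length(card)])),
                          nconf = as.integer(prod(card[-length(card)])))
    }
  }
  fams
}

schema_flat_dims <- function(struct) {
  schemas <- table_schemas(struct)
  lapply(schemas, schema_dims)
}

# ---- fully-observed (phase A) counts and loglik indices -------------------

phase_a <- function(struct, um, w) {
  fams <- family_layout(struct, colnames(um))
  dims <- schema_flat_dims(struct)
  counts <- lapply(dims, function(d) numeric(d[1L] * d[2L]))
  idx <- lapply(dims, function(d) integer(0))
  wt <- lapply(dims, function(d) numeric(0))
  for (fid in names(fams)) {
    fm <- fams[[fid]]
    sub <- um[, fm$cols, drop = FALSE]
    ok <- !rowAnyNA_int(sub)
    if (!any(ok)) next
    flat <- 1 + as.vector((sub[ok, , drop = FALSE] - 1L) %*% fm$stride)
    agg <- rowsum(w[ok], flat)
    counts[[fm$key]][as.integer(rownames(agg))] <-
      counts[[fm$key]][as.integer(rownames(agg))] + as.vector(agg)
    idx[[fm$key]] <- c(idx[[fm$key]], flat)
    wt[[fm$key]] <- c(wt[[fm$key]], w[ok])
  }
  list(counts = counts, idx = idx, wt = wt, fams = fams, dims = dims)
}

rowAnyNA_int <- function(m) {
  if (ncol(m) == 0L) return(rep(FALSE, nrow(m)))
  rowSums(is.na(m)) > 0L
}

# ---- per-record component plans (phase B) ---------------------------------

# L above which a component is not materialised as a joint table
.comp_joint_cap <- 4096L

build_plans <- function(struct, um, w, fams, card_by_col) {
  ncols <- ncol(um)
  touch <- vector("list", ncols)  # column -> family (ground node) names touching it
  for (fid in names(fams)) {
    for (cl in fams[[fid]]$cols) touch[[cl]] <- c(touch[[cl]], fid)
  }
  plans <- list()
  slow <- integer(0)
  for (i in seq_len(nrow(um))) {
    rec <- um[i, ]
    M <- which(is.na(rec))
    if (length(M) == 0L) next
    fam_ids <- unique(unlist(touch[M], use.names = FALSE))
    # union-find over missing columns through shared families
    parent <- stats::setNames(M, M)
    findp <- function(x) { while (parent[[as.character(x)]] != x) x <- parent[[as.character(x)]]; x }
    for (fid in fam_ids) {
      mm <- intersect(fams[[fid]]$cols, M)
      if (length(mm) > 1L) {
        r0 <- findp(mm[1L])
        for (m2 in mm[-1L]) parent[[as.character(findp(m2))]] <- r0
      }
    }
    roots <- vapply(M, findp, 0L)
    comp_split <- split(M, roots)
    entries <- list()
    rec_slow <- FALSE
    for (C in comp_split) {
      C <- sort(C)
      ccard <- card_by_col[C]
      L <- prod(ccard)
      cfams <- fam_ids[vapply(fam_ids, function(fid) any(fams[[fid]]$cols %in% C), logical(1))]
      if (L > .comp_joint_cap) { rec_slow <- TRUE; next }
      cstride <- cumprod(c(1L, ccard[-length(ccard)]))
      base_digits <- 0:(L - 1L)
      keys <- character(length(cfams))
      sels <- grps <- targets <- vector("list", length(cfams))
      for (k in seq_along(cfams)) {
        fm <- fams[[cfams[k]]]
        sel <- rep.int(1, L)
        for (j in seq_along(fm$cols)) {
          cl <- fm$cols[j]
          p <- match(cl, C)
          if (is.na(p)) {
            sel <- sel + (rec[cl] - 1L) * fm$stride[j]
          } else {
            digit <- (base_digits %/% cstride[p]) %% ccard[p]
            sel <- sel + digit * fm$stride[j]
          }
        }
        sel <- as.integer(sel)
        usel <- sort(unique(sel))
        keys[k] <- fm$key
        sels[[k]] <- sel
        grps[[k]] <- match(sel, usel)
        targets[[k]] <- usel
      }
      entries[[length(entries) + 1L]] <-
        list(w = w[i], keys = keys, sels = sels, grps = grps, targets = targets)
    }
    if (rec_slow) slow <- c(slow, i)
    if (length(entries) > 0L) plans[[length(plans) + 1L]] <- entries
  }
  list(entries = unlist(plans, recursive = FALSE), slow = slow)
}

# execute all plans against current flat tables; accumulate expected counts
# into `counts` (modified by reference semantics: returned), return loglik sum
run_plans <- function(entries, flat, counts) {
  ll <- 0
  for (e in entries) {
    val <- flat[[e$keys[1L]]][e$sels[[1L]]]
    if (length(e$keys) > 1L) {
      for (k in 2:length(e$keys)) val <- val * flat[[e$keys[k]]][e$sels[[k]]]
    }
    s <- sum(val)
    if (s <= 0) { ll <- -Inf; next }
    post <- (e$w / s) * val
    ll <- ll + e$w * log(s)
    for (k in seq_along(e$keys)) {
      agg <- rowsum(post, e$grps[[k]], reorder = TRUE)
      tg <- e$targets[[k]]
      counts[[e$keys[k]]][tg] <- counts[[e$keys[k]]][tg] + as.vector(agg)
    }
  }
  list(counts = counts, loglik = ll)
}

# ---- M-step ----------------------------------------------------------------

normalise_counts <- function(counts, dims, pseudocount) {
  probs <- list()
  for (key in names(dims)) {
    d <- dims[[key]]
    cm <- matrix(counts[[key]], d[1L], d[2L])
    tot <- rowSums(cm)
    pm <- (cm + pseudocount) / (tot + pseudocount * d[2L])
    zero <- tot + pseudocount * d[2L] == 0
    if (any(zero)) {
      warning("table ", key, ": ", sum(zero),
              " parent configuration(s) unseen with pseudocount 0; left uniform")
      pm[zero, ] <- 1 / d[2L]
    }
    probs[[key]] <- pm
  }
  probs
}

flat_probs <- function(probs) lapply(probs, as.vector)

table_loglik <- function(counts, probs) {
  ll <- 0
  for (key in names(probs)) {
    cm <- counts[[key]]
    pv <- as.vector(probs[[key]])
    pos <- cm > 0
    ll <- ll + sum(cm[pos] * log(pv[pos]))
  }
  ll
}

prior_term <- function(probs, pseudocount) {
  if (pseudocount <= 0) return(0)
  pseudocount * sum(vapply(probs, function(p) sum(log(pmax(p, 1e-300))), 0))
}

# ---- public fitting API ----------------------------------------------------

#' Maximum-likelihood estimation of conditional tables (complete data)
#'
#' Each table row is estimated as `(count + pseudocount) /
#' (row total + pseudocount * n_states)`, pooling counts across all waves
#' governed by the same transition table. With `pseudocount = 0` an unseen
#' parent configuration is left uniform with a warning, never 0/0.
#'
#' @param struct A [dbn_structure()].
#' @param data A complete [panel_dataset()] (no missing cells in the
#'   observable region).
#' @param pseudocount Non-negative Dirichlet pseudocount per table cell.
#' @return An object of class `dbn_fit`: `network`, `loglik`,
#'   `objective_trace`, `loglik_trace`, `counts`, `iterations`, `converged`.
#' @export
fit_mle <- function(struct, data, pseudocount = 1) {
  stopifnot(pseudocount >= 0)
  pm <- panel_matrix(data, struct)
  if (anyNA(pm))
    stop("fit_mle requires complete data; use fit_em for records with missing cells")
  pa <- phase_a(struct, pm, rep(1, nrow(pm)))
  probs <- normalise_counts(pa$counts, pa$dims, pseudocount)
  ll <- table_loglik(pa$counts, probs)
  counts_mat <- lapply(names(pa$dims), function(k)
    matrix(pa$counts[[k]], pa$dims[[k]][1L], pa$dims[[k]][2L]))
  names(counts_mat) <- names(pa$dims)
  structure(list(network = dbn_network(struct, tables_from_probs(struct, probs)),
                 loglik = ll, objective_trace = ll, loglik_trace = ll,
                 counts = counts_mat, iterations = 1L, converged = TRUE,
                 pseudocount = pseudocount, method = "mle"),
            class = "dbn_fit")
}

#' EM estimation of conditional tables with missing data
#'
#' E-step: expected family counts from exact per-record posteriors over the
#' missing cells (smoothing across waves included). M-step: [fit_mle()] on
#' expected counts. The iteration ascends the pseudocount-penalised
#' log-likelihood; `objective_trace` records it and is non-decreasing up to
#' numerical tolerance. Iteration stops when the objective gain drops below
#' `tol` or at `max_iter` (flagged, not an error).
#'
#' @inheritParams fit_mle
#' @param data A [panel_dataset()], possibly with missing cells (each
#'   variable must be observed somewhere).
#' @param max_iter Maximum EM iterations.
#' @param tol Absolute objective gain below which EM stops.
#' @param restarts Number of additional random-initialisation runs; the run
#'   with the best final objective wins. The first run always initialises
#'   from available-case counts.
#' @param verbose Print the objective per iteration?
#' @return An object of class `dbn_fit` (see [fit_mle()]).
#' @export
fit_em <- function(struct, data, pseudocount = 1, max_iter = 200L, tol = 1e-4,
                   restarts = 1L, verbose = FALSE) {
  stopifnot(pseudocount >= 0)
  pm <- panel_matrix(data, struct)
  if (!anyNA(pm)) {
    fit <- fit_mle(struct, data, pseudocount)
    fit$method <- "em"
    return(fit)
  }
  key <- apply(pm, 1L, paste, collapse = "\r")
  grp <- match(key, unique(key))
  w <- as.vector(rowsum(rep(1, nrow(pm)), grp, reorder = FALSE))
  um <- pm[!duplicated(grp), , drop = FALSE]

  pa <- phase_a(struct, um, w)
  card_by_col <- vapply(colnames(um), function(id) {
    v <- parse_node_id(id)$var
    length(struct$variables[[v]]$states)
  }, 0L)
  pl <- build_plans(struct, um, w, pa$fams, card_by_col)
  slow_recs <- pl$slow

  run_once <- function(probs0) {
    probs <- probs0
    obj_trace <- numeric(0)
    ll_trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      flat <- flat_probs(probs)
      counts <- pa$counts  # phase A counts are exact expected counts
      res <- run_plans(pl$entries, flat, counts)
      counts <- res$counts
      ll <- res$loglik
      # phase A loglik contribution of fully observed families
      for (k in names(pa$idx)) {
        if (length(pa$idx[[k]]) > 0L)
          ll <- ll + sum(pa$wt[[k]] * log(pmax(flat[[k]][pa$idx[[k]]], 1e-300)))
      }
      if (length(slow_recs) > 0L) {
        sr <- em_slow_records(struct, probs, um, w, slow_recs, pa$fams, counts)
        counts <- sr$counts
        ll <- ll + sr$loglik
      }
      obj <- ll + prior_term(probs, pseudocount)
      obj_trace <- c(obj_trace, obj)
      ll_trace <- c(ll_trace, ll)
      if (verbose) message("EM iter ", iter, ": loglik ", format(ll),
                           " objective ", format(obj))
      new_probs <- normalise_counts(counts, pa$dims, pseudocount)
      if (iter >= 2L && obj_trace[iter] - obj_trace[iter - 1L] < tol) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
      probs <- new_probs
    }
    list(probs = probs, counts = counts, obj_trace = obj_trace,
         ll_trace = ll_trace, converged = converged, iterations = iter)
  }

  init_probs <- normalise_counts(pa$counts, pa$dims, max(pseudocount, 0.5))
  best <- run_once(init_probs)
  if (restarts > 0L) {
    for (r in seq_len(restarts)) {
      rnd <- lapply(pa$dims, function(d) {
        m <- matrix(stats::rgamma(d[1L] * d[2L], 1, 1), d[1L], d[2L])
        m / rowSums(m)
      })
      cand <- run_once(rnd)
      if (utils::tail(cand$obj_trace, 1L) > utils::tail(best$obj_trace, 1L)) best <- cand
    }
  }
  counts_mat <- lapply(names(pa$dims), function(k)
    matrix(best$counts[[k]], pa$dims[[k]][1L], pa$dims[[k]][2L]))
  names(counts_mat) <- names(pa$dims)
  structure(list(network = dbn_network(struct, tables_from_probs(struct, best$probs)),
                 loglik = utils::tail(best$ll_trace, 1L),
                 objective_trace = best$obj_trace, loglik_trace = best$ll_trace,
                 counts = counts_mat, iterations = best$iterations,
                 converged = best$converged, pseudocount = pseudocount,
                 method = "em"),
            class = "dbn_fit")
}

# generic-inference fallback for records whose missing-cell components are too
# large to materialise: family posteriors by variable elimination
em_slow_records <- function(struct, probs, um, w, slow_recs, fams, counts) {
  net <- dbn_network(struct, tables_from_probs(struct, probs))
  ground <- unroll(net)
  ids <- colnames(um)
  ll <- 0
  for (i in slow_recs) {
    rec <- um[i, ]
    obs <- !is.na(rec)
    ev <- stats::setNames(lapply(which(obs), function(j) {
      ground$states[[ids[j]]][rec[j]]
    }), ids[obs])
    ll <- ll + w[i] * posterior(ground, ev, character(0))$log_evidence
    for (fid in names(fams)) {
      fm <- fams[[fid]]
      mm <- fm$cols[is.na(rec[fm$cols])]
      if (length(mm) == 0L) next
      qids <- ids[mm]
      jf <- posterior_joint(ground, ev, qids)
      # scatter the joint posterior over missing members into family counts
      L <- length(jf$val)
      sel <- rep.int(1, L)
      cstride <- cumprod(c(1L, jf$card[-length(jf$card)]))
      for (j in seq_along(fm$cols)) {
        p <- match(ids[fm$cols[j]], jf$vars)
        if (is.na(p)) {
          sel <- sel + (rec[fm$cols[j]] - 1L) * fm$stride[j]
        } else {
          digit <- ((0:(L - 1L)) %/% cstride[p]) %% jf$card[p]
          sel <- sel + digit * fm$stride[j]
        }
      }
      agg <- rowsum(w[i] * jf$val, as.integer(sel))
      tg <- as.integer(rownames(agg))
      counts[[fm$key]][tg] <- counts[[fm$key]][tg] + as.vector(agg)
    }
  }
  list(counts = counts, loglik = ll)
}

# normalised joint posterior factor over a small set of ground nodes
posterior_joint <- function(ground, evidence, vars) {
  ev <- check_evidence(ground, evidence)
  factors <- evidence_factors(ground, ev)
  all_vars <- unique(unlist(lapply(factors, `[[`, "vars"), use.names = FALSE))
  ord <- min_fill_order(lapply(factors, `[[`, "vars"), setdiff(all_vars, vars))
  res <- ve_eliminate(factors, ord, mode = "sum")$factors
  jf <- f_prod_all(res)
  jf <- f_marg_to(jf, vars)
  s <- sum(jf$val)
  if (s <= 0) impossible_evidence(-Inf)
  jf$val <- jf$val / s
  jf$lg <- 0
  jf
}

#' Dataset log-likelihood under a network
#'
#' Sum over subjects of [record_loglik()] (missing cells marginalised).
#'
#' @param net A [dbn_network()].
#' @param data A [panel_dataset()].
#' @return Log-likelihood (<= 0).
#' @export
dataset_loglik <- function(net, data) {
  ground <- unroll(net)
  pm <- panel_matrix(data, net$structure)
  key <- apply(pm, 1L, paste, collapse = "\r")
  grp <- match(key, unique(key))
  w <- as.vector(rowsum(rep(1, nrow(pm)), grp, reorder = FALSE))
  um <- pm[!duplicated(grp), , drop = FALSE]
  ids <- colnames(um)
  ll <- 0
  for (i in seq_len(nrow(um))) {
    rec <- um[i, ]
    obs <- which(!is.na(rec))
    r <- stats::setNames(rep(NA_character_, length(ids)), ids)
    for (j in obs) r[j] <- ground$states[[ids[j]]][rec[j]]
    ll <- ll + w[i] * record_loglik(ground, r)
  }
  ll
}

#' @export
print.dbn_fit <- function(x, ...) {
  cat("dbn_fit (", x$method, "): loglik ", format(x$loglik),
      ", ", x$iterations, " iteration(s), ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}
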
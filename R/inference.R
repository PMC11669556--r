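# Exact inference on the unrolled network by sum-product variable
# elimination with a min-fill elimination order. Evidence at later waves
# influences earlier-wave queries automatically (smoothing), which is how
# missing panel cells are treated: no static fill-in, just posteriors.

impossible_evidence <- function(logp) {
  stop(structure(class = c("dbn_impossible_evidence", "error", "condition"),
                 list(message = paste0("evidence has probability below 1e-300 (log p = ",
                                       format(logp), "); contradictory evidence"),
                      call = sys.call(-1))))
}

check_evidence <- function(ground, evidence) {
  if (length(evidence) == 0L) return(list(hard = character(0), soft = list()))
  ids <- names(evidence)
  if (is.null(ids) || anyDuplicated(ids))
    stop("evidence must be a uniquely named list of (variable@wave) entries")
  unknown <- setdiff(ids, ground$nodes$id)
  if (length(unknown) > 0L)
    stop("evidence on nodes absent from the ground network: ",
         paste(unknown, collapse = ", "))
  hard <- character(0); soft <- list()
  for (id in ids) {
    e <- evidence[[id]]
    if (is.character(e) || is.factor(e)) {
      e <- as.character(e)
      if (length(e) != 1L) stop("hard evidence for ", id, " must be one state")
      state_index(ground, id, e)
      hard[id] <- e
    } else if (is.numeric(e)) {
      if (length(e) != length(ground$states[[id]]))
        stop("soft evidence for ", id, " must have ", length(ground$states[[id]]),
             " weights")
      if (any(e < 0) || all(e == 0))
        stop("soft evidence for ", id, " must be non-negative and not all zero")
      soft[[id]] <- as.numeric(e)
    } else stop("evidence for ", id, " must be a state label or a likelihood vector")
  }
  list(hard = hard, soft = soft)
}

# reduce all CPT factors by hard evidence and fold soft evidence weights
# into each node's own factor
evidence_factors <- function(ground, ev) {
  factors <- ground$factors
  for (id in names(ev$soft)) factors[[id]] <- f_weight(factors[[id]], id, ev$soft[[id]])
  if (length(ev$hard) > 0L) {
    for (k in seq_along(factors)) {
      f <- factors[[k]]
      for (id in intersect(f$vars, names(ev$hard))) {
        f <- f_restrict(f, id, state_index(ground, id, ev$hard[[id]]))
      }
      factors[[k]] <- f
    }
  }
  factors
}

# connected components of factors over their (free-variable) scopes
factor_components <- function(factors) {
  n <- length(factors)
  comp <- integer(n); cur <- 0L
  var_of <- lapply(factors, `[[`, "vars")
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i; comp[i] <- cur
    vars_seen <- var_of[[i]]
    repeat {
      hit <- which(comp == 0L & vapply(var_of, function(v) any(v %in% vars_seen), logical(1)))
      if (length(hit) == 0L) break
      comp[hit] <- cur
      vars_seen <- unique(c(vars_seen, unlist(var_of[hit])))
    }
  }
  split(seq_len(n), comp)
}

#' Posterior marginals given evidence
#'
#' Computes `P(node | evidence)` for each query node by sum-product variable
#' elimination (min-fill order, lexicographic ties), together with the log
#' probability of the evidence. Evidence may be hard (a state label) or soft
#' (a likelihood vector over states). Smoothing across waves is automatic.
#'
#' @param ground A [unroll()]ed network.
#' @param evidence Named list: `"VAR@wave"` to a state label or a
#'   non-negative likelihood vector over that node's states.
#' @param query Character vector of ground node ids.
#' @return An object of class `dbn_posterior`: `marginals` (named list of
#'   named probability vectors) and `log_evidence`.
#' @export
posterior <- function(ground, evidence = list(), query = character(0)) {
  ev <- check_evidence(ground, evidence)
  unknown <- setdiff(query, ground$nodes$id)
  if (length(unknown) > 0L)
    stop("query nodes absent from the ground network: ", paste(unknown, collapse = ", "))
  factors <- evidence_factors(ground, ev)
  query_free <- setdiff(query, names(ev$hard))

  scopes <- lapply(factors, `[[`, "vars")
  all_vars <- unique(unlist(scopes, use.names = FALSE))
  # evidence probability: eliminate everything
  res <- ve_eliminate(factors, min_fill_order(scopes, all_vars), mode = "sum")$factors
  log_e <- sum(vapply(res, f_log_total, 0))
  if (!is.finite(log_e) || log_e < log(1e-300)) impossible_evidence(log_e)

  # one elimination per query node keeps intermediate factor scopes small
  marginals <- vector("list", length(query))
  names(marginals) <- query
  for (v in query_free) {
    mres <- ve_eliminate(factors, min_fill_order(scopes, setdiff(all_vars, v)),
                         mode = "sum")$factors
    mf <- f_prod_all(mres)
    mf <- f_marg_to(mf, v)
    s <- sum(mf$val)
    if (s <= 0) impossible_evidence(-Inf)
    marginals[[v]] <- stats::setNames(mf$val / s, ground$states[[v]])
  }
  for (id in intersect(query, names(ev$hard))) {
    p <- stats::setNames(rep(0, length(ground$states[[id]])), ground$states[[id]])
    p[ev$hard[[id]]] <- 1
    marginals[[id]] <- p
  }
  # query nodes independent of every factor component (fully marginalised nets
  # cannot produce this; defensive)
  structure(list(marginals = marginals, log_evidence = log_e, query = query),
            class = "dbn_posterior")
}

#' @export
print.dbn_posterior <- function(x, ...) {
  cat("Posterior report; log P(evidence) =", format(x$log_evidence), "\n")
  for (id in names(x$marginals)) {
    cat(" ", id, ":", paste(sprintf("%s=%.4f", names(x$marginals[[id]]),
                                    x$marginals[[id]]), collapse = " "), "\n")
  }
  invisible(x)
}

record_evidence <- function(record) {
  record <- unlist(record)
  as.list(record[!is.na(record)])
}

#' Posterior distributions for the missing cells of a record
#'
#' Treats every observed cell as hard evidence and returns, for each missing
#' cell, its posterior distribution (never a single filled-in value).
#'
#' @param ground A [unroll()]ed network.
#' @param record Named character vector over ground node ids; `NA` marks a
#'   missing cell, names not present are treated as missing too.
#' @return Named list of posterior distributions, one per missing cell.
#' @export
impute <- function(ground, record) {
  obs <- record_evidence(record)
  missing_ids <- setdiff(ground$nodes$id, names(obs))
  if (length(missing_ids) == 0L) return(list())
  posterior(ground, obs, query = missing_ids)$marginals
}

#' Log-likelihood of a (possibly incomplete) record
#'
#' Returns `log P(observed cells)`, marginalising the missing cells. A
#' complete record reduces to the log joint probability; a fully missing
#' record has log-likelihood 0.
#'
#' @inheritParams impute
#' @return Log probability (<= 0).
#' @export
record_loglik <- function(ground, record) {
  obs <- record_evidence(record)
  if (length(obs) == 0L) return(0)
  posterior(ground, obs, query = character(0))$log_evidence
}

#' Anomaly scores for a panel dataset
#'
#' Scores each subject by the negative log-likelihood of its record under
#' the network and flags subjects whose score lies strictly above the
#' `1 - flag_quantile` empirical quantile of the scores.
#'
#' @param ground A [unroll()]ed network.
#' @param data A [panel_dataset()].
#' @param flag_quantile Fraction in (0, 0.5) of subjects to flag.
#' @return Data frame with columns `subject_id`, `score`, `flagged`.
#' @export
anomaly_scores <- function(ground, data, flag_quantile = 0.05) {
  stopifnot(flag_quantile > 0, flag_quantile < 0.5)
  recs <- panel_records(data, ground)
  if (length(recs) == 0L) stop("empty dataset")
  scores <- vapply(recs, function(r) -record_loglik(ground, r), 0)
  thr <- stats::quantile(scores, 1 - flag_quantile, type = 7, names = FALSE)
  data.frame(subject_id = names(recs), score = unname(scores),
             flagged = unname(scores > thr), stringsAsFactors = FALSE)
}
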
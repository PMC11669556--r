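# Table schemas: which conditional tables a structure implies, which waves
# each governs, and their parent slots. fit_mle(), fit_em() and the network
# constructors all derive their bookkeeping from this single enumeration.

table_schemas <- function(struct) {
  out <- list()
  H <- struct$horizon
  for (v in names(struct$variables)) {
    vr <- struct$variables[[v]]
    full <- parent_slots(struct, v)
    for (t in vr$first_wave:(H - 1L)) {
      key <- governing_key(struct, v, t)
      if (is.null(out[[key]])) {
        avail <- available_slots(struct, v, t)
        out[[key]] <- list(
          key = key, var = v,
          kind = if (identical(key, paste0(v, "/transition"))) "transition" else "initial",
          slots = avail,
          parent_states = lapply(avail$parent, function(p) struct$variables[[p]]$states),
          child_states = vr$states,
          waves = t)
      } else {
        out[[key]]$waves <- c(out[[key]]$waves, t)
      }
    }
  }
  out
}

schema_cpt <- function(sch, prob) {
  dbn_cpt(sch$var, sch$child_states, sch$slots, sch$parent_states, prob)
}

schema_dims <- function(sch) {
  nconf <- prod(vapply(sch$parent_states, length, 0L))
  if (length(sch$parent_states) == 0L) nconf <- 1L
  c(nconf, length(sch$child_states))
}

tables_from_probs <- function(struct, probs) {
  schemas <- table_schemas(struct)
  tables <- list()
  for (key in names(schemas)) {
    sch <- schemas[[key]]
    cpt <- schema_cpt(sch, probs[[key]])
    if (sch$kind == "transition") {
      tables[[sch$var]]$transition <- cpt
    } else {
      tables[[sch$var]]$initial[[as.character(sch$waves[1L])]] <- cpt
    }
  }
  tables
}

#' Build a network with uniform or random tables
#'
#' Useful as an EM starting point, for property tests and for laying out the
#' table schemas a structure implies.
#'
#' @param struct A [dbn_structure()].
#' @param fill `"uniform"` or `"random"` (rows drawn from a symmetric
#'   Dirichlet with concentration `alpha` via normalised gammas).
#' @param alpha Dirichlet concentration for random fill.
#' @return A [dbn_network()].
#' @export
network_from_structure <- function(struct, fill = c("uniform", "random"), alpha = 1) {
  fill <- match.arg(fill)
  schemas <- table_schemas(struct)
  probs <- lapply(schemas, function(sch) {
    d <- schema_dims(sch)
    if (fill == "uniform") {
      matrix(1 / d[2L], d[1L], d[2L])
    } else {
      m <- matrix(stats::rgamma(d[1L] * d[2L], shape = alpha, rate = 1), d[1L], d[2L])
      m / rowSums(m)
    }
  })
  dbn_network(struct, tables_from_probs(struct, probs))
}
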
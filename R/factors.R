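# Internal discrete-factor algebra used by every inference routine.
#
# A factor is a list(vars, card, val, lg):
#   vars : character vector of ground-node ids, first var varies fastest
#   card : integer cardinalities parallel to vars
#   val  : numeric vector of length prod(card), non-negative
#   lg   : log-scale offset; the represented table is val * exp(lg)
#
# Carrying the scale in `lg` and renormalising after products keeps long
# chains of multiplications away from the double-precision floor without
# paying the cost of elementwise log-sum-exp; exact zeros stay exact.

new_factor <- function(vars, card, val, lg = 0) {
  list(vars = vars, card = as.integer(card), val = as.numeric(val), lg = lg)
}

f_scalar <- function(value, lg = 0) new_factor(character(0), integer(0), value, lg)

# map each linear index of the (vars_to, card_to) space onto the linear index
# of the subspace spanned by vars_from (vars_from must be a subset of vars_to)
f_index_map <- function(vars_to, card_to, vars_from, card_from) {
  n <- prod(card_to)
  base <- 0:(n - 1L)
  stride_to <- cumprod(c(1L, card_to[-length(card_to)]))
  stride_from <- cumprod(c(1L, card_from[-length(card_from)]))
  map <- rep.int(0, n)
  for (j in seq_along(vars_from)) {
    p <- match(vars_from[j], vars_to)
    digit <- (base %/% stride_to[p]) %% card_to[p]
    map <- map + digit * stride_from[j]
  }
  map + 1
}

f_rescale <- function(f) {
  m <- max(f$val)
  if (m > 0 && (m > 1e100 || m < 1e-100)) {
    f$val <- f$val / m
    f$lg <- f$lg + log(m)
  }
  f
}

f_prod <- function(f1, f2) {
  if (length(f1$vars) == 0L) {
    f2$val <- f2$val * f1$val
    f2$lg <- f2$lg + f1$lg
    return(f_rescale(f2))
  }
  if (length(f2$vars) == 0L) {
    f1$val <- f1$val * f2$val
    f1$lg <- f1$lg + f2$lg
    return(f_rescale(f1))
  }
  extra <- !(f2$vars %in% f1$vars)
  vars <- c(f1$vars, f2$vars[extra])
  card <- c(f1$card, f2$card[extra])
  if (identical(vars, f1$vars)) {
    map2 <- f_index_map(vars, card, f2$vars, f2$card)
    val <- f1$val * f2$val[map2]
  } else {
    map1 <- f_index_map(vars, card, f1$vars, f1$card)
    map2 <- f_index_map(vars, card, f2$vars, f2$card)
    val <- f1$val[map1] * f2$val[map2]
  }
  f_rescale(new_factor(vars, card, val, f1$lg + f2$lg))
}

f_prod_all <- function(factors) {
  if (length(factors) == 0L) return(f_scalar(1))
  out <- factors[[1L]]
  for (f in factors[-1L]) out <- f_prod(out, f)
  out
}

# split dimensions around position `pos` so the var can be addressed as the
# middle index of an (n1, d, n2) array
.f_split <- function(f, v) {
  pos <- match(v, f$vars)
  if (is.na(pos)) stop("factor does not contain variable ", v)
  d <- f$card[pos]
  n1 <- prod(f$card[seq_len(pos - 1L)])
  n2 <- prod(f$card[-seq_len(pos)])
  list(pos = pos, d = d, n1 = as.integer(n1), n2 = as.integer(n2))
}

f_sumout <- function(f, v) {
  s <- .f_split(f, v)
  if (length(f$vars) == 1L) return(f_scalar(sum(f$val), f$lg))
  a <- array(f$val, c(s$n1, s$d, s$n2))
  res <- a[, 1L, , drop = FALSE]
  if (s$d > 1L) for (k in 2:s$d) res <- res + a[, k, , drop = FALSE]
  new_factor(f$vars[-s$pos], f$card[-s$pos], as.vector(res), f$lg)
}

# max-marginalise v; also return the argmax (state index of v, first maximum
# wins so ties resolve toward the earlier state) per remaining configuration
f_maxout <- function(f, v) {
  s <- .f_split(f, v)
  a <- array(f$val, c(s$n1, s$d, s$n2))
  best <- a[, 1L, , drop = FALSE]
  arg <- array(1L, c(s$n1, 1L, s$n2))
  if (s$d > 1L) {
    for (k in 2:s$d) {
      upd <- a[, k, , drop = FALSE] > best
      best[upd] <- a[, k, , drop = FALSE][upd]
      arg[upd] <- k
    }
  }
  fac <- if (length(f$vars) == 1L) f_scalar(as.vector(best), f$lg) else
    new_factor(f$vars[-s$pos], f$card[-s$pos], as.vector(best), f$lg)
  list(factor = fac, arg = new_factor(f$vars[-s$pos], f$card[-s$pos], as.vector(arg), 0))
}

# condition on v = state index s_idx and drop the dimension
f_restrict <- function(f, v, s_idx) {
  s <- .f_split(f, v)
  a <- array(f$val, c(s$n1, s$d, s$n2))
  val <- as.vector(a[, s_idx, , drop = FALSE])
  if (length(f$vars) == 1L) return(f_scalar(val, f$lg))
  new_factor(f$vars[-s$pos], f$card[-s$pos], val, f$lg)
}

# multiply a per-state weight vector w (length card of v) into the factor
f_weight <- function(f, v, w) {
  s <- .f_split(f, v)
  stride <- prod(f$card[seq_len(s$pos - 1L)])
  digit <- ((0:(length(f$val) - 1L)) %/% stride) %% s$d
  f$val <- f$val * w[digit + 1L]
  f_rescale(f)
}

# marginalise down to vars_keep (order of vars_keep imposed on the result)
f_marg_to <- function(f, vars_keep) {
  for (v in setdiff(f$vars, vars_keep)) f <- f_sumout(f, v)
  if (length(vars_keep) <= 1L || identical(f$vars, vars_keep)) return(f)
  map <- f_index_map(vars_keep, f$card[match(vars_keep, f$vars)], f$vars, f$card)
  new_factor(vars_keep, f$card[match(vars_keep, f$vars)], f$val[map], f$lg)
}

f_log_total <- function(f) {
  s <- sum(f$val)
  if (s <= 0) -Inf else f$lg + log(s)
}

# min-fill elimination order over `elim` given the factor scopes; ties broken
# lexicographically so inference is deterministic
min_fill_order <- function(scopes, elim) {
  adj <- new.env(parent = emptyenv())
  nodes <- unique(unlist(scopes, use.names = FALSE))
  for (v in nodes) assign(v, character(0), envir = adj)
  for (sc in scopes) {
    for (v in sc) assign(v, union(get(v, envir = adj), setdiff(sc, v)), envir = adj)
  }
  elim <- sort(elim)
  order_out <- character(0)
  remaining <- elim
  while (length(remaining) > 0L) {
    fill <- vapply(remaining, function(v) {
      nb <- setdiff(get(v, envir = adj), order_out)
      if (length(nb) < 2L) return(0L)
      cnt <- 0L
      for (i in seq_len(length(nb) - 1L)) {
        ni <- get(nb[i], envir = adj)
        cnt <- cnt + sum(!(nb[(i + 1L):length(nb)] %in% ni))
      }
      cnt
    }, integer(1))
    v <- remaining[which.min(fill)]  # remaining is sorted: first min = lexicographic
    nb <- setdiff(get(v, envir = adj), order_out)
    for (i in seq_along(nb)) {
      assign(nb[i], union(get(nb[i], envir = adj), setdiff(nb, nb[i])), envir = adj)
    }
    order_out <- c(order_out, v)
    remaining <- setdiff(remaining, v)
  }
  order_out
}

# sum- or max- variable elimination over `order`; returns the remaining
# factors and, in max mode, the traceback stack
ve_eliminate <- function(factors, order, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  trace <- list()
  for (v in order) {
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(touch)) next
    prod_f <- f_prod_all(factors[touch])
    factors <- factors[!touch]
    if (mode == "sum") {
      factors <- c(factors, list(f_sumout(prod_f, v)))
    } else {
      mx <- f_maxout(prod_f, v)
      trace[[v]] <- mx$arg
      factors <- c(factors, list(mx$factor))
    }
  }
  list(factors = factors, trace = trace)
}
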
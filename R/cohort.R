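# Seeded synthetic five-wave cohort generator. The ground-truth dynamic
# network mirrors the structure the analysis assumes for a child-nutrition
# panel: an 8-state nutrition target (N plus the seven single and combined
# undernutrition conditions), an 8-category programme-participation variable
# entering at wave 2, binarised household/parental covariates, three-band
# ages, lag-1 self-dependencies everywhere and a lag-2 dependency in the
# child-age progression. Tables are built by a logistic-contrast recipe: a
# base distribution tilted per parent configuration by an effect parameter,
# not copied from any data product.

#' Variable roster of the synthetic nutrition cohort
#'
#' Fourteen variables: the 8-state nutrition target CNS, child age band CA
#' and sex CS, maternal/paternal covariates (MSW, MA, ME, DA, DE), household
#' covariates (HS, WQ, FS, HHA, HHS) and the 8-category programme
#' participation status PS. PS and FS enter the panel at wave 2; CS is the
#' only non-temporal variable.
#'
#' @return Named list of [dbn_variable()].
#' @export
cohort_variables <- function() {
  edu <- c("Illiterate", "Literate")
  age3 <- c("Under30", "30-50", "Over50")
  v <- list(
    dbn_variable("CNS", c("N", "U", "S", "W", "US", "UW", "SW", "USW")),
    dbn_variable("CA", c("Infant", "EarlyChildhood", "Preadolescence", "Adolescent")),
    dbn_variable("CS", c("Male", "Female"), temporal = FALSE),
    dbn_variable("MSW", c("Low", "High")),
    dbn_variable("DA", age3),
    dbn_variable("DE", edu),
    dbn_variable("MA", age3),
    dbn_variable("ME", edu),
    dbn_variable("HS", c("<=6", ">6")),
    dbn_variable("WQ", c("Poor", "Wealthy")),
    dbn_variable("FS", c("Secure", "Insecure"), first_wave = 2L),
    dbn_variable("HHA", age3),
    dbn_variable("HHS", c("Male", "Female")),
    dbn_variable("PS", c("C", "P", "E", "H", "PE", "PH", "EH", "PEH"), first_wave = 2L))
  stats::setNames(v, vapply(v, `[[`, "", "name"))
}

# number of programmes per participation state
ps_nprog <- c(C = 0, P = 1, E = 1, H = 1, PE = 2, PH = 2, EH = 2, PEH = 3)
# "goodness" of each nutrition state: N best, USW worst
cns_good <- c(N = 1.5, U = 0.5, S = 0.5, W = 0.5, US = -0.5, UW = -0.5,
              SW = -0.5, USW = -1.5)
# baseline nutrition mix (normal ~ 50%, combined conditions common)
cns_base <- c(N = 0.497, U = 0.038, S = 0.078, W = 0.053, US = 0.141,
              UW = 0.111, SW = 0.001, USW = 0.081)

cohort_arcs <- function() {
  lag0 <- rbind(
    data.frame(parent = "PS", child = c("MSW", "WQ", "FS"), lag = 0L),
    data.frame(parent = c("WQ", "HS"), child = "FS", lag = 0L),
    data.frame(parent = c("WQ", "FS", "ME", "DE"), child = "CNS", lag = 0L),
    data.frame(parent = "ME", child = "WQ", lag = 0L))
  self1 <- data.frame(parent = c("CNS", "CA", "MSW", "DA", "DE", "MA", "ME",
                                 "HS", "WQ", "FS", "HHA", "HHS", "PS"),
                      child = c("CNS", "CA", "MSW", "DA", "DE", "MA", "ME",
                                "HS", "WQ", "FS", "HHA", "HHS", "PS"), lag = 1L)
  self2 <- data.frame(parent = "CA", child = "CA", lag = 2L)
  rbind(lag0, self1, self2)
}

# enumerate parent configurations of a schema as a data frame of state labels
schema_grid <- function(sch) {
  if (length(sch$parent_states) == 0L)
    return(data.frame(row.names = 1L))
  g <- do.call(expand.grid, c(stats::setNames(sch$parent_states,
                                              paste0("p", seq_along(sch$parent_states))),
                              list(stringsAsFactors = FALSE)))
  names(g) <- paste(sch$slots$parent, sch$slots$lag, sep = ".")
  g
}

# binary table P(child = states[2]) = plogis(q0 + contrast)
binary_rows <- function(q0, contrast) {
  p2 <- stats::plogis(q0 + contrast)
  cbind(1 - p2, p2)
}

# softmax tilt of a base distribution by score * goodness
tilted_rows <- function(base, good, score) {
  t(vapply(score, function(s) {
    w <- base * exp(s * good)
    w / sum(w)
  }, numeric(length(base))))
}

#' Ground-truth dynamic network for the synthetic cohort
#'
#' Builds a valid 14-variable, 5-wave network whose table contrast scales
#' with `effect_strength`. Programme participation raises maternal
#' well-being, wealth and food security; wealth and food security (with
#' parental education) drive the nutrition target; child age advances
#' deterministically through the four bands; the expert-implausible arcs
#' (father's covariates into household headship, anything into child sex,
#' child sex into wealth, child age into mother's age) are absent.
#'
#' @param effect_strength `"weak"`, `"moderate"` or `"strong"`.
#' @return A [dbn_network()].
#' @export
default_truth <- function(effect_strength = c("strong", "moderate", "weak")) {
  effect_strength <- match.arg(effect_strength)
  e <- c(weak = 0.25, moderate = 0.6, strong = 1)[[effect_strength]]
  vars <- cohort_variables()
  struct <- dbn_structure(unname(vars), cohort_arcs(), horizon = 5L)
  schemas <- table_schemas(struct)
  sgn <- function(x, pos) ifelse(x == pos, 1, -1)
  probs <- list()
  for (key in names(schemas)) {
    sch <- schemas[[key]]
    g <- schema_grid(sch)
    col <- function(v, l) g[[paste(v, l, sep = ".")]]
    n <- max(nrow(g), 1L)
    probs[[key]] <- switch(sch$var,
      CS = matrix(c(0.51, 0.49), n, 2L, byrow = TRUE),
      CA = {
        m <- matrix(1 / 4, n, 4L)
        st <- vars$CA$states
        if (is.null(col("CA", 1L))) {          # wave 0: everyone an infant
          m <- matrix(c(1, 0, 0, 0), 1L, 4L)
        } else if (is.null(col("CA", 2L))) {   # wave 1: infants grow up
          l1 <- col("CA", 1L)
          m[l1 == "Infant", ] <- matrix(c(0, 1, 0, 0), sum(l1 == "Infant"), 4L, byrow = TRUE)
        } else {                               # waves 2+: deterministic ageing
          l1 <- col("CA", 1L); l2 <- col("CA", 2L)
          m[l1 == "EarlyChildhood" & l2 == "Infant", ] <-
            matrix(c(0, 0, 1, 0), sum(l1 == "EarlyChildhood" & l2 == "Infant"), 4L, byrow = TRUE)
          m[l1 == "Preadolescence" & l2 == "EarlyChildhood", ] <-
            matrix(c(0, 0, 1, 0), sum(l1 == "Preadolescence" & l2 == "EarlyChildhood"), 4L, byrow = TRUE)
          m[l1 == "Preadolescence" & l2 == "Preadolescence", ] <-
            matrix(c(0, 0, 0, 1), sum(l1 == "Preadolescence" & l2 == "Preadolescence"), 4L, byrow = TRUE)
        }
        m
      },
      HHS = {
        q0 <- stats::qlogis(0.22)  # P(Female head) base
        contrast <- if (!is.null(col("HHS", 1L))) 3.4 * sgn(col("HHS", 1L), "Female") else 0
        binary_rows(q0, contrast)
      },
      MSW = {
        q0 <- stats::qlogis(0.45)
        contrast <- 0
        if (!is.null(col("PS", 0L))) contrast <- contrast + e * 0.55 * (ps_nprog[col("PS", 0L)] - 1.5)
        if (!is.null(col("MSW", 1L))) contrast <- contrast + 0.8 * sgn(col("MSW", 1L), "High")
        binary_rows(q0, contrast)
      },
      WQ = {
        q0 <- stats::qlogis(0.30)
        contrast <- e * 0.5 * sgn(col("ME", 0L), "Literate")
        if (!is.null(col("PS", 0L))) contrast <- contrast + e * 0.6 * (ps_nprog[col("PS", 0L)] - 1.5)
        if (!is.null(col("WQ", 1L))) contrast <- contrast + 1.1 * sgn(col("WQ", 1L), "Wealthy")
        binary_rows(q0, contrast)
      },
      FS = {  # second state is Insecure, so flip the sign of the contrast
        q0 <- stats::qlogis(1 - 0.55)
        contrast <- e * (0.5 * (ps_nprog[col("PS", 0L)] - 1.5) +
                           0.7 * sgn(col("WQ", 0L), "Wealthy") +
                           0.4 * sgn(col("HS", 0L), "<=6"))
        if (!is.null(col("FS", 1L))) contrast <- contrast + 0.9 * sgn(col("FS", 1L), "Secure")
        binary_rows(q0, -contrast)
      },
      HS = {
        q0 <- stats::qlogis(1 - 0.62)  # second state is ">6"
        contrast <- if (!is.null(col("HS", 1L))) 1.6 * sgn(col("HS", 1L), "<=6") else 0
        binary_rows(q0, -contrast)
      },
      ME = {
        q0 <- stats::qlogis(0.32)
        contrast <- if (!is.null(col("ME", 1L))) 5 * sgn(col("ME", 1L), "Literate") else 0
        binary_rows(q0, contrast)
      },
      DE = {
        q0 <- stats::qlogis(0.42)
        contrast <- if (!is.null(col("DE", 1L))) 5 * sgn(col("DE", 1L), "Literate") else 0
        binary_rows(q0, contrast)
      },
      MA = age_rows(vars$MA$states, c(0.55, 0.40, 0.05), col("MA", 1L)),
      DA = age_rows(vars$DA$states, c(0.35, 0.55, 0.10), col("DA", 1L)),
      HHA = age_rows(vars$HHA$states, c(0.30, 0.55, 0.15), col("HHA", 1L)),
      PS = {
        if (is.null(col("PS", 1L))) {
          matrix(c(0.40, 0.12, 0.10, 0.08, 0.10, 0.06, 0.06, 0.08), 1L, 8L, byrow = TRUE)
        } else {
          st <- vars$PS$states
          t(vapply(col("PS", 1L), function(prev) {
            w <- exp(-1.2 * abs(ps_nprog[st] - ps_nprog[[prev]]) + 0.25 * ps_nprog[st])
            w[st == prev] <- w[st == prev] * 2.2
            w / sum(w)
          }, numeric(8L)))
        }
      },
      CNS = {
        score <- e * (0.4 * sgn(col("ME", 0L), "Literate") +
                        0.4 * sgn(col("DE", 0L), "Literate") +
                        0.8 * sgn(col("WQ", 0L), "Wealthy"))
        if (!is.null(col("FS", 0L))) score <- score + e * 0.8 * sgn(col("FS", 0L), "Secure")
        if (!is.null(col("CNS", 1L))) score <- score + 0.6 * (cns_good[col("CNS", 1L)] / 1.5)
        tilted_rows(cns_base[vars$CNS$states], cns_good[vars$CNS$states], score)
      },
      stop("no table recipe for ", sch$var))
  }
  dbn_network(struct, tables_from_probs(struct, probs))
}

# ordered 3-band age process: initial mix, then advance-or-stay
age_rows <- function(states, init, prev) {
  if (is.null(prev)) return(matrix(init, 1L, 3L, byrow = TRUE))
  t(vapply(prev, function(p) {
    switch(p,
           "Under30" = c(0.45, 0.55, 0),
           "30-50" = c(0, 0.85, 0.15),
           "Over50" = c(0, 0, 1))
  }, numeric(3L)))
}

#' Configuration for a synthetic cohort
#'
#' Defaults state the emulated panel: 1999 subjects, five waves, strong
#' effect contrast, 10% missingness completely at random.
#'
#' @param n_subjects Number of subjects.
#' @param effect_strength `"weak"`, `"moderate"` or `"strong"`.
#' @param missing_mechanism `"MCAR"` (uniform cell deletion) or `"MAR"`
#'   (rate depends on the always-observed child sex and the wave index).
#' @param missing_rate Cell deletion rate in `[0, 0.5]`.
#' @param seed Integer seed; identical configurations sample identical cohorts.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 1999L, effect_strength = "strong",
                          missing_mechanism = c("MCAR", "MAR"),
                          missing_rate = 0.1, seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  stopifnot(missing_rate >= 0, missing_rate <= 0.5, n_subjects >= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 waves = 5L,
                 effect_strength = effect_strength,
                 missing_mechanism = missing_mechanism,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Sample a synthetic cohort from the ground-truth network
#'
#' Ancestral (forward) sampling in topological order of the unrolled
#' network, followed by the configured missingness mechanism. Identical
#' configurations (including seed) give identical bundles; masked cells are
#' recorded before removal so imputation can be scored against the truth.
#'
#' @param config A [cohort_config()].
#' @param truth Optional [dbn_network()] to sample from; defaults to
#'   [default_truth()] at the configured effect strength.
#' @return An object of class `cohort_bundle`: `network`, `data` (a
#'   [panel_dataset()] with missing cells), `complete` (pre-mask data) and
#'   `mask` (data frame of removed cells with their true states).
#' @export
sample_cohort <- function(config = cohort_config(), truth = NULL) {
  net <- if (is.null(truth)) default_truth(config$effect_strength) else truth
  ground <- unroll(net)
  n <- config$n_subjects
  samp <- with_seed_(derive_seed(config$seed, "sample"), {
    out <- list()
    for (id in ground$topo) {
      f <- ground$factors[[id]]
      k <- length(ground$states[[id]])
      if (length(f$vars) == 1L) {
        rows <- rep(1L, n)
        pm <- matrix(f$val, 1L, k)
      } else {
        pcards <- f$card[-length(f$card)]
        stride <- cumprod(c(1L, pcards[-length(pcards)]))
        rows <- rep(1L, n)
        for (j in seq_along(f$vars[-length(f$vars)])) {
          rows <- rows + (out[[f$vars[j]]] - 1L) * stride[j]
        }
        pm <- matrix(f$val, ncol = k)
      }
      cp <- pm %*% upper.tri(diag(k), diag = TRUE)  # row-wise cumulative probs
      u <- stats::runif(n)
      out[[id]] <- 1L + as.integer(rowSums(u > cp[rows, , drop = FALSE]))
    }
    out
  })
  struct <- net$structure
  waves <- struct$horizon
  df <- data.frame(subject_id = rep(sprintf("S%05d", seq_len(n)), each = waves),
                   wave = rep.int(0:(waves - 1L), n), stringsAsFactors = FALSE)
  for (v in names(struct$variables)) {
    vals <- rep(NA_character_, nrow(df))
    st <- struct$variables[[v]]$states
    for (t in struct$variables[[v]]$first_wave:(waves - 1L)) {
      vals[df$wave == t] <- st[samp[[node_id(v, t)]]]
    }
    df[[v]] <- vals
  }
  complete <- panel_dataset(df, struct, waves = waves)

  masked <- df
  mask_rows <- NULL
  if (config$missing_rate > 0) {
    mask_rows <- with_seed_(derive_seed(config$seed, "missing"), {
      acc <- list()
      for (v in names(struct$variables)) {
        fw <- struct$variables[[v]]$first_wave
        eligible <- which(df$wave >= fw)
        if (config$missing_mechanism == "MCAR") {
          r <- rep(config$missing_rate, length(eligible))
        } else {
          if (v == "CS") next  # the MAR driver stays observed
          r <- config$missing_rate *
            (0.5 + 0.4 * (df$CS[eligible] == "Female") + 0.15 * df$wave[eligible])
          r <- pmin(r, 0.95)
        }
        hit <- eligible[stats::runif(length(eligible)) < r]
        if (length(hit) > 0L)
          acc[[v]] <- data.frame(subject_id = df$subject_id[hit], wave = df$wave[hit],
                                 variable = v, true_state = df[[v]][hit],
                                 stringsAsFactors = FALSE)
      }
      do.call(rbind, acc)
    })
    if (!is.null(mask_rows)) {
      for (v in unique(mask_rows$variable)) {
        mr <- mask_rows[mask_rows$variable == v, ]
        masked[[v]][match(paste(mr$subject_id, mr$wave),
                          paste(masked$subject_id, masked$wave))] <- NA_character_
      }
    }
  }
  if (is.null(mask_rows))
    mask_rows <- data.frame(subject_id = character(0), wave = integer(0),
                            variable = character(0), true_state = character(0))
  structure(list(network = net, config = config,
                 data = panel_dataset(masked, struct, waves = waves),
                 complete = complete, mask = mask_rows),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Synthetic cohort:", x$config$n_subjects, "subjects,",
      x$config$effect_strength, "effects,", nrow(x$mask), "masked cells\n")
  invisible(x)
}

#' Quantize a numeric series into ordered categorical bins
#'
#' Bins are half-open `[lo, hi)` with the last bin closed; the returned
#' edges can be reused on new data.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins (>= 2).
#' @param method `"equal-width"` or `"equal-frequency"` (quantile edges).
#' @return List with `labels` (character `"B1".."Bn"` per value), `edges`
#'   (length `n_bins + 1`) and `method`.
#' @export
quantize <- function(x, n_bins, method = c("equal-width", "equal-frequency")) {
  method <- match.arg(method)
  stopifnot(n_bins >= 2L, is.numeric(x), length(x) > 0L, !anyNA(x))
  if (method == "equal-frequency") {
    if (length(unique(x)) < n_bins)
      stop("series has fewer than n_bins distinct values; use method = \"equal-width\"")
    edges <- unname(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                                    type = 7))
    if (anyDuplicated(edges))
      stop("tied quantile edges; use method = \"equal-width\" or fewer bins")
  } else {
    if (min(x) == max(x)) stop("constant series cannot be binned")
    edges <- seq(min(x), max(x), length.out = n_bins + 1L)
  }
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  list(labels = sprintf("B%d", idx), edges = edges, method = method)
}
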
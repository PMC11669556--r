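# Information-theoretic metrics (base-2 throughout) for feature ranking and
# value-of-information, both model-based (exact inference) and empirical
# (counts with a pseudocount).

#' Shannon entropy of a categorical distribution, in bits
#'
#' @param p Normalised probability vector (`0 log 0 = 0`).
#' @return Entropy in bits, in `[0, log2(length(p))]`.
#' @export
entropy_bits <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("p must be a normalised probability vector")
  pos <- p > 0
  -sum(p[pos] * log2(p[pos]))
}

#' Mutual information of a two-way joint distribution, in bits
#'
#' `MI = H(X) + H(Y) - H(X, Y)`, clipped to zero from below (tolerance
#' 1e-12); symmetric in its arguments.
#'
#' @param joint Normalised matrix `P(X = row, Y = col)`.
#' @return Mutual information in bits (>= 0).
#' @export
mutual_information <- function(joint) {
  joint <- as.matrix(joint)
  if (any(joint < 0) || abs(sum(joint) - 1) > 1e-6)
    stop("joint must be a normalised probability matrix")
  mi <- entropy_bits(rowSums(joint)) + entropy_bits(colSums(joint)) -
    entropy_bits(as.vector(joint))
  if (mi < -1e-12) stop("internal: MI below -1e-12")
  max(mi, 0)
}

# model-based joint of two ground nodes (exact inference)
model_joint <- function(ground, x, y, evidence = list()) {
  jf <- posterior_joint(ground, evidence, c(x, y))
  matrix(jf$val, nrow = jf$card[1L], ncol = jf$card[2L],
         dimnames = list(ground$states[[x]], ground$states[[y]]))
}

# empirical joint from panel counts, pooled over waves where both variables
# are observable, with `pseudocount` added per cell to avoid log 0
empirical_joint <- function(data, feature, target, pseudocount = 0.5,
                            waves = NULL) {
  vars <- panel_variables(data)
  fv <- vars[[feature]]; tv <- vars[[target]]
  if (is.null(fv)) stop("feature '", feature, "' is absent at the requested waves")
  if (is.null(tv)) stop("unknown target variable: ", target)
  if (is.null(waves)) waves <- max(fv$first_wave, tv$first_wave):(panel_waves(data) - 1L)
  if (any(waves < fv$first_wave))
    stop("feature '", feature, "' is absent at the requested waves")
  sel <- data$wave %in% waves
  fx <- factor(data[[feature]][sel], levels = fv$states)
  fy <- factor(data[[target]][sel], levels = tv$states)
  tab <- table(fx, fy) + pseudocount
  tab / sum(tab)
}

#' Entropy reduction of the target from observing a feature
#'
#' `H(target) - H(target | feature)` with `H(target | feature) =
#' sum_x P(x) H(target | feature = x)`; for the pairwise definitions used
#' here this equals the mutual information. The model-based version
#' (`dbn_ground` input) uses exact inferred joints at a shared wave; the
#' empirical version (`panel_dataset` input) uses pooled counts with a
#' pseudocount.
#'
#' @param obj A `dbn_ground` network or a [panel_dataset()].
#' @param feature,target Variable names.
#' @param wave Wave at which the model-based joint is taken (default: first
#'   wave where both exist).
#' @param ... Passed on (`pseudocount`, `waves` for the empirical version).
#' @return Entropy reduction in bits.
#' @export
target_entropy_reduction <- function(obj, feature, target, ...) {
  mutual_information(feature_joint(obj, feature, target, ...))
}

feature_joint <- function(obj, feature, target, wave = NULL, ...) {
  if (inherits(obj, "dbn_ground")) {
    struct <- obj$network$structure
    fv <- struct$variables[[feature]]; tv <- struct$variables[[target]]
    if (is.null(fv)) stop("unknown feature variable: ", feature)
    if (is.null(wave)) wave <- max(fv$first_wave, tv$first_wave)
    x <- node_id(feature, wave); y <- node_id(target, wave)
    if (!(x %in% obj$nodes$id))
      stop("feature '", feature, "' is absent at wave ", wave)
    if (identical(x, y)) {
      p <- posterior(obj, list(), x)$marginals[[x]]
      return(diag(as.numeric(p)))
    }
    model_joint(obj, x, y)
  } else if (inherits(obj, "panel_dataset")) {
    empirical_joint(obj, feature, target, ...)
  } else stop("obj must be a dbn_ground or panel_dataset")
}

#' Rank candidate features by mutual information with the target
#'
#' Descending by MI, ties by entropy reduction then by name; candidates at
#' or above `selection_threshold` are flagged selected. The result is
#' invariant to the input order of `candidates`.
#'
#' @inheritParams target_entropy_reduction
#' @param candidates Character vector of feature names.
#' @param selection_threshold MI (bits) at/above which a feature is selected.
#' @return Data frame of class `dbn_ranking`: mutual information, entropy
#'   reduction, residual target entropy, rank and selection flag.
#' @export
rank_features <- function(obj, candidates, target, selection_threshold = 0, ...) {
  stopifnot(length(candidates) >= 1L)
  rows <- lapply(sort(unique(candidates)), function(v) {
    j <- feature_joint(obj, v, target, ...)
    ht <- entropy_bits(colSums(j))
    mi <- mutual_information(j)
    data.frame(variable = v, mutual_information = mi,
               target_entropy_reduction = mi,
               target_entropy = ht - mi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mutual_information, -out$target_entropy_reduction,
                   out$variable), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$selected <- out$mutual_information >= selection_threshold
  rownames(out) <- NULL
  class(out) <- c("dbn_ranking", "data.frame")
  out
}

#' Value of information of observing a candidate node
#'
#' Expected reduction in the target's posterior entropy from observing the
#' candidate, given current evidence:
#' `H(target | E) - sum_x P(x | E) H(target | E, candidate = x)`,
#' clipped to zero from below.
#'
#' @inheritParams posterior
#' @param target,candidate Ground node ids; the candidate must not already
#'   be hard-evidenced.
#' @return Value of information in bits (>= 0).
#' @export
value_of_information <- function(ground, target, candidate, evidence = list()) {
  ev <- check_evidence(ground, evidence)
  if (candidate %in% names(ev$hard))
    stop("candidate ", candidate, " is already hard-evidenced")
  base <- posterior(ground, evidence, c(target, candidate))
  h0 <- entropy_bits(base$marginals[[target]])
  px <- base$marginals[[candidate]]
  h1 <- 0
  for (s in names(px)) {
    if (px[[s]] <= 0) next
    ev2 <- evidence
    ev2[[candidate]] <- s
    h1 <- h1 + px[[s]] * entropy_bits(posterior(ground, ev2, target)$marginals[[target]])
  }
  max(h0 - h1, 0)
}

#' Write a feature ranking as delimited text
#' @param ranking A [rank_features()] result.
#' @param path File path.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.csv(as.data.frame(ranking), path, row.names = FALSE)
  invisible(path)
}
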
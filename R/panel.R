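#' Longitudinal panel dataset of categorical observations
#'
#' A panel dataset is a subjects x waves x variables grid of categorical
#' observations in long format: one row per subject-wave, columns
#' `subject_id`, `wave` (0-based) and one column per variable. `NA` marks a
#' missing cell. Cells before a variable's `first_wave` are structurally
#' absent (forced to `NA` and never counted as "missing" by learning code).
#'
#' @param df Data frame with columns `subject_id`, `wave` and one column per
#'   declared variable.
#' @param variables List of [dbn_variable()] (or a [dbn_structure()], whose
#'   variables are used).
#' @param waves Number of waves; defaults to `max(df$wave) + 1`.
#' @return An object of class `panel_dataset` (a data frame, grid-completed
#'   and ordered by subject then wave).
#' @export
panel_dataset <- function(df, variables, waves = NULL) {
  if (inherits(variables, "dbn_structure")) variables <- variables$variables
  if (inherits(variables, "dbn_variable")) variables <- list(variables)
  nm <- vapply(variables, `[[`, "", "name")
  names(variables) <- nm
  need <- c("subject_id", "wave", nm)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("panel is missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need, drop = FALSE]
  df$subject_id <- as.character(df$subject_id)
  df$wave <- as.integer(df$wave)
  if (is.null(waves)) waves <- max(df$wave) + 1L
  waves <- as.integer(waves)
  if (any(df$wave < 0L | df$wave >= waves))
    stop("wave indices outside [0, ", waves - 1L, "]")
  if (anyDuplicated(df[, c("subject_id", "wave")]))
    stop("duplicated subject-wave rows")
  # complete the subject x wave grid
  subjects <- unique(df$subject_id)
  grid <- data.frame(subject_id = rep(subjects, each = waves),
                     wave = rep.int(0:(waves - 1L), length(subjects)),
                     stringsAsFactors = FALSE)
  df <- merge(grid, df, by = c("subject_id", "wave"), all.x = TRUE, sort = FALSE)
  df <- df[order(match(df$subject_id, subjects), df$wave), , drop = FALSE]
  rownames(df) <- NULL
  bad <- character(0)
  for (v in nm) {
    df[[v]] <- as.character(df[[v]])
    unknown <- !is.na(df[[v]]) & !(df[[v]] %in% variables[[v]]$states)
    if (any(unknown)) {
      w <- which(unknown)[seq_len(min(10L, sum(unknown)))]
      bad <- c(bad, sprintf("column %s: state '%s' at subject %s wave %d",
                            v, df[[v]][w], df$subject_id[w], df$wave[w]))
    }
    df[[v]][df$wave < variables[[v]]$first_wave] <- NA_character_
  }
  if (length(bad) > 0L)
    stop("unknown states in panel:\n  ", paste(utils::head(bad, 10L), collapse = "\n  "))
  structure(df, variables = variables, waves = waves,
            class = c("panel_dataset", "data.frame"))
}

panel_variables <- function(data) attr(data, "variables")
panel_waves <- function(data) attr(data, "waves")
panel_subjects <- function(data) unique(data$subject_id)

#' @export
print.panel_dataset <- function(x, ...) {
  cat("Panel dataset:", length(panel_subjects(x)), "subjects,",
      panel_waves(x), "waves,", length(panel_variables(x)), "variables\n")
  NextMethod()
}

# integer state-index matrix: rows = subjects, columns = ground node ids
# (only observable variable-wave pairs); NA = missing
panel_matrix <- function(data, struct) {
  vars <- struct$variables
  waves <- struct$horizon
  subjects <- panel_subjects(data)
  stopifnot(panel_waves(data) >= waves)
  cols <- list()
  for (v in names(vars)) {
    vr <- vars[[v]]
    idx <- match(data[[v]], vr$states)
    for (t in vr$first_wave:(waves - 1L)) {
      cols[[node_id(v, t)]] <- idx[data$wave == t]
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- subjects
  m
}

# per-subject named state-label records over the ground node ids
panel_records <- function(data, ground) {
  struct <- ground$network$structure
  m <- panel_matrix(data, struct)
  ids <- intersect(colnames(m), ground$nodes$id)
  m <- m[, ids, drop = FALSE]
  states <- ground$states[ids]
  out <- lapply(seq_len(nrow(m)), function(i) {
    r <- vapply(seq_along(ids), function(j) {
      k <- m[i, j]
      if (is.na(k)) NA_character_ else states[[j]][k]
    }, "")
    stats::setNames(r, ids)
  })
  names(out) <- rownames(m)
  out
}

#' Read / write a panel dataset as delimited text
#'
#' The on-disk format is a delimited text file with a header row and columns
#' `subject_id`, `wave`, then one column per variable; missing cells are an
#' explicit token (default `"NA"`). `read_panel(write_panel(x))` is the
#' identity on cell values and missingness.
#'
#' @param path File path.
#' @param variables List of [dbn_variable()] or a [dbn_structure()].
#' @param missing_token Token encoding a missing cell.
#' @param sep Field separator.
#' @param waves Passed to [panel_dataset()].
#' @return A [panel_dataset()].
#' @export
read_panel <- function(path, variables, missing_token = "NA", sep = ",", waves = NULL) {
  dt <- data.table::fread(path, sep = sep, colClasses = "character",
                          na.strings = missing_token, header = TRUE,
                          data.table = FALSE, keepLeadingZeros = TRUE)
  if (!all(c("subject_id", "wave") %in% names(dt)))
    stop("panel file must have 'subject_id' and 'wave' columns: ", path)
  suppressWarnings(dt$wave <- as.integer(dt$wave))
  if (anyNA(dt$wave)) {
    off <- which(is.na(dt$wave))
    stop("malformed wave values at rows: ",
         paste(utils::head(off, 10L), collapse = ", "))
  }
  panel_dataset(dt, variables, waves = waves)
}

#' @param data A [panel_dataset()].
#' @rdname read_panel
#' @export
write_panel <- function(data, path, missing_token = "NA", sep = ",") {
  out <- as.data.frame(data)
  data.table::fwrite(out, path, sep = sep, na = missing_token, quote = FALSE)
  invisible(path)
}
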
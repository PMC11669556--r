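#' Write / read a dynamic network as JSON
#'
#' The serialization is a self-describing JSON document with sections
#' `variables`, `arcs` and `tables`; states are stored as strings and
#' probabilities as decimal numbers at full double precision, so the
#' round-trip is lossless to well below 1e-12.
#'
#' @param net A [dbn_network()].
#' @param path File path.
#' @return `write_dbn` returns `path` invisibly; `read_dbn` returns the network.
#' @export
write_dbn <- function(net, path) {
  struct <- net$structure
  ser_cpt <- function(cpt) {
    if (is.null(cpt)) return(NULL)
    list(slots = cpt$slots, prob = cpt$prob)
  }
  doc <- list(
    format = "dbnpanel-network",
    version = 1L,
    horizon = struct$horizon,
    variables = lapply(unname(struct$variables), function(v)
      list(name = v$name, states = v$states, temporal = v$temporal,
           first_wave = v$first_wave)),
    arcs = struct$arcs,
    tables = lapply(net$tables, function(tl) {
      list(transition = ser_cpt(tl$transition),
           initial = if (length(tl$initial) > 0L) lapply(tl$initial, ser_cpt))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dbn
#' @export
read_dbn <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE,
                             simplifyMatrix = TRUE)
  if (!identical(doc$format, "dbnpanel-network"))
    stop("not a dbnpanel network document: ", path)
  vars <- lapply(seq_len(nrow(doc$variables)), function(i) {
    v <- doc$variables[i, ]
    dbn_variable(v$name, unlist(v$states), v$temporal, v$first_wave)
  })
  arcs <- doc$arcs
  if (is.null(arcs) || length(arcs) == 0L || (is.data.frame(arcs) && nrow(arcs) == 0L))
    arcs <- NULL
  struct <- dbn_structure(vars, arcs, doc$horizon)
  de_cpt <- function(v, x) {
    if (is.null(x)) return(NULL)
    slots <- as.data.frame(x$slots)
    if (nrow(slots) == 0L) slots <- data.frame(parent = character(0), lag = integer(0))
    ps <- lapply(slots$parent, function(p) struct$variables[[p]]$states)
    prob <- x$prob
    if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1L)
    dbn_cpt(v, struct$variables[[v]]$states, slots, ps, prob)
  }
  tables <- list()
  for (v in names(doc$tables)) {
    tl <- doc$tables[[v]]
    tables[[v]] <- list(transition = de_cpt(v, tl$transition),
                        initial = if (!is.null(tl$initial))
                          lapply(tl$initial, function(x) de_cpt(v, x)))
  }
  dbn_network(struct, tables)
}

#' Export a network to Graphviz DOT
#'
#' @param net A [dbn_network()] or [dbn_structure()].
#' @param path Optional file to write to.
#' @param view `"template"` (one node per variable, arcs annotated with lag)
#'   or `"ground"` (one node per variable-wave pair).
#' @return The DOT source as a character scalar (invisibly if `path` given).
#' @export
dbn_to_dot <- function(net, path = NULL, view = c("template", "ground")) {
  view <- match.arg(view)
  struct <- if (inherits(net, "dbn_structure")) net else net$structure
  esc <- function(x) gsub('"', '\\"', x, fixed = TRUE)
  if (view == "template") {
    lines <- c("digraph dbn {", "  rankdir=LR;",
               sprintf('  "%s";', esc(names(struct$variables))),
               sprintf('  "%s" -> "%s" [label="lag %d"%s];',
                       esc(struct$arcs$parent), esc(struct$arcs$child), struct$arcs$lag,
                       ifelse(struct$arcs$lag > 0L, ", style=dashed", "")),
               "}")
  } else {
    if (inherits(net, "dbn_structure"))
      stop("ground view needs a full network")
    gr <- unroll(net)
    arcs <- ground_arcs(gr)
    lines <- c("digraph dbn_ground {", "  rankdir=LR;",
               sprintf('  "%s";', esc(gr$nodes$id)),
               sprintf('  "%s" -> "%s";', esc(arcs$from), esc(arcs$to)),
               "}")
  }
  src <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(src, path)
    return(invisible(src))
  }
  src
}
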
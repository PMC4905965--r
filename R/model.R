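#' Build a unified SEM from a node set and a directed edge list
#'
#' Every ROI enters the model as two observed variables, the original
#' series (unlagged) and its one-step-offset copy (lagged).  Each directed
#' edge A -> B expands to exactly three paths: A_unlagged -> B_unlagged,
#' A_lagged -> B_lagged and A_unlagged -> B_lagged; every node additionally
#' contributes its autoregressive path A_unlagged -> A_lagged.  Residual
#' variances of all `2n` variables are free; exogenous covariances are
#' fixed at zero.  An edge flagged bidirectional contributes both
#' directions' path triples (a non-recursive feedback loop).
#'
#' @param nodes character vector of node labels.
#' @param edges data frame with columns `source`, `target` and optionally
#'   `bidirectional` (default `FALSE`), or `NULL` for the null model that
#'   contains only the autoregressive paths.
#' @return A `usem_model`.
#' @export
build_usem <- function(nodes, edges = NULL) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(source = character(0), target = character(0),
                        bidirectional = logical(0), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(edges$bidirectional)) edges$bidirectional <- FALSE
    bad <- !(edges$source %in% nodes) | !(edges$target %in% nodes)
    if (any(bad))
      stop("edge endpoints not in node set: ",
           paste(edges$source[bad], "->", edges$target[bad], collapse = ", "))
    if (any(edges$source == edges$target))
      stop("self-edges are not allowed")
    key <- paste(edges$source, edges$target)
    if (anyDuplicated(key))
      stop("duplicate edge: ", key[duplicated(key)][1])
  }
  structure(list(nodes = nodes, edges = edges), class = "usem_model")
}

#' @export
print.usem_model <- function(x, ...) {
  cat(sprintf("usem_model: %d nodes, %d edges (%d bidirectional)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$bidirectional)))
  invisible(x)
}

# Directed edges after expanding bidirectional flags into both directions.
directed_edges <- function(model) {
  e <- model$edges
  if (nrow(e) == 0)
    return(data.frame(source = character(0), target = character(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(source = e$source, target = e$target,
                    stringsAsFactors = FALSE)
  if (any(e$bidirectional))
    out <- rbind(out, data.frame(source = e$target[e$bidirectional],
                                 target = e$source[e$bidirectional],
                                 stringsAsFactors = FALSE))
  out
}

#' Free parameters and degrees of freedom of a unified SEM
#'
#' With `n` nodes and `E` directed path triples, each group carries
#' `3E + n` path coefficients and `2n` residual variances.  The model
#' degrees of freedom are `G * p(p+1)/2 - q` with `p = 2n` observed
#' variables per group and `q` the total free-parameter count (`G`-fold
#' under per-cohort free parameters, shared under equality constraints).
#'
#' @param model a `usem_model`.
#' @param n_groups number of cohorts fitted jointly.
#' @param grouping `"free"` (per-cohort parameters) or `"equal"`.
#' @return List with `q_per_group`, `q`, `p`, `moments` and `df`.
#' @export
usem_df <- function(model, n_groups = 1L, grouping = c("free", "equal")) {
  grouping <- match.arg(grouping)
  n <- length(model$nodes)
  nd <- nrow(directed_edges(model))
  q_per_group <- 3L * nd + n + 2L * n
  q <- if (grouping == "free") n_groups * q_per_group else q_per_group
  p <- 2L * n
  moments <- n_groups * p * (p + 1L) / 2L
  list(q_per_group = q_per_group, q = q, p = p, moments = moments,
       df = as.integer(moments - q))
}

#' Read / write a model specification JSON
#'
#' Format: `{"nodes": [...], "edges": [{"source", "target",
#' "bidirectional"}], "grouping": "free"|"equal"}`.
#'
#' @param path JSON file path.
#' @return For the reader, a list with `model` and `grouping`.
#' @export
read_model_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  edges <- if (length(j$edges) == 0) NULL else as.data.frame(j$edges)
  list(model = build_usem(unlist(j$nodes), edges),
       grouping = if (is.null(j$grouping)) "free" else j$grouping)
}

#' @param model a `usem_model`.
#' @param grouping parameter grouping recorded alongside the model.
#' @rdname read_model_json
#' @export
write_model_json <- function(model, path, grouping = "free") {
  jsonlite::write_json(
    list(nodes = model$nodes,
         edges = model$edges,
         grouping = grouping),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
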
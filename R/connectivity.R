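#' Construct a connectivity table
#'
#' A directed weighted connectome: an edge list of synapse counts between
#' neuron ids plus an id-to-cell-class map. Duplicate (pre, post) pairs
#' are aggregated by summing counts.
#'
#' @param edges data frame with columns `pre`, `post`, `count` (positive
#'   integers).
#' @param class_map named character vector, neuron id -> class label,
#'   covering every id in `edges`.
#' @param side_map optional named character vector, id -> "left"/"right".
#' @return An object of class `connectivity_table`.
#' @export
connectivity_table <- function(edges, class_map, side_map = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("pre", "post", "count") %in% names(edges)))
  edges$pre <- as.character(edges$pre)
  edges$post <- as.character(edges$post)
  if (any(edges$count <= 0) || any(edges$count != round(edges$count)))
    stop("synapse counts must be positive integers")
  key <- paste(edges$pre, edges$post, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(edges$count, key, sum)
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    edges <- data.frame(pre = vapply(parts, `[`, "", 1L),
                        post = vapply(parts, `[`, "", 2L),
                        count = as.integer(agg),
                        stringsAsFactors = FALSE)
  }
  ids <- unique(c(edges$pre, edges$post))
  missing <- setdiff(ids, names(class_map))
  if (length(missing) > 0)
    stop("ids missing from class_map: ", paste(missing, collapse = ", "))
  rownames(edges) <- NULL
  structure(list(edges = edges, class_map = class_map,
                 side_map = side_map), class = "connectivity_table")
}

#' @export
print.connectivity_table <- function(x, ...) {
  cat(sprintf("connectivity_table: %d edges, %d neurons, %d classes\n",
              nrow(x$edges), length(x$class_map),
              length(unique(x$class_map))))
  invisible(x)
}

#' Per-class input fractions onto a target set
#'
#' For each upstream cell class, the percentage of all synapses received
#' by the target neurons that come from that class:
#' `100 * synapses(class -> targets) / synapses(all -> targets)`.
#' Percentages sum to 100.
#'
#' @param table a `connectivity_table`.
#' @param target_ids character vector of postsynaptic neuron ids.
#' @return Data frame sorted by decreasing percentage: `class`,
#'   `synapses`, `percent`.
#' @export
input_fractions <- function(table, target_ids) {
  stopifnot(inherits(table, "connectivity_table"))
  e <- table$edges[table$edges$post %in% target_ids, , drop = FALSE]
  if (nrow(e) == 0 || sum(e$count) == 0)
    stop("target set receives no synapses")
  cls <- table$class_map[e$pre]
  syn <- tapply(e$count, cls, sum)
  out <- data.frame(class = names(syn), synapses = as.integer(syn),
                    percent = 100 * as.numeric(syn) / sum(e$count),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent, out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top downstream hits of a source population
#'
#' Postsynaptic neurons receiving strictly more than `min_synapses`
#' synapses (aggregated over the whole source set; aggregation happens
#' before thresholding, so two sources giving 2 synapses each to the same
#' target count as 4). Two output percentages are reported: relative to
#' all output synapses of the sources, and relative to the top-hit
#' synapses only.
#'
#' @param table a `connectivity_table`.
#' @param source_ids character vector of presynaptic neuron ids.
#' @param min_synapses strict threshold (default 3: "> 3 synapses").
#' @return Data frame sorted by decreasing count then id: `post`, `class`,
#'   `synapses`, `pct_of_output`, `pct_of_tophit_output`. Empty when
#'   nothing passes the threshold.
#' @export
top_hits <- function(table, source_ids, min_synapses = 3L) {
  stopifnot(inherits(table, "connectivity_table"))
  e <- table$edges[table$edges$pre %in% source_ids, , drop = FALSE]
  empty <- data.frame(post = character(), class = character(),
                      synapses = integer(), pct_of_output = numeric(),
                      pct_of_tophit_output = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(e) == 0) return(empty)
  syn <- tapply(e$count, e$post, sum)
  total_out <- sum(e$count)
  syn <- syn[syn > min_synapses]
  if (length(syn) == 0) return(empty)
  out <- data.frame(post = names(syn),
                    class = unname(table$class_map[names(syn)]),
                    synapses = as.integer(syn),
                    pct_of_output = 100 * as.numeric(syn) / total_out,
                    pct_of_tophit_output = 100 * as.numeric(syn) / sum(syn),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$synapses, out$post), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate bounded-depth pathways between cell classes
#'
#' All simple directed paths from any neuron of `source_class` to any
#' neuron of `sink_class` using at most `max_hops` edges, restricted to
#' edges carrying at least `min_synapses_per_edge` synapses. Paths are
#' returned in lexicographic order of their id sequences.
#'
#' @param table a `connectivity_table`.
#' @param source_class,sink_class class labels present in the class map.
#' @param max_hops maximum number of edges per path (>= 1).
#' @param min_synapses_per_edge minimum synapse count for a usable edge.
#' @return List of character vectors (neuron id paths), possibly empty.
#' @export
enumerate_paths <- function(table, source_class, sink_class, max_hops,
                            min_synapses_per_edge = 1L) {
  stopifnot(inherits(table, "connectivity_table"), max_hops >= 1)
  classes <- unique(table$class_map)
  for (cl in c(source_class, sink_class))
    if (!cl %in% classes) stop("unknown class label: ", cl)
  e <- table$edges[table$edges$count >= min_synapses_per_edge, ,
                   drop = FALSE]
  sources <- names(table$class_map)[table$class_map == source_class]
  sinks <- names(table$class_map)[table$class_map == sink_class]
  if (nrow(e) == 0) return(list())
  g <- igraph::graph_from_data_frame(e[, c("pre", "post")],
                                     directed = TRUE)
  verts <- igraph::V(g)$name
  paths <- list()
  for (s in intersect(sources, verts)) {
    to <- setdiff(intersect(sinks, verts), s)
    if (length(to) == 0) next
    sp <- igraph::all_simple_paths(g, from = s, to = to, mode = "out",
                                   cutoff = max_hops)
    paths <- c(paths, lapply(sp, igraph::as_ids))
  }
  if (length(paths) == 0) return(list())
  keys <- vapply(paths, paste, "", collapse = "\r")
  paths[order(keys)]
}
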
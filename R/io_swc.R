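#' Read an SWC morphology file
#'
#' Standard SWC: one node per line, columns id/type/x/y/z/radius/parent,
#' 1-based ids, parent -1 at the root. Type codes: 1 soma, 2 axon,
#' 3 basal dendrite, 4 apical dendrite.
#'
#' @param path file path.
#' @param name morphology name; defaults to the file stem.
#' @return a \code{ca1_morphology} object.
#' @export
read_swc <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  nodes <- data.frame(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7]))
  if (is.null(name)) name <- sub("\\.swc$", "", basename(path))
  morphology(nodes, name = name, provenance = "original")
}

#' Write an SWC morphology file
#'
#' @param m a \code{ca1_morphology}.
#' @param path output path.
#' @export
write_swc <- function(m, path) {
  n <- m$nodes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s (%s)", m$name, m$provenance), con)
  writeLines(sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                     n$id, n$type, n$x, n$y, n$z, n$radius, n$parent), con)
  invisible(path)
}

#' Construct a morphology object
#'
#' @param nodes data.frame with id, type, x, y, z, radius, parent.
#' @param name morphology name.
#' @param provenance one of "original", "repaired", "clone".
#' @return object of class \code{ca1_morphology}.
#' @export
morphology <- function(nodes, name = "morph", provenance = "original") {
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  stopifnot(all(req %in% names(nodes)))
  nodes <- nodes[, req]
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1) stop("morphology must have exactly one root, got ", length(roots))
  if (any(nodes$radius <= 0)) stop("radii must be positive")
  # parents must precede children
  ord <- match(nodes$parent, nodes$id)
  bad <- which(!is.na(ord) & ord >= seq_len(nrow(nodes)))
  if (length(bad) > 0) {
    nodes <- topo_sort_nodes(nodes)
  }
  structure(list(nodes = nodes, name = name, provenance = provenance),
            class = "ca1_morphology")
}

# reorder nodes so every parent precedes its children, renumbering ids 1..n
topo_sort_nodes <- function(nodes) {
  children <- split(seq_len(nrow(nodes)), match(nodes$parent, nodes$id))
  root <- which(nodes$parent == -1)
  order_idx <- integer(0)
  stack <- root
  while (length(stack) > 0) {
    i <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_idx <- c(order_idx, i)
    kids <- children[[as.character(i)]]
    if (!is.null(kids)) stack <- c(stack, kids)
  }
  out <- nodes[order_idx, ]
  newid <- seq_len(nrow(out))
  map <- stats::setNames(newid, out$id)
  out$parent <- ifelse(out$parent == -1, -1L, as.integer(map[as.character(out$parent)]))
  out$id <- newid
  rownames(out) <- NULL
  out
}

#' @export
print.ca1_morphology <- function(x, ...) {
  cat(sprintf("<ca1_morphology> %s [%s]: %d nodes, total length %.1f um\n",
              x$name, x$provenance, nrow(x$nodes), total_length(x)))
  invisible(x)
}

#' Total neurite cable length of a morphology (micrometres)
#' @param m a \code{ca1_morphology}.
#' @param types optional subset of SWC type codes to include.
#' @export
total_length <- function(m, types = NULL) {
  n <- m$nodes
  keep <- n$parent != -1
  if (!is.null(types)) keep <- keep & n$type %in% types
  if (!any(keep)) return(0)
  p <- match(n$parent[keep], n$id)
  sum(sqrt((n$x[keep] - n$x[p])^2 + (n$y[keep] - n$y[p])^2 + (n$z[keep] - n$z[p])^2))
}

#' Extract neurite segments as a start/end point table
#'
#' One row per parent-child edge, in the morphology's local frame.
#' @param m a \code{ca1_morphology}.
#' @param types optional SWC type codes to keep.
#' @return data.frame x0,y0,z0,x1,y1,z1,type,node_id.
#' @export
morph_segments <- function(m, types = NULL) {
  n <- m$nodes
  keep <- n$parent != -1
  if (!is.null(types)) keep <- keep & n$type %in% types
  p <- match(n$parent[keep], n$id)
  data.frame(x0 = n$x[p], y0 = n$y[p], z0 = n$z[p],
             x1 = n$x[keep], y1 = n$y[keep], z1 = n$z[keep],
             type = n$type[keep], node_id = n$id[keep])
}
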
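#' Generate a synthetic morphology population
#'
#' Parametric branching trees standing in for biological reconstructions.
#' Two flavours:
#' \describe{
#'   \item{pc}{pyramidal-like: apical trunk along +y with a tuft, basal
#'     dendrites below the soma, and a long transverse axon along x with
#'     local collaterals (the branchier arbor on the -x, "subiculum" side).}
#'   \item{interneuron}{multipolar dendrites in all directions and a compact
#'     local axon.}
#' }
#' The morphology frame follows circuit conventions: +y is the radial
#' (depth) axis, x the transverse axis.
#'
#' @param n number of morphologies.
#' @param kind "pc" or "interneuron".
#' @param depth branching depth of dendritic trees (1 = unbranched).
#' @param seg_len mean branch segment length, micrometres.
#' @param axon_reach half-extent of the pyramidal axon along x, micrometres.
#' @param seed RNG seed.
#' @return list of \code{ca1_morphology}.
#' @export
make_morphologies <- function(n = 10, kind = c("interneuron", "pc"),
                              depth = 3, seg_len = 40, axon_reach = 400,
                              seed = 1) {
  kind <- match.arg(kind)
  with_seed(seed, lapply(seq_len(n), function(i) {
    synth_morph(kind, depth, seg_len, axon_reach,
                name = sprintf("%s_%03d", kind, i))
  }))
}

new_node_store <- function() {
  env <- new.env()
  env$nodes <- list()
  env$next_id <- 1L
  env
}

add_node <- function(st, type, xyz, radius, parent) {
  id <- st$next_id
  st$nodes[[id]] <- c(id, type, xyz, radius, parent)
  st$next_id <- id + 1L
  id
}

# random unit vector near `dir` (von Mises-Fisher-ish via jitter + renorm)
jitter_dir <- function(dir, sd) {
  v <- dir + stats::rnorm(3, 0, sd)
  v / sqrt(sum(v^2))
}

grow_tree <- function(st, parent_id, start, dir, type, depth, seg_len,
                      len_sd = 0.3, spread = 0.5) {
  len <- max(5, stats::rlnorm(1, log(seg_len), len_sd))
  npts <- 3L
  pos <- start
  pid <- parent_id
  for (k in seq_len(npts)) {
    pos <- pos + dir * (len / npts)
    pid <- add_node(st, type, pos, 0.5, pid)
  }
  if (depth > 1) {
    for (b in 1:2) {
      grow_tree(st, pid, pos, jitter_dir(dir, spread), type, depth - 1,
                seg_len * 0.8, len_sd, spread)
    }
  }
  invisible(pid)
}

synth_morph <- function(kind, depth, seg_len, axon_reach, name) {
  st <- new_node_store()
  soma <- add_node(st, SWC_SOMA, c(0, 0, 0), 6, -1L)
  if (kind == "pc") {
    # apical trunk + tuft
    grow_tree(st, soma, c(0, 6, 0), c(0, 1, 0), SWC_APICAL, depth,
              seg_len * 1.6, spread = 0.3)
    # basal skirt
    for (b in 1:3) {
      d <- jitter_dir(c(0, -1, 0), 0.5)
      grow_tree(st, soma, c(0, -6, 0), d, SWC_BASAL, max(1, depth - 1), seg_len)
    }
    # transverse axon: two main branches along +/- x, branchier on -x
    for (sgn in c(-1, 1)) {
      dir <- c(sgn, 0, 0)
      pos <- c(0, -6, 0); pid <- soma
      nseg <- max(3L, round(axon_reach / seg_len))
      for (k in seq_len(nseg)) {
        pos <- pos + jitter_dir(dir, 0.1) * seg_len
        pid <- add_node(st, SWC_AXON, pos, 0.4, pid)
        # local collaterals; denser on the -x (subiculum) side
        p_col <- if (sgn < 0) 0.5 else 0.2
        if (stats::runif(1) < p_col) {
          grow_tree(st, pid, pos, jitter_dir(c(0, 1, 0), 1), SWC_AXON, 1,
                    seg_len * 0.75)
        }
      }
    }
  } else {
    for (b in 1:4) {
      d <- jitter_dir(c(cos(b * pi / 2), sin(b * pi / 2), 0), 0.6)
      grow_tree(st, soma, d * 6, d, SWC_BASAL, depth, seg_len)
    }
    for (b in 1:3) {
      d <- jitter_dir(c(0, sign(stats::runif(1) - 0.3), 0), 0.8)
      grow_tree(st, soma, d * 6, d, SWC_AXON, max(1, depth - 1), seg_len * 1.2)
    }
  }
  m <- do.call(rbind, st$nodes)
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  morphology(nodes, name = name, provenance = "original")
}
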
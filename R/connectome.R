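#' Realize placed cells as world-frame geometries
#'
#' Applies each cell's rotation and translation to its selected morphology
#' and tags postsynaptic compartments: soma (sphere), dendrite segments, and
#' the axon initial segment (axon within \code{ais_length} micrometres of
#' path length from the soma).
#'
#' @param cells data.frame from \code{\link{place_somata}}.
#' @param morphs list of \code{ca1_morphology}, one per cell (recycled if
#'   length 1).
#' @param rotations list of 3 x 3 rotation matrices, one per cell (identity
#'   if NULL).
#' @param ais_length AIS extent from the soma, micrometres (default 60).
#' @return list of per-cell geometries: \code{soma} (center, radius),
#'   \code{segments} (world coordinates with \code{compartment} in
#'   axon/AIS/dend), \code{axon_length}.
#' @export
realize_cells <- function(cells, morphs, rotations = NULL, ais_length = 60) {
  n <- nrow(cells)
  if (length(morphs) == 1) morphs <- rep(morphs, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    m <- morphs[[i]]
    R <- if (is.null(rotations)) diag(3) else rotations[[i]]
    shift <- c(cells$x[i], cells$y[i], cells$z[i])
    nd <- m$nodes
    xyz <- cbind(nd$x, nd$y, nd$z) %*% t(R)
    xyz <- sweep(xyz, 2, shift, `+`)
    # axon path distance from root for AIS tagging
    pidx <- match(nd$parent, nd$id)
    seglen <- ifelse(is.na(pidx), 0,
                     sqrt(rowSums((cbind(nd$x, nd$y, nd$z) -
                                     cbind(nd$x, nd$y, nd$z)[ifelse(is.na(pidx), 1, pidx), ])^2)))
    pathd <- numeric(nrow(nd))
    for (k in seq_len(nrow(nd))) {
      pathd[k] <- if (is.na(pidx[k])) 0 else pathd[pidx[k]] + seglen[k]
    }
    keep <- !is.na(pidx) & nd$type != SWC_SOMA
    comp <- ifelse(nd$type[keep] == SWC_AXON,
                   ifelse(pathd[keep] <= ais_length, "AIS", "axon"), "dend")
    segs <- data.frame(
      x0 = xyz[pidx[keep], 1], y0 = xyz[pidx[keep], 2], z0 = xyz[pidx[keep], 3],
      x1 = xyz[keep, 1], y1 = xyz[keep, 2], z1 = xyz[keep, 3],
      compartment = comp, node_id = nd$id[keep], stringsAsFactors = FALSE)
    out[[i]] <- list(
      gid = cells$gid[i], mtype = cells$mtype[i],
      soma = list(center = shift, radius = soma_radius(m)),
      segments = segs,
      axon_length = sum(seglen[keep][nd$type[keep] == SWC_AXON]))
  }
  out
}

# minimum distances from one segment (q0-q1) to many segments in S
# (matrix with columns x0,y0,z0,x1,y1,z1); closest-point algorithm with the
# standard clamp sequence, vectorised over the rows of S
seg_dist_one_many <- function(q0, q1, S) {
  n <- nrow(S)
  P0 <- S[, 1:3, drop = FALSE]; P1 <- S[, 4:6, drop = FALSE]
  dq <- q1 - q0
  d2 <- P1 - P0
  r <- matrix(q0, n, 3, byrow = TRUE) - P0
  a <- sum(dq^2)                       # query segment squared length
  e <- rowSums(d2^2)
  f <- rowSums(d2 * r)
  c_ <- as.vector(r %*% dq)
  b <- as.vector(d2 %*% dq)
  denom <- a * e - b^2
  s <- numeric(n)
  ok <- denom > 1e-12
  s[ok] <- clamp((b[ok] * f[ok] - c_[ok] * e[ok]) / denom[ok], 0, 1)
  t_ <- ifelse(e > 1e-12, (b * s + f) / e, 0)
  low <- t_ < 0; high <- t_ > 1
  t_[low] <- 0; t_[high] <- 1
  if (a > 1e-12) {
    s[low] <- clamp(-c_[low] / a, 0, 1)
    s[high] <- clamp((b[high] - c_[high]) / a, 0, 1)
  } else {
    s[] <- 0
  }
  cp1 <- matrix(q0, n, 3, byrow = TRUE) + outer(s, dq)
  cp2 <- P0 + d2 * t_
  sqrt(rowSums((cp1 - cp2)^2))
}

is_pc <- function(mtype) grepl("PC$", mtype)

# admissible post compartments for a pre/post m-type pair, or NULL if the
# pair cannot connect at all
admissible_compartments <- function(pre_mtype, post_mtype) {
  pre_aa <- grepl("AA$", pre_mtype)
  no_pc_soma <- grepl("(SCA|Ivy|BS)$", pre_mtype)
  if (pre_aa) {
    if (!is_pc(post_mtype)) return(NULL)   # AA cells contact PCs only
    return("AIS")
  }
  if (is_pc(pre_mtype) && is_pc(post_mtype)) return("dend")
  if (no_pc_soma && is_pc(post_mtype)) return("dend")
  c("soma", "dend")
}

#' Find axo-somatic/dendritic appositions by proximity (touch detection)
#'
#' An apposition is recorded wherever a presynaptic axon segment passes
#' within the touch threshold of an admissible postsynaptic compartment:
#' 1.0 um onto pyramidal cells, 6.0 um onto interneurons. Compartment rules:
#' axo-axonic cells contact only the PC axon initial segment; PC-PC contacts
#' are dendritic only; SCA/Ivy/BS avoid PC somata.
#'
#' @param geoms list from \code{\link{realize_cells}}.
#' @param thresholds named vector \code{c(onto_PC = 1, onto_INT = 6)}
#'   (micrometres).
#' @param use_grid use a bounding-box prefilter (results identical to brute
#'   force).
#' @return data.frame pre_gid, post_gid, pre_node, post_node, distance,
#'   compartment.
#' @export
find_appositions <- function(geoms, thresholds = c(onto_PC = 1, onto_INT = 6),
                             use_grid = TRUE) {
  res <- list()
  n <- length(geoms)
  boxes <- lapply(geoms, function(g) {
    s <- g$segments
    rbind(c(min(s$x0, s$x1), min(s$y0, s$y1), min(s$z0, s$z1)),
          c(max(s$x0, s$x1), max(s$y0, s$y1), max(s$z0, s$z1)))
  })
  for (i in seq_len(n)) {
    pre <- geoms[[i]]
    axon <- pre$segments[pre$segments$compartment %in% c("axon", "AIS"), ,
                         drop = FALSE]
    if (nrow(axon) == 0) next
    for (j in seq_len(n)) {
      if (i == j) next
      post <- geoms[[j]]
      comps <- admissible_compartments(pre$mtype, post$mtype)
      if (is.null(comps)) next
      thr <- if (is_pc(post$mtype)) thresholds[["onto_PC"]] else
        thresholds[["onto_INT"]]
      if (use_grid) {
        bi <- boxes[[i]]; bj <- boxes[[j]]
        if (any(bi[1, ] > bj[2, ] + thr) || any(bj[1, ] > bi[2, ] + thr)) next
      }
      tgt <- post$segments[post$segments$compartment %in% setdiff(comps, "soma"),
                           , drop = FALSE]
      # AIS targets live on the post axon
      if ("AIS" %in% comps) {
        tgt <- post$segments[post$segments$compartment == "AIS", , drop = FALSE]
      }
      S <- as.matrix(tgt[, c("x0", "y0", "z0", "x1", "y1", "z1")])
      for (k in seq_len(nrow(axon))) {
        q0 <- as.numeric(axon[k, c("x0", "y0", "z0")])
        q1 <- as.numeric(axon[k, c("x1", "y1", "z1")])
        if (nrow(S) > 0) {
          dd <- seg_dist_one_many(q0, q1, S)
          hit <- which(dd <= thr)
          for (h in hit) {
            res[[length(res) + 1L]] <- data.frame(
              pre_gid = pre$gid, post_gid = post$gid,
              pre_node = axon$node_id[k], post_node = tgt$node_id[h],
              distance = dd[h], compartment = tgt$compartment[h],
              stringsAsFactors = FALSE)
          }
        }
        if ("soma" %in% comps) {
          # distance from axon segment to the soma sphere surface
          ds <- seg_dist_one_many(q0, q1, matrix(c(post$soma$center,
                                                   post$soma$center), 1)) -
            post$soma$radius
          if (ds <= thr) {
            res[[length(res) + 1L]] <- data.frame(
              pre_gid = pre$gid, post_gid = post$gid,
              pre_node = axon$node_id[k], post_node = 0L,
              distance = max(ds, 0), compartment = "soma",
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(pre_gid = integer(0), post_gid = integer(0),
                      pre_node = integer(0), post_node = integer(0),
                      distance = numeric(0), compartment = character(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Predict mean synapses per connection from appositions per connection
#'
#' Linear fits through the origin: 0.1096 x for inhibitory-inhibitory
#' pathways, 1.1690 x otherwise.
#'
#' @param appositions_per_connection non-negative scalar (or vector).
#' @param pathway_class "I-I" or "other".
#' @return predicted synapses per connection.
#' @export
predict_synapses_per_connection <- function(appositions_per_connection,
                                            pathway_class = c("other", "I-I")) {
  pathway_class <- match.arg(pathway_class)
  stopifnot(all(appositions_per_connection >= 0))
  coef <- if (pathway_class == "I-I") 0.1096 else 1.1690
  coef * appositions_per_connection
}

#' Prune appositions to synapses under anatomical constraints
#'
#' Two-stage stochastic pruning. Stage 1 thins synapses binomially with
#' probability target/current so the mean synapses per connection matches
#' \code{syn_per_conn} (connections losing all synapses disappear, which
#' removes whole connections first and preserves the positive skew of the
#' multiplicity distribution). Stage 2 draws a per-axon target bouton density
#' from a gamma distribution with mean \code{bouton_density} and coefficient
#' of variation \code{bouton_cv}, then thins each axon to it; bouton counts
#' are synapse counts divided by \code{syn_per_bouton}.
#'
#' @param appositions data.frame from \code{\link{find_appositions}}.
#' @param constraints list with any of: \code{syn_per_conn} (mean),
#'   \code{bouton_density} (mean boutons per um axon), \code{bouton_cv}
#'   (default 0.50), \code{syn_per_bouton} (default 1.15).
#' @param axon_length named vector of presynaptic axon lengths (um) keyed by
#'   gid; required for the bouton stage.
#' @param seed RNG seed.
#' @return pruned data.frame (subset of input rows); attribute
#'   \code{infeasible} lists pathway stages whose target exceeded the
#'   available material (kept unpruned).
#' @export
prune <- function(appositions, constraints, axon_length = NULL, seed = 1) {
  ap <- appositions
  flags <- character(0)
  with_seed(seed, {
    if (!is.null(constraints$syn_per_conn) && nrow(ap) > 0) {
      conn <- paste(ap$pre_gid, ap$post_gid)
      mu <- nrow(ap) / length(unique(conn))
      p <- constraints$syn_per_conn / mu
      if (p < 1) {
        ap <- ap[stats::runif(nrow(ap)) < p, , drop = FALSE]
      } else if (p > 1.05) {
        flags <- c(flags, "syn_per_conn")
      }
    }
    if (!is.null(constraints$bouton_density) && nrow(ap) > 0) {
      stopifnot(!is.null(axon_length))
      cv <- if (is.null(constraints$bouton_cv)) 0.50 else constraints$bouton_cv
      spb <- if (is.null(constraints$syn_per_bouton)) 1.15 else
        constraints$syn_per_bouton
      shape <- 1 / cv^2
      keep <- rep(TRUE, nrow(ap))
      for (g in unique(ap$pre_gid)) {
        idx <- which(ap$pre_gid == g)
        len <- axon_length[[as.character(g)]]
        dens <- (length(idx) / spb) / len
        tgt <- stats::rgamma(1, shape = shape,
                             scale = constraints$bouton_density / shape)
        f <- tgt / dens
        if (f < 1) {
          keep[idx] <- stats::runif(length(idx)) < f
        } else if (f > 1.05) {
          flags <- c(flags, paste0("bouton_density:gid", g))
        }
      }
      ap <- ap[keep, , drop = FALSE]
    }
  })
  rownames(ap) <- NULL
  attr(ap, "infeasible") <- unique(flags)
  ap
}

#' Mean, population SD and CV of per-connection synapse counts
#'
#' @param counts numeric vector of synapses per connection (non-empty).
#' @return list(mean, sd, cv); sd is the population (n-denominator) SD.
#' @export
bouton_stats <- function(counts) {
  stopifnot(length(counts) > 0)
  m <- mean(counts)
  if (m == 0) stop("zero mean synapse count")
  s <- sqrt(mean((counts - m)^2))
  list(mean = m, sd = s, cv = s / m)
}
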
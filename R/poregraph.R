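#' Extract the pore/constriction graph of a voxelized membrane
#'
#' Pores are the catchment basins of the fluid-phase Euclidean distance
#' transform under a watershed segmentation (basin maxima are the pore
#' centres); constrictions are the ridge saddles between adjacent basins.
#' Shallow basins whose peak exceeds the meeting saddle by less than the
#' merge threshold are absorbed into their neighbour, which suppresses
#' voxel-scale over-segmentation.
#'
#' Sizes follow the maximal-ball convention: a pore's equivalent diameter
#' is the diameter of the largest inscribed sphere (twice its distance
#' peak), and a constriction's diameter is twice the distance value at the
#' ridge saddle. Distances are measured between voxel centres; solid
#' centres sit about half a voxel behind the solid surface, which offsets
#' the staircase bite of voxelized walls, so no half-voxel correction is
#' applied (sizes of analytic fixtures come out within one voxel). By
#' construction a constriction is never wider than either adjacent pore.
#'
#' @param grid a \code{voxel_grid}.
#' @param h_merge watershed merge threshold in voxels (default 1).
#' @return a \code{pore_graph}: \code{pores} data frame (id, voxels,
#'   volume_nm3, diameter_nm, centroid, inlet/outlet attachment),
#'   \code{constrictions} data frame (a, b, diameter_nm, location),
#'   \code{labels} array assigning every fluid voxel to exactly one pore,
#'   and the voxel size.
#' @export
extract_pore_graph <- function(grid, h_merge = 1) {
  d <- grid$dim
  if (all(grid$mask)) {
    return(structure(list(
      pores = data.frame(id = integer(), voxels = numeric(),
                         volume_nm3 = numeric(), diameter_nm = numeric(),
                         x = numeric(), y = numeric(), z = numeric(),
                         inlet = logical(), outlet = logical(),
                         inlet_width_nm = numeric(),
                         outlet_width_nm = numeric()),
      constrictions = data.frame(a = integer(), b = integer(),
                                 diameter_nm = numeric(), x = numeric(),
                                 y = numeric(), z = numeric()),
      labels = array(0L, d), voxel_size = grid$voxel_size,
      dim = d), class = "pore_graph"))
  }
  h <- grid$voxel_size
  edt <- .edt_cpp(grid$mask, d[1], d[2], d[3])
  ws <- .watershed_cpp(edt, grid$mask, d[1], d[2], d[3], h_merge)
  diam <- 2 * ws$peak * h
  pores <- data.frame(
    id = seq_len(ws$n_pores),
    voxels = ws$voxels,
    volume_nm3 = ws$voxels * h^3,
    diameter_nm = diam,
    x = ws$centroid_i * h, y = ws$centroid_j * h, z = ws$centroid_k * h,
    inlet = ws$inlet == 1L, outlet = ws$outlet == 1L,
    inlet_width_nm = 2 * ws$inlet_w * h,
    outlet_width_nm = 2 * ws$outlet_w * h)
  constrictions <- data.frame(
    a = ws$edge_a, b = ws$edge_b,
    diameter_nm = 2 * ws$edge_saddle * h,
    x = ws$edge_i * h, y = ws$edge_j * h, z = ws$edge_k * h)
  structure(list(pores = pores, constrictions = constrictions,
                 labels = ws$labels, voxel_size = h, dim = d),
            class = "pore_graph")
}

#' @export
print.pore_graph <- function(x, ...) {
  cat("<pore_graph> ", nrow(x$pores), " pores, ", nrow(x$constrictions),
      " constrictions", sep = "")
  if (nrow(x$constrictions) > 0)
    cat(", median constriction ",
        signif(stats::median(x$constrictions$diameter_nm), 3), " nm",
        sep = "")
  cat("\n")
  invisible(x)
}

# igraph with virtual "inlet"/"outlet" vertices; constriction edges carry
# their diameter, attachment edges carry the pore's widest face opening
.pore_igraph <- function(pg, min_diameter = 0) {
  ed <- pg$constrictions
  keep <- ed$diameter_nm >= min_diameter
  ed <- ed[keep, , drop = FALSE]
  n <- nrow(pg$pores)
  verts <- c(as.character(seq_len(n)), "inlet", "outlet")
  from <- character(0); to <- character(0)
  width <- numeric(0); att <- logical(0)
  if (nrow(ed) > 0) {
    from <- as.character(ed$a); to <- as.character(ed$b)
    width <- ed$diameter_nm
    att <- rep(FALSE, nrow(ed))
  }
  ain <- which(pg$pores$inlet)
  aout <- which(pg$pores$outlet)
  from <- c(from, rep("inlet", length(ain)), as.character(aout))
  to <- c(to, as.character(ain), rep("outlet", length(aout)))
  width <- c(width, pg$pores$inlet_width_nm[ain],
             pg$pores$outlet_width_nm[aout])
  att <- c(att, rep(TRUE, length(ain) + length(aout)))
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, width = width, att = att),
    directed = FALSE, vertices = data.frame(name = verts))
}

#' Number of independent flow pathways through a pore
#'
#' Counts edge-disjoint inlet-to-outlet paths that pass through the given
#' pore, using only constrictions at least \code{min_diameter} wide: the
#' minimum of the two unit-capacity max-flow values inlet->pore and
#' pore->outlet. A sealed pore (no open neck towards either face) has
#' zero pathways.
#'
#' @param pg a \code{pore_graph}.
#' @param pore_id pore id.
#' @param min_diameter minimum constriction diameter (nm) for a neck to
#'   count as open; defaults to one voxel.
#' @return non-negative integer.
#' @export
through_path_count <- function(pg, pore_id, min_diameter = pg$voxel_size) {
  if (!pore_id %in% pg$pores$id) stop("unknown pore_id: ", pore_id)
  g <- .pore_igraph(pg, min_diameter)
  # unit capacity per constriction; attachments bounded high enough never
  # to limit the count
  cap <- ifelse(igraph::E(g)$att, igraph::ecount(g) + 1, 1)
  v <- as.character(pore_id)
  f1 <- igraph::max_flow(g, source = "inlet", target = v, capacity = cap)$value
  f2 <- igraph::max_flow(g, source = v, target = "outlet", capacity = cap)$value
  as.integer(floor(min(f1, f2)))
}

# widest-path bottlenecks from a source set to every pore, by a
# max-bottleneck Dijkstra over the constriction graph (edge width =
# constriction diameter, attachments unconstrained). One pass serves all
# pores at once. Returns a vector over pores (-Inf if unreachable; Inf
# for pores in the source set themselves).
.widest_from <- function(pg, from = c("inlet", "outlet")) {
  from <- match.arg(from)
  n <- nrow(pg$pores)
  best <- rep(-Inf, n)
  src <- if (from == "inlet") pg$pores$inlet else pg$pores$outlet
  w0 <- if (from == "inlet") pg$pores$inlet_width_nm else
    pg$pores$outlet_width_nm
  best[src] <- w0[src]
  if (n == 0) return(best)
  ed <- pg$constrictions
  adj_a <- split(seq_len(nrow(ed)), ed$a)
  adj_b <- split(seq_len(nrow(ed)), ed$b)
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & best > -Inf)
    if (length(cand) == 0) break
    u <- cand[which.max(best[cand])]
    done[u] <- TRUE
    for (e in c(adj_a[[as.character(u)]], adj_b[[as.character(u)]])) {
      v <- if (ed$a[e] == u) ed$b[e] else ed$a[e]
      b <- min(best[u], ed$diameter_nm[e])
      if (b > best[v]) best[v] <- b
    }
  }
  best
}

#' Obstruction index of a pore
#'
#' Quantifies how strongly microfibrils impede the through-thickness flow
#' pathway of a pore: one minus the ratio of the widest achievable
#' inlet-outlet bottleneck through the pore to the pore's own equivalent
#' diameter, clamped to \[0, 1\]. A straight uniform channel scores 0; a
#' sealed cavity scores 1.
#'
#' @param pg a \code{pore_graph}.
#' @param pore_id pore id.
#' @return fraction in \[0, 1\].
#' @export
obstruction_index <- function(pg, pore_id) {
  idx <- match(pore_id, pg$pores$id)
  if (is.na(idx)) stop("unknown pore_id: ", pore_id)
  if (through_path_count(pg, pore_id) == 0) return(1)
  b <- min(.widest_from(pg, "inlet")[idx], .widest_from(pg, "outlet")[idx])
  dpore <- pg$pores$diameter_nm[idx]
  min(max(1 - b / dpore, 0), 1)
}

#' Per-pore obstruction report
#'
#' Through-path counts, obstruction indices and best-path bottleneck
#' diameters for every pore of a membrane.
#'
#' @param pg a \code{pore_graph}.
#' @param min_diameter minimum open-constriction diameter (nm) for the
#'   path count.
#' @return data frame with one row per pore.
#' @export
obstruction_report <- function(pg, min_diameter = pg$voxel_size) {
  n <- nrow(pg$pores)
  out <- data.frame(id = pg$pores$id,
                    diameter_nm = pg$pores$diameter_nm,
                    through_path_count = integer(n),
                    obstruction_index = numeric(n),
                    bottleneck_nm = numeric(n))
  if (n == 0) return(out)
  gq <- .pore_igraph(pg, min_diameter)
  capq <- ifelse(igraph::E(gq)$att, igraph::ecount(gq) + 1, 1)
  bin <- .widest_from(pg, "inlet")
  bout <- .widest_from(pg, "outlet")
  for (i in seq_len(n)) {
    v <- as.character(pg$pores$id[i])
    f1 <- igraph::max_flow(gq, "inlet", v, capacity = capq)$value
    f2 <- igraph::max_flow(gq, v, "outlet", capacity = capq)$value
    out$through_path_count[i] <- as.integer(floor(min(f1, f2)))
    b <- min(bin[i], bout[i])
    out$bottleneck_nm[i] <- if (is.finite(b)) b else
      if (b == Inf) pg$pores$diameter_nm[i] else 0
    out$obstruction_index[i] <- if (out$through_path_count[i] == 0) 1 else
      min(max(1 - b / pg$pores$diameter_nm[i], 0), 1)
  }
  out
}
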
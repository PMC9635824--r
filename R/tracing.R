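#' Tracing configuration
#'
#' Parameters of the automated neurite tracer. Defaults follow the printed
#' analysis values (40-point minimum, 1-um terminal-subbranch minimum, 70%
#' overlap exclusion, 5-px skeleton-loss limit) and field-standard choices
#' where unspecified: a grey-opening disk larger than a neurite's width but
#' smaller than the soma, a 5% soma-area tolerance, a threshold step of 1%
#' of the dynamic range, a 45-degree gap-closing cone, and a [0.5, 2]
#' intensity-ratio band for accepting branch continuations at crossings.
#'
#' @param grey_open_radius_px radius of the grey-opening disk.
#' @param soma_area_tol relative soma-area tolerance for the threshold seed.
#' @param threshold_step_frac threshold step as a fraction of the frame's
#'   dynamic range.
#' @param skeleton_loss_limit skeleton pixels lost in one step that end the
#'   threshold search (default 5).
#' @param skeleton_loss_cumulative compare skeleton loss to the first
#'   threshold's skeleton instead of the previous step's.
#' @param gap_angle_tol_deg angular tolerance for gap-closing bridges.
#' @param min_branch_points minimum skeleton points per neurite (default 40).
#' @param min_terminal_um minimum terminal subbranch length (default 1 um).
#' @param overlap_exclusion branch-overlap fraction for cross-frame
#'   exclusion (default 0.7).
#' @param crossing_ratio_band accepted emerging/incoming median intensity
#'   ratio range at branch points.
#' @param min_soma_area_px smallest acceptable soma area.
#' @param soma_dilate_px dilation of the soma mask before removal from the
#'   neurite skeleton.
#' @return list of class `TracingConfig`.
#' @export
tracing_config <- function(grey_open_radius_px = 10L,
                           soma_area_tol = 0.05,
                           threshold_step_frac = 0.01,
                           skeleton_loss_limit = 5L,
                           skeleton_loss_cumulative = FALSE,
                           gap_angle_tol_deg = 45,
                           min_branch_points = 40L,
                           min_terminal_um = 1,
                           overlap_exclusion = 0.7,
                           crossing_ratio_band = c(0.5, 2),
                           min_soma_area_px = 50L,
                           soma_dilate_px = 2L) {
  cfg <- list(grey_open_radius_px = grey_open_radius_px,
              soma_area_tol = soma_area_tol,
              threshold_step_frac = threshold_step_frac,
              skeleton_loss_limit = skeleton_loss_limit,
              skeleton_loss_cumulative = isTRUE(skeleton_loss_cumulative),
              gap_angle_tol_deg = gap_angle_tol_deg,
              min_branch_points = min_branch_points,
              min_terminal_um = min_terminal_um,
              overlap_exclusion = overlap_exclusion,
              crossing_ratio_band = crossing_ratio_band,
              min_soma_area_px = min_soma_area_px,
              soma_dilate_px = soma_dilate_px)
  stopifnot(cfg$soma_area_tol > 0, cfg$soma_area_tol <= 1,
            cfg$threshold_step_frac > 0, cfg$overlap_exclusion > 0,
            cfg$overlap_exclusion <= 1, all(cfg$crossing_ratio_band > 0))
  class(cfg) <- "TracingConfig"
  cfg
}

#' Skeletonize a binary mask
#'
#' Zhang-Suen thinning: iteratively peels boundary pixels that have 2-6
#' foreground neighbours and exactly one 0-to-1 transition around them,
#' alternating the two sub-iteration connectivity conditions until the
#' image is stable. The result is an 8-connected, 1-px-wide skeleton.
#'
#' @param mask logical matrix.
#' @return logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- mask
  h <- nrow(m); w <- ncol(m)
  shift <- function(M, dy, dx) {
    out <- matrix(FALSE, h, w)
    ys <- seq_len(h) - dy; xs <- seq_len(w) - dx
    okY <- ys >= 1L & ys <= h; okX <- xs >= 1L & xs <= w
    out[okY, okX] <- M[ys[okY], xs[okX]]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbours clockwise from north
      P2 <- shift(m, -1, 0); P3 <- shift(m, -1, 1); P4 <- shift(m, 0, 1)
      P5 <- shift(m, 1, 1); P6 <- shift(m, 1, 0); P7 <- shift(m, 1, -1)
      P8 <- shift(m, 0, -1); P9 <- shift(m, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      seqs <- list(P2, P3, P4, P5, P6, P7, P8, P9, P2)
      A <- matrix(0L, h, w)
      for (k in 1:8) A <- A + (!seqs[[k]] & seqs[[k + 1]])
      if (phase == 1) {
        c3 <- !(P2 & P4 & P6); c4 <- !(P4 & P6 & P8)
      } else {
        c3 <- !(P2 & P4 & P8); c4 <- !(P2 & P6 & P8)
      }
      del <- m & B >= 2 & B <= 6 & A == 1L & c3 & c4
      if (any(del)) { m[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Grey opening with a disk structuring element.
grey_open <- function(frame, radius_px) {
  br <- EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
  rng <- range(frame)
  if (diff(rng) == 0) return(frame)
  sc <- (frame - rng[1]) / diff(rng)
  out <- EBImage::opening(EBImage::Image(sc), br)
  matrix(as.numeric(EBImage::imageData(out)), nrow(frame)) * diff(rng) + rng[1]
}

# Scharr gradient magnitude.
scharr_edges <- function(frame) {
  kx <- matrix(c(3, 0, -3, 10, 0, -10, 3, 0, -3), 3, 3, byrow = TRUE) / 16
  ky <- t(kx)
  img <- EBImage::Image(frame)
  gx <- EBImage::imageData(EBImage::filter2(img, kx))
  gy <- EBImage::imageData(EBImage::filter2(img, ky))
  matrix(sqrt(as.numeric(gx)^2 + as.numeric(gy)^2), nrow(frame))
}

#' Locate the soma in a frame
#'
#' Grey-opens the frame (removing thin neurites), extracts Scharr edge
#' magnitude, Otsu-thresholds the edges, fills the enclosed region and
#' returns the largest filled component as the soma.
#'
#' @param frame numeric intensity matrix.
#' @param config a [tracing_config()].
#' @return a `SomaMask` list: `mask` (logical matrix), `centroid` (0-based
#'   `c(y, x)`), `area` (pixels).
#' @export
extract_soma <- function(frame, config = tracing_config()) {
  if (length(frame) == 0L) stop("empty frame")
  if (diff(range(frame)) == 0) stop("no soma found: frame has no contrast")
  opened <- grey_open(frame, config$grey_open_radius_px)
  edges <- scharr_edges(opened)
  thr <- otsu_threshold(edges)
  filled <- fill_holes(edges >= thr)
  # the filled region extends to the outer flank of the gradient band;
  # one 4-connected erosion recentres the boundary on the true rim
  filled <- binary_erode_cross(filled)
  comp <- largest_component(filled)
  if (sum(comp) < config$min_soma_area_px)
    stop(sprintf("no soma found: largest filled component has %d px (minimum %d)",
                 sum(comp), config$min_soma_area_px))
  idx <- which(comp, arr.ind = TRUE)
  structure(list(mask = comp,
                 centroid = c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1),
                 area = sum(comp)),
            class = "SomaMask")
}

#' Find the neuron segmentation threshold
#'
#' Stage 1: on the grey-opened frame (where the opening has removed the
#' neurites), scan thresholds upward and take the lowest one whose soma
#' component area matches the edge-derived soma area within the configured
#' tolerance. Stage 2: from there, keep raising the threshold on the raw
#' frame, skeletonizing each step, and return the threshold one step before
#' the first step at which `skeleton_loss_limit` or more skeleton pixels
#' are lost (relative to the previous step, or to the first step in
#' cumulative mode).
#'
#' @param frame numeric intensity matrix.
#' @param soma a `SomaMask` from [extract_soma()].
#' @param config a [tracing_config()].
#' @return the selected threshold value.
#' @export
find_neuron_threshold <- function(frame, soma, config = tracing_config()) {
  rng <- range(frame)
  if (diff(rng) == 0) stop("uniform frame: no threshold reproduces the soma")
  step <- config$threshold_step_frac * diff(rng)
  thrs <- seq(rng[1] + step, rng[2], by = step)
  opened <- grey_open(frame, config$grey_open_radius_px)
  ctr <- round(soma$centroid) + 1L
  soma_comp_area <- function(thr) {
    bin <- opened >= thr
    if (!bin[ctr[1], ctr[2]]) return(0L)
    lab <- label_components(bin)
    sum(lab == lab[ctr[1], ctr[2]])
  }
  areas <- vapply(thrs, soma_comp_area, 0L)
  match_ok <- abs(areas - soma$area) <= config$soma_area_tol * soma$area
  if (!any(match_ok))
    stop(sprintf(
      "no threshold reproduces the soma area %d within %.0f%% (component areas %d..%d)",
      soma$area, 100 * config$soma_area_tol,
      min(areas), max(areas)))
  i0 <- which(match_ok)[1]
  skel_count <- function(thr) sum(skeletonize(frame >= thr))
  prev <- ref <- skel_count(thrs[i0])
  best <- thrs[i0]
  i <- i0
  while (i < length(thrs)) {
    i <- i + 1L
    cnt <- skel_count(thrs[i])
    base <- if (config$skeleton_loss_cumulative) ref else prev
    if (base - cnt >= config$skeleton_loss_limit) return(best)
    best <- thrs[i]
    prev <- cnt
  }
  best
}

#' Reconnect detached neurite segments
#'
#' Components of the binary image not touching the soma-connected component
#' are joined by a 1-px straight bridge from their soma-closest point to
#' the nearest soma-connected point whose bearing lies within the angular
#' tolerance of the segment's own principal orientation (preventing
#' reattachment to a wrong nearby neurite). Segments with no admissible
#' bridge are left detached.
#'
#' @param binary logical matrix including the soma component.
#' @param soma a `SomaMask`.
#' @param config a [tracing_config()].
#' @return the bridged logical matrix.
#' @export
close_gaps <- function(binary, soma, config = tracing_config()) {
  ctr <- round(soma$centroid) + 1L
  repeat {
    lab <- label_components(binary)
    soma_lab <- lab[ctr[1], ctr[2]]
    if (soma_lab == 0L) {
      # soma centroid not on the mask: use the component overlapping the
      # soma mask most
      ov <- table(lab[soma$mask & lab > 0L])
      if (!length(ov)) return(binary)
      soma_lab <- as.integer(names(ov)[which.max(ov)])
    }
    others <- setdiff(unique(lab[lab > 0L]), soma_lab)
    if (!length(others)) return(binary)
    anchor_idx <- which(lab == soma_lab, arr.ind = TRUE)
    bridged <- FALSE
    for (cl in others) {
      seg_idx <- which(lab == cl, arr.ind = TRUE)
      if (nrow(seg_idx) < 2L) next
      # segment orientation from the principal axis of its pixels
      cen <- colMeans(seg_idx)
      cv <- stats::cov(seg_idx)
      ev <- eigen(cv, symmetric = TRUE)$vectors[, 1]
      seg_ang <- atan2(ev[1], ev[2])
      # segment point closest to the soma-connected component
      dmat_min <- apply(seg_idx, 1, function(p)
        min((anchor_idx[, 1] - p[1])^2 + (anchor_idx[, 2] - p[2])^2))
      p <- seg_idx[which.min(dmat_min), ]
      d2 <- (anchor_idx[, 1] - p[1])^2 + (anchor_idx[, 2] - p[2])^2
      bearing <- atan2(anchor_idx[, 1] - p[1], anchor_idx[, 2] - p[2])
      dd <- abs(bearing - seg_ang) %% pi
      dd <- pmin(dd, pi - dd)   # axial difference in [0, pi/2]
      adm <- which(dd <= config$gap_angle_tol_deg * pi / 180 & d2 > 0)
      if (!length(adm)) next
      q <- anchor_idx[adm[which.min(d2[adm])], ]
      line <- bresenham(p[1], p[2], q[1], q[2])
      binary[line] <- TRUE
      bridged <- TRUE
      break   # relabel and continue with the enlarged soma component
    }
    if (!bridged) return(binary)
  }
}

# skeleton pixel graph over 8-neighbours with step-length edge weights
skeleton_graph <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  key <- paste(idx[, 1], idx[, 2])
  id <- stats::setNames(seq_len(nrow(idx)), key)
  edges <- integer(0); wts <- numeric(0)
  for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1))) {
    ny <- idx[, 1] + d[1]; nx <- idx[, 2] + d[2]
    nk <- paste(ny, nx)
    hit <- !is.na(id[nk])
    if (any(hit)) {
      edges <- c(edges, rbind(id[key[hit]], id[nk[hit]]))
      wts <- c(wts, rep(sqrt(sum(d^2)), sum(hit)))
    }
  }
  g <- igraph::make_empty_graph(n = nrow(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges, weight = wts)
  list(graph = g, coords = idx)
}

#' Decompose a traced neuron into neurite branches
#'
#' Removes the dilated soma from the binary image, skeletonizes the rest,
#' and builds one branch per root-to-tip path, each branch starting at a
#' skeleton point adjacent to the soma. Terminal subbranches shorter than
#' the configured minimum are pruned; neurites with fewer than
#' `min_branch_points` skeleton points are dropped; at branch points the
#' continuation is accepted only when the emerging branch's median
#' intensity is within the configured ratio band of the incoming branch
#' (crossing disambiguation; needs `intensity`). Against `context_branches`
#' (typically branches traced in other frames), neurites with a different
#' origin whose path overlaps at least `overlap_exclusion` are excluded.
#'
#' @param binary logical neuron mask including the soma.
#' @param soma a `SomaMask`.
#' @param pixel_size um per pixel.
#' @param config a [tracing_config()].
#' @param intensity optional intensity matrix for per-point intensities and
#'   the crossing rule.
#' @param context_branches optional list of `NeuriteBranch` from other
#'   frames for the overlap exclusion.
#' @return list of `NeuriteBranch` data frames
#'   (`y_px, x_px, arclen_um[, intensity]`, 0-based coordinates).
#' @export
build_branches <- function(binary, soma, pixel_size,
                           config = tracing_config(), intensity = NULL,
                           context_branches = NULL) {
  soma_dil <- binary_dilate3(soma$mask, config$soma_dilate_px)
  neuron <- binary & !soma_dil
  skel <- skeletonize(neuron)
  if (!any(skel)) return(list())
  sg <- skeleton_graph(skel)
  g <- sg$graph; coords <- sg$coords
  # roots: skeleton pixels adjacent to the dilated soma (3-px tolerance:
  # thinning retracts free line ends by up to 2 px)
  soma_adj <- binary_dilate3(soma_dil, 3L) & skel
  root_ids <- which(soma_adj[coords])
  if (!length(root_ids)) return(list())
  comp <- igraph::components(g)$membership
  branches <- list()
  for (cmp in unique(comp[root_ids])) {
    nodes <- which(comp == cmp)
    if (length(nodes) < config$min_branch_points) next
    roots_here <- intersect(root_ids, nodes)
    d2soma <- (coords[roots_here, 1] - 1 - soma$centroid[1])^2 +
      (coords[roots_here, 2] - 1 - soma$centroid[2])^2
    root <- roots_here[which.min(d2soma)]
    sub <- igraph::induced_subgraph(g, nodes)
    map <- nodes                       # subgraph vertex -> full id
    rloc <- match(root, map)
    deg <- igraph::degree(sub)
    # prune terminal subbranches shorter than the minimum
    repeat {
      deg <- igraph::degree(sub)
      leaves <- setdiff(which(deg == 1L), rloc)
      drop_nodes <- integer(0)
      for (lf in leaves) {
        path <- lf
        cur <- lf
        prev <- -1L
        len_um <- 0
        repeat {
          nb <- setdiff(as.integer(igraph::neighbors(sub, cur)), prev)
          if (length(nb) != 1L) break
          step <- sqrt(sum((coords[map[nb], ] - coords[map[cur], ])^2))
          if (igraph::degree(sub)[nb] >= 3L || nb == rloc) {
            len_um <- len_um + step * pixel_size
            break
          }
          len_um <- len_um + step * pixel_size
          prev <- cur; cur <- nb
          path <- c(path, cur)
          if (len_um > config$min_terminal_um) break
        }
        if (len_um < config$min_terminal_um) {
          drop_nodes <- c(drop_nodes, path)
        }
      }
      drop_nodes <- setdiff(unique(drop_nodes), rloc)
      if (!length(drop_nodes)) break
      keep <- setdiff(seq_len(igraph::vcount(sub)), drop_nodes)
      map <- map[keep]
      sub <- igraph::induced_subgraph(sub, keep)
      rloc <- match(root, map)
      if (is.na(rloc)) break
    }
    if (is.na(rloc) || igraph::vcount(sub) < config$min_branch_points) next
    deg <- igraph::degree(sub)
    tips <- setdiff(which(deg == 1L), rloc)
    if (!length(tips) && igraph::vcount(sub) >= 2L) tips <- which.max(
      igraph::distances(sub, v = rloc)[1, ])
    bid <- 1L
    for (tp in tips) {
      sp <- igraph::shortest_paths(sub, from = rloc, to = tp)$vpath[[1]]
      ids <- map[as.integer(sp)]
      y <- coords[ids, 1] - 1; x <- coords[ids, 2] - 1
      inten <- if (!is.null(intensity)) intensity[cbind(y + 1L, x + 1L)]
               else NULL
      br <- new_neurite_branch(y, x, pixel_size, neurite_id = cmp,
                               branch_id = bid, intensity = inten)
      if (!is.null(intensity)) {
        br <- truncate_at_crossing(br, sp, sub, config)
      }
      branches[[length(branches) + 1L]] <- br
      bid <- bid + 1L
    }
  }
  # overlap exclusion against context branches with a different origin
  if (!is.null(context_branches) && length(branches)) {
    keep <- vapply(branches, function(b) {
      for (cb in context_branches) {
        same_origin <- sqrt((b$y_px[1] - cb$y_px[1])^2 +
                              (b$x_px[1] - cb$x_px[1])^2) <= 3
        if (!same_origin &&
            branch_overlap(b, cb) >= config$overlap_exclusion) return(FALSE)
      }
      TRUE
    }, TRUE)
    branches <- branches[keep]
  }
  branches
}

# At junctions along the path, reject continuations whose emerging median
# intensity falls outside the configured ratio band of the incoming
# segment (crossing neurites produce intensity mismatches).
truncate_at_crossing <- function(branch, path_nodes, sub, config) {
  deg <- igraph::degree(sub)
  jn <- which(deg[as.integer(path_nodes)] >= 3L)
  jn <- jn[jn > 1L & jn < nrow(branch)]
  if (!length(jn)) return(branch)
  bounds <- c(1L, jn, nrow(branch))
  for (k in seq_len(length(bounds) - 2L)) {
    inc <- branch$intensity[bounds[k]:bounds[k + 1L]]
    out <- branch$intensity[bounds[k + 1L]:bounds[k + 2L]]
    ratio <- stats::median(out) / max(stats::median(inc), 1e-12)
    if (ratio < config$crossing_ratio_band[1] ||
        ratio > config$crossing_ratio_band[2]) {
      return(branch[seq_len(bounds[k + 1L]), , drop = FALSE])
    }
  }
  branch
}

#' Path overlap fraction of two branches
#'
#' The share of the first branch's points lying within a 1-px (Chebyshev)
#' dilation of the second branch's points.
#'
#' @param b1,b2 `NeuriteBranch` data frames.
#' @return fraction in \[0, 1\].
#' @export
branch_overlap <- function(b1, b2) {
  if (!nrow(b1) || !nrow(b2)) return(0)
  hits <- vapply(seq_len(nrow(b1)), function(i) {
    any(abs(b2$y_px - b1$y_px[i]) <= 1 & abs(b2$x_px - b1$x_px[i]) <= 1)
  }, TRUE)
  mean(hits)
}

#' Trace a frame end to end
#'
#' Convenience wrapper: soma extraction, threshold search, gap closing and
#' branch construction on one frame.
#'
#' @param frame numeric intensity matrix.
#' @param pixel_size um per pixel.
#' @param config a [tracing_config()].
#' @param context_branches passed to [build_branches()].
#' @return list with `soma`, `threshold`, `branches`.
#' @export
trace_frame <- function(frame, pixel_size, config = tracing_config(),
                        context_branches = NULL) {
  soma <- extract_soma(frame, config)
  thr <- find_neuron_threshold(frame, soma, config)
  bin <- frame >= thr
  bin <- close_gaps(bin, soma, config)
  # keep only the soma-connected component
  lab <- label_components(bin)
  ctr <- round(soma$centroid) + 1L
  if (lab[ctr[1], ctr[2]] > 0L) bin <- lab == lab[ctr[1], ctr[2]]
  branches <- build_branches(bin, soma, pixel_size, config,
                             intensity = frame,
                             context_branches = context_branches)
  list(soma = soma, threshold = thr, branches = branches)
}
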
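#' Build a neuron image from comet tracks
#'
#' Accumulates all comet track points from all time points into a binary
#' image, dilates by 1 px and keeps the largest connected component — the
#' EB3-comet footprint of the neuron, ready for skeletonization by the
#' tracing module.
#'
#' @param tracks data frame with `y_px, x_px` (0-based) columns.
#' @param image_size `c(height, width)`; default fits the tracks plus a
#'   margin.
#' @return logical matrix.
#' @export
tracks_to_neuron_image <- function(tracks, image_size = NULL) {
  if (is.null(tracks) || !nrow(tracks)) stop("empty track set")
  if (is.null(image_size)) {
    image_size <- c(ceiling(max(tracks$y_px)) + 6L,
                    ceiling(max(tracks$x_px)) + 6L)
  }
  largest_component(accumulate_tracks(tracks, image_size))
}

# accumulated + dilated track footprint, all components; consecutive points
# of one comet are joined by a rasterized segment (a comet's displacement
# between frames is continuous motion, not isolated dots)
accumulate_tracks <- function(tracks, image_size) {
  img <- matrix(FALSE, image_size[1], image_size[2])
  clamp <- function(v, hi) pmin(pmax(round(v) + 1L, 1L), hi)
  ids <- if ("comet_id" %in% names(tracks)) tracks$comet_id
         else rep(1L, nrow(tracks))
  for (tr in split(tracks, ids)) {
    yy <- clamp(tr$y_px, image_size[1])
    xx <- clamp(tr$x_px, image_size[2])
    img[cbind(yy, xx)] <- TRUE
    if (nrow(tr) > 1L) {
      for (i in seq_len(nrow(tr) - 1L)) {
        img[bresenham(yy[i], xx[i], yy[i + 1L], xx[i + 1L])] <- TRUE
      }
    }
  }
  binary_dilate3(img, 1L)
}

#' Skeleton context for orientation calling
#'
#' Pools the ordered points of all neurite branches (soma-to-tip with arc
#' length) into one lookup table. The soma used for arc-length ordering is
#' the densest accumulation region of the track points unless an explicit
#' soma coordinate is supplied.
#'
#' @param tracks track data frame (`y_px, x_px`).
#' @param pixel_size um per pixel.
#' @param soma_center optional 0-based `c(y, x)` overriding the density
#'   estimate.
#' @param config a [tracing_config()]; the default lowers
#'   `min_branch_points` to 20 because comet coverage is sparser than a
#'   cytosolic fill.
#' @return list with `points` (data frame `y_px, x_px, arclen_um,
#'   branch`), `branches`, `soma_center`.
#' @export
comet_skeleton_context <- function(tracks, pixel_size,
                                   soma_center = NULL,
                                   config = tracing_config(
                                     min_branch_points = 20L)) {
  if (is.null(tracks) || !nrow(tracks)) stop("empty track set")
  img <- accumulate_tracks(tracks,
                           c(ceiling(max(tracks$y_px)) + 6L,
                             ceiling(max(tracks$x_px)) + 6L))
  h <- nrow(img); w <- ncol(img)
  if (is.null(soma_center)) {
    # densest accumulation of track points: smoothed 2D histogram peak
    counts <- matrix(0, h, w)
    yy <- pmin(pmax(round(tracks$y_px) + 1L, 1L), h)
    xx <- pmin(pmax(round(tracks$x_px) + 1L, 1L), w)
    for (i in seq_along(yy)) counts[yy[i], xx[i]] <- counts[yy[i], xx[i]] + 1
    sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(counts), sigma = 4))
    pk <- which(sm == max(sm), arr.ind = TRUE)[1, ]
    soma_center <- c(pk[1] - 1, pk[2] - 1)
  }
  # synthetic soma disk so the tracing machinery can root the branches;
  # the radius grows until the disk touches the track footprint
  yy <- matrix(seq_len(h) - 1L, h, w)
  xx <- matrix(rep(seq_len(w) - 1L, each = h), h, w)
  d2 <- (yy - soma_center[1])^2 + (xx - soma_center[2])^2
  # reach every footprint component (neurites connect only through the
  # soma, which comet tracks cover poorly)
  lab <- label_components(img)
  r_touch <- max(vapply(seq_len(max(lab)), function(l) {
    sel <- lab == l
    if (sum(sel) < 5L) return(0)
    sqrt(min(d2[sel]))
  }, 0))
  disk <- d2 <= max(3, r_touch + 2)^2
  img <- largest_component(img | disk)
  soma <- structure(list(mask = disk, centroid = soma_center,
                         area = sum(disk)), class = "SomaMask")
  branches <- build_branches(img, soma, pixel_size, config)
  pts <- do.call(rbind, lapply(seq_along(branches), function(i) {
    b <- branches[[i]]
    data.frame(y_px = b$y_px, x_px = b$x_px, arclen_um = b$arclen_um,
               branch = i, idx = seq_len(nrow(b)))
  }))
  list(points = pts, branches = branches, soma_center = soma_center,
       soma_radius_px = max(3, r_touch + 2))
}

#' Classify the orientation of one comet track
#'
#' Endpoint rule first: the nearest skeleton points of the first and last
#' track points are compared by arc length from the soma — further away at
#' the end means plus-end-out, closer means minus-end-out. When both map to
#' the same skeleton point, per-timepoint angle votes decide: the comet
#' direction from t to t+2 is compared with the local neurite direction
#' (skeleton points two before to two after the nearest point); an unsigned
#' angle difference below 70 degrees votes plus-end-out, above 110 degrees
#' minus-end-out, the band between votes nothing. The winning label needs
#' at least the consensus share (default 65%) of the cast votes, else the
#' comet is `undetermined`.
#'
#' @param track data frame (`frame, y_px, x_px`) of one comet, >= 3 rows.
#' @param context a [comet_skeleton_context()].
#' @param consensus consensus vote share (default 0.65).
#' @param max_dist_px maximum track-to-skeleton assignment distance.
#' @param count_nonvoting if `TRUE`, the consensus denominator includes
#'   non-voting timepoints (the 70-110 degree band).
#' @return an `OrientationCall` list: `label` (`plus_end_out`,
#'   `minus_end_out`, `undetermined` or `unassigned`), `votes`
#'   (plus/minus counts), `vote_share`, `method` (`endpoint` or `angle`).
#' @export
classify_comet <- function(track, context, consensus = 0.65,
                           max_dist_px = 5, count_nonvoting = FALSE) {
  if (nrow(track) < 3L) stop("track must span at least 3 frames")
  pts <- context$points
  if (is.null(pts) || !nrow(pts)) stop("empty skeleton context")
  soma_r <- context$soma_radius_px %||% 0
  nearest <- function(y, x) {
    # points inside the soma sit at arc length 0 by definition
    if (!is.null(context$soma_center) &&
        sqrt(sum((c(y, x) - context$soma_center)^2)) <= soma_r)
      return(list(i = 0L, dist = 0, arclen = 0))
    d2 <- (pts$y_px - y)^2 + (pts$x_px - x)^2
    i <- which.min(d2)
    list(i = i, dist = sqrt(d2[i]), arclen = pts$arclen_um[i])
  }
  call <- function(label, votes, share, method) {
    structure(list(label = label, votes = votes, vote_share = share,
                   method = method), class = "OrientationCall")
  }
  n <- nrow(track)
  nf <- nearest(track$y_px[1], track$x_px[1])
  nl <- nearest(track$y_px[n], track$x_px[n])
  if (nf$dist > max_dist_px || nl$dist > max_dist_px)
    return(call("unassigned", c(plus = 0L, minus = 0L), NA_real_, "endpoint"))
  a_first <- nf$arclen
  a_last <- nl$arclen
  if (a_last != a_first) {
    lab <- if (a_last > a_first) "plus_end_out" else "minus_end_out"
    return(call(lab, c(plus = 0L, minus = 0L), 1, "endpoint"))
  }
  # tie: angle votes per timepoint
  plus <- 0L; minus <- 0L; novote <- 0L
  for (t in seq_len(n - 2L)) {
    cd <- c(track$y_px[t + 2L] - track$y_px[t],
            track$x_px[t + 2L] - track$x_px[t])
    if (all(cd == 0)) { novote <- novote + 1L; next }
    # anchor the neurite direction at the midpoint of the 3-point window,
    # which makes the vote set exactly mirror under time reversal
    np <- nearest(track$y_px[t + 1L], track$x_px[t + 1L])
    if (np$dist > max_dist_px || np$i == 0L) { novote <- novote + 1L; next }
    b <- pts$branch[np$i]; i <- pts$idx[np$i]
    bb <- context$branches[[b]]
    i0 <- max(1L, i - 2L); i1 <- min(nrow(bb), i + 2L)
    nd <- c(bb$y_px[i1] - bb$y_px[i0], bb$x_px[i1] - bb$x_px[i0])
    if (all(nd == 0)) { novote <- novote + 1L; next }
    ang <- acos(pmin(pmax(sum(cd * nd) /
                            (sqrt(sum(cd^2)) * sqrt(sum(nd^2))), -1), 1)) *
      180 / pi
    if (ang < 70) plus <- plus + 1L
    else if (ang > 110) minus <- minus + 1L
    else novote <- novote + 1L
  }
  denom <- if (count_nonvoting) plus + minus + novote else plus + minus
  if (denom == 0L)
    return(call("undetermined", c(plus = plus, minus = minus), NA_real_,
                "angle"))
  share <- max(plus, minus) / denom
  lab <- if (share >= consensus && plus != minus) {
    if (plus > minus) "plus_end_out" else "minus_end_out"
  } else "undetermined"
  call(lab, c(plus = plus, minus = minus), share, "angle")
}

#' Orientation calls for a whole track set
#'
#' @param tracks data frame (`comet_id, frame, y_px, x_px`).
#' @param context a [comet_skeleton_context()]; built from `tracks` when
#'   `NULL`.
#' @param pixel_size um per pixel (needed when building the context).
#' @param ... passed to [classify_comet()].
#' @return data frame `(comet_id, label, vote_share, method)`.
#' @export
classify_comets <- function(tracks, context = NULL, pixel_size = 0.22, ...) {
  if (is.null(context)) context <- comet_skeleton_context(tracks, pixel_size)
  ids <- unique(tracks$comet_id)
  out <- lapply(ids, function(id) {
    tr <- tracks[tracks$comet_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    cc <- classify_comet(tr, context, ...)
    data.frame(comet_id = id, label = cc$label,
               vote_share = cc$vote_share, method = cc$method)
  })
  do.call(rbind, out)
}

#' Summarize orientation calls
#'
#' Plus-end-out fraction among determined comets, with the undetermined
#' (and unassigned) fractions reported separately.
#'
#' @param calls data frame from [classify_comets()] (or a vector of
#'   labels).
#' @return list with `fraction_plus_end_out` (among determined),
#'   `n_determined`, `fractions` over the three labels (summing to 1),
#'   `n`.
#' @export
orientation_summary <- function(calls) {
  labels <- if (is.data.frame(calls)) calls$label else as.character(calls)
  labels <- labels[labels != "unassigned"]
  n <- length(labels)
  det <- labels[labels %in% c("plus_end_out", "minus_end_out")]
  frac <- c(plus_end_out = sum(labels == "plus_end_out") / n,
            minus_end_out = sum(labels == "minus_end_out") / n,
            undetermined = sum(labels == "undetermined") / n)
  list(
    fraction_plus_end_out = if (length(det))
      mean(det == "plus_end_out") else NA_real_,
    n_determined = length(det),
    fractions = frac,
    n = n
  )
}
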
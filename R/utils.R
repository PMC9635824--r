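#' Cyclically roll a matrix
#'
#' Shifts a matrix by whole pixels with wrap-around, the discrete analogue of
#' `numpy.roll`. Positive `dy` moves content down (towards higher row index),
#' positive `dx` moves content right.
#'
#' @param m numeric matrix.
#' @param dy,dx integer shifts in rows/columns.
#' @return matrix of the same dimension.
#' @export
roll_matrix <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  dy <- as.integer(round(dy)) %% h
  dx <- as.integer(round(dx)) %% w
  if (dy == 0L && dx == 0L) return(m)
  ri <- ((seq_len(h) - 1L - dy) %% h) + 1L
  ci <- ((seq_len(w) - 1L - dx) %% w) + 1L
  m[ri, ci, drop = FALSE]
}

#' Translate a matrix, zero-filling the vacated margin
#'
#' Same displacement as [roll_matrix()] but pixels wrapped around the border
#' are replaced by zeros, the convention used when writing registered movies.
#'
#' @inheritParams roll_matrix
#' @return matrix of the same dimension with `|dy|*W + |dx|*H - |dy|*|dx|`
#'   zeroed pixels.
#' @export
translate_zero <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  dy <- as.integer(round(dy)); dx <- as.integer(round(dx))
  out <- roll_matrix(m, dy, dx)
  if (dy > 0) out[seq_len(min(dy, h)), ] <- 0
  if (dy < 0) out[(h + max(dy, -h) + 1L):h, ] <- 0
  if (dx > 0) out[, seq_len(min(dx, w))] <- 0
  if (dx < 0) out[, (w + max(dx, -w) + 1L):w] <- 0
  out
}

# Median filter with a rectangular footprint and edge replication.
# size is c(rows, cols); even sizes use the window [i, i+size-1] like
# a trailing window, median of an even count = mean of the middle two.
median_filter_rect <- function(m, size) {
  sr <- size[1]; sc <- size[2]
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  # pad by edge replication so windows near the border stay full
  pr <- sr - 1L; pc <- sc - 1L
  ri <- pmin(pmax(seq_len(h + pr) - floor(pr / 2), 1L), h)
  ci <- pmin(pmax(seq_len(w + pc) - floor(pc / 2), 1L), w)
  mp <- m[ri, ci, drop = FALSE]
  for (i in seq_len(h)) {
    block <- mp[i:(i + sr - 1L), , drop = FALSE]
    for (j in seq_len(w)) {
      out[i, j] <- stats::median(block[, j:(j + sc - 1L)])
    }
  }
  out
}

# Dilate a binary matrix with a 3x3 square brush, n iterations.
binary_dilate3 <- function(mask, iterations = 1L) {
  m <- mask
  h <- nrow(m); w <- ncol(m)
  for (k in seq_len(iterations)) {
    p <- matrix(FALSE, h + 2L, w + 2L)
    p[2:(h + 1L), 2:(w + 1L)] <- m
    acc <- matrix(FALSE, h, w)
    for (dy in 0:2) for (dx in 0:2) {
      acc <- acc | p[(1L + dy):(h + dy), (1L + dx):(w + dx)]
    }
    m <- acc
  }
  m
}

# Erode a binary matrix with a plus-shaped (4-connected) element.
binary_erode_cross <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  p <- matrix(FALSE, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- mask
  p[2:(h + 1L), 2:(w + 1L)] &
    p[1:h, 2:(w + 1L)] & p[3:(h + 2L), 2:(w + 1L)] &
    p[2:(h + 1L), 1:w] & p[2:(h + 1L), 3:(w + 2L)]
}

# Fill holes in a binary matrix (regions of FALSE not connected to the
# border, 4-connectivity for the background as is conventional).
fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- !mask
  # flood fill background from the border using a queue on the padded image
  lab <- matrix(FALSE, h, w)  # reachable background
  queue <- integer(0)
  idx <- function(i, j) (j - 1L) * h + i
  border <- c(idx(1L, seq_len(w)), idx(h, seq_len(w)),
              idx(seq_len(h), 1L), idx(seq_len(h), w))
  seed <- border[bg[border]]
  lab[seed] <- TRUE
  queue <- seed
  while (length(queue)) {
    cur <- queue
    queue <- integer(0)
    i <- ((cur - 1L) %% h) + 1L
    j <- ((cur - 1L) %/% h) + 1L
    for (d in 1:4) {
      ii <- i + c(-1L, 1L, 0L, 0L)[d]
      jj <- j + c(0L, 0L, -1L, 1L)[d]
      ok <- ii >= 1L & ii <= h & jj >= 1L & jj <= w
      nb <- idx(ii[ok], jj[ok])
      nb <- nb[bg[nb] & !lab[nb]]
      if (length(nb)) {
        lab[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    queue <- unique(queue)
  }
  mask | (bg & !lab)
}

# Connected-component labelling with 8-connectivity: EBImage's bwlabel is
# 4-connected, so labels that touch diagonally are merged by union-find.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab < 2L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # \ diagonal
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1]))   # / diagonal
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nlab), find, 0L)
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

# Largest connected component of a binary mask; returns logical matrix,
# all-FALSE if the mask is empty.
largest_component <- function(mask) {
  if (!any(mask)) return(mask & FALSE)
  lab <- label_components(mask)
  tab <- tabulate(lab[lab > 0L])
  lab == which.max(tab)
}

# Pearson correlation of two matrices as flat vectors; NA if degenerate.
mat_cor <- function(a, b) {
  av <- as.vector(a); bv <- as.vector(b)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
  stats::cor(av, bv)
}

# Bresenham line between two pixel coordinates, inclusive.
bresenham <- function(y0, x0, y1, x1) {
  dy <- abs(y1 - y0); dx <- abs(x1 - x0)
  sy <- sign(y1 - y0); sx <- sign(x1 - x0)
  err <- dx - dy
  ys <- integer(0); xs <- integer(0)
  y <- y0; x <- x0
  repeat {
    ys <- c(ys, y); xs <- c(xs, x)
    if (y == y1 && x == x1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dx; y <- y + sy }
  }
  cbind(y = ys, x = xs)
}

# Arc length of an ordered pixel path in um (steps of 1 or sqrt(2) px).
path_arclength <- function(y, x, pixel_size) {
  if (length(y) < 2L) return(rep(0, length(y)))
  steps <- sqrt(diff(y)^2 + diff(x)^2)
  c(0, cumsum(steps)) * pixel_size
}
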
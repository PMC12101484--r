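#' Extract a square analysis window around a spot centre
#'
#' Returns the `(2*half+1)`-pixel square subimage centred on the spot.  A
#' spot whose window would cross the frame edge is excluded (flagged, not
#' padded): a sufficiently large window cannot be constructed.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param center integer pair `(row, col)` of the central pixel.
#' @param half window half-size in pixels.
#' @return list with `ok`; on success `subimage` and `offset` (row/col of
#'   subimage pixel (1,1) in the frame), otherwise `reason = "edge"`.
#' @export
extract_window <- function(image, center, half = 5) {
  stopifnot(is.matrix(image), length(center) == 2)
  r <- round(center[1])
  c <- round(center[2])
  if (r < 1 || c < 1 || r > nrow(image) || c > ncol(image))
    stop("center lies outside the image")
  if (r - half < 1 || c - half < 1 ||
      r + half > nrow(image) || c + half > ncol(image))
    return(list(ok = FALSE, reason = "edge"))
  list(ok = TRUE,
       subimage = image[(r - half):(r + half), (c - half):(c + half)],
       offset = c(r - half, c - half))
}

#' Binarize a subimage at a fraction of its maximum intensity
#'
#' Global threshold at `frac` of the brightest pixel; pixels `>=` the
#' threshold are foreground.  An all-zero (dark) subimage is an excluded
#' outcome, not an error.
#'
#' @param subimage numeric matrix.
#' @param frac threshold fraction of the maximum intensity.
#' @return list with `ok` and `mask` (logical matrix), or `reason = "dark"`.
#' @export
binarize <- function(subimage, frac = 0.33) {
  stopifnot(is.matrix(subimage), length(subimage) > 0)
  m <- max(subimage)
  if (m <= 0) return(list(ok = FALSE, reason = "dark"))
  list(ok = TRUE, mask = subimage >= frac * m)
}

# 8-connected component labelling of a logical mask (two-pass union-find);
# label ids are assigned in raster (column-major) order of first contact
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  nxt <- 0L
  for (cc in seq_len(nc)) {
    for (rr in seq_len(nr)) {
      if (!mask[rr, cc]) next
      nbr <- integer(0)
      for (dc in -1:0) for (dr in -1:1) {
        if (dc == 0 && dr >= 0) next # already-visited neighbours only
        r2 <- rr + dr
        c2 <- cc + dc
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && lab[r2, c2] > 0)
          nbr <- c(nbr, lab[r2, c2])
      }
      if (length(nbr) == 0) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[rr, cc] <- nxt
      } else {
        roots <- vapply(unique(nbr), find, integer(1))
        keep <- min(roots)
        lab[rr, cc] <- keep
        for (r0 in roots) parent[r0] <- keep
      }
    }
  }
  if (nxt > 0) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    remap <- integer(nxt)
    remap[sort(unique(roots))] <- seq_along(unique(sort(roots)))
    idx <- lab > 0
    lab[idx] <- remap[roots[lab[idx]]]
  }
  lab
}

#' Connected component nearest to the central pixel
#'
#' 8-connected components of the mask are labelled; the component whose
#' nearest pixel (Euclidean pixel distance) to the central pixel is
#' smallest wins (distance 0 when the centre lies inside a component).
#' Ties go to the lower label id, deterministically.
#'
#' @param mask logical matrix from [binarize()].
#' @param center integer pair `(row, col)` within the mask (defaults to
#'   the central pixel of the matrix).
#' @return list with `ok`; on success `component` (logical matrix),
#'   `label`, `distance`; for an empty mask, `reason = "dark"`.
#' @export
nearest_component <- function(mask, center = NULL) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) return(list(ok = FALSE, reason = "dark"))
  if (is.null(center)) center <- (dim(mask) + 1) / 2
  lab <- label_components(mask)
  nlab <- max(lab)
  dmin <- rep(Inf, nlab)
  idx <- which(mask, arr.ind = TRUE)
  dd <- sqrt((idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2)
  ll <- lab[mask]
  for (k in seq_along(ll)) if (dd[k] < dmin[ll[k]]) dmin[ll[k]] <- dd[k]
  best <- which(dmin == min(dmin))[1] # tie -> lower label id
  list(ok = TRUE, component = lab == best, label = best,
       distance = dmin[best])
}

#' Moment-based ellipse fit and area of a component
#'
#' The standard region-property ellipse: axes are
#' \eqn{4\sqrt{\lambda}} for the eigenvalues \eqn{\lambda} of the
#' covariance matrix of the component's pixel coordinates, with the
#' \eqn{+1/12} per-pixel variance correction (each pixel treated as a unit
#' square).  The area is \eqn{A = \pi (\mathrm{major}/2)(\mathrm{minor}/2)}
#' in px\eqn{^2}, converted to \eqn{\mu m^2} by the squared pixel size.
#'
#' @param component logical matrix (a single connected component).
#' @param pixel_size pixel edge length in um/px.
#' @param track,frame optional identifiers carried into the record.
#' @return a one-row `area_record` tibble: `track`, `frame`, `row`, `col`
#'   (centroid), `major`, `minor` (px), `orientation` (degrees), `area_px2`,
#'   `area_um2`, `excluded`, `reason`.
#' @export
ellipse_area <- function(component, pixel_size = 1,
                         track = NA_integer_, frame = NA_integer_) {
  stopifnot(is.matrix(component), any(component))
  idx <- which(component, arr.ind = TRUE)
  mu <- colMeans(idx)
  n <- nrow(idx)
  cr <- idx[, 1] - mu[1]
  cc <- idx[, 2] - mu[2]
  cov <- matrix(c(mean(cr^2) + 1 / 12, mean(cr * cc),
                  mean(cr * cc), mean(cc^2) + 1 / 12), 2, 2)
  ev <- eigen(cov, symmetric = TRUE)
  major <- 4 * sqrt(ev$values[1])
  minor <- 4 * sqrt(ev$values[2])
  orient <- atan2(ev$vectors[1, 1], ev$vectors[2, 1]) * 180 / pi
  area_px2 <- pi * (major / 2) * (minor / 2)
  area_record(track = track, frame = frame, row = mu[1], col = mu[2],
              major = major, minor = minor, orientation = orient,
              area_px2 = area_px2, area_um2 = area_px2 * pixel_size^2,
              excluded = FALSE, reason = NA_character_)
}

area_record <- function(track = NA_integer_, frame = NA_integer_,
                        row = NA_real_, col = NA_real_,
                        major = NA_real_, minor = NA_real_,
                        orientation = NA_real_,
                        area_px2 = NA_real_, area_um2 = NA_real_,
                        excluded = FALSE, reason = NA_character_) {
  tibble::tibble(track = track, frame = frame, row = row, col = col,
                 major = major, minor = minor, orientation = orientation,
                 area_px2 = area_px2, area_um2 = area_um2,
                 excluded = excluded, reason = reason)
}

#' Measure condensate areas for tracked spots in an image stack
#'
#' Runs the full per-spot pipeline: window extraction
#' ([extract_window()]), 33%-of-max thresholding ([binarize()]), nearest
#' connected component ([nearest_component()]) and moment-based ellipse
#' sizing ([ellipse_area()]).  Excluded spots (edge windows, dark
#' subimages) are kept in the output with their reason, so
#' `excluded + measured` always accounts for every spot.
#'
#' @param frames list of numeric matrices (one per frame), or a single
#'   matrix.
#' @param spots tibble with columns `track`, `frame` (1-based index into
#'   `frames`), `row`, `col` (pixel coordinates of the spot centre).
#' @param pixel_size um/px conversion.
#' @param half window half-size in px.
#' @param frac binarisation threshold fraction.
#' @return an `area_record` tibble with one row per spot.
#' @export
measure_areas <- function(frames, spots, pixel_size = 1, half = 5,
                          frac = 0.33) {
  if (is.matrix(frames)) frames <- list(frames)
  out <- vector("list", nrow(spots))
  for (i in seq_len(nrow(spots))) {
    tr <- spots$track[i]
    fr <- spots$frame[i]
    ctr <- c(spots$row[i], spots$col[i])
    rec <- NULL
    img <- frames[[fr]]
    w <- extract_window(img, ctr, half = half)
    if (!w$ok) {
      rec <- area_record(track = tr, frame = fr, row = ctr[1], col = ctr[2],
                         excluded = TRUE, reason = w$reason)
    } else {
      b <- binarize(w$subimage, frac = frac)
      if (!b$ok) {
        rec <- area_record(track = tr, frame = fr, row = ctr[1],
                           col = ctr[2], excluded = TRUE, reason = b$reason)
      } else {
        comp <- nearest_component(b$mask)
        if (!comp$ok) {
          rec <- area_record(track = tr, frame = fr, row = ctr[1],
                             col = ctr[2], excluded = TRUE,
                             reason = comp$reason)
        } else {
          rec <- ellipse_area(comp$component, pixel_size = pixel_size,
                              track = tr, frame = fr)
          rec$row <- rec$row + w$offset[1] - 1
          rec$col <- rec$col + w$offset[2] - 1
        }
      }
    }
    out[[i]] <- rec
  }
  do.call(rbind, out)
}
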
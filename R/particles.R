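# Nuclear-body particle quantification in multi-channel fluorescence images.
#
# Images are numeric matrices (rows = y, columns = x). Centroids are
# intensity-weighted and reported in 0-based pixel coordinates (x = column,
# y = row, pixel centers), so a uniform square covering rows/cols 10..14
# has centroid (12, 12). Inputs are assumed pre-masked to nuclear regions.

.shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  ri <- max(1L, 1L + dr):min(nr, nr + dr)
  rj <- max(1L, 1L + dc):min(nc, nc + dc)
  out[ri, rj] <- m[ri - dr, rj - dc]
  out
}

# 8-connected component labeling by iterative minimum-label propagation.
# Returns an integer matrix with labels 1..k (0 = background).
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- which(mask)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  repeat {
    new <- lab
    for (k in seq_len(nrow(offs))) {
      sh <- .shift_mat(lab, offs$dr[k], offs$dc[k])
      take <- mask & sh > 0L & sh < new
      new[take] <- sh[take]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

#' Detect particles in one image channel
#'
#' Particles are 8-connected components of pixels at or above `threshold`
#' with at least `min_area` pixels (the fixed-threshold particle-analyzer
#' convention). Centroids are intensity-weighted centers of mass.
#'
#' @param image numeric matrix of intensities.
#' @param threshold fixed intensity threshold (pixels >= threshold are
#'   foreground).
#' @param min_area minimum component area in pixels (default 1).
#' @param channel_name label stored on the result.
#' @return a `particle_set` data.frame: label, area, total_intensity,
#'   mean_intensity, x, y; the label matrix is kept in the `labels`
#'   attribute.
#' @export
detect_particles <- function(image, threshold, min_area = 1L,
                             channel_name = "channel") {
  if (!is.matrix(image) || length(image) == 0)
    stop("image must be a non-empty matrix")
  if (!all(is.finite(image))) stop("image contains non-finite intensities")
  mask <- image >= threshold
  lab <- label_components(mask)
  keep_empty <- function() {
    out <- data.frame(label = integer(), area = integer(),
                      total_intensity = numeric(),
                      mean_intensity = numeric(),
                      x = numeric(), y = numeric())
    attr(out, "labels") <- lab
    attr(out, "channel") <- channel_name
    class(out) <- c("particle_set", "data.frame")
    return(out)
  }
  if (!any(mask)) return(keep_empty())
  idx <- which(lab > 0L)
  l <- lab[idx]
  inten <- image[idx]
  row0 <- (idx - 1L) %% nrow(image)        # 0-based row (y)
  col0 <- (idx - 1L) %/% nrow(image)       # 0-based column (x)
  area <- as.vector(rowsum(rep(1L, length(l)), l))
  tot <- as.vector(rowsum(inten, l))
  cx <- as.vector(rowsum(inten * col0, l)) / tot
  cy <- as.vector(rowsum(inten * row0, l)) / tot
  labels_kept <- sort(unique(l))
  keep <- area >= min_area
  if (!any(keep)) {
    lab[lab %in% labels_kept[!keep]] <- 0L
    out <- keep_empty()
    return(out)
  }
  # relabel compactly after the area filter
  old <- labels_kept[keep]
  lab[!(lab %in% old)] <- 0L
  lab[lab > 0L] <- match(lab[lab > 0L], old)
  out <- data.frame(label = seq_along(old), area = area[keep],
                    total_intensity = tot[keep],
                    mean_intensity = tot[keep] / area[keep],
                    x = cx[keep], y = cy[keep])
  attr(out, "labels") <- lab
  attr(out, "channel") <- channel_name
  class(out) <- c("particle_set", "data.frame")
  out
}

#' @export
print.particle_set <- function(x, ...) {
  cat("particle_set [", attr(x, "channel"), "]: ", nrow(x),
      " particle(s)\n", sep = "")
  NextMethod()
}

#' Associate anchor particles with partner particles by mask overlap
#'
#' An anchor-partner pair is associated when their pixel masks overlap by at
#' least `min_overlap_px` pixels. Per anchor, the occupied fraction is the
#' share of its pixels covered by any partner. Association frequencies are
#' reported for both channels (anchors with >= 1 partner / total anchors,
#' and symmetrically), supporting "148 of 300 particles"-style counts.
#'
#' @param anchors,partners `particle_set`s from the same image frame.
#' @param min_overlap_px minimum pixel overlap to call a pair associated
#'   (default 1).
#' @return an `association_result` list: `pairs` (anchor_label,
#'   partner_label, overlap_px), `anchor_table` (label, occupied_fraction,
#'   associated), `partner_table`, and counts/frequencies per channel.
#' @export
associate <- function(anchors, partners, min_overlap_px = 1L) {
  la <- attr(anchors, "labels"); lp <- attr(partners, "labels")
  stopifnot(!is.null(la), !is.null(lp), identical(dim(la), dim(lp)))
  if (nrow(anchors) == 0)
    warning("empty anchor set; association frequency undefined")
  both <- la > 0L & lp > 0L
  if (any(both)) {
    pa <- la[both]; pp <- lp[both]
    key <- paste(pa, pp)
    cnt <- table(key)
    ij <- do.call(rbind, strsplit(names(cnt), " ", fixed = TRUE))
    pairs <- data.frame(anchor_label = as.integer(ij[, 1]),
                        partner_label = as.integer(ij[, 2]),
                        overlap_px = as.integer(cnt))
    pairs <- pairs[pairs$overlap_px >= min_overlap_px, , drop = FALSE]
    pairs <- pairs[order(pairs$anchor_label, pairs$partner_label), ,
                   drop = FALSE]
    rownames(pairs) <- NULL
    cover <- rowsum(as.integer(lp[la > 0L] > 0L), la[la > 0L])
    occupied <- as.vector(cover)[match(anchors$label,
                                       as.integer(rownames(cover)))]
    occupied[is.na(occupied)] <- 0L
  } else {
    pairs <- data.frame(anchor_label = integer(), partner_label = integer(),
                        overlap_px = integer())
    occupied <- if (nrow(anchors)) rep(0L, nrow(anchors)) else integer()
  }
  anchor_table <- data.frame(
    label = anchors$label,
    occupied_fraction = if (nrow(anchors)) occupied / anchors$area
                        else numeric(),
    associated = anchors$label %in% pairs$anchor_label)
  partner_table <- data.frame(
    label = partners$label,
    associated = partners$label %in% pairs$partner_label)
  structure(list(
    pairs = pairs,
    anchor_table = anchor_table,
    partner_table = partner_table,
    n_anchors = nrow(anchors),
    n_partners = nrow(partners),
    anchor_associated = sum(anchor_table$associated),
    partner_associated = sum(partner_table$associated),
    anchor_frequency = if (nrow(anchors)) mean(anchor_table$associated)
                       else NA_real_,
    partner_frequency = if (nrow(partners)) mean(partner_table$associated)
                        else NA_real_),
    class = "association_result")
}

#' Associate particles by centroid distance
#'
#' Alternative association criterion for point-like loci (e.g. DNA-FISH
#' foci): a pair is associated when the centroid distance is at most
#' `radius` (in micrometres).
#'
#' @param anchors,partners `particle_set`s.
#' @param radius association radius in micrometres (default 0.5).
#' @param pixel_size micrometres per pixel.
#' @return an `association_result` (occupied fractions are NA; overlap_px is
#'   replaced by distance_um in `pairs`).
#' @export
associate_by_distance <- function(anchors, partners, radius = 0.5,
                                  pixel_size = 1) {
  if (nrow(anchors) == 0)
    warning("empty anchor set; association frequency undefined")
  dx <- outer(anchors$x, partners$x, `-`)
  dy <- outer(anchors$y, partners$y, `-`)
  d <- sqrt(dx^2 + dy^2) * pixel_size
  hit <- which(d <= radius, arr.ind = TRUE)
  pairs <- data.frame(anchor_label = anchors$label[hit[, 1]],
                      partner_label = partners$label[hit[, 2]],
                      distance_um = d[hit])
  pairs <- pairs[order(pairs$anchor_label, pairs$partner_label), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  anchor_table <- data.frame(label = anchors$label,
                             occupied_fraction = NA_real_,
                             associated = anchors$label %in%
                               pairs$anchor_label)
  partner_table <- data.frame(label = partners$label,
                              associated = partners$label %in%
                                pairs$partner_label)
  structure(list(pairs = pairs, anchor_table = anchor_table,
                 partner_table = partner_table,
                 n_anchors = nrow(anchors), n_partners = nrow(partners),
                 anchor_associated = sum(anchor_table$associated),
                 partner_associated = sum(partner_table$associated),
                 anchor_frequency = if (nrow(anchors))
                   mean(anchor_table$associated) else NA_real_,
                 partner_frequency = if (nrow(partners))
                   mean(partner_table$associated) else NA_real_),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("association_result: ", x$anchor_associated, "/", x$n_anchors,
      " anchors and ", x$partner_associated, "/", x$n_partners,
      " partners associated (", nrow(x$pairs), " pair(s))\n", sep = "")
  invisible(x)
}

#' Centroid distances of associated pairs
#'
#' Euclidean distance between anchor and partner intensity-weighted
#' centroids, scaled to micrometres, one value per associated pair.
#'
#' @param result an `association_result`.
#' @param anchors,partners the `particle_set`s used to build it.
#' @param pixel_size micrometres per pixel (default 1).
#' @return numeric vector of distances, named `anchor:partner`.
#' @export
center_distances <- function(result, anchors, partners, pixel_size = 1) {
  p <- result$pairs
  ai <- match(p$anchor_label, anchors$label)
  pi <- match(p$partner_label, partners$label)
  d <- sqrt((anchors$x[ai] - partners$x[pi])^2 +
            (anchors$y[ai] - partners$y[pi])^2) * pixel_size
  stats::setNames(d, paste0(p$anchor_label, ":", p$partner_label))
}

#' Average multi-channel crops centred on anchor particles
#'
#' For each channel, averages the (2*half_width+1)^2 pixel crop centred at
#' the rounded centroid of every anchor that fits inside the frame; anchors
#' whose crop would cross the frame edge are skipped and counted. A
#' horizontal line profile through the crop centre is emitted per channel.
#'
#' @param channels named list of numeric matrices (one frame, same size).
#' @param anchors a `particle_set` providing the anchor centroids.
#' @param half_width crop half width in pixels.
#' @return list: `crops` (named list of mean crop matrices), `profiles`
#'   (named list of centre-row vectors), `n_used`, `n_skipped`.
#' @export
average_anchored_image <- function(channels, anchors, half_width) {
  stopifnot(is.list(channels), length(channels) >= 1)
  dims <- dim(channels[[1]])
  for (ch in channels) stopifnot(identical(dim(ch), dims))
  cy <- round(anchors$y) + 1L    # back to 1-based matrix rows
  cx <- round(anchors$x) + 1L
  ok <- cy - half_width >= 1 & cy + half_width <= dims[1] &
        cx - half_width >= 1 & cx + half_width <= dims[2]
  if (!any(ok)) stop("all anchors skipped: crops exceed the frame")
  w <- 2L * half_width + 1L
  crops <- lapply(channels, function(ch) {
    acc <- matrix(0, w, w)
    for (i in which(ok))
      acc <- acc + ch[(cy[i] - half_width):(cy[i] + half_width),
                      (cx[i] - half_width):(cx[i] + half_width)]
    acc / sum(ok)
  })
  profiles <- lapply(crops, function(cr) cr[half_width + 1L, ])
  list(crops = crops, profiles = profiles,
       n_used = sum(ok), n_skipped = sum(!ok))
}

#' Write a particle table as TSV
#' @param particles a `particle_set`.
#' @param path output file.
#' @export
write_particles <- function(particles, path) {
  utils::write.table(as.data.frame(particles), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
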
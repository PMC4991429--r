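# Topology-preserving thinning and branch-point detection.
#
# Zhang-Suen thinning reduces a filled region to a 1-px-wide, 8-connected
# skeleton. Thinning a blunt-ended tube produces short diagonal spurs at the
# corners (the medial axis of a rectangle has four corner branches), so before
# counting branch points the skeleton is pruned by iteratively deleting
# endpoints to a depth just past the local tube radius (the maximum of the
# region's distance transform). A straight tube then yields a clean path with
# no branch nodes, while junctions of arms longer than the tube radius
# survive.

# one Zhang-Suen pass; step is 1 or 2. Returns updated logical matrix.
zs_pass <- function(m, step) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  ri <- 2:(nr + 1); ci <- 2:(nc + 1)
  P2 <- p[ri - 1, ci];     P3 <- p[ri - 1, ci + 1]
  P4 <- p[ri, ci + 1];     P5 <- p[ri + 1, ci + 1]
  P6 <- p[ri + 1, ci];     P7 <- p[ri + 1, ci - 1]
  P8 <- p[ri, ci - 1];     P9 <- p[ri - 1, ci - 1]
  B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
  A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
       (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
  if (step == 1) {
    cnd <- (!(P2 & P4 & P6)) & (!(P4 & P6 & P8))
  } else {
    cnd <- (!(P2 & P4 & P8)) & (!(P2 & P6 & P8))
  }
  del <- m & B >= 2 & B <= 6 & A == 1 & cnd
  m & !del
}

#' Skeletonize a binary region
#'
#' Zhang-Suen topology-preserving thinning to a 1-px-wide skeleton.
#'
#' @param mask logical/0-1 matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- mask != 0
  repeat {
    m1 <- zs_pass(zs_pass(m, 1), 2)
    if (identical(m1, m)) break
    m <- m1
  }
  m
}

# 8-neighbor count of each TRUE pixel
neighbor_counts <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  ri <- 2:(nr + 1); ci <- 2:(nc + 1)
  p[ri - 1, ci] + p[ri - 1, ci + 1] + p[ri, ci + 1] + p[ri + 1, ci + 1] +
    p[ri + 1, ci] + p[ri + 1, ci - 1] + p[ri, ci - 1] + p[ri - 1, ci - 1]
}

#' Prune skeleton spurs
#'
#' Iteratively removes endpoint pixels (skeleton pixels with exactly one
#' 8-neighbor) `depth` times, erasing side branches shorter than `depth`.
#'
#' @param skel logical skeleton matrix.
#' @param depth number of pruning iterations.
#' @return Pruned logical matrix.
#' @export
prune_spurs <- function(skel, depth) {
  m <- skel != 0
  for (i in seq_len(depth)) {
    ends <- m & neighbor_counts(m) == 1L
    if (!any(ends)) break
    m <- m & !ends
  }
  m
}

# circular 0->1 transition count (crossing number) of each pixel's
# 8-neighborhood, in the order N, NE, E, SE, S, SW, W, NW, N
crossing_number <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  ri <- 2:(nr + 1); ci <- 2:(nc + 1)
  P2 <- p[ri - 1, ci];     P3 <- p[ri - 1, ci + 1]
  P4 <- p[ri, ci + 1];     P5 <- p[ri + 1, ci + 1]
  P6 <- p[ri + 1, ci];     P7 <- p[ri + 1, ci - 1]
  P8 <- p[ri, ci - 1];     P9 <- p[ri - 1, ci - 1]
  (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
    (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
}

#' Count skeleton branch points of a vessel
#'
#' The filled region is thinned, spur-pruned to a depth of the local tube
#' radius (maximum distance-transform value) plus 2 px, re-thinned, and
#' branch pixels are identified by a crossing number (0->1 transitions
#' around the 8-neighborhood) of three or more. Thinning decomposes one
#' anatomical n-way junction into several nearby 3-way nodes, so branch
#' pixels closer than the local radius are merged into a single node before
#' counting. A vessel is "branched" iff the count is >= 1.
#'
#' @param region a `vessel_region`, or a logical mask matrix.
#' @param prune_depth pruning depth in px; `NULL` (default) derives it from
#'   the distance transform.
#' @return Integer branch-node count (>= 0).
#' @export
branch_count <- function(region, prune_depth = NULL) {
  if (inherits(region, "vessel_region")) {
    px <- region$pixels
    r0 <- min(px[, 1]); c0 <- min(px[, 2])
    m <- matrix(FALSE, max(px[, 1]) - r0 + 3, max(px[, 2]) - c0 + 3)
    m[cbind(px[, 1] - r0 + 2L, px[, 2] - c0 + 2L)] <- TRUE
  } else {
    m <- region != 0
    # pad so border pixels have a full neighborhood
    mm <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
    mm[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
    m <- mm
  }
  if (!any(m)) return(0L)
  radius <- max(EBImage::distmap(m * 1))
  if (is.null(prune_depth)) prune_depth <- ceiling(radius) + 2L
  sk <- prune_spurs(skeletonize(m), prune_depth)
  if (!any(sk)) return(0L)
  sk <- skeletonize(sk)                   # re-thin stubs left by pruning
  nodes <- sk & crossing_number(sk) >= 3L
  if (!any(nodes)) return(0L)
  merge_r <- max(2L, round(radius / 2))
  fat <- EBImage::dilate(nodes * 1, EBImage::makeBrush(2 * merge_r + 1,
                                                       "disc")) > 0
  max(label_regions(fat))
}
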
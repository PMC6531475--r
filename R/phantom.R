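# Synthetic multichannel fluorescent-cell phantoms with known ground truth.
#
# The generator emulates the statistical shape of simulated fluorescent
# cell-population images: clustered elliptical cytoplasms, one interior
# nucleus per cell, punctate subcellular particles, three channels, Gaussian
# blur. It does not model optics beyond the blur, photobleaching, or time
# series.

# Boolean support of the ellipse centred at (cy, cx) with semi-axes (a, b)
# rotated by theta, evaluated on the pixel grid.
ellipseMask <- function(nr, nc, cy, cx, a, b, theta) {
  y <- matrix(seq_len(nr), nr, nc) - cy
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  u <- cos(theta) * x + sin(theta) * y
  v <- -sin(theta) * x + cos(theta) * y
  (u / a)^2 + (v / b)^2 <= 1
}

# Normalized squared elliptical distance of every pixel to a cell; used to
# resolve overlapping cytoplasms in the label map (nearest wins).
ellipseDist2 <- function(nr, nc, cy, cx, a, b, theta) {
  y <- matrix(seq_len(nr), nr, nc) - cy
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  u <- cos(theta) * x + sin(theta) * y
  v <- -sin(theta) * x + cos(theta) * y
  (u / a)^2 + (v / b)^2
}

diskMask <- function(nr, nc, cy, cx, r) {
  y <- matrix(seq_len(nr), nr, nc) - cy
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  x^2 + y^2 <= r^2
}

#' Generate a synthetic multichannel cell phantom
#'
#' Produces a three-channel (cytoplasm, nucleus, particles) image of a
#' simulated fluorescent cell population together with full ground truth:
#' cell centres, a per-pixel ownership label map, and per-cell cytoplasm,
#' nucleus and particle masks. Cells are elliptical blobs scattered around
#' `nClusters` cluster centres; each carries one concentric nucleus (axes
#' scaled by `nucleusFraction`, hence always inside the cytoplasm) and
#' `nSubcellularObjects` small bright particles placed so their support stays
#' inside the cytoplasm. All channels are Gaussian-blurred and clipped to
#' `[0, 1]`. The output is deterministic for a fixed spec (including seed).
#'
#' @param spec a [PhantomSpec-class]; see [phantomSpec()].
#' @return a [PhantomTruth-class] object.
#' @examples
#' ph <- generatePhantom(phantomSpec(128, 128, nCells = 5, seed = 7))
#' ph
#' range(getChannel(phantomImage(ph), "nucleus"))
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  nr <- spec@height
  nc <- spec@width
  n <- spec@nCells

  if (n == 0L) {
    z <- matrix(0, nr, nc)
    return(new("PhantomTruth",
               image = multichannelImage(list(z, z, z)),
               cellCenters = matrix(numeric(0), 0, 2),
               labelMap = matrix(0L, nr, nc),
               cellMasks = list(), nucleusMasks = list(),
               particleMasks = list()))
  }

  withSeed(spec@seed, {
    rmax <- spec@cellRadiusRange[2]
    margin <- rmax + 2
    if (nr - 2 * margin < 1 || nc - 2 * margin < 1)
      stop("image too small for the requested cell radii", call. = FALSE)

    clusterY <- runif(spec@nClusters, margin, nr - margin)
    clusterX <- runif(spec@nClusters, margin, nc - margin)
    assignment <- rep_len(seq_len(spec@nClusters), n)
    scatter <- min(nr, nc) / 6

    centers <- matrix(NA_real_, n, 2)
    for (k in seq_len(n)) {
      cl <- assignment[k]
      placed <- FALSE
      for (attempt in seq_len(200L)) {
        cy <- clusterY[cl] + rnorm(1, sd = scatter)
        cx <- clusterX[cl] + rnorm(1, sd = scatter)
        inBounds <- cy >= margin && cy <= nr - margin &&
          cx >= margin && cx <= nc - margin
        # distinct centre pixels guarantee every cell owns >= 1 label pixel
        clash <- k > 1L && any(round(centers[seq_len(k - 1L), 1]) == round(cy) &
                               round(centers[seq_len(k - 1L), 2]) == round(cx))
        if (inBounds && !clash) {
          centers[k, ] <- c(cy, cx)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        # fall back to a uniform in-bounds draw, still avoiding centre clashes
        repeat {
          cy <- runif(1, margin, nr - margin)
          cx <- runif(1, margin, nc - margin)
          clash <- k > 1L &&
            any(round(centers[seq_len(k - 1L), 1]) == round(cy) &
                round(centers[seq_len(k - 1L), 2]) == round(cx))
          if (!clash) break
        }
        centers[k, ] <- c(cy, cx)
      }
    }

    cyto <- matrix(0, nr, nc)
    nucl <- matrix(0, nr, nc)
    part <- matrix(0, nr, nc)
    dist2 <- array(Inf, c(nr, nc))
    labelMap <- matrix(0L, nr, nc)
    cellMasks <- vector("list", n)
    nucleusMasks <- vector("list", n)
    particleMasks <- vector("list", n)

    for (k in seq_len(n)) {
      cy <- centers[k, 1]; cx <- centers[k, 2]
      a <- runif(1, spec@cellRadiusRange[1], spec@cellRadiusRange[2])
      ecc <- runif(1, 0.6, 1)
      b <- a * ecc
      theta <- runif(1, 0, pi)

      d2 <- ellipseDist2(nr, nc, cy, cx, a, b, theta)
      cm <- d2 <= 1
      cellMasks[[k]] <- cm
      closer <- cm & (d2 < dist2)
      labelMap[closer] <- k
      dist2[closer] <- d2[closer]

      nm <- d2 <= spec@nucleusFraction^2
      nucleusMasks[[k]] <- nm

      # smooth radial profile keeps interiors gently shaded, not flat
      prof <- pmax(1 - d2, 0)
      cyto <- pmax(cyto, spec@intensityLevels[1] * sqrt(prof) * cm)
      nprof <- pmax(1 - d2 / spec@nucleusFraction^2, 0)
      nucl <- pmax(nucl, spec@intensityLevels[2] * sqrt(nprof) * nm)

      pm <- matrix(FALSE, nr, nc)
      bmin <- min(a, b)
      for (p in seq_len(spec@nSubcellularObjects)) {
        pr <- runif(1, spec@particleRadiusRange[1],
                    spec@particleRadiusRange[2])
        # particle centre at normalized elliptical radius small enough that
        # the whole disk stays inside the cytoplasm ellipse
        umax <- max(0, 1 - pr / bmin)
        u <- sqrt(runif(1)) * umax
        ang <- runif(1, 0, 2 * pi)
        pu <- u * a * cos(ang)
        pv <- u * b * sin(ang)
        py <- cy + sin(theta) * pu + cos(theta) * pv
        px <- cx + cos(theta) * pu - sin(theta) * pv
        dm <- diskMask(nr, nc, py, px, pr) & cm
        pm <- pm | dm
        part <- pmax(part, spec@intensityLevels[3] * dm)
      }
      particleMasks[[k]] <- pm
    }

    # each cell always owns its (distinct) centre pixel, so the label count
    # equals nCells even under heavy overlap
    for (k in seq_len(n)) {
      labelMap[round(centers[k, 1]), round(centers[k, 2])] <- k
    }

    channels <- lapply(list(cyto, nucl, part), function(ch)
      pmin(pmax(gaussianBlur(ch, spec@blurSigma), 0), 1))

    new("PhantomTruth",
        image = multichannelImage(channels),
        cellCenters = centers,
        labelMap = labelMap,
        cellMasks = cellMasks,
        nucleusMasks = nucleusMasks,
        particleMasks = particleMasks)
  })
}
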
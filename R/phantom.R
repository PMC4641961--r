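# Synthetic dermoscopic phantoms with exactly known ground truth.
#
# A phantom is a roughly elliptical dark lesion on lighter homogeneous
# skin, with boundary bumps of controllable count and amplitude, optional
# dark hair strokes, an optional black digitization frame, and optional
# "canopy" lobes (a blob held radially above the boundary by an offset
# neck) that make centroid rays cross the boundary three or more times.
# Everything is determined by the spec and its seed.

#' Specify a synthetic lesion phantom
#'
#' Builds a validated phantom specification. Three difficulty tiers set
#' the artifact defaults: `"clean"` (no noise, hairs or frame),
#' `"standard"` (pixel noise and a black frame) and `"hard"` (noise,
#' hairs, frame and a 30 degree lesion orientation). Any field can be
#' overridden explicitly.
#'
#' Boundary bumps come in two modes: `k > 0` with `bump_angles = NULL`
#' superposes a sinusoidal perturbation with exactly `k` uniformly spaced
#' maxima per revolution (seeded random phase); `bump_angles` places
#' compact raised-cosine bumps at the given screen angles (degrees,
#' x right, y down, so -90 is straight up).
#'
#' @param tier Difficulty tier: `"clean"`, `"standard"` or `"hard"`.
#' @param k Number of sinusoidal boundary bumps (0 = smooth ellipse).
#' @param seed Integer seed determining every random element.
#' @param canvas `(H, W)` canvas size in pixels.
#' @param a,b Ellipse semi-axes in pixels (`a > b > 0`).
#' @param phi Ellipse orientation in radians (screen convention).
#' @param bump_amp Bump amplitude in pixels (must be below `b / 2`).
#' @param bump_sharpness Exponent sharpening sinusoidal bumps (1 = pure
#'   cosine).
#' @param bump_angles Optional vector of screen angles (degrees) for
#'   compact bumps; overrides `k`.
#' @param bump_halfwidth_deg Angular half-width of compact bumps.
#' @param skin,lesion Skin and lesion intensity on the `[0, 255]` scale.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param n_hairs Number of dark hair strokes.
#' @param hair_intensity Hair stroke intensity.
#' @param frame_width Black digitization frame width in pixels (0 = none).
#' @param canopies Optional data frame of canopy lobes with columns
#'   `angle_deg`, `dist`, `rho`, `root_angle_deg`, `neck_halfwidth`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(tier = c("clean", "standard", "hard"),
                         k = 8, seed = 1,
                         canvas = c(340, 400), a = 80, b = 60, phi = NULL,
                         bump_amp = 10, bump_sharpness = 1,
                         bump_angles = NULL, bump_halfwidth_deg = 12,
                         skin = 190, lesion = 70,
                         noise_sd = NULL, n_hairs = NULL,
                         hair_intensity = 30, frame_width = NULL) {
  tier <- match.arg(tier)
  defaults <- switch(tier,
    clean    = list(noise_sd = 0, n_hairs = 0L, frame_width = 0L, phi = 0),
    standard = list(noise_sd = 8, n_hairs = 0L, frame_width = 12L, phi = 0),
    hard     = list(noise_sd = 8, n_hairs = 3L, frame_width = 12L,
                    phi = 30 * pi / 180)
  )
  if (is.null(noise_sd)) noise_sd <- defaults$noise_sd
  if (is.null(n_hairs)) n_hairs <- defaults$n_hairs
  if (is.null(frame_width)) frame_width <- defaults$frame_width
  if (is.null(phi)) phi <- defaults$phi
  stopifnot(a > b, b > 0, bump_amp >= 0, bump_amp < b / 2,
            length(canvas) == 2L, all(canvas > 0),
            abs(skin - lesion) > 4 * noise_sd)
  k <- as.integer(k)
  phase <- if (is.null(bump_angles) && k > 0L) {
    withr::with_seed(as.integer(seed), stats::runif(1)) * 2 * pi / k
  } else 0
  structure(list(
    tier = tier, k = k, seed = as.integer(seed),
    canvas = as.integer(canvas), a = a, b = b, phi = phi,
    bump_amp = bump_amp, bump_sharpness = bump_sharpness,
    bump_angles = bump_angles,
    bump_halfwidth = bump_halfwidth_deg * pi / 180,
    phase = phase,
    skin = skin, lesion = lesion, noise_sd = noise_sd,
    n_hairs = as.integer(n_hairs), hair_intensity = hair_intensity,
    frame_width = as.integer(frame_width),
    canopies = NULL
  ), class = "phantom_spec")
}

#' Lobed phantom with canopy overhangs
#'
#' A phantom whose boundary is not radially single-valued: four "canopy"
#' lobes (a blob of radius `rho` held at distance `dist` from the lesion
#' centre, connected by a neck rooted on the boundary at an offset angle)
#' hover radially above the four diagonal boundary bumps. Rays from the
#' centroid through a canopy cross the boundary at least three times, and
#' the outermost crossing — all the radial distance curve can see — is the
#' canopy, not the bump beneath it, while the four side-view profiles of
#' the borderline construction still see the bump (the canopy occupies a
#' different column/row band). One canopy per diagonal quadrant keeps the
#' mask's principal axis horizontal and every shadowed bump inside a
#' left/right segment.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [phantom_spec()].
#' @return A `phantom_spec` with canopies.
#' @export
lobed_phantom_spec <- function(seed = 1, ...) {
  spec <- phantom_spec(tier = "clean", k = 0L, seed = seed,
                       canvas = c(400, 460), noise_sd = 8,
                       a = 70, b = 66, bump_amp = 12,
                       bump_angles = c(-30, -70, -110, -150,
                                       30, 70, 110, 150),
                       bump_halfwidth_deg = 12, ...)
  spec$canopies <- tibble::tibble(
    angle_deg = c(-30, -150, 30, 150),
    dist = 160, rho = 16,
    root_angle_deg = c(-60, -120, 60, 120),
    neck_halfwidth = 8  # wider than the hair top-hat structuring element
  )
  spec
}

# polar radius of an ellipse with semi-axes a >= b and orientation phi
ellipse_radius <- function(t, a, b, phi = 0) {
  a * b / sqrt((b * cos(t - phi))^2 + (a * sin(t - phi))^2)
}

# bump height component of the phantom radius, vectorised over t
bump_height <- function(spec) {
  force(spec)
  function(t) {
    if (!is.null(spec$bump_angles)) {
      w <- spec$bump_halfwidth
      h <- numeric(length(t))
      for (ang in spec$bump_angles * pi / 180) {
        d <- atan2(sin(t - ang), cos(t - ang))  # wrapped difference
        inb <- abs(d) < w
        h[inb] <- h[inb] + spec$bump_amp * (1 + cos(pi * d[inb] / w)) / 2
      }
      h
    } else if (spec$k > 0L) {
      u <- (cos(spec$k * t - spec$phase * spec$k) + 1) / 2
      spec$bump_amp * (2 * u^spec$bump_sharpness - 1)
    } else {
      numeric(length(t))
    }
  }
}

#' Polar radius function of a phantom contour
#'
#' @param spec A `phantom_spec`.
#' @return A function of angle (radians, screen convention) returning the
#'   contour radius in pixels.
#' @export
phantom_radius <- function(spec) {
  bump <- bump_height(spec)
  function(t) ellipse_radius(t, spec$a, spec$b, spec$phi) + bump(t)
}

#' Analytic phantom contour and ground-truth bump positions
#'
#' Evaluates the phantom's polar contour on a dense angular grid and
#' locates the ground-truth bump apexes as the local maxima of the radius
#' function (for sinusoidal bumps these are verified to number exactly
#' `k`; compact bumps report their nominal angles). Canopies are not part
#' of the polar contour; their apexes are added by [render_phantom()].
#'
#' @param spec A `phantom_spec`.
#' @param n Number of contour vertices (default 2048).
#' @return List with `points` (tibble `t`, `row`, `col`), `truth`
#'   (tibble `angle`, `row`, `col`, `arc_frac`), `center`, `perimeter`.
#' @export
make_contour <- function(spec, n = 2048) {
  rf <- phantom_radius(spec)
  H <- spec$canvas[1]; W <- spec$canvas[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- rf(t)
  pts <- tibble::tibble(t = t, row = cy + r * sin(t), col = cx + r * cos(t))
  seg <- sqrt(diff(pts$row)^2 + diff(pts$col)^2)
  perim <- sum(seg) + sqrt((pts$row[1] - pts$row[n])^2 +
                             (pts$col[1] - pts$col[n])^2)
  arc <- c(0, cumsum(seg))
  truth_angles <- if (!is.null(spec$bump_angles)) {
    sort((spec$bump_angles * pi / 180) %% (2 * pi))
  } else if (spec$k > 0L) {
    tg <- seq(0, 2 * pi, length.out = 7201L)[-7201L]
    rg <- rf(tg)
    up <- rg > rg[c(length(rg), seq_len(length(rg) - 1L))]
    dn <- rg > rg[c(2:length(rg), 1L)]
    mx <- tg[up & dn]
    if (length(mx) == spec$k) sort(mx) else
      sort((spec$phase + 2 * pi * (seq_len(spec$k) - 1L) / spec$k) %% (2 * pi))
  } else {
    numeric(0)
  }
  rt <- rf(truth_angles)
  truth <- tibble::tibble(
    angle = truth_angles,
    row = cy + rt * sin(truth_angles),
    col = cx + rt * cos(truth_angles),
    arc_frac = vapply(truth_angles, function(a) {
      arc[which.min(abs(t - a))] / perim
    }, numeric(1))
  )
  list(points = pts, truth = truth, center = c(cy, cx), perimeter = perim)
}

# squared distance from points (x, y) to the segment p0 -> p1
seg_dist2 <- function(x, y, p0, p1) {
  dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
  len2 <- dx^2 + dy^2
  s <- ((x - p0[1]) * dx + (y - p0[2]) * dy) / len2
  s <- pmin(pmax(s, 0), 1)
  (x - (p0[1] + s * dx))^2 + (y - (p0[2] + s * dy))^2
}

#' Render a phantom image with full ground truth
#'
#' Rasterizes the lesion (plus any canopy lobes), paints it at the lesion
#' intensity on the skin background, adds Gaussian pixel noise, optional
#' anti-pattern hair strokes (random quadratic curves, 1-3 px wide) and
#' an optional black digitization frame, and returns the RGB image
#' together with the exact ground truth.
#'
#' @param spec A `phantom_spec`.
#' @return List with `image` (`H x W x 3` integer array), `mask` (logical
#'   ground-truth lesion mask), `truth` (tibble `row`, `col`, `kind` of
#'   true irregularity apexes: bumps and canopies), `contour` (traced
#'   ground-truth boundary), `hair_mask`, `perimeter`, and `spec`.
#' @export
render_phantom <- function(spec) {
  H <- spec$canvas[1]; W <- spec$canvas[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rf <- phantom_radius(spec)
  dy <- matrix(seq_len(H) - cy, H, W)
  dx <- matrix(rep(seq_len(W) - cx, each = H), H, W)
  th <- atan2(dy, dx)
  rad <- sqrt(dx^2 + dy^2)
  mask <- rad <= rf(th)

  truth <- make_contour(spec)$truth[, c("row", "col")]
  if (nrow(truth) > 0L) truth$kind <- "bump"

  if (!is.null(spec$canopies)) {
    for (i in seq_len(nrow(spec$canopies))) {
      cp <- spec$canopies[i, ]
      ang <- cp$angle_deg * pi / 180
      bcx <- cx + cp$dist * cos(ang); bcy <- cy + cp$dist * sin(ang)
      mask <- mask | ((dx + cx - bcx)^2 + (dy + cy - bcy)^2 <= cp$rho^2)
      rang <- cp$root_angle_deg * pi / 180
      rr <- rf(rang) - 20  # embed the neck root inside the lesion body
      root <- c(cx + rr * cos(rang), cy + rr * sin(rang))
      d2 <- seg_dist2(dx + cx, dy + cy, root, c(bcx, bcy))
      mask <- mask | (d2 <= cp$neck_halfwidth^2)
      apex <- c(bcy + cp$rho * sin(ang), bcx + cp$rho * cos(ang))
      truth <- rbind(truth, tibble::tibble(row = apex[1], col = apex[2],
                                           kind = "canopy"))
    }
  }

  v <- matrix(spec$skin, H, W)
  v[mask] <- spec$lesion

  hair_mask <- matrix(FALSE, H, W)
  img <- withr::with_seed(spec$seed + 1L, {
    if (spec$n_hairs > 0L) {
      # hairs grow as a near-parallel tuft: shared orientation and bow,
      # distinct perpendicular offsets so strokes stay separate
      base_ang <- stats::runif(1, 0, pi)
      base_ctr <- c(stats::runif(1, 2 * H / 5, 3 * H / 5),
                    stats::runif(1, 2 * W / 5, 3 * W / 5))
      base_bow <- stats::runif(1, -25, 25)
      perp0 <- c(cos(base_ang), -sin(base_ang))
      for (h in seq_len(spec$n_hairs)) {
        ang <- base_ang + stats::rnorm(1, 0, 0.02)
        offs <- (h - (spec$n_hairs + 1) / 2) * 50 + stats::runif(1, -8, 8)
        ctr <- base_ctr + offs * perp0
        len <- sqrt(H^2 + W^2)
        dirv <- c(sin(ang), cos(ang))
        p0 <- ctr - len / 2 * dirv
        p2 <- ctr + len / 2 * dirv
        bow <- base_bow + stats::runif(1, -4, 4)
        p1 <- ctr + bow * c(cos(ang), -sin(ang))
        tt <- seq(0, 1, length.out = 4L * (H + W))
        br <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1]
        bc <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2]
        wdt <- sample(1:3, 1)
        off <- expand.grid(r = -2:2, c = -2:2)
        off <- off[off$r^2 + off$c^2 <= (wdt / 2)^2 + 0.26, ]
        for (o in seq_len(nrow(off))) {
          ir <- round(br) + off$r[o]; ic <- round(bc) + off$c[o]
          ok <- ir >= 1 & ir <= H & ic >= 1 & ic <= W
          hair_mask[cbind(ir[ok], ic[ok])] <- TRUE
        }
      }
      v[hair_mask] <- spec$hair_intensity
    }
    arr <- array(0, c(H, W, 3L))
    arr[, , 1] <- v + 15
    arr[, , 2] <- v
    arr[, , 3] <- v - 12
    if (spec$noise_sd > 0) {
      arr <- arr + array(stats::rnorm(length(arr), 0, spec$noise_sd),
                         dim(arr))
    }
    arr
  })
  if (spec$frame_width > 0L) {
    f <- spec$frame_width
    img[c(1:f, (H - f + 1L):H), , ] <- 5
    img[, c(1:f, (W - f + 1L):W), ] <- 5
  }
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"

  contour <- trace_boundary(mask)
  pos <- contour_arc_positions(contour)
  list(image = img, mask = mask, truth = truth, contour = contour,
       hair_mask = hair_mask, perimeter = attr(pos, "perimeter"),
       spec = spec)
}
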
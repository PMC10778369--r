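#' Specification of a synthetic IHC tile
#'
#' Describes one procedurally generated immunohistochemistry-like field:
#' stain style, scenario (which epithelial tissue types are present), marker
#' positivity of tumor nuclei, nest geometry and background confounders.
#' Scenarios mirror the four ROI categories used for region-level tumor
#' segmentation: `normal` (all epithelium belongs to normal ducts/lobules,
#' background class), `dcis` (large rounded nests with a continuous
#' myoepithelial-like rim), `invasive` (small irregular nests), and `mixed`.
#'
#' @param size_px square tile side in pixels; must be >= 64 and divisible by 8
#'   (the network output stride)
#' @param stain one of "ER", "PR", "HER2", "Ki67". HER2 renders the chromogen
#'   on cell membranes; the others render it in nuclei.
#' @param positivity fraction in 0..1 of tumor nuclei rendered
#'   chromogen-positive
#' @param scenario one of "normal", "dcis", "invasive", "mixed"
#' @param nest_size_range pixel-radius interval for invasive-carcinoma nests
#' @param dcis_radius_range pixel-radius interval for DCIS nests
#' @param confounders character subset of c("lobule", "lymphocytes"); rendered
#'   but labeled background (class 0)
#' @param seed integer seed; generation is bit-reproducible for a fixed spec
#' @return object of class `tile_spec`
#' @export
tile_spec <- function(size_px = 256L,
                      stain = c("Ki67", "ER", "PR", "HER2"),
                      positivity = 0.3,
                      scenario = c("mixed", "normal", "dcis", "invasive"),
                      nest_size_range = c(9, 20),
                      dcis_radius_range = c(32, 56),
                      confounders = character(0),
                      seed = 1L) {
  stain <- match.arg(stain)
  scenario <- match.arg(scenario)
  size_px <- as.integer(size_px)
  if (size_px < 64L) stop("size_px must be >= 64")
  if (size_px %% 8L != 0L)
    stop("size_px must be divisible by 8 (network stride requirement)")
  if (positivity < 0 || positivity > 1) stop("positivity must be in [0,1]")
  if (min(nest_size_range) <= 0 || min(dcis_radius_range) <= 0)
    stop("radius intervals must have positive lower bounds")
  if (!all(confounders %in% c("lobule", "lymphocytes")))
    stop("confounders must be a subset of {lobule, lymphocytes}")
  structure(list(
    size_px = size_px, stain = stain, positivity = positivity,
    scenario = scenario, nest_size_range = nest_size_range,
    dcis_radius_range = dcis_radius_range,
    confounders = unique(confounders), seed = as.integer(seed)
  ), class = "tile_spec")
}

# ---- internal scene renderer (shared by tiles and pseudo-WSIs) -------------

# radial outline: r(theta) = R * (1 + sum_k a_k cos(k t) + b_k sin(k t))
new_outline <- function(radius, amp, harmonics) {
  k <- seq_len(harmonics)
  a <- rnorm(harmonics, 0, amp / k)
  b <- rnorm(harmonics, 0, amp / k)
  function(theta) {
    r <- rep(1, length(theta))
    for (i in k) r <- r + a[i] * cos(i * theta) + b[i] * sin(i * theta)
    radius * pmax(r, 0.25)
  }
}

scene_new <- function(size) {
  e <- new.env(parent = emptyenv())
  e$size <- size
  e$H <- matrix(0, size, size)   # hematoxylin OD
  e$D <- matrix(0, size, size)   # DAB OD
  e$R <- matrix(0, size, size)   # residual OD
  e$mask <- matrix(0L, size, size)
  e$occ <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0))
  e$placements <- data.frame(nest = integer(0), class = integer(0),
                             cx = numeric(0), cy = numeric(0),
                             n_pixels = integer(0))
  e$nuclei <- data.frame(x = numeric(0), y = numeric(0),
                         class = character(0), marker_positive = logical(0),
                         stringsAsFactors = FALSE)
  e
}

scene_background <- function(sc) {
  n <- max(8L, sc$size %/% 32L)
  sc$H <- sc$H + 0.02 + 0.03 * resize_bilinear(matrix(runif(n * n), n, n),
                                               sc$size, sc$size)
  sc$R <- sc$R + 0.04 + 0.05 * resize_bilinear(matrix(runif(n * n), n, n),
                                               sc$size, sc$size)
  invisible(sc)
}

# try to find a center at least (r + margin) away from existing occupants
scene_find_center <- function(sc, r, margin = 6, tries = 60,
                              interior_frac = 0.0) {
  lo <- 1 + interior_frac * sc$size
  hi <- sc$size - interior_frac * sc$size
  for (t in seq_len(tries)) {
    cx <- runif(1, lo, hi); cy <- runif(1, lo, hi)
    if (nrow(sc$occ) == 0) return(c(cx, cy))
    d <- sqrt((sc$occ$cx - cx)^2 + (sc$occ$cy - cy)^2)
    if (all(d > sc$occ$r + r + margin)) return(c(cx, cy))
  }
  NULL
}

# soft elliptical nucleus splat; returns nothing, paints OD maps in place
paint_nucleus <- function(sc, x, y, a, b, phi, od_h, od_d,
                          membrane_od = 0) {
  rr <- ceiling(max(a, b) + (if (membrane_od > 0) 3 else 1))
  i0 <- max(1, floor(y - rr)); i1 <- min(sc$size, ceiling(y + rr))
  j0 <- max(1, floor(x - rr)); j1 <- min(sc$size, ceiling(x + rr))
  if (i0 > i1 || j0 > j1) return(invisible(NULL))
  ii <- i0:i1; jj <- j0:j1
  dy <- ii - y; dx <- jj - x
  DX <- matrix(dx, length(ii), length(jj), byrow = TRUE)
  DY <- matrix(dy, length(ii), length(jj))
  u <- (DX * cos(phi) + DY * sin(phi)) / a
  v <- (-DX * sin(phi) + DY * cos(phi)) / b
  q <- sqrt(u^2 + v^2)
  w <- clamp(2 * (1.05 - q), 0, 1)  # soft disc profile
  if (od_h > 0) sc$H[ii, jj] <- sc$H[ii, jj] + od_h * w
  if (od_d > 0) sc$D[ii, jj] <- sc$D[ii, jj] + od_d * w
  if (membrane_od > 0) {  # ring just outside the nucleus (membrane chromogen)
    ring <- clamp(1 - abs(q - 1.35) / 0.35, 0, 1)
    sc$D[ii, jj] <- sc$D[ii, jj] + membrane_od * ring
  }
  invisible(NULL)
}

# place nuclei on a jittered grid inside an outline; paints and records them
populate_nest <- function(sc, cx, cy, outline, rmax, class_label, stain,
                          positivity, spacing) {
  xs <- seq(cx - rmax, cx + rmax, by = spacing)
  ys <- seq(cy - rmax, cy + rmax, by = spacing)
  pts <- expand.grid(x = xs, y = ys)
  pts$x <- pts$x + runif(nrow(pts), -spacing / 3, spacing / 3)
  pts$y <- pts$y + runif(nrow(pts), -spacing / 3, spacing / 3)
  th <- atan2(pts$y - cy, pts$x - cx)
  d <- sqrt((pts$x - cx)^2 + (pts$y - cy)^2)
  keep <- d <= outline(th) - 3.5 &
    pts$x >= 2 & pts$x <= sc$size - 1 & pts$y >= 2 & pts$y <= sc$size - 1
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0) return(invisible(NULL))
  pos <- runif(nrow(pts)) < positivity
  for (i in seq_len(nrow(pts))) {
    a <- runif(1, 2.2, 3.2); b <- a * runif(1, 0.7, 0.95)
    phi <- runif(1, 0, pi)
    if (stain == "HER2") {
      paint_nucleus(sc, pts$x[i], pts$y[i], a, b, phi,
                    od_h = runif(1, 0.5, 0.7), od_d = 0,
                    membrane_od = if (pos[i]) runif(1, 0.55, 0.8) else 0)
    } else if (pos[i]) {
      paint_nucleus(sc, pts$x[i], pts$y[i], a, b, phi,
                    od_h = 0.12, od_d = runif(1, 0.7, 0.95))
    } else {
      paint_nucleus(sc, pts$x[i], pts$y[i], a, b, phi,
                    od_h = runif(1, 0.5, 0.7), od_d = 0)
    }
  }
  sc$nuclei <- rbind(sc$nuclei, data.frame(
    x = pts$x, y = pts$y,
    class = if (class_label == 1L) "tumor_dcis" else "tumor_ic",
    marker_positive = pos, stringsAsFactors = FALSE
  ))
  invisible(NULL)
}

# one epithelial nest: label pixels, rim for DCIS, cytoplasm wash, nuclei
scene_add_nest <- function(sc, class_label, radius, stain, positivity) {
  margin <- if (class_label == 1L) 4 else 2
  ctr <- scene_find_center(sc, radius, margin = margin)
  if (is.null(ctr)) return(FALSE)
  cx <- ctr[1]; cy <- ctr[2]
  outline <- if (class_label == 1L) {
    new_outline(radius, amp = 0.06, harmonics = 3)    # rounded DCIS nest
  } else {
    new_outline(radius, amp = 0.22, harmonics = 8)    # jagged IC nest
  }
  rmax <- radius * 1.6
  i0 <- max(1, floor(cy - rmax)); i1 <- min(sc$size, ceiling(cy + rmax))
  j0 <- max(1, floor(cx - rmax)); j1 <- min(sc$size, ceiling(cx + rmax))
  ii <- i0:i1; jj <- j0:j1
  DX <- matrix(jj - cx, length(ii), length(jj), byrow = TRUE)
  DY <- matrix(ii - cy, length(ii), length(jj))
  TH <- atan2(DY, DX)
  DIST <- sqrt(DX^2 + DY^2)
  RR <- matrix(outline(as.vector(TH)), length(ii), length(jj))
  inside <- DIST <= RR
  n_new <- sum(inside & sc$mask[ii, jj] == 0L)
  m <- sc$mask[ii, jj]
  m[inside & m == 0L] <- class_label
  sc$mask[ii, jj] <- m
  # faint epithelial cytoplasm wash so nests are visible between nuclei
  sc$H[ii, jj] <- sc$H[ii, jj] + 0.10 * inside
  if (class_label == 1L) {  # continuous dark myoepithelial-like rim, ~2 px
    rim <- inside & (DIST >= RR - 2)
    sc$H[ii, jj] <- sc$H[ii, jj] + 0.55 * rim
  }
  sc$occ <- rbind(sc$occ, data.frame(cx = cx, cy = cy, r = radius))
  sc$placements <- rbind(sc$placements, data.frame(
    nest = nrow(sc$placements) + 1L, class = class_label,
    cx = cx, cy = cy, n_pixels = n_new
  ))
  populate_nest(sc, cx, cy, outline, rmax, class_label, stain, positivity,
                spacing = if (class_label == 1L) 7 else 6.2)
  TRUE
}

scene_add_lobule <- function(sc) {
  r_cluster <- runif(1, 18, 28)
  ctr <- scene_find_center(sc, r_cluster)
  if (is.null(ctr)) return(FALSE)
  n_acini <- sample(4:7, 1)
  for (k in seq_len(n_acini)) {
    ang <- runif(1, 0, 2 * pi)
    rad <- runif(1, 0, r_cluster - 8)
    ax <- ctr[1] + rad * cos(ang); ay <- ctr[2] + rad * sin(ang)
    r_ac <- runif(1, 5, 8)
    n_n <- max(6L, round(2 * pi * r_ac / 5))
    for (t in seq_len(n_n)) {  # ring of normal epithelial nuclei round a lumen
      a2 <- 2 * pi * t / n_n + runif(1, -0.2, 0.2)
      nx <- ax + (r_ac - 2) * cos(a2); ny <- ay + (r_ac - 2) * sin(a2)
      if (nx < 2 || ny < 2 || nx > sc$size - 1 || ny > sc$size - 1) next
      paint_nucleus(sc, nx, ny, 2.2, 1.7, a2, od_h = runif(1, 0.45, 0.6),
                    od_d = 0)
      sc$nuclei <- rbind(sc$nuclei, data.frame(
        x = nx, y = ny, class = "normal_epithelial",
        marker_positive = FALSE, stringsAsFactors = FALSE
      ))
    }
  }
  sc$occ <- rbind(sc$occ, data.frame(cx = ctr[1], cy = ctr[2], r = r_cluster))
  TRUE
}

scene_add_lymphocytes <- function(sc) {
  r_cluster <- runif(1, 14, 26)
  ctr <- scene_find_center(sc, r_cluster)
  if (is.null(ctr)) return(FALSE)
  outline <- new_outline(r_cluster, amp = 0.15, harmonics = 4)
  xs <- seq(ctr[1] - r_cluster, ctr[1] + r_cluster, by = 4)
  ys <- seq(ctr[2] - r_cluster, ctr[2] + r_cluster, by = 4)
  pts <- expand.grid(x = xs, y = ys)
  pts$x <- pts$x + runif(nrow(pts), -1.4, 1.4)
  pts$y <- pts$y + runif(nrow(pts), -1.4, 1.4)
  th <- atan2(pts$y - ctr[2], pts$x - ctr[1])
  d <- sqrt((pts$x - ctr[1])^2 + (pts$y - ctr[2])^2)
  keep <- d <= outline(th) - 2 &
    pts$x >= 2 & pts$x <= sc$size - 1 & pts$y >= 2 & pts$y <= sc$size - 1
  pts <- pts[keep, , drop = FALSE]
  for (i in seq_len(nrow(pts)))  # small, dense, very dark; marker-negative
    paint_nucleus(sc, pts$x[i], pts$y[i], runif(1, 1.6, 2.1), runif(1, 1.5, 1.9),
                  runif(1, 0, pi), od_h = runif(1, 0.8, 1.0), od_d = 0)
  if (nrow(pts) > 0)
    sc$nuclei <- rbind(sc$nuclei, data.frame(
      x = pts$x, y = pts$y, class = "lymphocyte",
      marker_positive = FALSE, stringsAsFactors = FALSE
    ))
  sc$occ <- rbind(sc$occ, data.frame(cx = ctr[1], cy = ctr[2], r = r_cluster))
  TRUE
}

scene_render <- function(sc) {
  od_to_rgb(sc$H, sc$D, sc$R)
}

# ---- public operations ------------------------------------------------------

#' Generate one labeled synthetic IHC tile
#'
#' Deterministic for a fixed spec (including seed). DCIS nests are large and
#' rounded with a continuous dark rim emulating the myoepithelial boundary;
#' invasive nests are small with jagged perimeters, so the discriminative cue
#' between the two classes lives in boundary morphology, as it does in tissue.
#' Confounders (normal lobules, lymphocyte aggregates) are rendered but carry
#' the background label.
#'
#' @param spec a [tile_spec()]
#' @param boundary_width half-width (in the dilation sense of
#'   [derive_boundary_gt()]) of the boundary ground truth band
#' @return object of class `labeled_tile`: list with `image` (H x W x 3,
#'   0..255), `mask` (integer matrix, 0 = background, 1 = DCIS, 2 = IC),
#'   `boundary` (binary matrix), `stain`, `scenario`, `placements` (the
#'   generator's placement log), `nuclei` (nucleus ledger) and `spec`.
#' @export
generate_tile <- function(spec, boundary_width = 2L) {
  stopifnot(inherits(spec, "tile_spec"))
  # placement is rejection-sampled; retry whole scenes deterministically when
  # a required nest cannot be placed (tight geometry on small tiles)
  last_err <- NULL
  for (attempt in 0:7) {
    seed_a <- if (attempt == 0) spec$seed else
      derive_seed(spec$seed, "retry", attempt)
    out <- tryCatch(generate_tile_once(spec, seed_a, boundary_width),
                    error = function(e) {
                      if (!grepl("failed to place", conditionMessage(e)))
                        stop(e)
                      last_err <<- e
                      NULL
                    })
    if (!is.null(out)) return(out)
  }
  stop(last_err)
}

generate_tile_once <- function(spec, seed, boundary_width) {
  with_seed(seed, {
    sc <- scene_new(spec$size_px)
    scene_background(sc)
    scale2 <- (spec$size_px / 256)^2
    n_dcis <- 0L; n_ic <- 0L
    if (spec$scenario == "dcis") n_dcis <- max(1L, round(runif(1, 1, 2.4) * scale2))
    if (spec$scenario == "invasive") n_ic <- max(1L, round(runif(1, 4, 9) * scale2))
    if (spec$scenario == "mixed") {
      n_dcis <- max(1L, round(runif(1, 1, 2) * scale2))
      n_ic <- max(1L, round(runif(1, 3, 6) * scale2))
    }
    placed_dcis <- 0L
    for (k in seq_len(n_dcis)) {
      r <- runif(1, spec$dcis_radius_range[1], spec$dcis_radius_range[2])
      if (scene_add_nest(sc, 1L, r, spec$stain, spec$positivity))
        placed_dcis <- placed_dcis + 1L
    }
    placed_ic <- 0L
    for (k in seq_len(n_ic)) {
      r <- runif(1, spec$nest_size_range[1], spec$nest_size_range[2])
      if (scene_add_nest(sc, 2L, r, spec$stain, spec$positivity))
        placed_ic <- placed_ic + 1L
    }
    if (spec$scenario %in% c("dcis", "mixed") && placed_dcis == 0L)
      stop("failed to place a required DCIS nest")
    if (spec$scenario %in% c("invasive", "mixed") && placed_ic == 0L)
      stop("failed to place a required IC nest")
    if (spec$scenario == "normal" || "lobule" %in% spec$confounders)
      scene_add_lobule(sc)
    if ("lymphocytes" %in% spec$confounders)
      for (k in seq_len(sample(1:2, 1))) scene_add_lymphocytes(sc)
    structure(list(
      image = scene_render(sc),
      mask = sc$mask,
      boundary = derive_boundary_gt(sc$mask, boundary_width),
      stain = spec$stain, scenario = spec$scenario,
      placements = sc$placements, nuclei = sc$nuclei, spec = spec
    ), class = "labeled_tile")
  })
}

#' Boundary ground truth from a class-index mask
#'
#' A pixel is a class-transition pixel when its 4-neighborhood contains a
#' different class. The returned band contains all pixels within Chebyshev
#' distance `width_px - 1` of a transition pixel, so `width_px = 1` marks the
#' transition pixels themselves (a 2-pixel band across any straight
#' interface, one pixel on either side) and increasing `width_px` dilates the
#' band monotonically.
#'
#' @param mask integer matrix with values in {0, 1, 2}
#' @param width_px band half-width, >= 1
#' @return binary (0/1) integer matrix of the same dimensions
#' @export
derive_boundary_gt <- function(mask, width_px = 2L) {
  stopifnot(is.matrix(mask), width_px >= 1)
  if (!all(mask %in% 0:2)) stop("mask values must be in {0,1,2}")
  h <- nrow(mask); w <- ncol(mask)
  trans <- matrix(FALSE, h, w)
  trans[-h, ] <- trans[-h, ] | (mask[-h, ] != mask[-1, ])
  trans[-1, ] <- trans[-1, ] | (mask[-1, ] != mask[-h, ])
  trans[, -w] <- trans[, -w] | (mask[, -w] != mask[, -1])
  trans[, -1] <- trans[, -1] | (mask[, -1] != mask[, -w])
  if (width_px > 1L) {
    dil <- max_filter_cpp(trans * 1.0, as.integer(width_px - 1L))
    trans <- dil > 0.5
  }
  matrix(as.integer(trans), h, w)
}

#' Generate a pseudo whole-slide image with an exact nucleus ledger
#'
#' A desk-scale stand-in for a scanned slide: a large synthetic IHC field
#' containing several DCIS and invasive regions, lymphocyte aggregates and a
#' normal lobule, with every rendered nucleus recorded (position, class,
#' marker positivity). DCIS and IC positivity can differ, which is what makes
#' mask-conditioned Ki-67 scoring non-trivial on these images.
#'
#' @param side_px canvas side; must be at least `2 * context_side`
#' @param context_side the multi-scale context window the image is meant to be
#'   inferred with (validation only)
#' @param stain stain style (default Ki67)
#' @param positivity_ic,positivity_dcis marker-positive fractions of IC / DCIS
#'   tumor nuclei
#' @param n_dcis,n_ic,n_lymph region counts (defaults scale with area)
#' @param seed integer seed
#' @return object of class `pseudo_wsi`: list with `image`, `mask`,
#'   `boundary`, `nuclei` (ledger data.frame: x, y, class, marker_positive),
#'   `truth` (list with `index_ic`, `index_tumor`, `index_image`, in %),
#'   `placements`, and the generation parameters.
#' @export
generate_pseudo_wsi <- function(side_px = 1024L, context_side = 512L,
                                stain = "Ki67",
                                positivity_ic = 0.35, positivity_dcis = 0.7,
                                n_dcis = NULL, n_ic = NULL, n_lymph = NULL,
                                seed = 1L) {
  side_px <- as.integer(side_px)
  if (side_px < 2L * context_side)
    stop("pseudo-WSI side must be >= 2x the context window side")
  if (side_px %% 8L != 0L) stop("side_px must be divisible by 8")
  scale2 <- (side_px / 1024)^2
  with_seed(seed, {
    # realistic slide composition: DCIS a minority of the tumor nuclei
    # (well above 10% of tumor area, as in mixed-type cases), many small IC
    # nests, and abundant marker-negative non-tumor tissue (lymphocyte
    # aggregates, lobules) so unmasked counting is dominated by it
    if (is.null(n_dcis)) n_dcis <- max(1L, round(sample(2:3, 1) * scale2))
    if (is.null(n_ic)) n_ic <- max(4L, round(sample(14:22, 1) * scale2))
    if (is.null(n_lymph)) n_lymph <- max(2L, round(sample(5:8, 1) * scale2))
    sc <- scene_new(side_px)
    scene_background(sc)
    for (k in seq_len(n_dcis))
      scene_add_nest(sc, 1L, runif(1, 30, 45), stain, positivity_dcis)
    for (k in seq_len(n_ic))
      scene_add_nest(sc, 2L, runif(1, 12, 26), stain, positivity_ic)
    for (k in seq_len(n_lymph)) scene_add_lymphocytes(sc)
    scene_add_lobule(sc)
    scene_add_lobule(sc)
    nuc <- sc$nuclei
    n_pos_ic <- sum(nuc$class == "tumor_ic" & nuc$marker_positive)
    n_ic_tot <- sum(nuc$class == "tumor_ic")
    n_pos_tum <- sum(nuc$marker_positive &
                       nuc$class %in% c("tumor_ic", "tumor_dcis"))
    n_tum <- sum(nuc$class %in% c("tumor_ic", "tumor_dcis"))
    truth <- list(
      index_ic = 100 * n_pos_ic / n_ic_tot,
      index_tumor = 100 * n_pos_tum / n_tum,
      index_image = 100 * n_pos_tum / nrow(nuc)
    )
    structure(list(
      image = scene_render(sc), mask = sc$mask,
      boundary = derive_boundary_gt(sc$mask, 2L),
      nuclei = nuc, truth = truth, placements = sc$placements,
      stain = stain, positivity_ic = positivity_ic,
      positivity_dcis = positivity_dcis, seed = seed
    ), class = "pseudo_wsi")
  })
}

#' Generate a labeled synthetic training set
#'
#' Convenience wrapper drawing scenarios, stains and confounders for `n`
#' tiles. Tiles are grouped into pseudo-cases (`cases_per_n` tiles per case
#' id) so cross-validation splits can respect case boundaries.
#'
#' @param n number of tiles
#' @param seed base seed; tile i uses a sub-seed derived from it
#' @param size_px tile side
#' @param scenarios scenario pool to draw from
#' @param stains stain pool to draw from
#' @param positivity_range tumor positivity drawn uniformly from this interval
#' @param confounder_prob probability that each confounder type is present
#' @param tiles_per_case tiles sharing one synthetic case id
#' @return list of `labeled_tile`s; each carries `case_id` and `tumor_type`
#' @export
synth_dataset <- function(n, seed = 1L, size_px = 256L,
                          scenarios = c("dcis", "invasive", "mixed"),
                          stains = c("ER", "PR", "HER2", "Ki67"),
                          positivity_range = c(0.1, 0.8),
                          confounder_prob = 0.3,
                          tiles_per_case = 4L) {
  sc <- size_px / 256
  dcis_range <- pmax(c(32, 56) * sc, c(12, 20))
  ic_range <- pmax(c(9, 20) * sc, c(5, 10))
  lapply(seq_len(n), function(i) {
    si <- derive_seed(seed, "synth_dataset", i)
    with_seed(si, {
      scn <- sample(scenarios, 1)
      stn <- sample(stains, 1)
      pos <- runif(1, positivity_range[1], positivity_range[2])
      conf <- c("lobule", "lymphocytes")[runif(2) < confounder_prob]
    })
    tl <- generate_tile(tile_spec(
      size_px = size_px, stain = stn, positivity = pos, scenario = scn,
      nest_size_range = ic_range, dcis_radius_range = dcis_range,
      confounders = conf, seed = derive_seed(seed, "tile", i)
    ))
    tl$case_id <- sprintf("case%03d", (i - 1L) %/% tiles_per_case + 1L)
    tl$tumor_type <- switch(scn, dcis = "DCIS", invasive = "IC",
                            mixed = "mixed", normal = "normal")
    tl
  })
}
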
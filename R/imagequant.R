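#' Read a multi-page grayscale TIFF as an image stack
#'
#' Slices are returned as numeric matrices in native integer units
#' (arbitrary units, AU), indexed `[row, column]` with the origin at the
#' top-left. Multi-channel pages are reduced to their first channel with a
#' warning.
#'
#' @param path Path to a TIFF file.
#' @return A list of numeric matrices (one per page), class `image_stack`.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  slices <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) {
      warn("multi-channel TIFF page: using the first channel")
      p <- p[, , 1]
    }
    p
  })
  dims <- vapply(slices, dim, integer(2))
  if (ncol(dims) > 1 && any(dims != dims[, 1])) abort("all slices must share dimensions")
  structure(slices, class = "image_stack")
}

#' Write an image stack to a 16-bit grayscale TIFF
#'
#' Inverse of [read_image_stack()] for intensities in \[0, 65535\].
#'
#' @param stack List of numeric matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  vals <- unlist(lapply(stack, range))
  if (any(vals < 0) || any(vals > 65535)) abort("intensities must lie in [0, 65535] for 16-bit TIFF")
  tiff::writeTIFF(lapply(stack, function(m) round(m) / 65535), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Maximum-intensity projection of confocal slices
#'
#' Elementwise maximum over the selected slices. The quantification
#' protocol projects 2 slices of similar focal planes; acquisitions use
#' 2-4, so ranges outside 2-4 slices are allowed but warned about.
#'
#' @param stack A list of numeric matrices (e.g. from
#'   [read_image_stack()]).
#' @param slice_range Indices of the slices to project; defaults to all.
#' @return A numeric matrix.
#' @export
max_project <- function(stack, slice_range = seq_along(stack)) {
  if (length(slice_range) == 0) abort("empty slice range")
  if (any(slice_range < 1 | slice_range > length(stack))) {
    abort("slice range outside the stack")
  }
  if (length(slice_range) < 2 || length(slice_range) > 4) {
    warn(paste0("projecting ", length(slice_range),
                " slice(s); the acquisition protocol uses 2-4"))
  }
  Reduce(pmax, stack[slice_range])
}

#' Polyline probe along a membrane segment
#'
#' Coordinates are in pixels with the origin at the top-left corner, x
#' rightward (columns) and y downward (rows); pixel centers sit at integer
#' coordinates starting from 0.
#'
#' @param x,y Numeric vectors of vertex coordinates (>= 2 vertices).
#' @param width Sampling width in pixels, perpendicular to the path
#'   (default 1 = a single line).
#' @return A `line_probe` object with the vertex table, `length` (path
#'   length in pixels) and `width`.
#' @export
line_probe <- function(x, y, width = 1) {
  stopifnot(length(x) == length(y), length(x) >= 2, width >= 1)
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(seg == 0)) abort("zero-length probe segment")
  structure(
    list(vertices = tibble::tibble(x = x, y = y), length = sum(seg), width = width),
    class = "line_probe"
  )
}

#' Polygonal region probe (e.g. the cytoplasm of a nurse cell)
#'
#' @param x,y Polygon vertex coordinates (pixel units, >= 3 vertices); the
#'   polygon is closed implicitly.
#' @return A `region_probe` object.
#' @export
region_probe <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  structure(list(vertices = tibble::tibble(x = x, y = y)), class = "region_probe")
}

#' Read a line probe from JSON or CSV
#'
#' JSON files hold a list of `{x, y}` vertices (optionally under a
#' `vertices` field, with optional `width`); CSV files hold `x,y` columns.
#'
#' @param path File path ending in `.json` or `.csv`.
#' @param width Probe width when the file does not specify one.
#' @return A `line_probe`.
#' @export
read_line_probe <- function(path, width = 1) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    if (is.data.frame(obj)) {
      v <- obj
    } else {
      v <- obj$vertices
      width <- obj$width %||% width
    }
    line_probe(v$x, v$y, width = width)
  } else {
    v <- readr::read_csv(path, col_types = "dd", progress = FALSE)
    line_probe(v$x, v$y, width = width)
  }
}

# Bilinear interpolation at pixel coordinates (x right, y down, origin 0).
bilinear <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  if (any(x < 0 | x > nc - 1 | y < 0 | y > nr - 1)) {
    bad <- which(x < 0 | x > nc - 1 | y < 0 | y > nr - 1)[1]
    abort(paste0("sample point outside image bounds at (x = ", format(x[bad]),
                 ", y = ", format(y[bad]), ")"))
  }
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- image[cbind(y0 + 1, x0 + 1)]
  i01 <- image[cbind(y0 + 1, x0 + 2)]
  i10 <- image[cbind(y0 + 2, x0 + 1)]
  i11 <- image[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Sample points along a polyline at spacing <= `spacing` px, with
# perpendicular offsets covering the probe width at unit spacing.
probe_samples <- function(probe, spacing = 0.5) {
  v <- probe$vertices
  pts <- list()
  for (i in seq_len(nrow(v) - 1)) {
    dx <- v$x[i + 1] - v$x[i]; dy <- v$y[i + 1] - v$y[i]
    len <- sqrt(dx^2 + dy^2)
    n <- max(2L, ceiling(len / spacing) + 1L)
    tt <- seq(0, 1, length.out = n)
    if (i > 1) tt <- tt[-1] # avoid duplicating shared vertices
    ux <- -dy / len; uy <- dx / len # unit normal
    offs <- if (probe$width > 1) {
      seq(-(probe$width - 1) / 2, (probe$width - 1) / 2, by = 1)
    } else 0
    for (o in offs) {
      pts[[length(pts) + 1L]] <- cbind(
        x = v$x[i] + tt * dx + o * ux,
        y = v$y[i] + tt * dy + o * uy
      )
    }
  }
  do.call(rbind, pts)
}

#' Mean intensity along a line probe
#'
#' Samples the image by bilinear interpolation at sub-pixel spacing (<= 0.5
#' px) along the probe path, averaging across the probe width, and returns
#' the mean intensity in AU — the line-profile measurement used for
#' membrane fluorescence.
#'
#' @param image Numeric matrix.
#' @param probe A [line_probe()].
#' @param spacing Sampling spacing along the path in pixels (<= 0.5).
#' @return Mean intensity (numeric scalar, AU).
#' @export
probe_mean <- function(image, probe, spacing = 0.5) {
  stopifnot(inherits(probe, "line_probe"), spacing > 0, spacing <= 0.5)
  pts <- probe_samples(probe, spacing)
  mean(bilinear(image, pts[, "x"], pts[, "y"]))
}

# Even-odd point-in-polygon test, vectorized over points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xin <- px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & xin)
    j <- i
  }
  inside
}

region_mask <- function(image, region) {
  nr <- nrow(image); nc <- ncol(image)
  grid <- expand.grid(x = 0:(nc - 1), y = 0:(nr - 1))
  inside <- points_in_polygon(grid$x, grid$y, region$vertices$x, region$vertices$y)
  matrix(inside, nrow = nr, ncol = nc, byrow = TRUE)
}

#' Mean intensity over a polygonal region
#'
#' @param image Numeric matrix.
#' @param region A [region_probe()].
#' @return Mean intensity over the pixels whose centers fall inside the
#'   polygon (numeric scalar, AU).
#' @export
region_mean <- function(image, region) {
  stopifnot(inherits(region, "region_probe"))
  mask <- region_mask(image, region)
  if (!any(mask)) abort("region contains no pixel centers")
  mean(image[mask])
}

#' Background-corrected membrane intensity
#'
#' The membrane readout of the fluorescence assay: mean intensity along the
#' membrane probe minus the mean intensity of the same cell's cytoplasm
#' region, correcting for per-follicle variation in stain intensity. An
#' image-wide constant offset therefore cancels exactly. Negative corrected
#' values are retained and flagged, never clipped, so downstream t-tests
#' stay valid.
#'
#' @param image Numeric matrix (typically a [max_project()] output).
#' @param membrane A [line_probe()] along the nurse cell membrane.
#' @param cytoplasm A [region_probe()] inside the same cell, disjoint from
#'   the membrane probe's sampled band.
#' @return A one-row tibble: `membrane_mean`, `cytoplasm_mean`, `corrected`,
#'   `flagged_negative`.
#' @export
corrected_membrane_intensity <- function(image, membrane, cytoplasm) {
  pts <- probe_samples(membrane, 0.5)
  inside <- points_in_polygon(pts[, "x"], pts[, "y"],
                              cytoplasm$vertices$x, cytoplasm$vertices$y)
  if (any(inside)) {
    abort("membrane probe overlaps the cytoplasm region; probes must be disjoint")
  }
  m <- probe_mean(image, membrane)
  c <- region_mean(image, cytoplasm)
  tibble::tibble(
    membrane_mean = m, cytoplasm_mean = c, corrected = m - c,
    flagged_negative = (m - c) < 0
  )
}

#' Synthetic follicle image with known membrane and cytoplasm intensities
#'
#' Renders a polygonal "nurse cell" whose boundary carries a bright
#' membrane band over a dimmer interior, as in stained follicle imagery.
#' The band has a resolved flat core of half-width `core` pixels (a
#' finite-thickness membrane sampled above Nyquist) with Gaussian
#' shoulders: intensity is `cytoplasm + (membrane - cytoplasm) *
#' exp(-max(0, d - core)^2 / (2 * ridge_sigma^2))`, `d` being the distance
#' to the cell boundary. Because every pixel within the core reads exactly
#' `membrane`, a 1-px line probe along the boundary recovers the membrane
#' level without interpolation bias; a band rendered as a bare Gaussian
#' crest would instead read a few AU low, since bilinear interpolation
#' underestimates a concave profile. The profile is evaluated
#' analytically, so the generator knows its ground truth exactly: along
#' the returned membrane probe (the middle of one straight edge) the
#' noiseless intensity is `membrane` and inside the returned cytoplasm
#' region it is `cytoplasm`, up to far-edge shoulder tails well below the
#' 2 AU interpolation tolerance at the default geometry. Optional i.i.d.
#' Gaussian noise is added per slice.
#'
#' @param membrane Peak (crest) membrane intensity, AU >= 0.
#' @param cytoplasm Interior intensity, AU >= 0.
#' @param size Image side in pixels (square image).
#' @param ridge_sigma SD of the Gaussian shoulders flanking the core, px.
#' @param core Half-width of the flat membrane core, px (>= 1.5 keeps the
#'   1-px probe's bilinear support entirely inside the core).
#' @param noise_sd SD of additive Gaussian noise per slice (0 = noiseless).
#' @param n_slices Number of slices in the returned stack.
#' @param seed Seed controlling vertex jitter and noise.
#' @return A list: `stack` (list of matrices), `membrane_probe`,
#'   `cytoplasm_probe`, and `truth` (tibble with `membrane_mean`,
#'   `cytoplasm_mean`, `corrected`).
#' @export
synth_follicle_image <- function(membrane = 200, cytoplasm = 50, size = 96,
                                 ridge_sigma = 2, core = 1.6, noise_sd = 0,
                                 n_slices = 2, seed = 1) {
  stopifnot(membrane >= 0, cytoplasm >= 0, size >= 48, noise_sd >= 0,
            n_slices >= 1, core >= 0)
  withr::with_seed(seed, {
    cx <- (size - 1) / 2; cy <- (size - 1) / 2
    r <- size * 0.34
    ang <- seq(0, 2 * pi, length.out = 7)[-7] + pi / 12
    jitter <- runif(6, -0.03, 0.03) * size
    vx <- cx + (r + jitter) * cos(ang)
    vy <- cy + (r + jitter) * sin(ang)

    grid <- expand.grid(x = 0:(size - 1), y = 0:(size - 1))
    d2min <- rep(Inf, nrow(grid))
    nvert <- length(vx)
    for (i in seq_len(nvert)) {
      j <- if (i == nvert) 1L else i + 1L
      ex <- vx[j] - vx[i]; ey <- vy[j] - vy[i]
      len2 <- ex^2 + ey^2
      t <- pmin(pmax(((grid$x - vx[i]) * ex + (grid$y - vy[i]) * ey) / len2, 0), 1)
      d2 <- (grid$x - (vx[i] + t * ex))^2 + (grid$y - (vy[i] + t * ey))^2
      d2min <- pmin(d2min, d2)
    }
    shoulder <- pmax(sqrt(d2min) - core, 0)
    base <- cytoplasm + (membrane - cytoplasm) * exp(-shoulder^2 / (2 * ridge_sigma^2))
    base <- matrix(base, nrow = size, ncol = size, byrow = TRUE)

    stack <- lapply(seq_len(n_slices), function(s) {
      if (noise_sd > 0) base + matrix(rnorm(size^2, 0, noise_sd), size, size) else base
    })

    # membrane probe: middle 60% of the first edge
    ex <- vx[2] - vx[1]; ey <- vy[2] - vy[1]
    mem <- line_probe(
      x = c(vx[1] + 0.2 * ex, vx[1] + 0.8 * ex),
      y = c(vy[1] + 0.2 * ey, vy[1] + 0.8 * ey)
    )
    # cytoplasm region: small square about the centroid, far from all edges
    half <- r * 0.35
    cyt <- region_probe(
      x = c(cx - half, cx + half, cx + half, cx - half),
      y = c(cy - half, cy - half, cy + half, cy + half)
    )
    list(
      stack = stack,
      membrane_probe = mem,
      cytoplasm_probe = cyt,
      truth = tibble::tibble(
        membrane_mean = membrane, cytoplasm_mean = cytoplasm,
        corrected = membrane - cytoplasm
      )
    )
  })
}

#' Normalize western-blot densitometry to a loading control
#'
#' Completes per-lane densitometry records: each lane's band intensity is
#' divided by its loading-control band (`normalized = band / loading`), and
#' expressed relative to the mean normalized value of the designated
#' control lanes (`relative_to_control`), the form in which knockdown
#' levels are reported (e.g. "80% of wild-type controls").
#'
#' @param records Data frame with columns `lane`, `band_intensity`,
#'   `loading_intensity`.
#' @param control_lanes Character vector of lane labels forming the
#'   wild-type reference (>= 1 lane, present in `records`).
#' @return `records` as a tibble with added `normalized` and
#'   `relative_to_control` columns.
#' @export
densitometry_normalize <- function(records, control_lanes) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("lane", "band_intensity", "loading_intensity") %in% names(records)))
  if (length(control_lanes) < 1 || !all(control_lanes %in% records$lane)) {
    abort("control_lanes must name at least one lane present in the records")
  }
  zero <- which(records$loading_intensity <= 0)
  if (length(zero)) {
    abort(paste0("zero or negative loading intensity in lane(s): ",
                 paste(records$lane[zero], collapse = ", ")))
  }
  out <- dplyr::mutate(records, normalized = .data$band_intensity / .data$loading_intensity)
  ref <- mean(out$normalized[out$lane %in% control_lanes])
  dplyr::mutate(out, relative_to_control = .data$normalized / ref)
}
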
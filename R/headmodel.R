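#' Sensor montage on a spherical head
#'
#' Builds a deterministic quasi-uniform electrode layout on the upper
#' hemisphere of a sphere, standing in for a dense-array net. Channels are
#' placed on a golden-angle (Fibonacci) spiral so that any montage size is
#' available and repeated calls are bit-identical.
#'
#' @param n_channels number of electrodes, at least 8. Default 256, the
#'   dense-array net size the pipeline is designed around.
#' @param radius sphere radius in meters (default 0.09).
#' @return An object of class `sensor_array` with fields `labels`
#'   (e.g. "E001"), `positions` (n x 3 matrix, meters, head-centered, +z up,
#'   +y anterior), `radius` and `reference = "average"`.
#' @examples
#' sens <- make_standard_montage(32)
#' range(sqrt(rowSums(sens$positions^2)))  # all on the 9 cm sphere
#' @export
make_standard_montage <- function(n_channels = 256L, radius = 0.09) {
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 8L) {
    stop_invalid("n_channels must be an integer >= 8 (got %s)", n_channels)
  }
  if (!is.finite(radius) || radius <= 0) stop_invalid("radius must be positive")
  i <- seq_len(n_channels)
  # upper hemisphere: z uniform in (0, radius], golden-angle azimuth
  z <- radius * (i - 0.5) / n_channels
  rho <- sqrt(pmax(radius^2 - z^2, 0))
  golden <- pi * (3 - sqrt(5))
  phi <- golden * (i - 1)
  pos <- cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
  labels <- sprintf("E%03d", i)
  structure(
    list(labels = labels, positions = pos, radius = radius,
         reference = "average"),
    class = "sensor_array"
  )
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d channels on %.3g m sphere, %s reference\n",
              length(x$labels), x$radius, x$reference))
  invisible(x)
}

#' Volumetric source space on a cubic grid
#'
#' Cubic grid of candidate source locations clipped to a sphere. The grid is
#' centered on the origin with deterministic ordering (x varies slowest,
#' then y, then z).
#'
#' @param spacing grid step in meters; a step larger than the radius leaves
#'   the degenerate single-voxel grid at the origin.
#' @param radius source-sphere radius in meters (default 0.08). Voxels with
#'   `|p| <= radius` are kept; with the default sensor sphere of 0.09 m this
#'   leaves a 1 cm margin between sources and sensors.
#' @return An object of class `source_space` with fields `positions`
#'   (n x 3 matrix), `n_voxels` and `spacing`.
#' @examples
#' make_grid_source_space(0.07, 0.08)$n_voxels  # 7: origin +/- one step per axis
#' @export
make_grid_source_space <- function(spacing, radius = 0.08) {
  if (!is.finite(spacing) || !is.finite(radius) || spacing <= 0 || radius <= 0) {
    stop_invalid("spacing and radius must be positive finite numbers")
  }
  k <- floor(radius / spacing)
  ax <- spacing * seq(-k, k)
  g <- expand.grid(z = ax, y = ax, x = ax, KEEP.OUT.ATTRS = FALSE)
  pos <- cbind(x = g$x, y = g$y, z = g$z)          # x slowest, z fastest
  keep <- sqrt(rowSums(pos^2)) <= radius
  pos <- pos[keep, , drop = FALSE]
  rownames(pos) <- NULL
  structure(
    list(positions = pos, n_voxels = nrow(pos), spacing = spacing,
         radius = radius),
    class = "source_space"
  )
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d voxels, %.3g m grid in %.3g m sphere\n",
              x$n_voxels, x$spacing, x$radius))
  invisible(x)
}

#' Spherical-head lead field
#'
#' Quasi-static potential of a current dipole in an infinite homogeneous
#' medium, evaluated at the electrode positions and average-referenced.
#' For a dipole component \eqn{e} at voxel \eqn{r_0} and sensor \eqn{r} the
#' gain is \eqn{(1/4\pi\sigma)\, e\cdot(r - r_0)/|r - r_0|^3}. Gains are
#' expressed in microvolts per nanoampere-meter of dipole moment, so
#' forward-projected data are directly on the EEG amplitude scale.
#'
#' This analytic single-sphere model replaces the proprietary head model of
#' dense-array acquisition software: it is deterministic, dependency-free,
#' and sufficient for the exact zero-localization-error property of the
#' standardized inverse (see [localization_error_sweep()]).
#'
#' @param sensors a `sensor_array`.
#' @param sources a `source_space`; every voxel must lie strictly inside
#'   the sensor sphere.
#' @param conductivity tissue conductivity in S/m (default 0.33).
#' @return An object of class `leadfield`: `matrix` is the
#'   n_channels x (3 * n_voxels) gain with columns ordered voxel-major
#'   (x, y, z components per voxel), plus `sensors`, `sources`,
#'   `conductivity` and `units = "uV per nA*m"`.
#' @export
make_spherical_leadfield <- function(sensors, sources, conductivity = 0.33) {
  stopifnot(inherits(sensors, "sensor_array"), inherits(sources, "source_space"))
  if (!is.finite(conductivity) || conductivity <= 0) {
    stop_invalid("conductivity must be positive")
  }
  rs <- sqrt(rowSums(sources$positions^2))
  if (any(rs >= sensors$radius)) {
    stop_invalid("all source voxels must lie strictly inside the sensor sphere")
  }
  n_ch <- length(sensors$labels)
  n_vox <- sources$n_voxels
  K <- matrix(0, n_ch, 3L * n_vox)
  # 1e-3 = (1 nA*m -> A*m) * (V -> uV)
  scale <- 1e-3 / (4 * pi * conductivity)
  for (j in seq_len(n_vox)) {
    d <- sweep(sensors$positions, 2, sources$positions[j, ])   # r - r0
    r3 <- rowSums(d^2)^1.5
    K[, (3L * j - 2L):(3L * j)] <- scale * d / r3
  }
  # average reference: remove channel mean of every column
  K <- K - matrix(colMeans(K), n_ch, ncol(K), byrow = TRUE)
  if (any(!is.finite(K))) stop_invalid("lead field contains non-finite gains")
  structure(
    list(matrix = K, sensors = sensors, sources = sources,
         conductivity = conductivity, units = "uV per nA*m"),
    class = "leadfield"
  )
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d channels x %d voxels (%s), sigma = %.3g S/m\n",
              nrow(x$matrix), x$sources$n_voxels, x$units, x$conductivity))
  invisible(x)
}

# -- atlas ------------------------------------------------------------------

#' Label merge map used for reporting
#'
#' The somatosensory areas BA1, BA2 and BA3 of both hemispheres are reported
#' together as "S1"; every other label maps to itself. Applying the map
#' twice equals applying it once.
#'
#' @param labels character vector of region labels (e.g. "L1", "R41", "S1").
#' @return character vector of reported labels.
#' @examples
#' merge_labels(c("L1", "R3", "R46", "S1"))  # "S1" "S1" "R46" "S1"
#' @export
merge_labels <- function(labels) {
  s1 <- c("L1", "R1", "L2", "R2", "L3", "R3")
  ifelse(labels %in% s1, "S1", labels)
}

#' Assign region labels to a source space
#'
#' Deterministic partition of the voxels into labeled regions. The packaged
#' synthetic scheme divides each hemisphere (left/right by the sign of the
#' x-coordinate; x >= 0 is right) into angular sectors, each mapped to a
#' Brodmann-area number, and labels voxels within `deep_radius` of the head
#' center as hippocampus/amygdala (Hipp anterior, Amyg posterior). This
#' reproduces the reporting vocabulary of cytoarchitectonic atlases without
#' claiming anatomical accuracy; a real atlas can be supplied through
#' [read_atlas_csv()].
#'
#' @param sources a `source_space`.
#' @param scheme optional list: `ba_numbers` (integers drawn from 1..47
#'   assigned to sectors, recycled), `n_polar` and `n_azimuth` (sector
#'   counts, defaults 3 and 8), `deep_radius` (meters, default 0.02).
#' @return An object of class `ba_atlas`: `region_of_voxel` (character,
#'   one label per voxel), `regions` (sorted unique labels) and
#'   `merge_map` (function, [merge_labels()]).
#' @export
assign_regions <- function(sources, scheme = list()) {
  stopifnot(inherits(sources, "source_space"))
  ba_numbers <- scheme$ba_numbers %||%
    c(1L, 2L, 3L, 4L, 9L, 10L, 17L, 18L, 19L, 20L, 21L, 22L, 23L, 27L,
      28L, 36L, 37L, 39L, 41L, 42L, 44L, 45L, 46L, 47L)
  n_polar <- scheme$n_polar %||% 3L
  n_az <- scheme$n_azimuth %||% 8L
  deep_radius <- scheme$deep_radius %||% 0.02
  pos <- sources$positions
  r <- sqrt(rowSums(pos^2))
  hemi <- ifelse(pos[, 1] < 0, "L", "R")
  lab <- character(nrow(pos))

  deep <- r <= deep_radius
  lab[deep] <- paste0(hemi[deep], ifelse(pos[deep, 2] >= 0, "Hipp", "Amyg"))

  sh <- !deep
  if (any(sh)) {
    # polar band from z; azimuth from the midline (|x|) so the partition is
    # mirror-symmetric and every area number can occur in both hemispheres
    theta <- acos(pmin(pmax(pos[sh, 3] / r[sh], -1), 1))      # 0..pi
    phi <- atan2(pos[sh, 2], abs(pos[sh, 1])) %% (2 * pi)     # 0..2pi
    ib <- pmin(floor(theta / pi * n_polar), n_polar - 1)
    ia <- pmin(floor(phi / (2 * pi) * n_az), n_az - 1)
    sector <- ib * n_az + ia                                   # 0-based
    ba <- ba_numbers[(sector %% length(ba_numbers)) + 1L]
    lab[sh] <- paste0(hemi[sh], ba)
  }

  structure(
    list(region_of_voxel = lab,
         regions = sort(unique(lab)),
         merge_map = merge_labels),
    class = "ba_atlas"
  )
}

#' @export
print.ba_atlas <- function(x, ...) {
  cat(sprintf("<ba_atlas> %d voxels in %d regions (%d after S1 merge)\n",
              length(x$region_of_voxel), length(x$regions),
              length(unique(x$merge_map(x$regions)))))
  invisible(x)
}

# -- plain-text persistence -------------------------------------------------

#' Read and write montage and atlas tables
#'
#' Montage CSV has columns `label, x, y, z` (meters); atlas CSV has columns
#' `voxel_index` (0-based) and `region_label`.
#'
#' @param sensors,atlas objects to write.
#' @param path file path.
#' @param sources the `source_space` an atlas read from CSV refers to
#'   (used for validation only).
#' @return the object read, or the path invisibly for writers.
#' @name atlas_io
NULL

#' @rdname atlas_io
#' @export
write_montage_csv <- function(sensors, path) {
  stopifnot(inherits(sensors, "sensor_array"))
  df <- data.frame(label = sensors$labels,
                   x = sensors$positions[, 1],
                   y = sensors$positions[, 2],
                   z = sensors$positions[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname atlas_io
#' @export
read_montage_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop_invalid("montage CSV needs columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$label)) stop_invalid("montage labels must be unique")
  pos <- as.matrix(df[, c("x", "y", "z")])
  colnames(pos) <- c("x", "y", "z")
  structure(
    list(labels = as.character(df$label), positions = pos,
         radius = max(sqrt(rowSums(pos^2))), reference = "average"),
    class = "sensor_array"
  )
}

#' @rdname atlas_io
#' @export
write_atlas_csv <- function(atlas, path) {
  stopifnot(inherits(atlas, "ba_atlas"))
  df <- data.frame(voxel_index = seq_along(atlas$region_of_voxel) - 1L,
                   region_label = atlas$region_of_voxel)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname atlas_io
#' @export
read_atlas_csv <- function(path, sources = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("voxel_index", "region_label") %in% names(df))) {
    stop_invalid("atlas CSV needs columns voxel_index, region_label")
  }
  df <- df[order(df$voxel_index), ]
  if (!identical(as.integer(df$voxel_index), seq_len(nrow(df)) - 1L)) {
    stop_invalid("atlas voxel_index must cover 0..n-1 exactly once")
  }
  if (!is.null(sources) && nrow(df) != sources$n_voxels) {
    stop_invalid("atlas covers %d voxels but source space has %d",
                 nrow(df), sources$n_voxels)
  }
  lab <- as.character(df$region_label)
  structure(
    list(region_of_voxel = lab, regions = sort(unique(lab)),
         merge_map = merge_labels),
    class = "ba_atlas"
  )
}
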
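#' Default material table
#'
#' Vertical stiffness (slope of normal force against indentation depth,
#' N/mm) of the five silicone rubbers used for the phantom: Dragon Skin 10
#' (the soft matrix), Dragon Skin 20, Dragon Skin 30, PDMS Sylgard 184 and
#' Sorta Clear 40 (the stiffest inclusion material).
#'
#' @return a data.frame with columns `name` and `stiffness_k` (N/mm).
#' @export
#' @examples
#' default_materials()
default_materials <- function() {
  data.frame(
    name = c("DS10", "DS20", "DS30", "PDMS", "SC"),
    stiffness_k = c(2.14, 2.74, 2.88, 3.68, 3.69),
    stringsAsFactors = FALSE
  )
}

material_stiffness <- function(materials, name) {
  i <- match(name, materials$name)
  if (any(is.na(i))) abort("unknown material(s): %s",
                           paste(name[is.na(i)], collapse = ", "))
  materials$stiffness_k[i]
}

#' Default phantom configuration
#'
#' A 100 x 100 x 15 mm block of the softest rubber carrying 12 hemispherical
#' inclusions (3 replicas each of the four stiffer materials) of 5 mm radius,
#' placed uniformly at random with a 5 mm edge margin and a hard non-overlap
#' constraint.
#'
#' @param ... named overrides of the default fields.
#' @return a list with fields `size_xyz`, `matrix_material`, `materials`,
#'   `inclusion_materials`, `replicas`, `radius`, `margin`, `blend_width`,
#'   `max_attempts`.
#' @export
phantom_config <- function(...) {
  cfg <- list(
    size_xyz = c(100, 100, 15),      # mm
    matrix_material = "DS10",
    materials = default_materials(),
    inclusion_materials = c("DS20", "DS30", "PDMS", "SC"),
    replicas = 3L,
    radius = 5,                      # mm
    margin = 5,                      # mm clearance from block edges
    blend_width = 0,                 # mm; 0 = hard-edged stiffness disks
    max_attempts = 10000L
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) abort("unknown phantom config key(s): %s",
                             paste(unknown, collapse = ", "))
  modifyList(cfg, override)
}

#' Generate a virtual phantom
#'
#' Places the requested hemispherical inclusions uniformly at random on the
#' block surface by rejection sampling: a candidate centre is redrawn until it
#' respects the edge margin and does not overlap any already-placed inclusion
#' (centre distance greater than the sum of radii). The layout is a pure
#' function of `(config, seed)`.
#'
#' @param config a [phantom_config()] list.
#' @param seed integer seed for the placement stream.
#' @return an object of class `telepalp_phantom`: list with `size_xyz`,
#'   `matrix_material`, `matrix_k`, `blend_width` and a data.frame
#'   `inclusions` (`id`, `material`, `x`, `y`, `radius`, `stiffness_k`).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_config(), seed = 1)
#' nrow(ph$inclusions)  # 12
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  size <- config$size_xyz
  r <- config$radius
  check_scalar_num(r, "radius", 0, strict_lower = TRUE)
  margin <- config$margin
  lo <- r + margin
  hi_x <- size[1] - r - margin
  hi_y <- size[2] - r - margin
  mats <- rep(config$inclusion_materials, each = config$replicas)
  if (length(mats) && (hi_x <= lo || hi_y <= lo))
    abort("inclusions of radius %g with margin %g do not fit a %g x %g block",
          r, margin, size[1], size[2])

  set.seed(derive_seed(seed, "phantom-placement"))
  n <- length(mats)
  xs <- ys <- numeric(n)
  placed <- 0L
  for (i in seq_len(n)) {
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (attempts > config$max_attempts)
        abort("failed to place inclusion %d (%s) after %d attempts",
              i, mats[i], config$max_attempts)
      cx <- runif(1, lo, hi_x)
      cy <- runif(1, lo, hi_y)
      if (placed == 0L ||
          all((xs[seq_len(placed)] - cx)^2 + (ys[seq_len(placed)] - cy)^2 >
              (2 * r)^2)) break
    }
    placed <- i
    xs[i] <- cx
    ys[i] <- cy
  }

  inclusions <- data.frame(
    id = seq_len(n),
    material = mats,
    x = xs, y = ys,
    radius = rep(r, n),
    stiffness_k = material_stiffness(config$materials, mats),
    stringsAsFactors = FALSE
  )
  if (n == 0L) inclusions <- inclusions[0, ]

  structure(
    list(size_xyz = size,
         matrix_material = config$matrix_material,
         matrix_k = material_stiffness(config$materials,
                                       config$matrix_material),
         blend_width = config$blend_width,
         inclusions = inclusions),
    class = "telepalp_phantom"
  )
}

#' @export
print.telepalp_phantom <- function(x, ...) {
  cat(sprintf("<telepalp_phantom> %g x %g x %g mm, matrix %s (k = %.2f N/mm)\n",
              x$size_xyz[1], x$size_xyz[2], x$size_xyz[3],
              x$matrix_material, x$matrix_k))
  if (nrow(x$inclusions)) {
    tab <- table(x$inclusions$material)
    cat(sprintf("  %d inclusions (r = %g mm): %s\n", nrow(x$inclusions),
                x$inclusions$radius[1],
                paste(sprintf("%s x%d", names(tab), tab), collapse = ", ")))
  } else cat("  no inclusions\n")
  invisible(x)
}

#' Query the local vertical stiffness of a phantom
#'
#' Inside an inclusion footprint (horizontal distance to the centre at most
#' the radius) the inclusion material's stiffness is returned; at and beyond
#' `radius + blend_width` the matrix stiffness applies; within the blend band
#' the two are linearly interpolated. With the default `blend_width = 0` the
#' field is piecewise constant and the footprint boundary belongs to the
#' inclusion.
#'
#' @param phantom a `telepalp_phantom`.
#' @param point_xy numeric length-2 position (mm) or an n x 2 matrix.
#' @return stiffness in N/mm (vector of length n).
#' @export
local_stiffness <- function(phantom, point_xy) {
  pts <- if (is.matrix(point_xy)) point_xy else matrix(point_xy, ncol = 2)
  if (ncol(pts) != 2) abort("point_xy must have two columns (x, y)")
  out_of_block <- pts[, 1] < 0 | pts[, 1] > phantom$size_xyz[1] |
    pts[, 2] < 0 | pts[, 2] > phantom$size_xyz[2]
  if (any(out_of_block))
    abort("point (%g, %g) outside the block footprint",
          pts[which(out_of_block)[1], 1], pts[which(out_of_block)[1], 2])

  k <- rep(phantom$matrix_k, nrow(pts))
  inc <- phantom$inclusions
  if (!nrow(inc)) return(k)
  bw <- phantom$blend_width
  for (j in seq_len(nrow(pts))) {
    d <- sqrt((inc$x - pts[j, 1])^2 + (inc$y - pts[j, 2])^2)
    i <- which.min(d)
    if (d[i] <= inc$radius[i]) {
      k[j] <- inc$stiffness_k[i]
    } else if (bw > 0 && d[i] < inc$radius[i] + bw) {
      w <- (d[i] - inc$radius[i]) / bw
      k[j] <- (1 - w) * inc$stiffness_k[i] + w * phantom$matrix_k
    }
  }
  k
}

#' Linear contact force
#'
#' The polymers respond linearly over the applied force range, so the normal
#' force is simply `F = k * z` for stiffness `k` (N/mm) and indentation
#' depth `z` (mm).
#'
#' @param stiffness vertical stiffness, N/mm (vectorised).
#' @param indentation_depth depth into the surface, mm, non-negative.
#' @return force in N.
#' @export
contact_force <- function(stiffness, indentation_depth) {
  if (any(stiffness <= 0)) abort("stiffness must be positive")
  if (any(indentation_depth < 0)) abort("indentation depth must be >= 0")
  stiffness * indentation_depth
}

#' Simulate one indentation trial
#'
#' Reproduces the characterization protocol: the indenter advances into the
#' surface at constant speed and the trial stops at the first sample at which
#' the measured vertical force reaches `force_stop`. Optional additive
#' Gaussian noise models load-cell noise; measured forces are floored at 0 N.
#'
#' @param phantom a `telepalp_phantom`.
#' @param point_xy indentation site, mm.
#' @param force_stop stop threshold, N (default 0.5).
#' @param speed indentation speed, mm/s (default 0.125).
#' @param sample_rate sampling rate, Hz (default 100).
#' @param noise_sd force noise SD, N (default 0 = noiseless).
#' @param seed seed for the noise stream.
#' @return a `telepalp_indentation`: data.frame (`depth_mm`, `force_N`) with
#'   attribute `stiffness_true`.
#' @export
simulate_indentation <- function(phantom, point_xy, force_stop = 0.5,
                                 speed = 0.125, sample_rate = 100,
                                 noise_sd = 0, seed = 1L) {
  check_scalar_num(force_stop, "force_stop", 0, strict_lower = TRUE)
  check_scalar_num(speed, "speed", 0, strict_lower = TRUE)
  check_scalar_num(sample_rate, "sample_rate", 0, strict_lower = TRUE)
  k <- local_stiffness(phantom, point_xy)
  dz <- speed / sample_rate
  # enough steps to exceed the threshold even under -5 sd noise
  n_max <- ceiling((force_stop + 5 * noise_sd) / (k * dz)) + 2L
  depths <- dz * seq_len(n_max)
  forces <- contact_force(k, depths)
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, "indentation-noise"))
    forces <- pmax(0, forces + rnorm(n_max, sd = noise_sd))
  }
  stop_i <- which(forces >= force_stop)[1]
  if (is.na(stop_i)) stop_i <- n_max
  out <- data.frame(depth_mm = depths[seq_len(stop_i)],
                    force_N = forces[seq_len(stop_i)])
  structure(out, stiffness_true = k, class = c("telepalp_indentation",
                                               "data.frame"))
}

#' Estimate stiffness from indentation series
#'
#' Per series, the vertical stiffness estimate is the least-squares slope of
#' force against depth. Across series the pooled summary reports median,
#' interquartile range and full range, matching how repeated indentation
#' trials are summarised.
#'
#' @param series_set a single indentation series (data.frame with `depth_mm`,
#'   `force_N`) or a list of them.
#' @return a list: `per_series` slopes (N/mm), and `summary` with `median`,
#'   `iqr`, `range`, `n`.
#' @export
characterize_stiffness <- function(series_set) {
  if (is.data.frame(series_set)) series_set <- list(series_set)
  if (!length(series_set)) abort("need at least one indentation series")
  slopes <- vapply(series_set, function(s) {
    if (nrow(s) < 2) abort("each indentation series needs >= 2 points")
    if (is.unsorted(s$depth_mm, strictly = TRUE))
      abort("indentation depths must be strictly increasing")
    coef(lm(force_N ~ depth_mm, data = s))[["depth_mm"]]
  }, numeric(1))
  list(per_series = slopes,
       summary = list(median = median(slopes),
                      iqr = IQR(slopes),
                      range = range(slopes),
                      n = length(slopes)))
}

#' Write / read a phantom layout as JSON
#'
#' The layout file stores block size, matrix material and per-inclusion
#' records; a write/read round trip reproduces the phantom exactly.
#'
#' @param phantom a `telepalp_phantom`.
#' @param path file path.
#' @return `read_phantom` returns the `telepalp_phantom`;
#'   `write_phantom` returns `path` invisibly.
#' @export
write_phantom <- function(phantom, path) {
  obj <- list(
    size_xyz = phantom$size_xyz,
    matrix_material = phantom$matrix_material,
    matrix_k = phantom$matrix_k,
    blend_width = phantom$blend_width,
    inclusions = phantom$inclusions
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  inc <- as.data.frame(obj$inclusions, stringsAsFactors = FALSE)
  if (!nrow(inc))
    inc <- data.frame(id = integer(), material = character(), x = numeric(),
                      y = numeric(), radius = numeric(),
                      stiffness_k = numeric(), stringsAsFactors = FALSE)
  structure(
    list(size_xyz = as.numeric(obj$size_xyz),
         matrix_material = obj$matrix_material,
         matrix_k = obj$matrix_k,
         blend_width = obj$blend_width,
         inclusions = inc),
    class = "telepalp_phantom"
  )
}

#' Write / read an indentation series as CSV
#'
#' Two columns, `depth_mm` and `force_N`, with a one-line header.
#'
#' @param series an indentation series data.frame.
#' @param path file path.
#' @export
write_indentation <- function(series, path) {
  write.csv(as.data.frame(series)[c("depth_mm", "force_N")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_indentation
#' @export
read_indentation <- function(path) {
  read.csv(path)
}
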
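# Synthetic T1-like volume rendering. Morphology encodes effective age through
# two monotone features: a central ellipsoidal cavity (ventricle-like) whose
# radius grows linearly with effective age, and a cortical shell that thins
# with effective age. Both are measurable by brute-force voxel counting, and
# learnable by a small 3D CNN.

voxel_radius_grid <- function(dims) {
  cx <- lapply(dims, function(d) (seq_len(d) - (d + 1) / 2) / (d / 2))
  r2 <- outer(outer(cx[[1]]^2, cx[[2]]^2, "+"), cx[[3]]^2, "+")
  sqrt(r2)
}

.radius_cache <- new.env(parent = emptyenv())

radius_grid <- function(dims) {
  key <- paste(dims, collapse = "x")
  g <- .radius_cache[[key]]
  if (is.null(g)) {
    g <- voxel_radius_grid(dims)
    .radius_cache[[key]] <- g
  }
  g
}

# Age-dependent geometry, on a normalized age scale a = (age - 20) / 80.
cavity_radius <- function(age) 0.10 + 0.35 * pmin(pmax((age - 20) / 80, 0), 1.2)
shell_thickness <- function(age) 0.22 - 0.12 * pmin(pmax((age - 20) / 80, 0), 1.2)

render_volume_for_age <- function(age, dims) {
  r <- radius_grid(dims)
  vol <- array(0, dims)
  vol[r <= 0.92] <- 0.7
  th <- shell_thickness(age)
  vol[r <= 0.92 & r > 0.92 - th] <- 1.0
  vol[r <= cavity_radius(age)] <- 0.05
  vol
}

#' Render a synthetic scan volume
#'
#' Produces a 3D intensity grid for one subject visit. The morphology is a
#' deterministic function of the subject's effective age at `t` (see
#' [effective_age()]); when `noise = TRUE` the effective age is perturbed by
#' `params$noise_sd` years and voxel noise of SD `params$voxel_noise_sd` is
#' added, both drawn from a stream seeded by `seed`, so identical seeds give
#' identical voxels.
#'
#' @param subject A subject specification from [generate_cohort()].
#' @param t Visit time in years since baseline.
#' @param params A [generator_params()].
#' @param noise Add effective-age and voxel noise.
#' @param seed Seed for the noise stream (ignored when `noise = FALSE`).
#' @return A 3D array with attributes `subject_id`, `visit_time`,
#'   `effective_age`.
#' @export
render_volume <- function(subject, t, params = generator_params(),
                          noise = TRUE, seed = 1L) {
  dims <- params$volume_shape
  ea <- effective_age(subject, t, params)
  if (noise) {
    vol <- with_seed(seed, {
      ea <- ea + stats::rnorm(1, 0, params$noise_sd)
      v <- render_volume_for_age(ea, dims)
      v + array(stats::rnorm(length(v), 0, params$voxel_noise_sd), dims)
    })
  } else {
    vol <- render_volume_for_age(ea, dims)
  }
  structure(vol, subject_id = subject$subject_id, visit_time = t,
            effective_age = ea)
}

scan_seed <- function(params, index) {
  as.integer((as.numeric(params$seed) * 7919 + index * 104729) %% 2147483647)
}

#' Render volumes for a cohort
#'
#' Renders one volume per requested visit for every subject, flattening each
#' into a row of the returned matrix. Per-scan noise streams are derived
#' deterministically from `params$seed` and the scan index.
#'
#' @param cohort A [generate_cohort()] result.
#' @param params A [generator_params()].
#' @param visits Either "baseline" (first visit only) or "all".
#' @param noise Add generator noise (see [render_volume()]).
#' @return A list: `x` (matrix, one flattened volume per row), `meta` (data
#'   frame with scan_id, subject_id, visit_time, CA, group, sex), `dims`.
#' @export
cohort_volumes <- function(cohort, params = generator_params(),
                           visits = c("baseline", "all"), noise = TRUE) {
  visits <- match.arg(visits)
  dims <- params$volume_shape
  rows <- list(); meta <- list()
  idx <- 0L
  for (s in cohort$subjects) {
    vt <- if (visits == "baseline") s$visit_times[1] else s$visit_times
    for (j in seq_along(vt)) {
      idx <- idx + 1L
      vol <- render_volume(s, vt[j], params, noise = noise,
                           seed = scan_seed(params, idx))
      rows[[idx]] <- as.vector(vol)
      meta[[idx]] <- data.frame(
        scan_id = sprintf("%s_V%02d", s$subject_id, j),
        subject_id = s$subject_id, visit_time = vt[j],
        CA = s$CA0 + vt[j], group = s$true_group, sex = s$sex,
        stringsAsFactors = FALSE)
    }
  }
  if (idx == 0L) {
    return(list(x = matrix(numeric(0), 0, prod(dims)),
                meta = data.frame(), dims = dims))
  }
  list(x = do.call(rbind, rows), meta = do.call(rbind, meta), dims = dims)
}

#' Synthetic region atlas aligned to the generator's geometry
#'
#' Integer region labels on the volume grid: three radial zones (central,
#' deep, cortical) crossed with the eight octants, giving up to 24 named
#' regions; background is 0. Serves as the desk-scale stand-in for an
#' anatomical parcellation when summarizing saliency maps.
#'
#' @param dims Voxel grid dimensions.
#' @return A list of class `region_atlas`: `labels` (integer 3D array) and
#'   `regions` (data frame of id, name).
#' @export
synth_atlas <- function(dims) {
  r <- radius_grid(dims)
  zone <- array(0L, dims)
  zone[r <= 0.95] <- 3L
  zone[r <= 0.70] <- 2L
  zone[r <= 0.35] <- 1L
  cx <- lapply(dims, function(d) (seq_len(d) - (d + 1) / 2) / (d / 2))
  octant <- outer(outer((cx[[1]] > 0) * 1L, (cx[[2]] > 0) * 2L, "+"),
                  (cx[[3]] > 0) * 4L, "+") + 1L
  labels <- array(0L, dims)
  inside <- zone > 0L
  labels[inside] <- (zone[inside] - 1L) * 8L + octant[inside]
  zones <- c("central", "deep", "cortical")
  regions <- data.frame(
    id = 1:24,
    name = paste0(rep(zones, each = 8), ".oct", rep(1:8, times = 3)),
    stringsAsFactors = FALSE)
  regions <- regions[regions$id %in% unique(as.vector(labels)), ]
  structure(list(labels = labels, regions = regions), class = "region_atlas")
}
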
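## Synthetic image generators with planted ground truth.
##
## Scenes are rendered as unions of capsules/spheres (tubes, spine necks
## and heads, plaques) or additive Gaussian blobs (puncta), blurred with
## an anisotropic Gaussian PSF and degraded with shot + read noise.
## Every planted object is recorded in a ground-truth list so that each
## downstream measurement can be validated by round-trip recovery.

# Canonical geometry per morphological class. Values are conventional
# spine dimensions (um); jitter is kept small enough that no draw can
# cross a classification boundary, so the planted class always equals
# the class assigned by classify_spine().
spine_geometry_defaults <- function() {
  list(
    mushroom = list(head = 0.95, neck = 0.34, length = 2.0,
                    neck_visible = TRUE,  n_heads = 1L),
    thin     = list(head = 0.48, neck = 0.34, length = 1.8,
                    neck_visible = TRUE,  n_heads = 1L),
    stubby   = list(head = 0.55, neck = 0.65, length = 0.8,
                    neck_visible = FALSE, n_heads = 1L),
    branched = list(head = 0.62, neck = 0.36, length = 2.4,
                    neck_visible = TRUE,  n_heads = 2L))
}

sample_spine_geometry <- function(class, jitter = 0.06, min_neck_um = 0) {
  g <- spine_geometry_defaults()[[class]]
  j <- function(v) v * exp(rnorm(1L, 0, jitter))
  head_d <- j(g$head); neck_d <- j(g$neck); len <- j(g$length)
  # resolvability floor, then keep each draw inside its class region
  neck_d <- max(neck_d, min_neck_um)
  if (class == "mushroom") {
    head_d <- max(head_d, 2.4 * min_neck_um)
    neck_d <- min(neck_d, head_d / 2.4)
  }
  if (class == "thin") {
    head_d <- max(head_d, min_neck_um / 0.8)
    neck_d <- max(neck_d, head_d / 1.9)
    neck_d <- min(neck_d, head_d * 0.8)
  }
  if (class == "stubby") neck_d <- max(neck_d, head_d * 1.1)
  list(head_diameter_um = head_d, neck_diameter_um = neck_d,
       protrusion_length_um = max(len, if (class == "stubby") head_d * 1.05
                                       else head_d + 0.35),
       neck_visible = g$neck_visible, n_heads = g$n_heads)
}

# Capsule rows (p1, p2, radius, value) for one spine attached at `anchor`
# on the shaft, pointing along unit vector `u` (perpendicular to shaft).
spine_capsules <- function(anchor_pt, u, geom, shaft_radius, value) {
  L <- geom$protrusion_length_um
  tip <- anchor_pt + u * (shaft_radius + L)
  head_r <- geom$head_diameter_um / 2
  rows <- NULL
  if (geom$n_heads >= 2L) {
    neck_end <- anchor_pt + u * (shaft_radius + 0.4 * L)
    rows <- rbind(rows, c(anchor_pt, neck_end, geom$neck_diameter_um / 2, value))
    # split heads along the shaft axis (x): in-plane, so the lateral
    # PSF can resolve them (an axial split would be blurred together)
    v <- c(1, 0, 0)
    ang <- 47 * pi / 180
    for (s in c(-1, 1)) {
      dir <- u * cos(ang) + s * v * sin(ang)
      hc <- neck_end + dir * (L * 0.6 - head_r)
      rows <- rbind(rows, c(hc, hc, head_r, value),
                    c(neck_end, hc, geom$neck_diameter_um / 2, value))
    }
  } else if (!geom$neck_visible) {
    # stubby: wide-based bump, no constriction
    base <- anchor_pt + u * (shaft_radius * 0.3)
    hc <- anchor_pt + u * (shaft_radius + L - head_r)
    rows <- rbind(rows, c(base, hc, geom$neck_diameter_um / 2, value),
                  c(hc, hc, head_r, value))
  } else {
    hc <- tip - u * head_r
    rows <- rbind(rows, c(anchor_pt, hc - u * head_r * 0.6,
                          geom$neck_diameter_um / 2, value),
                  c(hc, hc, head_r, value))
  }
  rows
}

#' Generate a dendrite-shaft stack with planted spines
#'
#' Renders one shaft tube spanning the field with spines planted along it
#' as a homogeneous Poisson process per morphological class, then applies
#' PSF blur and noise. The returned ground truth lists every planted
#' spine's geometry and its class, which is the class [classify_spine()]
#' assigns to that geometry by construction.
#'
#' @param recipe a [stack_recipe()].
#' @param shaft_diameter_um true shaft diameter (um).
#' @param segment_length_um shaft length (um); must be at least 20 so the
#'   segment passes the inclusion filter used for analysis.
#' @param spine_spec named per-um Poisson rates for classes
#'   `mushroom`, `thin`, `stubby`, `branched` (missing classes = 0).
#' @param amplitude fill-channel intensity of the structure over background.
#' @return list with `stack` (an [image_stack()], channel `fill`) and
#'   `truth` (spines data.frame, `dendrite_path`, shaft diameter).
#' @export
make_dendrite_stack <- function(recipe, shaft_diameter_um = 1.2,
                                segment_length_um = 25,
                                spine_spec = c(mushroom = 0.22, thin = 0.17,
                                               stubby = 0.1, branched = 0.04),
                                amplitude = 200) {
  if (segment_length_um < 20)
    stop("segment_length_um must be >= 20 um (analysis inclusion filter)")
  if (segment_length_um > recipe$field_size_um[1L] - 2)
    stop("segment longer than the field")
  classes <- c("mushroom", "thin", "stubby", "branched")
  rates <- stats::setNames(rep(0, 4L), classes)
  rates[names(spine_spec)] <- spine_spec
  # resolvability: planted necks must span >= 2 lateral pixels
  min_neck <- min(vapply(spine_geometry_defaults(),
                         function(g) g$neck, 1))
  if (any(rates > 0) && min_neck < 2 * recipe$xy_pixel_um)
    stop("calibration error: requested spine geometry unresolvable at ",
         "xy_pixel_um = ", recipe$xy_pixel_um,
         " (neck diameter must be >= 2 lateral pixels)")

  fx <- recipe$field_size_um[1L]; fy <- recipe$field_size_um[2L]
  zc <- recipe$z_depth_um / 2
  x0 <- (fx - segment_length_um) / 2
  path <- cbind(x = c(x0, x0 + segment_length_um), y = fy / 2, z = zc)
  r_shaft <- shaft_diameter_um / 2

  # shorten the rendered capsule so the spherical caps end exactly at
  # the nominal segment extent
  p1 <- path[1L, ] + c(r_shaft, 0, 0)
  p2 <- path[2L, ] - c(r_shaft, 0, 0)
  caps <- rbind(c(p1, p2, r_shaft, amplitude))
  spines <- NULL
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    if (rates[cl] <= 0) next
    n <- with_seed(sub_seed(recipe$seed, 100L + ci),
                   rpois(1L, rates[cl] * segment_length_um))
    for (k in seq_len(n)) {
      draw <- with_seed(sub_seed(recipe$seed, 200L + ci, k), {
        a <- runif(1L, 1.5, segment_length_um - 1.5)
        side <- sample(c(-1, 1), 1L)
        tilt <- runif(1L, -pi / 9, pi / 9)
        geom <- sample_spine_geometry(cl,
                                      min_neck_um = 2 * recipe$xy_pixel_um)
        list(a = a, u = c(0, side * cos(tilt), sin(tilt)), geom = geom)
      })
      anchor_pt <- c(x0 + draw$a, fy / 2, zc)
      true_class <- classify_spine(draw$geom$head_diameter_um,
                                   draw$geom$neck_diameter_um,
                                   draw$geom$neck_visible,
                                   draw$geom$n_heads)
      stopifnot(true_class == cl)
      caps <- rbind(caps, spine_capsules(anchor_pt, draw$u, draw$geom,
                                         r_shaft, amplitude))
      spines <- rbind(spines, data.frame(
        anchor_um = draw$a,
        protrusion_length_um = draw$geom$protrusion_length_um,
        head_diameter_um = draw$geom$head_diameter_um,
        neck_diameter_um = draw$geom$neck_diameter_um,
        neck_visible = draw$geom$neck_visible,
        n_heads = draw$geom$n_heads,
        true_class = true_class,
        dir_y = draw$u[2L], dir_z = draw$u[3L],
        stringsAsFactors = FALSE))
    }
  }
  d <- recipe_dims(recipe); vs <- recipe_voxel_size(recipe)
  clean <- cpp_render_capsules(as.integer(d), vs, c(0, 0, 0), caps)
  fill <- finish_channel(recipe, array(clean, d))
  stack <- image_stack(list(fill = fill), vs, origin = c(0, 0, 0))
  truth <- list(spines = spines %||% data.frame(),
                dendrite_path = path,
                shaft_diameter_um = shaft_diameter_um,
                segment_length_um = segment_length_um)
  list(stack = stack, truth = truth)
}

#' Generate a plaque (ThioS-like) channel with planted blobs
#'
#' Plaques are quasi-spherical: a core sphere plus a few noise-perturbed
#' surface bumps so edges are irregular. Exact centres and radii are
#' recorded in the ground truth.
#'
#' @param recipe a [stack_recipe()].
#' @param plaque_centres n x 3 matrix of centres (um), or NULL for none.
#' @param plaque_radii radii (um), recycled to n.
#' @param amplitude intensity over background.
#' @return list(stack = 1-channel [image_stack()] `thios`, truth = list).
#' @export
make_plaque_field <- function(recipe, plaque_centres = NULL,
                              plaque_radii = numeric(), amplitude = 250) {
  d <- recipe_dims(recipe); vs <- recipe_voxel_size(recipe)
  extent <- c(recipe$field_size_um, recipe$z_depth_um)
  n <- if (is.null(plaque_centres)) 0L else nrow(plaque_centres)
  caps <- NULL
  if (n > 0L) {
    plaque_radii <- rep_len(plaque_radii, n)
    if (any(plaque_radii <= 0)) stop("plaque radii must be positive")
    for (i in seq_len(n)) {
      ce <- as.numeric(plaque_centres[i, ])
      r <- plaque_radii[i]
      if (any(ce + r < 0) || any(ce - r > extent))
        stop("plaque ", i, " lies fully outside the stack bounds")
      caps <- rbind(caps, c(ce, ce, r, amplitude))
      # surface bumps stay inside the nominal radius so the recorded
      # radius remains the true outer envelope
      bumps <- with_seed(sub_seed(recipe$seed, 300L, i), {
        nb <- 6L
        u <- matrix(rnorm(3L * nb), ncol = 3L)
        u <- u / sqrt(rowSums(u^2))
        list(u = u, br = runif(nb, 0.12, 0.2) * r)
      })
      for (b in seq_len(nrow(bumps$u))) {
        bc <- ce + bumps$u[b, ] * (r * 0.8)
        caps <- rbind(caps, c(bc, bc, bumps$br[b], amplitude))
      }
    }
  }
  clean <- if (is.null(caps)) array(0, d)
           else array(cpp_render_capsules(as.integer(d), vs, c(0, 0, 0), caps), d)
  thios <- finish_channel(recipe, clean, seed_offset = 3L)
  stack <- image_stack(list(thios = thios), vs, origin = c(0, 0, 0))
  truth <- list(plaque_centres = plaque_centres, plaque_radii = plaque_radii)
  list(stack = stack, truth = truth)
}

#' Generate a soma stack for intensity normalisation
#'
#' A quasi-spherical cell body of mean stain level `soma_mean` sits on a
#' flat background of `background_mean` in channel `stain`; channel
#' `fill` is a clean ROI marker of the soma.
#'
#' @param recipe a [stack_recipe()].
#' @param soma_mean mean stain intensity inside the soma (>= background).
#' @param background_mean mean background intensity (> 0).
#' @param soma_radius_um soma radius (um).
#' @return list(stack, truth) where truth records the planted levels and
#'   the expected normalised intensity `soma_mean / background_mean`.
#' @export
make_soma_stack <- function(recipe, soma_mean = 300, background_mean = 100,
                            soma_radius_um = 5) {
  if (!(soma_mean >= background_mean) || background_mean <= 0)
    stop("need soma_mean >= background_mean > 0")
  d <- recipe_dims(recipe); vs <- recipe_voxel_size(recipe)
  centre <- c(recipe$field_size_um / 2, recipe$z_depth_um / 2)
  rad <- min(soma_radius_um, recipe$z_depth_um / 2 - vs[3L])
  caps <- rbind(c(centre, centre, rad, soma_mean - background_mean))
  clean <- array(cpp_render_capsules(as.integer(d), vs, c(0, 0, 0), caps), d)
  stain <- finish_channel(recipe, clean, seed_offset = 5L,
                          background = background_mean)
  # ROI marks the deep interior, clear of edge blur in z
  roi <- array(cpp_render_capsules(as.integer(d), vs, c(0, 0, 0),
                                   rbind(c(centre, centre, rad * 0.55, 1))), d)
  stack <- image_stack(list(stain = stain, fill = roi), vs)
  truth <- list(soma_centre = centre, soma_radius_um = rad,
                soma_intensity = soma_mean,
                background_intensity = background_mean,
                expected_ratio = soma_mean / background_mean)
  list(stack = stack, truth = truth)
}

# Smooth planar curve across the field with an exact path/chord ratio.
# Lateral deviation is a two-harmonic sine whose amplitude is solved
# numerically for the requested tortuosity.
tortuous_path <- function(chord_um, tortuosity_target, phase = 0,
                          max_amplitude = Inf, n = 200L) {
  stopifnot(tortuosity_target >= 1)
  t <- seq(0, 1, length.out = n)
  shape <- sin(2 * pi * 3 * t + phase) + 0.5 * sin(2 * pi * 5 * t + 2 * phase)
  shape <- shape - (shape[1L] + t * (shape[n] - shape[1L]))   # pin endpoints
  shape <- shape / max(abs(shape))     # unit amplitude: |offset| <= A exactly
  ratio_for <- function(A) {
    p <- cbind(t * chord_um, A * shape)
    sum(sqrt(rowSums(diff(p)^2))) / chord_um
  }
  if (tortuosity_target <= 1 + 1e-9) {
    A <- 0
  } else {
    upper <- chord_um
    if (ratio_for(upper) < tortuosity_target)
      stop("unreachable tortuosity for this field size")
    A <- stats::uniroot(function(a) ratio_for(a) - tortuosity_target,
                        c(0, upper), tol = 1e-10)$root
  }
  if (A > max_amplitude) stop("unreachable tortuosity for this field size")
  cbind(x = t * chord_um, y = A * shape)
}

#' Generate an iPSC-like 3-channel field (MAP2 / Homer / Kv3.4)
#'
#' Curved neurite tubes are drawn in the MAP2 channel with an exactly
#' controlled path/chord tortuosity; Homer puncta are planted along each
#' path at `puncta_rates["homer"]` per um; a binomial fraction
#' `coloc_fraction` of the Kv3.4 puncta is placed coincident with Homer
#' puncta and the remainder off-synapse, away from every Homer punctum.
#'
#' @param recipe a [stack_recipe()].
#' @param n_neurites number of neurite paths.
#' @param tortuosity_target target path/chord ratio (>= 1) per neurite.
#' @param puncta_rates named rates per um: `homer`, `kv34`.
#' @param coloc_fraction fraction of Kv3.4 puncta on Homer synapses, between 0 and 1.
#' @param neurite_diameter_um MAP2 tube diameter.
#' @param kv_dendrite_amplitude optional diffuse Kv3.4 level along the
#'   neurite tube (for dendritic-intensity round-trips).
#' @param amplitude structure intensity over background (MAP2 tube).
#' @param punctum_amplitude peak intensity of a planted punctum.
#' @return list(stack = channels map2/homer/kv34, truth = paths, puncta,
#'   per-neurite true tortuosity, planted colocalisation counts).
#' @export
make_ipsc_field <- function(recipe, n_neurites = 3,
                            tortuosity_target = 1.2,
                            puncta_rates = c(homer = 0.4, kv34 = 0.4),
                            coloc_fraction = 0.6,
                            neurite_diameter_um = 1.4,
                            kv_dendrite_amplitude = 0,
                            amplitude = 200,
                            punctum_amplitude = 1000) {
  if (tortuosity_target < 1) stop("tortuosity_target must be >= 1")
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stop("coloc_fraction must be in [0, 1]")
  d <- recipe_dims(recipe); vs <- recipe_voxel_size(recipe)
  fx <- recipe$field_size_um[1L]; fy <- recipe$field_size_um[2L]
  zc <- recipe$z_depth_um / 2
  chord <- fx - 4
  lane <- fy / (n_neurites + 1)

  paths <- list(); tort <- numeric(n_neurites)
  caps <- NULL
  for (i in seq_len(n_neurites)) {
    # some phases need a larger amplitude than the lane allows; retry
    # with fresh phases before declaring the target unreachable
    pc <- NULL
    for (try_i in seq_len(20L)) {
      phase <- with_seed(sub_seed(recipe$seed, 400L + try_i, i),
                         runif(1L, 0, 2 * pi))
      pc <- tryCatch(tortuous_path(chord, tortuosity_target, phase = phase,
                                   max_amplitude = lane * 0.45),
                     error = function(e) NULL)
      if (!is.null(pc)) break
    }
    if (is.null(pc)) stop("unreachable tortuosity for this field size")
    path <- cbind(x = 2 + pc[, 1L], y = lane * i + pc[, 2L], z = zc)
    paths[[i]] <- path
    tort[i] <- polyline_length(path) /
      sqrt(sum((path[nrow(path), ] - path[1L, ])^2))
    for (j in seq_len(nrow(path) - 1L))
      caps <- rbind(caps, c(path[j, ], path[j + 1L, ],
                            neurite_diameter_um / 2, amplitude))
  }
  map2_clean <- array(cpp_render_capsules(as.integer(d), vs, c(0, 0, 0), caps), d)

  # Homer puncta along each path
  homer <- NULL
  for (i in seq_len(n_neurites)) {
    path <- paths[[i]]
    len <- polyline_length(path)
    pos <- with_seed(sub_seed(recipe$seed, 500L, i), {
      n <- rpois(1L, (puncta_rates["homer"] %||% 0) * len)
      p <- sort(runif(n, 0, len))
      # hard-core thinning: sub-resolution pairs are one synapse
      keep <- !logical(length(p))
      if (length(p) > 1L) for (k in 2:length(p)) {
        prev <- max(p[seq_len(k - 1L)][keep[seq_len(k - 1L)]], -Inf)
        if (p[k] - prev < 0.8) keep[k] <- FALSE
      }
      p[keep]
    })
    if (length(pos)) homer <- rbind(homer, points_at_arclength(path, pos))
  }
  n_homer <- if (is.null(homer)) 0L else nrow(homer)

  # Kv3.4 puncta: binomial split between synaptic (on Homer) and off-synapse
  total_len <- sum(vapply(paths, polyline_length, 1))
  kv <- NULL; n_coloc_planted <- 0L
  kvdraw <- with_seed(sub_seed(recipe$seed, 600L), {
    n_kv <- rpois(1L, (puncta_rates["kv34"] %||% 0) * total_len)
    n_on <- if (n_kv > 0L && n_homer > 0L)
      rbinom(1L, n_kv, coloc_fraction) else 0L
    if (n_on > n_homer) {          # one Kv cluster per synapse at most
      n_kv <- n_kv - (n_on - n_homer)
      n_on <- n_homer
    }
    on_idx <- if (n_on > 0L) sample.int(n_homer, n_on) else integer()
    off <- matrix(numeric(), ncol = 3L)
    n_off <- n_kv - n_on
    if (n_off > 0L) {
      acc <- NULL; tries <- 0L
      while ((is.null(acc) || nrow(acc) < n_off) && tries < 2000L) {
        cand <- c(runif(1L, 1, fx - 1), runif(1L, 1, fy - 1), zc)
        ok <- (n_homer == 0L ||
          min(sqrt(rowSums(sweep(homer, 2L, cand)^2))) > 1.2) &&
          (is.null(acc) ||
             min(sqrt(rowSums(sweep(acc, 2L, cand)^2))) > 0.8)
        if (ok) acc <- rbind(acc, cand)
        tries <- tries + 1L
      }
      off <- acc
    }
    list(on_idx = on_idx, off = off)
  })
  if (length(kvdraw$on_idx)) {
    kv <- homer[kvdraw$on_idx, , drop = FALSE]
    n_coloc_planted <- length(kvdraw$on_idx)
  }
  if (!is.null(kvdraw$off) && nrow(kvdraw$off)) kv <- rbind(kv, kvdraw$off)
  n_kv <- if (is.null(kv)) 0L else nrow(kv)

  blob_sigma <- c(0.15, 0.15, 0.25)
  homer_clean <- if (n_homer) array(cpp_render_blobs(
    as.integer(d), vs, c(0, 0, 0), homer, blob_sigma,
    rep(punctum_amplitude, n_homer)), d) else array(0, d)
  kv_clean <- if (n_kv) array(cpp_render_blobs(
    as.integer(d), vs, c(0, 0, 0), kv, blob_sigma,
    rep(punctum_amplitude, n_kv)), d) else array(0, d)
  if (kv_dendrite_amplitude > 0)
    kv_clean <- kv_clean + map2_clean / amplitude * kv_dendrite_amplitude

  stack <- image_stack(list(
    map2  = finish_channel(recipe, map2_clean, seed_offset = 7L),
    homer = finish_channel(recipe, homer_clean, seed_offset = 8L),
    kv34  = finish_channel(recipe, kv_clean, seed_offset = 9L)), vs)
  truth <- list(paths = paths, true_tortuosity = tort,
                homer_centres = homer, kv_centres = kv,
                n_kv = n_kv, n_coloc_planted = n_coloc_planted,
                coloc_fraction_planted = if (n_kv > 0) n_coloc_planted / n_kv
                                         else NA_real_,
                kv_dendrite_amplitude = kv_dendrite_amplitude)
  list(stack = stack, truth = truth)
}

# Physical points at given arc-length positions along a polyline
# (vectorised over s).
points_at_arclength <- function(path, s) {
  cum <- cumulative_arclength(path)
  j <- findInterval(s, cum, all.inside = TRUE)
  f <- (s - cum[j]) / pmax(cum[j + 1L] - cum[j], 1e-12)
  path[j, , drop = FALSE] + f * (path[j + 1L, , drop = FALSE] -
                                 path[j, , drop = FALSE])
}
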
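#' Recipe for a synthetic confocal stack
#'
#' Captures the acquisition geometry and noise model used by all image
#' generators. The default field emulates a 63x confocal acquisition:
#' 61.5 um x 61.5 um laterally with a 0.3 um z-step. Desk-scale work
#' normally shrinks `field_size_um` / `z_depth_um` rather than the
#' sampling, so planted structures stay resolvable.
#'
#' @param field_size_um lateral (x, y) extent in um.
#' @param z_depth_um axial extent in um.
#' @param z_step_um axial sampling in um.
#' @param xy_pixel_um lateral sampling in um.
#' @param psf_sigma_um Gaussian PSF sigmas (lateral, axial) in um.
#' @param noise list with `photon_scale` (photons per intensity unit;
#'   0 disables shot noise) and `read_sd` (additive Gaussian sd).
#' @param background_level mean background intensity.
#' @param seed integer seed; recipe + seed fully determine every
#'   generated voxel.
#' @return a `stack_recipe`.
#' @export
stack_recipe <- function(field_size_um = c(61.5, 61.5),
                         z_depth_um = 12,
                         z_step_um = 0.3,
                         xy_pixel_um = 0.24,
                         psf_sigma_um = c(0.2, 0.6),
                         noise = list(photon_scale = 1, read_sd = 2),
                         background_level = 20,
                         seed = 1L) {
  field_size_um <- rep_len(as.numeric(field_size_um), 2L)
  for (v in list(field_size_um, z_depth_um, z_step_um, xy_pixel_um,
                 background_level))
    if (any(!is.finite(v)) || any(v <= 0))
      stop("all physical recipe sizes must be strictly positive")
  psf_sigma_um <- rep_len(as.numeric(psf_sigma_um), 2L)
  if (any(psf_sigma_um < 0)) stop("psf_sigma_um must be non-negative")
  noise <- utils::modifyList(list(photon_scale = 1, read_sd = 2), noise)
  structure(
    list(field_size_um = field_size_um, z_depth_um = z_depth_um,
         z_step_um = z_step_um, xy_pixel_um = xy_pixel_um,
         psf_sigma_um = psf_sigma_um, noise = noise,
         background_level = background_level, seed = as.integer(seed)),
    class = "stack_recipe")
}

#' @export
print.stack_recipe <- function(x, ...) {
  cat("stack_recipe:",
      paste(signif(c(x$field_size_um, x$z_depth_um), 4), collapse = " x "),
      "um; xy", x$xy_pixel_um, "um; z-step", x$z_step_um, "um; seed",
      x$seed, "\n")
  invisible(x)
}

recipe_dims <- function(recipe) {
  c(max(2L, round(recipe$field_size_um[1L] / recipe$xy_pixel_um)),
    max(2L, round(recipe$field_size_um[2L] / recipe$xy_pixel_um)),
    max(2L, round(recipe$z_depth_um / recipe$z_step_um)))
}

recipe_voxel_size <- function(recipe) {
  c(recipe$xy_pixel_um, recipe$xy_pixel_um, recipe$z_step_um)
}

# Apply PSF blur, add background and apply the recipe's noise model.
# `clean` is the noiseless structure image (0 where empty).
finish_channel <- function(recipe, clean, seed_offset = 0L,
                           background = recipe$background_level,
                           blur = TRUE, noisy = TRUE) {
  d <- recipe_dims(recipe)
  vs <- recipe_voxel_size(recipe)
  img <- clean
  if (blur && any(recipe$psf_sigma_um > 0)) {
    sig_vox <- c(recipe$psf_sigma_um[1L] / vs[1L],
                 recipe$psf_sigma_um[1L] / vs[2L],
                 recipe$psf_sigma_um[2L] / vs[3L])
    img <- cpp_gauss3d(as.numeric(img), as.integer(d), sig_vox)
  }
  img <- img + background
  if (noisy) {
    img <- with_seed(sub_seed(recipe$seed, 17L, seed_offset), {
      ps <- recipe$noise$photon_scale
      out <- if (!is.null(ps) && ps > 0) rpois(length(img), pmax(img, 0) * ps) / ps
             else img
      rs <- recipe$noise$read_sd
      if (!is.null(rs) && rs > 0) out <- out + rnorm(length(out), 0, rs)
      out
    })
  }
  array(pmax(img, 0), dim = d)
}
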
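## Neurite segmentation, skeletonisation and segment morphometry.

# Otsu's between-class-variance threshold on a numeric sample.
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) > 2e5) x <- x[seq(1L, length(x), length.out = 2e5)]
  rng <- range(x)
  if (diff(rng) <= 0) return(rng[1L])
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1L]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  mids <- rng[1L] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Segment tube-like neurites from a fill or MAP2 channel
#'
#' Smooths at the shaft scale, then applies a hysteresis threshold: a
#' strong (Otsu) level seeds objects, which grow into all connected
#' voxels above a weak level placed a fixed fraction of the way from
#' background to the robust foreground peak (half-peak by default, so
#' the mask approximates the half-maximum surface of bright tubes).
#' All levels are derived from the stack itself, so the mask is
#' invariant to a global intensity gain. Components below a volume
#' floor are discarded. When nothing rises above the background noise,
#' an empty mask is returned with a warning.
#'
#' @param stack an [image_stack()].
#' @param channel channel to segment.
#' @param smooth_sigma_um pre-smoothing Gaussian sigma (um).
#' @param weak_factor weak threshold position between background and the
#'   foreground peak (0.5 = half-maximum).
#' @param min_volume_um3 minimum object volume.
#' @return logical 3-D array (the mask).
#' @export
segment_neurites <- function(stack, channel, smooth_sigma_um = 0.2,
                             weak_factor = 0.5, min_volume_um3 = 0.5) {
  img <- get_channel(stack, channel)
  d <- dim(img); vs <- stack$voxel_size_um
  sm <- array(cpp_gauss3d(as.numeric(img), as.integer(d),
                          smooth_sigma_um / vs), d)
  bg <- stats::median(sm)
  noise_mad <- stats::mad(sm[sm <= stats::quantile(sm, 0.8)], center = bg)
  strong <- otsu_threshold(sm)
  if (strong <= bg + 5 * noise_mad) {
    warning("no foreground above background noise; returning empty mask")
    return(array(FALSE, d))
  }
  fg_peak <- stats::quantile(sm[sm >= strong], 0.95, names = FALSE)
  weak <- bg + weak_factor * (fg_peak - bg)
  weak <- min(weak, strong)   # never above the seed level
  mask_weak <- sm >= weak
  lab <- array(cpp_label3d(as.logical(mask_weak), as.integer(d)), d)
  seeded <- unique(lab[sm >= strong & mask_weak])
  seeded <- seeded[seeded > 0L]
  keep <- array(lab %in% seeded, d)
  # volume floor
  vol_vox <- prod(vs)
  tab <- tabulate(lab[keep])
  small <- which(tab > 0 & tab * vol_vox < min_volume_um3)
  if (length(small)) keep[lab %in% small] <- FALSE
  keep
}

# Moving-average smoothing of a voxel-chain path; endpoints pinned,
# window shrinks near the ends.
smooth_path <- function(coords, w = 5L) {
  n <- nrow(coords)
  if (n <= 2L || w < 2L) return(coords)
  out <- coords
  half <- w %/% 2L
  for (i in 2:(n - 1L)) {
    k <- min(half, i - 1L, n - i)
    out[i, ] <- colMeans(coords[(i - k):(i + k), , drop = FALSE])
  }
  out
}

backtrace_path <- function(pred, from0) {
  path <- integer(0)
  v <- from0
  while (v >= 0L) {
    path <- c(path, v)
    v <- pred[v + 1L]
  }
  rev(path)   # seed first
}

#' Skeletonise a neurite mask into a medial-path graph
#'
#' Traces medial paths by iterative farthest-point geodesic tracing:
#' the two geodesically farthest voxels of each component are joined by
#' a centredness-weighted shortest path (weights derived from the
#' Euclidean distance transform keep the route on the medial axis);
#' remaining side branches longer than `min_branch_um` are traced onto
#' the growing skeleton in turn. Edge lengths are physical
#' (anisotropy-corrected) polyline lengths of smoothed voxel chains.
#'
#' @param mask logical 3-D array from [segment_neurites()].
#' @param voxel_size_um voxel pitch (x, y, z) in um.
#' @param min_branch_um shortest side branch traced as skeleton (keeps
#'   spine-scale protrusions out of the backbone).
#' @param min_component_um3 components smaller than this are skipped.
#' @return a `skeleton_graph`: list with `nodes` (data.frame id, x, y, z,
#'   degree), `edges` (list of from/to/path/length_um), `voxel_size_um`.
#' @export
skeletonize <- function(mask, voxel_size_um, min_branch_um = 5,
                        min_component_um3 = 2) {
  d <- dim(mask); vs <- as.numeric(voxel_size_um)
  empty <- list(nodes = data.frame(id = integer(), x = numeric(),
                                   y = numeric(), z = numeric(),
                                   degree = integer()),
                edges = list(), voxel_size_um = vs)
  class(empty) <- "skeleton_graph"
  if (!any(mask)) return(empty)
  lab <- array(cpp_label3d(as.logical(mask), as.integer(d)), d)
  edt <- cpp_edt3d(as.logical(mask), as.integer(d), vs)
  wt <- 1 / (edt + 0.25 * min(vs))^2
  vol_vox <- prod(vs)

  adj <- list()   # skeleton voxel adjacency: names = 0-based index
  add_edge <- function(a, b) {
    ka <- as.character(a); kb <- as.character(b)
    adj[[ka]] <<- unique(c(adj[[ka]], b))
    adj[[kb]] <<- unique(c(adj[[kb]], a))
  }
  comp_ids <- which(tabulate(lab[lab > 0L]) * vol_vox >= min_component_um3)
  for (ci in comp_ids) {
    cmask <- lab == ci
    in_comp0 <- which(cmask) - 1L
    seed <- in_comp0[which.max(edt[cmask])]
    g0 <- cpp_geodesic(as.logical(cmask), as.integer(d), vs, seed, numeric())
    dd <- g0$dist[in_comp0 + 1L]
    A <- in_comp0[which.max(ifelse(is.finite(dd), dd, -1))]
    g1 <- cpp_geodesic(as.logical(cmask), as.integer(d), vs, A, numeric())
    dd <- g1$dist[in_comp0 + 1L]
    B <- in_comp0[which.max(ifelse(is.finite(dd), dd, -1))]
    g2 <- cpp_geodesic(as.logical(cmask), as.integer(d), vs, A, wt)
    trunk <- backtrace_path(g2$pred, B)
    if (length(trunk) < 2L) next
    for (j in seq_len(length(trunk) - 1L)) add_edge(trunk[j], trunk[j + 1L])
    skel <- trunk
    # side branches
    for (iter in seq_len(12L)) {
      gS <- cpp_geodesic(as.logical(cmask), as.integer(d), vs, skel, numeric())
      dd <- gS$dist[in_comp0 + 1L]
      far_i <- which.max(ifelse(is.finite(dd), dd, -1))
      reach <- dd[far_i]
      tip <- in_comp0[far_i]
      if (!is.finite(reach) || reach - edt[tip + 1L] < min_branch_um) break
      gW <- cpp_geodesic(as.logical(cmask), as.integer(d), vs, skel, wt)
      br <- backtrace_path(gW$pred, tip)
      if (length(br) < 2L) break
      for (j in seq_len(length(br) - 1L)) add_edge(br[j], br[j + 1L])
      skel <- unique(c(skel, br))
    }
  }
  if (!length(adj)) return(empty)

  vox0 <- as.integer(names(adj))
  deg <- vapply(adj, length, 1L)
  coords <- function(v0) {
    ijk <- arrayInd(v0 + 1L, d)
    sweep(ijk - 0.5, 2L, vs, "*")
  }
  is_node <- deg != 2L
  node_vox <- vox0[is_node]
  # walk maximal chains between nodes
  edges <- list()
  visited <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  for (nv in node_vox) {
    for (nb in adj[[as.character(nv)]]) {
      if (!is.null(visited[[ekey(nv, nb)]])) next
      chain <- c(nv, nb)
      visited[[ekey(nv, nb)]] <- TRUE
      prev <- nv; cur <- nb
      while (!(cur %in% node_vox)) {
        nxt <- setdiff(adj[[as.character(cur)]], prev)
        if (!length(nxt)) break
        nxt <- nxt[1L]
        visited[[ekey(cur, nxt)]] <- TRUE
        chain <- c(chain, nxt)
        prev <- cur; cur <- nxt
      }
      # trim free tips while they run through sub-radius structure
      # (end-cap corners, or a protrusion the farthest-point search
      # wandered into); keeps the backbone on the shaft proper
      ev <- edt[chain + 1L]
      med_e <- stats::median(ev)
      co <- coords(chain)
      steps <- c(0, sqrt(rowSums(diff(co)^2)))
      trim_from <- 1L; trim_to <- length(chain)
      if (!(chain[1L] %in% node_vox && deg[match(chain[1L], vox0)] > 1L)) {
        cum_f <- cumsum(steps)
        ok <- which(ev >= 0.75 * med_e | cum_f > 3)
        if (length(ok)) trim_from <- ok[1L]
      }
      if (!(chain[length(chain)] %in% node_vox &&
            deg[match(chain[length(chain)], vox0)] > 1L)) {
        cum_b <- rev(cumsum(rev(c(steps[-1L], 0))))
        ok <- which(ev >= 0.75 * med_e | cum_b > 3)
        if (length(ok)) trim_to <- ok[length(ok)]
      }
      if (trim_to - trim_from < 2L) { trim_from <- 1L; trim_to <- length(chain) }
      chain_t <- chain[trim_from:trim_to]
      pth <- smooth_path(coords(chain_t))
      edges[[length(edges) + 1L]] <-
        list(from = chain_t[1L], to = chain_t[length(chain_t)], path = pth,
             length_um = polyline_length(pth))
    }
  }
  nd <- coords(node_vox)
  nodes <- data.frame(id = node_vox, x = nd[, 1L], y = nd[, 2L],
                      z = nd[, 3L],
                      degree = deg[match(node_vox, vox0)])
  out <- list(nodes = nodes, edges = edges, voxel_size_um = vs)
  class(out) <- "skeleton_graph"
  out
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("skeleton_graph:", nrow(x$nodes), "node(s),", length(x$edges),
      "edge(s); total length",
      round(sum(vapply(x$edges, `[[`, 1, "length_um")), 2), "um\n")
  invisible(x)
}

#' A traced dendritic segment
#'
#' @param path n x 3 matrix of ordered physical points (um).
#' @param source image/channel identifier.
#' @param labels named list of condition labels (mouse, genotype,
#'   treatment, ...).
#' @return a `dendrite_segment` with `length_um` set to the polyline
#'   length of `path`.
#' @export
dendrite_segment <- function(path, source = NA_character_, labels = list()) {
  path <- as.matrix(path)
  stopifnot(ncol(path) == 3L, nrow(path) >= 2L)
  structure(list(path = path, length_um = polyline_length(path),
                 shaft_diameters_um = c(end1 = NA_real_, mid = NA_real_,
                                        end2 = NA_real_),
                 mean_diameter_um = NA_real_,
                 source = source, labels = labels),
            class = "dendrite_segment")
}

#' @export
print.dendrite_segment <- function(x, ...) {
  cat("dendrite_segment:", round(x$length_um, 2), "um,",
      nrow(x$path), "points; mean diameter",
      round(x$mean_diameter_um, 2), "um\n")
  invisible(x)
}

#' Extract analysable segments from a skeleton
#'
#' Branch-free paths between branch/end nodes, filtered to path length
#' strictly greater than `min_length_um` (20 um by default, the
#' inclusion filter applied before any spine counting). The filter acts
#' on skeleton path length, not on straight-line extent.
#'
#' @param skeleton a `skeleton_graph`.
#' @param min_length_um inclusion threshold (um); 0 keeps everything.
#' @param source,labels passed to [dendrite_segment()].
#' @return list of `dendrite_segment`.
#' @export
extract_segments <- function(skeleton, min_length_um = 20,
                             source = NA_character_, labels = list()) {
  segs <- list()
  for (e in skeleton$edges) {
    if (e$length_um > min_length_um)
      segs[[length(segs) + 1L]] <- dendrite_segment(e$path, source, labels)
  }
  segs
}

path_tangent <- function(path, i) {
  n <- nrow(path)
  j1 <- max(1L, i - 8L); j2 <- min(n, i + 8L)
  t <- path[j2, ] - path[j1, ]
  t / sqrt(sum(t^2))
}

# Width of the mask across the local path normal, measured in the
# station's z-slice as (in-slab area) / (slab thickness), with an
# optional PSF deconvolution in quadrature.
slab_width <- function(mask, vs, station, tangent, slab_um, max_r_um,
                       psf_fwhm_um) {
  d <- dim(mask)
  kz0 <- max(1L, min(d[3L], round(station[3L] / vs[3L] + 0.5)))
  ix <- pmax(1L, floor((station[1L] - max_r_um) / vs[1L])):
        pmin(d[1L], ceiling((station[1L] + max_r_um) / vs[1L]))
  iy <- pmax(1L, floor((station[2L] - max_r_um) / vs[2L])):
        pmin(d[2L], ceiling((station[2L] + max_r_um) / vs[2L]))
  txy <- tangent[1:2]
  nt <- sqrt(sum(txy^2))
  if (nt < 1e-6) return(0)
  txy <- txy / nt
  # the widest of the station slice and its z-neighbours (a slightly
  # off-centre medial path otherwise understates the true diameter)
  best <- 0
  for (kz in intersect(kz0 + (-3L:3L), seq_len(d[3L]))) {
    sub <- mask[ix, iy, kz, drop = FALSE]
    if (!any(sub)) next
    w <- which(sub, arr.ind = TRUE)
    cx <- (ix[w[, 1L]] - 0.5) * vs[1L] - station[1L]
    cy <- (iy[w[, 2L]] - 0.5) * vs[2L] - station[2L]
    along <- cx * txy[1L] + cy * txy[2L]
    across <- -cx * txy[2L] + cy * txy[1L]
    sel <- abs(along) <= slab_um / 2 & abs(across) <= max_r_um
    if (!any(sel)) next
    # normalise by the along-extent actually sampled (voxel columns can
    # straddle the slab boundary depending on the station's phase)
    n_cols <- length(unique(round(along[sel] / vs[1L])))
    best <- max(best, sum(sel) * vs[1L] * vs[2L] / (n_cols * vs[1L]))
  }
  if (best == 0) return(0)
  sqrt(max(best^2 - psf_fwhm_um^2, (0.5 * vs[1L])^2))
}

# Photometric width at one station: integrated flux in a short slab
# around the tangent line, divided by the fill amplitude, gives the true
# cross-section area regardless of blur or threshold. The median over
# three sub-stations resists a spine sitting on one of them.
flux_width <- function(sm, bg, amp, vs, path, cum, s, slab_um, max_r_um = 3) {
  d <- dim(sm)
  sub_w <- numeric(0)
  for (off in c(-0.7, 0, 0.7)) {
    so <- min(max(s + off, 0), cum[length(cum)])
    i <- which.min(abs(cum - so))
    p <- path[i, ]
    tg <- path_tangent(path, i)
    lo <- pmax(1L, floor((p - max_r_um) / vs))
    hi <- pmin(d, ceiling((p + max_r_um) / vs))
    gx <- (lo[1L]:hi[1L] - 0.5) * vs[1L]
    gy <- (lo[2L]:hi[2L] - 0.5) * vs[2L]
    gz <- (lo[3L]:hi[3L] - 0.5) * vs[3L]
    gg <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    rel <- sweep(gg, 2L, p)
    tt <- as.numeric(rel %*% tg)
    rho2 <- rowSums(rel^2) - tt^2
    sel <- abs(tt) <= slab_um / 2 & rho2 <= max_r_um^2
    if (!any(sel)) next
    w <- as.numeric(sm[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]])[sel] - bg
    n_cols <- length(unique(round(tt[sel] / vs[1L])))
    area <- sum(w) * prod(vs) / (amp * n_cols * vs[1L])
    sub_w <- c(sub_w, 2 * sqrt(max(area, 0) / pi))
  }
  if (!length(sub_w)) 0 else stats::median(sub_w)
}

#' Shaft diameter at the ends and midpoint of a segment
#'
#' Measures the shaft's full cross-width at three stations -- 2 um
#' inboard of each end (the width is ill-defined on an endpoint cap)
#' and the midpoint -- and returns the three values with their
#' arithmetic mean. When the originating stack is supplied the width is
#' measured photometrically: the integrated intensity of a short slab,
#' divided by the fill amplitude (estimated from the shaft's flux per
#' unit length and blurred peak), gives the true cross-section area
#' independent of PSF blur or threshold choice; the median over three
#' nearby sub-stations resists spines. Without the stack, the mask's
#' width across the local path normal is used, measured in the
#' station's own z-slice and corrected in quadrature for the effective
#' edge spread.
#'
#' @param segment a `dendrite_segment`.
#' @param mask the segmentation mask the segment was traced from.
#' @param voxel_size_um voxel pitch (um).
#' @param stack optional [image_stack()] for photometric widths.
#' @param channel intensity channel when `stack` is given.
#' @param slab_um slab thickness along the path used to average.
#' @param psf_fwhm_um effective edge spread subtracted in quadrature in
#'   mask mode (0 disables the correction).
#' @param psf_sigma_um PSF sigmas used for the amplitude model in
#'   photometric mode.
#' @param inboard_um end stations sit this far inside the endpoints.
#' @return the segment with `shaft_diameters_um` and `mean_diameter_um`
#'   filled in.
#' @export
shaft_diameter <- function(segment, mask, voxel_size_um, stack = NULL,
                           channel = 1L, slab_um = 0.6,
                           psf_fwhm_um = 0.9, psf_sigma_um = c(0.2, 0.6),
                           inboard_um = 2) {
  cum <- cumulative_arclength(segment$path)
  L <- segment$length_um
  stations_s <- c(min(inboard_um, L / 4), L / 2, L - min(inboard_um, L / 4))
  vals <- numeric(3L)
  photometric <- !is.null(stack)
  if (photometric) {
    vs <- stack$voxel_size_um
    d <- stack_dim(stack)
    img <- get_channel(stack, channel)
    sm <- array(cpp_gauss3d(as.numeric(img), as.integer(d), 0.15 / vs), d)
    bg <- stats::median(sm)
    pvx <- phys_to_voxel(stack, segment$path)
    pli <- linear_index(d, pvx)
    peak <- stats::median(sm[pli])
    gg_flux <- {
      lo <- pmax(1L, floor((apply(segment$path, 2L, min) - 2.3) / vs))
      hi <- pmin(d, ceiling((apply(segment$path, 2L, max) + 2.3) / vs))
      gg <- as.matrix(expand.grid(x = (lo[1L]:hi[1L] - 0.5) * vs[1L],
                                  y = (lo[2L]:hi[2L] - 0.5) * vs[2L],
                                  z = (lo[3L]:hi[3L] - 0.5) * vs[3L]))
      gd <- cpp_dist_points_to_polyline(gg, segment$path)
      gs <- cpp_project_onto_polyline(gg[gd <= 2.3, , drop = FALSE],
                                      segment$path)
      gw <- as.numeric(sm[lo[1L]:hi[1L], lo[2L]:hi[2L],
                          lo[3L]:hi[3L]])[gd <= 2.3] - bg
      slab <- floor(gs)
      slabs <- seq(2L, max(1L, floor(L) - 2L))
      stats::median(vapply(slabs, function(b)
        sum(gw[slab == b]) * prod(vs), 1))
    }
    psf_eff <- sqrt(psf_sigma_um^2 + 0.15^2)
    amp <- estimate_fill_amplitude(gg_flux, peak - bg, psf_eff)$amplitude
  }
  for (k in 1:3) {
    i <- which.min(abs(cum - stations_s[k]))
    p <- segment$path[i, ]
    ijk <- pmax(1L, pmin(dim(mask), round(p / voxel_size_um + 0.5)))
    if (!mask[ijk[1L], ijk[2L], ijk[3L]])
      stop("diameter station lies outside the mask; inconsistent inputs")
    vals[k] <- if (photometric)
      flux_width(sm, bg, amp, voxel_size_um, segment$path, cum,
                 stations_s[k], slab_um)
      else slab_width(mask, voxel_size_um, p,
                      path_tangent(segment$path, i), slab_um,
                      max_r_um = 4, psf_fwhm_um)
  }
  segment$shaft_diameters_um <- c(end1 = vals[1L], mid = vals[2L],
                                  end2 = vals[3L])
  segment$mean_diameter_um <- mean(vals)
  segment
}

#' Tortuosity of a segment
#'
#' Path length divided by the direct Euclidean distance between the
#' segment's endpoints; 1 for a straight segment, always >= 1 up to
#' numerical tolerance. Undefined (error) when the endpoints coincide.
#'
#' @param segment a `dendrite_segment`, or an n x 3 path matrix.
#' @return the tortuosity ratio.
#' @export
tortuosity <- function(segment) {
  path <- if (inherits(segment, "dendrite_segment")) segment$path
          else as.matrix(segment)
  if (nrow(path) < 2L) stop("path needs at least 2 points")
  chord <- sqrt(sum((path[nrow(path), ] - path[1L, ])^2))
  if (chord < 1e-9)
    stop("coincident endpoints: tortuosity is undefined on closed loops")
  polyline_length(path) / chord
}
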
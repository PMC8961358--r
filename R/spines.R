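## Spine detection, geometry measurement, classification and density.

#' Classify a dendritic spine from its measured geometry
#'
#' Deterministic, total classification rule with precedence
#' branched > stubby > mushroom > thin:
#' \itemize{
#'   \item branched: more than one head;
#'   \item stubby: no visible neck, or head diameter < neck diameter;
#'   \item mushroom: head diameter >= 2 x neck diameter (the boundary
#'     ratio of exactly 2 is mushroom);
#'   \item thin: otherwise (head and neck of similar diameter,
#'     head < 2 x neck).
#' }
#'
#' @param head_diameter_um,neck_diameter_um positive diameters (um).
#' @param neck_visible logical; FALSE when no cross-section narrower
#'   than the head exists between head and shaft.
#' @param n_heads integer >= 1.
#' @return one of `"mushroom"`, `"thin"`, `"stubby"`, `"branched"`.
#' @export
classify_spine <- function(head_diameter_um, neck_diameter_um,
                           neck_visible = TRUE, n_heads = 1L) {
  n <- max(length(head_diameter_um), length(neck_diameter_um),
           length(neck_visible), length(n_heads))
  head_diameter_um <- rep_len(head_diameter_um, n)
  neck_diameter_um <- rep_len(neck_diameter_um, n)
  neck_visible <- rep_len(as.logical(neck_visible), n)
  n_heads <- rep_len(as.integer(n_heads), n)
  if (any(!is.finite(head_diameter_um)) || any(head_diameter_um <= 0) ||
      any(!is.finite(neck_diameter_um)) || any(neck_diameter_um <= 0))
    stop("diameters must be positive")
  if (any(n_heads < 1L)) stop("n_heads must be >= 1")
  out <- character(n)
  branched <- n_heads > 1L
  stubby <- !branched & (!neck_visible | head_diameter_um < neck_diameter_um)
  mushroom <- !branched & !stubby &
    head_diameter_um >= 2 * neck_diameter_um
  out[branched] <- "branched"
  out[stubby] <- "stubby"
  out[mushroom] <- "mushroom"
  out[!branched & !stubby & !mushroom] <- "thin"
  out
}

#' Detect spine candidates along a dendrite segment
#'
#' Protrusions are found at a sensitive detection level (a small fixed
#' fraction of the shaft's peak intensity over background, so dim thin
#' spines survive): connected components standing off the shaft tube
#' laterally, touching the shaft surface, with a protrusion length
#' inside `[min_length_um, max_length_um]`. Because the axial PSF
#' smears the shaft into a halo along z, the search is restricted to
#' near-plane directions (voxels within the shaft's axial half-thickness
#' of the path plane): protrusions pointing along the optical axis are
#' not resolvable at confocal axial resolution and are out of reach by
#' design. Merged neighbours are split on gaps between their base
#' anchor positions. Each candidate carries a background-subtracted,
#' intensity-weighted voxel cloud so that geometry can be measured
#' photometrically (flux-preserving, hence robust to PSF blur) by
#' [measure_spine()].
#'
#' @param stack the [image_stack()] the mask came from.
#' @param mask tight segmentation mask from [segment_neurites()] (used
#'   for the shaft-radius reference).
#' @param segment a `dendrite_segment` traced from this mask.
#' @param min_length_um,max_length_um protrusion length window (um).
#' @param detect_fraction detection level as a fraction of (shaft peak -
#'   background).
#' @param min_volume_um3 minimal flux-equivalent volume of a candidate
#'   (rejects halo/noise specks).
#' @param channel channel to measure; defaults to the first.
#' @return list of `spine_candidate`.
#' @export
detect_spines <- function(stack, mask, segment, min_length_um = 0.2,
                          max_length_um = 4, detect_fraction = 0.12,
                          min_volume_um3 = 0.01, channel = 1L,
                          psf_sigma_um = c(0.2, 0.6)) {
  d <- dim(mask); vs <- stack$voxel_size_um
  img <- get_channel(stack, channel)
  sm <- array(cpp_gauss3d(as.numeric(img), as.integer(d), 0.15 / vs), d)
  bg <- stats::median(sm)
  noise_mad <- stats::mad(sm[sm <= stats::quantile(sm, 0.8)], center = bg)

  # shaft lateral radius (half-maximum) and axial half-thickness from
  # the tight mask along the path
  edt <- array(cpp_edt3d(as.logical(mask), as.integer(d), vs), d)
  pvx <- phys_to_voxel(stack, segment$path)
  pli <- linear_index(d, pvx)
  r_half <- stats::median(edt[pli])
  zcols <- vapply(seq_len(nrow(pvx)), function(i)
    sum(mask[pvx[i, 1L], pvx[i, 2L], ]), 1L)
  r_z <- stats::median(zcols) * vs[3L] / 2
  peak <- stats::median(sm[pli])
  thr <- max(bg + detect_fraction * (peak - bg), bg + 5 * noise_mad)

  # fill amplitude from shaft flux per unit length + peak (flux is
  # conserved under blur, so this pins the unblurred intensity)
  lo <- pmax(1L, floor((apply(segment$path, 2L, min) - 2.3) / vs))
  hi <- pmin(d, ceiling((apply(segment$path, 2L, max) + 2.3) / vs))
  gg <- as.matrix(expand.grid(x = (lo[1L]:hi[1L] - 0.5) * vs[1L],
                              y = (lo[2L]:hi[2L] - 0.5) * vs[2L],
                              z = (lo[3L]:hi[3L] - 0.5) * vs[3L]))
  gdist <- cpp_dist_points_to_polyline(gg, segment$path)
  gsel <- gdist <= 2.3
  gs <- cpp_project_onto_polyline(gg[gsel, , drop = FALSE], segment$path)
  gw <- as.numeric(sm[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]])[gsel] - bg
  slab <- floor(gs)
  slabs <- seq(2L, max(1L, floor(segment$length_um) - 2L))
  fl <- vapply(slabs, function(b) sum(gw[slab == b]) * prod(vs), 1)
  flux_per_um <- stats::median(fl)
  # the measurement image sm carries an extra 0.15 um smoothing on top
  # of the optical PSF; the peak model must use the combined blur
  psf_eff <- sqrt(psf_sigma_um^2 + 0.15^2)
  est <- estimate_fill_amplitude(flux_per_um, peak - bg, psf_eff)
  fill_amp <- est$amplitude

  det <- sm > thr
  idx <- which(det)
  if (!length(idx)) return(list())
  cc <- voxel_centres(stack, idx)
  s_all <- cpp_project_onto_polyline(cc, segment$path)
  proj <- points_at_arclength(segment$path, s_all)
  dxy <- sqrt((cc[, 1L] - proj[, 1L])^2 + (cc[, 2L] - proj[, 2L])^2)
  dz <- abs(cc[, 3L] - proj[, 3L])
  dpath <- sqrt(dxy^2 + dz^2)

  r_cut <- r_half + 2 * vs[1L]
  z_band <- max(r_z - vs[3L] / 2, 2 * vs[3L])
  prot <- dxy > r_cut & dz <= z_band & dpath <= max_length_um + r_half + 1
  if (!any(prot)) return(list())
  pm <- array(FALSE, d); pm[idx[prot]] <- TRUE
  lab <- cpp_label3d(as.logical(pm), as.integer(d))
  labs <- lab[idx[prot]]
  prot_i <- which(prot)
  amp_est <- (peak - bg)   # for the volume floor only
  cand <- list()
  pending <- list()
  for (li in unique(labs)) {
    sel <- prot_i[labs == li]
    if (length(sel) < 3L) next
    if (min(dxy[sel]) > r_cut + 4 * vs[1L]) next     # detached speck
    # split merged neighbours: find distinct bright cores (greedy
    # non-maximum suppression), assign voxels to the nearest core, and
    # keep only groups that own part of the shaft-surface base (a
    # branched spine's twin heads share one base and are re-merged)
    wsel <- sm[idx[sel]] - bg
    groups <- rep(1L, length(sel))
    distal_ok <- dxy[sel] >= r_cut + 2 * vs[1L]   # cores live in heads,
    ord <- order(wsel, decreasing = TRUE)         # not in base spill
    ord <- ord[distal_ok[ord]]
    peaks <- integer(0)
    for (oi in ord) {
      if (wsel[oi] < max(0.15 * max(wsel), 8 * noise_mad)) break
      if (length(peaks) >= 6L) break
      if (!length(peaks) ||
          min(sqrt(rowSums(sweep(cc[sel[peaks], , drop = FALSE], 2L,
                                 cc[sel[oi], ])^2))) >= 0.6)
        peaks <- c(peaks, oi)
    }
    if (length(peaks) >= 2L) {
      pk <- cc[sel[peaks], , drop = FALSE]
      dmat <- vapply(seq_len(nrow(pk)), function(j)
        sqrt(rowSums(sweep(cc[sel, , drop = FALSE], 2L, pk[j, ])^2)),
        numeric(length(sel)))
      groups <- max.col(-dmat, ties.method = "first")
      has_base <- vapply(seq_len(nrow(pk)), function(g)
        any(dxy[sel[groups == g]] <= r_cut + 2 * vs[1L]), TRUE)
      if (any(has_base) && any(!has_base)) {
        based <- which(has_base)
        for (g in which(!has_base)) {
          near <- based[which.min(sqrt(rowSums(sweep(
            pk[based, , drop = FALSE], 2L, pk[g, ])^2)))]
          groups[groups == g] <- near
        }
      } else if (!any(has_base)) groups <- rep(1L, length(sel))
      # twin heads of one branched spine (and the two flanks of one
      # wide bump) share a base: merge groups whose base anchors
      # nearly coincide
      gids <- sort(unique(groups))
      if (length(gids) >= 2L) {
        banc <- vapply(gids, function(g) {
          bi <- sel[groups == g][dxy[sel[groups == g]] <= r_cut + 2 * vs[1L]]
          if (!length(bi)) NA_real_ else stats::median(s_all[bi])
        }, 1)
        for (a in seq_along(gids))
          for (b in seq_len(a - 1L)) {
            if (!is.na(banc[a]) && !is.na(banc[b]) &&
                abs(banc[a] - banc[b]) < 0.45)
              groups[groups == gids[a]] <- gids[b]
          }
      }
    }
    # secondary split: a group whose shaft-surface base is clearly
    # bimodal along the path holds two merged neighbours (exact 1-D
    # two-means; deterministic, no RNG involved)
    for (g in unique(groups)) {
      gi <- groups == g
      bs <- s_all[sel[gi]][dxy[sel[gi]] <= r_cut + 2 * vs[1L]]
      if (length(bs) < 6L) next
      km <- split_1d_2means(bs)
      if (abs(diff(km$centers)) >= 0.55 && min(km$sizes) >= 3L) {
        cut <- mean(km$centers)
        groups[gi & s_all[sel] >= cut] <- max(groups) + 1L
      }
    }
    for (g in unique(groups)) {
      ii <- sel[groups == g]
      if (length(ii) < 3L) next
      len <- max(dpath[ii]) - r_half
      if (len < min_length_um || len > max_length_um) next
      if (min(dxy[ii]) > r_cut + 4 * vs[1L]) next
      # dead zone at the traced tips: residual end-cap corners mimic
      # short protrusions there
      s_med <- stats::median(s_all[ii])
      if (s_med < 0.6 || s_med > segment$length_um - 0.6) next
      wts <- pmax(sm[idx[ii]] - bg, 0)
      if (sum(wts) * prod(vs) / amp_est < min_volume_um3) next
      base <- ii[dpath[ii] <= stats::quantile(dpath[ii], 0.35)]
      anchor <- stats::median(s_all[base])
      anchor_pt <- points_at_arclength(segment$path, anchor)[1L, ]
      cen <- colSums(cc[ii, , drop = FALSE] * wts) / sum(wts)
      u <- cen - anchor_pt
      u <- u / sqrt(sum(u^2))
      pending[[length(pending) + 1L]] <-
        list(ii = ii, anchor = anchor, anchor_pt = anchor_pt, u = u,
             len = len, wts = wts)
    }
  }

  # measurement clouds, masking out voxels owned by any other
  # protrusion so neighbours cannot contaminate the flux profile
  s_max <- segment$length_um
  for (p in pending) {
    excl <- array(FALSE, d)
    excl[idx[prot_i]] <- TRUE
    excl[idx[p$ii]] <- FALSE
    mcloud <- spine_measure_cloud(sm, bg, d, vs, p$anchor_pt, p$u,
                                  r_half, p$len, excl = excl)
    # reference clouds at spine-free offsets along the path capture
    # the shaft's own blur spill, subtracted bin-wise at measurement
    refs <- list()
    for (o in c(-2.5, -1.5, 1.5, 2.5)) {
      ra <- p$anchor + o
      if (ra < 0.3 || ra > s_max - 0.3) next
      rp <- points_at_arclength(segment$path, ra)[1L, ]
      refs[[length(refs) + 1L]] <-
        spine_measure_cloud(sm, bg, d, vs, rp, p$u, r_half, p$len,
                            excl = excl)
    }
    mcloud$m_refs <- refs
    cand[[length(cand) + 1L]] <- structure(
      c(list(voxels = idx[p$ii], coords = cc[p$ii, , drop = FALSE],
             weights = p$wts,
             radial_um = dpath[p$ii] - r_half,
             anchor_um = p$anchor, anchor_point = p$anchor_pt,
             direction = p$u,
             protrusion_length_um = p$len,
             shaft_radius_um = r_half,
             fill_amplitude = fill_amp,
             peak_minus_bg = peak - bg),
        mcloud),
      class = "spine_candidate")
  }
  cand
}

# Exact 1-D two-means: the split of the sorted values minimising the
# within-class sum of squares.
split_1d_2means <- function(x) {
  x <- sort(x)
  n <- length(x)
  best <- Inf; best_k <- 1L
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  for (k in seq_len(n - 1L)) {
    ss1 <- cs2[k] - cs[k]^2 / k
    ss2 <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
    if (ss1 + ss2 < best) { best <- ss1 + ss2; best_k <- k }
  }
  list(centers = c(mean(x[seq_len(best_k)]), mean(x[(best_k + 1L):n])),
       sizes = c(best_k, n - best_k))
}

# Unthresholded measurement cloud for one protrusion: every voxel in a
# capsule around the spine axis (anchor + t * u, t from just inside the
# shaft surface to the tip plus a blur margin), with raw
# background-subtracted weights so that flux is conserved.
spine_measure_cloud <- function(sm, bg, d, vs, anchor_pt, u, r_half, len,
                                window_um = 0.95, excl = NULL) {
  t_max <- r_half + len + 0.5
  ends <- rbind(anchor_pt + u * 0.1, anchor_pt + u * t_max)
  lo <- pmax(1L, floor((apply(ends, 2L, min) - window_um) / vs))
  hi <- pmin(d, ceiling((apply(ends, 2L, max) + window_um) / vs))
  gx <- (lo[1L]:hi[1L] - 0.5) * vs[1L]
  gy <- (lo[2L]:hi[2L] - 0.5) * vs[2L]
  gz <- (lo[3L]:hi[3L] - 0.5) * vs[3L]
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  rel <- sweep(grid, 2L, anchor_pt)
  tt <- rel %*% u
  rho2 <- rowSums(rel^2) - tt^2
  keep <- tt >= max(0.25 * r_half, r_half - 0.3) & tt <= t_max &
    rho2 <= window_um^2
  if (!any(keep)) return(list(m_t = numeric(), m_weights = numeric(),
                              m_coords = matrix(numeric(), ncol = 3L)))
  sub <- sm[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
  if (!is.null(excl)) {
    esub <- excl[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
    keep <- keep & !as.numeric(esub)
  }
  list(m_t = as.numeric(tt[keep]) - r_half,
       m_weights = as.numeric(sub)[keep] - bg,
       m_coords = grid[keep, , drop = FALSE])
}

# Peak attenuation of a cylinder of radius r blurred with an
# anisotropic Gaussian PSF: numeric integral of the 2-D Gaussian over
# the disk cross-section.
psf_peak_attenuation <- function(r, psf_sigma_um, n = 41L) {
  s1 <- psf_sigma_um[1L]; s2 <- psf_sigma_um[2L]
  g <- seq(-r, r, length.out = n)
  hx <- g[2L] - g[1L]
  xx <- matrix(g, n, n); yy <- t(xx)
  inside <- xx^2 + yy^2 <= r^2
  sum(exp(-xx[inside]^2 / (2 * s1^2) - yy[inside]^2 / (2 * s2^2))) *
    hx^2 / (2 * pi * s1 * s2)
}

# Joint estimate of the fill amplitude A and true shaft radius from the
# shaft's peak intensity P (over background) and its flux per unit
# length F: F = A * pi * r^2 and P = A * atten(r) determine both.
estimate_fill_amplitude <- function(flux_per_um, peak_minus_bg, psf_sigma_um,
                                    r_bounds = c(0.1, 4)) {
  f <- function(r) flux_per_um / (pi * r^2) *
    psf_peak_attenuation(r, psf_sigma_um) - peak_minus_bg
  root <- tryCatch(
    stats::uniroot(f, r_bounds, tol = 1e-4)$root,
    error = function(e) NA_real_)
  if (is.na(root))
    return(list(amplitude = peak_minus_bg, radius = NA_real_))
  list(amplitude = flux_per_um / (pi * root^2), radius = root)
}

#' Measure head/neck geometry of a detected protrusion
#'
#' Profiles the protrusion's cross-section area along its radial axis
#' (height above the shaft surface) photometrically: in-bin integrated
#' intensity over background, divided by the estimated fill amplitude,
#' gives the true in-bin volume independent of PSF blur (blur conserves
#' flux). Widths are equivalent-circle diameters of those areas. The
#' head is the maximal width of the distal bulb; the neck the minimal
#' width between bulb and shaft; the neck counts as visible only when
#' at least two consecutive stations are clearly narrower than the
#' head. Heads are counted as distinct bright cores in the distal
#' region (>= 2 marks a branched spine).
#'
#' @param candidate a `spine_candidate` from [detect_spines()].
#' @param voxel_size_um voxel pitch (um).
#' @param psf_sigma_um PSF sigmas (lateral, axial) used to correct the
#'   fill-amplitude estimate.
#' @return list(head_diameter_um, neck_diameter_um, neck_visible,
#'   n_heads).
#' @export
measure_spine <- function(candidate, voxel_size_um,
                          psf_sigma_um = c(0.2, 0.6)) {
  vs <- voxel_size_um
  vol_vox <- prod(vs)
  if (length(candidate$m_t %||% numeric()) < 6L)
    stop("protrusion thinner than one voxel everywhere; rejected as noise")
  amp <- candidate$fill_amplitude %||%
    (candidate$peak_minus_bg /
       psf_peak_attenuation(max(candidate$shaft_radius_um, vs[1L]),
                            psf_sigma_um))
  s <- candidate$m_t                     # height above shaft surface
  w <- candidate$m_weights
  L <- candidate$protrusion_length_um
  h <- max(vs[1L], min(0.25, L / 6))
  nb <- max(2L, ceiling((L + 0.3) / h))
  s0 <- min(s)
  bin <- pmax(1L, pmin(nb, 1L + floor((s - s0) / h)))
  flux <- vapply(seq_len(nb), function(b) sum(w[bin == b]) * vol_vox, 1)
  # subtract the shaft's own blur spill, profiled at spine-free offsets
  refs <- candidate$m_refs %||% list()
  if (length(refs)) {
    rf <- vapply(refs, function(r) {
      rb <- pmax(1L, pmin(nb, 1L + floor((r$m_t - s0) / h)))
      vapply(seq_len(nb), function(b) sum(r$m_weights[rb == b]) * vol_vox, 1)
    }, numeric(nb))
    # spines only ever add flux: a low quantile across the
    # reference profiles resists refs that graze a neighbour
    flux <- flux - apply(rf, 1L, stats::quantile, probs = 0.35)
  }
  area <- pmax(flux, 0) / (amp * h)
  width <- 2 * sqrt(area / pi)
  centres <- s0 + (seq_len(nb) - 0.5) * h
  occupied <- which(width > 0.5 * vs[1L])
  if (!length(occupied))
    stop("protrusion thinner than one voxel everywhere; rejected as noise")

  # head: the distal bulb, sized from its integrated flux volume
  # (V = pi d^3 / 6 for a spherical bulb; cube-root flux is robust to
  # both the 1-D binning and moderate amplitude error)
  distal <- occupied[centres[occupied] >= 0.4 * L]
  if (!length(distal)) distal <- occupied
  i_head <- distal[which.max(width[distal])]
  r0 <- max(width[i_head] / 2, h)
  head_bins <- which(centres > centres[i_head] - r0)
  v_head <- sum(pmax(flux[head_bins], 0)) / amp
  head_d <- max((6 * v_head / pi)^(1 / 3), width[i_head])
  # neck: minimal width between shaft spill zone and the head station
  pre <- occupied[occupied < i_head & centres[occupied] >= 0.15]
  if (length(pre)) {
    neck_d <- min(width[pre])
    # neck visibility from the profile shape: a clear distal bulge
    # (head) implies a neck; a flat profile is a neck-less bump when
    # short and a thin spine's shaft+head when long; a proximally
    # dominated profile is a stubby bump
    i_widest <- occupied[which.max(width[occupied])]
    extent <- centres[max(occupied)]
    valid <- occupied[centres[occupied] >= 0.15]
    flatness <- if (length(valid))
      max(width[valid]) / max(stats::median(width[valid]), 1e-6) else 1
    pos <- centres[i_widest] / max(extent, 1e-6)
    neck_visible <- if (flatness < 1.25) extent > 1.1 else pos > 0.45
  } else {
    neck_d <- head_d
    neck_visible <- FALSE
  }
  # heads: distinct bright cores in the distal region; scanning the
  # core threshold finds the level at which twin heads separate while
  # a single head stays one core
  n_heads <- 1L
  # count over both voxel clouds: the thresholded component (bright,
  # compact) and the neighbour-masked capsule cloud (catches a dim
  # second head below the detection level)
  clouds <- list(list(w = candidate$weights,
                      p = candidate$coords,
                      r = candidate$radial_um),
                 list(w = w, p = candidate$m_coords, r = s))
  for (cl in clouds) {
    # cut above the branch vertex: twin necks converge below ~0.6 L and
    # would single-link the two head cores
    distal_sel <- cl$r > 0.55 * L
    if (sum(distal_sel) < 6L) next
    wts <- cl$w[distal_sel]
    pts_all <- cl$p[distal_sel, , drop = FALSE]
    for (q in c(0.85, 0.75, 0.65, 0.55)) {
      core <- wts >= q * max(wts)
      if (sum(core) < 4L) next
      nh <- count_head_cores(pts_all[core, , drop = FALSE], wts[core],
                             link_um = 0.45, brightness = 0.5)
      n_heads <- max(n_heads, nh)
    }
  }
  # twin heads also show as a wide flux-weighted lateral spread of the
  # distal region about the spine axis (robust when the cores bridge)
  dsel <- candidate$radial_um > 0.55 * L
  if (sum(dsel) >= 8L) {
    wts <- candidate$weights[dsel]
    core <- wts >= 0.3 * max(wts)   # keep the z-blur tails out
    if (sum(core) >= 8L) {
      pts <- candidate$coords[dsel, , drop = FALSE][core, , drop = FALSE]
      rel <- sweep(pts, 2L, candidate$anchor_point)
      # axis through the distal flux centroid: robust to a slightly
      # misaligned anchor direction on a wiggly backbone
      ax <- colSums(rel * wts[core]) / sum(wts[core])
      ax <- ax / sqrt(sum(ax^2))
      tt <- as.numeric(rel %*% ax)
      perp2 <- pmax(rowSums(rel^2) - tt^2, 0)
      rms <- sqrt(sum(perp2 * wts[core]) / max(sum(wts[core]), 1e-9))
      if (rms > 0.62) n_heads <- max(n_heads, 2L)
    }
  }
  list(head_diameter_um = head_d, neck_diameter_um = max(neck_d, 0.5 * vs[1L]),
       neck_visible = neck_visible, n_heads = n_heads)
}

# clusters qualifying as spine heads: single linkage, then only
# clusters that are both populous and comparably bright count (twin
# heads of a branched spine are near-equal; dim noise shards are not)
count_head_cores <- function(pts, wts, link_um, min_size = 4L,
                             brightness = 0.6) {
  n <- nrow(pts)
  if (n <= min_size) return(1L)
  dmat <- as.matrix(stats::dist(pts))
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(dmat[i, ] <= link_um)
      m <- min(lab[nb])
      if (any(lab[nb] != m)) { lab[nb] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  wmax <- max(wts)
  good <- 0L
  for (l in unique(lab)) {
    sel <- lab == l
    if (sum(sel) >= min_size && max(wts[sel]) >= brightness * wmax)
      good <- good + 1L
  }
  max(1L, good)
}

# single-linkage cluster count with a hard merge radius; small n only
count_point_clusters <- function(pts, link_um, min_size = 3L) {
  n <- nrow(pts)
  if (n <= min_size) return(1L)
  dmat <- as.matrix(stats::dist(pts))
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(dmat[i, ] <= link_um)
      m <- min(lab[nb])
      if (any(lab[nb] != m)) { lab[nb] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  sizes <- table(lab)
  max(1L, sum(sizes >= min_size))
}

#' Measure and classify all spines along a segment
#'
#' Convenience wrapper: [detect_spines()], then [measure_spine()] and
#' [classify_spine()] for each candidate.
#'
#' @inheritParams detect_spines
#' @return data.frame with one row per spine: anchor, geometry, class.
#' @export
quantify_spines <- function(stack, mask, segment, min_length_um = 0.2,
                            max_length_um = 4) {
  cands <- detect_spines(stack, mask, segment, min_length_um, max_length_um)
  if (!length(cands))
    return(data.frame(anchor_um = numeric(), protrusion_length_um = numeric(),
                      head_diameter_um = numeric(),
                      neck_diameter_um = numeric(),
                      neck_visible = logical(), n_heads = integer(),
                      spine_class = character(), stringsAsFactors = FALSE))
  rows <- lapply(cands, function(cd) {
    m <- tryCatch(measure_spine(cd, stack$voxel_size_um),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    data.frame(anchor_um = cd$anchor_um,
               protrusion_length_um = cd$protrusion_length_um,
               head_diameter_um = m$head_diameter_um,
               neck_diameter_um = m$neck_diameter_um,
               neck_visible = m$neck_visible, n_heads = m$n_heads,
               spine_class = classify_spine(m$head_diameter_um,
                                            m$neck_diameter_um,
                                            m$neck_visible, m$n_heads),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Linear spine density of a segment
#'
#' @param segment a `dendrite_segment` (or anything with `length_um`).
#' @param spines data.frame of spines (one row each) or an integer count.
#' @return spines per um of dendrite path length.
#' @export
spine_density <- function(segment, spines) {
  L <- if (is.numeric(segment)) segment else segment$length_um
  if (!is.finite(L) || L <= 0) stop("segment length must be positive")
  n <- if (is.data.frame(spines)) nrow(spines) else as.numeric(spines)
  n / L
}

#' Per-class spine proportions, aggregated the mouse-first way
#'
#' Computes per-mouse class proportions first and averages them across
#' mice within each condition (the plotted aggregation), and also
#' returns raw pooled counts per condition (the chi-square surface).
#' Mice with zero spines contribute nothing to the per-mouse average and
#' are flagged.
#'
#' @param spines data.frame with columns `mouse_id`, `condition`,
#'   `spine_class` (or per-class count columns `n_mushroom`, ...).
#' @param classes class order for the output.
#' @return list: `per_mouse` (proportions per mouse x class),
#'   `condition_mean` (mean of mouse proportions per condition),
#'   `pooled_counts` (condition x class counts),
#'   `excluded_mice` (zero-spine mice).
#' @export
class_proportions <- function(spines,
                              classes = c("mushroom", "thin", "stubby",
                                          "branched")) {
  if (all(paste0("n_", classes) %in% names(spines))) {
    counts <- as.matrix(spines[, paste0("n_", classes)])
    colnames(counts) <- classes
    mouse <- spines$mouse_id
    cond <- spines$condition
    agg <- rowsum(counts, group = paste(mouse, cond, sep = "\r"))
    key <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  } else {
    tab <- table(paste(spines$mouse_id, spines$condition, sep = "\r"),
                 factor(spines$spine_class, classes))
    agg <- matrix(tab, nrow = nrow(tab), dimnames = dimnames(tab))
    key <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  }
  totals <- rowSums(agg)
  excluded <- key[totals == 0, 1L]
  if (length(excluded))
    warning("mouse with zero spines excluded from per-mouse averages: ",
            paste(unique(excluded), collapse = ", "))
  props <- agg[totals > 0, , drop = FALSE] / totals[totals > 0]
  keyp <- key[totals > 0, , drop = FALSE]
  per_mouse <- data.frame(mouse_id = keyp[, 1L], condition = keyp[, 2L],
                          props, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cm <- rowsum(props, keyp[, 2L]) /
    as.vector(table(keyp[, 2L])[sort(unique(keyp[, 2L]))])
  pooled <- rowsum(agg, key[, 2L])
  list(per_mouse = per_mouse, condition_mean = cm, pooled_counts = pooled,
       excluded_mice = unique(excluded))
}
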
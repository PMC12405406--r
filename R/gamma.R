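# Gamma-index engine. For each reference point r the gamma index is
#
#   gamma(r) = min over evaluated positions e of
#              sqrt( |e - r|^2 / r_m^2  +  (D_e(e) - D(r))^2 / D_m^2 )
#
# with r_m the distance-to-agreement criterion (mm), D_m the dose criterion
# in absolute units (percent of the global reference maximum under "global"
# normalization, of the local reference dose under "local"), and D_e the
# piecewise-(multi)linear interpolant of the evaluated distribution. The
# minimum is taken over the continuous interpolant: in 1-D by closed-form
# per-segment minimization (gamma^2 is quadratic on each linear dose
# segment), in 2-D/3-D by a windowed candidate scan at `interp_step_mm`
# followed by iterative grid-zoom refinement. `interp_step_mm` therefore
# controls basin-finding, not the final precision.

#' Gamma comparison criteria
#'
#' @param dose_tolerance_percent Dose-difference criterion D_m, percent
#'   (e.g. 3 for 3\%).
#' @param dta_mm Distance-to-agreement criterion r_m, mm (e.g. 3).
#' @param normalization \code{"global"}: D_m is a percentage of the global
#'   reference maximum (standard clinical practice, the default);
#'   \code{"local"}: a percentage of each reference point's own dose.
#' @param dose_threshold_percent Reference points below this percentage of
#'   the global reference maximum are excluded from analysis (0 = none).
#' @param search_limit_factor Search radius as a multiple of \code{dta_mm}.
#' @param interp_step_mm Candidate-scan step for the evaluated distribution,
#'   mm; must not exceed \code{dta_mm}.
#' @return Object of class \code{gamma_criteria}.
#' @export
gamma_criteria <- function(dose_tolerance_percent = 3,
                           dta_mm = 3,
                           normalization = c("global", "local"),
                           dose_threshold_percent = 0,
                           search_limit_factor = 3,
                           interp_step_mm = dta_mm / 10) {
  normalization <- match.arg(normalization)
  if (dose_tolerance_percent <= 0) abort_input("dose tolerance must be positive")
  if (dta_mm <= 0) abort_input("DTA must be positive")
  if (search_limit_factor < 1) abort_input("search_limit_factor must be >= 1")
  if (dose_threshold_percent < 0 || dose_threshold_percent >= 100)
    abort_input("dose threshold must be in [0, 100)")
  if (interp_step_mm <= 0 || interp_step_mm > dta_mm)
    abort_input("interp_step_mm must be positive and <= dta_mm")
  structure(list(dose_tolerance_percent = dose_tolerance_percent,
                 dta_mm = dta_mm,
                 normalization = normalization,
                 dose_threshold_percent = dose_threshold_percent,
                 search_limit_factor = search_limit_factor,
                 interp_step_mm = interp_step_mm),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("<gamma_criteria> %g%%/%gmm, %s normalization, threshold %g%%\n",
              x$dose_tolerance_percent, x$dta_mm, x$normalization,
              x$dose_threshold_percent))
  invisible(x)
}

# ---- input adaptation ------------------------------------------------------

# Reduce either a 1-D scan or a dose_grid to reference points (matrix, mm)
# or an evaluated sampling (axes in mm + value array).
gamma_input <- function(obj) {
  if (inherits(obj, c("depth_dose_curve", "lateral_profile"))) {
    list(axes = list(scan_coords_mm(obj)), values = scan_doses(obj),
         shape = length(scan_doses(obj)))
  } else if (inherits(obj, "dose_grid")) {
    axes <- grid_axes_mm(obj)
    list(axes = axes, values = obj$values,
         shape = unname(vapply(axes, length, integer(1))))
  } else {
    abort_input("gamma inputs must be scans or dose grids")
  }
}

grid_axes_mm <- function(grid) {
  axes <- grid$axes
  if ("z" %in% names(axes)) axes$z <- axes$z * 10
  axes
}

# ---- continuous evaluated interpolant --------------------------------------

# Multilinear interpolation of `values` (array over `axes`) at the rows of
# `pts` (clamped to the domain box). Vectorized over points; d <= 3.
interp_multilinear <- function(axes, values, pts) {
  d <- length(axes)
  npt <- nrow(pts)
  dims <- vapply(axes, length, integer(1))
  idx <- matrix(1L, npt, d)
  frac <- matrix(0, npt, d)
  for (k in seq_len(d)) {
    ax <- axes[[k]]
    p <- pmin(max(ax), pmax(min(ax), pts[, k]))
    if (dims[k] == 1L) next
    i <- findInterval(p, ax, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), dims[k] - 1L)
    idx[, k] <- i
    frac[, k] <- (p - ax[i]) / (ax[i + 1L] - ax[i])
  }
  stride <- cumprod(c(1L, dims[-d]))
  out <- numeric(npt)
  vals <- as.vector(values)
  for (corner in seq_len(2^d) - 1L) {
    w <- rep(1, npt)
    lin <- rep(1, npt)
    for (k in seq_len(d)) {
      hi <- bitwAnd(corner, bitwShiftL(1L, k - 1L)) > 0L
      if (hi && dims[k] == 1L) { w <- 0; break }
      w <- w * if (hi) frac[, k] else 1 - frac[, k]
      lin <- lin + (idx[, k] - 1L + as.integer(hi && dims[k] > 1L)) * stride[k]
    }
    if (length(w) == 1L && all(w == 0)) next
    out <- out + w * vals[lin]
  }
  out
}

# ---- core search -----------------------------------------------------------

# Exact 1-D minimum of gamma^2 over the piecewise-linear evaluated scan,
# restricted to |x - r| <= R. gamma^2 is quadratic on each segment.
gamma2_min_1d <- function(xe, de, r, dr, rm, dm, R) {
  lo <- max(r - R, xe[1])
  hi <- min(r + R, xe[length(xe)])
  if (lo > hi) { lo <- pmin(pmax(r, xe[1]), xe[length(xe)]); hi <- lo }
  i <- seq_len(length(xe) - 1L)
  keep <- which(xe[i + 1L] >= lo & xe[i] <= hi)
  g2 <- function(x, dval) (x - r)^2 / rm^2 + (dval - dr)^2 / dm^2
  if (!length(keep)) {          # single-point evaluated or empty overlap
    xc <- pmin(hi, pmax(lo, xe))
    return(min(g2(xc, de)))
  }
  x0 <- xe[keep]; x1 <- xe[keep + 1L]
  d0 <- de[keep]; d1 <- de[keep + 1L]
  m <- (d1 - d0) / (x1 - x0)
  # stationary point of the per-segment quadratic
  xs <- (r / rm^2 + m * (dr - d0 + m * x0) / dm^2) / (1 / rm^2 + m^2 / dm^2)
  a0 <- pmax(x0, lo); a1 <- pmin(x1, hi)
  xs <- pmin(a1, pmax(a0, xs))
  dxs <- d0 + m * (xs - x0)
  min(g2(xs, dxs), g2(a0, d0 + m * (a0 - x0)), g2(a1, d0 + m * (a1 - x0)))
}

# Greedy selection of refinement seeds: best candidates first, keeping a
# minimum spatial separation so distinct local basins each get a seed.
select_seeds <- function(pts, vals, min_sep, max_seeds, slack) {
  ord <- order(vals)
  best <- vals[ord[1]]
  seeds <- pts[ord[1], , drop = FALSE]
  for (j in ord[-1]) {
    if (nrow(seeds) >= max_seeds || vals[j] > best + slack) break
    d2 <- rowSums(sweep(seeds, 2L, pts[j, ], "-")^2)
    if (min(d2) > min_sep^2) seeds <- rbind(seeds, pts[j, ])
  }
  seeds
}

# n-D minimum: candidate scan (window grid at `step`, evaluated nodes in the
# window, the reference point itself) then pattern-search refinement on the
# continuous interpolant from each seed basin.
gamma2_min_nd <- function(axes, values, dom_lo, dom_hi, offsets, node_idx,
                          r, dr, rm, dm, R, step) {
  d <- length(axes)
  pts <- sweep(offsets, 2L, r, "+")
  for (k in seq_len(d))
    pts[, k] <- pmin(dom_hi[k], pmax(dom_lo[k], pts[, k]))
  nodes <- lapply(seq_len(d), function(k) {
    ax <- axes[[k]]
    ax[ax >= r[k] - R & ax <= r[k] + R]
  })
  if (all(lengths(nodes) > 0L)) {
    node_pts <- as.matrix(expand.grid(nodes, KEEP.OUT.ATTRS = FALSE))
    dimnames(node_pts) <- NULL
    pts <- rbind(pts, node_pts)
  }
  pts <- rbind(pts, matrix(pmin(dom_hi, pmax(dom_lo, r)), 1L))
  g2 <- function(p) {
    dd <- interp_multilinear(axes, values, p)
    rowSums(sweep(p, 2L, r, "-")^2) / rm^2 + (dd - dr)^2 / dm^2
  }
  v <- g2(pts)
  seeds <- select_seeds(pts, v, min_sep = 1.5 * step, max_seeds = 4, slack = 1)
  bv_global <- min(v)
  # pattern search on the continuous interpolant from each seed: recenter at
  # the current scale while it improves (follows curved gamma valleys), then
  # shrink
  for (si in seq_len(nrow(seeds))) {
    best <- seeds[si, ]
    bv <- g2(matrix(best, 1L))
    h <- step / 2
    while (h > 1e-9) {
      repeat {
        loc <- lapply(seq_len(d), function(k)
          unique(pmin(dom_hi[k], pmax(dom_lo[k], best[k] + h * (-1:1)))))
        cand <- as.matrix(expand.grid(loc, KEEP.OUT.ATTRS = FALSE))
        dimnames(cand) <- NULL
        cv <- g2(cand)
        if (min(cv) < bv - 1e-15) {
          bv <- min(cv)
          best <- cand[which.min(cv), ]
        } else break
      }
      h <- h / 2
    }
    bv_global <- min(bv_global, bv)
  }
  bv_global
}

gamma_core <- function(ref, ev, crit) {
  rp <- as.matrix(expand.grid(ref$axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(rp) <- NULL
  rd <- as.vector(ref$values)
  if (!length(rd) || !length(as.vector(ev$values)))
    abort_input("empty gamma inputs")
  gmax <- max(rd)
  if (gmax <= 0) abort_input("reference distribution is identically zero")
  mask <- rd >= crit$dose_threshold_percent / 100 * gmax
  rm <- crit$dta_mm
  R <- crit$search_limit_factor * rm
  d <- length(ev$axes)
  gam <- rep(NA_real_, length(rd))
  dm_global <- crit$dose_tolerance_percent / 100 * gmax
  if (d == 1L) {
    xe <- ev$axes[[1]]
    de <- as.vector(ev$values)
    for (i in which(mask)) {
      dm <- if (crit$normalization == "global") dm_global
            else crit$dose_tolerance_percent / 100 * rd[i]
      if (dm <= 0) abort_input("local normalization at a zero-dose reference point")
      gam[i] <- sqrt(gamma2_min_1d(xe, de, rp[i, 1L], rd[i], rm, dm, R))
    }
  } else {
    dom_lo <- vapply(ev$axes, min, numeric(1))
    dom_hi <- vapply(ev$axes, max, numeric(1))
    off1 <- seq(-R, R, by = crit$interp_step_mm)
    offsets <- as.matrix(expand.grid(rep(list(off1), d), KEEP.OUT.ATTRS = FALSE))
    dimnames(offsets) <- NULL
    offsets <- offsets[rowSums(offsets^2) <= R^2 + 1e-12, , drop = FALSE]
    for (i in which(mask)) {
      dm <- if (crit$normalization == "global") dm_global
            else crit$dose_tolerance_percent / 100 * rd[i]
      if (dm <= 0) abort_input("local normalization at a zero-dose reference point")
      gam[i] <- sqrt(gamma2_min_nd(ev$axes, ev$values, dom_lo, dom_hi,
                                   offsets, NULL, rp[i, ], rd[i], rm, dm, R,
                                   crit$interp_step_mm))
    }
  }
  new_gamma_map(gam, mask, ref$shape, crit)
}

new_gamma_map <- function(gamma, mask, shape, criteria) {
  if (length(shape) > 1L) {
    dim(gamma) <- shape
    dim(mask) <- shape
  }
  structure(list(gamma = gamma, evaluated_mask = mask, criteria = criteria),
            class = "gamma_map")
}

#' Compute the gamma index between two dose distributions
#'
#' Evaluates, for every reference point passing the dose threshold, the
#' minimum combined dose-difference / distance-to-agreement metric against
#' the linearly interpolated evaluated distribution (see the criteria object
#' for the exact normalization). The comparison direction is fixed:
#' reference to evaluated (the gamma index is not symmetric).
#'
#' @param reference,evaluated Two [depth_dose_curve()]s, two
#'   [lateral_profile()]s, or two [dose_grid()]s sharing axis names.
#' @param criteria A [gamma_criteria()] object (default 3\%/3mm, global).
#' @return A \code{gamma_map}: gamma values shaped like the reference
#'   (\code{NA} where masked), the threshold mask, and the criteria.
#' @seealso [gamma_oracle()] for the brute-force verification
#'   implementation, [summarize_gamma()] for binned agreement fractions.
#' @export
#' @examples
#' p <- beam_model_params("6MV")
#' ref <- make_profile(p, 10, seq(-80, 80, 2))
#' ev <- make_profile(p, 10, seq(-80, 80, 2))
#' summarize_gamma(compute_gamma(ref, ev))
compute_gamma <- function(reference, evaluated, criteria = gamma_criteria()) {
  stopifnot(inherits(criteria, "gamma_criteria"))
  check_gamma_pair(reference, evaluated)
  gamma_core(gamma_input(reference), gamma_input(evaluated), criteria)
}

check_gamma_pair <- function(reference, evaluated) {
  scan <- c("depth_dose_curve", "lateral_profile")
  if (inherits(reference, scan) && inherits(evaluated, scan)) return(invisible())
  if (inherits(reference, "dose_grid") && inherits(evaluated, "dose_grid")) {
    if (!identical(names(reference$axes), names(evaluated$axes)))
      abort_input("reference and evaluated grids have different dimensionality")
    return(invisible())
  }
  abort_input("reference and evaluated must share dimensionality (both scans or both grids)")
}

#' Brute-force gamma oracle
#'
#' Independent verification implementation used in tests: exhaustively scans
#' a dense resampling of the evaluated distribution at
#' \code{interp_step_mm / 5} over the whole domain (no search window, no
#' algorithmic shortcuts), then polishes the best candidate on the
#' continuous interpolant with a generic optimizer ([stats::optimize] in
#' 1-D, Nelder-Mead otherwise).
#'
#' @inheritParams compute_gamma
#' @param max_points Resource guard on the reference point count.
#' @return A \code{gamma_map}.
#' @export
gamma_oracle <- function(reference, evaluated, criteria = gamma_criteria(),
                         max_points = 1e4) {
  stopifnot(inherits(criteria, "gamma_criteria"))
  check_gamma_pair(reference, evaluated)
  ref <- gamma_input(reference)
  ev <- gamma_input(evaluated)
  if (prod(ref$shape) > max_points)
    abort_resource(sprintf("oracle limited to %g reference points", max_points))
  rp <- as.matrix(expand.grid(ref$axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(rp) <- NULL
  rd <- as.vector(ref$values)
  if (!length(rd) || !length(as.vector(ev$values)))
    abort_input("empty gamma inputs")
  gmax <- max(rd)
  if (gmax <= 0) abort_input("reference distribution is identically zero")
  mask <- rd >= crit_threshold_abs(criteria, gmax)
  step <- criteria$interp_step_mm / 5
  dense_axes <- lapply(ev$axes, function(ax) {
    if (length(ax) == 1L) return(ax)
    seq(min(ax), max(ax), by = step)
  })
  dense_pts <- as.matrix(expand.grid(dense_axes, KEEP.OUT.ATTRS = FALSE))
  dimnames(dense_pts) <- NULL
  dense_dose <- interp_multilinear(ev$axes, ev$values, dense_pts)
  d <- length(ev$axes)
  rm <- criteria$dta_mm
  dom_lo <- vapply(ev$axes, min, numeric(1))
  dom_hi <- vapply(ev$axes, max, numeric(1))
  gam <- rep(NA_real_, length(rd))
  for (i in which(mask)) {
    dm <- if (criteria$normalization == "global")
      criteria$dose_tolerance_percent / 100 * gmax
    else criteria$dose_tolerance_percent / 100 * rd[i]
    if (dm <= 0) abort_input("local normalization at a zero-dose reference point")
    r <- rp[i, ]
    g2d <- rowSums(sweep(dense_pts, 2L, r, "-")^2) / rm^2 +
      (dense_dose - rd[i])^2 / dm^2
    # refinement by exhaustive multi-level box scans around each candidate
    # basin: a full grid over a shrinking box, recentered on the running
    # minimum at every level -- no descent heuristics to stall on kinks or
    # curved valleys
    g2vec <- function(pmat) {
      rowSums(sweep(pmat, 2L, r, "-")^2) / rm^2 +
        (interp_multilinear(ev$axes, ev$values, pmat) - rd[i])^2 / dm^2
    }
    nax <- if (d == 3L) 21L else 41L
    shrink <- nax / 4   # each level keeps two sample spacings of coverage
    beams <- if (d == 1L) 3L else 2L
    box_scan <- function(p) {
      centers <- matrix(p, 1L)
      half <- 2 * criteria$interp_step_mm   # span the seed-separation scale
      v_best <- min(g2vec(centers))
      while (half > 5e-7) {
        cand <- do.call(rbind, lapply(seq_len(nrow(centers)), function(ci) {
          loc <- lapply(seq_len(d), function(k)
            unique(pmin(dom_hi[k], pmax(dom_lo[k],
                                        centers[ci, k] +
                                          seq(-half, half, length.out = nax)))))
          m <- as.matrix(expand.grid(loc, KEEP.OUT.ATTRS = FALSE))
          dimnames(m) <- NULL
          m
        }))
        cv <- g2vec(cand)
        v_best <- min(v_best, cv)
        # several near-tied sub-minima can coexist below the sampling
        # resolution; track the best separated ones rather than one track
        spacing <- 2 * half / (nax - 1)
        centers <- select_seeds(cand, cv, min_sep = 1.5 * spacing,
                                max_seeds = beams, slack = Inf)
        half <- half / shrink
      }
      v_best
    }
    seeds <- select_seeds(dense_pts, g2d, min_sep = criteria$interp_step_mm,
                          max_seeds = 4, slack = 0.5)
    val <- min(g2d)
    for (si in seq_len(nrow(seeds)))
      val <- min(val, box_scan(seeds[si, ]))
    gam[i] <- sqrt(val)
  }
  new_gamma_map(gam, mask, ref$shape, criteria)
}

crit_threshold_abs <- function(criteria, gmax) {
  criteria$dose_threshold_percent / 100 * gmax
}

#' @export
print.gamma_map <- function(x, ...) {
  g <- x$gamma[x$evaluated_mask]
  cat(sprintf("<gamma_map> %d/%d points evaluated, %g%%/%gmm (%s)\n",
              sum(x$evaluated_mask), length(x$evaluated_mask),
              x$criteria$dose_tolerance_percent, x$criteria$dta_mm,
              x$criteria$normalization))
  if (length(g))
    cat(sprintf("  gamma: median %.3f, max %.3f, pass (<1) %.1f%%\n",
                stats::median(g), max(g), 100 * mean(g < 1)))
  invisible(x)
}

#' Summarize a gamma map into the standard agreement bins
#'
#' Bins the evaluated gamma values into excellent (\eqn{\gamma \le 0.5}),
#' good (\eqn{0.5 < \gamma < 1}) and poor (\eqn{\gamma \ge 1}) agreement
#' fractions, plus the overall passing rate (\eqn{\gamma < 1}).
#'
#' @param map A \code{gamma_map} from [compute_gamma()], or a bare numeric
#'   vector of gamma values.
#' @return Object of class \code{gamma_summary} with fields
#'   \code{frac_excellent}, \code{frac_good}, \code{frac_poor},
#'   \code{pass_rate} (all fractions in [0, 1]) and \code{n}.
#' @export
summarize_gamma <- function(map) {
  g <- if (inherits(map, "gamma_map")) map$gamma[map$evaluated_mask]
       else as.numeric(map)
  g <- g[!is.na(g)]
  if (!length(g)) abort_input("no unmasked gamma values to summarize")
  if (any(g < 0)) abort_input("gamma values must be non-negative")
  structure(list(frac_excellent = mean(g <= 0.5),
                 frac_good = mean(g > 0.5 & g < 1),
                 frac_poor = mean(g >= 1),
                 pass_rate = mean(g < 1),
                 n = length(g)),
            class = "gamma_summary")
}

#' @export
print.gamma_summary <- function(x, ...) {
  cat(sprintf(paste0("<gamma_summary> n=%d: excellent (<=0.5) %.1f%%, ",
                     "good (0.5,1) %.1f%%, poor (>=1) %.1f%%; pass %.1f%%\n"),
              x$n, 100 * x$frac_excellent, 100 * x$frac_good,
              100 * x$frac_poor, 100 * x$pass_rate))
  invisible(x)
}
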
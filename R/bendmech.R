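# Whole-bone mechanics from three-point bending force-displacement curves,
# plus engineering beam theory for tissue-level material properties.

#' Force-displacement curve
#'
#' Container for a sampled three-point bending record.
#'
#' @param displacement Strictly increasing displacement samples, mm.
#' @param force Force samples, N (same length, >= 10 samples).
#' @param span Bottom support span, mm (default 7).
#' @param preload Preload force, N (informational; default -0.1).
#' @param rate Loading rate, mm/s (informational).
#' @param id Optional curve identifier.
#' @return Object of class `fd_curve`.
#' @export
fd_curve <- function(displacement, force, span = 7, preload = -0.1,
                     rate = 0.1, id = NULL) {
  displacement <- as.numeric(displacement)
  force <- as.numeric(force)
  if (length(displacement) != length(force)) {
    stop("fd_curve: displacement and force must have equal length",
         call. = FALSE)
  }
  if (length(displacement) < 10L) {
    stop("fd_curve: need at least 10 samples", call. = FALSE)
  }
  if (any(diff(displacement) <= 0)) {
    stop("fd_curve: displacement must be strictly increasing", call. = FALSE)
  }
  structure(list(displacement = displacement, force = force,
                 meta = list(span = span, preload = preload, rate = rate,
                             id = id)),
            class = "fd_curve")
}

#' @export
print.fd_curve <- function(x, ...) {
  cat(sprintf("<fd_curve> %d samples, d in [%.4g, %.4g] mm, Fmax = %.4g N\n",
              length(x$displacement), min(x$displacement),
              max(x$displacement), max(x$force)))
  invisible(x)
}

#' Beam cross-section geometry for three-point bending
#'
#' @param I Second moment of area about the bending axis, mm^4 (> 0).
#' @param c Distance from the neutral axis to the outermost failure-side
#'   fiber, mm (> 0).
#' @param L Support span, mm (> 0; default 7).
#' @return Object of class `beam_geometry`.
#' @export
beam_geometry <- function(I, c, L = 7) {
  if (!all(is.finite(c(I, c, L))) || I <= 0 || c <= 0 || L <= 0) {
    stop("beam_geometry: I, c and L must all be > 0", call. = FALSE)
  }
  structure(list(I = I, c = c, L = L), class = "beam_geometry")
}

#' Stiffness from the steepest linear window of the elastic region
#'
#' Bending stiffness K is the maximum least-squares slope over all
#' contiguous windows of `ceiling(window_frac * n_pre)` samples, where
#' `n_pre` counts samples up to the ultimate force. The sliding maximal
#' window is robust to the toe region created by preloading.
#'
#' @param curve An [fd_curve()].
#' @param window_frac Window width as a fraction of the pre-ultimate samples
#'   (in (0.05, 0.9]; default 0.2).
#' @return List: `K` (N/mm), `window` (start/end indices of the winning
#'   window).
#' @export
fit_stiffness <- function(curve, window_frac = 0.2) {
  stopifnot(inherits(curve, "fd_curve"))
  if (window_frac <= 0.05 || window_frac > 0.9) {
    stop("fit_stiffness: window_frac must be in (0.05, 0.9]", call. = FALSE)
  }
  if (diff(range(curve$force)) < .Machine$double.eps) {
    stop("fit_stiffness: degenerate curve (constant force)", call. = FALSE)
  }
  n_pre <- which.max(curve$force)
  if (n_pre < 3L) {
    stop("fit_stiffness: fewer than 3 samples before the ultimate force",
         call. = FALSE)
  }
  d <- curve$displacement[seq_len(n_pre)]
  f <- curve$force[seq_len(n_pre)]
  w <- max(3L, as.integer(ceiling(window_frac * n_pre)))
  w <- min(w, n_pre)
  # rolling least-squares slope via cumulative sums
  cs <- function(v) c(0, cumsum(v))
  sx <- cs(d); sy <- cs(f); sxx <- cs(d^2); sxy <- cs(d * f)
  i0 <- seq_len(n_pre - w + 1L)
  i1 <- i0 + w - 1L
  Sx <- sx[i1 + 1L] - sx[i0]
  Sy <- sy[i1 + 1L] - sy[i0]
  Sxx <- sxx[i1 + 1L] - sxx[i0]
  Sxy <- sxy[i1 + 1L] - sxy[i0]
  denom <- w * Sxx - Sx^2
  slope <- (w * Sxy - Sx * Sy) / denom
  slope[denom <= 0] <- -Inf
  best <- which.max(slope)
  K <- slope[best]
  if (!is.finite(K) || K <= 0) {
    stop("fit_stiffness: degenerate curve (non-positive best slope)",
         call. = FALSE)
  }
  list(K = K, window = c(start = i0[best], end = i1[best]))
}

#' Yield and failure points by the offset-line criterion
#'
#' The ultimate force `Fu` is the curve maximum. Yield is the first sample
#' at or after the elastic window where the force falls below the offset
#' line `K * (d - offset_displacement)`; if no sample violates the offset
#' line before failure the bone is treated as brittle (`Fy = Fu`, yield at
#' the ultimate point). Failure is the first post-ultimate sample whose
#' force drops below `drop_frac * Fu`, or the last sample when no such drop
#' is recorded. Post-yield displacement is
#' `failure_displacement - yield_displacement`.
#'
#' @param curve An [fd_curve()].
#' @param K Stiffness from [fit_stiffness()] on the same curve (N/mm).
#' @param offset_displacement Offset of the yield line, mm (>= 0). The
#'   conventional default is `0.002 * L^2 / (6c)` (a 0.2% strain offset
#'   mapped to displacement through beam theory) when geometry is known,
#'   else 0.01 mm; see [analyze_curve()].
#' @param drop_frac Failure threshold as a fraction of `Fu` (default 0.10).
#' @param elastic_end Index of the end of the elastic window (search start;
#'   default 1).
#' @return List: `Fy`, `yield_displacement`, `Fu`, `failure_displacement`,
#'   `PYD`, `brittle` flag.
#' @export
find_yield_and_failure <- function(curve, K, offset_displacement = 0.01,
                                   drop_frac = 0.10, elastic_end = 1L) {
  stopifnot(inherits(curve, "fd_curve"), is.finite(K), K > 0)
  if (offset_displacement < 0) {
    stop("find_yield_and_failure: offset_displacement must be >= 0",
         call. = FALSE)
  }
  d <- curve$displacement
  f <- curve$force
  iu <- which.max(f)
  Fu <- f[iu]
  post <- which(seq_along(f) > iu & f < drop_frac * Fu)
  ifail <- if (length(post)) post[1L] else length(f)
  offset_line <- K * (d - offset_displacement)
  cand <- which(seq_along(f) >= max(1L, elastic_end) &
                  seq_along(f) < ifail & f < offset_line)
  if (length(cand)) {
    iy <- cand[1L]
    Fy <- min(f[iy], Fu)
    brittle <- FALSE
    dy <- d[iy]
  } else {
    iy <- iu
    Fy <- Fu
    dy <- d[iu]
    brittle <- TRUE
  }
  list(Fy = Fy, yield_displacement = dy, Fu = Fu,
       failure_displacement = d[ifail],
       PYD = max(0, d[ifail] - dy), brittle = brittle)
}

#' Work-to-fracture by trapezoidal integration
#'
#' Integrates force over displacement from the first non-negative-force
#' sample up to the failure displacement. Negative force samples (preload)
#' are clipped to zero. With force in N and displacement in mm the result
#' is in mJ.
#'
#' @param curve An [fd_curve()].
#' @param failure_displacement Upper integration limit, mm (within the
#'   recorded range).
#' @return Work-to-fracture, mJ.
#' @export
compute_work <- function(curve, failure_displacement) {
  stopifnot(inherits(curve, "fd_curve"))
  d <- curve$displacement
  if (failure_displacement < d[1L] - 1e-12 ||
      failure_displacement > d[length(d)] + 1e-12) {
    stop("compute_work: failure_displacement outside the recorded range",
         call. = FALSE)
  }
  f <- pmax(curve$force, 0)
  keep <- d <= failure_displacement + 1e-12
  first <- which(curve$force >= 0)[1L]
  if (is.na(first)) return(0)
  keep[seq_len(first - 1L)] <- FALSE
  if (sum(keep) < 2L) return(0)
  pracma::trapz(d[keep], f[keep])
}

#' Tissue-level material properties from engineering beam theory
#'
#' Standard three-point-bending relations for a beam of span `L`, second
#' moment of area `I` and outer-fiber distance `c`:
#' `Su = Fu * L * c / (4 I)`, `Sy = Fy * L * c / (4 I)`,
#' `E = K * L^3 / (48 I)`. With forces in N, K in N/mm and lengths in mm
#' the results are in MPa.
#'
#' @param K Stiffness, N/mm.
#' @param Fy Yield force, N.
#' @param Fu Ultimate force, N.
#' @param geometry A [beam_geometry()].
#' @return List: `Su`, `Sy`, `E` (MPa).
#' @export
beam_material_props <- function(K, Fy, Fu, geometry) {
  if (!inherits(geometry, "beam_geometry")) {
    stop("beam_material_props: 'geometry' must be a beam_geometry",
         call. = FALSE)
  }
  with(geometry, list(
    Su = Fu * L * c / (4 * I),
    Sy = Fy * L * c / (4 * I),
    E = K * L^3 / (48 * I)))
}

#' Analyze a force-displacement curve end to end
#'
#' Composition of [fit_stiffness()], [find_yield_and_failure()],
#' [compute_work()] and, when geometry is supplied,
#' [beam_material_props()]. Leading samples with negative force (preload)
#' are trimmed and displacement is re-zeroed at the first crossing of
#' F = 0 before analysis.
#'
#' @param curve An [fd_curve()].
#' @param geometry Optional [beam_geometry()]; when present the material
#'   fields `Su`, `Sy`, `E` are computed and the default yield offset
#'   becomes `0.002 * L^2 / (6 c)`.
#' @param window_frac Passed to [fit_stiffness()].
#' @param offset_displacement Yield offset, mm; `NULL` (default) selects
#'   the geometry-based offset or 0.01 mm as described above.
#' @param drop_frac Passed to [find_yield_and_failure()].
#' @return Object of class `mechanical_result`: `K`, `Fy`, `Fu`, `PYD`,
#'   `work`, `yield_displacement`, `failure_displacement`, plus `Su`, `Sy`,
#'   `E` when geometry is given; `flags` records brittle yields and the
#'   chosen elastic window.
#' @export
analyze_curve <- function(curve, geometry = NULL, window_frac = 0.2,
                          offset_displacement = NULL, drop_frac = 0.10) {
  stopifnot(inherits(curve, "fd_curve"))
  # preload handling: drop leading negative-force samples, re-zero d
  f <- curve$force
  pos <- which(f >= 0)
  if (!length(pos)) {
    stop("analyze_curve: no non-negative force samples", call. = FALSE)
  }
  if (pos[1L] > 1L) {
    d <- curve$displacement[pos[1L]:length(f)]
    curve <- fd_curve(d - d[1L], f[pos[1L]:length(f)],
                      span = curve$meta$span, preload = curve$meta$preload,
                      rate = curve$meta$rate, id = curve$meta$id)
  }
  if (is.null(offset_displacement)) {
    offset_displacement <- if (!is.null(geometry)) {
      0.002 * geometry$L^2 / (6 * geometry$c)
    } else {
      0.01
    }
  }
  st <- fit_stiffness(curve, window_frac = window_frac)
  yf <- find_yield_and_failure(curve, st$K,
                               offset_displacement = offset_displacement,
                               drop_frac = drop_frac,
                               elastic_end = st$window[["end"]])
  if (yf$Fy > yf$Fu) yf$Fy <- yf$Fu
  work <- compute_work(curve, yf$failure_displacement)
  out <- list(K = st$K, Fy = yf$Fy, Fu = yf$Fu, PYD = yf$PYD, work = work,
              yield_displacement = yf$yield_displacement,
              failure_displacement = yf$failure_displacement,
              Su = NA_real_, Sy = NA_real_, E = NA_real_,
              flags = list(brittle = yf$brittle,
                           elastic_window = st$window,
                           offset_displacement = offset_displacement),
              id = curve$meta$id)
  if (!is.null(geometry)) {
    mp <- beam_material_props(st$K, yf$Fy, yf$Fu, geometry)
    out[c("Su", "Sy", "E")] <- mp[c("Su", "Sy", "E")]
  }
  structure(out, class = "mechanical_result")
}

#' @export
print.mechanical_result <- function(x, ...) {
  cat(sprintf(paste0("<mechanical_result> K = %.4g N/mm, Fy = %.4g N, ",
                     "Fu = %.4g N, PYD = %.4g mm, work = %.4g mJ%s\n"),
              x$K, x$Fy, x$Fu, x$PYD, x$work,
              if (is.finite(x$E)) sprintf(", E = %.4g MPa", x$E) else ""))
  invisible(x)
}

#' @export
as.data.frame.mechanical_result <- function(x, ...) {
  data.frame(id = if (is.null(x$id)) NA_character_ else x$id,
             K = x$K, Fy = x$Fy, Fu = x$Fu, PYD = x$PYD, work = x$work,
             yield_displacement = x$yield_displacement,
             failure_displacement = x$failure_displacement,
             Su = x$Su, Sy = x$Sy, E = x$E,
             brittle = x$flags$brittle,
             stringsAsFactors = FALSE)
}

#' Analyze a batch of curves
#'
#' @param curves List of [fd_curve()] objects (names become ids).
#' @param ... Passed to [analyze_curve()].
#' @return Data frame with one row per curve, order preserved; failed
#'   curves yield a row of `NA`s and a warning naming the curve.
#' @export
analyze_curves <- function(curves, ...) {
  res <- lapply(seq_along(curves), function(i) {
    id <- names(curves)[i] %||% as.character(i)
    r <- tryCatch(analyze_curve(curves[[i]], ...), error = function(e) {
      warning("curve '", id, "' failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(r)) {
      data.frame(id = id, K = NA_real_, Fy = NA_real_, Fu = NA_real_,
                 PYD = NA_real_, work = NA_real_,
                 yield_displacement = NA_real_,
                 failure_displacement = NA_real_, Su = NA_real_,
                 Sy = NA_real_, E = NA_real_, brittle = NA,
                 stringsAsFactors = FALSE)
    } else {
      df <- as.data.frame(r)
      df$id <- id
      df
    }
  })
  do.call(rbind, res)
}
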
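## Calibrated pinhole stereo geometry: projection, triangulation, refinement.

#' Project 3D points through a camera
#'
#' Perspective projection with two-term radial distortion applied in
#' normalized coordinates before the intrinsics. Points must lie in front of
#' the camera (positive depth in the camera frame).
#'
#' @param p A 3-vector (mm) or an `n x 3` matrix of points.
#' @param cam A [cameraModel()].
#' @return For a single point, a named `c(x, y)` pixel position; for a matrix,
#'   an `n x 2` matrix.
#' @export
projectPoint <- function(p, cam) {
  single <- is.null(dim(p))
  P <- if (single) matrix(p, 1, 3) else as.matrix(p)
  Pc <- P %*% t(cam@rotation)
  Pc <- sweep(Pc, 2, cam@translation, "+")
  if (any(Pc[, 3] <= 0)) stop("point has non-positive depth in the camera frame")
  x <- Pc[, 1] / Pc[, 3]
  y <- Pc[, 2] / Pc[, 3]
  r2 <- x^2 + y^2
  d <- 1 + cam@distortion[1] * r2 + cam@distortion[2] * r2^2
  uv <- cbind(x = cam@fx * x * d + cam@cx, y = cam@fy * y * d + cam@cy)
  if (single) uv[1, ] else uv
}

#' Undistort pixel observations to normalized camera coordinates
#'
#' Inverts the radial distortion by fixed-point iteration (exact at zero
#' distortion, sub-1e-10 residual for the mild distortions used here).
#'
#' @param uv A `c(x, y)` pixel pair or `n x 2` matrix.
#' @param cam A [cameraModel()].
#' @return Normalized (unit-depth) coordinates, same shape as the input.
#' @export
undistortPoint <- function(uv, cam) {
  single <- is.null(dim(uv))
  U <- if (single) matrix(uv, 1, 2) else as.matrix(uv)
  xd <- (U[, 1] - cam@cx) / cam@fx
  yd <- (U[, 2] - cam@cy) / cam@fy
  x <- xd; y <- yd
  for (i in 1:20) {
    r2 <- x^2 + y^2
    d <- 1 + cam@distortion[1] * r2 + cam@distortion[2] * r2^2
    x <- xd / d
    y <- yd / d
  }
  out <- cbind(x = x, y = y)
  if (single) out[1, ] else out
}

#' Camera center and world-frame ray through a pixel
#' @noRd
.cameraRay <- function(uv, cam) {
  n <- undistortPoint(uv, cam)
  d <- as.numeric(t(cam@rotation) %*% c(n[1], n[2], 1))
  list(origin = as.numeric(-t(cam@rotation) %*% cam@translation),
       dir = d / sqrt(sum(d^2)))
}

#' Triangulate a stereo observation pair
#'
#' Undistorts both observations, intersects the two viewing rays in the
#' least-squares sense, then refines the point with a few Gauss-Newton steps
#' on the summed squared reprojection error. The reported residual is the RMS
#' reprojection distance over the two views.
#'
#' @param obsFront,obsSide `c(x, y)` pixel observations in the two views.
#' @param rig A [stereoRig()].
#' @param refine Run the Gauss-Newton reprojection refinement (default TRUE).
#' @return List with `point` (3-vector, mm) and `residual` (px).
#' @export
triangulate <- function(obsFront, obsSide, rig, refine = TRUE) {
  if (any(!is.finite(c(obsFront, obsSide))))
    stop("observations must be finite")
  r1 <- .cameraRay(obsFront, rig@front)
  r2 <- .cameraRay(obsSide, rig@side)
  ang <- acos(min(1, max(-1, abs(sum(r1$dir * r2$dir)))))
  if (ang < 1e-3)
    stop("degenerate geometry: viewing rays are near-parallel")
  A <- matrix(0, 3, 3); b <- numeric(3)
  for (r in list(r1, r2)) {
    M <- diag(3) - tcrossprod(r$dir)
    A <- A + M
    b <- b + M %*% r$origin
  }
  X <- as.numeric(solve(A, b))
  reproj <- function(X) {
    pf <- projectPoint(X, rig@front)
    ps <- projectPoint(X, rig@side)
    c(pf - obsFront, ps - obsSide)
  }
  if (refine) {
    h <- 1e-4
    for (it in 1:8) {
      r0 <- reproj(X)
      J <- vapply(1:3, function(j) {
        Xp <- X; Xp[j] <- Xp[j] + h
        (reproj(Xp) - r0) / h
      }, numeric(4))
      step <- tryCatch(solve(crossprod(J) + 1e-12 * diag(3), -crossprod(J, r0)),
                       error = function(e) rep(0, 3))
      X <- X + as.numeric(step)
      if (sqrt(sum(step^2)) < 1e-10) break
    }
  }
  r0 <- reproj(X)
  list(point = X,
       residual = sqrt(mean(c(sum(r0[1:2]^2), sum(r0[3:4]^2)))))
}

#' Triangulate paired 2D tracks into a 3D trajectory
#'
#' @param trackFront,trackSide `n x 2` matrices of pixel observations.
#' @param rig A [stereoRig()].
#' @param refine Passed to [triangulate()].
#' @return Data frame with columns `frame` (0-based), `x_mm`, `y_mm`, `z_mm`,
#'   `residual_px`. Frames with non-finite observations yield `NA` rows.
#' @export
triangulateTrack <- function(trackFront, trackSide, rig, refine = TRUE) {
  n <- nrow(trackFront)
  stopifnot(nrow(trackSide) == n)
  out <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    if (all(is.finite(c(trackFront[i, ], trackSide[i, ])))) {
      tr <- triangulate(trackFront[i, ], trackSide[i, ], rig, refine = refine)
      out[i, ] <- c(tr$point, tr$residual)
    }
  }
  data.frame(frame = seq_len(n) - 1, x_mm = out[, 1], y_mm = out[, 2],
             z_mm = out[, 3], residual_px = out[, 4])
}

## Rodrigues rotation parameterization -------------------------------------

#' Rotation vector to rotation matrix (Rodrigues)
#' @noRd
.rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation matrix to rotation vector
#' @noRd
.rodriguesInv <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  th <- acos(min(1, max(-1, ct)))
  if (th < 1e-12) return(c(0, 0, 0))
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  v / (2 * sin(th)) * th
}

#' Refine stereo calibration from tracked correspondences
#'
#' Per-animal calibration fine-tuning: starting from an initial rig, adjusts
#' the side camera's extrinsics (and optionally the intrinsics of both
#' cameras) to minimize the total squared reprojection error of the
#' triangulated correspondences. The front camera's extrinsics are held fixed
#' to pin the world frame (gauge). The returned rig never has a larger total
#' reprojection error than the input rig.
#'
#' @param rig Initial [stereoRig()].
#' @param trackFront,trackSide `n x 2` matrices of corresponding pixel
#'   observations (n >= 20, spanning the workspace).
#' @param refineIntrinsics Also release `fx, fy, cx, cy, k1, k2` of both
#'   cameras (off by default to avoid overfitting a single animal's
#'   trajectories).
#' @param maxit Iteration budget for the optimizer.
#' @return A refined `StereoRig`.
#' @export
refineCalibration <- function(rig, trackFront, trackSide,
                              refineIntrinsics = FALSE, maxit = 300) {
  trackFront <- as.matrix(trackFront); trackSide <- as.matrix(trackSide)
  n <- nrow(trackFront)
  if (n < 20 || nrow(trackSide) != n)
    stop("at least 20 paired correspondences are required")
  pts <- triangulateTrack(trackFront, trackSide, rig, refine = FALSE)
  P <- as.matrix(pts[, c("x_mm", "y_mm", "z_mm")])
  P <- P[complete.cases(P), , drop = FALSE]
  if (nrow(P) < 20) stop("fewer than 20 correspondences triangulated")
  sv <- svd(scale(P, scale = FALSE))$d
  if (sv[2] < 1e-6 * max(sv[1], 1))
    stop("degenerate correspondences: points are collinear")

  packRig <- function(rig) {
    p <- c(.rodriguesInv(rig@side@rotation), rig@side@translation)
    if (refineIntrinsics)
      p <- c(p,
             rig@front@fx, rig@front@fy, rig@front@cx, rig@front@cy, rig@front@distortion,
             rig@side@fx, rig@side@fy, rig@side@cx, rig@side@cy, rig@side@distortion)
    p
  }
  unpackRig <- function(p) {
    side <- rig@side
    side@rotation <- .rodrigues(p[1:3])
    side@translation <- p[4:6]
    front <- rig@front
    if (refineIntrinsics) {
      front@fx <- p[7]; front@fy <- p[8]; front@cx <- p[9]; front@cy <- p[10]
      front@distortion <- p[11:12]
      side@fx <- p[13]; side@fy <- p[14]; side@cx <- p[15]; side@cy <- p[16]
      side@distortion <- p[17:18]
    }
    stereoRig(front, side)
  }
  objective <- function(p) {
    r <- tryCatch(unpackRig(p), error = function(e) NULL)
    if (is.null(r)) return(1e12)
    tot <- tryCatch({
      tk <- triangulateTrack(trackFront, trackSide, r, refine = FALSE)
      ok <- is.finite(tk$residual_px)
      if (!any(ok)) return(1e12)
      sum(tk$residual_px[ok]^2) + 1e6 * sum(!ok)
    }, error = function(e) 1e12)
    tot
  }
  p0 <- packRig(rig)
  e0 <- objective(p0)
  fit <- optim(p0, objective, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  if (fit$value <= e0) unpackRig(fit$par) else rig
}

#' Read/write calibration files
#'
#' Calibration is stored as YAML with explicit field names and units
#' (focal lengths and principal points in px, translations in mm, radial
#' distortion unitless; world frame right-handed, mm, origin at the perch).
#'
#' @param rig A [stereoRig()].
#' @param path File path.
#' @return `writeCalibration` returns `path` invisibly; `readCalibration`
#'   returns a `StereoRig`.
#' @export
writeCalibration <- function(rig, path) {
  camList <- function(cam) list(
    fx_px = cam@fx, fy_px = cam@fy, cx_px = cam@cx, cy_px = cam@cy,
    distortion_radial = as.numeric(cam@distortion),
    rotation_world_to_camera = lapply(seq_len(3), function(i) as.numeric(cam@rotation[i, ])),
    translation_mm = as.numeric(cam@translation))
  yaml::write_yaml(list(
    world_frame = "right-handed, millimeters, origin at perch",
    front = camList(rig@front), side = camList(rig@side)), path)
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  y <- yaml::read_yaml(path)
  camFrom <- function(l) cameraModel(
    l$fx_px, l$fy_px, l$cx_px, l$cy_px, distortion = unlist(l$distortion_radial),
    rotation = do.call(rbind, lapply(l$rotation_world_to_camera, unlist)),
    translation = unlist(l$translation_mm))
  stereoRig(camFrom(y$front), camFrom(y$side))
}
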
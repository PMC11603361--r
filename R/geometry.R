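# Landmark registration and stereotactic targeting helpers.

#' Rigid landmark registration (orthogonal Procrustes without scaling)
#'
#' Closed-form Kabsch solution: finds the rotation R (det +1) and translation
#' t minimising the sum of squared distances between `R src + t` and `dst`.
#'
#' @param src,dst n x 3 matrices of corresponding points (n >= 3,
#'   non-collinear).
#' @return A rigid `ntatlas_transform`.
#' @export
estimate_rigid_from_landmarks <- function(src, dst) {
  src <- as_points(src); dst <- as_points(dst)
  if (nrow(src) != nrow(dst))
    stop("`src` and `dst` must have the same number of points", call. = FALSE)
  if (nrow(src) < 3L)
    stop("at least 3 point pairs are required", call. = FALSE)
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  cs <- sweep(src, 2, mu_s); cd <- sweep(dst, 2, mu_d)
  if (svd(cs)$d[2] < 1e-9 * max(svd(cs)$d[1], 1))
    stop("landmarks are collinear; the rotation is not identifiable",
         call. = FALSE)
  h <- crossprod(cs, cd)              # 3x3 covariance
  sv <- svd(h)
  s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  r <- sv$v %*% s %*% t(sv$u)
  t_vec <- mu_d - as.numeric(r %*% mu_s)
  rigid_transform(r, t_vec)
}

#' Indirect stereotactic target from AC-PC landmarks
#'
#' Computes the targeting point used for VIM thalamotomy: 11 mm lateral to
#' the lateral wall of the third ventricle, one quarter of the AC-PC distance
#' anterior to PC along the intercommissural axis, and 2 mm superior to the
#' intercommissural plane.
#'
#' The AC-PC pair fixes the anterior axis only; the superior direction is the
#' component of `superior_hint` (default world +z) orthogonal to it, and the
#' lateral axis completes the right-handed RAS frame.
#'
#' @param ac,pc anterior / posterior commissure world points (mm).
#' @param third_ventricle_wall_x distance (mm, nonnegative) of the lateral
#'   wall of the third ventricle from the midsagittal plane.
#' @param side `"left"` or `"right"`.
#' @param superior_hint approximate superior direction (default `c(0, 0, 1)`).
#' @return Length-3 world point (mm).
#' @export
stereotactic_target <- function(ac, pc, third_ventricle_wall_x,
                                side = c("right", "left"),
                                superior_hint = c(0, 0, 1)) {
  side <- match.arg(side)
  ac <- as.numeric(ac); pc <- as.numeric(pc)
  d <- sqrt(sum((ac - pc)^2))
  if (d < 1e-9) stop("degenerate AC-PC axis", call. = FALSE)
  y_hat <- (ac - pc) / d
  z_raw <- superior_hint - sum(superior_hint * y_hat) * y_hat
  if (sqrt(sum(z_raw^2)) < 1e-9)
    stop("superior hint is parallel to the AC-PC axis", call. = FALSE)
  z_hat <- z_raw / sqrt(sum(z_raw^2))
  x_hat <- c(y_hat[2] * z_hat[3] - y_hat[3] * z_hat[2],
             y_hat[3] * z_hat[1] - y_hat[1] * z_hat[3],
             y_hat[1] * z_hat[2] - y_hat[2] * z_hat[1])
  lateral <- (third_ventricle_wall_x + 11) * if (side == "right") 1 else -1
  pc + 0.25 * d * y_hat + 2 * z_hat + lateral * x_hat
}
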
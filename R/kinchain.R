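# Marker-based kinematic chain shared by the simulator (forward/inverse
# kinematics) and the joint-angle extractor. Keeping one documented
# convention on both sides is what makes prescribed joint excursions
# recoverable: the proprietary model used with commercial capture systems
# is replaced here by explicit projection-based angles in a thorax frame.
#
# Coordinates are right-handed: +Z vertical (up), +Y anterior (toward the
# target panel), +X to the subject's right. Units cm and seconds. Left-arm
# trials are mirrored about the sagittal (x = 0) plane to a canonical
# right-arm configuration before any angle is computed.

# Row-wise cross product of n x 3 matrices.
.cross3 <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

.unit_rows <- function(m) {
  n <- .rownorm(m)
  if (any(n < 1e-12)) {
    abort("degenerate (zero-length) segment vector",
          class = "reachkin_error_geometry")
  }
  m / n
}

# Thorax anatomical frame per frame, from the four trunk markers plus the
# two acromions. Axes: z = spine line (midpoint(T10, STRN) -> midpoint(C7,
# CLAV), i.e. pointing up), x = inter-acromion line orthogonalised against
# z (pointing right), y = z x x (anterior). Returns list of n x 3 matrices.
.thorax_frame <- function(c7, clav, t10, strn, sho_l, sho_r) {
  zax <- .unit_rows((c7 + clav) / 2 - (t10 + strn) / 2)
  xraw <- sho_r - sho_l
  xax <- xraw - rowSums(xraw * zax) * zax
  xax <- .unit_rows(xax)
  yax <- .cross3(zax, xax)
  list(x = xax, y = yax, z = zax)
}

# Express world-frame vectors u (n x 3) in a thorax frame.
.in_frame <- function(u, frame) {
  cbind(rowSums(u * frame$x), rowSums(u * frame$y), rowSums(u * frame$z))
}

# Projection-based shoulder decomposition of a humerus direction expressed
# in thorax coordinates (columns: lateral, anterior, up). The reference
# posture (arm hanging along the thorax vertical) maps to FE = AA = 0.
# FE: sagittal-plane projection angle; AA: frontal-plane projection angle.
# Frames in which the relevant projection degenerates (humerus along the
# decomposition axis) are flagged NA.
.shoulder_fe_aa <- function(u_local) {
  uy <- u_local[, 2]
  uz <- u_local[, 3]
  ux <- u_local[, 1]
  fe <- ifelse(sqrt(uy^2 + uz^2) < 1e-9, NA_real_,
               atan2(uy, -uz) * 180 / pi)
  aa <- ifelse(sqrt(ux^2 + uz^2) < 1e-9, NA_real_,
               atan2(ux, -uz) * 180 / pi)
  list(fe = fe, aa = aa)
}

# Elbow flexion angle series in degrees; 0 = full extension (upper-arm and
# forearm vectors parallel).
.elbow_angle <- function(sho, elb, wri) {
  ua <- .unit_rows(elb - sho)
  fa <- .unit_rows(wri - elb)
  acos(.clamp1(rowSums(ua * fa))) * 180 / pi
}

# Transverse-plane rotation of the inter-acromion line relative to its
# orientation at the first supplied frame, signed, in degrees.
.acromion_rotation <- function(sho_l, sho_r) {
  a <- (sho_r - sho_l)[, 1:2, drop = FALSE]
  if (any(sqrt(rowSums(a^2)) < 1e-9)) {
    abort("acromion markers coincide in the transverse plane",
          class = "reachkin_error_geometry")
  }
  a0 <- a[1L, ]
  atan2(a[, 1] * a0[2] - a[, 2] * a0[1], a[, 1] * a0[1] + a[, 2] * a0[2]) *
    (-180 / pi)
}

# Two-link inverse kinematics, vectorised over frames. Given shoulder and
# hand (endpoint) paths plus segment lengths, places the elbow using a
# planar-elevation convention: the elbow lies in the plane spanned by the
# shoulder->hand line and the global vertical, displaced downward (the
# relaxed "elbow drops under gravity" posture). Errors if the target is out
# of reach.
.ik_elbow <- function(sho, hand, d1, d2) {
  w <- hand - sho
  r <- .rownorm(w)
  if (any(r > (d1 + d2) * (1 - 1e-12))) {
    abort("endpoint out of reach for the given segment lengths",
          class = "reachkin_error_infeasible_configuration")
  }
  if (any(r < abs(d1 - d2) + 1e-9)) {
    abort("endpoint too close to the shoulder for the given segment lengths",
          class = "reachkin_error_infeasible_configuration")
  }
  what <- w / r
  # unit vector perpendicular to the reach line, pointing as far "down" as
  # possible; fall back to the lateral axis for a vertical reach line
  down <- matrix(rep(c(0, 0, -1), each = nrow(w)), ncol = 3)
  v <- down - rowSums(down * what) * what
  vn <- .rownorm(v)
  flat <- vn < 1e-9
  if (any(flat)) {
    v[flat, ] <- matrix(rep(c(1, 0, 0), each = sum(flat)), ncol = 3)
    vn[flat] <- 1
  }
  nhat <- v / vn
  cos_alpha <- .clamp1((d1^2 + r^2 - d2^2) / (2 * d1 * r))
  sin_alpha <- sqrt(pmax(0, 1 - cos_alpha^2))
  sho + d1 * (cos_alpha * what + sin_alpha * nhat)
}

# Forward kinematics: humerus direction in world coordinates from shoulder
# projection angles (degrees) and a thorax frame. Valid for |FE|, |AA| < 90.
.fk_humerus_dir <- function(fe_deg, aa_deg, frame) {
  fe <- fe_deg * pi / 180
  aa <- aa_deg * pi / 180
  local <- cbind(tan(aa), tan(fe), -1)
  local <- local / .rownorm(local)
  local[, 1] * frame$x + local[, 2] * frame$y + local[, 3] * frame$z
}
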
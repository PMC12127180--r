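# fixtures are built in code; nothing on disk

# rigid six-landmark trajectory from a body-centre path (mm) and angles (deg)
make_traj <- function(com_mm, heading = 0, tail_angle = 0, yaw = 0,
                      frame_rate = 30, pixel_scale = 0.1) {
  n <- nrow(com_mm)
  heading <- rep_len(heading, n)
  tail_angle <- rep_len(tail_angle, n)
  yaw <- rep_len(yaw, n)
  u <- cbind(cos(heading), sin(heading))
  skull <- com_mm + 4 * u
  td <- heading + pi + tail_angle * pi / 180
  tail1 <- com_mm + 6 * cbind(cos(td), sin(td))
  tail2 <- com_mm + 10 * cbind(cos(td), sin(td))
  ed <- heading + pi / 2 + yaw * pi / 180
  ev <- cbind(cos(ed), sin(ed))
  le <- skull + 2.5 * ev
  re <- skull - 2.5 * ev
  px <- function(m) m / pixel_scale
  coords <- tibble::tibble(
    left_eye_x = px(le)[, 1], left_eye_y = px(le)[, 2],
    right_eye_x = px(re)[, 1], right_eye_y = px(re)[, 2],
    skull_center_x = px(skull)[, 1], skull_center_y = px(skull)[, 2],
    body_com_x = px(com_mm)[, 1], body_com_y = px(com_mm)[, 2],
    tail1_x = px(tail1)[, 1], tail1_y = px(tail1)[, 2],
    tail2_x = px(tail2)[, 1], tail2_y = px(tail2)[, 2])
  landmark_trajectory(coords, frame_rate = frame_rate,
                      pixel_scale = pixel_scale)
}

# voxelized straight tube along the x axis: radius and length in um
straight_tube <- function(radius = 40, length = 1000, voxel = 4) {
  rv <- ceiling(radius / voxel)
  lv <- round(length / voxel)
  d1 <- 2 * rv + 9; d2 <- 2 * rv + 9; d3 <- lv + 13
  arr <- array(0, dim = c(d1, d2, d3))
  ci <- (d1 + 1) / 2; cj <- (d2 + 1) / 2
  i <- rep(seq_len(d1), times = d2 * d3)
  j <- rep(rep(seq_len(d2), each = d1), times = d3)
  k <- rep(seq_len(d3), each = d1 * d2)
  inside <- ((i - ci)^2 + (j - cj)^2) * voxel^2 <= radius^2 &
    k >= 7 & k <= 7 + lv
  arr[inside] <- 1
  canal_volume(arr, voxel, is_binary = TRUE)
}

# voxelized solid ellipsoid with semi-axes (ax, ay, az) um
solid_ellipsoid <- function(ax, ay, az, voxel = 5) {
  nx <- ceiling(ax / voxel) + 3
  ny <- ceiling(ay / voxel) + 3
  nz <- ceiling(az / voxel) + 3
  d <- c(2 * nz + 1, 2 * ny + 1, 2 * nx + 1)
  i <- rep(seq_len(d[1]), times = d[2] * d[3])
  j <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  k <- rep(seq_len(d[3]), each = d[1] * d[2])
  arr <- array(0, dim = d)
  arr[(((k - nx - 1) / (ax / voxel))^2 +
         ((j - ny - 1) / (ay / voxel))^2 +
         ((i - nz - 1) / (az / voxel))^2) <= 1] <- 1
  canal_volume(arr, voxel, is_binary = TRUE)
}

ellipse_points <- function(a, b, n = 100, angle = 0, center = c(0, 0),
                           noise_sd = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  r <- cbind(a * cos(th), b * sin(th))
  if (noise_sd > 0) {
    r <- r * (1 + matrix(stats::rnorm(2 * n, 0, noise_sd), n, 2))
  }
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  p <- r %*% t(R)
  tibble::tibble(x = p[, 1] + center[1], y = p[, 2] + center[2])
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}

# two-species cohort with a programmed between-species offset on the first
# three variables and optional missing cells
make_cohort <- function(n_per = 8, n_var = 6, missing = TRUE, effect = 3,
                        seed = 19) {
  set.seed(seed)
  coh <- tibble::tibble(animal_id = sprintf("an%02d", 1:(2 * n_per)),
                        species = rep(c("xenopus", "axolotl"), each = n_per))
  for (v in seq_len(n_var)) {
    coh[[paste0("v", v)]] <- stats::rnorm(2 * n_per) +
      (v <= 3) * rep(c(0, effect), each = n_per)
  }
  if (missing) {
    coh$v1[c(2, n_per + 3)] <- NA
    coh$v4[c(5, n_per + 1)] <- NA
  }
  coh
}
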
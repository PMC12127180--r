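#' Circular summary of phase values
#'
#' Mean direction and mean resultant vector length ("vector strength") of a
#' sample of angles, the standard summary of phase clustering: r ranges from
#' 0 (phases dispersed around the circle) to 1 (all phases identical).
#'
#' @param phases angles in degrees.
#' @return A one-row tibble: `mean_direction` (degrees, in (-180, 180]),
#'   `r`, `n`.
#' @export
circular_summary <- function(phases) {
  if (length(phases) == 0) {
    abort("empty phase vector", class = "gazestab_input_error")
  }
  a <- phases * pi / 180
  s <- mean(sin(a)); c <- mean(cos(a))
  r <- sqrt(s^2 + c^2)
  mu <- atan2(s, c) * 180 / pi
  if (r < 1e-12) mu <- NA_real_
  tibble(mean_direction = mu, r = r, n = length(phases))
}

# maximum-likelihood concentration estimate from the mean resultant length
# (Fisher 1993, eq. 4.40-4.42)
a1inv <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams test for equal mean directions
#'
#' High-concentration F test comparing the mean directions of two or more
#' groups of angles, with the standard correction factor
#' `1 + 3 / (8 kappa)`. Valid for reasonably concentrated samples; a warning
#' is raised when the pooled mean resultant length falls below 0.45.
#'
#' @param phases angles in degrees, or a list of per-group angle vectors.
#' @param group group labels (ignored when `phases` is a list).
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p.value`,
#'   `kappa`, `r_bar`.
#' @export
watson_williams <- function(phases, group = NULL) {
  if (is.list(phases) && !is.data.frame(phases)) {
    groups <- phases
  } else {
    stopifnot(!is.null(group), length(group) == length(phases))
    groups <- split(phases, group)
  }
  k <- length(groups)
  ns <- lengths(groups)
  if (k < 2) abort("need at least two groups", class = "gazestab_input_error")
  if (any(ns < 2)) {
    abort("every group needs at least two phase values",
          class = "gazestab_input_error")
  }
  N <- sum(ns)
  res_len <- function(a) {
    a <- a * pi / 180
    sqrt(sum(sin(a))^2 + sum(cos(a))^2)
  }
  Ri <- vapply(groups, res_len, numeric(1))
  R <- res_len(unlist(groups))
  r_w <- sum(Ri) / N
  if (r_w < 0.45) {
    warn("pooled concentration is low (r < 0.45); the F approximation may be poor")
  }
  kappa <- a1inv(r_w)
  K <- 1 + 3 / (8 * kappa)
  Fstat <- K * ((N - k) * (sum(Ri) - R)) / ((k - 1) * (N - sum(Ri)))
  Fstat <- max(0, Fstat)
  tibble(statistic = Fstat, df1 = k - 1, df2 = N - k,
         p.value = pf(Fstat, k - 1, N - k, lower.tail = FALSE),
         kappa = kappa, r_bar = r_w)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; used to build synthetic phase samples for
#' validating the circular tests.
#'
#' @param n number of draws.
#' @param mu mean direction, degrees.
#' @param kappa concentration (>= 0).
#' @return Angles in degrees in (-180, 180].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(runif(n, -180, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + rr * z) / (rr + z)
      cc <- kappa * (rr - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        theta <- sign(u[3] - 0.5) * acos(f)
        out[i] <- theta
        break
      }
    }
  }
  ang <- (out * 180 / pi + mu)
  ang <- ((ang + 180) %% 360) - 180
  ifelse(ang == -180, 180, ang)
}
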
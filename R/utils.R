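# Internal helpers shared across modules.

#' @importFrom rlang abort .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

abort_input <- function(msg) abort(msg, class = c("pdbshape_error_input", "pdbshape_error"))
abort_empty <- function(msg) abort(msg, class = c("pdbshape_error_empty", "pdbshape_error"))
abort_contract <- function(msg) abort(msg, class = c("pdbshape_error_contract", "pdbshape_error"))
abort_notfound <- function(msg) abort(msg, class = c("pdbshape_error_notfound", "pdbshape_error"))

# round-half-up ("commercial" rounding); base round() is half-even
round_half_up <- function(x) floor(x + 0.5)

coords_matrix <- function(structure) {
  as.matrix(structure[, c("x", "y", "z")])
}

#' Convert HSL color coordinates to an RGB triple
#'
#' Hue in degrees (any real, wrapped to \[0, 360)), saturation and
#' lightness in \[0, 1\]. Returns values in \[0, 1\].
#'
#' @param h,s,l numeric vectors of equal length.
#' @return a matrix with columns `r`, `g`, `b` in \[0, 1\].
#' @keywords internal
hsl_to_rgb <- function(h, s, l) {
  h <- ((h %% 360) + 360) %% 360
  c1 <- (1 - abs(2 * l - 1)) * s
  hp <- h / 60
  x <- c1 * (1 - abs(hp %% 2 - 1))
  m <- l - c1 / 2
  r <- g <- b <- numeric(length(h))
  seg <- floor(hp) %% 6
  r <- ifelse(seg %in% c(0, 5), c1, ifelse(seg %in% c(1, 4), x, 0))
  g <- ifelse(seg %in% c(1, 2), c1, ifelse(seg %in% c(0, 3), x, 0))
  b <- ifelse(seg %in% c(3, 4), c1, ifelse(seg %in% c(2, 5), x, 0))
  cbind(r = r + m, g = g + m, b = b + m)
}

# deterministic uniformly distributed rotation matrix (det +1)
random_rotation <- function(seed = NULL) {
  rot <- function() {
    m <- matrix(stats::rnorm(9), 3, 3)
    qr_ <- qr(m)
    q <- qr.Q(qr_)
    d <- sign(diag(qr.R(qr_)))
    q <- q %*% diag(d)
    if (det(q) < 0) q[, 3] <- -q[, 3]
    q
  }
  if (is.null(seed)) rot() else withr::with_seed(seed, rot())
}

# apply a rigid-body transform to the coordinate columns of a structure
transform_structure <- function(structure, rotation = diag(3), translation = c(0, 0, 0)) {
  p <- coords_matrix(structure) %*% t(rotation)
  structure$x <- p[, 1] + translation[1]
  structure$y <- p[, 2] + translation[2]
  structure$z <- p[, 3] + translation[3]
  structure
}
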
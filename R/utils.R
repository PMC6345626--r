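#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm rnorm runif rbinom sd var coef kmeans median quantile
#' @importFrom utils head tail read.csv write.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib osteoscaffold, .registration = TRUE
NULL

## Deterministic child seeds: one user-facing seed fans out to per-stage
## streams so stages are independently reproducible. Kept below 2^31.
child_seed <- function(seed, stage, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 2654435.0 + h * 97.0 + k * 1013.0) %% 2147483629)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Rotation matrix about z then y such that the unit direction
## (sin t cos p, sin t sin p, cos t) maps onto +z.
rotation_to_z <- function(phi_deg, theta_deg) {
  p <- phi_deg * pi / 180
  t <- theta_deg * pi / 180
  Rz <- matrix(c(cos(-p), -sin(-p), 0,
                 sin(-p),  cos(-p), 0,
                 0,        0,       1), 3, 3, byrow = TRUE)
  a <- -t
  Ry <- matrix(c(cos(a), 0, sin(a),
                 0,      1, 0,
                 -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
  Ry %*% Rz
}

direction_from_angles <- function(phi_deg, theta_deg) {
  p <- phi_deg * pi / 180
  t <- theta_deg * pi / 180
  c(sin(t) * cos(p), sin(t) * sin(p), cos(t))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
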
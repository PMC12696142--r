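#' Build a single-shell diffusion acquisition scheme
#'
#' Gradient directions are distributed approximately uniformly on the sphere
#' with a spherical Fibonacci lattice, then rotated by a seeded random
#' rotation so different seeds give different (but reproducible) schemes.
#' The default matches a common clinical single-shell protocol: 55
#' directions at b = 2,000 s/mm^2 plus one b = 0 volume.
#'
#' @param n_directions Number of diffusion-weighted directions (>= 6).
#' @param b_value Shell b-value in s/mm^2.
#' @param n_b0 Number of non-weighted (b = 0) volumes (>= 1).
#' @param seed Integer seed for the orienting rotation.
#' @return A `diffusion_scheme`: list with `bvals` (length n_b0 +
#'   n_directions) and `bvecs` (matrix, one unit row per volume; zero rows
#'   for b = 0).
#' @export
make_diffusion_scheme <- function(n_directions = 55, b_value = 2000,
                                  n_b0 = 1, seed = 0) {
  if (n_directions < 6) abort("`n_directions` must be at least 6.")
  if (n_b0 < 1) abort("`n_b0` must be at least 1.")
  if (b_value <= 0) abort("`b_value` must be positive.")
  dirs <- fibonacci_sphere(n_directions)
  dirs <- dirs %*% t(random_rotation(seed))
  bvals <- c(rep(0, n_b0), rep(b_value, n_directions))
  bvecs <- rbind(matrix(0, n_b0, 3), dirs)
  structure(list(bvals = bvals, bvecs = bvecs), class = "diffusion_scheme")
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  golden <- pi * (1 + sqrt(5))
  theta <- golden * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

random_rotation <- function(seed) {
  r <- local_rng(seed)
  # QR of a Gaussian matrix gives a Haar-ish random orthogonal matrix
  m <- matrix(r$norm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Seeded RNG stream that does not disturb the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    get(".Random.seed", globalenv())
  })
  draw <- function(fn, n, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn(n, ...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(norm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
       unif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
       int  = function(n, max) draw(function(k, mx) sample.int(mx, k, replace = TRUE), n, max))
}

#' @export
print.diffusion_scheme <- function(x, ...) {
  b <- unique(x$bvals[x$bvals > 0])
  cat(sprintf("<diffusion_scheme> %d volumes: %d b=0, %d weighted at b = %s s/mm^2\n",
              length(x$bvals), sum(x$bvals == 0), sum(x$bvals > 0),
              paste(b, collapse = ", ")))
  invisible(x)
}

validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "diffusion_scheme"))
  w <- scheme$bvals > 0
  if (sum(!w) < 1) abort("Scheme must include at least one b = 0 volume.")
  nrm <- sqrt(rowSums(scheme$bvecs[w, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    abort("Weighted directions must be unit vectors (tolerance 1e-6).")
  }
  invisible(scheme)
}
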
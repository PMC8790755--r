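#' @include accessors.R
NULL

# Evaluate code under a local RNG state seeded by `seed`; the caller's RNG
# stream is untouched. seed = NULL evaluates in the current stream.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Derived child seed for sub-tasks, kept within 32-bit integer range.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

# Uniform random unit vector.
.randomUnitVector <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# Uniform random rotation matrix (quaternion method, Shoemake).
.randomRotationMatrix <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  .quatToMatrix(q)
}

.quatToMatrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Rotation by angle theta about unit axis u (Rodrigues).
.axisAngleMatrix <- function(u, theta) {
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

.coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])

.setCoords <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

# Minimum heavy-atom distance between two coordinate sets.
.minPairDist <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Minimum protein-ligand heavy-atom distance of a complex
#' @param complex a [ComplexStructure].
#' @return distance in Angstrom.
#' @export
minContactDistance <- function(complex) {
  p <- proteinAtoms(complex); l <- ligandAtoms(complex)
  .minPairDist(.coords(p[p$heavy, , drop = FALSE]),
               .coords(l[l$heavy, , drop = FALSE]))
}
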
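#' Diffusion gradient scheme
#'
#' Bundle the scalar b-value with the table of unit gradient directions that
#' defines a DTI acquisition. The tensor has six unique elements, so at least
#' seven diffusion-weighted volumes are required for a determined fit.
#'
#' @param b_value Diffusion weighting in s/mm^2; must be positive.
#' @param directions Numeric matrix with one row per gradient (J x 3). Rows
#'   are renormalised to unit length; zero rows are rejected.
#' @return An object of class `gradient_scheme` with fields `b_value`,
#'   `directions` (J x 3, unit rows) and `J`.
#' @export
gradient_scheme <- function(b_value, directions) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L && nrow(directions) == 3L)
    directions <- t(directions)
  if (ncol(directions) != 3L)
    stop("gradient directions must be a J x 3 matrix")
  if (!is.numeric(b_value) || length(b_value) != 1L || b_value <= 0)
    stop("b_value must be a positive scalar (s/mm^2)")
  nrm <- sqrt(rowSums(directions^2))
  if (any(nrm < 1e-8))
    stop("zero-length gradient direction in table")
  directions <- directions / nrm
  dimnames(directions) <- NULL
  if (nrow(directions) < 7L)
    stop("at least 7 gradient directions are required to fit 6 tensor elements")
  structure(
    list(b_value = b_value, directions = directions, J = nrow(directions)),
    class = "gradient_scheme"
  )
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme> J = %d directions, b = %g s/mm^2\n",
              x$J, x$b_value))
  invisible(x)
}

#' Generate a gradient table by electrostatic repulsion
#'
#' Places `n` points on the unit sphere by minimising the Coulomb energy of
#' the antipodally symmetric point set (each direction and its negation repel
#' all others), the standard construction for DTI sampling schemes. The
#' optimisation is a fixed number of projected gradient-descent steps from a
#' seeded random start, so the table is deterministic given the seed.
#'
#' @param n Number of directions.
#' @param seed Integer seed for the random initialisation.
#' @param n_iter Descent iterations (default 300).
#' @return An n x 3 matrix of unit row vectors.
#' @export
gradient_table_repulsion <- function(n, seed = 1L, n_iter = 300L) {
  stopifnot(n >= 1)
  g <- withr_seed(seed, {
    m <- matrix(stats::rnorm(3L * n), ncol = 3L)
    m / sqrt(rowSums(m^2))
  })
  step <- 0.05
  for (it in seq_len(n_iter)) {
    frc <- matrix(0, n, 3L)
    for (i in seq_len(n)) {
      d <- g[rep(i, n), , drop = FALSE] - g        # repulsion from g_k
      d2 <- g[rep(i, n), , drop = FALSE] + g       # ... and from -g_k
      r1 <- rowSums(d^2);  r1[i] <- Inf
      r2 <- rowSums(d2^2)
      frc[i, ] <- colSums(d / (r1^1.5 + 1e-12)) + colSums(d2 / (r2^1.5 + 1e-12))
    }
    g <- g + step * frc
    g <- g / sqrt(rowSums(g^2))
    step <- step * 0.99
  }
  g
}

# Evaluate an expression under a temporary RNG state (local seed, restores
# the caller's .Random.seed).
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
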
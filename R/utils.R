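# Shared helpers: seed derivation, unit constants, RNG scoping.

# Avogadro's number; with volumes in um^3, concentration in mM is
# count / (volume_um3 * MM_PER_COUNT_UM3)
N_AVOGADRO <- 6.02214076e23
MM_DENOM <- 6.02214076e5 # N_A * 1e-15 L/um^3 / 1e3 (per mM)

#' Derive a reproducible sub-stream seed
#'
#' Maps a master seed plus any number of integer indices (condition, run,
#' module, ...) onto a deterministic seed in `[1, 2^31 - 2]` via iterated
#' Lehmer steps. Used throughout so that every environment realisation,
#' particle trajectory and Monte Carlo volume estimate in an experiment is
#' independently reproducible from the one master seed.
#'
#' @param master Master integer seed.
#' @param ... Integer indices identifying the sub-stream.
#' @return A single integer-valued seed.
#' @export
#' @examples
#' derive_seed(1, 2, 3)
derive_seed <- function(master, ...) {
  m <- 2147483647
  s <- as.double(master) %% m
  if (s <= 0) s <- s + m - 1
  for (k in c(...)) {
    s <- (s * 48271) %% m
    s <- (s + as.double(k)) %% m
    if (s == 0) s <- 1
  }
  s
}

# evaluate `expr` under a temporary R RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# extract an n x 3 numeric matrix of coordinates from a matrix or data frame
as_position_matrix <- function(positions) {
  if (is.data.frame(positions)) {
    stopifnot(all(c("x", "y", "z") %in% names(positions)))
    positions <- cbind(positions$x, positions$y, positions$z)
  }
  positions <- as.matrix(positions)
  stopifnot(is.numeric(positions), ncol(positions) == 3)
  positions
}

status_levels <- c("free", "bound", "retained", "escaped")

status_factor <- function(code) {
  factor(status_levels[code + 1L], levels = status_levels)
}
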
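# Internal helpers shared across modules.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Affine min-max rescale of a numeric array to [0, 1]; returns the scaled
# array plus the offset/scale needed to undo it. Constant input maps to 0.
rescale01 <- function(x) {
  lo <- min(x)
  hi <- max(x)
  if (hi <= lo) {
    list(x = array(0, dim = dim(x) %||% length(x)), lo = lo, scale = 1, constant = TRUE)
  } else {
    list(x = (x - lo) / (hi - lo), lo = lo, scale = hi - lo, constant = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reflect-pad a matrix by `r` pixels on every side.
reflect_pad <- function(m, r) {
  ny <- nrow(m)
  nx <- ncol(m)
  if (r >= ny || r >= nx) {
    stop("padding radius must be smaller than both image dimensions")
  }
  yi <- c(rev(seq_len(r) + 1L), seq_len(ny), ny - seq_len(r))
  xi <- c(rev(seq_len(r) + 1L), seq_len(nx), nx - seq_len(r))
  m[yi, xi, drop = FALSE]
}

# Boolean disc membership offsets for an ImageJ-style radius-r neighborhood
# (dy^2 + dx^2 <= r^2), returned as a (2r+1) x (2r+1) 0/1 kernel.
disc_kernel <- function(radius) {
  r <- as.integer(radius)
  stopifnot(r >= 1)
  d <- 2L * r + 1L
  off <- seq(-r, r)
  k <- outer(off^2, off^2, "+") <= radius^2
  storage.mode(k) <- "double"
  k
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name))
  }
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name))
  invisible(x)
}
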
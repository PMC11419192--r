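# Internal helpers shared across modules.

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
# All generators and training loops route their randomness through this so
# results are pure functions of (inputs, seed).
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
    set.seed(as.integer(seed))
  }
  force(code)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Rotate a matrix by a multiple of 90 degrees
#'
#' Exact pixel permutation (no interpolation). Positive `k` rotates clockwise;
#' four applications of `k = 1` are the identity.
#'
#' @param m A matrix.
#' @param k Integer number of clockwise quarter turns (may be negative).
#' @return The rotated matrix.
#' @export
rot90k <- function(m, k = 1L) {
  k <- ((as.integer(k) %% 4L) + 4L) %% 4L
  for (i in seq_len(k)) m <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  m
}

#' Mirror a matrix left-right
#'
#' Horizontal flip (columns reversed); an involution.
#'
#' @param m A matrix.
#' @return The flipped matrix.
#' @export
flip_horizontal <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

check_same_shape <- function(a, b, what = c("a", "b")) {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("`%s` (%s) and `%s` (%s) must have identical shapes",
                  what[1], paste(dim(a), collapse = "x"),
                  what[2], paste(dim(b), collapse = "x")))
  }
  invisible(TRUE)
}

is_binary <- function(m) all(m %in% c(0, 1))

as_binary_mask <- function(m, arg = "mask") {
  if (is.logical(m)) {
    storage.mode(m) <- "integer"
    return(m)
  }
  if (!is_binary(m)) {
    abort(sprintf("`%s` must be binary (values in {0, 1})", arg))
  }
  storage.mode(m) <- "integer"
  m
}

# Coerce a matrix / list of matrices / (H,W,C,N) array to a 4-d batch array.
as_batch4 <- function(x, arg = "x") {
  if (is.list(x)) {
    d <- dim(x[[1]])
    x <- array(unlist(x, use.names = FALSE), dim = c(d[1], d[2], 1L, length(x)))
  } else if (is.matrix(x)) {
    x <- array(x, dim = c(dim(x), 1L, 1L))
  } else if (is.array(x) && length(dim(x)) == 4L) {
    # already batched
  } else {
    abort(sprintf("`%s` must be a matrix, a list of matrices, or a 4-d array",
                  arg))
  }
  x
}
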
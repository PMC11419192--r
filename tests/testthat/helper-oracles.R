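# Independent brute-force oracles and small fixtures used across tests.
# These deliberately share no code with the implementation paths they check.

# Pixel-count oracles -----------------------------------------------------

oracle_dice <- function(a, b) {
  inter <- 0; sa <- 0; sb <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      sa <- sa + a[i, j]; sb <- sb + b[i, j]
      if (a[i, j] == 1 && b[i, j] == 1) inter <- inter + 1
    }
  }
  if (sa + sb == 0) return(1)
  2 * inter / (sa + sb)
}

oracle_iou <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (a[i, j] == 1 && b[i, j] == 1) inter <- inter + 1
      if (a[i, j] == 1 || b[i, j] == 1) uni <- uni + 1
    }
  }
  if (uni == 0) return(1)
  inter / uni
}

# Boundary band by exhaustive all-pairs distances; the image border counts
# as background (a virtual zero ring one pixel outside).
oracle_boundary_band <- function(m, d) {
  H <- nrow(m); W <- ncol(m)
  bg <- rbind(which(m == 0, arr.ind = TRUE),
              cbind(0, 0:(W + 1)), cbind(H + 1, 0:(W + 1)),
              cbind(1:H, 0), cbind(1:H, W + 1))
  band <- matrix(FALSE, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (m[i, j] == 1) {
        dist <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
        band[i, j] <- dist <= d
      }
    }
  }
  band
}

oracle_boundary_iou <- function(a, b, d) {
  oracle_iou(oracle_boundary_band(a, d) + 0L, oracle_boundary_band(b, d) + 0L)
}

# Recursive flood fill (on an explicit stack) for component labeling.
oracle_components <- function(m, connectivity = 8) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W); nxt <- 0L
  nb <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  for (si in seq_len(H)) {
    for (sj in seq_len(W)) {
      if (m[si, sj] == 1 && lab[si, sj] == 0L) {
        nxt <- nxt + 1L
        stack <- list(c(si, sj)); lab[si, sj] <- nxt
        while (length(stack)) {
          p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
          for (k in seq_len(nrow(nb))) {
            r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
            if (r >= 1 && r <= H && c >= 1 && c <= W &&
                m[r, c] == 1 && lab[r, c] == 0L) {
              lab[r, c] <- nxt
              stack[[length(stack) + 1]] <- c(r, c)
            }
          }
        }
      }
    }
  }
  lab
}

oracle_largest_component <- function(m, connectivity = 8) {
  lab <- oracle_components(m, connectivity)
  if (max(lab) == 0) return(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes == max(sizes))[1]
  out <- (lab == keep); storage.mode(out) <- "integer"
  out
}

# Enumeration of the branching recursion: with bifurcation certain at every
# step, a budget of b steps yields 1 + 2 * f(b - 1) segments (one step is
# consumed before each split).
oracle_full_binary_segments <- function(budget) {
  if (budget <= 1) return(1)
  1 + 2 * oracle_full_binary_segments(budget - 1)
}

# Fixtures -----------------------------------------------------------------

# A single straight horizontal vessel through the image center.
straight_tree <- function(size = 64, width = 3, margin = 10) {
  mid <- size / 2
  vessel_tree(
    segments = list(cbind(c(mid, mid), c(margin, size - margin))),
    widths = width, extent = c(size, size))
}

random_mask <- function(h = 16, w = 16, p = 0.35) {
  matrix(rbinom(h * w, 1, p), h, w)
}

tiny_patch_set <- function(masks, patch_size = NULL) {
  if (is.null(patch_size)) patch_size <- nrow(masks[[1]])
  sets <- lapply(seq_along(masks), function(i) {
    img <- matrix(0.5, nrow(masks[[i]]), ncol(masks[[i]]))
    extract_patches(annotated_image(img, masks[[i]], id = paste0("m", i)),
                    patch_size = patch_size)
  })
  bind_patches(sets)
}
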
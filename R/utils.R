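# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# world coordinates (mm) of all voxel centres of a grid, in raster order
# (x fastest), as an n x 3 matrix
voxel_centres <- function(dim, spacing, origin) {
  idx <- as.matrix(expand.grid(
    x = seq_len(dim[1]) - 1L,
    y = seq_len(dim[2]) - 1L,
    z = seq_len(dim[3]) - 1L
  ))
  sweep(sweep(idx, 2L, spacing, `*`), 2L, origin, `+`)
}

# 0-based voxel index containing a world position, with the tie convention
# that a position exactly on the boundary between voxels i and i+1 belongs
# to voxel i (the lower index). positions: n x 3 matrix. Returns n x 3
# integer matrix; rows outside the grid contain NA.
containing_voxel <- function(positions, dim, spacing, origin) {
  u <- sweep(sweep(positions, 2L, origin, `-`), 2L, spacing, `/`)
  idx <- ceiling(u - 0.5)
  for (k in 1:3) {
    bad <- idx[, k] < 0 | idx[, k] > dim[k] - 1L
    idx[bad, k] <- NA_integer_
  }
  bad_row <- rowSums(is.na(idx)) > 0L
  idx[bad_row, ] <- NA_integer_
  storage.mode(idx) <- "integer"
  idx
}

#' Exponent table of the third-order polynomial basis
#'
#' All 20 monomials x^a y^b z^c with a + b + c <= 3, in the fixed order used
#' by [fit_background_polynomial()] and by the phantom's
#' \code{background_coef} argument.
#'
#' @param order maximum total degree (default 3).
#' @return integer matrix with columns a, b, c.
#' @export
polynomial_exponents <- function(order = 3L) {
  ex <- expand.grid(a = 0:order, b = 0:order, c = 0:order)
  ex <- ex[rowSums(ex) <= order, , drop = FALSE]
  ex <- ex[order(rowSums(ex), ex$a, ex$b, ex$c), , drop = FALSE]
  rownames(ex) <- NULL
  as.matrix(ex)
}

# design matrix of scaled monomials at positions (n x 3, already scaled to
# roughly [-1, 1])
polynomial_design <- function(scaled_pos, exponents) {
  n <- nrow(scaled_pos)
  X <- matrix(1, n, nrow(exponents))
  for (j in seq_len(nrow(exponents))) {
    e <- exponents[j, ]
    col <- rep(1, n)
    if (e[1] > 0) col <- col * scaled_pos[, 1]^e[1]
    if (e[2] > 0) col <- col * scaled_pos[, 2]^e[2]
    if (e[3] > 0) col <- col * scaled_pos[, 3]^e[3]
    X[, j] <- col
  }
  colnames(X) <- apply(exponents, 1L, function(e)
    paste0("x", e[1], "y", e[2], "z", e[3]))
  X
}

# label connected components of a 3-D logical array under 6-connectivity;
# returns an integer array (0 = background)
label_components <- function(mask) {
  dim3 <- dim(mask)
  lab <- array(0L, dim3)
  nvox <- prod(dim3)
  strides <- c(1L, dim3[1], dim3[1] * dim3[2])
  idx_all <- which(mask)
  if (length(idx_all) == 0L) return(lab)
  current <- 0L
  # decode linear index -> 0-based (i,j,k)
  decode <- function(lin) {
    lin0 <- lin - 1L
    i <- lin0 %% dim3[1]
    j <- (lin0 %/% dim3[1]) %% dim3[2]
    k <- lin0 %/% (dim3[1] * dim3[2])
    cbind(i, j, k)
  }
  for (start in idx_all) {
    if (lab[start] != 0L) next
    current <- current + 1L
    frontier <- start
    lab[frontier] <- current
    while (length(frontier) > 0L) {
      ijk <- decode(frontier)
      nb <- integer(0)
      for (ax in 1:3) {
        for (d in c(-1L, 1L)) {
          ok <- ijk[, ax] + d >= 0L & ijk[, ax] + d <= dim3[ax] - 1L
          if (!any(ok)) next
          nb <- c(nb, frontier[ok] + d * strides[ax])
        }
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- current
      frontier <- nb
    }
  }
  lab
}
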
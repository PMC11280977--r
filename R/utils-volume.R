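# Low-level voxel-grid helpers shared by the phantom, ROI and feature code.
# All grids are plain 3-D arrays; voxel centers sit at (index - 1) * spacing
# (mm), so the origin voxel center is at 0 on every axis.

gaussian_kernel <- function(sigma_mm, step_mm) {
  r <- max(1L, as.integer(ceiling(3 * sigma_mm / step_mm)))
  k <- dnorm(seq(-r, r) * step_mm, sd = sigma_mm)
  k / sum(k)
}

# Separable Gaussian smoothing with replicate padding at the edges.
smooth_gaussian <- function(a, sigma_mm, spacing_mm) {
  if (sigma_mm <= 0) return(a)
  dims <- dim(a)
  for (ax in 1:3) {
    if (dims[ax] == 1L) next
    k <- gaussian_kernel(sigma_mm, spacing_mm[ax])
    if (length(k) == 1L) next
    r <- (length(k) - 1L) / 2L
    n <- dims[ax]
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(a, perm), nrow = n)
    mp <- rbind(
      m[rep(1L, r), , drop = FALSE],
      m,
      m[rep(n, r), , drop = FALSE]
    )
    sm <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      sm <- sm + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    }
    a <- aperm(array(sm, dims[perm]), order(perm))
  }
  a
}

# Squared Euclidean distance (mm^2) from every voxel to the nearest source
# voxel, exact, with anisotropic spacing.
edt_squared <- function(sources, spacing_mm) {
  dims <- dim(sources)
  out <- .edt_squared_cpp(as.logical(sources), as.integer(dims),
                          as.numeric(spacing_mm))
  array(out, dims)
}

# Signed Euclidean distance to the mask boundary: negative inside, positive
# outside, in mm. Thresholding at 0 recovers the mask exactly.
signed_distance <- function(mask, spacing_mm) {
  sqrt(edt_squared(mask, spacing_mm)) - sqrt(edt_squared(!mask, spacing_mm))
}

# Largest 6-connected component of a binary array. Index-based breadth-first
# flood fill: neighbour offsets are applied to the linear indices of the
# current front, with coordinate guards against wrapping across grid edges.
largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  dims <- dim(mask)
  nx <- dims[1]
  nxy <- dims[1] * dims[2]
  remaining <- which(mask)
  in_mask <- mask
  best <- integer(0)
  while (length(remaining)) {
    comp <- integer(0)
    front <- remaining[1]
    visited <- in_mask
    visited[] <- FALSE
    visited[front] <- TRUE
    while (length(front)) {
      comp <- c(comp, front)
      i0 <- front - 1L
      x <- i0 %% nx
      y <- (i0 %/% nx) %% dims[2]
      z <- i0 %/% nxy
      nbr <- c(front[x > 0] - 1L, front[x < nx - 1L] + 1L,
               front[y > 0] - nx, front[y < dims[2] - 1L] + nx,
               front[z > 0] - nxy, front[z < dims[3] - 1L] + nxy)
      nbr <- unique(nbr[in_mask[nbr] & !visited[nbr]])
      visited[nbr] <- TRUE
      front <- nbr
    }
    if (length(comp) > length(best)) best <- comp
    remaining <- setdiff(remaining, comp)
    in_mask[comp] <- FALSE
  }
  out <- mask
  out[] <- FALSE
  out[best] <- TRUE
  out
}

# Dice similarity coefficient between two binary masks.
#' Dice similarity coefficient
#'
#' Spatial overlap between two binary masks of identical shape:
#' `2 |A ∩ B| / (|A| + |B|)`.
#'
#' @param a,b Logical arrays of identical dimensions.
#' @return A number in `[0, 1]`; `NaN` when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Dimensions of the resampling grid covering the same physical extent.
resample_grid_dims <- function(dims, spacing_mm, target_mm) {
  extent <- (dims - 1) * spacing_mm
  pmax(1L, as.integer(floor(extent / target_mm + 1e-9)) + 1L)
}

ax_interp <- function(x, n) {
  if (n == 1L) {
    return(list(i0 = rep(1L, length(x)), i1 = rep(1L, length(x)),
                w = rep(0, length(x))))
  }
  i0 <- pmin(n - 1L, pmax(1L, as.integer(floor(x))))
  w <- pmin(1, pmax(0, x - i0))
  list(i0 = i0, i1 = i0 + 1L, w = w)
}

# Resample a volume onto an axis-aligned grid with the requested spacing.
# Target voxel centers sit at (j - 1) * target_mm, so resampling onto the
# native spacing is the identity. "linear" = trilinear interpolation with NA
# propagation restricted to corners that actually carry weight; "nearest" =
# nearest-neighbour (used for masks).
resample_volume <- function(a, spacing_mm, target_mm,
                            method = c("linear", "nearest")) {
  method <- match.arg(method)
  dims <- dim(a)
  nd <- resample_grid_dims(dims, spacing_mm, target_mm)
  idx <- lapply(1:3, function(ax) {
    (seq_len(nd[ax]) - 1) * target_mm[ax] / spacing_mm[ax] + 1
  })
  g <- expand.grid(x = seq_len(nd[1]), y = seq_len(nd[2]), z = seq_len(nd[3]))
  if (method == "nearest") {
    ii <- lapply(1:3, function(ax) {
      pmin(dims[ax], pmax(1L, as.integer(round(idx[[ax]]))))
    })
    v <- a[cbind(ii[[1]][g$x], ii[[2]][g$y], ii[[3]][g$z])]
    return(array(v, nd))
  }
  X <- ax_interp(idx[[1]], dims[1])
  Y <- ax_interp(idx[[2]], dims[2])
  Z <- ax_interp(idx[[3]], dims[3])
  xw <- X$w[g$x]; yw <- Y$w[g$y]; zw <- Z$w[g$z]
  v <- numeric(nrow(g))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wi <- (if (cx) xw else 1 - xw) *
          (if (cy) yw else 1 - yw) *
          (if (cz) zw else 1 - zw)
    ind <- cbind(
      if (cx) X$i1[g$x] else X$i0[g$x],
      if (cy) Y$i1[g$y] else Y$i0[g$y],
      if (cz) Z$i1[g$z] else Z$i0[g$z]
    )
    term <- wi * a[ind]
    term[wi == 0] <- 0
    v <- v + term
  }
  array(v, nd)
}
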
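#' @include AllClasses.R
NULL

## Evaluate expr under a local RNG state; the caller's stream is untouched.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

## Derive a sub-seed from a master seed and a stage label, kept < 2^31.
.subSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

## ---- grid helpers -------------------------------------------------------

## Cell centers in row-major order (row 1 = top). Returns matrix [x, y].
.cellCenters <- function(geom) {
  cs <- geom@cellSize
  xs <- geom@xmin + (seq_len(geom@ncol) - 0.5) * cs
  ys <- geom@ymax - (seq_len(geom@nrow) - 0.5) * cs
  cbind(x = rep(xs, times = geom@nrow), y = rep(ys, each = geom@ncol))
}

## Row-major cell index from matrix row/col.
.cellFromRowCol <- function(geom, row, col) (row - 1L) * geom@ncol + col

.rowColFromCell <- function(geom, cell) {
  cell <- as.integer(cell)
  row <- (cell - 1L) %/% geom@ncol + 1L
  col <- (cell - 1L) %% geom@ncol + 1L
  cbind(row = row, col = col)
}

## Cell index containing projected coordinates; NA outside the grid.
.cellFromXY <- function(geom, x, y) {
  col <- floor((x - geom@xmin) / geom@cellSize) + 1
  row <- floor((geom@ymax - y) / geom@cellSize) + 1
  ok <- col >= 1 & col <= geom@ncol & row >= 1 & row <= geom@nrow
  out <- rep(NA_integer_, length(x))
  out[ok] <- .cellFromRowCol(geom, as.integer(row[ok]), as.integer(col[ok]))
  out
}

## Matrix value lookup by row-major cell index.
.valueAtCell <- function(mat, geom, cell) {
  rc <- .rowColFromCell(geom, cell)
  mat[cbind(rc[, "row"], rc[, "col"])]
}

## ---- Gaussian field smoothing ------------------------------------------

## Separable Gaussian convolution with edge renormalization; NA-free input
## assumed. sigma in cell units; sigma <= 0 returns the input unchanged.
.gaussianSmooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  sm1 <- function(m) {  # smooth down the rows (i.e. along each column)
    acc <- matrix(0, nrow(m), ncol(m))
    wgt <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      s <- j - half - 1L
      src <- seq_len(nrow(m)) + s
      ok <- src >= 1L & src <= nrow(m)
      acc[ok, ] <- acc[ok, ] + k[j] * m[src[ok], , drop = FALSE]
      wgt[ok, ] <- wgt[ok, ] + k[j]
    }
    acc / wgt
  }
  t(sm1(t(sm1(mat))))
}

## Lag-1 spatial autocorrelation of a matrix field (rook neighbors),
## a cheap Moran's-I-like diagnostic used by the generator tests.
.lag1Correlation <- function(mat) {
  h <- stats::cor(as.vector(mat[, -ncol(mat)]), as.vector(mat[, -1]))
  v <- stats::cor(as.vector(mat[-nrow(mat), ]), as.vector(mat[-1, ]))
  mean(c(h, v))
}

## ---- planar geometry ----------------------------------------------------

## Distance from points (px, py) to one segment (x0,y0)-(x1,y1).
.pointSegmentDistance <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x0)^2 + (py - y0)^2))
  t <- ((px - x0) * dx + (py - y0) * dy) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
}

## Length of one segment clipped to a disc of radius r centered at (cx, cy).
.segmentLengthInCircle <- function(x0, y0, x1, y1, cx, cy, r) {
  dx <- x1 - x0; dy <- y1 - y0
  fx <- x0 - cx; fy <- y0 - cy
  a <- dx * dx + dy * dy
  if (a == 0) return(0)
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx * fx + fy * fy - r * r
  disc <- b * b - 4 * a * cc
  if (disc <= 0) return(0)
  sq <- sqrt(disc)
  t1 <- max(0, (-b - sq) / (2 * a))
  t2 <- min(1, (-b + sq) / (2 * a))
  if (t2 <= t1) return(0)
  (t2 - t1) * sqrt(a)
}

## Row-wise softmax of a matrix of linear predictors.
.softmax <- function(eta) {
  m <- apply(eta, 1, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

## Standardize columns; returns list(x, center, scale); zero-sd columns
## get scale 1 so they standardize to 0.
.standardize <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}
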
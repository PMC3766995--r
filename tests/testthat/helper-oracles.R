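# Independent oracles used across the test files. These deliberately avoid
# the package's own algorithms: components come from igraph on the pixel
# adjacency graph, perimeters from explicit edge enumeration, the plane fit
# from normal equations, and GP trees from a scalar recursive interpreter.

# number of connected components of TRUE pixels under 4- or 8-connectivity
oracle_components <- function(mask, connectivity = 8) {
  idx <- which(mask)
  if (length(idx) == 0L) return(0L)
  nr <- nrow(mask)
  nc <- ncol(mask)
  r <- ((idx - 1L) %% nr) + 1L
  cl <- ((idx - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0L)
  to <- integer(0L)
  for (o in offs) {
    r2 <- r + o[1L]
    c2 <- cl + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    from <- c(from, idx[ok])
    to <- c(to, (c2[ok] - 1L) * nr + r2[ok])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(idx)))
  igraph::components(g)$no
}

# Euler characteristic by the labeling definition: 8-connected foreground
# components minus 4-connected background components not touching the
# exterior (counted on the background-padded complement).
oracle_euler <- function(mask) {
  padded <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  n_fg <- oracle_components(mask, 8)
  n_bg <- oracle_components(!padded, 4)
  holes <- n_bg - 1L   # the exterior is one component thanks to the pad ring
  n_fg - holes
}

# boundary length by explicit enumeration of the 4 edges of every fg pixel
oracle_contour <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  total <- 0L
  at <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!mask[r, c]) next
      total <- total + (!at(r - 1L, c)) + (!at(r + 1L, c)) +
        (!at(r, c - 1L)) + (!at(r, c + 1L))
    }
  }
  total
}

# least-squares plane fit via explicit normal equations
oracle_plane_residuals <- function(hm) {
  nr <- nrow(hm)
  nc <- ncol(hm)
  col_idx <- rep(0:(nc - 1L), each = nr)
  row_idx <- rep(0:(nr - 1L), times = nc)
  X <- cbind(1, col_idx, row_idx)
  beta <- solve(t(X) %*% X, t(X) %*% as.vector(hm))
  matrix(as.vector(hm) - X %*% beta, nr, nc)
}

# scalar recursive-descent interpreter for GP trees, independent of the
# package's vectorized evaluator
oracle_eval_tree <- function(node, fv) {
  if (node$kind == "const") return(node$value)
  if (node$kind == "feat") return(unname(fv[[node$name]]))
  vals <- lapply(node$args, oracle_eval_tree, fv = fv)
  a <- vals[[1L]]
  b <- if (length(vals) > 1L) vals[[2L]] else NULL
  switch(node$name,
         NOT = !a,
         AND = a && b,
         OR = a || b,
         XOR = sum(c(a, b)) == 1L,
         LT = a < b, LE = a <= b, GT = a > b, GE = a >= b,
         ADD = a + b, SUB = a - b, MUL = a * b,
         PDIV = if (abs(b) < 1e-12) 1 else a / b)
}

oracle_classify <- function(tree, fv) {
  if (isTRUE(oracle_eval_tree(tree, fv))) "gradeIV" else "gradeII"
}

# binary image with two disjoint 8-connected objects jointly enclosing four
# 4-connected interior holes: a block with three single-pixel holes and an
# annulus with one 2x2 hole
two_objects_four_holes_mask <- function() {
  m <- matrix(FALSE, 20L, 20L)
  m[2:10, 2:10] <- TRUE
  m[4, 4] <- FALSE
  m[4, 8] <- FALSE
  m[8, 4] <- FALSE
  m[13:18, 13:18] <- TRUE
  m[15:16, 15:16] <- FALSE
  m
}

rand_mask <- function(nr, nc, p) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# all 512 binary 3x3 images
all_3x3_masks <- function() {
  lapply(0:511, function(code) {
    matrix(bitwAnd(bitwShiftR(code, 0:8), 1L) == 1L, 3L, 3L)
  })
}

# gray image from a matrix of integers, clipping to [0, 255]
as_gray <- function(m) {
  matrix(pmin(pmax(as.integer(round(m)), 0L), 255L), nrow(m), ncol(m))
}

# piecewise-linear curve through (x, y) anchor points sampled at t = 0..255
piecewise_curve <- function(x, y) {
  stats::approx(x, y, xout = 0:255, rule = 2)$y
}

# synthetic curve object with given euler / contour values (defaults zero)
make_curve <- function(id = "s", euler = numeric(256L),
                       contour = numeric(256L)) {
  minkowski_curve(id, area = rep(100, 256L), contour_length = contour,
                  euler = euler)
}
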
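#' Region adjacency graph with higher-order neighbour weights
#'
#' Builds the spatial weight matrix used for Moran's I from a first-order
#' adjacency matrix. With `order = 2` (the default) neighbours are the
#' pure second-order set: neighbours-of-neighbours excluding self and
#' excluding first-order neighbours. The weight matrix is row-standardized
#' (rows of non-isolated regions sum to 1); isolated regions keep
#' all-zero rows and are flagged.
#'
#' @param adjacency Symmetric 0/1 (or logical) adjacency matrix with zero
#'   diagonal and region names as dimnames.
#' @param order Neighbour order: 1 (the adjacency itself) or 2 (pure
#'   second order).
#' @return List of class `region_graph`: `regions`, `adjacency` (input),
#'   `neighbours` (order-selected 0/1 matrix), `w` (row-standardized),
#'   `isolated` (region names with no neighbours at this order).
#' @export
region_graph <- function(adjacency, order = 2) {
  a <- (as.matrix(adjacency) != 0) * 1
  if (nrow(a) != ncol(a) || any(a != t(a)) || any(diag(a) != 0)) {
    abort("adjacency must be symmetric with a zero diagonal.",
          class = "accel_argument_error")
  }
  regions <- rownames(a) %||% paste0("region_", seq_len(nrow(a)))
  dimnames(a) <- list(regions, regions)
  nb <- if (order == 1) a else if (order == 2) {
    a2 <- ((a %*% a) > 0) * 1
    diag(a2) <- 0
    a2 * (1 - a)  # pure second order: drop first-order neighbours
  } else {
    abort("`order` must be 1 or 2.", class = "accel_argument_error")
  }
  rs <- rowSums(nb)
  w <- nb / ifelse(rs == 0, 1, rs)
  structure(list(regions = regions, adjacency = a, neighbours = nb, w = w,
                 order = order, isolated = regions[rs == 0]),
            class = "region_graph")
}

#' First-order adjacency of the nine English regions
#'
#' Land-border adjacency of the nine Government Office Regions of
#' England (North East, North West, Yorkshire and the Humber, East
#' Midlands, West Midlands, East of England, London, South East, South
#' West), for use with [region_graph()].
#'
#' @return A 9 x 9 0/1 matrix.
#' @export
england_region_adjacency <- function() {
  regions <- c("North East", "North West", "Yorkshire and the Humber",
               "East Midlands", "West Midlands", "East of England",
               "London", "South East", "South West")
  a <- matrix(0, 9, 9, dimnames = list(regions, regions))
  link <- function(i, j) { a[i, j] <<- 1; a[j, i] <<- 1 }
  link("North East", "North West")
  link("North East", "Yorkshire and the Humber")
  link("North West", "Yorkshire and the Humber")
  link("North West", "East Midlands")
  link("North West", "West Midlands")
  link("Yorkshire and the Humber", "East Midlands")
  link("East Midlands", "West Midlands")
  link("East Midlands", "East of England")
  link("East Midlands", "South East")
  link("West Midlands", "South East")
  link("West Midlands", "South West")
  link("East of England", "London")
  link("East of England", "South East")
  link("London", "South East")
  link("South East", "South West")
  a
}

#' Moran's I spatial autocorrelation with a permutation test
#'
#' Computes Moran's I over a region weight matrix,
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}} \cdot
#'       \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2},}
#' with \eqn{z} the centred values, and a two-sided p-value from seeded
#' random permutations of the values over regions (default 9999).
#'
#' @param values Numeric vector, one value per region (order matching
#'   the graph).
#' @param graph A [region_graph()] (or a bare weight matrix).
#' @param n_perm Number of permutations (>= 99).
#' @param seed Seed for the permutation draw.
#' @return Object of class `moran_test`: `I`, `expected` (-1/(n-1)),
#'   `p_value`, `n`, `n_perm`.
#' @export
morans_i <- function(values, graph, n_perm = 9999, seed = NULL) {
  w <- if (inherits(graph, "region_graph")) graph$w else as.matrix(graph)
  n <- length(values)
  if (n < 3L || nrow(w) != n) {
    abort("need >= 3 regions and a matching weight matrix.",
          class = "accel_argument_error")
  }
  z <- values - mean(values)
  if (all(z == 0)) {
    abort("Moran's I is undefined for constant values.",
          class = "accel_estimation_error")
  }
  s0 <- sum(w)
  i_stat <- function(zz) (n / s0) * sum(zz * (w %*% zz)) / sum(zz^2)
  i_obs <- i_stat(z)
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) i_stat(z[sample.int(n)]), numeric(1))
  })
  p_hi <- (1 + sum(perms >= i_obs)) / (n_perm + 1)
  p_lo <- (1 + sum(perms <= i_obs)) / (n_perm + 1)
  structure(list(I = i_obs, expected = -1 / (n - 1),
                 p_value = min(1, 2 * min(p_hi, p_lo)),
                 n = n, n_perm = n_perm),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Moran's I = %.3f (expected %.3f under no autocorrelation), permutation p = %.3f (%d regions, %d permutations)\n",
              x$I, x$expected, x$p_value, x$n, x$n_perm))
  invisible(x)
}
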
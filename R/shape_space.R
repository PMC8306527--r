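#' @useDynLib gcohort, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rgamma rpois sd median quantile cor optim
#' @importFrom utils read.csv write.csv head tail
NULL

# Default lattice: 4 axes, integer coordinates 0..9.
.default_bounds <- c(0L, 9L)

#' Construct a shape-space position
#'
#' Positions live on a 4-dimensional integer lattice. The Euclidean distance
#' between a B-cell position and an epitope's optimal position encodes BCR
#' affinity (see [affinity()]).
#'
#' @param coords integer vector of length 4.
#' @param bounds length-2 integer vector, inclusive per-axis range.
#' @return an integer vector of class `shape_position`.
#' @export
shape_position <- function(coords, bounds = .default_bounds) {
  if (length(coords) != 4L) {
    stop("a shape-space position has exactly 4 coordinates, got ",
         length(coords))
  }
  coords <- as.integer(coords)
  if (anyNA(coords)) stop("shape-space coordinates must be integer-valued")
  if (any(coords < bounds[1]) || any(coords > bounds[2])) {
    stop("shape-space coordinates must lie within [", bounds[1], ", ",
         bounds[2], "]")
  }
  structure(coords, class = "shape_position")
}

#' Construct an epitope
#'
#' An epitope is a predefined optimal position in shape space together with
#' its abundance fraction, i.e. the proportion of the total antigen on FDCs
#' that displays this epitope.
#'
#' @param optimum coordinates of the optimal position (length 4).
#' @param abundance_fraction fraction of total antigen in `[0, 1]`.
#' @return a list of class `epitope`.
#' @export
epitope <- function(optimum, abundance_fraction = 1) {
  stopifnot(is.numeric(abundance_fraction), length(abundance_fraction) == 1L,
            abundance_fraction >= 0, abundance_fraction <= 1)
  structure(list(optimum = shape_position(optimum),
                 abundance_fraction = abundance_fraction),
            class = "epitope")
}

#' Construct and validate a panel of epitopes
#'
#' Abundance fractions must sum to 1, and "unrelated" epitopes must be at
#' least `min_separation` lattice steps apart (unrelated epitopes are placed
#' far from each other so that affinity to one implies negligible affinity to
#' the others).
#'
#' @param ... `epitope` objects.
#' @param min_separation minimum pairwise distance between optima.
#' @return a list of class `epitope_panel`.
#' @export
epitope_panel <- function(..., min_separation = 6) {
  eps <- list(...)
  if (length(eps) == 1L && is.list(eps[[1]]) && !inherits(eps[[1]], "epitope")) {
    eps <- eps[[1]]
  }
  if (!length(eps)) stop("at least one epitope is required")
  if (!all(vapply(eps, inherits, logical(1), "epitope"))) {
    stop("all elements must be epitope objects")
  }
  fr <- vapply(eps, function(e) e$abundance_fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("epitope abundance fractions must sum to 1, got ", sum(fr))
  }
  if (length(eps) > 1L) {
    for (i in seq_along(eps)[-length(eps)]) {
      for (j in (i + 1L):length(eps)) {
        d <- sqrt(sum((as.numeric(eps[[i]]$optimum) -
                       as.numeric(eps[[j]]$optimum))^2))
        if (d < min_separation) {
          stop("epitopes ", i, " and ", j, " are only ", round(d, 2),
               " lattice steps apart (min ", min_separation, ")")
        }
      }
    }
  }
  structure(eps, class = "epitope_panel")
}

#' Default single-epitope panel
#'
#' One epitope with its optimum at the lattice centre.
#' @export
default_epitopes <- function() {
  epitope_panel(epitope(c(5, 5, 5, 5), 1))
}

#' Three unrelated epitopes in unequal proportions
#'
#' Used by the multi-epitope founder-specificity scenario: three optima
#' pairwise more than 6 lattice steps apart, with abundances 0.6/0.3/0.1 so
#' that one epitope dominates and one is rare.
#'
#' @param fractions abundance fractions, length 3, summing to 1.
#' @export
three_epitope_panel <- function(fractions = c(0.6, 0.3, 0.1)) {
  stopifnot(length(fractions) == 3L)
  epitope_panel(
    epitope(c(2, 2, 2, 2), fractions[1]),
    epitope(c(7, 7, 2, 2), fractions[2]),
    epitope(c(2, 2, 7, 7), fractions[3])
  )
}

.optima_matrix <- function(epitopes) {
  do.call(rbind, lapply(epitopes, function(e) as.integer(e$optimum)))
}

.fractions <- function(epitopes) {
  vapply(epitopes, function(e) e$abundance_fraction, numeric(1))
}

#' BCR affinity from shape-space distance
#'
#' Affinity is a Gaussian kernel of the Euclidean distance `d` between the
#' B-cell position and the epitope optimum: `exp(-d^2 / gamma^2)`. It is 1 at
#' the optimum and decays smoothly with distance; `gamma` sets the width of
#' the affinity landscape.
#'
#' @param p a `shape_position` (or 4-vector of coordinates).
#' @param e an `epitope` (or 4-vector taken as the optimum).
#' @param gamma width of the Gaussian affinity kernel (lattice units).
#' @return affinity in `(0, 1]`.
#' @export
affinity <- function(p, e, gamma = 2.8) {
  p <- if (inherits(p, "shape_position")) as.numeric(p) else as.numeric(shape_position(p))
  opt <- if (inherits(e, "epitope")) as.numeric(e$optimum) else as.numeric(shape_position(e))
  d2 <- sum((p - opt)^2)
  exp(-d2 / gamma^2)
}

#' Multi-epitope affinity
#'
#' The operative affinity of a cell against a panel of unrelated epitopes is
#' the maximum of its per-epitope affinities.
#'
#' @param p a `shape_position`.
#' @param epitopes an `epitope_panel`.
#' @inheritParams affinity
#' @export
affinity_max <- function(p, epitopes, gamma = 2.8) {
  max(vapply(epitopes, function(e) affinity(p, e, gamma), numeric(1)))
}

#' Somatic hypermutation move
#'
#' With probability `mutation_prob`, shifts the position by one lattice step
#' along a single axis (direction and axis uniform over the 8 signed moves;
#' a move that would leave the lattice is redrawn). Otherwise the position is
#' returned unchanged.
#'
#' @param p a `shape_position`.
#' @param mutation_prob probability of a mutation per division.
#' @param bounds inclusive per-axis coordinate range.
#' @return a `shape_position`.
#' @export
mutate_position <- function(p, mutation_prob = 0.5, bounds = .default_bounds) {
  stopifnot(mutation_prob >= 0, mutation_prob <= 1)
  p <- shape_position(p, bounds)
  if (runif(1) >= mutation_prob) return(p)
  repeat {
    axis <- sample.int(4L, 1L)
    step <- if (runif(1) < 0.5) -1L else 1L
    new <- unclass(p)
    new[axis] <- new[axis] + step
    if (new[axis] >= bounds[1] && new[axis] <= bounds[2]) {
      return(shape_position(new, bounds))
    }
  }
}

# All lattice points within bounds, as an n x 4 integer matrix. 10^4 points
# with default bounds, so exhaustive enumeration is cheap.
.lattice_points <- function(bounds = .default_bounds) {
  ax <- bounds[1]:bounds[2]
  as.matrix(expand.grid(ax, ax, ax, ax, KEEP.OUT.ATTRS = FALSE))
}

#' Lattice shell around a position
#'
#' All lattice points whose Euclidean distance to `center`, rounded to the
#' nearest integer, equals `distance`.
#'
#' @param center a `shape_position`.
#' @param distance non-negative integer lattice distance.
#' @param bounds inclusive per-axis coordinate range.
#' @return integer matrix, one point per row.
#' @export
shell_points <- function(center, distance, bounds = .default_bounds) {
  center <- as.numeric(shape_position(center, bounds))
  pts <- .lattice_points(bounds)
  d <- sqrt(rowSums((pts - matrix(center, nrow(pts), 4, byrow = TRUE))^2))
  pts[round(d) == round(distance), , drop = FALSE]
}

#' Founder-cell specification
#'
#' Founder (seeder) B cells either carry random low-affinity receptors
#' (`mode = "random"`: uniform over lattice points at least
#' `min_distance_random` steps from every epitope optimum) or are specific to
#' one epitope (`mode = "epitope_specific"`: uniform over the lattice shell at
#' `distance_from_optimum` steps from that epitope's optimum).
#'
#' @param mode `"random"` or `"epitope_specific"`.
#' @param target_epitope index of the target epitope (epitope-specific mode).
#' @param distance_from_optimum lattice distance of epitope-specific founders
#'   from their target optimum.
#' @param min_distance_random minimum distance of random founders from every
#'   optimum (naive founders are low-affinity).
#' @return a list of class `founder_spec`.
#' @export
founder_spec <- function(mode = c("random", "epitope_specific"),
                         target_epitope = NULL,
                         distance_from_optimum = 2L,
                         min_distance_random = 5) {
  mode <- match.arg(mode)
  if (mode == "epitope_specific") {
    if (is.null(target_epitope)) {
      stop("epitope_specific founders require a target_epitope index")
    }
    stopifnot(distance_from_optimum >= 0)
  }
  structure(list(mode = mode,
                 target_epitope = target_epitope,
                 distance_from_optimum = distance_from_optimum,
                 min_distance_random = min_distance_random),
            class = "founder_spec")
}

#' Sample founder-cell positions
#'
#' @param spec a [founder_spec()].
#' @param epitopes an `epitope_panel`.
#' @param n number of founder positions to draw.
#' @param bounds inclusive per-axis coordinate range.
#' @return integer matrix with `n` rows (one position per row).
#' @export
sample_founders <- function(spec, epitopes, n = 1L, bounds = .default_bounds) {
  stopifnot(inherits(spec, "founder_spec"), length(epitopes) >= 1L, n >= 0)
  if (n == 0L) return(matrix(integer(0), 0, 4))
  if (spec$mode == "epitope_specific") {
    k <- spec$target_epitope
    if (k < 1L || k > length(epitopes)) {
      stop("target_epitope index ", k, " out of range")
    }
    shell <- shell_points(epitopes[[k]]$optimum, spec$distance_from_optimum,
                          bounds)
    if (!nrow(shell)) {
      stop("no lattice point at distance ", spec$distance_from_optimum,
           " from the target optimum")
    }
    shell[sample.int(nrow(shell), n, replace = TRUE), , drop = FALSE]
  } else {
    pts <- .lattice_points(bounds)
    keep <- rep(TRUE, nrow(pts))
    for (e in epitopes) {
      opt <- as.numeric(e$optimum)
      d <- sqrt(rowSums((pts - matrix(opt, nrow(pts), 4, byrow = TRUE))^2))
      keep <- keep & (d >= spec$min_distance_random)
    }
    pool <- pts[keep, , drop = FALSE]
    if (!nrow(pool)) {
      stop("no lattice point at distance >= ", spec$min_distance_random,
           " from all optima")
    }
    pool[sample.int(nrow(pool), n, replace = TRUE), , drop = FALSE]
  }
}
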
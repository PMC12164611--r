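#' Canonical movement behaviour labels
#'
#' The five parts of the 24-hour movement composition in the canonical
#' reporting order used throughout the package: sedentary time (SED), light
#' (LPA), moderate (MPA) and vigorous (VPA) physical activity, and sleep.
#'
#' @return Character vector of length five.
#' @export
#' @examples
#' movement_parts()
movement_parts <- function() {
  c("SED", "LPA", "MPA", "VPA", "Sleep")
}

# Coerce a vector or matrix of part durations to a one-row-per-individual
# matrix with part labels as column names. Unnamed input is assumed to be in
# the given part order.
as_part_matrix <- function(x, parts = NULL) {
  if (is.null(dim(x))) {
    nm <- names(x)
    x <- matrix(as.numeric(x), nrow = 1L)
    colnames(x) <- nm
  } else {
    x <- as.matrix(x)
  }
  if (is.null(colnames(x))) {
    if (is.null(parts)) {
      parts <- if (ncol(x) == 5L) movement_parts() else paste0("p", seq_len(ncol(x)))
    }
    colnames(x) <- parts
  }
  storage.mode(x) <- "double"
  x
}

#' Close a composition to a constant total
#'
#' Rescales strictly positive part durations so they sum to `total`
#' (1440 minutes for a full day). Closure preserves all ratios between
#' parts, which is the only information a composition carries.
#'
#' @param values Numeric vector of part durations, or a matrix with one row
#'   per individual and one column per part.
#' @param total Closure constant in the same units as `values` (default
#'   1440, the minutes in a day).
#' @return Object of the same shape as `values`, with parts summing to
#'   `total` (to within floating point) in each row.
#' @export
#' @examples
#' close_composition(c(SED = 3, LPA = 7), total = 100)
close_composition <- function(values, total = 1440) {
  if (length(values) == 0L) stop("empty composition", call. = FALSE)
  if (length(total) != 1L || !is.finite(total) || total <= 0) {
    stop("`total` must be a single positive number", call. = FALSE)
  }
  vec <- is.null(dim(values))
  x <- as_part_matrix(values)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("all parts must be strictly positive; apply zero_replace() first",
         call. = FALSE)
  }
  out <- x / rowSums(x) * total
  if (vec) stats::setNames(drop(out), colnames(x)) else out
}

#' Replace zero parts before log-ratio analysis
#'
#' Log-ratio transforms are undefined at zero, and zero vigorous-activity
#' days are certain in paediatric accelerometer data. Two strategies are
#' offered: `"fixed_floor"` sets each zero to `floor` and leaves the other
#' parts untouched (the caller re-closes afterwards), while
#' `"multiplicative"` sets zeros to `floor` and shrinks the non-zero parts
#' proportionally so the row total is preserved exactly.
#'
#' @param values Non-negative numeric vector or matrix of part durations.
#' @param strategy `"fixed_floor"` (default) or `"multiplicative"`.
#' @param floor Replacement value in minutes (default 0.5).
#' @return Strictly positive object of the same shape as `values`.
#' @export
#' @examples
#' zero_replace(c(300, 300, 30, 0, 600), floor = 0.5)
#' zero_replace(c(0, 100), strategy = "multiplicative", floor = 1)
zero_replace <- function(values, strategy = c("fixed_floor", "multiplicative"),
                         floor = 0.5) {
  strategy <- match.arg(strategy)
  if (length(values) == 0L) stop("empty composition", call. = FALSE)
  if (floor <= 0) stop("`floor` must be positive", call. = FALSE)
  vec <- is.null(dim(values))
  x <- as_part_matrix(values)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("parts must be finite and non-negative", call. = FALSE)
  }
  if (any(rowSums(x > 0) == 0L)) {
    stop("composition with all parts zero cannot be replaced", call. = FALSE)
  }
  zero <- x == 0
  if (any(zero)) {
    if (strategy == "fixed_floor") {
      x[zero] <- floor
    } else {
      tot <- rowSums(x)
      nz <- rowSums(zero)
      scale <- (tot - nz * floor) / tot
      if (any(scale <= 0)) {
        stop("`floor` too large for multiplicative replacement", call. = FALSE)
      }
      x <- x * scale
      x[zero] <- floor
    }
  }
  if (vec) stats::setNames(drop(x), colnames(x)) else x
}

#' Compositional centre of a sample
#'
#' Part-wise geometric mean across individuals, re-closed to the common
#' total. This is the compositional centre: the point whose ILR
#' coordinates are the arithmetic mean of the sample's ILR coordinates.
#'
#' @param x Matrix of strictly positive compositions, one row per
#'   individual, columns as parts.
#' @param total Closure constant (default 1440 minutes).
#' @return Named numeric vector, one entry per part, summing to `total`.
#' @export
geometric_mean_composition <- function(x, total = 1440) {
  x <- as_part_matrix(x)
  if (nrow(x) == 0L) stop("empty collection of compositions", call. = FALSE)
  if (any(x <= 0)) stop("all parts must be strictly positive", call. = FALSE)
  gm <- exp(colMeans(log(x)))
  close_composition(gm, total = total)
}

#' Centred log-ratio transform
#'
#' `clr(x)_i = ln(x_i) - mean_j ln(x_j)`; maps a D-part composition to a
#' zero-sum vector in real space. Mostly useful as the ambient space in
#' which ILR bases are orthonormal.
#'
#' @param x Strictly positive composition vector or matrix.
#' @return Same shape as `x`; rows sum to zero.
#' @export
clr_transform <- function(x) {
  vec <- is.null(dim(x))
  m <- as_part_matrix(x)
  if (any(m <= 0)) stop("all parts must be strictly positive", call. = FALSE)
  lx <- log(m)
  out <- lx - rowMeans(lx)
  if (vec) stats::setNames(drop(out), colnames(m)) else out
}

# Build the (D-1) x D pivot contrast matrix for parts in the given order.
# Row i contrasts part i against the geometric mean of parts i+1..D:
#   V[i, i]   =  sqrt((D - i) / (D - i + 1))
#   V[i, j>i] = -sqrt(1 / ((D - i) * (D - i + 1)))
# Rows are orthonormal and each sums to zero.
pivot_contrast <- function(D) {
  V <- matrix(0, nrow = D - 1L, ncol = D)
  for (i in seq_len(D - 1L)) {
    r <- D - i
    V[i, i] <- sqrt(r / (r + 1))
    V[i, (i + 1L):D] <- -sqrt(1 / (r * (r + 1)))
  }
  V
}

#' Pivot-coordinate ILR basis
#'
#' Builds the isometric log-ratio basis in which the first coordinate is
#' the pivot balance of `first_part` against the geometric mean of all
#' remaining parts, with coefficient `sqrt((D-1)/D)` on the log of the
#' pivot part. One such rotated basis per behaviour is what lets a single
#' "coefficient of the behaviour" be reported from a compositional
#' regression.
#'
#' @param first_part Label of the pivot part.
#' @param parts All part labels; `first_part` must be among them. The
#'   remaining parts keep their order in `parts` (default the canonical
#'   movement behaviours).
#' @return An `ilr_basis` object: list with `part_order` (pivot first) and
#'   `contrast`, the (D-1) x D orthonormal contrast matrix with columns
#'   named by `part_order`.
#' @export
#' @examples
#' pivot_basis("VPA")
pivot_basis <- function(first_part, parts = movement_parts()) {
  if (anyDuplicated(parts)) stop("duplicate part labels", call. = FALSE)
  if (length(first_part) != 1L || !first_part %in% parts) {
    stop("`first_part` must be exactly one of `parts`", call. = FALSE)
  }
  if (length(parts) < 2L) stop("need at least two parts", call. = FALSE)
  part_order <- c(first_part, setdiff(parts, first_part))
  V <- pivot_contrast(length(parts))
  colnames(V) <- part_order
  structure(list(part_order = part_order, contrast = V), class = "ilr_basis")
}

#' @export
print.ilr_basis <- function(x, ...) {
  cat("ILR pivot basis:", x$part_order[1], "vs {",
      paste(x$part_order[-1], collapse = ", "), "}\n")
  print(round(x$contrast, 4))
  invisible(x)
}

check_basis_parts <- function(x, basis) {
  if (is.null(colnames(x)) && ncol(x) == length(basis$part_order)) {
    colnames(x) <- basis$part_order
  }
  missing <- setdiff(basis$part_order, colnames(x))
  if (length(missing)) {
    stop("composition lacks parts: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x[, basis$part_order, drop = FALSE]
}

#' Isometric log-ratio transform
#'
#' Projects the centred log-ratio of a composition onto the orthonormal
#' contrasts of `basis`, yielding D-1 unconstrained coordinates suitable
#' for ordinary linear modelling. Parts are matched to the basis by name
#' when named.
#'
#' @param x Strictly positive composition vector, or matrix with one row
#'   per individual.
#' @param basis An [pivot_basis()] object.
#' @return Numeric vector of length D-1, or an n x (D-1) matrix.
#' @export
ilr_transform <- function(x, basis) {
  vec <- is.null(dim(x))
  m <- as_part_matrix(x, parts = basis$part_order)
  m <- check_basis_parts(m, basis)
  if (any(m <= 0)) stop("all parts must be strictly positive", call. = FALSE)
  lx <- log(m)
  z <- (lx - rowMeans(lx)) %*% t(basis$contrast)
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  if (vec) drop(z) else z
}

#' Inverse isometric log-ratio transform
#'
#' Maps ILR coordinates back to a composition closed to `total`; the exact
#' right-inverse of [ilr_transform()] in the same basis.
#'
#' @param z Numeric vector of length D-1, or matrix with one row per
#'   individual.
#' @param basis The [pivot_basis()] used for the forward transform.
#' @param total Closure constant (default 1440 minutes).
#' @return Composition with parts in `basis$part_order`.
#' @export
ilr_inverse <- function(z, basis, total = 1440) {
  vec <- is.null(dim(z))
  zm <- if (vec) matrix(z, nrow = 1L) else as.matrix(z)
  D <- length(basis$part_order)
  if (ncol(zm) != D - 1L) {
    stop("expected ", D - 1L, " ILR coordinates, got ", ncol(zm), call. = FALSE)
  }
  clr <- zm %*% basis$contrast
  comp <- exp(clr)
  comp <- comp / rowSums(comp) * total
  colnames(comp) <- basis$part_order
  if (vec) stats::setNames(drop(comp), basis$part_order) else comp
}

#' Pairwise log-ratio variation matrix
#'
#' Entry (i, j) is the sample variance (n-1 denominator) of
#' `ln(x_i / x_j)` across individuals. Small entries indicate parts that
#' move together (high codependency); the matrix is symmetric with a zero
#' diagonal and non-negative entries by construction.
#'
#' @param x Matrix of strictly positive compositions, one row per
#'   individual.
#' @return D x D symmetric matrix with part labels as dimnames.
#' @export
variation_matrix <- function(x) {
  m <- as_part_matrix(x)
  if (nrow(m) < 2L) stop("need at least two compositions", call. = FALSE)
  if (any(m <= 0)) stop("all parts must be strictly positive", call. = FALSE)
  lx <- log(m)
  D <- ncol(lx)
  out <- matrix(0, D, D, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(D - 1L)) {
    for (j in (i + 1L):D) {
      v <- stats::var(lx[, i] - lx[, j])
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}
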
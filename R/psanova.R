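# PS-ANOVA basis for two-dimensional field-trial surfaces. The smooth
# surface f(r, c) is decomposed into a non-penalized part {1, r, c, rc} and
# five penalized blocks: a row smooth f1(r), a column smooth f2(c), two
# linear-by-smooth interactions h3(r)c and h4(c)r, and a smooth-by-smooth
# tensor block f5(r,c). Each penalized block is a cubic B-spline basis with
# a second-order difference penalty, rotated into its penalty eigenbasis so
# that it enters the mixed model as an i.i.d. random-effect design.

bspline_basis <- function(x, nseg, degree = 3) {
  xl <- min(x); xr <- max(x)
  dx <- (xr - xl) / nseg
  knots <- seq(xl - degree * dx, xr + degree * dx, by = dx)
  splines::splineDesign(knots, x, ord = degree + 1, outer.ok = TRUE)
}

# Mixed-model reparameterization of a penalized B-spline: returns the random
# design whose i.i.d. coefficients reproduce the second-order difference
# penalty; the penalty null space {1, x} is handled by the fixed part.
smooth_block <- function(x, nseg) {
  B <- bspline_basis(x, nseg)
  nb <- ncol(B)
  D <- diff(diag(nb), differences = 2)
  e <- eigen(crossprod(D), symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values)
  U <- e$vectors[, keep, drop = FALSE]
  Z <- B %*% U %*% diag(1 / sqrt(e$values[keep]), sum(keep))
  Z
}

#' Build the PS-ANOVA basis for a row-column layout
#'
#' Returns the fixed (non-penalized) design \code{X} with columns
#' \{1, r, c, rc\} on centered, scaled coordinates, and the five penalized
#' blocks of the surface decomposition, each already in mixed-model form
#' (i.i.d. coefficients).
#'
#' @param rows,cols integer plot coordinates (one entry per plot).
#' @param n_knots_r,n_knots_c number of B-spline segments per dimension;
#'   default one segment per two distinct positions, clamped to [5, 20].
#' @return list: \code{X} (n x 4), \code{Z} (named list of five matrices:
#'   row_smooth, col_smooth, row_smooth_by_col, col_smooth_by_row,
#'   smooth_by_smooth), plus the scaled coordinates.
#' @export
build_psanova_basis <- function(rows, cols, n_knots_r = NULL,
                                n_knots_c = NULL) {
  stop_if(length(unique(rows)) < 4 || length(unique(cols)) < 4,
          "need at least 4 distinct row and column positions")
  default_nseg <- function(x)
    max(5, min(20, floor(length(unique(x)) / 2)))
  n_knots_r <- n_knots_r %||% default_nseg(rows)
  n_knots_c <- n_knots_c %||% default_nseg(cols)
  stop_if(n_knots_r > length(unique(rows)) ||
            n_knots_c > length(unique(cols)),
          "knot count exceeds number of distinct coordinates")
  sc <- function(x) (x - mean(range(x))) / (diff(range(x)) / 2)
  r <- sc(rows); c_ <- sc(cols)
  Zr <- smooth_block(r, n_knots_r)
  Zc <- smooth_block(c_, n_knots_c)
  # row-wise tensor (Khatri-Rao) product for the smooth-by-smooth block
  Zrc <- Zr[, rep(seq_len(ncol(Zr)), each = ncol(Zc)), drop = FALSE] *
    Zc[, rep(seq_len(ncol(Zc)), times = ncol(Zr)), drop = FALSE]
  X <- cbind(intercept = 1, r = r, c = c_, rc = r * c_)
  list(X = X,
       Z = list(row_smooth = Zr,
                col_smooth = Zc,
                row_smooth_by_col = Zr * c_,
                col_smooth_by_row = Zc * r,
                smooth_by_smooth = Zrc),
       r = r, c = c_,
       n_knots = c(r = n_knots_r, c = n_knots_c))
}
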
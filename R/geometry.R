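# Rigid-body superposition, RMSD / radius-of-gyration series, and
# probability-density summaries of trajectory observables.

#' Time series of a trajectory observable
#'
#' @param times numeric, ns, strictly increasing.
#' @param values observable values; units given by `units`.
#' @param label observable label (e.g. "RMSD").
#' @param units unit string ("A" for RMSD/Rg, "A^2" for areas).
#' @return object of class `md_timeseries`.
#' @export
md_timeseries <- function(times, values, label = "", units = "") {
  stopifnot(length(times) == length(values))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label, units = units),
            class = "md_timeseries")
}

#' @export
print.md_timeseries <- function(x, ...) {
  cat(sprintf("md_timeseries '%s' (%s): %d frames, mean %.3f, sd %.3f\n",
              x$label, x$units, length(x$values), mean(x$values),
              stats::sd(x$values)))
  invisible(x)
}

#' @export
plot.md_timeseries <- function(x, ...) {
  plot(x$times, x$values, type = "l", xlab = "time (ns)",
       ylab = paste0(x$label, " (", x$units, ")"), ...)
  invisible(x)
}

#' Export a time series to TSV
#'
#' Two tab-separated columns, `time_ns` and `value_<units>`, with a
#' header naming the units.
#'
#' @param series an `md_timeseries`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_tsv <- function(series, path) {
  unit_tag <- gsub("[^A-Za-z0-9]+", "", series$units)
  df <- data.frame(time_ns = sprintf("%.6f", series$times),
                   value = sprintf("%.6f", series$values))
  names(df)[2] <- paste0("value_", unit_tag)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- superposition -------------------------------------------------------

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) least-squares deviation of `mobile` onto `reference`, via the
#' SVD of the weighted covariance matrix with the usual determinant
#' correction so reflections are never returned.
#'
#' @param mobile n x 3 coordinate matrix.
#' @param reference n x 3 coordinate matrix, same n.
#' @param weights optional per-atom weights (e.g. masses); default uniform.
#' @return list with `rotation` (3 x 3, det +1), `translation`
#'   (length 3) and `rmsd` (angstroms).  The superposed coordinates are
#'   `mobile %*% rotation + translation` (rows).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3 || nrow(reference) != n) {
    stop("superposition needs >= 3 paired points")
  }
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  # collinearity check: rank of the weighted mobile cloud
  sv_in <- svd(A * sqrt(w))$d
  if (sv_in[2] < 1e-8 * max(sv_in[1], 1)) {
    stop("degenerate (collinear) configuration: superposition undefined")
  }
  H <- t(A * w) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)   # rows of mobile right-multiply: A %*% R
  resid <- B - A %*% R
  msd <- sum(w * rowSums(resid^2))
  list(rotation = R,
       translation = as.numeric(cr - cm %*% R),
       rmsd = sqrt(max(msd, 0)))
}

# minimum RMSD over rigid motions for rank-deficient configurations
# (1 or 2 points, or collinear sets), where the SVD route is undefined:
# a rank-1 cloud can be rotated onto any axis, so the optimum aligns the
# weighted mixed moment vector v = sum_i w_i a_i b_i with itself, giving
# msd = sum w a^2 + sum w |b|^2 - 2 |v|
collinear_rmsd <- function(mobile, reference, w) {
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  sv <- svd(A * sqrt(w))
  a <- as.numeric(A %*% sv$v[, 1])   # signed coords along the single axis
  v <- colSums(B * (a * w))
  msd <- sum(w * a^2) + sum(w * rowSums(B^2)) - 2 * sqrt(sum(v^2))
  sqrt(max(msd, 0))
}

# dispatch: full-rank clouds go through Kabsch, degenerate ones through
# the closed-form axis fit
min_rmsd <- function(mobile, reference, weights = NULL) {
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  if (n >= 3) {
    A <- sweep(mobile, 2, colSums(mobile * w))
    sv <- svd(A * sqrt(w))$d
    if (sv[2] >= 1e-8 * max(sv[1], 1)) {
      return(kabsch_superpose(mobile, reference, weights)$rmsd)
    }
  }
  if (n == 1) return(0)
  collinear_rmsd(mobile, reference, w)
}

#' RMSD time series against a reference structure
#'
#' For each frame, the selected atoms are superposed onto the same atoms
#' of the reference by [kabsch_superpose()] and the minimum RMSD is
#' recorded.  The conventional default selection is C-alpha atoms with
#' uniform weights.
#'
#' @param traj an `md_trajectory`.
#' @param reference reference `md_structure`; default the topology at
#'   frame 1 coordinates (the trajectory's own first frame).
#' @param selection selection string or `md_selection`; default
#'   `"calpha"` (falls back to `"all"` when the topology has no CA atoms).
#' @param weights `"uniform"` or `"mass"`.
#' @return an [md_timeseries()] labelled "RMSD", units angstrom.
#' @export
rmsd_series <- function(traj, reference = NULL, selection = NULL,
                        weights = c("uniform", "mass")) {
  weights <- match.arg(weights)
  top <- traj$topology
  if (is.null(selection)) {
    selection <- if (any(top$atoms$name == "CA")) "calpha" else "all"
  }
  sel <- as_selection(top, selection)
  if (!length(sel$indices)) stop("RMSD selection is empty")
  if (is.null(reference)) {
    reference <- set_coords(top, frame_coords(traj, 1))
  }
  rsel <- as_selection(reference, sel$label)
  if (length(rsel$indices) != length(sel$indices)) {
    stop("selection resolves to ", length(sel$indices),
         " atoms in the trajectory but ", length(rsel$indices),
         " in the reference")
  }
  w <- if (weights == "mass") {
    m <- top$atoms$mass[sel$indices]
    if (anyNA(m)) stop("mass weighting requested but masses are missing")
    m
  } else NULL
  ref_xyz <- coords(reference)[rsel$indices, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    m <- traj$coords[sel$indices, , f, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    min_rmsd(m, ref_xyz, w)
  }, numeric(1))
  md_timeseries(traj$times, vals, label = "RMSD", units = "A")
}

## ---- radius of gyration --------------------------------------------------

#' Radius of gyration of one coordinate set
#'
#' `Rg = sqrt( sum_i w_i ||r_i - rbar||^2 / sum_i w_i )` with `rbar` the
#' weighted centroid.
#'
#' @param xyz n x 3 coordinate matrix (angstroms).
#' @param weights optional per-point weights (masses); default uniform.
#' @return Rg in angstroms (0 for a single point).
#' @export
radius_of_gyration <- function(xyz, weights = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("expected an n x 3 coordinate matrix")
  n <- nrow(xyz)
  stopifnot(n >= 1)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  ctr <- colSums(xyz * w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Radius-of-gyration time series
#'
#' @param traj an `md_trajectory`.
#' @param selection selection string or `md_selection`; default `"all"`
#'   (solvent and ions, if present, can be dropped with `"protein"`).
#' @param weights `"uniform"` or `"mass"`.
#' @return an [md_timeseries()] labelled "Rg", units angstrom.
#' @export
rg_series <- function(traj, selection = "all",
                      weights = c("uniform", "mass")) {
  weights <- match.arg(weights)
  sel <- as_selection(traj$topology, selection)
  if (!length(sel$indices)) stop("Rg selection is empty")
  w <- if (weights == "mass") {
    m <- traj$topology$atoms$mass[sel$indices]
    if (anyNA(m)) stop("mass weighting requested but masses are missing")
    m
  } else NULL
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    radius_of_gyration(traj$coords[sel$indices, , f], w)
  }, numeric(1))
  md_timeseries(traj$times, vals, label = "Rg", units = "A")
}

## ---- probability densities -----------------------------------------------

#' Probability density of an observable series
#'
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth
#' (the default), or a histogram density.  The returned density is
#' renormalized so its trapezoidal integral over the grid is 1 within 1%.
#' A constant series cannot support a KDE; it falls back to a narrow
#' histogram around the single value, with a warning.
#'
#' @param series an `md_timeseries` or a numeric vector.
#' @param method `"kde"` or `"histogram"`.
#' @param bandwidth KDE bandwidth override (same units as the values).
#' @param bins histogram bin count (default Sturges).
#' @param n_grid grid size for the KDE evaluation.
#' @return object of class `md_density`: list with `grid`, `density`,
#'   `bandwidth`, `method`.
#' @export
probability_density <- function(series, method = c("kde", "histogram"),
                                bandwidth = NULL, bins = NULL,
                                n_grid = 512) {
  method <- match.arg(method)
  x <- if (inherits(series, "md_timeseries")) series$values else
    as.numeric(series)
  if (length(x) < 2) stop("need at least 2 values for a density estimate")
  if (method == "kde" && length(unique(x)) < 2) {
    warning("constant series: falling back to a narrow histogram")
    method <- "histogram"
  }
  if (method == "kde") {
    bw <- if (is.null(bandwidth)) stats::bw.nrd0(x) else bandwidth
    d <- stats::density(x, bw = bw, n = n_grid)
    grid <- d$x; dens <- d$y
  } else {
    rng <- range(x)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(1e-6, abs(rng[1]) * 1e-6)
    nb <- if (is.null(bins)) max(1L, nclass.Sturges(x)) else bins
    h <- hist(x, breaks = seq(rng[1], rng[2], length.out = nb + 1),
              plot = FALSE)
    grid <- h$mids; dens <- h$density
    bw <- diff(h$breaks[1:2])
  }
  integral <- trapz(grid, dens)
  if (integral <= 0) stop("degenerate density estimate")
  dens <- dens / integral
  structure(list(grid = grid, density = dens, bandwidth = bw,
                 method = method),
            class = "md_density")
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' @export
print.md_density <- function(x, ...) {
  cat(sprintf("md_density (%s, bw %.4g): %d grid points, integral %.4f\n",
              x$method, x$bandwidth, length(x$grid),
              trapz(x$grid, x$density)))
  invisible(x)
}

#' Export a density estimate to TSV
#' @param dens an `md_density`.
#' @param path output path.
#' @param units unit string for the grid column header.
#' @return `path`, invisibly.
#' @export
write_density_tsv <- function(dens, path, units = "") {
  unit_tag <- gsub("[^A-Za-z0-9]+", "", units)
  df <- data.frame(grid = sprintf("%.6f", dens$grid),
                   density = sprintf("%.8f", dens$density))
  if (nzchar(unit_tag)) names(df)[1] <- paste0("grid_", unit_tag)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
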
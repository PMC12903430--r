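#' Construct a conformer point cloud
#'
#' A weighted 3-D point set standing in for a simulation snapshot of a
#' macromolecule: one point per atom (or bead) with a positive mass
#' weight.
#'
#' @param points Numeric matrix with 3 columns (x, y, z) or something
#'   coercible to one.
#' @param weights Per-point masses; default uniform.
#' @param unit Length unit label, `"A"` (Angstrom) or `"nm"`; recorded,
#'   not converted.
#' @return An object of class `"conformer_cloud"`.
#' @export
conformer_cloud <- function(points, weights = NULL, unit = "A") {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns", call. = FALSE)
  if (nrow(points) < 1L) stop("cloud must contain at least one point",
                              call. = FALSE)
  if (!is.numeric(points) || anyNA(points))
    stop("points must be numeric and free of NAs", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(points))
  if (length(weights) != nrow(points))
    stop("need one weight per point", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be > 0", call. = FALSE)
  structure(list(points = unname(points), weights = as.numeric(weights),
                 unit = unit), class = "conformer_cloud")
}

#' @export
print.conformer_cloud <- function(x, ...) {
  cat("<conformer_cloud> ", nrow(x$points), " points [", x$unit, "], Rg ",
      round(radius_of_gyration(x), 3), ", Rmax ", round(r_max(x), 3),
      "\n", sep = "")
  invisible(x)
}

#' Radius of gyration of a point cloud
#'
#' The square root of the mass-weighted mean of the squared distances of
#' all points from their centre of mass.  Invariant under rigid rotation
#' and translation; for points uniformly filling a ball of radius R it
#' converges to sqrt(3/5) R.
#'
#' @param cloud A [conformer_cloud()].
#' @return Length in the cloud's unit.
#' @examples
#' radius_of_gyration(conformer_cloud(rbind(c(0, 0, 0), c(2, 0, 0))))  # 1
#' @export
radius_of_gyration <- function(cloud) {
  stopifnot(inherits(cloud, "conformer_cloud"))
  w <- cloud$weights / sum(cloud$weights)
  com <- colSums(cloud$points * w)
  d2 <- rowSums(sweep(cloud$points, 2, com)^2)
  sqrt(sum(w * d2))
}

#' Maximal radius of a point cloud
#'
#' The largest Euclidean distance of any point from the unweighted centre
#' of geometry.  For compact, spherical molecules this estimates the
#' molecular radius; note the deliberate contrast with
#' [radius_of_gyration()], which uses the mass-weighted centre of mass.
#'
#' @param cloud A [conformer_cloud()].
#' @return Length in the cloud's unit; always >= the radius of gyration.
#' @export
r_max <- function(cloud) {
  stopifnot(inherits(cloud, "conformer_cloud"))
  cog <- colMeans(cloud$points)
  sqrt(max(rowSums(sweep(cloud$points, 2, cog)^2)))
}

#' Shape factor rho = Rg / Rh
#'
#' The ratio of the radius of gyration to the hydrodynamic (solvodynamic)
#' radius.  A uniform hard sphere gives sqrt(3/5) = 0.775; elongated or
#' solvent-drained structures push rho above that, compact globules with
#' mass concentrated towards the centre push it below.
#'
#' @param r_g Radius of gyration (> 0).
#' @param r_h Hydrodynamic radius (> 0), same unit.
#' @return The ratio, with a `"classification"` attribute comparing it to
#'   the hard-sphere reference.
#' @examples
#' shape_factor(2.3, 3.0)
#' hard_sphere_rho()   # 0.7746
#' @export
shape_factor <- function(r_g, r_h) {
  if (any(r_g <= 0) || any(r_h <= 0))
    stop("r_g and r_h must be > 0", call. = FALSE)
  rho <- r_g / r_h
  cls <- ifelse(rho > hard_sphere_rho() + 0.05, "elongated/flexible",
         ifelse(rho < hard_sphere_rho() - 0.05, "compact (dense core)",
                "globular (hard-sphere-like)"))
  attr(rho, "classification") <- cls
  rho
}

#' Hard-sphere reference value of the shape factor
#'
#' @return sqrt(3/5), approximately 0.775.
#' @export
hard_sphere_rho <- function() sqrt(3 / 5)

# CODATA Boltzmann constant, J/K (exact since the 2019 SI)
.k_B <- 1.380649e-23

#' Stokes-Einstein conversion between D and Rh
#'
#' `D = k_B T / (6 pi eta R_h)` for a sphere of hydrodynamic radius
#' `R_h` diffusing in a solvent of viscosity `eta` at temperature `T`.
#' Supply exactly one of `D` or `r_h` and the function returns the other.
#' Temperature and viscosity carry no defaults: they are properties of
#' the experiment, not of the model.
#'
#' @param D Diffusion coefficient in m^2/s.
#' @param r_h Hydrodynamic radius in m.
#' @param temperature Absolute temperature in K.
#' @param viscosity Dynamic viscosity in Pa s.
#' @return The missing quantity (m^2/s or m).
#' @examples
#' stokes_einstein(r_h = 1e-9, temperature = 298.15, viscosity = 0.543e-3)
#' @export
stokes_einstein <- function(D = NULL, r_h = NULL, temperature, viscosity) {
  if (temperature <= 0 || viscosity <= 0)
    stop("temperature and viscosity must be > 0", call. = FALSE)
  if (is.null(D) == is.null(r_h))
    stop("supply exactly one of D or r_h", call. = FALSE)
  known <- if (is.null(D)) r_h else D
  if (any(known <= 0)) stop("D and r_h must be > 0", call. = FALSE)
  .k_B * temperature / (6 * pi * viscosity * known)
}

#' Log-log scaling exponent of diffusion versus atom count
#'
#' For structurally related macromolecules the diffusion coefficient
#' follows an approximate power law in the number of atoms N,
#' `D = a N^b`; the exponent b is the slope of the log-log plot.
#' Fitted by unweighted ordinary least squares on (log N, log D), natural
#' logarithms.
#'
#' @param records A data.frame with columns `N` (atom count) and `D`
#'   (diffusion coefficient), at least 3 rows with distinct N.
#' @return A list with `slope`, `slope_se`, `intercept`, `intercept_se`,
#'   `r_squared` and the underlying `fit` (an `lm` object).
#' @examples
#' rec <- gen_diffusion_series(b = -0.29, prefactor = 4e-9,
#'                             N = c(2000, 8000, 26000), sigma = 0)
#' scaling_exponent(rec)$slope   # -0.29
#' @export
scaling_exponent <- function(records) {
  if (!all(c("N", "D") %in% names(records)))
    stop("records must have columns N and D", call. = FALSE)
  if (nrow(records) < 3L)
    stop("need at least 3 records", call. = FALSE)
  if (length(unique(records$N)) < 3L)
    stop("need at least 3 distinct N values", call. = FALSE)
  if (any(records$N < 1) || any(records$D <= 0))
    stop("N must be >= 1 and D > 0", call. = FALSE)
  fit <- stats::lm(log(D) ~ log(N), data = records)
  # zero-noise generator data fits perfectly; the "essentially perfect
  # fit" note from summary.lm is expected there, not a defect
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(slope = unname(stats::coef(fit)[2L]),
       slope_se = sm$coefficients[2L, 2L],
       intercept = unname(stats::coef(fit)[1L]),
       intercept_se = sm$coefficients[1L, 2L],
       r_squared = sm$r.squared,
       fit = fit)
}

#' Number- and weight-average molar mass and dispersity
#'
#' `M_n = sum(n M) / sum(n)`, `M_w = sum(n M^2) / sum(n M)`,
#' dispersity `D = M_w / M_n` (>= 1, with equality only for a
#' monodisperse population).
#'
#' @param mass Molar masses of the species.
#' @param abundance Number abundances (>= 0, at least one positive).
#' @return A list with `Mn`, `Mw`, `dispersity`.
#' @examples
#' mn_mw_dispersity(c(100, 200), c(1, 1))   # Mn 150, Mw 166.7, D 1.111
#' @export
mn_mw_dispersity <- function(mass, abundance) {
  stopifnot(length(mass) == length(abundance))
  if (any(abundance < 0)) stop("abundances must be >= 0", call. = FALSE)
  if (all(abundance == 0)) stop("at least one abundance must be positive",
                                call. = FALSE)
  if (any(mass <= 0)) stop("molar masses must be > 0", call. = FALSE)
  mn <- sum(abundance * mass) / sum(abundance)
  mw <- sum(abundance * mass^2) / sum(abundance * mass)
  list(Mn = mn, Mw = mw, dispersity = mw / mn)
}
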
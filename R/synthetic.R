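# Seeded generators for every data shape the analysis stages consume.
# All noise is multiplicative log-normal (the modelled quantities are
# strictly positive); sigma = 0 reduces every generator to its closed
# form, and a fixed seed makes reruns bit-identical.  Generators restore
# the caller's RNG state.

# evaluate `expr` under a local RNG seed without disturbing the caller's
# stream; distinct `stream` strings fan one global seed out into
# independent substreams
with_local_seed <- function(seed, stream, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  offset <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  set.seed((as.integer(seed) + offset * 10007L) %% .Machine$integer.max)
  expr
}

#' Generate a noisy batch-filtration mass series
#'
#' Emulates the per-cycle impurity record of a purification run: under
#' the constant-transmission model the retained mass after cycle i is
#' `m0 f^(r i)`, and measurement noise multiplies each value by
#' `exp(sigma Z)`, Z standard normal.
#'
#' @param r True transmission.
#' @param f Volume reduction factor per cycle.
#' @param cycles Number of cycles.
#' @param m0 Initial mass.
#' @param sigma Log-normal noise scale (0.05 emulates NMR-grade
#'   quantification; 0 gives the exact geometric decay).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return Numeric vector of length `cycles + 1` (cycle 0 first).
#' @examples
#' gen_filtration_series(0.17, cycles = 6, sigma = 0)
#' @export
gen_filtration_series <- function(r, f = 0.1, cycles = 10, m0 = 1,
                                  sigma = 0.05, seed = NULL) {
  if (r < 0) stop("r must be >= 0", call. = FALSE)
  if (f <= 0 || f >= 1) stop("f must lie in (0, 1)", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  clean <- m0 * f^(r * (0:cycles))
  if (sigma == 0) return(clean)
  with_local_seed(seed, "filtration",
                  clean * exp(sigma * stats::rnorm(cycles + 1L)))
}

#' Generate a power-law diffusion series
#'
#' Emulates a diffusion-NMR dataset: `D = prefactor * N^b` with
#' multiplicative log-normal noise.  Three atom counts per series mirror
#' a homolayered generation ladder.
#'
#' @param b True scaling exponent (negative: larger molecules diffuse
#'   more slowly).
#' @param prefactor Prefactor a in `D = a N^b` (m^2/s at N = 1).
#' @param N Atom counts of the perfect structures.
#' @param sigma Log-normal noise scale.
#' @param seed Integer seed.
#' @return A data.frame with columns `label`, `N`, `D`.
#' @examples
#' gen_diffusion_series(-0.29, 4e-9, c(2000, 8000, 26000), sigma = 0)
#' @export
gen_diffusion_series <- function(b, prefactor, N, sigma = 0.02,
                                 seed = NULL) {
  if (prefactor <= 0) stop("prefactor must be > 0", call. = FALSE)
  if (any(N < 1)) stop("N must be >= 1", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  d <- prefactor * N^b
  if (sigma > 0)
    d <- with_local_seed(seed, "diffusion",
                         d * exp(sigma * stats::rnorm(length(N))))
  data.frame(label = paste0("N", N), N = N, D = d, stringsAsFactors = FALSE)
}

#' Generate a uniform-ball point cloud
#'
#' Samples points uniformly inside a sphere of radius R by the
#' radial-CDF method: direction from a normalised standard-normal
#' triple, radius `R * U^(1/3)` so the volume element is uniform.  The
#' cloud's radius of gyration converges to `sqrt(3/5) R`, the hard-sphere
#' reference geometry.
#'
#' @param R Ball radius (> 0).
#' @param n_points Number of points (>= 1).
#' @param seed Integer seed.
#' @param unit Length unit label for the cloud.
#' @return A [conformer_cloud()] with uniform weights.
#' @examples
#' radius_of_gyration(gen_sphere_cloud(1, 1e4, seed = 1))  # ~0.775
#' @export
gen_sphere_cloud <- function(R, n_points, seed = NULL, unit = "A") {
  if (R <= 0) stop("R must be > 0", call. = FALSE)
  if (n_points < 1) stop("n_points must be >= 1", call. = FALSE)
  pts <- with_local_seed(seed, "sphere", {
    dir <- matrix(stats::rnorm(3 * n_points), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    rad <- R * stats::runif(n_points)^(1 / 3)
    dir * rad
  })
  conformer_cloud(pts, unit = unit)
}

#' Generate a binomial end-group defect ensemble
#'
#' Emulates the species population a mass spectrum of a capped dendrimer
#' samples: each molecule independently misses `k ~ Binomial(N_PG, p)`
#' caps, its mass descending the defect ladder by k cap masses.  At the
#' sub-1% defect levels seen in practice the resulting dispersity is
#' barely above 1.
#'
#' @param spec A [dendrimer_spec()] in ammonium form.
#' @param p_missing Per-site probability that a cap is missing, in
#'   `[0, 1)`.
#' @param n_molecules Ensemble size.
#' @param seed Integer seed.
#' @return A data.frame with columns `missing_caps`, `mass` (average
#'   mass, g/mol) and `abundance` (molecule counts), one row per distinct
#'   defect count.
#' @examples
#' sp <- parse_dendrimer_name("G2-6-6-N")
#' gen_defect_ensemble(sp, 0.01, 1000, seed = 1)
#' @export
gen_defect_ensemble <- function(spec, p_missing, n_molecules = 1e4,
                                seed = NULL) {
  stopifnot(inherits(spec, "dendrimer_spec"))
  if (p_missing < 0 || p_missing >= 1)
    stop("p_missing must lie in [0, 1)", call. = FALSE)
  if (n_molecules < 1) stop("n_molecules must be >= 1", call. = FALSE)
  n_pg <- peripheral_group_count(spec)
  k <- with_local_seed(seed, "defects",
                       stats::rbinom(n_molecules, n_pg, p_missing))
  tab <- table(k)
  kk <- as.integer(names(tab))
  perfect <- average_mass(spec)
  cap_mass <- average_mass(spec$cap$composition)
  data.frame(missing_caps = kk,
             mass = perfect - kk * cap_mass,
             abundance = as.integer(tab))
}
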
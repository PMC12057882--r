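#' Configuration for the synthetic oasis-desert landscape generator
#'
#' Bundles every knob of the synthetic data generators: a concentric
#' NDVI field (oasis core fading into desert), a multi-epoch categorical
#' land-use series driven by a known Markov transition matrix, and a
#' driver table with planted effects on the ecological risk response.
#'
#' The defaults describe a 20 km x 20 km arid-zone scene (200 x 200 cells
#' of 100 m): an NDVI peak of 0.6 at the oasis centre decaying
#' exponentially so that all three belts (oasis >= 0.30, transition
#' 0.10-0.30, desert <= 0.10) are present, seven land-use classes with
#' diagonal-dominant decadal dynamics, and nine risk drivers of which the
#' two accessibility measures (distance to towns and to roads) carry the
#' signal.
#'
#' @param grid_shape integer vector `(rows, cols)` of the cell grid.
#' @param cellsize cell side in metres.
#' @param seed integer seed; every generator derives its own sub-stream
#'   from it, so partial regeneration is stable.
#' @param oasis_center `(row, col)` of the NDVI peak; default grid centre.
#' @param v0 NDVI at the oasis centre.
#' @param radial_decay exponential decay rate of NDVI per cell of distance
#'   from the centre (must be > 0).
#' @param noise_sd standard deviation of additive NDVI noise (>= 0).
#' @param n_classes number of land-use classes.
#' @param class_names class labels, length `n_classes`.
#' @param markov_P row-stochastic `n_classes` x `n_classes` transition
#'   matrix applied per decade.
#' @param initial_shares class shares of the first epoch (sums to 1);
#'   default is an oasis-city mix dominated by cropland, low-cover
#'   grassland and unused land.
#' @param n_epochs number of land-use epochs to generate (>= 2).
#' @param driver_effects named numeric vector of linear effects of the nine
#'   drivers on the synthetic risk response; zero-effect drivers are pure
#'   noise.
#' @param driver_noise_sd standard deviation of the Gaussian noise added to
#'   the driver response.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(grid_shape = c(200L, 200L),
                             cellsize = 100,
                             seed = 1L,
                             oasis_center = NULL,
                             v0 = 0.6,
                             radial_decay = 0.02,
                             noise_sd = 0.03,
                             n_classes = 7L,
                             class_names = default_landuse_classes(),
                             markov_P = default_markov_matrix(),
                             initial_shares = default_initial_shares(),
                             n_epochs = 4L,
                             driver_effects = default_driver_effects(),
                             driver_noise_sd = 0.1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 2L || any(grid_shape <= 0L) ||
      any(is.na(grid_shape)))
    stop("`grid_shape` must be two positive integers", call. = FALSE)
  if (is.null(oasis_center))
    oasis_center <- (grid_shape + 1) / 2
  if (!is.numeric(radial_decay) || any(radial_decay <= 0))
    stop("`radial_decay` must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (n_epochs < 2L) stop("`n_epochs` must be >= 2", call. = FALSE)
  n_classes <- as.integer(n_classes)
  if (length(class_names) != n_classes)
    stop("`class_names` must have length `n_classes`", call. = FALSE)
  check_stochastic(markov_P, n_classes)
  if (length(initial_shares) != n_classes || any(initial_shares < 0) ||
      abs(sum(initial_shares) - 1) > 1e-9)
    stop("`initial_shares` must be a length-", n_classes,
         " probability vector", call. = FALSE)
  if (length(driver_effects) == 0L || is.null(names(driver_effects)))
    stop("`driver_effects` must be a named numeric vector", call. = FALSE)
  structure(
    list(grid_shape = grid_shape, cellsize = cellsize, seed = as.integer(seed),
         oasis_center = as.numeric(oasis_center), v0 = v0,
         radial_decay = radial_decay, noise_sd = noise_sd,
         n_classes = n_classes, class_names = class_names,
         markov_P = markov_P, initial_shares = as.numeric(initial_shares),
         n_epochs = as.integer(n_epochs),
         driver_effects = driver_effects, driver_noise_sd = driver_noise_sd),
    class = "synthetic_config"
  )
}

check_stochastic <- function(P, K = nrow(P), tol = 1e-9) {
  if (!is.matrix(P) || nrow(P) != K || ncol(P) != K)
    stop("transition matrix must be square with one row per class",
         call. = FALSE)
  if (any(P < 0))
    stop("transition matrix entries must be non-negative", call. = FALSE)
  if (any(abs(rowSums(P) - 1) > tol))
    stop("transition matrix rows must sum to 1", call. = FALSE)
  invisible(TRUE)
}

#' Default land-use classes
#'
#' Seven classes typical of arid-region land-use products: cropland,
#' forest, two grassland cover classes, water, built-up and unused land.
#' @export
default_landuse_classes <- function() {
  c("cropland", "forest", "grassland_high", "grassland_low",
    "water", "builtup", "unused")
}

#' Default decadal land-use transition matrix
#'
#' A diagonal-dominant row-stochastic matrix emulating the dynamics of a
#' developing oasis city: cropland and built-up land grow at the expense of
#' grassland and unused land, forest and high-cover grassland churn, water
#' is nearly inert.
#' @export
default_markov_matrix <- function() {
  cls <- default_landuse_classes()
  P <- matrix(0, 7, 7, dimnames = list(cls, cls))
  P["cropland", ]       <- c(0.940, 0.005, 0.002, 0.015, 0.003, 0.025, 0.010)
  P["forest", ]         <- c(0.080, 0.850, 0.020, 0.030, 0.005, 0.010, 0.005)
  P["grassland_high", ] <- c(0.080, 0.040, 0.720, 0.120, 0.005, 0.010, 0.025)
  P["grassland_low", ]  <- c(0.120, 0.015, 0.020, 0.730, 0.003, 0.012, 0.100)
  P["water", ]          <- c(0.020, 0.005, 0.000, 0.010, 0.950, 0.005, 0.010)
  P["builtup", ]        <- c(0.020, 0.010, 0.005, 0.010, 0.000, 0.945, 0.010)
  P["unused", ]         <- c(0.090, 0.005, 0.005, 0.060, 0.002, 0.008, 0.830)
  stopifnot(all(abs(rowSums(P) - 1) < 1e-12))
  P
}

#' Default first-epoch class shares
#'
#' Cropland, low-cover grassland and unused land together make up about
#' 90% of an arid oasis city's land, with forest, high-cover grassland,
#' water and built-up land as minor classes.
#' @export
default_initial_shares <- function() {
  c(cropland = 0.43, forest = 0.03, grassland_high = 0.01,
    grassland_low = 0.36, water = 0.005, builtup = 0.015, unused = 0.15)
}

#' Default planted driver effects
#'
#' Accessibility dominates (distance to towns 1.0, distance to roads 0.5);
#' the seven remaining drivers are pure noise. This mirrors the situation
#' the importance harness must detect: a dominant socioeconomic driver
#' against a background of inert predictors.
#' @export
default_driver_effects <- function() {
  c(elevation = 0, slope = 0, soil_erosion = 0, temperature = 0,
    precipitation = 0, gdp = 0, population = 0,
    distance_to_roads = 0.5, distance_to_towns = 1.0)
}

# deterministic sub-stream seeds, kept below 2^31
substream <- function(seed, k) {
  (as.numeric(seed) * 97L + k * 7919) %% 2147483647
}

#' Generate a concentric NDVI field
#'
#' NDVI falls off exponentially with distance from the oasis centre:
#' `v(d) = v0 * exp(-radial_decay * d)` with `d` in cells, plus optional
#' Gaussian noise, clamped to `[-1, 1]`. With `noise_sd = 0` the field is
#' exactly the deterministic radial profile, so the three NDVI belts are
#' concentric rings whose radii follow in closed form.
#'
#' @param config a [synthetic_config()].
#' @param radial_decay optional override of the config decay (used to march
#'   the profile across epochs: a smaller decay is a larger oasis).
#' @param epoch epoch index; each epoch draws its noise from its own
#'   deterministic sub-stream of `config$seed`.
#' @return a continuous `oasis_raster` in `[-1, 1]`.
#' @export
generate_ndvi <- function(config, radial_decay = config$radial_decay,
                          epoch = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (radial_decay <= 0) stop("`radial_decay` must be > 0", call. = FALSE)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  d <- outer(seq_len(nr) - config$oasis_center[1],
             seq_len(nc) - config$oasis_center[2],
             function(i, j) sqrt(i^2 + j^2))
  v <- config$v0 * exp(-radial_decay * d)
  if (config$noise_sd > 0) {
    set.seed(substream(config$seed, 1L + 13L * (as.integer(epoch) - 1L)))
    v <- v + matrix(stats::rnorm(nr * nc, sd = config$noise_sd), nr, nc)
  }
  v <- pmin(pmax(v, -1), 1)
  new_raster(v, cellsize = config$cellsize, categorical = FALSE)
}

#' Generate a multi-epoch categorical land-use series
#'
#' Epoch 1 is a Voronoi mosaic: random seed points (about one per
#' `patch_scale`^2 cells) each carry a class drawn from
#' `config$initial_shares`, and every cell takes the class of its
#' nearest seed, giving contiguous patches at a controllable spatial
#' scale. Each later epoch applies `markov_P` independently per cell,
#' followed by one 3x3 majority pass when `smooth = TRUE`. Disable
#' smoothing to keep the cell-wise process an exact Markov chain, e.g. for
#' transition-matrix recovery studies.
#'
#' @param config a [synthetic_config()].
#' @param smooth logical; apply the majority filter (default `TRUE`).
#' @param patch_scale approximate initial patch diameter in cells
#'   (default 20).
#' @return a list of `config$n_epochs` categorical `oasis_raster`s.
#' @export
generate_landuse_series <- function(config, smooth = TRUE,
                                    patch_scale = 20) {
  stopifnot(inherits(config, "synthetic_config"))
  P <- config$markov_P
  check_stochastic(P, config$n_classes)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  K <- config$n_classes
  set.seed(substream(config$seed, 2L))
  pi0 <- config$initial_shares
  n_seeds <- max(K, round(nr * nc / patch_scale^2))
  sr <- stats::runif(n_seeds, 0.5, nr + 0.5)
  sc <- stats::runif(n_seeds, 0.5, nc + 0.5)
  # every class gets at least one seed so rare classes are not lost
  scls <- c(seq_len(K),
            sample.int(K, n_seeds - K, replace = TRUE, prob = pi0))
  cr <- rep(seq_len(nr), times = nc)
  cc <- rep(seq_len(nc), each = nr)
  nearest <- max.col(-(outer(cr, sr, "-")^2 + outer(cc, sc, "-")^2),
                     ties.method = "first")
  first <- matrix(scls[nearest], nr, nc)
  cumP <- t(apply(P, 1L, cumsum))
  cumP[, K] <- 1  # guard against rounding in the last column
  out <- vector("list", config$n_epochs)
  out[[1]] <- new_raster(first, cellsize = config$cellsize,
                         categorical = TRUE)
  cur <- first
  for (t in 2:config$n_epochs) {
    u <- stats::runif(nr * nc)
    cur <- .cpp_markov_step(cur, cumP, u)
    if (smooth) cur <- .cpp_majority_filter(cur, K)
    out[[t]] <- new_raster(cur, cellsize = config$cellsize,
                           categorical = TRUE)
  }
  out
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of `P` for eigenvalue 1, normalised to sum to 1.
#' @param P row-stochastic matrix.
#' @export
stationary_distribution <- function(P) {
  check_stochastic(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-8)) stop("no non-negative stationary vector found",
                           call. = FALSE)
  pmax(v, 0) / sum(pmax(v, 0))
}

#' Generate a driver table with planted effects
#'
#' One row per sampling-grid cell (or a random subsample of `n` cells):
#' nine named predictors drawn independently on `[0, 1]`, and a synthetic
#' risk response equal to the linear combination given by
#' `config$driver_effects` plus Gaussian noise. Predictors with a zero
#' effect are pure noise with respect to the response.
#'
#' @param config a [synthetic_config()].
#' @param risk a `risk_grid` (see [build_risk_grid()]) supplying the cells.
#' @param n optional number of cells to sample (without replacement).
#' @return a data.frame with `cell_id`, the nine predictors and `eri`.
#' @export
generate_drivers <- function(config, risk, n = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!inherits(risk, "risk_grid") || nrow(risk$cells) == 0L)
    stop("`risk` must be a non-empty risk_grid", call. = FALSE)
  if (nrow(risk$cells) < 50L)
    stop("need at least 50 sampling cells to build a driver table",
         call. = FALSE)
  set.seed(substream(config$seed, 3L))
  ids <- risk$cells$cell_id
  if (!is.null(n)) {
    if (n > length(ids))
      stop("`n` exceeds the number of available cells", call. = FALSE)
    ids <- sort(sample(ids, n))
  }
  m <- length(ids)
  eff <- config$driver_effects
  preds <- matrix(stats::runif(m * length(eff)), nrow = m,
                  dimnames = list(NULL, names(eff)))
  response <- as.numeric(preds %*% eff)
  if (config$driver_noise_sd > 0)
    response <- response + stats::rnorm(m, sd = config$driver_noise_sd)
  out <- data.frame(cell_id = ids, preds, eri = response)
  rownames(out) <- NULL
  out
}
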
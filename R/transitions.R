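#' Cross-tabulate two co-registered categorical rasters
#'
#' `area_flows[i, j]` is the area (km2) of cells mapped as class i at the
#' first date and class j at the second. Cells that are nodata in either
#' map are excluded, so the matrix total is the commonly mapped area.
#'
#' @param map_t0,map_t1 categorical `oasis_raster`s of identical geometry.
#' @param classes class codes fixing the matrix order (default: sorted
#'   union of codes present).
#' @param class_names optional labels.
#' @param interval optional `(t0, t1)` years, stored as an attribute.
#' @return a `transition_matrix`: K x K numeric matrix of km2.
#' @export
cross_tabulate <- function(map_t0, map_t1, classes = NULL,
                           class_names = NULL, interval = NULL) {
  stopifnot(is_raster(map_t0), is_raster(map_t1))
  if (!identical(dim(map_t0$values), dim(map_t1$values)))
    stop("rasters must share the same shape", call. = FALSE)
  v0 <- map_t0$values; v1 <- map_t1$values
  ok <- !is.na(v0) & !is.na(v1)
  if (!any(ok)) stop("no commonly mapped cells", call. = FALSE)
  if (is.null(classes))
    classes <- sort(unique(c(v0[ok], v1[ok])))
  a <- cell_area_km2(map_t0)
  tab <- table(from = factor(v0[ok], levels = classes),
               to = factor(v1[ok], levels = classes))
  labs <- if (is.null(class_names)) as.character(classes)
          else class_names[classes]
  m <- matrix(as.numeric(tab) * a, nrow = length(classes),
              dimnames = list(from = labs, to = labs))
  structure(m, interval = interval, class = c("transition_matrix",
                                              class(m)))
}

#' Signed percent change between two areas
#'
#' `100 * (area_t1 - area_t0) / area_t0`.
#' @param area_t0 area at the start of the interval (> 0).
#' @param area_t1 area at the end.
#' @export
percent_change <- function(area_t0, area_t1) {
  if (any(area_t0 <= 0))
    stop("`area_t0` must be > 0 for a percent change", call. = FALSE)
  100 * (area_t1 - area_t0) / area_t0
}

#' Estimate a Markov transition matrix from area flows
#'
#' Row-normalises a transfer matrix: `P[i, j] = flows[i, j] / rowsum_i`.
#' A class with no area at the start of the interval cannot be sourced;
#' its row is replaced by the identity row with a warning.
#'
#' @param tm a `transition_matrix` (or any non-negative K x K matrix).
#' @return a `markov_matrix` (row-stochastic).
#' @export
estimate_markov <- function(tm) {
  m <- unclass(as.matrix(tm))
  if (nrow(m) != ncol(m) || any(m < 0))
    stop("need a square non-negative flow matrix", call. = FALSE)
  rs <- rowSums(m)
  P <- m
  empty <- rs == 0
  if (any(empty)) {
    warning("class(es) with no source area get identity rows: ",
            paste(rownames(m)[empty], collapse = ", "), call. = FALSE)
    P[empty, ] <- diag(nrow(m))[empty, , drop = FALSE]
    rs[empty] <- 1
  }
  P <- P / rs
  structure(P, class = c("markov_matrix", class(P)))
}

#' Scenario specification: multiplicative transfer adjustments
#'
#' A scenario is a list of rules, each multiplying the transition
#' probabilities from a set of source classes to a set of destination
#' classes by a positive factor.
#'
#' @param ... rules created with `scenario_rule()`.
#' @export
scenario_spec <- function(...) {
  rules <- list(...)
  for (r in rules) {
    if (!inherits(r, "scenario_rule"))
      stop("all arguments must be scenario_rule()s", call. = FALSE)
  }
  structure(rules, class = "scenario_spec")
}

#' @rdname scenario_spec
#' @param from,to character vectors of class names (or integer codes).
#' @param multiplier positive factor applied to the targeted entries.
#' @export
scenario_rule <- function(from, to, multiplier) {
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier <= 0)
    stop("`multiplier` must be a single positive number", call. = FALSE)
  structure(list(from = from, to = to, multiplier = multiplier),
            class = "scenario_rule")
}

#' Government-control scenario for oasis land management
#'
#' The three policy levers of an ecological-restoration programme:
#' transfers of cropland, woodland (forest) and grassland to built-up and
#' unused land are cut by 20% (x0.8); conversion of unused land to
#' cropland, woodland and grassland rises by 30% (x1.3); conversion of
#' built-up land to woodland and grassland rises by 10% (x1.1).
#'
#' @param classes class-name vector; defaults to the package's seven-class
#'   scheme, with both grassland cover classes counting as grassland.
#' @export
government_control_scenario <- function(classes = default_landuse_classes()) {
  veg <- intersect(c("cropland", "forest", "grassland_high",
                     "grassland_low"), classes)
  grasswood <- intersect(c("forest", "grassland_high", "grassland_low"),
                         classes)
  scenario_spec(
    scenario_rule(veg, intersect(c("builtup", "unused"), classes), 0.8),
    scenario_rule("unused", veg, 1.3),
    scenario_rule("builtup", grasswood, 1.1)
  )
}

#' Apply a scenario to a Markov matrix
#'
#' Multiplies the targeted off-diagonal transition probabilities by their
#' rule multipliers, then restores row-stochasticity by adjusting each
#' row's diagonal (persistence) entry. If a diagonal would go negative the
#' whole row is rescaled proportionally instead, with a warning; entries
#' pushed above 1 are clipped with a warning.
#'
#' @param P a `markov_matrix` (row-stochastic, named dims).
#' @param spec a [scenario_spec()].
#' @return adjusted `markov_matrix` with rows summing to 1.
#' @export
apply_scenario <- function(P, spec) {
  m <- unclass(as.matrix(P))
  check_stochastic(m)
  if (!inherits(spec, "scenario_spec"))
    stop("`spec` must be a scenario_spec", call. = FALSE)
  resolve <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    i <- match(x, rownames(m))
    if (any(is.na(i)))
      stop("unknown class(es): ", paste(x[is.na(i)], collapse = ", "),
           call. = FALSE)
    i
  }
  for (r in spec) {
    fi <- resolve(r$from); ti <- resolve(r$to)
    for (i in fi) {
      cols <- setdiff(ti, i)  # never touch the persistence entry
      m[i, cols] <- m[i, cols] * r$multiplier
    }
  }
  over <- m > 1
  if (any(over)) {
    warning("adjusted probabilities above 1 clipped", call. = FALSE)
    m[over] <- 1
  }
  for (i in seq_len(nrow(m))) {
    off <- sum(m[i, -i])
    if (off <= 1) {
      m[i, i] <- 1 - off
    } else {
      warning(sprintf(
        "row %d: off-diagonal mass %.3f exceeds 1; row rescaled", i, off),
        call. = FALSE)
      m[i, ] <- m[i, ] / sum(m[i, ])
    }
  }
  structure(m, class = c("markov_matrix", class(m)))
}

#' Project class areas with a Markov chain
#'
#' `areas_{t+1} = areas_t %*% P`, iterated `n_steps` times (one step per
#' calibration interval, e.g. a decade). The total area is conserved.
#'
#' @param areas named vector of class areas (km2), length K.
#' @param P row-stochastic K x K matrix.
#' @param n_steps number of steps (>= 0).
#' @return projected area vector.
#' @export
project_areas <- function(areas, P, n_steps = 1L) {
  m <- unclass(as.matrix(P))
  check_stochastic(m)
  if (length(areas) != nrow(m))
    stop("`areas` length must match the matrix dimension", call. = FALSE)
  if (any(areas < 0)) stop("areas must be non-negative", call. = FALSE)
  v <- as.numeric(areas)
  for (s in seq_len(n_steps)) v <- as.numeric(v %*% m)
  names(v) <- rownames(m)
  v
}

#' Land-use composition of the oasis / transition / desert belts
#'
#' For each land-use class, the percentage of its area falling in each
#' zone; rows sum to 100.
#'
#' @param zones categorical zone raster ([classify_zones()]).
#' @param landuse categorical land-use raster of identical geometry.
#' @param class_names optional labels for land-use codes.
#' @return matrix (classes x zones) of percentages.
#' @export
zone_composition <- function(zones, landuse, class_names = NULL) {
  stopifnot(is_raster(zones), is_raster(landuse))
  if (!identical(dim(zones$values), dim(landuse$values)))
    stop("rasters must share the same shape", call. = FALSE)
  ok <- !is.na(zones$values) & !is.na(landuse$values)
  if (!any(ok)) stop("no commonly mapped cells", call. = FALSE)
  zc <- zone_codes()
  lu <- sort(unique(landuse$values[ok]))
  tab <- table(class = factor(landuse$values[ok], levels = lu),
               zone = factor(zones$values[ok], levels = zc))
  m <- matrix(as.numeric(tab), nrow = length(lu),
              dimnames = list(
                class = if (is.null(class_names)) as.character(lu)
                        else class_names[lu],
                zone = names(zc)))
  100 * m / rowSums(m)
}
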
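#' Patch statistics of a categorical landscape
#'
#' Counts connected patches and areas per landscape type. Two cells belong
#' to the same patch when they share a class and are adjacent under the
#' chosen connectivity; 8-connectivity (edge or corner, the common
#' remote-sensing convention) is the default.
#'
#' @param landuse categorical `oasis_raster`.
#' @param connectivity 4 or 8.
#' @param class_names optional labels for the class codes.
#' @return data.frame with one row per class present: `class`,
#'   `class_name`, `n_patches` (Ni), `area_km2` (Ai); total mapped area A
#'   (km2) as attribute `total_area_km2`.
#' @export
patch_stats <- function(landuse, connectivity = 8L, class_names = NULL) {
  stopifnot(is_raster(landuse))
  v <- landuse$values
  storage.mode(v) <- "integer"
  if (!any(!is.na(v))) stop("raster has no data cells", call. = FALSE)
  labels <- .cpp_label_components(v, as.integer(connectivity))
  a <- cell_area_km2(landuse)
  ok <- !is.na(v)
  # patch count per class: number of distinct labels whose cells carry it
  lab_class <- tapply(v[ok], labels[ok], function(x) x[1])
  n_patches <- table(factor(lab_class, levels = sort(unique(v[ok]))))
  cell_counts <- table(factor(v[ok], levels = sort(unique(v[ok]))))
  cls <- as.integer(names(cell_counts))
  out <- data.frame(
    class = cls,
    class_name = if (is.null(class_names)) as.character(cls)
                 else class_names[cls],
    n_patches = as.integer(n_patches),
    area_km2 = as.numeric(cell_counts) * a,
    row.names = NULL
  )
  attr(out, "total_area_km2") <- sum(ok) * a
  attr(out, "connectivity") <- as.integer(connectivity)
  out
}

#' Landscape fragmentation index (Ci)
#'
#' Patches per unit area of the type: `Ci = Ni / Ai`.
#' @param n_patches patch count Ni.
#' @param area_km2 type area Ai in km2 (> 0).
#' @export
fragmentation <- function(n_patches, area_km2) {
  if (any(area_km2 <= 0)) stop("`area_km2` must be > 0", call. = FALSE)
  n_patches / area_km2
}

#' Landscape separation index (Si)
#'
#' `Si = (A / (2 Ai)) * sqrt(Ni / A)`: sparse, scattered types score high,
#' a single patch filling the study area scores lowest.
#' @param n_patches patch count Ni.
#' @param area_km2 type area Ai (> 0).
#' @param total_area_km2 study area A (> 0).
#' @export
separation <- function(n_patches, area_km2, total_area_km2) {
  if (any(area_km2 <= 0) || any(total_area_km2 <= 0))
    stop("areas must be > 0", call. = FALSE)
  (total_area_km2 / (2 * area_km2)) * sqrt(n_patches / total_area_km2)
}

#' Landscape dominance index (Di)
#'
#' `Di = (Qi + Mi) / 4 + Li / 2` where Qi is the fraction of sampling
#' cells in which the type occurs, Mi its share of all patches, and Li its
#' share of the total area. Bounded in `[0, 1]`.
#' @param q,m,l the Qi, Mi, Li fractions.
#' @export
dominance <- function(q, m, l) (q + m) / 4 + l / 2

#' Landscape disturbance index (LDI)
#'
#' Weighted combination `a*Ci + b*Si + c*Di`. Utilized land (cropland,
#' forest, grassland, water, built-up) uses weights (0.5, 0.3, 0.2) —
#' fragmentation matters most where people work the land; unutilized land
#' uses (0.3, 0.2, 0.5), emphasising dominance.
#'
#' @param ci,si,di the component indices.
#' @param land_status `"utilized"` or `"unutilized"`, recycled.
#' @export
disturbance <- function(ci, si, di, land_status) {
  if (!all(land_status %in% c("utilized", "unutilized")))
    stop("`land_status` must be 'utilized' or 'unutilized'", call. = FALSE)
  w <- cbind(ifelse(land_status == "utilized", 0.5, 0.3),
             ifelse(land_status == "utilized", 0.3, 0.2),
             ifelse(land_status == "utilized", 0.2, 0.5))
  w[, 1] * ci + w[, 2] * si + w[, 3] * di
}

#' Landscape fragility index (LFI)
#'
#' Sum-normalised vulnerability ranks: `LFI_i = rank_i / sum(ranks)`, so
#' the values sum to 1 over the landscape types.
#' @param ranks named positive numeric vector of vulnerability ranks.
#' @export
fragility <- function(ranks) {
  if (any(is.na(ranks)) || any(ranks <= 0))
    stop("all fragility ranks must be positive", call. = FALSE)
  ranks / sum(ranks)
}

#' Default fragility ranks for the seven land-use classes
#'
#' Vulnerability ordered construction (6) > forest (5) > cropland (4) >
#' grassland (3, both cover classes share the rank) > water (2) >
#' unused/desert (1).
#' @export
default_fragility_ranks <- function() {
  c(cropland = 4, forest = 5, grassland_high = 3, grassland_low = 3,
    water = 2, builtup = 6, unused = 1)
}

#' Default utilized/unutilized status for the seven land-use classes
#' @export
default_land_status <- function() {
  c(cropland = "utilized", forest = "utilized",
    grassland_high = "utilized", grassland_low = "utilized",
    water = "utilized", builtup = "utilized", unused = "unutilized")
}

#' Build a square sampling grid over a land-use raster
#'
#' Aggregates the raster into `grid_size` x `grid_size` sampling cells
#' (default 1 km) and records, per cell, the in-study area `A_k` and the
#' composition `A_ki` by land-use class. Cells whose data coverage falls
#' below `min_coverage` of the nominal cell area are dropped so boundary
#' slivers do not produce unstable compositions.
#'
#' @param landuse categorical `oasis_raster`.
#' @param grid_size sampling-cell side in metres.
#' @param min_coverage minimum fraction of the nominal cell area that must
#'   carry data (default 0.1).
#' @param class_names optional labels for class codes.
#' @return a `risk_grid`: list with `cells` (data.frame: `cell_id`, `grow`,
#'   `gcol`, `x`, `y` centre coordinates, `A_k`) and `comp` (cells x
#'   classes matrix of km2).
#' @export
build_risk_grid <- function(landuse, grid_size = 1000, min_coverage = 0.1,
                            class_names = NULL) {
  stopifnot(is_raster(landuse))
  bs <- grid_size / landuse$cellsize
  if (abs(bs - round(bs)) > 1e-8)
    stop("`grid_size` must be a whole multiple of the raster cell size",
         call. = FALSE)
  bs <- as.integer(round(bs))
  v <- landuse$values
  nr <- nrow(v); nc <- ncol(v)
  grow <- ceiling(row(v) / bs)
  gcol <- ceiling(col(v) / bs)
  ngr <- max(grow); ngc <- max(gcol)
  block <- (grow - 1L) * ngc + gcol
  a <- cell_area_km2(landuse)
  classes <- sort(unique(v[!is.na(v)]))
  counts <- table(block = factor(block[!is.na(v)],
                                 levels = seq_len(ngr * ngc)),
                  class = factor(v[!is.na(v)], levels = classes))
  comp <- matrix(as.numeric(counts), nrow = ngr * ngc,
                 dimnames = list(NULL, classes)) * a
  A_k <- rowSums(comp)
  nominal <- bs^2 * a
  keep <- A_k >= min_coverage * nominal
  ids <- which(keep)
  gr <- ((ids - 1L) %/% ngc) + 1L
  gc_ <- ((ids - 1L) %% ngc) + 1L
  cells <- data.frame(
    cell_id = ids, grow = gr, gcol = gc_,
    x = landuse$xll + (gc_ - 0.5) * grid_size,
    y = landuse$yll + (nrow(v) * landuse$cellsize) - (gr - 0.5) * grid_size,
    A_k = A_k[keep]
  )
  structure(
    list(cells = cells, comp = comp[keep, , drop = FALSE],
         classes = classes,
         class_names = if (is.null(class_names)) as.character(classes)
                       else class_names[classes],
         grid_size = grid_size, ngrow = ngr, ngcol = ngc),
    class = "risk_grid"
  )
}

#' @export
print.risk_grid <- function(x, ...) {
  cat(sprintf("<risk_grid> %d cells of %g m (%d x %d blocks), %d classes\n",
              nrow(x$cells), x$grid_size, x$ngrow, x$ngcol,
              length(x$classes)))
  if (!is.null(x$cells$eri))
    cat(sprintf("  ERI range: [%.4f, %.4f]\n",
                min(x$cells$eri), max(x$cells$eri)))
  invisible(x)
}

#' Per-type landscape indices over a sampling grid
#'
#' Computes, globally per landscape type for one epoch: patch count Ni and
#' area Ai, fragmentation Ci, separation Si, dominance Di (whose occurrence
#' term Qi is the fraction of sampling cells containing the type),
#' disturbance LDI and fragility LFI.
#'
#' @param landuse categorical `oasis_raster`.
#' @param grid a `risk_grid` built on the same raster.
#' @param connectivity patch connectivity, 4 or 8.
#' @param fragility_ranks named vector of vulnerability ranks keyed by
#'   class name (default [default_fragility_ranks()]).
#' @param land_status named character vector `"utilized"`/`"unutilized"`
#'   keyed by class name (default [default_land_status()]).
#' @return data.frame, one row per class present, with all indices.
#' @export
landscape_indices <- function(landuse, grid, connectivity = 8L,
                              fragility_ranks = default_fragility_ranks(),
                              land_status = default_land_status()) {
  stopifnot(inherits(grid, "risk_grid"))
  codebook <- rep(NA_character_, max(grid$classes))
  codebook[grid$classes] <- grid$class_names
  ps <- patch_stats(landuse, connectivity = connectivity,
                    class_names = codebook)
  A <- attr(ps, "total_area_km2")
  # occurrence fraction Qi over the sampling cells
  occ <- colSums(grid$comp > 0) / nrow(grid$comp)
  qi <- occ[match(ps$class, as.integer(colnames(grid$comp)))]
  qi[is.na(qi)] <- 0
  mi <- ps$n_patches / sum(ps$n_patches)
  li <- ps$area_km2 / A
  status <- land_status[ps$class_name]
  if (any(is.na(status)))
    stop("`land_status` missing for class(es): ",
         paste(ps$class_name[is.na(status)], collapse = ", "),
         call. = FALSE)
  ranks <- fragility_ranks[ps$class_name]
  if (any(is.na(ranks)))
    stop("`fragility_ranks` missing for class(es): ",
         paste(ps$class_name[is.na(ranks)], collapse = ", "),
         call. = FALSE)
  ci <- fragmentation(ps$n_patches, ps$area_km2)
  si <- separation(ps$n_patches, ps$area_km2, A)
  di <- dominance(qi, mi, li)
  out <- data.frame(
    class = ps$class, class_name = ps$class_name,
    n_patches = ps$n_patches, area_km2 = ps$area_km2,
    Qi = qi, Mi = mi, Li = li,
    Ci = ci, Si = si, Di = di,
    LDI = disturbance(ci, si, di, status),
    LFI = as.numeric(fragility(ranks)),
    land_status = unname(status),
    row.names = NULL
  )
  attr(out, "total_area_km2") <- A
  out
}

#' Ecological risk index per sampling cell
#'
#' `ERI_k = sum_i (A_ki / A_k) * LDI_i * LFI_i`: the composition-weighted
#' disturbance-times-fragility of the landscape types present in cell k.
#' Being a convex combination, `0 <= ERI_k <= max_i LDI_i * LFI_i`.
#'
#' @param grid a `risk_grid`.
#' @param indices output of [landscape_indices()] for the same epoch.
#' @return the grid with an `eri` column added to `cells`.
#' @export
eri <- function(grid, indices) {
  stopifnot(inherits(grid, "risk_grid"))
  need <- c("class", "LDI", "LFI")
  if (!all(need %in% names(indices)))
    stop("`indices` must carry class, LDI and LFI columns", call. = FALSE)
  risk_per_class <- indices$LDI * indices$LFI
  idx <- match(as.integer(colnames(grid$comp)), indices$class)
  w <- ifelse(is.na(idx), 0, risk_per_class[idx])
  grid$cells$eri <- as.numeric((grid$comp %*% w) / grid$cells$A_k)
  grid
}

#' Assess ecological risk of a land-use raster
#'
#' Convenience wrapper: builds the sampling grid, computes the landscape
#' indices and attaches the per-cell ERI.
#'
#' @inheritParams build_risk_grid
#' @inheritParams landscape_indices
#' @return a `risk_grid` with `eri`; the index table is attached as
#'   attribute `indices`.
#' @export
assess_risk <- function(landuse, grid_size = 1000, connectivity = 8L,
                        min_coverage = 0.1, class_names = NULL,
                        fragility_ranks = default_fragility_ranks(),
                        land_status = default_land_status()) {
  grid <- build_risk_grid(landuse, grid_size = grid_size,
                          min_coverage = min_coverage,
                          class_names = class_names)
  ind <- landscape_indices(landuse, grid, connectivity = connectivity,
                           fragility_ranks = fragility_ranks,
                           land_status = land_status)
  out <- eri(grid, ind)
  attr(out, "indices") <- ind
  out
}

#' Ordinal risk levels from ERI values
#'
#' Cuts ERI into `n_levels` equal-interval classes over the pooled min-max
#' of all grids supplied, so levels are comparable across epochs. A
#' constant ERI field yields a single level with a warning.
#'
#' @param grids a `risk_grid` with `eri`, or a list of them (pooled
#'   breaks).
#' @param n_levels number of ordinal classes (default 5).
#' @return the input (same shape) with a `risk_level` column; the break
#'   vector is attached to each grid as attribute `risk_breaks`.
#' @export
classify_risk_levels <- function(grids, n_levels = 5L) {
  single <- inherits(grids, "risk_grid")
  gl <- if (single) list(grids) else grids
  stopifnot(all(vapply(gl, inherits, logical(1), "risk_grid")))
  vals <- unlist(lapply(gl, function(g) g$cells$eri))
  if (is.null(vals)) stop("grids carry no ERI values", call. = FALSE)
  rng <- range(vals)
  if (diff(rng) <= 0) {
    warning("constant ERI field; assigning a single risk level",
            call. = FALSE)
    breaks <- c(rng[1] - 1e-12, rng[2] + 1e-12)
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_levels + 1L)
  }
  gl <- lapply(gl, function(g) {
    lv <- findInterval(g$cells$eri, breaks, rightmost.closed = TRUE,
                       all.inside = TRUE)
    g$cells$risk_level <- as.integer(lv)
    attr(g, "risk_breaks") <- breaks
    g
  })
  if (single) gl[[1]] else gl
}

#' Inverse-distance-weighted ERI surface (display only)
#'
#' Interpolates cell-centre ERI values onto an arbitrary set of points with
#' inverse-distance weighting (power 2). Analysis always uses the raw cell
#' values; this exists for map rendering.
#'
#' @param grid `risk_grid` with `eri`.
#' @param x,y coordinates of the interpolation points.
#' @param power IDW exponent.
#' @export
interpolate_eri <- function(grid, x, y, power = 2) {
  stopifnot(inherits(grid, "risk_grid"), !is.null(grid$cells$eri))
  cx <- grid$cells$x; cy <- grid$cells$y; z <- grid$cells$eri
  vapply(seq_along(x), function(i) {
    d2 <- (cx - x[i])^2 + (cy - y[i])^2
    hit <- which(d2 < 1e-12)
    if (length(hit)) return(z[hit[1]])
    w <- 1 / d2^(power / 2)
    sum(w * z) / sum(w)
  }, numeric(1))
}
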
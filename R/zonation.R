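#' NDVI zonation thresholds
#'
#' Oasis, transition and desert belts are delimited by two NDVI cutoffs:
#' cells with NDVI >= `oasis_min` are oasis, cells with NDVI <= `desert_max`
#' are desert, anything strictly between is transition zone. Defaults are
#' the 30% / 10% cutoffs customary for arid-region oasis delineation.
#' Values may be given as fractions (0.30) or percent (30).
#'
#' @param oasis_min lower NDVI bound of the oasis belt (inclusive).
#' @param desert_max upper NDVI bound of the desert belt (inclusive).
#' @export
zone_thresholds <- function(oasis_min = 0.30, desert_max = 0.10) {
  if (oasis_min > 1 || desert_max > 1) {  # percent notation
    oasis_min <- oasis_min / 100
    desert_max <- desert_max / 100
  }
  if (!(desert_max >= 0 && desert_max < oasis_min && oasis_min <= 1))
    stop("need 0 <= desert_max < oasis_min <= 1", call. = FALSE)
  structure(list(oasis_min = oasis_min, desert_max = desert_max),
            class = "zone_thresholds")
}

#' Zone codes
#' @export
zone_codes <- function() c(oasis = 1L, transition = 2L, desert = 3L)

#' Classify an NDVI raster into oasis / transition / desert belts
#'
#' Cell assignment follows the threshold inequalities exactly:
#' NDVI >= `oasis_min` is oasis (code 1), NDVI <= `desert_max` is desert
#' (code 3), strictly between is transition (code 2). Nodata propagates.
#'
#' @param ndvi continuous `oasis_raster` with values in `[-1, 1]`.
#' @param thresholds a [zone_thresholds()].
#' @return a categorical `oasis_raster` (the zone map).
#' @export
classify_zones <- function(ndvi, thresholds = zone_thresholds()) {
  stopifnot(is_raster(ndvi), inherits(thresholds, "zone_thresholds"))
  v <- ndvi$values
  ok <- !is.na(v)
  if (any(v[ok] < -1 | v[ok] > 1))
    stop("NDVI values must lie in [-1, 1]", call. = FALSE)
  z <- matrix(NA_integer_, nrow(v), ncol(v))
  z[ok] <- 2L
  z[ok & v >= thresholds$oasis_min] <- 1L
  z[ok & v <= thresholds$desert_max] <- 3L
  out <- new_raster(z, cellsize = ndvi$cellsize, xll = ndvi$xll,
                    yll = ndvi$yll, categorical = TRUE)
  attr(out, "zone_names") <- names(zone_codes())
  out
}

#' Belt areas of a zone map
#'
#' @param zones categorical zone raster from [classify_zones()].
#' @return named numeric vector of areas in km2 (oasis, transition, desert).
#' @export
zone_areas <- function(zones) {
  stopifnot(is_raster(zones))
  a <- cell_area_km2(zones)
  codes <- zone_codes()
  vapply(codes, function(k) sum(zones$values == k, na.rm = TRUE) * a,
         numeric(1))
}

#' Confusion matrix from labelled sample points
#'
#' Looks up the mapped class at each reference point (nearest cell, 1-based
#' `row`/`col` indices, origin top-left) and cross-tabulates mapped against
#' reference labels. Points outside the raster or over nodata are skipped
#' with a warning; their count is attached as attribute `n_skipped`.
#'
#' @param map categorical `oasis_raster`.
#' @param points data.frame with columns `row`, `col`, `reference` (class
#'   codes drawn from the map's coding).
#' @param labels class codes defining the matrix order; defaults to the
#'   sorted union of codes seen in map and reference.
#' @return K x K integer matrix, rows = mapped class, cols = reference.
#' @export
confusion_matrix <- function(map, points, labels = NULL) {
  stopifnot(is_raster(map), is.data.frame(points))
  need <- c("row", "col", "reference")
  if (!all(need %in% names(points)))
    stop("`points` needs columns row, col, reference", call. = FALSE)
  d <- dim(map$values)
  inside <- points$row >= 1 & points$row <= d[1] &
            points$col >= 1 & points$col <= d[2]
  mapped <- rep(NA_integer_, nrow(points))
  mapped[inside] <- map$values[cbind(points$row[inside], points$col[inside])]
  usable <- inside & !is.na(mapped) & !is.na(points$reference)
  n_skipped <- sum(!usable)
  if (n_skipped > 0)
    warning(sprintf("%d point(s) outside the raster or over nodata skipped",
                    n_skipped), call. = FALSE)
  if (!any(usable)) stop("no usable sample points", call. = FALSE)
  if (is.null(labels))
    labels <- sort(unique(c(mapped[usable], points$reference[usable])))
  f <- factor(mapped[usable], levels = labels)
  g <- factor(points$reference[usable], levels = labels)
  cm <- table(map = f, reference = g)
  cm <- matrix(as.integer(cm), nrow = length(labels),
               dimnames = list(map = labels, reference = labels))
  attr(cm, "n_skipped") <- n_skipped
  cm
}

#' Classification accuracy metrics from a confusion matrix
#'
#' Overall accuracy, Cohen's kappa, and per-class user's and producer's
#' accuracies. With `orientation = "rows_map"` (the default) rows are the
#' mapped class, so UA is the row-wise and PA the column-wise diagonal
#' fraction; `"rows_reference"` swaps the two. A zero row or column sum
#' yields `NA` for the corresponding UA/PA rather than 0.
#'
#' @param cm K x K non-negative count matrix.
#' @param orientation which margin holds the mapped class.
#' @return list with elements `oa`, `kappa`, `ua`, `pa`, `n`.
#' @export
accuracy_metrics <- function(cm, orientation = c("rows_map",
                                                 "rows_reference")) {
  orientation <- match.arg(orientation)
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square",
                                 call. = FALSE)
  if (any(cm < 0)) stop("confusion matrix entries must be >= 0",
                        call. = FALSE)
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix total must be > 0", call. = FALSE)
  if (orientation == "rows_reference") cm <- t(cm)
  oa <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- (oa - pe) / (1 - pe)
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  ua <- safe_div(diag(cm), rowSums(cm))
  pa <- safe_div(diag(cm), colSums(cm))
  names(ua) <- names(pa) <- rownames(cm)
  list(oa = oa, kappa = kappa, ua = ua, pa = pa, n = total)
}
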
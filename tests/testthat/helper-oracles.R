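# Independent oracles and fixture builders shared across the suite.

# Brute-force flood-fill patch counter: recursive frontier expansion over a
# class-coded matrix, independent of the package's labeling code.
flood_fill_counts <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  counts <- integer(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (seen[r, c] || is.na(m[r, c])) next
    cls <- m[r, c]
    frontier <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(frontier)) {
      cur <- frontier[[1]]; frontier <- frontier[-1]
      for (o in offs) {
        rr <- cur[1] + o[1]; cc <- cur[2] + o[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (seen[rr, cc] || is.na(m[rr, cc]) || m[rr, cc] != cls) next
        seen[rr, cc] <- TRUE
        frontier <- c(frontier, list(c(rr, cc)))
      }
    }
    key <- as.character(cls)
    counts[key] <- if (is.na(counts[key])) 1L else counts[key] + 1L
  }
  counts[order(as.integer(names(counts)))]
}

rand_landuse <- function(nr = 20, nc = 20, K = 3, cellsize = 1000,
                         p_na = 0) {
  v <- matrix(sample.int(K, nr * nc, replace = TRUE), nr, nc)
  if (p_na > 0) v[runif(nr * nc) < p_na] <- NA
  new_raster(v, cellsize = cellsize, categorical = TRUE)
}

# Minimal full-coverage lattice risk_grid for spatial-weights tests:
# every block is one cell of unit area, single land-use class.
lattice_grid <- function(nr, nc) {
  cells <- expand.grid(gcol = seq_len(nc), grow = seq_len(nr))
  cells <- cells[order(cells$grow, cells$gcol), ]
  n <- nrow(cells)
  structure(
    list(cells = data.frame(cell_id = seq_len(n), grow = cells$grow,
                            gcol = cells$gcol,
                            x = cells$gcol - 0.5, y = nr - cells$grow + 0.5,
                            A_k = 1),
         comp = matrix(1, n, 1, dimnames = list(NULL, "1")),
         classes = 1L, class_names = "1", grid_size = 1,
         ngrow = nr, ngcol = nc),
    class = "risk_grid"
  )
}

# Table of printed three-belt confusion matrices (rows = mapped class)
published_confusions <- function() {
  list(
    `1990` = matrix(c(536, 66, 3, 34, 436, 54, 16, 33, 822), 3, 3,
                    byrow = TRUE),
    `2000` = matrix(c(566, 41, 7, 49, 388, 30, 29, 29, 861), 3, 3,
                    byrow = TRUE),
    `2010` = matrix(c(748, 21, 15, 43, 382, 40, 16, 41, 694), 3, 3,
                    byrow = TRUE),
    `2020` = matrix(c(1024, 26, 23, 23, 273, 44, 9, 35, 514), 3, 3,
                    byrow = TRUE)
  )
}

two_class_config <- function(seed = 1, shape = c(200L, 200L)) {
  synthetic_config(
    grid_shape = shape, seed = seed, n_classes = 2L,
    class_names = c("a", "b"),
    markov_P = matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE,
                      dimnames = list(c("a", "b"), c("a", "b"))),
    initial_shares = c(0.5, 0.5),
    n_epochs = 2L
  )
}
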
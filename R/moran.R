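#' Contiguity spatial weights for a sampling grid
#'
#' Builds sparse contiguity weights between sampling cells: rook (shared
#' edge) or queen (shared edge or corner, the default). Weights may be
#' left binary or row-standardised (each row sums to 1; islands keep an
#' all-zero row).
#'
#' @param grid a `risk_grid`.
#' @param scheme `"queen"` or `"rook"`.
#' @param standardization `"row"` or `"binary"`.
#' @return a `dgCMatrix` with attributes `scheme` and `standardization`.
#' @export
build_weights <- function(grid, scheme = c("queen", "rook"),
                          standardization = c("row", "binary")) {
  scheme <- match.arg(scheme)
  standardization <- match.arg(standardization)
  stopifnot(inherits(grid, "risk_grid"))
  n <- nrow(grid$cells)
  if (n < 2L) stop("need at least two cells to build weights", call. = FALSE)
  r <- grid$cells$grow; c_ <- grid$cells$gcol
  offs <- if (scheme == "rook") {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  key <- r * (grid$ngcol + 2L) + c_
  lut <- seq_len(n)
  names(lut) <- key
  ii <- integer(0); jj <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb_key <- (r + offs[k, 1]) * (grid$ngcol + 2L) + (c_ + offs[k, 2])
    j <- lut[as.character(nb_key)]
    hit <- !is.na(j)
    ii <- c(ii, which(hit)); jj <- c(jj, unname(j[hit]))
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  if (standardization == "row") {
    rs <- Matrix::rowSums(W)
    rs[rs == 0] <- 1  # islands: keep zero rows
    W <- Matrix::Diagonal(x = 1 / rs) %*% W
  }
  W <- methods::as(W, "CsparseMatrix")
  attr(W, "scheme") <- scheme
  attr(W, "standardization") <- standardization
  W
}

#' Global Moran's I
#'
#' `I = n * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#'  (sum_ij w_ij * sum_i (x_i - xbar)^2)`. Values near 1 indicate strong
#' positive spatial autocorrelation, near -1 strong negative, near
#' `-1/(n-1)` (the permutation-null expectation) none.
#'
#' @param x numeric values, one per cell.
#' @param W spatial weights from [build_weights()].
#' @return scalar I.
#' @export
global_moran <- function(x, W) {
  n <- length(x)
  if (n < 2L) stop("need at least two observations", call. = FALSE)
  if (nrow(W) != n) stop("weights do not match the data length",
                         call. = FALSE)
  z <- x - mean(x)
  m2 <- sum(z^2)
  if (m2 == 0) stop("Moran's I is undefined for a constant field",
                    call. = FALSE)
  S0 <- sum(W)
  as.numeric(n * (t(z) %*% (W %*% z)) / (S0 * m2))
}

#' Null expectation of Moran's I
#' @param n number of observations.
#' @export
moran_expectation <- function(n) -1 / (n - 1)

#' Local Moran statistics with LISA cluster typing
#'
#' Per-cell local Moran `I_i = n (x_i - xbar) * lag_i / sum (x - xbar)^2`
#' with `lag_i = sum_j w_ij (x_j - xbar)`. Significance is assessed by
#' conditional permutation: holding `x_i` fixed, the neighbour values are
#' redrawn from the remaining cells `n_permutations` times and the
#' pseudo-p is the one-sided rank of the observed `I_i` (GeoDa's
#' convention). Cells with pseudo-p below `alpha` are typed by the sign
#' quadrant of `(x_i - xbar, lag_i)` as High-High, High-Low, Low-High or
#' Low-Low; all others are `"ns"`. Islands (no neighbours) have lag 0 and
#' are never significant.
#'
#' For row-standardised weights the identity
#' `sum_i I_i / S0 = I_global` (S0 the total weight) holds exactly.
#'
#' @param x numeric values, one per cell.
#' @param W spatial weights.
#' @param n_permutations conditional permutations (>= 99).
#' @param alpha significance cutoff for cluster labels.
#' @param seed RNG seed for the permutations.
#' @return a `moran_result`: data.frame with `I_i`, `lag`, `pseudo_p`,
#'   `cluster`; global I and its expectation as attributes.
#' @export
local_moran <- function(x, W, n_permutations = 999L, alpha = 0.05,
                        seed = 1L) {
  n <- length(x)
  if (n_permutations < 99L)
    stop("`n_permutations` must be at least 99", call. = FALSE)
  z <- x - mean(x)
  m2 <- sum(z^2)
  if (m2 == 0) stop("local Moran is undefined for a constant field",
                    call. = FALSE)
  lag <- as.numeric(W %*% z)
  Ii <- n * z * lag / m2
  Wl <- methods::as(W, "TsparseMatrix")
  nb_i <- Wl@i + 1L; nb_j <- Wl@j + 1L; nb_w <- Wl@x
  set.seed(seed)
  pseudo_p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sel <- nb_i == i
    k <- sum(sel)
    if (k == 0L) next  # island
    wts <- nb_w[sel]
    pool <- z[-i]
    draws <- matrix(pool[sample.int(length(pool), n_permutations * k,
                                    replace = TRUE)],
                    nrow = n_permutations)
    sim_lag <- as.numeric(draws %*% wts)
    sim_I <- n * z[i] * sim_lag / m2
    if (Ii[i] >= 0) {
      pseudo_p[i] <- (1 + sum(sim_I >= Ii[i])) / (n_permutations + 1)
    } else {
      pseudo_p[i] <- (1 + sum(sim_I <= Ii[i])) / (n_permutations + 1)
    }
  }
  cluster <- rep("ns", n)
  sig <- !is.na(pseudo_p) & pseudo_p <= alpha
  cluster[sig & z > 0 & lag > 0] <- "HH"
  cluster[sig & z > 0 & lag < 0] <- "HL"
  cluster[sig & z < 0 & lag > 0] <- "LH"
  cluster[sig & z < 0 & lag < 0] <- "LL"
  out <- data.frame(I_i = Ii, lag = lag, pseudo_p = pseudo_p,
                    cluster = cluster)
  attr(out, "I_global") <- global_moran(x, W)
  attr(out, "expectation") <- moran_expectation(n)
  attr(out, "alpha") <- alpha
  attr(out, "n_permutations") <- as.integer(n_permutations)
  class(out) <- c("moran_result", "data.frame")
  out
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("<moran_result> %d cells, global I = %.4f (E[I] = %.4f)\n",
              nrow(x), attr(x, "I_global"), attr(x, "expectation")))
  print(table(x$cluster))
  invisible(x)
}
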
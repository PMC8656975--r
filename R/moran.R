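#' Spatial weights from an adjacency graph
#'
#' @param graph an `adjacency_graph`.
#' @param style `"row"` (row-standardized, the GeoDa convention for LISA;
#'   default) or `"binary"`.
#' @return An object of class `spatial_weights`: neighbour index list, weight
#'   list, `S0` (total weight), style and tract ids. Isolated tracts get an
#'   all-zero weight row with a warning.
#' @export
make_weights <- function(graph, style = c("row", "binary")) {
  style <- match.arg(style)
  d <- unname(lengths(graph$nbr))
  if (any(d == 0))
    warning("isolated tract(s) get zero weight rows: ",
            paste(graph$tract_ids[d == 0], collapse = ", "))
  wts <- lapply(seq_len(graph$n), function(i) {
    if (d[i] == 0) return(numeric(0))
    if (style == "row") rep(1 / d[i], d[i]) else rep(1, d[i])
  })
  structure(list(nbr = graph$nbr, wts = wts, n = graph$n,
                 S0 = sum(unlist(wts)), style = style,
                 tract_ids = graph$tract_ids),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("Spatial weights:", x$n, "tracts, style =", x$style, ", S0 =", x$S0, "\n")
  invisible(x)
}

# spatial lag Wx given a permutation-free value vector
.lag <- function(x, W) {
  vapply(seq_len(W$n), function(i) {
    if (length(W$nbr[[i]]) == 0) return(NA_real_)
    sum(W$wts[[i]] * x[W$nbr[[i]]])
  }, numeric(1))
}

.check_moran_input <- function(x, W) {
  if (length(x) != W$n) stop("x must have one value per tract", call. = FALSE)
  if (anyNA(x)) stop("x contains missing values", call. = FALSE)
  if (W$n < 3) stop("need at least 3 tracts", call. = FALSE)
  if (stats::var(x) == 0) stop("x has zero variance", call. = FALSE)
}

#' Global Moran's I
#'
#' `I = (n/S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`,
#' the standard measure of global spatial autocorrelation; expectation under
#' spatial randomness is `-1/(n-1)`.
#'
#' @param x numeric vector of per-tract values (in graph order).
#' @param W a `spatial_weights` object.
#' @return the scalar statistic.
#' @export
morans_i <- function(x, W) {
  .check_moran_input(x, W)
  z <- x - mean(x)
  lag <- .lag(z, W)
  lag[is.na(lag)] <- 0
  (W$n / W$S0) * sum(z * lag) / sum(z^2)
}

#' Permutation (or analytic) test of global Moran's I
#'
#' The permutation null randomly relabels `x` over tracts. The pseudo p-value
#' is two-sided, `(#\{|I_perm| >= |I_obs|\} + 1) / (n_perm + 1)`, and the
#' z-score standardizes `I_obs` by the permutation moments. The analytic
#' alternative uses the classical randomization mean and variance with a
#' kurtosis correction.
#'
#' @param x per-tract values.
#' @param W a `spatial_weights` object.
#' @param n_perm number of random permutations (>= 99).
#' @param seed optional integer seed for reproducibility.
#' @param method `"permutation"` (default) or `"normal"`.
#' @return An object of class `moran_test` with fields `I`, `expectation`
#'   (`-1/(n-1)`), `z`, `p_value`, `n_perm`, `method`, `seed`.
#' @export
morans_i_test <- function(x, W, n_perm = 999, seed = NULL,
                          method = c("permutation", "normal")) {
  method <- match.arg(method)
  .check_moran_input(x, W)
  n <- W$n
  I_obs <- morans_i(x, W)
  EI <- -1 / (n - 1)
  if (method == "permutation") {
    if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    I_perm <- vapply(seq_len(n_perm),
                     function(k) morans_i(x[sample.int(n)], W), numeric(1))
    z <- (I_obs - mean(I_perm)) / stats::sd(I_perm)
    p <- (sum(abs(I_perm) >= abs(I_obs)) + 1) / (n_perm + 1)
  } else {
    # randomization moments (Cliff & Ord), symmetrized weights
    wmat <- matrix(0, n, n)
    for (i in seq_len(n)) wmat[i, W$nbr[[i]]] <- W$wts[[i]]
    S0 <- W$S0
    S1 <- 0.5 * sum((wmat + t(wmat))^2)
    S2 <- sum((rowSums(wmat) + colSums(wmat))^2)
    z0 <- x - mean(x)
    b2 <- n * sum(z0^4) / sum(z0^2)^2
    EI2 <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
              b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2)
    vI <- EI2 - EI^2
    z <- (I_obs - EI) / sqrt(vI)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(I = I_obs, expectation = EI, z = z, p_value = p,
                 n_perm = if (method == "permutation") n_perm else NA_integer_,
                 method = method, seed = seed),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f), z = %.2f, p = %.4g [%s]\n",
              x$I, x$expectation, x$z, x$p_value, x$method))
  invisible(x)
}

#' Anselin local Moran statistics
#'
#' `I_i = z_i * sum_j w_ij z_j` with `z` the deviations from the mean scaled
#' by the population (divide-by-n) variance of `x`. With row-standardized
#' weights the statistics satisfy `sum_i I_i = n * I_global`.
#'
#' @param x per-tract values.
#' @param W a `spatial_weights` object.
#' @return named numeric vector of local statistics (`NA` for isolated
#'   tracts).
#' @export
local_moran <- function(x, W) {
  .check_moran_input(x, W)
  z <- x - mean(x)
  m2 <- sum(z^2) / W$n
  Ii <- (z / m2) * .lag(z, W)
  names(Ii) <- W$tract_ids
  Ii
}

#' LISA cluster detection
#'
#' Local indicators of spatial association: per-tract conditional permutation
#' test of the local Moran statistic (hold `x_i` fixed, permute the remaining
#' values among the other tracts), with cluster classification from the
#' quadrant of `(z_i, lag z_i)`. Pseudo p-values are two-sided (twice the
#' smaller tail, capped at 1), so the significance fraction under spatial
#' randomness is close to `alpha`.
#'
#' @param x per-tract values.
#' @param W a `spatial_weights` object.
#' @param n_perm conditional permutations per tract (>= 99).
#' @param alpha significance level for classification.
#' @param seed optional integer seed.
#' @param fdr apply a Benjamini-Hochberg correction to the pseudo p-values
#'   before classification (off by default).
#' @return An object of class `lisa_result`: data.frame with `tract_id`,
#'   `I_local`, `pseudo_p`, `class` in
#'   `{high-high, low-low, high-low, low-high, not-significant}`. Isolated
#'   tracts get `NA` statistics and class `not-significant`.
#' @export
lisa <- function(x, W, n_perm = 999, alpha = 0.05, seed = NULL, fdr = FALSE) {
  .check_moran_input(x, W)
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- W$n
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  zs <- z / m2
  lag <- .lag(z, W)
  Ii <- zs * lag
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    di <- length(W$nbr[[i]])
    if (di == 0) next
    others <- z[-i]
    wi <- W$wts[[i]]
    # n_perm conditional draws of d_i neighbour values without replacement
    perm_lag <- vapply(seq_len(n_perm), function(k)
      sum(wi * others[sample.int(n - 1L, di)]), numeric(1))
    perm_I <- zs[i] * perm_lag
    p_hi <- (sum(perm_I >= Ii[i]) + 1) / (n_perm + 1)
    p_lo <- (sum(perm_I <= Ii[i]) + 1) / (n_perm + 1)
    p[i] <- min(1, 2 * min(p_hi, p_lo))
  }
  p_adj <- p
  if (fdr) p_adj[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  cls <- rep("not-significant", n)
  sig <- !is.na(p_adj) & p_adj <= alpha
  cls[sig & z > 0 & lag > 0] <- "high-high"
  cls[sig & z < 0 & lag < 0] <- "low-low"
  cls[sig & z > 0 & lag < 0] <- "high-low"
  cls[sig & z < 0 & lag > 0] <- "low-high"
  out <- data.frame(tract_id = W$tract_ids, I_local = Ii, pseudo_p = p,
                    class = cls, stringsAsFactors = FALSE)
  structure(out, class = c("lisa_result", "data.frame"),
            alpha = alpha, n_perm = n_perm, fdr = fdr, seed = seed)
}
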
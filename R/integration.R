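#' Preference-integration algorithms
#'
#' Scalar forms of the six algorithms that integrate a multi-dimensional
#' preference block and a candidate's trait vector into a single attraction
#' score. Conventions:
#' \describe{
#'   \item{euclidean}{`attraction_euclidean()` returns the raw Euclidean
#'     distance between the ideal-point preference vector and the candidate's
#'     traits; *shorter* distances mean greater attraction. The matrix builder
#'     negates it so larger always means more attractive.}
#'   \item{cosine}{cosine of the angle, at the origin, between preference and
#'     trait vectors; in \[-1, 1\].}
#'   \item{aspiration}{each trait dimension has two preferences defining an
#'     ideal range (sorted at evaluation time); attraction is the count of
#'     trait values falling inside their range, an integer in \[0, n\].}
#'   \item{linear}{per dimension a slope and an intercept; attraction is the
#'     summed linear function of trait values.}
#'   \item{curvilinear}{per dimension a frequency and a phase of a sine wave;
#'     attraction is the summed sinusoid `sin(freq * t + phase)`.}
#'   \item{polynomial}{per dimension an intercept and three slopes of a cubic
#'     `b0 + b1 t + b2 t^2 + b3 t^3`, summed over dimensions.}
#' }
#'
#' @param prefs,traits numeric vectors of equal length.
#' @return a single attraction score.
#' @seealso [build_attraction_matrix()] for the vectorized market-level form,
#'   [implied_ideal()] for each rule's most-preferred trait vector.
#' @export
attraction_euclidean <- function(prefs, traits) {
  if (length(prefs) != length(traits))
    stop("preference and trait vectors differ in length (",
         length(prefs), " vs ", length(traits), ")")
  sqrt(sum((prefs - traits)^2))
}

#' @rdname attraction_euclidean
#' @export
attraction_cosine <- function(prefs, traits) {
  if (length(prefs) != length(traits))
    stop("preference and trait vectors differ in length")
  np <- sqrt(sum(prefs^2)); nt <- sqrt(sum(traits^2))
  if (np == 0 || nt == 0)
    stop("cosine attraction is undefined for an all-zero vector")
  sum(prefs * traits) / (np * nt)
}

#' @rdname attraction_euclidean
#' @param ranges numeric `n x 2` matrix of raw range endpoints (unsorted
#'   pairs allowed; each row is sorted before the inclusive interval test).
#' @export
attraction_aspiration <- function(ranges, traits) {
  ranges <- rbind(ranges)
  if (ncol(ranges) != 2L || nrow(ranges) != length(traits))
    stop("ranges must be an n x 2 matrix matching the trait vector")
  lo <- pmin(ranges[, 1], ranges[, 2])
  hi <- pmax(ranges[, 1], ranges[, 2])
  sum(traits >= lo & traits <= hi)
}

#' @rdname attraction_euclidean
#' @param slopes,intercepts per-dimension linear coefficients.
#' @export
attraction_linear <- function(slopes, intercepts, traits) {
  if (length(slopes) != length(traits) || length(intercepts) != length(traits))
    stop("slopes, intercepts and traits must have equal length")
  sum(slopes * traits + intercepts)
}

#' @rdname attraction_euclidean
#' @param freqs,phases per-dimension sine frequency and phase.
#' @export
attraction_curvilinear <- function(freqs, phases, traits) {
  if (length(freqs) != length(traits) || length(phases) != length(traits))
    stop("freqs, phases and traits must have equal length")
  sum(sin(freqs * traits + phases))
}

#' @rdname attraction_euclidean
#' @param coeffs numeric `n x 4` matrix; columns are the intercept and the
#'   three slopes `(b0, b1, b2, b3)` of the per-dimension cubic.
#' @export
attraction_polynomial <- function(coeffs, traits) {
  coeffs <- rbind(coeffs)
  if (ncol(coeffs) != 4L || nrow(coeffs) != length(traits))
    stop("coeffs must be an n x 4 matrix matching the trait vector")
  sum(coeffs[, 1] + coeffs[, 2] * traits + coeffs[, 3] * traits^2 +
        coeffs[, 4] * traits^3)
}

# Extract the j-th preference column per trait dimension from a wide
# preference matrix (n_agents x n_traits*k, dimension-major blocks).
.pref_slice <- function(prefs, k, j) {
  p <- ncol(prefs) / k
  prefs[, seq.int(j, by = k, length.out = p), drop = FALSE]
}

#' Implied ideal trait vector of a preference block
#'
#' Every integration rule implies a most-preferred trait vector, used by the
#' Euclidean metric layer to place all rules on a common scale: for
#' ideal-point rules (euclidean, cosine, and the null models) it is the stored
#' preference vector unchanged; for the aspiration rule the midpoint of each
#' sorted range; for the linear, curvilinear and polynomial rules the
#' per-dimension argmax of that dimension's attraction term over the grid
#' `seq(low, high, by = grid_step)`, with ties broken toward the lowest grid
#' value.
#'
#' @param prefs for `implied_ideal()`, one agent's preference block: a vector
#'   (width-1 rules) or an `n_traits x k` matrix; for `implied_ideal_all()`,
#'   a wide `n_agents x (n_traits*k)` matrix in dimension-major column order.
#' @param rule integration-rule name.
#' @param trait_bounds length-2 numeric, the trait scale (default `c(1, 7)`).
#' @param grid_step argmax grid resolution (default 0.01).
#' @return `implied_ideal()`: a length-`n_traits` vector; the `_all` form a
#'   matrix with one row per agent.
#' @export
implied_ideal <- function(prefs, rule, trait_bounds = c(1, 7),
                          grid_step = 0.01) {
  rule <- match.arg(rule, names(.RULES))
  k <- .RULES[[rule]]
  if (is.matrix(prefs)) {
    if (ncol(prefs) != k)
      stop("rule '", rule, "' expects ", k, " preference column(s)")
    wide <- matrix(as.vector(t(prefs)), nrow = 1L)
  } else {
    if (k != 1L) stop("rule '", rule, "' expects an n x ", k,
                      " preference matrix")
    wide <- matrix(prefs, nrow = 1L)
  }
  drop(implied_ideal_all(wide, rule, trait_bounds, grid_step))
}

#' @rdname implied_ideal
#' @export
implied_ideal_all <- function(prefs, rule, trait_bounds = c(1, 7),
                              grid_step = 0.01) {
  rule <- match.arg(rule, names(.RULES))
  if (grid_step <= 0) stop("grid_step must be positive")
  k <- .RULES[[rule]]
  p <- ncol(prefs) / k
  if (p != round(p)) stop("preference matrix width is not a multiple of ", k)
  p <- as.integer(p)

  if (k == 1L) return(prefs)
  if (rule == "aspiration")
    return((.pref_slice(prefs, k, 1L) + .pref_slice(prefs, k, 2L)) / 2)

  grid <- seq(trait_bounds[1], trait_bounds[2], by = grid_step)
  if (grid[length(grid)] < trait_bounds[2] - 1e-12)
    grid <- c(grid, trait_bounds[2])
  out <- matrix(NA_real_, nrow(prefs), p)
  for (d in seq_len(p)) {
    cols <- ((d - 1L) * k + 1L):(d * k)
    b <- prefs[, cols, drop = FALSE]
    vals <- switch(rule,
      linear = outer(b[, 1], grid),
      curvilinear = sin(outer(b[, 1], grid) + b[, 2]),
      polynomial = outer(b[, 2], grid) + outer(b[, 3], grid^2) +
        outer(b[, 4], grid^3)
    )
    out[, d] <- grid[max.col(vals, ties.method = "first")]
  }
  out
}

#' Build an attraction matrix for one sex of choosers
#'
#' Applies an integration rule pairwise between every chooser's preference
#' block and every candidate's trait vector, vectorized over the market. For
#' the euclidean rule the stored value is the *negated* distance, so larger
#' always means more attractive. The two null models score attraction exactly
#' as the euclidean rule (their pairing stage then ignores or post-processes
#' it).
#'
#' @param prefs chooser preference matrix, `n_choosers x (n_traits*k)`,
#'   dimension-major column order.
#' @param traits candidate trait matrix, `n_candidates x n_traits`.
#' @param rule integration-rule name.
#' @return an `mm_attraction` matrix (`n_choosers x n_candidates`) with
#'   attributes `rule` and `normalized = FALSE`.
#' @export
build_attraction_matrix <- function(prefs, traits, rule) {
  rule <- match.arg(rule, names(.RULES))
  prefs <- rbind(prefs); traits <- rbind(traits)
  k <- .RULES[[rule]]
  p <- ncol(traits)
  if (ncol(prefs) != p * k)
    stop("preference width ", ncol(prefs), " does not match ", p,
         " traits under rule '", rule, "'")
  nf <- nrow(prefs); nm <- nrow(traits)

  a <- switch(rule,
    euclidean = , random = , pref_update = {
      d2 <- outer(rowSums(prefs^2), rep(1, nm)) +
        outer(rep(1, nf), rowSums(traits^2)) - 2 * tcrossprod(prefs, traits)
      -sqrt(pmax(d2, 0))
    },
    cosine = {
      np <- sqrt(rowSums(prefs^2)); nt <- sqrt(rowSums(traits^2))
      if (any(np == 0) || any(nt == 0))
        stop("cosine attraction is undefined for an all-zero vector")
      tcrossprod(prefs / np, traits / nt)
    },
    aspiration = {
      m <- matrix(0, nf, nm)
      p1 <- .pref_slice(prefs, k, 1L); p2 <- .pref_slice(prefs, k, 2L)
      lo <- pmin(p1, p2); hi <- pmax(p1, p2)
      for (d in seq_len(p))
        m <- m + (outer(lo[, d], traits[, d], "<=") &
                    outer(hi[, d], traits[, d], ">="))
      m
    },
    linear = {
      tcrossprod(.pref_slice(prefs, k, 1L), traits) +
        rowSums(.pref_slice(prefs, k, 2L))
    },
    curvilinear = {
      m <- matrix(0, nf, nm)
      fr <- .pref_slice(prefs, k, 1L); ph <- .pref_slice(prefs, k, 2L)
      for (d in seq_len(p))
        m <- m + sin(outer(fr[, d], traits[, d]) + ph[, d])
      m
    },
    polynomial = {
      rowSums(.pref_slice(prefs, k, 1L)) +
        tcrossprod(.pref_slice(prefs, k, 2L), traits) +
        tcrossprod(.pref_slice(prefs, k, 3L), traits^2) +
        tcrossprod(.pref_slice(prefs, k, 4L), traits^3)
    })
  structure(a, rule = rule, normalized = FALSE, class = "mm_attraction")
}

#' Min-max normalize an attraction matrix
#'
#' Rescales the whole matrix (one global min-max, preserving between-chooser
#' differences) to \[0, 1\] so that the elementwise product used in mutual
#' pairing is well-defined for rules with negative or unbounded outputs. A
#' constant matrix maps to all 0.5. The map is strictly monotone, so rank
#' order is preserved.
#'
#' @param m an attraction matrix (any numeric matrix accepted).
#' @return the normalized matrix with attribute `normalized = TRUE`.
#' @export
normalize_attraction <- function(m) {
  if (!all(is.finite(m))) stop("attraction matrix has non-finite entries")
  lo <- min(m); hi <- max(m)
  out <- if (hi > lo) (m - lo) / (hi - lo) else array(0.5, dim(m))
  structure(out, rule = attr(m, "rule"), normalized = TRUE,
            dim = dim(m), class = "mm_attraction")
}
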
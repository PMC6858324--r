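#' Pair agents by mutual attraction
#'
#' Combines the two sexes' normalized attraction matrices into a mutual
#' attraction matrix — elementwise product (`combine = "product"`) or
#' elementwise minimum, treating the least attracted member of each possible
#' couple as the limiting factor (`combine = "minimum"`) — then forms couples
#' greedily: the most mutually attracted available couple pairs and both
#' agents leave the pool, iterating until no formable couple remains. Exact
#' ties are broken toward the lowest (row, column) index so matchings are
#' reproducible.
#'
#' If either matrix carries a visibility mask from [restrict_search()], a
#' couple is formable only if each member evaluated the other; agents whose
#' remaining candidates are all masked stay unpaired.
#'
#' @param fa normalized female-chooser attraction matrix
#'   (`n_females x n_males`).
#' @param ma normalized male-chooser attraction matrix
#'   (`n_males x n_females`).
#' @param combine `"product"` or `"minimum"`.
#' @return an `mm_matching`: a data frame with columns `female`, `male` (row
#'   indices into the two matrices) and `score` (the pair's mutual
#'   attraction), with attribute `pairing`. Pairs appear in extraction order,
#'   so `score` is non-increasing.
#' @export
pair_by_mutual_attraction <- function(fa, ma, combine = c("product", "minimum")) {
  combine <- match.arg(combine)
  if (nrow(fa) != ncol(ma) || ncol(fa) != nrow(ma))
    stop("attraction matrices have incompatible shapes: ",
         nrow(fa), "x", ncol(fa), " vs ", nrow(ma), "x", ncol(ma))
  if (min(fa) < -1e-9 || max(fa) > 1 + 1e-9 ||
      min(ma) < -1e-9 || max(ma) > 1 + 1e-9)
    stop("attraction matrices must be normalized to [0, 1] before pairing")

  mutual <- switch(combine,
                   product = unclass(fa) * t(unclass(ma)),
                   minimum = pmin(unclass(fa), t(unclass(ma))))
  mask_f <- attr(fa, "mask"); mask_m <- attr(ma, "mask")
  if (!is.null(mask_f)) mutual[!mask_f] <- -Inf
  if (!is.null(mask_m)) mutual[!t(mask_m)] <- -Inf

  n_pairs <- min(dim(mutual))
  female <- integer(0); male <- integer(0); score <- numeric(0)
  for (i in seq_len(n_pairs)) {
    mx <- max(mutual)
    if (!is.finite(mx)) break
    hits <- which(mutual == mx, arr.ind = TRUE)
    best <- hits[order(hits[, 1L], hits[, 2L])[1L], , drop = TRUE]
    female <- c(female, best[[1L]]); male <- c(male, best[[2L]])
    score <- c(score, mx)
    mutual[best[[1L]], ] <- -Inf
    mutual[, best[[2L]]] <- -Inf
  }
  structure(data.frame(female = female, male = male, score = score),
            pairing = combine, class = c("mm_matching", "data.frame"))
}

#' Pair agents randomly
#'
#' Uniform random perfect matching between the sexes, ignoring attraction:
#' the pairing stage of the two null models.
#'
#' @param females,males integer counts, or vectors whose lengths give the
#'   counts (must be equal).
#' @param seed optional integer; if supplied, pairing is drawn from a local
#'   RNG stream and the caller's RNG state is untouched.
#' @return an `mm_matching` with `score = NA`.
#' @export
pair_randomly <- function(females, males, seed = NULL) {
  nf <- if (length(females) == 1L && is.numeric(females)) as.integer(females)
        else length(females)
  nm <- if (length(males) == 1L && is.numeric(males)) as.integer(males)
        else length(males)
  if (nf != nm) stop("random pairing requires balanced sexes (", nf,
                     " females vs ", nm, " males)")
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  structure(data.frame(female = seq_len(nf), male = sample.int(nm),
                       score = NA_real_),
            pairing = "random", class = c("mm_matching", "data.frame"))
}

#' Move ideal-point preferences toward a chosen mate
#'
#' The preference-updating null model selects mates randomly and then shifts
#' each agent's ideal-point preference vector a fixed fraction of the way
#' toward the chosen partner's traits (0.9 in the canonical model):
#' `new_pref = pref + fraction * (mate_trait - pref)`.
#'
#' @param prefs ideal-point preference vector (one preference per trait);
#'   multi-column preference blocks are rejected.
#' @param mate_traits the partner's trait vector.
#' @param fraction in \[0, 1\]; 0 leaves preferences unchanged, 1 copies the
#'   partner's traits exactly.
#' @return the updated preference vector.
#' @export
update_preferences_toward_mate <- function(prefs, mate_traits, fraction = 0.9) {
  if (is.matrix(prefs) && ncol(prefs) > 1L)
    stop("preference updating applies only to one-column (ideal-point) ",
         "preference blocks")
  prefs <- drop(prefs)
  if (length(prefs) != length(mate_traits))
    stop("preference and mate trait vectors differ in length")
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  prefs + fraction * (mate_traits - prefs)
}

#' Restrict each chooser to a random candidate subset
#'
#' Models incomplete mate search: each chooser evaluates only `k` uniformly
#' chosen candidates of the opposite sex. All other entries are set to the
#' matrix minimum (so they are never extracted first) and flagged in a
#' visibility mask; [pair_by_mutual_attraction()] excludes masked couples
#' entirely, so unmatched agents become possible. Subsets are drawn
#' independently per chooser (female f may evaluate male m without the
#' reverse).
#'
#' @param fa,ma the two attraction matrices.
#' @param k number of candidates each chooser evaluates (at most the
#'   opposite-sex count; `k` equal to it restores complete search).
#' @param seed optional integer for a local RNG stream.
#' @return list with elements `fa` and `ma`, each carrying a logical `mask`
#'   attribute (`TRUE` = evaluated).
#' @export
restrict_search <- function(fa, ma, k, seed = NULL) {
  if (k < 1 || k > ncol(fa) || k > ncol(ma))
    stop("k must be between 1 and the opposite-sex count")
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  mask_one <- function(m) {
    keep <- matrix(FALSE, nrow(m), ncol(m))
    for (i in seq_len(nrow(m)))
      keep[i, sample.int(ncol(m), k)] <- TRUE
    out <- unclass(m)
    out[!keep] <- min(m)
    structure(out, rule = attr(m, "rule"), normalized = attr(m, "normalized"),
              mask = keep, class = "mm_attraction")
  }
  list(fa = mask_one(fa), ma = mask_one(ma))
}
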
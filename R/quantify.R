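#' Boundary indices included in curvature quantification
#'
#' Curvature near the head and tail reflects the shape of the tips, not
#' body bending, so every index within `exclusion` ring positions of
#' either tip is dropped. With 300 points and the default exclusion of 25,
#' 300 - 2 * (2 * 25 + 1) = 198 indices remain per frame (the two tips and
#' 25 neighbours on each side of each).
#'
#' @param kymo a `kymograph` (tips per frame already detected).
#' @param exclusion index radius of the excluded head/tail zones.
#' @return List (one per frame) of included 1-based index vectors.
#' @export
included_points <- function(kymo, exclusion = 25L) {
  stopifnot(inherits(kymo, "kymograph"))
  n <- kymo$n_points
  if (exclusion >= n / 4)
    stop("exclusion zones overlap: exclusion must be < n_points / 4")
  lapply(seq_len(nrow(kymo$ci)), function(t) {
    idx <- seq_len(n)
    keep <- circ_dist(idx, kymo$tips$head[t], n) > exclusion &
      circ_dist(idx, kymo$tips$tail[t], n) > exclusion
    idx[keep]
  })
}

# Pooled positive (concave) CI values over the included point-frames.
pool_positive_ci <- function(kymo, exclusion = 25L) {
  inc <- included_points(kymo, exclusion)
  unlist(lapply(seq_along(inc), function(t) {
    v <- kymo$ci[t, inc[[t]]]
    v[v > 0]
  }))
}

#' Low/high curvature cutoff from a control group
#'
#' The cutoff separating low from high concave curvature is the median of
#' all pooled positive included CI values across the control animals'
#' kymographs. (For the even-count case the usual mean-of-middle-two
#' median is used.) The cutoff is resolution-dependent — it is a CI in
#' 1/pixels at the recording's magnification — which is why it is
#' recomputed from the control group rather than fixed.
#'
#' @param control_kymos list of `kymograph` objects (control group).
#' @param exclusion head/tail exclusion radius.
#' @return Cutoff in 1/pixels.
#' @export
cutoff_from_control <- function(control_kymos, exclusion = 25L) {
  if (inherits(control_kymos, "kymograph"))
    control_kymos <- list(control_kymos)
  pooled <- unlist(lapply(control_kymos, pool_positive_ci,
                          exclusion = exclusion))
  if (length(pooled) == 0) stop("no positive CI values in the control pool")
  stats::median(pooled)
}

#' Summarise one animal's concave curvature
#'
#' Over all included point-frames with positive (concave) CI: `pct_low` is
#' the percentage with `0 < CI < cutoff` and `pct_high` the percentage
#' with `CI > cutoff`; a CI exactly at the cutoff counts as high. With the
#' default `"positive"` denominator the two percentages sum to 100. The
#' `"all"` denominator (all included point-frames, concave or not) is
#' available for sensitivity checks.
#'
#' @param kymo a `kymograph`.
#' @param cutoff low/high CI cutoff (> 0), 1/pixels.
#' @param exclusion head/tail exclusion radius.
#' @param animal_id label carried into the summary.
#' @param denominator `"positive"` (default) or `"all"`.
#' @return An object of class `curvature_summary` (also a one-row data
#'   frame): `animal_id`, `pct_low`, `pct_high`, `n_included`, `cutoff`,
#'   `exclusion`.
#' @export
summarize_animal <- function(kymo, cutoff, exclusion = 25L,
                             animal_id = "animal",
                             denominator = c("positive", "all")) {
  stopifnot(inherits(kymo, "kymograph"), cutoff > 0)
  denominator <- match.arg(denominator)
  inc <- included_points(kymo, exclusion)
  all_ci <- unlist(lapply(seq_along(inc), function(t) kymo$ci[t, inc[[t]]]))
  pos <- all_ci[all_ci > 0]
  n_low <- sum(pos < cutoff)
  n_high <- sum(pos >= cutoff)
  denom <- if (denominator == "positive") length(pos) else length(all_ci)
  if (denom == 0) stop("no included points to summarise for ", animal_id)
  out <- data.frame(animal_id = animal_id,
                    pct_low = 100 * n_low / denom,
                    pct_high = 100 * n_high / denom,
                    n_included = length(all_ci),
                    cutoff = cutoff, exclusion = as.integer(exclusion),
                    stringsAsFactors = FALSE)
  class(out) <- c("curvature_summary", class(out))
  out
}

#' Compare concave-curvature summaries between two groups
#'
#' Tests whether the per-animal percentage of high-curvature boundary
#' points differs between groups with a Welch two-sample t-test. Because
#' `pct_low` and `pct_high` are complementary (they sum to 100 per
#' animal), a multivariate test over both would be rank-deficient; the
#' single t-test on `pct_high` carries the same information. When the
#' within-group variance is degenerate (a group of identical values) the
#' t-test is replaced by an exact permutation test on the difference of
#' group means.
#'
#' @param groupA,groupB lists of `curvature_summary` objects (or data
#'   frames of stacked summaries), >= 2 animals each.
#' @param variable column to test (default `"pct_high"`).
#' @param max_exact largest number of group relabellings enumerated
#'   exhaustively by the permutation fallback; beyond it, Monte Carlo
#'   with 10000 draws.
#' @return An object of class `curvature_group_test`: list with
#'   `statistic`, `p_value`, `method`, `means` (per-group mean and sd of
#'   both percentages), and the raw per-group values.
#' @export
compare_groups <- function(groupA, groupB, variable = "pct_high",
                           max_exact = 200000) {
  pull <- function(g) {
    if (is.data.frame(g)) return(g)
    do.call(rbind, lapply(g, as.data.frame))
  }
  A <- pull(groupA); B <- pull(groupB)
  if (nrow(A) < 2 || nrow(B) < 2)
    stop("need >= 2 animals per group")
  a <- A[[variable]]; b <- B[[variable]]
  msd <- function(g) data.frame(
    mean_pct_low = mean(g$pct_low), sd_pct_low = stats::sd(g$pct_low),
    mean_pct_high = mean(g$pct_high), sd_pct_high = stats::sd(g$pct_high),
    n = nrow(g))
  means <- rbind(A = msd(A), B = msd(B))
  degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
  if (!degenerate) {
    tt <- stats::t.test(b, a, var.equal = FALSE)
    res <- list(statistic = unname(tt$statistic), p_value = tt$p.value,
                method = "Welch two-sample t-test")
  } else {
    obs <- mean(b) - mean(a)
    pooled <- c(a, b)
    nA <- length(a)
    ntot <- length(pooled)
    ncomb <- choose(ntot, nA)
    if (ncomb <= max_exact) {
      splits <- utils::combn(ntot, nA)
      diffs <- apply(splits, 2L, function(ix)
        mean(pooled[-ix]) - mean(pooled[ix]))
      p <- mean(abs(diffs) >= abs(obs) - 1e-12)
      method <- "exact permutation test (degenerate variance)"
    } else {
      diffs <- replicate(10000, {
        ix <- sample.int(ntot, nA)
        mean(pooled[-ix]) - mean(pooled[ix])
      })
      p <- mean(abs(diffs) >= abs(obs) - 1e-12)
      method <- "Monte Carlo permutation test (degenerate variance)"
    }
    res <- list(statistic = obs, p_value = p, method = method)
  }
  structure(c(res, list(variable = variable, means = means,
                        values = list(A = a, B = b))),
            class = "curvature_group_test")
}

#' @export
print.curvature_group_test <- function(x, ...) {
  cat("Group comparison on", x$variable, "\n")
  cat("  method:", x$method, "\n")
  cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  cat("  group means (pct_low / pct_high, mean +/- sd):\n")
  for (g in rownames(x$means)) {
    m <- x$means[g, ]
    cat(sprintf("    %s (n=%d): %.1f +/- %.1f / %.1f +/- %.1f\n", g, m$n,
                m$mean_pct_low, m$sd_pct_low,
                m$mean_pct_high, m$sd_pct_high))
  }
  invisible(x)
}
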
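# Per-point bandwidth rules for the sample-point adaptive estimator.
#
# KNN1 sets h_i to the distance from x_i to its k-th nearest neighbor among
# the other points. In a configuration of two dense clusters separated by a
# wide gap, every point's k nearest neighbors can lie inside its own cluster,
# so no kernel spans the gap and the density there is exactly zero -- the
# "zero problem" that collapses held-out likelihoods. KNN2 repairs this: when
# all k nearest neighbors of x_i lie on one side, h_i becomes the distance to
# the single nearest point on the opposite side, which guarantees a strictly
# positive density everywhere between x_1 and x_n.

# Duplicate shifted reads give k-th neighbor distance 0; a kernel needs
# positive width, so bandwidths are floored at 1 bp.
H_MIN_BANDWIDTH <- 1

# k-th smallest |x_j - x_i| over j != i for every i, plus the distances to
# the nearest strictly-left and strictly-right points needed by the KNN2
# override. In sorted 1-D data the k nearest neighbors of x_i are among its
# k immediate neighbors on each side; the C++ core merges the two sorted
# distance lists.
knn_distance_core <- function(x, k) {
  m <- knn_core_cpp(x, k)
  list(hk = m[, 1L], left = m[, 2L], right = m[, 3L])
}

#' KNN1 per-point bandwidths
#'
#' Assigns each position the absolute distance to its k-th nearest neighbor
#' among the other positions (duplicate positions contribute zero distances
#' to the multiset). Bandwidths are floored at 1 bp so that duplicated
#' positions still receive a usable kernel.
#'
#' @param X A [position_array()] (or sorted numeric vector).
#' @param k Number of nearest neighbors; must satisfy `1 <= k < n`.
#' @return Numeric vector of bandwidths, one per position, same order.
#' @examples
#' knn1_bandwidths(position_array(c(0, 10, 30) + 1), k = 1)  # 10 10 20
#' @export
knn1_bandwidths <- function(X, k) {
  X <- as_position_array(X)
  if (!is_count(k) || k < 1) stopf("k must be a positive integer")
  if (k >= X$n) stopf("k = %d must be smaller than n = %d", k, X$n)
  pmax(knn_distance_core(X$positions, as.integer(k))$hk, H_MIN_BANDWIDTH)
}

#' KNN2 per-point bandwidths
#'
#' Same as [knn1_bandwidths()] unless all k nearest neighbors of a point lie
#' on the same side (strictly closer than the nearest opposite-side point;
#' a distance tie at rank k counts as mixed-side and triggers no override).
#' In that case the bandwidth becomes the distance to the single nearest
#' point on the opposite side, which makes the resulting density strictly
#' positive everywhere between the extreme positions. Points with no
#' opposite-side point at all (the extreme ends of the range) fall back to
#' their KNN1 value.
#'
#' @inheritParams knn1_bandwidths
#' @return Numeric vector of bandwidths, one per position.
#' @export
knn2_bandwidths <- function(X, k) {
  X <- as_position_array(X)
  if (!is_count(k) || k < 1) stopf("k must be a positive integer")
  if (k >= X$n) stopf("k = %d must be smaller than n = %d", k, X$n)
  core <- knn_distance_core(X$positions, as.integer(k))
  h <- core$hk
  # Directional-coverage form of the rule: a direction is covered when the
  # nearest strictly-left (-right) point is within the k-th neighbor
  # distance, i.e. some of the k nearest lie that way (a distance tie at
  # rank k counts as covered / mixed-side). If a direction with at least one
  # point is uncovered, extend the bandwidth to its nearest point. With no
  # duplicated positions this is exactly the all-on-one-side override
  # (the nearest opposite point is then farther than the k-th neighbor, so
  # the override only grows h); duplicates of x_i count toward neither side
  # but can never fulfil coverage, keeping the density positive between the
  # extreme positions. Points lacking any opposite point keep their KNN1
  # value in that direction.
  ov_left <- is.finite(core$left) & core$left > core$hk
  ov_right <- is.finite(core$right) & core$right > core$hk
  h[ov_left] <- pmax(h[ov_left], core$left[ov_left])
  h[ov_right] <- pmax(h[ov_right], core$right[ov_right])
  pmax(h, H_MIN_BANDWIDTH)
}
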
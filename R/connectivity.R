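#' @include flow-model.R
NULL

#' Pearson correlation network from regional time series
#'
#' Standard Pearson correlation between every pair of regional BOLD time
#' series; the symmetric matrix (unit diagonal) defines the weights of the
#' functional connectivity network.
#'
#' @param ts numeric region x time matrix (rows are regions).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearsonNetwork <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3) stop("need at least 3 time points")
  v <- apply(ts, 1, stats::var)
  if (any(v == 0)) {
    lab <- rownames(ts)
    if (is.null(lab)) lab <- as.character(seq_len(nrow(ts)))
    stop("constant time series for region ", lab[which(v == 0)[1]])
  }
  r <- stats::cor(t(ts))
  (r + t(r)) / 2
}

#' Fisher z-averaged correlation
#'
#' Averages correlation coefficients on the variance-stabilized atanh scale
#' and transforms back: `tanh(mean(atanh(r)))`. Values are clipped to
#' |r| <= 1 - 1e-7 to keep the transform finite.
#'
#' @param r numeric vector of correlations.
#' @return a single averaged correlation.
#' @export
#' @examples
#' fisherAverage(c(0.5, 0.9))  # ~0.766
fisherAverage <- function(r) {
  if (length(r) == 0) stop("empty correlation vector")
  if (any(!is.finite(r))) stop("non-finite correlations")
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  tanh(mean(atanh(r)))
}

#' Regional activation from spatial maps
#'
#' The average magnitude of a spatial map within a region is interpreted as
#' that region's functional activation for the mode: \eqn{R_i^m} is the mean
#' absolute map value over the locations labeled \eqn{i} (ICA maps are
#' signed, so magnitude is taken before averaging; set `magnitude = FALSE`
#' for the raw mean). Locations outside the parcellation are ignored.
#'
#' @param maps numeric location x mode matrix with location row names, or an
#'   already region-level matrix.
#' @param parcelLabels named character/factor mapping location -> region;
#'   names must match `maps` row names. `NULL` treats rows as regions.
#' @param magnitude take absolute values before averaging (default TRUE).
#' @return an [ActivationMatrix-class].
#' @export
regionActivation <- function(maps, parcelLabels = NULL, magnitude = TRUE) {
  m <- as.matrix(maps)
  if (magnitude) m <- abs(m)
  if (is.null(parcelLabels)) {
    return(activationMatrix(m))
  }
  locs <- names(parcelLabels)
  if (is.null(locs)) stop("parcelLabels must be named by location")
  missing <- setdiff(locs, rownames(m))
  if (length(missing))
    stop("labeled location(s) absent from maps: ", missing[1])
  m <- m[locs, , drop = FALSE]
  regions <- unique(as.character(parcelLabels))
  out <- matrix(0, length(regions), ncol(m),
                dimnames = list(regions, colnames(m)))
  for (rg in regions) {
    ix <- which(as.character(parcelLabels) == rg)
    if (!length(ix)) stop("region with zero locations: ", rg)
    out[rg, ] <- colMeans(m[ix, , drop = FALSE])
  }
  activationMatrix(out)
}

# exact 1-D 2-means: minimizes within-cluster SSE over all sorted splits;
# returns logical "in upper cluster"
split2means <- function(x) {
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  csum <- cumsum(xs); csq <- cumsum(xs^2)
  best <- Inf; bestk <- 1L
  for (k in seq_len(n - 1)) {
    s1 <- csum[k]; q1 <- csq[k]
    s2 <- csum[n] - s1; q2 <- csq[n] - q1
    sse <- (q1 - s1^2 / k) + (q2 - s2^2 / (n - k))
    if (sse < best - 1e-15) { best <- sse; bestk <- k }
  }
  upper <- logical(n)
  upper[o[(bestk + 1):n]] <- TRUE
  upper
}

#' Mask inactive regions per mode via 2-means
#'
#' For each mode independently, regions are split into active and inactive
#' by 2-means on the activation values (solved exactly in one dimension by
#' enumerating sorted splits, which is deterministic and globally optimal);
#' the cluster with the smaller centroid is inactive and its activations are
#' set to zero. If all values are equal the mode is left untouched (zeroing
#' everything would silently drop the mode).
#'
#' @param activation an [ActivationMatrix-class] (>= 2 regions).
#' @return a masked [ActivationMatrix-class].
#' @export
kmeansActivityMask <- function(activation) {
  v <- activation@values
  if (nrow(v) < 2) stop("need at least 2 regions per mode")
  for (m in seq_len(ncol(v))) {
    x <- v[, m]
    if (max(x) - min(x) <= 0) next  # all equal: keep all active
    v[!split2means(x), m] <- 0
  }
  new("ActivationMatrix", values = v)
}

# optimal one-to-one assignment maximizing sum of score[i, assigned(i)];
# exhaustive for small problems, assignment LP (integral vertices) otherwise
optimalAssignment <- function(score) {
  nr <- nrow(score); nc <- ncol(score)
  k <- min(nr, nc)
  if (max(nr, nc) <= 7) {
    if (nr <= nc) {
      perms <- permuteIdx(nc, nr)
      tot <- apply(perms, 1, function(p) sum(score[cbind(seq_len(nr), p)]))
      p <- perms[which.max(tot), ]
      return(cbind(row = seq_len(nr), col = p))
    } else {
      a <- optimalAssignment(t(score))
      return(cbind(row = a[, "col"], col = a[, "row"]))
    }
  }
  # LP relaxation of the assignment problem (vertex solutions are integral)
  nv <- nr * nc
  idx <- function(i, j) (j - 1L) * nr + i
  A <- matrix(0, nr + nc, nv)
  for (i in seq_len(nr)) A[i, idx(i, seq_len(nc))] <- 1
  for (j in seq_len(nc)) A[nr + j, idx(seq_len(nr), j)] <- 1
  b <- rep(1, nr + nc)
  # maximize => minimize negative; add tiny pull so exactly k matches occur
  res <- .lp_simplex(as.numeric(-(score + 1e-9)), A, b, 1e-9, 0L)
  x <- matrix(res$x, nr, nc)
  pairs <- which(x > 0.5, arr.ind = TRUE)
  cbind(row = pairs[, 1], col = pairs[, 2])
}

permuteIdx <- function(n, k) {
  # all ordered selections of k items from 1..n
  if (k == 1) return(matrix(seq_len(n), ncol = 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- permuteIdx(n, k - 1)
    sub <- sub[apply(sub != i, 1, all), , drop = FALSE]
    out <- rbind(out, cbind(i, sub))
  }
  out
}

#' Match subject modes to reference spatial maps
#'
#' One-to-one assignment of subject maps (e.g. ICA components) to reference
#' maps maximizing total absolute spatial correlation; the optimal
#' assignment is computed, not a greedy pass, and the sign of each match is
#' recorded (ICA components have sign indeterminacy).
#'
#' @param subjectMaps numeric location x mode matrix.
#' @param referenceMaps numeric location x reference matrix over the same
#'   locations.
#' @return data.frame with columns `mode`, `reference`, `r` (signed
#'   correlation of the match) and `sign`.
#' @export
matchModes <- function(subjectMaps, referenceMaps) {
  s <- as.matrix(subjectMaps); rf <- as.matrix(referenceMaps)
  if (nrow(s) != nrow(rf)) stop("maps must share a location domain")
  if (ncol(s) < ncol(rf))
    warning("fewer subject modes than references: partial assignment")
  cc <- stats::cor(s, rf)
  a <- optimalAssignment(abs(cc))
  modes <- colnames(s); if (is.null(modes)) modes <- paste0("mode", seq_len(ncol(s)))
  refs <- colnames(rf); if (is.null(refs)) refs <- paste0("ref", seq_len(ncol(rf)))
  r <- cc[a]
  data.frame(mode = modes[a[, "row"]], reference = refs[a[, "col"]],
             r = r, sign = ifelse(r >= 0, 1L, -1L),
             stringsAsFactors = FALSE)
}

#' Top-k edge consistency across subjects
#'
#' For each subject the k largest-weight edges are selected (ties broken by
#' canonical lexicographic edge order for reproducibility); the output is
#' the per-edge frequency of selection across subjects, the quantity shown
#' as edge width in cross-subject consistency graphs.
#'
#' @param networks list of per-subject edge-weight representations: either
#'   named numeric vectors over a common canonical edge set, or symmetric
#'   weight matrices with identical dimnames.
#' @param k number of top edges per subject.
#' @return data.frame with columns `edge` and `frequency` in canonical edge
#'   order.
#' @export
topkConsistency <- function(networks, k) {
  toVec <- function(x) {
    if (is.matrix(x)) {
      n <- nrow(x)
      e <- allPairs(n)
      lab <- rownames(x); if (is.null(lab)) lab <- paste0("R", seq_len(n))
      stats::setNames(x[e], paste(lab[e[, 1]], lab[e[, 2]], sep = "|"))
    } else x
  }
  vecs <- lapply(networks, toVec)
  ref <- names(vecs[[1]])
  if (is.null(ref)) stop("edge names required")
  for (v in vecs) if (!identical(names(v), ref))
    stop("all subjects must share an identical canonical edge set")
  L <- length(ref)
  if (k > L) stop("k exceeds the number of candidate edges")
  counts <- numeric(L)
  for (v in vecs) {
    o <- order(-v, seq_len(L))  # weight desc, canonical order for ties
    counts[o[seq_len(k)]] <- counts[o[seq_len(k)]] + 1
  }
  data.frame(edge = ref, frequency = counts / length(vecs),
             stringsAsFactors = FALSE)
}
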
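#' @include phantom.R
NULL

# links with suppressed structural evidence but intact function (the
# crossing-related connections the structural feature misses entirely)
.faSuppressed <- c("P3|P4", "P5|P7", "P9|P12", "P15|P16")
# links with anisotropy support (true edges minus the suppressed ones, plus
# partial-volume artifacts at crossings/kissings)
.faSpurious <- c("P4|P5", "P5|P6", "P7|P9", "P8|P9", "P9|P10", "P12|P15")

#' Emulate per-link (structural, functional) features for the GMM baseline
#'
#' Builds the joint feature table the mixture baseline consumes: for every
#' candidate link, a mean-anisotropy-like structural value (high where the
#' diffusion signal supports a pathway, near zero elsewhere; the four
#' crossing-suppressed true links P3-P4, P5-P7, P9-P12, P15-P16 get no
#' structural support) and the functional correlation computed from a
#' simulated fMRI instance of the phantom.
#'
#' @param phantom a [PhantomSpec-class].
#' @param seed integer seed.
#' @param recipe a [BoldRecipe-class] for the functional instance.
#' @param faHigh,faNoiseSd structural feature level and noise.
#' @return data.frame with columns `edge`, `structural`, `correlation` and
#'   the generator's ground-truth annotations `trueEdge`, `suppressed`.
#' @export
emulateLinkFeatures <- function(phantom, seed = 1L, recipe = boldRecipe(),
                                faHigh = 0.5, faNoiseSd = 0.03) {
  nodes <- phantom@nodes
  e <- allPairs(length(nodes))
  keys <- paste(nodes[e[, 1]], nodes[e[, 2]], sep = "|")
  trueKeys <- paste(nodes[phantom@edges[, 1]], nodes[phantom@edges[, 2]],
                    sep = "|")
  supported <- setdiff(trueKeys, .faSuppressed)
  faSet <- c(supported, .faSpurious)

  ts <- simulateInstance(phantom, recipe, seed)
  r <- pearsonNetwork(ts)[e]

  s <- withSeed(as.integer(seed) + 24001L, {
    base <- ifelse(keys %in% faSet, faHigh, 0)
    pmax(base + stats::rnorm(length(keys), 0, faNoiseSd), 0)
  })
  data.frame(edge = keys, structural = s, correlation = r,
             trueEdge = keys %in% trueKeys,
             suppressed = keys %in% .faSuppressed,
             stringsAsFactors = FALSE)
}

# log density of a bivariate normal, vectorized over rows of x
dmvnorm2Log <- function(x, mu, sigma) {
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mu)
  -log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

# k-means++ style seeding on standardized features
ppSeed <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (k == 1) return(centers)
  d2 <- rowSums((x - rep(centers[1, ], each = n))^2)
  for (j in 2:k) {
    p <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1, prob = pmax(p, 1e-12)), ]
    d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
  }
  centers
}

#' Fit the joint Gaussian mixture over link features by EM
#'
#' A K-component bivariate Gaussian mixture over per-link (structural,
#' functional correlation) pairs, fit with expectation-maximization:
#' k-means++ seeding (best of `nStart` restarts by final log-likelihood),
#' responsibility-weighted M-step, and a covariance regularization floor of
#' `1e-6` times the feature variances. The log-likelihood is non-decreasing
#' across iterations. Six components model the product of anatomical state
#' (connected / not) and functional sign (positive / negative /
#' uncorrelated).
#'
#' @param features data.frame with `structural` and `correlation` columns
#'   (or a two-column matrix).
#' @param k number of components (6 for the baseline).
#' @param seed integer seed.
#' @param maxIter,tol EM stopping parameters (log-likelihood change).
#' @param nStart number of seeded restarts.
#' @return a [GmmModel-class].
#' @export
fitLinkGMM <- function(features, k = 6L, seed = 1L, maxIter = 500L,
                       tol = 1e-8, nStart = 10L) {
  x <- as.matrix(if (is.data.frame(features))
    features[, c("structural", "correlation")] else features)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < k) stop("need at least k rows")
  if (any(apply(x, 2, stats::var) == 0)) stop("degenerate feature spread")
  regular <- diag(1e-6 * apply(x, 2, stats::var), 2)

  emOnce <- function(centers) {
    mu <- centers
    w <- rep(1 / k, k)
    sig <- array(0, c(2, 2, k))
    v0 <- diag(apply(x, 2, stats::var), 2)
    for (j in seq_len(k)) sig[, , j] <- v0
    ll <- -Inf
    trace <- numeric(0)
    conv <- FALSE
    for (it in seq_len(maxIter)) {
      logd <- vapply(seq_len(k), function(j)
        log(w[j]) + dmvnorm2Log(x, mu[j, ], sig[, , j]), numeric(n))
      mx <- apply(logd, 1, max)
      lse <- mx + log(rowSums(exp(logd - mx)))
      resp <- exp(logd - lse)
      llNew <- sum(lse)
      trace <- c(trace, llNew)
      if (is.finite(ll) && llNew - ll < tol) { conv <- TRUE; ll <- llNew; break }
      ll <- llNew
      nk <- colSums(resp)
      w <- nk / n
      for (j in seq_len(k)) {
        if (nk[j] < 1e-10) stop("singular component after regularization")
        mu[j, ] <- colSums(resp[, j] * x) / nk[j]
        xc <- t(x) - mu[j, ]
        sig[, , j] <- (xc %*% (resp[, j] * t(xc))) / nk[j] + regular
      }
    }
    list(w = w, mu = mu, sig = sig, trace = trace, conv = conv, ll = ll)
  }

  xs <- scale(x)
  best <- NULL
  withSeed(as.integer(seed) + 555L, {
    for (s in seq_len(nStart)) {
      centers <- ppSeed(xs, k)
      centers <- centers * rep(attr(xs, "scaled:scale"), each = k) +
        rep(attr(xs, "scaled:center"), each = k)
      fit <- tryCatch(emOnce(centers), error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$ll > best$ll)) best <- fit
    }
  })
  if (is.null(best)) stop("EM failed for all restarts")
  model <- new("GmmModel", weights = best$w, means = best$mu,
               covariances = best$sig, logLik = best$trace,
               converged = best$conv, categories = data.frame())
  model@categories <- componentCategories(model)
  model
}

# assign (connected x sign) semantics to fitted components. Either kind of
# evidence supports a connection: strong structural signal, or strong
# functional correlation (the premise of the joint model is that functional
# coupling betrays anatomical pathways the structural feature missed). A
# component is therefore "not connected" only when it sits in the lower
# cluster on BOTH axes, with each axis split by exact 1-D 2-means over the
# component means. Functional sign from the mean correlation vs +/- tau.
componentCategories <- function(model, tau = 0.25) {
  mu <- model@means
  k <- nrow(mu)
  upperS <- if (max(mu[, 1]) - min(mu[, 1]) > 0) split2means(mu[, 1])
            else rep(TRUE, k)
  absR <- abs(mu[, 2])
  upperR <- if (max(absR) - min(absR) > 0) split2means(absR)
            else rep(TRUE, k)
  connected <- upperS | upperR
  sign <- ifelse(mu[, 2] >= tau, "positive",
                 ifelse(mu[, 2] <= -tau, "negative", "uncorrelated"))
  data.frame(component = seq_len(k), connected = connected,
             sign = sign, stringsAsFactors = FALSE)
}

#' Classify links with a fitted mixture model
#'
#' Maximal-posterior assignment of each link to one of the mixture
#' components (ties broken by lowest component index), together with the
#' binary anatomical-connectivity call (the union of the connected-state
#' components) and the functional sign category.
#'
#' @param model a fitted [GmmModel-class].
#' @param features data.frame or matrix as in [fitLinkGMM()].
#' @return data.frame with `component`, `connected`, `sign` and the
#'   posterior probability matrix as attribute `posterior`.
#' @export
classifyLinks <- function(model, features) {
  x <- as.matrix(if (is.data.frame(features))
    features[, c("structural", "correlation")] else features)
  storage.mode(x) <- "double"
  n <- nrow(x)
  k <- length(model@weights)
  logd <- vapply(seq_len(k), function(j)
    log(model@weights[j]) + dmvnorm2Log(x, model@means[j, ],
                                        model@covariances[, , j]),
    numeric(n))
  if (n == 1) logd <- matrix(logd, 1)
  mx <- apply(logd, 1, max)
  post <- exp(logd - mx)
  post <- post / rowSums(post)
  comp <- apply(post, 1, function(p) which(p >= max(p) - 1e-12)[1])
  cats <- model@categories
  out <- data.frame(component = comp,
                    connected = cats$connected[comp],
                    sign = cats$sign[comp], stringsAsFactors = FALSE)
  if (is.data.frame(features) && "edge" %in% names(features))
    out <- cbind(edge = features$edge, out, stringsAsFactors = FALSE)
  attr(out, "posterior") <- post
  out
}

#' Repeated-trial GMM classification of phantom links
#'
#' Runs the feature emulation + EM fit + maximal-posterior classification
#' over `nTrials` seeds and reports, per link, the fraction of trials in
#' which it was called anatomically connected (the modal call is
#' `frequency > 0.5`).
#'
#' @param phantom a [PhantomSpec-class].
#' @param nTrials number of trials.
#' @param seed integer base seed.
#' @param recipe a [BoldRecipe-class].
#' @return data.frame with `edge`, `trueEdge`, `suppressed`,
#'   `connectedFrequency`.
#' @export
gmmTrialSummary <- function(phantom = buildPhantom(), nTrials = 100L,
                            seed = 1L, recipe = boldRecipe()) {
  feats0 <- emulateLinkFeatures(phantom, seed + 1L, recipe)
  counts <- numeric(nrow(feats0))
  for (t in seq_len(nTrials)) {
    feats <- emulateLinkFeatures(phantom, seed + t, recipe)
    model <- fitLinkGMM(feats, seed = seed + t)
    cls <- classifyLinks(model, feats)
    counts <- counts + as.numeric(cls$connected)
  }
  data.frame(edge = feats0$edge, trueEdge = feats0$trueEdge,
             suppressed = feats0$suppressed,
             connectedFrequency = counts / nTrials,
             stringsAsFactors = FALSE)
}
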
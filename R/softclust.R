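#' Standardize per-gene temporal profiles of group means
#'
#' Per gene the group means are computed in group order, then z-scored
#' across groups with the population SD (divide by sqrt(mean squared
#' deviation)), so each retained row has mean 0 and SD 1. Genes whose group
#' means are constant carry no temporal shape and are dropped; their ids
#' are attached as attribute \code{dropped} and reported via a message.
#'
#' @param x log2-scale \linkS4class{TimecourseExperiment} with >= 2 groups.
#' @return numeric matrix (genes x groups) of standardized profiles with
#'   attribute \code{dropped}.
#' @export
standardizeProfiles <- function(x) {
    .requireScale(x, "log2")
    go <- groupOrder(x)
    if (length(go) < 2L) stop("need >= 2 groups")
    means <- vapply(go, function(g)
        rowMeans(.groupValues(x, g)), numeric(nrow(x)))
    mu <- rowMeans(means)
    sdPop <- sqrt(rowMeans((means - mu)^2))
    keep <- sdPop > 0
    if (any(!keep))
        message(sprintf("dropped %d constant-profile gene(s)", sum(!keep)))
    prof <- (means[keep, , drop = FALSE] - mu[keep]) / sdPop[keep]
    attr(prof, "dropped") <- rownames(x)[!keep]
    prof
}

# k-means++ style seeding over profile rows (deterministic given the RNG
# state); returns a c x ncol(X) centroid matrix
.kppInit <- function(X, c) {
    n <- nrow(X)
    centers <- matrix(NA_real_, c, ncol(X))
    i <- sample.int(n, 1L)
    centers[1L, ] <- X[i, ]
    d2 <- rowSums((X - rep(centers[1L, ], each = n))^2)
    for (k in seq_len(c - 1L) + 1L) {
        prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        i <- sample.int(n, 1L, prob = prob)
        centers[k, ] <- X[i, ]
        d2 <- pmin(d2, rowSums((X - rep(centers[k, ], each = n))^2))
    }
    centers
}

#' Fuzzy c-means clustering of temporal profiles
#'
#' Standard fuzzy c-means on Euclidean distance (the algorithm behind
#' Mfuzz-style soft time-course clustering): memberships
#' \code{u_ij = (sum_k (d_ij/d_ik)^(2/(m-1)))^-1}, centroids the
#' \code{u^m}-weighted means, iterated until the largest centroid
#' displacement falls below \code{tol} or \code{maxIter} is reached.
#' Profiles coinciding with a centroid get a hard indicator membership.
#' The objective \code{sum u^m d^2} is recorded each iteration and checked
#' to be non-increasing.
#'
#' @param profiles matrix from \code{\link{standardizeProfiles}} (rows =
#'   genes).
#' @param c number of clusters, default 8 (the conventional eight temporal
#'   trend groups).
#' @param m fuzzifier > 1, default 1.25.
#' @param tol convergence tolerance on centroid displacement.
#' @param maxIter iteration cap; hitting it returns \code{converged =
#'   FALSE} with a warning.
#' @param seed integer seed for the k-means++ initialization.
#' @return a \linkS4class{FuzzyClustering}
#' @export
fuzzyCMeans <- function(profiles, c = 8, m = 1.25, tol = 1e-6,
                        maxIter = 500L, seed = 1L) {
    X <- as.matrix(profiles)
    if (c < 2L) stop("c must be >= 2")
    if (m <= 1) stop("fuzzifier m must be > 1")
    if (nrow(unique(X)) < c)
        stop(sprintf("need >= %d distinct profiles", c))
    set.seed(as.integer(seed))
    centers <- .kppInit(X, c)
    n <- nrow(X)
    expo <- -1 / (m - 1)
    trace <- numeric()
    converged <- FALSE
    iter <- 0L
    u <- NULL
    repeat {
        iter <- iter + 1L
        d2 <- vapply(seq_len(c), function(k)
            rowSums((X - rep(centers[k, ], each = n))^2), numeric(n))
        zero <- d2 < .Machine$double.eps
        w <- d2^expo
        u <- w / rowSums(w)
        hit <- rowSums(zero) > 0
        if (any(hit)) {       # profile sits on a centroid
            u[hit, ] <- 0
            u[cbind(which(hit), max.col(-d2[hit, , drop = FALSE]))] <- 1
        }
        obj <- sum(u^m * d2)
        if (length(trace) && obj > trace[length(trace)] * (1 + 1e-10) +
            1e-12)
            stop("internal error: fuzzy c-means objective increased")
        trace <- c(trace, obj)
        um <- u^m
        newCenters <- t(vapply(seq_len(c), function(k) {
            wk <- um[, k]
            if (sum(wk) == 0) centers[k, ]
            else colSums(X * wk) / sum(wk)
        }, numeric(ncol(X))))
        shift <- max(abs(newCenters - centers))
        centers <- newCenters
        if (shift < tol) { converged <- TRUE; break }
        if (iter >= maxIter) break
    }
    if (!converged)
        warning(sprintf("fuzzy c-means did not converge in %d iterations",
                        maxIter))
    dimnames(u) <- list(rownames(X), paste0("Cluster", seq_len(c)))
    dimnames(centers) <- list(paste0("Cluster", seq_len(c)), colnames(X))
    new("FuzzyClustering", centers = centers, membership = u, m = m,
        objective = trace, iterations = iter, converged = converged)
}

#' Hard cluster assignment from memberships
#'
#' Arg-max membership per gene; ties go to the lowest cluster index, and
#' genes whose maximal membership falls below \code{minMembership} are left
#' unassigned (NA).
#'
#' @param fc a \linkS4class{FuzzyClustering}.
#' @param minMembership threshold in [0, 1], default 0 (assign everything).
#' @return named integer vector of cluster indices (NA = unassigned).
#' @export
assignClusters <- function(fc, minMembership = 0) {
    u <- membershipMatrix(fc)
    idx <- max.col(u, ties.method = "first")
    mx <- u[cbind(seq_len(nrow(u)), idx)]
    idx[mx < minMembership] <- NA_integer_
    setNames(idx, rownames(u))
}

#' Label the temporal shape of a centroid
#'
#' Successive differences are compared against a dead zone of
#' \code{eps} times the centroid range: all >= -eps gives \code{mono_up},
#' all <= eps gives \code{mono_down}, a single sign change from positive to
#' negative (interior peak) gives \code{up_down}, anything else
#' \code{other}.
#'
#' @param centroid numeric vector over >= 3 ordered groups.
#' @param eps dead-zone fraction of the range, default 0.05.
#' @return one of \code{"mono_up"}, \code{"mono_down"}, \code{"up_down"},
#'   \code{"other"}.
#' @export
labelClusterShape <- function(centroid, eps = 0.05) {
    if (length(centroid) < 3L) stop("centroid needs >= 3 groups")
    tolV <- eps * diff(range(centroid))
    d <- diff(centroid)
    if (all(d >= -tolV)) return("mono_up")
    if (all(d <= tolV)) return("mono_down")
    s <- sign(d)
    s[abs(d) <= tolV] <- 0
    s <- s[s != 0]
    s <- s[c(TRUE, diff(s) != 0)]   # collapse runs
    if (identical(s, c(1, -1))) return("up_down")
    "other"
}
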
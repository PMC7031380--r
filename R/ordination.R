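# Community-composition statistics: Bray-Curtis dissimilarity, NMDS,
# ANOSIM with permutation (or exhaustive) inference, and marginal
# distance-based linear modelling (DistLM / dbRDA-style variance fractions).

#' Bray-Curtis dissimilarity matrix between samples
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over features, bounded in
#' \[0, 1\]. Samples are the columns of the profile.
#'
#' @param profile Feature x sample matrix of non-negative abundances.
#' @return Symmetric matrix of dissimilarities with sample dimnames.
#' @export
bray_curtis <- function(profile) {
  m <- as.matrix(profile)
  abort_if(any(m < 0), "bray_curtis: negative abundances")
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- sum(m[, i] + m[, j])
      abort_if(denom == 0, "bray_curtis: two all-zero samples (",
               colnames(m)[i], ", ", colnames(m)[j], ")")
      d[i, j] <- d[j, i] <- sum(abs(m[, i] - m[, j])) / denom
    }
  }
  d
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 NMDS via monotone regression (vegan's monoMDS engine),
#' best of `n_restarts` random starts, deterministic given `seed`.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param k Target dimensions (default 2).
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @param n_restarts Number of random starts (default 20).
#' @param maxit Maximum iterations per start.
#' @return List with `points` (n x k, centered), `stress` (stress-1),
#'   `converged`, `seed`.
#' @export
nmds <- function(d, k = 2, seed = 1, n_restarts = 20, maxit = 200) {
  d <- as.matrix(d)
  n <- nrow(d)
  abort_if(k < 1, "nmds: k must be >= 1")
  abort_if(n < k + 2, "nmds: need at least k + 2 samples")
  dd <- stats::as.dist(d)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- vegan::monoMDS(dd, k = k, model = "global", maxit = maxit)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    pts <- scale(best$points, center = TRUE, scale = FALSE)
    attr(pts, "scaled:center") <- NULL
    dimnames(pts) <- list(rownames(d), paste0("NMDS", seq_len(k)))
    list(points = pts, stress = best$stress,
         converged = best$iters < best$maxits,
         seed = seed)
  })
}

# ANOSIM R statistic from the rank vector of the lower-triangle distances
# and a logical within-group mask (both of length n(n-1)/2).
.anosim_r <- function(rank_d, within, n) {
  (mean(rank_d[!within]) - mean(rank_d[within])) / (n * (n - 1) / 4)
}

.within_mask <- function(groups) {
  n <- length(groups)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  groups[idx[, 1L]] == groups[idx[, 2L]]
}

#' Analysis of similarities (ANOSIM)
#'
#' R contrasts mean between-group vs within-group dissimilarity ranks,
#' normalized by M/2 with M = n(n-1)/2; R = 0 under no structure, 1 under
#' complete separation. The p-value counts label permutations whose R is
#' greater than or equal to the observed one (ties count as exceedances):
#' `p = (1 + #exceedances) / (1 + n_perm)`. With `method = "exact"` (two
#' groups only) all distinct label assignments are enumerated instead.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param groups Group labels, >= 2 groups each with >= 2 members.
#' @param n_perm Number of random permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param method `"permutation"` or `"exact"` (exhaustive; 2 groups).
#' @return List with `R`, `p`, `n_perm` (or number of enumerated splits).
#' @export
anosim <- function(d, groups, n_perm = 999, seed = 1,
                   method = c("permutation", "exact")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  n <- nrow(d)
  groups <- factor(groups)
  abort_if(length(groups) != n, "anosim: groups length mismatch")
  abort_if(nlevels(groups) < 2, "anosim: need >= 2 groups")
  abort_if(any(table(groups) < 2), "anosim: singleton group")
  rank_d <- rank(d[lower.tri(d)])
  r_obs <- .anosim_r(rank_d, .within_mask(groups), n)
  if (method == "exact") {
    abort_if(nlevels(groups) != 2, "anosim: exact enumeration needs 2 groups")
    k <- sum(groups == levels(groups)[1L])
    splits <- utils::combn(n, k)
    r_perm <- apply(splits, 2L, function(sel) {
      g <- rep(levels(groups)[2L], n)
      g[sel] <- levels(groups)[1L]
      .anosim_r(rank_d, .within_mask(g), n)
    })
    p <- mean(r_perm >= r_obs - 1e-12)
    return(list(R = r_obs, p = p, n_perm = ncol(splits), method = "exact"))
  }
  r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    .anosim_r(rank_d, .within_mask(sample(groups)), n)
  }, 0))
  p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm)
  list(R = r_obs, p = p, n_perm = n_perm, method = "permutation")
}

# Gower-centered inner-product matrix from a distance matrix.
gower_center <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

.distlm_one <- function(g, x, n_perm, seed) {
  n <- nrow(g)
  abort_if(stats::sd(x) == 0, "distlm: constant predictor")
  trg <- sum(diag(g))
  abort_if(trg <= 0, "distlm: non-positive total sum of squares (tr G <= 0)")
  xm <- cbind(1, x)
  h <- xm %*% solve(crossprod(xm)) %*% t(xm)
  m <- qr(xm)$rank - 1L
  fstat_of <- function(gmat) {
    ss_fit <- sum(diag(h %*% gmat %*% h))
    ihg <- (diag(n) - h) %*% gmat %*% (diag(n) - h)
    ss_res <- sum(diag(ihg))
    (ss_fit / m) / (ss_res / (n - m - 1))
  }
  prop <- sum(diag(h %*% g %*% h)) / trg
  f_obs <- fstat_of(g)
  f_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample(n)
    fstat_of(g[idx, idx])
  }, 0))
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  list(proportion = prop, pseudo_F = f_obs, p = p)
}

#' Marginal distance-based linear model (DistLM)
#'
#' For each predictor alone: Gower-centers the squared distances into G,
#' projects onto the predictor's hat matrix H (with intercept), and reports
#' the explained proportion tr(HGH)/tr(G) with a pseudo-F tested by
#' permutation of sample labels. In the Euclidean univariate limit the
#' proportion equals the OLS R-squared. Bonferroni adjusts across the tested
#' predictors.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param predictors Numeric vector (one predictor) or data.frame/matrix of
#'   predictors, rows aligned with the samples of `d`.
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed.
#' @return data.frame: predictor, proportion, pseudo_F, p, p_bonferroni.
#' @export
distlm_marginal <- function(d, predictors, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  n <- nrow(d)
  abort_if(n < 4, "distlm: need >= 4 samples")
  if (is.null(dim(predictors))) {
    predictors <- data.frame(predictor = predictors)
  }
  predictors <- as.data.frame(predictors)
  abort_if(nrow(predictors) != n, "distlm: predictor length mismatch")
  abort_if(any(!vapply(predictors, is.numeric, TRUE)),
           "distlm: predictors must be numeric")
  abort_if(anyNA(predictors), "distlm: predictors must be finite (no NA)")
  g <- gower_center(d)
  rows <- lapply(seq_along(predictors), function(i) {
    res <- .distlm_one(g, predictors[[i]], n_perm, seed + i - 1L)
    data.frame(predictor = names(predictors)[i],
               proportion = res$proportion, pseudo_F = res$pseudo_F,
               p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni(out$p, m = nrow(out))
  out
}

#' Write a distance matrix as square TSV
#' @param d Symmetric matrix with sample dimnames.
#' @param path Output path.
#' @export
write_distance <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), as.matrix(d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square distance matrix TSV
#' @param path File written by [write_distance()].
#' @return Symmetric numeric matrix.
#' @export
read_distance <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  abort_if(!is_square_symmetric(m, tol = 1e-8), "distance matrix not symmetric")
  m
}
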
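change_matrix <- function(table, regions) {
  m <- as.matrix(table[, paste0("d_", regions), drop = FALSE])
  colnames(m) <- regions
  m
}

#' Cross-region correlation of yearly change
#'
#' Pairwise complete-case Pearson correlations of the regional change
#' columns, with a summary of the off-diagonal coefficients.
#'
#' @param table change table.
#' @param regions region names (>= 2; default all).
#' @return List with `matrix` (symmetric, unit diagonal) and `summary`
#'   (mean, sd, range of the off-diagonal entries).
#' @export
change_correlation <- function(table, regions = region_cols(table)) {
  if (length(regions) < 2) stop("need >= 2 regions", call. = FALSE)
  m <- change_matrix(table, regions)
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds)) || any(sds == 0))
    stop("region with zero variance: ",
         paste(regions[!is.finite(sds) | sds == 0], collapse = ", "), call. = FALSE)
  C <- stats::cor(m, use = "pairwise.complete.obs")
  off <- C[lower.tri(C)]
  list(matrix = C,
       summary = c(mean = mean(off), sd = stats::sd(off),
                   min = min(off), max = max(off)))
}

#' PCA of regional change
#'
#' Eigen-decomposition of the change correlation matrix (or of a supplied
#' symmetric matrix). The first component is oriented so its mean loading is
#' positive; a shared-sign PC1 indicates a global factor of brain decline.
#'
#' @param x a change table, or a symmetric correlation matrix.
#' @param regions regions used when `x` is a table.
#' @return List with `var_fraction` (sums to 1), `eigenvalues` and
#'   `loadings` (PC1).
#' @export
pca_summary <- function(x, regions = NULL) {
  C <- if (is.matrix(x) && nrow(x) == ncol(x) &&
           isTRUE(all.equal(unname(diag(x)), rep(1, ncol(x))))) x
  else change_correlation(x, if (is.null(regions)) region_cols(x) else regions)$matrix
  if (max(abs(C - t(C))) > 1e-8) stop("matrix is not symmetric", call. = FALSE)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(e$values))
    stop("matrix is not positive semi-definite", call. = FALSE)
  l <- e$vectors[, 1]
  if (mean(l) < 0) l <- -l
  names(l) <- colnames(C)
  list(var_fraction = e$values / sum(e$values), eigenvalues = e$values,
       loadings = l)
}

## spectral clustering of regions from a subjects x regions matrix:
## correlation distance -> Gaussian affinity (sigma = median off-diagonal
## distance) -> symmetric normalized Laplacian -> k-means on the top
## eigenvectors. Returns assignments for each K in `Ks`.
spectral_assignments <- function(X, Ks, nstart = 10) {
  C <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- 0
  D <- sqrt(pmax(2 * (1 - C), 0))
  sig <- stats::median(D[lower.tri(D)])
  if (!is.finite(sig) || sig <= 0) sig <- 1
  A <- exp(-D^2 / (2 * sig^2))
  diag(A) <- 0
  deg <- pmax(rowSums(A), 1e-12)
  L <- diag(nrow(A)) - sweep(sweep(A, 1, sqrt(deg), "/"), 2, sqrt(deg), "/")
  ev <- eigen(L, symmetric = TRUE)
  p <- nrow(A)
  lapply(Ks, function(K) {
    U <- ev$vectors[, seq(p, p - K + 1), drop = FALSE]
    rn <- sqrt(rowSums(U^2)); rn[rn == 0] <- 1
    U <- U / rn
    stats::kmeans(U, centers = K, nstart = nstart, iter.max = 50)$cluster
  })
}

## sorted eigenvalues of the symmetric normalized affinity Laplacian of the
## full data (used for model-order tie-breaks)
laplacian_eigenvalues <- function(X) {
  C <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- 0
  D <- sqrt(pmax(2 * (1 - C), 0))
  sig <- stats::median(D[lower.tri(D)])
  if (!is.finite(sig) || sig <= 0) sig <- 1
  A <- exp(-D^2 / (2 * sig^2))
  diag(A) <- 0
  deg <- pmax(rowSums(A), 1e-12)
  L <- diag(nrow(A)) - sweep(sweep(A, 1, sqrt(deg), "/"), 2, sqrt(deg), "/")
  sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
}

## PAC (proportion of ambiguous clustering) per K for one dataset: consensus
## over `reps` subsamples of `frac` of the subjects
pac_profile <- function(X, Ks, reps, frac = 0.8, window = c(0.1, 0.9)) {
  p <- ncol(X)
  cons <- lapply(Ks, function(K) matrix(0, p, p))
  n <- nrow(X)
  for (b in seq_len(reps)) {
    rows <- sample.int(n, max(2, floor(frac * n)))
    asg <- spectral_assignments(X[rows, , drop = FALSE], Ks)
    for (j in seq_along(Ks))
      cons[[j]] <- cons[[j]] + outer(asg[[j]], asg[[j]], "==")
  }
  vapply(seq_along(Ks), function(j) {
    M <- cons[[j]] / reps
    off <- M[lower.tri(M)]
    mean(off > window[1] & off < window[2])
  }, numeric(1))
}

## structureless reference data: regions drawn as independent Gaussian
## vectors with the observed per-region variances. Under the null of "no
## region structure" the clustered units (regions) are exchangeable and
## mutually uncorrelated; any null that re-injects the observed spectrum
## into random region subsets is itself stably clusterable (the cluster
## signal lives in the spectrum) and would defeat the K = 1 test.
reference_null_data <- function(X) {
  n <- nrow(X); p <- ncol(X)
  sds <- apply(X, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  sweep(matrix(stats::rnorm(n * p), n, p), 2, sds, "*")
}

#' Monte-Carlo reference consensus clustering of regional change
#'
#' Selects the number of clusters of regions by consensus clustering with a
#' simulated structureless reference. For each K in `2..K_max`, a consensus
#' matrix is accumulated over `reps` spectral clusterings of 80% subject
#' subsamples and summarized by the PAC (proportion of ambiguous clustering:
#' consensus entries in (0.1, 0.9); lower is more stable). The same
#' procedure applied to `null_reps` reference datasets (independent
#' Gaussian regions with the observed per-region variances: the
#' structureless null under which the clustered units are exchangeable)
#' yields a null PAC distribution per K; the stability score is
#' `mean(log PAC_ref) - log PAC_obs` and the per-K p-value is the fraction
#' of reference PACs at or below the observed one. `K*` is the
#' stability-maximizing K among those rejecting K = 1 at `alpha`, else 1.
#' Because several K are scanned, rejection of K = 1 is gated on a
#' family-wise test (`p_global`): the best observed stability against the
#' distribution of the best null stability. When several significant K sit
#' at the PAC floor (essentially perfect consensus, typical for clean
#' structure at large n) the Laplacian eigengap of the full-data affinity
#' breaks the tie.
#'
#' @param table change table (or a plain subjects x regions data frame of
#'   change columns named `d_<region>`).
#' @param regions regions to cluster (>= 4).
#' @param K_max largest K considered (`< length(regions)`).
#' @param reps consensus subsamples per dataset (default 100).
#' @param null_reps reference datasets (default 100).
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @param alpha level of the K = 1 rejection test.
#' @return Object of class `cluster_solution`: list with `K_star`,
#'   `assignments` (region -> cluster, for `K_star`; all regions in cluster
#'   1 when `K_star = 1`), and `stats` (per-K data frame: `K`, `pac`,
#'   `pac_ref_mean`, `stability`, `p`).
#' @export
consensus_cluster <- function(table, regions = region_cols(table), K_max = 6,
                              reps = 100, null_reps = 100, seed = 1,
                              alpha = 0.05) {
  if (length(regions) < 4) stop("need >= 4 regions to cluster", call. = FALSE)
  if (K_max >= length(regions)) stop("K_max must be < number of regions", call. = FALSE)
  X <- change_matrix(table, regions)
  X <- X[rowSums(is.na(X)) == 0, , drop = FALSE]
  Ks <- 2:K_max
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pac_obs <- pac_profile(X, Ks, reps)
  pac_ref <- matrix(NA_real_, null_reps, length(Ks))
  for (r in seq_len(null_reps))
    pac_ref[r, ] <- pac_profile(reference_null_data(X), Ks, reps)
  eps <- 1e-4
  ref_mean_log <- colMeans(log(pac_ref + eps))
  stability <- ref_mean_log - log(pac_obs + eps)
  pK <- vapply(seq_along(Ks), function(j)
    (1 + sum(pac_ref[, j] <= pac_obs[j])) / (null_reps + 1), numeric(1))
  ## family-wise K = 1 test: several K are scanned, so comparing the best
  ## observed stability against the distribution of the best *null*
  ## stability keeps the rejection of K = 1 at its nominal level
  stab_null_max <- apply(sweep(-log(pac_ref + eps), 2, ref_mean_log, "+"), 1, max)
  p_global <- (1 + sum(stab_null_max >= max(stability))) / (null_reps + 1)
  sig <- if (p_global < alpha) which(pK < alpha) else integer(0)
  ## degenerate-PAC handler: when several significant K are at the PAC floor
  ## the log-stability score cannot rank them; the Laplacian eigengap of the
  ## full-data affinity then decides (largest gap after the K-th eigenvalue)
  K_star <- if (!length(sig)) 1L else {
    floor_set <- sig[pac_obs[sig] < 0.005]
    if (length(floor_set) > 1) {
      lam <- laplacian_eigenvalues(X)
      gaps <- lam[Ks[floor_set] + 1] - lam[Ks[floor_set]]
      Ks[floor_set][which.max(gaps)]
    } else Ks[sig[which.max(stability[sig])]]
  }
  assignments <- if (K_star > 1)
    stats::setNames(spectral_assignments(X, K_star)[[1]], regions)
  else stats::setNames(rep(1L, length(regions)), regions)
  structure(list(K_star = as.integer(K_star), assignments = assignments,
                 stats = data.frame(K = Ks, pac = pac_obs,
                                    pac_ref_mean = colMeans(pac_ref),
                                    stability = stability, p = pK),
                 p_global = p_global, seed = seed),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("Consensus clustering: K* =", x$K_star,
      sprintf("(family-wise K=1 test p = %.3f)\n", x$p_global))
  print(x$stats, row.names = FALSE, digits = 3)
  invisible(x)
}

## sign-aligned mean score over a cluster's member regions: each region is
## flipped to agree with the cluster's mean pattern, then averaged
cluster_score <- function(table, members) {
  M <- change_matrix(table, members)
  if (length(members) == 1) return(list(score = M[, 1], weight = table[[paste0("w_", members)]]))
  base <- rowMeans(M, na.rm = TRUE)
  sgn <- vapply(seq_along(members), function(j) {
    r <- suppressWarnings(stats::cor(M[, j], base, use = "pairwise.complete.obs"))
    if (!is.finite(r) || r >= 0) 1 else -1
  }, numeric(1))
  W <- as.matrix(table[, paste0("w_", members), drop = FALSE])
  list(score = rowMeans(sweep(M, 2, sgn, "*"), na.rm = FALSE),
       weight = rowMeans(W, na.rm = FALSE))
}

#' Cluster-score models of memory change
#'
#' Asks whether change in each cluster of regions carries information about
#' memory change beyond (i) the hippocampal (reference) cluster, (ii) the
#' global PC1 decline score, and (iii) the other clusters (all clusters
#' jointly). Cluster scores are sign-aligned means of member-region change;
#' the models are weighted smooth fits with dataset offsets and
#' wild-bootstrap p-values. Also reports the partial variance explained by
#' the joint-cluster model relative to a PC1-only model.
#'
#' @param table change table.
#' @param solution a `cluster_solution` (or named region -> cluster vector).
#' @param reference_cluster id of the control cluster for family (i)
#'   (default: the cluster whose score correlates most with memory change).
#' @param B,seed wild-bootstrap settings.
#' @return List with `per_cluster` (data frame: cluster, family, beta_w,
#'   edf, p_boot, n) and `joint_vs_pc1` (partial R^2).
#' @export
cluster_memory_models <- function(table, solution, reference_cluster = NULL,
                                  B = 199, seed = 1) {
  asg <- if (inherits(solution, "cluster_solution")) solution$assignments else solution
  clusters <- sort(unique(asg))
  if (length(clusters) < 2) stop("need >= 2 clusters", call. = FALSE)
  regions <- names(asg)
  scores <- lapply(clusters, function(cl) cluster_score(table, regions[asg == cl]))
  names(scores) <- paste0("cl", clusters)
  pc <- pca_summary(table, regions)
  M <- change_matrix(table, regions)
  pc1 <- as.numeric(scale(M, center = TRUE, scale = FALSE) %*% pc$loadings)

  dd <- data.frame(d_memory = table$d_memory, dataset_id = factor(table$dataset_id),
                   pc1 = pc1)
  for (nm in names(scores)) {
    dd[[nm]] <- scores[[nm]]$score
    dd[[paste0("w_", nm)]] <- scores[[nm]]$weight
  }
  sc_cols <- names(scores)
  for (a in sc_cols) for (b in setdiff(sc_cols, a)) {
    r <- suppressWarnings(stats::cor(dd[[a]], dd[[b]], use = "pairwise.complete.obs"))
    if (is.finite(r) && abs(r) > 1 - 1e-10)
      stop("control cluster score is identical to the predictor (collinear)",
           call. = FALSE)
  }
  if (is.null(reference_cluster)) {
    rmem <- vapply(sc_cols, function(nm)
      abs(suppressWarnings(stats::cor(dd[[nm]], dd$d_memory,
                                      use = "pairwise.complete.obs"))), numeric(1))
    reference_cluster <- clusters[which.max(rmem)]
  }
  ref_col <- paste0("cl", reference_cluster)

  fit_family <- function(target, controls, wcol, sd_off) {
    rhs_ctl <- c(vapply(controls, smooth_term, ""), offset_term("dataset_id"))
    full <- fit_wgam(stats::reformulate(c(smooth_term(target), rhs_ctl),
                                        response = "d_memory"), dd, weights = wcol)
    null <- fit_wgam(stats::reformulate(rhs_ctl, response = "d_memory"),
                     dd[rownames(full$data), , drop = FALSE],
                     weights = full$weights)
    bt <- wild_bootstrap_p(full, null, B = B, seed = seed + sd_off)
    data.frame(beta_w = density_weighted_beta(full, target),
               edf = term_edf(full, paste0("s(", target, ")")),
               p_boot = bt$p, n = nrow(full$data))
  }

  out <- list(); k <- 0
  for (cl in clusters) {
    nm <- paste0("cl", cl); wc <- paste0("w_", nm)
    fams <- list()
    if (nm != ref_col)
      fams$vs_reference <- fit_family(nm, ref_col, wc, k + 1)
    fams$vs_pc1 <- fit_family(nm, "pc1", wc, k + 2)
    fams$joint <- fit_family(nm, setdiff(sc_cols, nm), wc, k + 3)
    for (f in names(fams)) {
      out[[length(out) + 1]] <- cbind(data.frame(cluster = cl, family = f),
                                      fams[[f]])
    }
    k <- k + 10
  }
  per_cluster <- do.call(rbind, out)

  ## joint-cluster vs PC1-only variance explained (non-nested, descriptive)
  wavg <- rowMeans(as.matrix(dd[, paste0("w_", sc_cols), drop = FALSE]))
  dd$.wavg <- wavg
  keep <- stats::complete.cases(dd[, c("d_memory", sc_cols, "pc1", ".wavg")])
  joint <- fit_wgam(stats::reformulate(c(vapply(sc_cols, smooth_term, ""),
                                         offset_term("dataset_id")),
                                       response = "d_memory"),
                    dd[keep, ], weights = ".wavg")
  pc1m <- fit_wgam(stats::reformulate(c(smooth_term("pc1"), offset_term("dataset_id")),
                                      response = "d_memory"),
                   dd[keep, ], weights = ".wavg")
  base <- fit_wgam(stats::reformulate(offset_term("dataset_id"),
                                      response = "d_memory"),
                   dd[keep, ], weights = ".wavg")
  joint_vs_pc1 <- partial_r2(joint, base) - partial_r2(pc1m, base)
  list(per_cluster = per_cluster, joint_vs_pc1 = joint_vs_pc1,
       reference_cluster = reference_cluster)
}
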
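#' Bray-Curtis dissimilarity matrix
#'
#' `d(u, v) = sum |u_i - v_i| / sum (u_i + v_i)` between nonnegative
#' abundance rows; 0 for identical rows, 1 for disjoint support.
#'
#' @param x nonnegative matrix (items x features), e.g. an OTU table.
#' @return a `dist` object with attribute `metric = "bray-curtis"`.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("rows must be nonnegative")
  zero <- rowSums(x) == 0
  if (sum(zero) >= 2)
    stop("distance undefined between all-zero rows: ",
         paste(rownames(x)[zero], collapse = ", "))
  d <- vegan::vegdist(x, method = "bray")
  attr(d, "metric") <- "bray-curtis"
  d
}

#' Euclidean distance matrix
#'
#' Standard Euclidean distance between rows; for a scalar trait (a
#' vector) this is the absolute difference.
#'
#' @param x numeric vector (one scalar per item) or matrix (items x
#'   dimensions); names/rownames label the items.
#' @return a `dist` object with attribute `metric = "euclidean"`.
#' @export
euclidean_dist <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1, dimnames = list(names(x)))
  if (anyNA(x)) {
    bad <- rownames(x)[apply(is.na(x), 1, any)] %||%
      which(apply(is.na(x), 1, any))
    stop("missing values for: ", paste(bad, collapse = ", "))
  }
  d <- dist(x)
  attr(d, "metric") <- "euclidean"
  d
}

#' Principal coordinates analysis
#'
#' Classical scaling: eigendecomposition of the Gower double-centred
#' matrix \eqn{-\tfrac12 J D^2 J}, coordinates scaled by the square root
#' of each eigenvalue. Negative eigenvalues are reported raw and excluded
#' from the proportion-explained denominator; a Lingoes correction is
#' available via `correction`.
#'
#' @param d a `dist` object (or symmetric matrix).
#' @param n_axes number of axes to return (default 2).
#' @param correction `"none"` (default) or `"lingoes"`.
#' @return object of class `pcoa_result`: `coordinates` (items x axes),
#'   `eigenvalues`, `proportion_explained`, `correction`.
#' @export
pcoa <- function(d, n_axes = 2, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  d <- as.dist(d)
  n <- attr(d, "Size")
  if (n < 3) stop("need at least 3 items")
  fit <- suppressWarnings(
    cmdscale(d, k = n - 1, eig = TRUE, add = correction == "lingoes"))
  eig <- fit$eig
  pos <- sum(eig > max(eig) * 1e-9)
  if (n_axes > pos) {
    warning(sprintf("only %d positive eigenvalue(s); truncating axes", pos))
    n_axes <- pos
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(n_axes))
  prop <- ifelse(eig > 0, eig / sum(eig[eig > 0]), 0)
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 proportion_explained = prop[seq_len(n_axes)],
                 n_positive = pos,
                 correction = correction),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d items, %d axes (of %d positive eigenvalues)\n",
              nrow(x$coordinates), ncol(x$coordinates), x$n_positive))
  cat("proportion explained:",
      paste(sprintf("%.1f%%", 100 * x$proportion_explained),
            collapse = ", "), "\n")
  invisible(x)
}

#' Group centroids with standard errors in ordination space
#'
#' @param pcoa_result a [pcoa()] result.
#' @param groups factor of group membership, in item order.
#' @return data frame with per-group mean and SE of each axis.
#' @export
group_centroids <- function(pcoa_result, groups) {
  groups <- as.factor(groups)
  co <- pcoa_result$coordinates
  out <- do.call(rbind, lapply(levels(groups), function(g) {
    m <- co[groups == g, , drop = FALSE]
    data.frame(group = g,
               axis = colnames(co),
               mean = colMeans(m),
               se = apply(m, 2, sd) / sqrt(nrow(m)),
               row.names = NULL)
  }))
  out
}

## within-group sum of squared distances / group sizes, from the squared
## distance matrix and an integer group index vector
.ss_within <- function(D2, idx_by_group) {
  s <- 0
  for (ix in idx_by_group) s <- s + sum(D2[ix, ix]) / (2 * length(ix))
  s
}

#' One-way PERMANOVA
#'
#' Anderson's permutational multivariate ANOVA on a distance matrix:
#' pseudo-F from within-group pairwise squared distances,
#' \eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / N},
#' \eqn{SS_{within} = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g},
#' \eqn{F = (SS_{between}/(a-1)) / (SS_{within}/(N-a))}. Significance by
#' permuting group labels: `p = (1 + #{F* >= F}) / (1 + n_permutations)`.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param groups factor of group membership, in item order.
#' @param n_permutations number of label permutations (default 999).
#' @param seed optional seed for reproducible permutations.
#' @return object of class `permanova`: `pseudo_F`, `R2`, `p_value`,
#'   sums of squares, `n_permutations`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = NULL) {
  D2 <- as.matrix(as.dist(d))^2
  groups <- droplevels(as.factor(groups))
  N <- nrow(D2)
  if (length(groups) != N) stop("groups length must match distance matrix")
  a <- nlevels(groups)
  if (a < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 members")
  ss_total <- sum(D2) / (2 * N)
  if (ss_total <= .Machine$double.eps) {
    ## all items coincide: no variation to partition
    return(structure(list(pseudo_F = NaN, R2 = 0, p_value = 1,
                          ss_total = 0, ss_between = 0, ss_within = 0,
                          df = c(between = a - 1, within = N - a),
                          n_permutations = n_permutations),
                     class = "permanova"))
  }
  obs_idx <- split(seq_len(N), groups)
  ss_w <- .ss_within(D2, obs_idx)
  ss_b <- ss_total - ss_w
  f_obs <- (ss_b / (a - 1)) / (ss_w / (N - a))
  if (!is.null(seed)) set.seed(seed)
  sizes <- lengths(obs_idx)
  f_perm <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(N)
    idx <- split(perm, rep.int(seq_along(sizes), sizes))
    ssw <- .ss_within(D2, idx)
    f_perm[b] <- ((ss_total - ssw) / (a - 1)) / (ssw / (N - a))
  }
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
  structure(list(pseudo_F = f_obs, R2 = ss_b / ss_total, p_value = p,
                 ss_total = ss_total, ss_between = ss_b, ss_within = ss_w,
                 df = c(between = a - 1, within = N - a),
                 n_permutations = n_permutations),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (one-way)\n")
  cat(sprintf("  pseudo-F = %.4f  R2 = %.4f  p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p_value, x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA over all unordered group pairs
#'
#' Runs a two-group PERMANOVA on the sub-matrix of each pair's members.
#' Benjamini-Hochberg adjustment across pairs is on by default; raw
#' p-values are always reported.
#'
#' @inheritParams permanova
#' @param adjust `"BH"` (default) or `"none"`.
#' @return data frame of class `pairwise_permanova`: one row per pair
#'   with `group_1`, `group_2`, `pseudo_F`, `R2`, `p_value`, `p_adjusted`.
#' @export
pairwise_permanova <- function(d, groups, n_permutations = 999, seed = NULL,
                               adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  D <- as.matrix(as.dist(d))
  groups <- droplevels(as.factor(groups))
  levs <- levels(groups)
  pairs <- combn(levs, 2, simplify = FALSE)
  res <- do.call(rbind, lapply(seq_along(pairs), function(k) {
    pr <- pairs[[k]]
    keep <- groups %in% pr
    sub <- as.dist(D[keep, keep, drop = FALSE])
    fit <- permanova(sub, droplevels(groups[keep]), n_permutations,
                     seed = if (is.null(seed)) NULL else seed + k)
    data.frame(group_1 = pr[1], group_2 = pr[2],
               pseudo_F = fit$pseudo_F, R2 = fit$R2,
               p_value = fit$p_value, stringsAsFactors = FALSE)
  }))
  res$p_adjusted <- if (adjust == "BH") p.adjust(res$p_value, "BH")
                    else res$p_value
  class(res) <- c("pairwise_permanova", "data.frame")
  attr(res, "n_permutations") <- n_permutations
  res
}

#' Species-level community profiles
#'
#' Aggregates replicate samples to one profile per species: the mean of
#' per-sample relative abundances (default) or pooled counts.
#'
#' @param otu_table count matrix (samples x OTUs).
#' @param metadata data frame with `sample_id`, `species_id`.
#' @param method `"mean_relative"` (default) or `"pooled"`.
#' @return matrix (species x OTUs) of relative abundances.
#' @export
species_profiles <- function(otu_table, metadata,
                             method = c("mean_relative", "pooled")) {
  method <- match.arg(method)
  validate_tables(otu_table, metadata)
  sp <- metadata$species_id[match(rownames(otu_table), metadata$sample_id)]
  if (method == "mean_relative") {
    tot <- rowSums(otu_table)
    if (any(tot == 0)) stop("all-zero sample(s) cannot be normalised")
    rel <- otu_table / tot
    prof <- rowsum(rel, sp) / as.vector(table(sp)[sort(unique(sp))])
  } else {
    pooled <- rowsum(otu_table, sp)
    prof <- pooled / rowSums(pooled)
  }
  prof[unique(sp), , drop = FALSE]
}
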
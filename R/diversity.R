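#' Rarefy a count table to a common depth
#'
#' Subsamples each sample's reads without replacement (hypergeometric) so
#' every row sums exactly to `depth`. One draw per call; deterministic
#' under `seed`.
#'
#' @param otu_table integer matrix (samples x OTUs).
#' @param depth target depth, or `"min"` for the minimum sample total.
#' @param seed optional integer seed.
#' @return integer matrix with equal row sums.
#' @export
rarefy <- function(otu_table, depth = "min", seed = NULL) {
  totals <- rowSums(otu_table)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(depth)
  short <- rownames(otu_table)[totals < depth]
  if (length(short))
    stop("sample total below requested depth for: ",
         paste(short, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  ## inputs are validated above; silence vegan's heuristic warning that
  ## fires whenever the smallest positive count exceeds 1
  out <- withCallingHandlers(
    vegan::rrarefy(otu_table, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(otu_table)
  out
}

#' Per-sample alpha diversity
#'
#' OTU richness (taxa with count > 0) and Shannon diversity
#' `H = -sum p_i log p_i` over nonzero proportions (natural log by
#' default, as in vegan).
#'
#' @param otu_table nonnegative count matrix (samples x OTUs).
#' @param base logarithm base for Shannon (default `exp(1)`).
#' @return data frame with `sample_id`, `richness`, `shannon`.
#' @examples
#' alpha_diversity(rbind(s1 = c(10, 10, 10, 10)))  # shannon = log(4)
#' @export
alpha_diversity <- function(otu_table, base = exp(1)) {
  if (any(otu_table < 0)) stop("counts must be nonnegative")
  tot <- rowSums(otu_table)
  if (any(tot == 0))
    warning("all-zero sample(s): ",
            paste(rownames(otu_table)[tot == 0], collapse = ", "),
            " (richness 0, shannon 0)")
  data.frame(
    sample_id = rownames(otu_table) %||% as.character(seq_len(nrow(otu_table))),
    richness = as.integer(rowSums(otu_table > 0)),
    shannon = as.numeric(vegan::diversity(otu_table, index = "shannon",
                                          base = base)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a one-factor GLM of a diversity metric on functional group
#'
#' Poisson with log link for richness-like counts, Gaussian with identity
#' link for Shannon-like metrics; fitted by iteratively reweighted least
#' squares to convergence tolerance 1e-8 (error if not converged). With a
#' single group an intercept-only model is fitted.
#'
#' @param values numeric response, one per sample.
#' @param groups factor or character of the same length.
#' @param family `"poisson"` or `"gaussian"`.
#' @return object of class `group_glm`: the `glm` fit plus a coefficient
#'   table (Wald z for Poisson, t for Gaussian), group means, reference
#'   level.
#' @export
fit_group_glm <- function(values, groups, family = c("poisson", "gaussian")) {
  family <- match.arg(family)
  groups <- droplevels(as.factor(groups))
  if (length(values) != length(groups))
    stop("values and groups must have equal length")
  if (any(table(groups) < 2) && nlevels(groups) > 1)
    stop("every group needs at least 2 samples")
  if (family == "poisson" && any(abs(values - round(values)) > 1e-8))
    stop("poisson family requires integer responses")
  fam <- if (family == "poisson") poisson(link = "log")
         else gaussian(link = "identity")
  dat <- data.frame(y = values, group = groups)
  fml <- if (nlevels(groups) > 1) y ~ group else y ~ 1
  fit <- glm(fml, family = fam, data = dat,
             control = glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("GLM did not converge")
  ct <- summary(fit)$coefficients
  structure(list(fit = fit, family = family,
                 coefficients = ct,
                 reference = levels(groups)[1],
                 group_means = tapply(values, groups, mean)),
            class = "group_glm")
}

#' @export
print.group_glm <- function(x, ...) {
  cat(sprintf("Group GLM (%s, reference %s)\n", x$family, x$reference))
  stats::printCoefmat(x$coefficients)
  invisible(x)
}

#' @export
coef.group_glm <- function(object, ...) coef(object$fit)

#' Pairwise group p-values from Wald contrasts
#'
#' Refits the one-factor GLM with each group as the reference level and
#' collects the Wald p-value of every pairwise contrast into a symmetric
#' matrix (diagonal NA). Unadjusted by default, matching a plain
#' p < 0.05 letter display; set `adjust` for a p.adjust method.
#'
#' @inheritParams fit_group_glm
#' @param adjust p-adjustment method (default `"none"`).
#' @return symmetric matrix of p-values over groups.
#' @export
pairwise_group_p <- function(values, groups, family = c("poisson", "gaussian"),
                             adjust = "none") {
  family <- match.arg(family)
  groups <- droplevels(as.factor(groups))
  levs <- levels(groups)
  if (length(levs) < 2) stop("need at least 2 groups")
  p <- matrix(NA_real_, length(levs), length(levs),
              dimnames = list(levs, levs))
  for (ref in levs[-length(levs)]) {
    fit <- fit_group_glm(values, relevel(groups, ref = ref), family)
    ct <- fit$coefficients
    rows <- grep("^group", rownames(ct), value = TRUE)
    for (r in rows) {
      other <- sub("^group", "", r)
      if (is.na(p[ref, other])) {
        p[ref, other] <- p[other, ref] <- ct[r, 4]
      }
    }
  }
  if (adjust != "none") {
    up <- upper.tri(p)
    p[up] <- p.adjust(p[up], method = adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  p
}

## All cliques of the "not significantly different" graph on <= n
## vertices, as logical membership vectors.
.ns_cliques <- function(ns) {
  n <- nrow(ns)
  cliques <- list()
  for (code in seq_len(2^n - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (length(members) > 1) {
      pr <- combn(members, 2)
      ok <- all(ns[cbind(pr[1, ], pr[2, ])])
    }
    if (ok) cliques[[length(cliques) + 1]] <- members
  }
  ## keep maximal cliques only
  keep <- vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(cj)
      length(cj) > length(cliques[[i]]) && all(cliques[[i]] %in% cj),
      logical(1)))
  }, logical(1))
  cliques[keep]
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Groups sharing a letter are not significantly different at `alpha`;
#' groups with no shared letter differ. For up to 8 groups the display
#' uses the provably minimal number of letters (an exact minimum edge
#' clique cover of the non-significance graph); larger problems fall back
#' to a greedy cover.
#'
#' @param pairwise_p symmetric matrix of p-values with group dimnames.
#' @param alpha significance threshold (default 0.05).
#' @return object of class `letter_display`: named letter strings, the
#'   p matrix and `alpha`.
#' @export
sig_letters <- function(pairwise_p, alpha = 0.05) {
  p <- as.matrix(pairwise_p)
  if (nrow(p) != ncol(p) ||
      !isTRUE(all.equal(p[upper.tri(p)], t(p)[upper.tri(p)])))
    stop("pairwise_p must be a symmetric matrix")
  n <- nrow(p)
  levs <- rownames(p) %||% as.character(seq_len(n))
  ns <- !(p < alpha)          # non-significant (NA diagonal -> TRUE)
  ns[is.na(ns)] <- TRUE
  diag(ns) <- TRUE
  cliques <- .ns_cliques(ns)
  ## items to cover: every vertex and every non-significant pair
  edges <- which(upper.tri(ns) & ns, arr.ind = TRUE)
  covers <- function(sel) {
    cl <- cliques[sel]
    vs <- unique(unlist(cl))
    if (length(vs) < n) return(FALSE)
    if (nrow(edges) == 0) return(TRUE)
    all(apply(edges, 1, function(e)
      any(vapply(cl, function(cc) all(e %in% cc), logical(1)))))
  }
  chosen <- NULL
  if (n <= 8) {
    for (k in seq_along(cliques)) {
      combs <- combn(length(cliques), k, simplify = FALSE)
      hit <- Filter(covers, combs)
      if (length(hit)) { chosen <- hit[[1]]; break }
    }
  }
  if (is.null(chosen)) {       # greedy fallback
    chosen <- integer(0)
    while (!covers(chosen)) {
      gain <- vapply(seq_along(cliques), function(i) {
        if (i %in% chosen) return(-1L)
        length(cliques[[i]])
      }, integer(1))
      chosen <- c(chosen, which.max(gain))
    }
  }
  letters_out <- rep("", n)
  for (i in seq_along(chosen)) {
    l <- letters[i]
    members <- cliques[[chosen[i]]]
    letters_out[members] <- paste0(letters_out[members], l)
  }
  structure(list(letters = setNames(letters_out, levs),
                 p = p, alpha = alpha),
            class = "letter_display")
}

#' @export
print.letter_display <- function(x, ...) {
  cat(sprintf("Compact letter display (alpha = %g)\n", x$alpha))
  print(x$letters)
  invisible(x)
}
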
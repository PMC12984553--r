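#' Cross-group species-pair distance design
#'
#' Builds the regression design linking community turnover to trait and
#' abundance differences: one row per unordered pair of species from
#' *different* functional groups, with the Bray-Curtis dissimilarity of
#' the species' replicate-aggregated community profiles as the response
#' and the absolute difference of each trait (nitrogen, root length,
#' root biomass, C:N, water content, field abundance) as predictors.
#'
#' @param otu_table count matrix (samples x OTUs).
#' @param metadata data frame with `sample_id`, `species_id`, `group`.
#' @param traits data frame with `species_id` and the six trait columns.
#' @param profile_method replicate aggregation, see [species_profiles()].
#' @return data frame of class `pair_design` with columns `species_1`,
#'   `species_2`, `group_1`, `group_2`, `dissimilarity` and one column
#'   per predictor; predictor names in attribute `"predictors"`.
#' @export
build_pair_design <- function(otu_table, metadata, traits,
                              profile_method = "mean_relative") {
  validate_tables(otu_table, metadata, traits)
  for (tn in .trait_names) {
    bad <- traits$species_id[is.na(traits[[tn]])]
    if (length(bad))
      stop(sprintf("missing trait '%s' for species: %s", tn,
                   paste(bad, collapse = ", ")))
  }
  prof <- species_profiles(otu_table, metadata, profile_method)
  sp <- rownames(prof)
  sp_group <- metadata$group[match(sp, metadata$species_id)]
  d <- as.matrix(bray_curtis(prof))
  tr <- traits[match(sp, traits$species_id), ]
  pairs <- combn(seq_along(sp), 2)
  cross <- sp_group[pairs[1, ]] != sp_group[pairs[2, ]]
  i <- pairs[1, cross]; j <- pairs[2, cross]
  out <- data.frame(species_1 = sp[i], species_2 = sp[j],
                    group_1 = sp_group[i], group_2 = sp_group[j],
                    dissimilarity = d[cbind(i, j)],
                    stringsAsFactors = FALSE)
  for (tn in .trait_names)
    out[[tn]] <- abs(tr[[tn]][i] - tr[[tn]][j])
  attr(out, "predictors") <- .trait_names
  class(out) <- c("pair_design", "data.frame")
  out
}

#' Random-forest importance of trait distances with permutation p-values
#'
#' Regresses pairwise community dissimilarity on the predictor distances
#' with a random-forest ensemble and reports each predictor's %IncMSE:
#' the percentage increase in out-of-bag mean squared error when that
#' predictor is permuted. Significance follows the rfPermute recipe: the
#' model is refitted on `n_null_reps` response-permuted copies of the
#' design and `p = (1 + #{null importance >= observed}) / (1 +
#' n_null_reps)`. Deterministic under `seed`; single-threaded.
#'
#' Note: pair-level observations are not independent (each species
#' enters many pairs), so p-values are calibrated against the permuted
#' response, not against an iid sampling model.
#'
#' @param design a `pair_design` (or data frame with a `dissimilarity`
#'   column and predictor columns named in attribute `"predictors"`).
#' @param n_trees trees per forest (default 500).
#' @param mtry predictors tried per split; default `max(1, floor(p/3))`.
#' @param n_null_reps null refits for the permutation test (default 100).
#' @param seed integer seed (default 1).
#' @param predictors optional character vector of predictor columns.
#' @return object of class `rfe_importance`: a table of predictor,
#'   `inc_mse`, `p_value`, `significance`, plus model settings.
#' @export
fit_importance <- function(design, n_trees = 500, mtry = NULL,
                           n_null_reps = 100, seed = 1,
                           predictors = NULL) {
  predictors <- predictors %||% attr(design, "predictors")
  if (is.null(predictors)) stop("predictor columns not specified")
  if (length(predictors) < 2) stop("need at least 2 predictors")
  if (nrow(design) < 30) stop("need at least 30 pairs")
  y <- design$dissimilarity
  if (var(y) == 0) stop("constant response")
  X <- design[, predictors, drop = FALSE]
  p <- length(predictors)
  if (is.null(mtry)) mtry <- max(1, floor(p / 3))
  if (mtry > p) stop("mtry exceeds the number of predictors")
  dat <- cbind(y = y, X)

  one_fit <- function(yy, s) {
    dat$y <- yy
    fit <- ranger::ranger(y ~ ., data = dat, num.trees = n_trees,
                          mtry = mtry, importance = "permutation",
                          seed = s, num.threads = 1)
    100 * fit$variable.importance / fit$prediction.error
  }
  obs <- one_fit(y, seed)
  set.seed(seed)
  null_seeds <- sample.int(.Machine$integer.max %/% 2, n_null_reps)
  null_imp <- matrix(NA_real_, n_null_reps, p,
                     dimnames = list(NULL, predictors))
  for (b in seq_len(n_null_reps)) {
    set.seed(null_seeds[b])
    null_imp[b, ] <- one_fit(sample(y), null_seeds[b])
  }
  pval <- (1 + colSums(sweep(null_imp, 2, obs, ">=")))/(1 + n_null_reps)
  sig <- ifelse(pval < 0.01, "**", ifelse(pval < 0.05, "*", "ns"))
  tab <- data.frame(predictor = predictors,
                    inc_mse = as.numeric(obs),
                    p_value = as.numeric(pval),
                    significance = sig,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$inc_mse), ]
  rownames(tab) <- NULL
  structure(list(importance = tab,
                 settings = list(n_trees = n_trees, mtry = mtry,
                                 n_null_reps = n_null_reps, seed = seed),
                 null_importance = null_imp),
            class = "rfe_importance")
}

#' @export
print.rfe_importance <- function(x, ...) {
  cat(sprintf("Random-forest importance (%d trees, mtry %d, %d null reps)\n",
              x$settings$n_trees, x$settings$mtry, x$settings$n_null_reps))
  cat("  (**: p < 0.01; *: p < 0.05; ns: not significant)\n")
  print(x$importance, digits = 4)
  invisible(x)
}
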
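#' Run the full endophyte community analysis
#'
#' Convenience wrapper chaining every stage on a bundled dataset:
#' rarefaction to the minimum depth, alpha diversity with Poisson
#' (richness) and Gaussian (Shannon) GLMs and compact letter displays,
#' Bray-Curtis distances with PCoA and one-way plus pairwise PERMANOVA,
#' phylum-level composition, the cross-group pair design with
#' random-forest trait attribution, SPEC-OCCU marker discovery (with
#' recovery against ground truth when present) and marker trophic-mode
#' composition with its own pairwise PERMANOVA.
#'
#' @param dataset an `rfe_dataset` (from [simulate_dataset()] or
#'   [read_dataset()]).
#' @param seed integer seed driving every stochastic stage.
#' @param n_permutations permutations for PERMANOVA stages.
#' @param n_trees,n_null_reps random-forest settings, see
#'   [fit_importance()].
#' @param threshold marker threshold, see [spec_occu()].
#' @return list of class `rfe_analysis` with one element per stage.
#' @export
analyze_dataset <- function(dataset, seed = 1, n_permutations = 999,
                            n_trees = 500, n_null_reps = 100,
                            threshold = 0.7) {
  validate_tables(dataset$otu_table, dataset$metadata, dataset$traits)
  rare <- rarefy(dataset$otu_table, "min", seed = seed)
  md <- dataset$metadata
  grp <- md$group[match(rownames(rare), md$sample_id)]

  alpha <- alpha_diversity(rare)
  rich_glm <- fit_group_glm(alpha$richness, grp, "poisson")
  rich_p <- pairwise_group_p(alpha$richness, grp, "poisson")
  shan_glm <- fit_group_glm(alpha$shannon, grp, "gaussian")
  shan_p <- pairwise_group_p(alpha$shannon, grp, "gaussian")

  d <- bray_curtis(rare)
  ord <- pcoa(d, n_axes = 2)
  overall <- permanova(d, grp, n_permutations, seed = seed)
  pairwise <- pairwise_permanova(d, grp, n_permutations, seed = seed)

  phyla <- phylum_relative_abundance(rare, dataset$taxonomy, md)

  design <- build_pair_design(rare, md, dataset$traits)
  importance <- fit_importance(design, n_trees = n_trees,
                               n_null_reps = n_null_reps, seed = seed)

  records <- spec_occu(rare, md, threshold = threshold)
  markers <- marker_set(records, rare, md)
  recovery <- if (!is.null(dataset$truth)) recover_markers(records, dataset)
              else NULL
  fc <- functional_composition(rare, md, dataset$guilds, markers)
  fperm <- tryCatch(
    functional_permanova(rare, md, dataset$guilds, markers,
                         n_permutations = n_permutations, seed = seed),
    error = function(e) NULL)

  structure(list(
    rarefied = rare, depth = min(rowSums(dataset$otu_table)),
    alpha = alpha,
    richness_glm = rich_glm,
    richness_letters = sig_letters(rich_p),
    shannon_glm = shan_glm,
    shannon_letters = sig_letters(shan_p),
    pcoa = ord, permanova = overall, pairwise_permanova = pairwise,
    phylum_composition = phyla,
    pair_design = design, importance = importance,
    spec_occu = records, markers = markers, recovery = recovery,
    functional_composition = fc, functional_permanova = fperm
  ), class = "rfe_analysis")
}

#' @export
print.rfe_analysis <- function(x, ...) {
  cat("Root-endophyte community analysis\n")
  cat(sprintf("  rarefied to depth %d; %d samples x %d OTUs\n",
              x$depth, nrow(x$rarefied), ncol(x$rarefied)))
  cat(sprintf("  richness letters: %s\n",
              paste(names(x$richness_letters$letters),
                    x$richness_letters$letters, sep = "=", collapse = " ")))
  cat(sprintf("  PERMANOVA: F = %.2f, R2 = %.3f, p = %.4g\n",
              x$permanova$pseudo_F, x$permanova$R2, x$permanova$p_value))
  sig <- sum(x$pairwise_permanova$p_adjusted < 0.05)
  cat(sprintf("  pairwise PERMANOVA: %d of %d pairs significant (BH 0.05)\n",
              sig, nrow(x$pairwise_permanova)))
  top <- x$importance$importance[1, ]
  cat(sprintf("  top predictor: %s (%%IncMSE %.1f, p = %.3g)\n",
              top$predictor, top$inc_mse, top$p_value))
  nm <- sum(lengths(x$markers$markers))
  cat(sprintf("  marker OTUs: %d (%s)\n", nm,
              paste(names(x$markers$markers), lengths(x$markers$markers),
                    sep = ":", collapse = ", ")))
  invisible(x)
}
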
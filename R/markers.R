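#' Specificity and occupancy of every OTU in every functional group
#'
#' For each (OTU, group) pair computes
#' \itemize{
#'   \item specificity: the OTU's mean abundance over the group's samples
#'     divided by the sum of those group means over all groups (sums to 1
#'     across groups for any OTU with nonzero total);
#'   \item occupancy: the fraction of the group's samples in which the
#'     OTU is present (count > 0).
#' }
#' An OTU is flagged a marker of a group when both statistics are greater
#' than or equal to `threshold` (inclusive). OTUs absent from every
#' sample get specificity 0 in every group and are flagged degenerate.
#'
#' Abundances should normally be rarefied counts so group means are
#' comparable across samples; relative abundances are also accepted.
#'
#' @param otu_table nonnegative matrix (samples x OTUs).
#' @param metadata data frame with `sample_id`, `group`.
#' @param threshold dual marker threshold (default 0.7).
#' @return data frame of class `spec_occu`, one row per (OTU, group):
#'   `otu_id`, `group`, `specificity`, `occupancy`, `is_marker`,
#'   `degenerate`.
#' @examples
#' tab <- rbind(a1 = c(x = 4), a2 = c(x = 6), b1 = c(x = 0), b2 = c(x = 0))
#' colnames(tab) <- "OTU1"
#' md <- data.frame(sample_id = rownames(tab), group = c("A", "A", "B", "B"))
#' spec_occu(tab, md)  # specificity_A = occupancy_A = 1
#' @export
spec_occu <- function(otu_table, metadata, threshold = 0.7) {
  grp <- metadata$group[match(rownames(otu_table), metadata$sample_id)]
  if (anyNA(grp)) stop("samples absent from metadata")
  grp <- droplevels(as.factor(grp))
  if (nlevels(grp) < 2) stop("need at least 2 groups")
  n_g <- table(grp)
  means <- rowsum(otu_table, grp) / as.vector(n_g[levels(grp)])  # grp x otu
  denom <- colSums(means)
  spec <- sweep(means, 2, ifelse(denom > 0, denom, 1), "/")
  spec[, denom == 0] <- 0
  occ <- rowsum((otu_table > 0) + 0, grp) / as.vector(n_g[levels(grp)])
  levs <- levels(grp)
  out <- data.frame(
    otu_id = rep(colnames(otu_table), each = length(levs)),
    group = rep(levs, times = ncol(otu_table)),
    specificity = as.vector(spec[levs, , drop = FALSE]),
    occupancy = as.vector(occ[levs, , drop = FALSE]),
    stringsAsFactors = FALSE
  )
  out$is_marker <- out$specificity >= threshold & out$occupancy >= threshold
  out$degenerate <- rep(denom == 0, each = length(levs))
  class(out) <- c("spec_occu", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' @export
print.spec_occu <- function(x, ...) {
  cat(sprintf("SPEC-OCCU records: %d OTUs x %d groups (threshold %.2f)\n",
              length(unique(x$otu_id)), length(unique(x$group)),
              attr(x, "threshold")))
  mk <- table(factor(x$group[x$is_marker], unique(x$group)))
  cat(sprintf("  marker flags: %s\n",
              paste(names(mk), mk, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Marker OTU sets per group with sequence fractions
#'
#' @param records a [spec_occu()] result.
#' @param otu_table the count matrix the records were computed from
#'   (used for the marker sequence fraction: marker counts over total
#'   group counts).
#' @param metadata data frame with `sample_id`, `group`.
#' @return object of class `marker_set`: named list `markers` (group ->
#'   OTU ids, ordered by decreasing specificity) and numeric
#'   `sequence_fraction` per group.
#' @export
marker_set <- function(records, otu_table, metadata) {
  grp <- metadata$group[match(rownames(otu_table), metadata$sample_id)]
  levs <- unique(records$group)
  markers <- lapply(setNames(levs, levs), function(g) {
    r <- records[records$group == g & records$is_marker, ]
    r$otu_id[order(-r$specificity)]
  })
  frac <- vapply(levs, function(g) {
    rows <- grp == g
    tot <- sum(otu_table[rows, , drop = FALSE])
    if (tot == 0) return(0)
    sum(otu_table[rows, markers[[g]], drop = FALSE]) / tot
  }, numeric(1))
  structure(list(markers = markers, sequence_fraction = frac),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("Marker OTUs per group:\n")
  for (g in names(x$markers))
    cat(sprintf("  %s: %d markers (%.1f%% of group sequences)\n", g,
                length(x$markers[[g]]), 100 * x$sequence_fraction[[g]]))
  invisible(x)
}

#' Recovery of planted markers
#'
#' Compares the marker flags of a [spec_occu()] run on a synthetic
#' dataset against the planted ground truth: sensitivity (planted
#' markers flagged for their home group / planted markers) and false
#' discovery proportion (flags that are not planted home-group markers /
#' all flags).
#'
#' @param records a [spec_occu()] result.
#' @param truth either an `rfe_dataset` or its `truth` list.
#' @return list with `sensitivity`, `fdr`, `n_planted`, `n_flagged`,
#'   `n_recovered`.
#' @export
recover_markers <- function(records, truth) {
  if (inherits(truth, "rfe_dataset")) truth <- truth$truth
  planted <- unlist(lapply(names(truth$markers), function(g)
    paste(g, truth$markers[[g]])), use.names = FALSE)
  flags <- records[records$is_marker, ]
  flagged <- paste(flags$group, flags$otu_id)
  n_rec <- sum(planted %in% flagged)
  list(sensitivity = if (length(planted)) n_rec / length(planted) else NA_real_,
       fdr = if (length(flagged)) sum(!(flagged %in% planted)) / length(flagged)
             else 0,
       n_planted = length(planted),
       n_flagged = length(flagged),
       n_recovered = n_rec)
}

#' Trophic-mode composition of marker OTUs
#'
#' Restricts the count table to the union of marker OTUs, assigns each
#' marker its canonical trophic-mode category (multi-mode OTUs form
#' their own category, e.g. "Pathotroph–Saprotroph–Symbiotroph";
#' unannotated markers are "Unassigned"), and returns relative
#' abundances over categories pooled per group (default) or per sample.
#'
#' @param otu_table count matrix (samples x OTUs).
#' @param metadata data frame with `sample_id`, `group`.
#' @param guilds data frame with `otu_id`, `trophic_mode`.
#' @param markers a [marker_set()] (or named list group -> OTU ids).
#' @param level `"group"` (default) or `"sample"`.
#' @return matrix of fractions (groups or samples x categories); rows
#'   with no marker counts are all-zero with a warning.
#' @export
functional_composition <- function(otu_table, metadata, guilds, markers,
                                   level = c("group", "sample")) {
  level <- match.arg(level)
  if (inherits(markers, "marker_set")) markers <- markers$markers
  marker_otus <- unique(unlist(markers, use.names = FALSE))
  if (!length(marker_otus)) stop("empty marker set")
  marker_otus <- intersect(colnames(otu_table), marker_otus)
  modes <- guilds$trophic_mode[match(marker_otus, guilds$otu_id)]
  modes[is.na(modes)] <- "Unassigned"
  modes <- vapply(modes, canonical_mode, character(1))
  sub <- otu_table[, marker_otus, drop = FALSE]
  by_mode <- t(rowsum(t(sub), modes))          # samples x categories
  if (level == "group") {
    grp <- metadata$group[match(rownames(otu_table), metadata$sample_id)]
    by_mode <- rowsum(by_mode, grp)
  }
  tot <- rowSums(by_mode)
  if (any(tot == 0))
    warning("no marker counts for: ",
            paste(rownames(by_mode)[tot == 0], collapse = ", "),
            " (all-zero row)")
  frac <- sweep(by_mode, 1, ifelse(tot > 0, tot, 1), "/")
  frac
}

#' Pairwise PERMANOVA on marker functional composition
#'
#' Computes sample-level trophic-mode profiles of the marker OTUs,
#' Bray-Curtis distances between them, and delegates to
#' [pairwise_permanova()]. Samples without marker counts are dropped
#' with a warning.
#'
#' @inheritParams functional_composition
#' @inheritParams pairwise_permanova
#' @return a `pairwise_permanova` data frame.
#' @export
functional_permanova <- function(otu_table, metadata, guilds, markers,
                                 n_permutations = 999, seed = NULL,
                                 adjust = "BH") {
  fc <- suppressWarnings(
    functional_composition(otu_table, metadata, guilds, markers,
                           level = "sample"))
  keep <- rowSums(fc) > 0
  if (!all(keep))
    warning("dropping sample(s) without marker counts: ",
            paste(rownames(fc)[!keep], collapse = ", "))
  fc <- fc[keep, , drop = FALSE]
  grp <- metadata$group[match(rownames(fc), metadata$sample_id)]
  d <- bray_curtis(fc)
  pairwise_permanova(d, grp, n_permutations = n_permutations, seed = seed,
                     adjust = adjust)
}
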
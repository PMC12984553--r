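## Tabular IO: all five table kinds are tab-separated with one header
## row; the first column is the identifier. Samples are rows and OTUs are
## columns in the on-disk count table (use `transpose = TRUE` for the
## other dialect).

.check_ids <- function(ids, what, file) {
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate %s id(s) in %s: %s", what, file,
                 paste(unique(dup), collapse = ", ")))
  if (any(!nzchar(ids)) || anyNA(ids))
    stop(sprintf("empty or missing %s id in %s", what, file))
  invisible(ids)
}

#' Read an OTU count table
#'
#' @param path tab-separated file; first column sample ids, remaining
#'   columns integer OTU counts.
#' @param transpose set `TRUE` when the file stores OTUs as rows.
#' @return integer matrix (samples x OTUs) with dimnames.
#' @export
read_otu_table <- function(path, transpose = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  rownames(m) <- ids
  if (transpose) m <- t(m)
  .check_ids(rownames(m), "sample", path)
  .check_ids(colnames(m), "OTU", path)
  if (anyNA(m)) stop("missing counts in ", path)
  if (any(m < 0)) stop("negative counts in ", path)
  if (any(abs(m - round(m)) > 1e-8)) stop("non-integer counts in ", path)
  storage.mode(m) <- "integer"
  m
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `species_id`, `group`, `replicate`.
#' @param path tab-separated file.
#' @return data frame with those columns.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "species_id", "group", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  .check_ids(df$sample_id, "sample", path)
  sp_grp <- unique(df[, c("species_id", "group")])
  dup <- sp_grp$species_id[duplicated(sp_grp$species_id)]
  if (length(dup))
    stop("species mapped to more than one group: ",
         paste(unique(dup), collapse = ", "))
  if (anyDuplicated(df[, c("species_id", "replicate")]))
    stop("replicate indices not unique within species in ", path)
  df[, need]
}

#' Read the species trait / field-abundance table
#'
#' Expects columns `species_id`, `root_length`, `root_biomass`,
#' `water_content`, `nitrogen`, `cn_ratio`, `abundance`.
#' @param path tab-separated file.
#' @return data frame.
#' @export
read_traits <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_id", .trait_names)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("traits missing column(s): ",
                         paste(miss, collapse = ", "))
  .check_ids(df$species_id, "species", path)
  num <- df[, .trait_names]
  if (anyNA(num) || !all(vapply(num, is.numeric, logical(1))))
    stop("unparseable or missing trait values in ", path)
  if (any(df$water_content < 0 | df$water_content > 100))
    stop("water_content outside [0, 100] in ", path)
  if (any(df$cn_ratio <= 0)) stop("nonpositive cn_ratio in ", path)
  if (any(df$abundance < 0)) stop("negative abundance in ", path)
  df[, need]
}

#' Read the OTU taxonomy table (phylum level)
#'
#' Expects columns `otu_id` and `phylum`. OTUs missing from the file can
#' be completed to "Other" via [complete_taxonomy()].
#' @param path tab-separated file.
#' @return data frame.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("otu_id", "phylum") %in% names(df)))
    stop("taxonomy must have columns otu_id and phylum")
  .check_ids(df$otu_id, "OTU", path)
  df[, c("otu_id", "phylum")]
}

#' Read the OTU guild (trophic mode) table
#'
#' Expects columns `otu_id` and `trophic_mode` (FUNGuild-style mode
#' strings, e.g. "Pathotroph-Saprotroph"); strings are canonicalised with
#' sorted components joined by an en dash. Unannotated OTUs should carry
#' "Unassigned".
#' @param path tab-separated file.
#' @return data frame with canonical mode strings.
#' @export
read_guilds <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("otu_id", "trophic_mode") %in% names(df)))
    stop("guild table must have columns otu_id and trophic_mode")
  .check_ids(df$otu_id, "OTU", path)
  df$trophic_mode <- vapply(df$trophic_mode, canonical_mode, character(1))
  df[, c("otu_id", "trophic_mode")]
}

#' Canonicalise a trophic-mode string
#'
#' Splits on "-", "–" or "_", keeps the known single modes in the
#' fixed order Pathotroph, Saprotroph, Symbiotroph and joins with an en
#' dash; anything unrecognised (or empty) becomes "Unassigned".
#' @param x a mode string.
#' @return canonical mode string.
#' @export
canonical_mode <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return("Unassigned")
  parts <- trimws(strsplit(x, "[-–_]")[[1]])
  modes <- c("Pathotroph", "Saprotroph", "Symbiotroph")
  keep <- modes[modes %in% parts]
  if (!length(keep)) return("Unassigned")
  paste(keep, collapse = "–")
}

#' Complete a taxonomy table over a set of OTU ids
#'
#' OTUs absent from the table are assigned phylum "Other".
#' @param taxonomy data frame from [read_taxonomy()].
#' @param otu_ids character vector of OTU ids to cover.
#' @return data frame covering every id in `otu_ids`.
#' @export
complete_taxonomy <- function(taxonomy, otu_ids) {
  extra <- setdiff(otu_ids, taxonomy$otu_id)
  if (length(extra))
    taxonomy <- rbind(taxonomy,
                      data.frame(otu_id = extra, phylum = "Other",
                                 stringsAsFactors = FALSE))
  taxonomy[match(otu_ids, taxonomy$otu_id), , drop = FALSE]
}

#' Cross-validate the bundled tables
#'
#' Raises an error on any inconsistency: samples in the count table
#' missing from metadata (and vice versa), species in metadata missing
#' from the trait table.
#' @param otu_table integer matrix (samples x OTUs).
#' @param metadata data frame as from [read_metadata()].
#' @param traits data frame as from [read_traits()].
#' @return invisibly `TRUE`.
#' @export
validate_tables <- function(otu_table, metadata, traits = NULL) {
  miss <- setdiff(rownames(otu_table), metadata$sample_id)
  if (length(miss))
    stop("samples absent from metadata: ", paste(miss, collapse = ", "))
  miss <- setdiff(metadata$sample_id, rownames(otu_table))
  if (length(miss))
    stop("metadata samples absent from the OTU table: ",
         paste(miss, collapse = ", "))
  if (!is.null(traits)) {
    miss <- setdiff(metadata$species_id, traits$species_id)
    if (length(miss))
      stop("species in metadata absent from traits: ",
           paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write an OTU count table
#' @param otu_table integer matrix (samples x OTUs).
#' @param path output file.
#' @export
write_otu_table <- function(otu_table, path) {
  df <- data.frame(sample_id = rownames(otu_table), otu_table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a data-frame table as TSV
#' @param df data frame.
#' @param path output file.
#' @export
write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `otu_table.tsv`, `metadata.tsv`, `traits.tsv`, `taxonomy.tsv`,
#' `guilds.tsv` and a `truth.json` ground-truth file.
#' @param dataset an `rfe_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly the directory.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_otu_table(dataset$otu_table, file.path(dir, "otu_table.tsv"))
  write_tsv_table(dataset$metadata, file.path(dir, "metadata.tsv"))
  write_tsv_table(dataset$traits, file.path(dir, "traits.tsv"))
  write_tsv_table(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_tsv_table(dataset$guilds, file.path(dir, "guilds.tsv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a synthetic dataset back from a directory
#' @param dir directory written by [write_dataset()].
#' @return an `rfe_dataset` (without the generating config).
#' @export
read_dataset <- function(dir) {
  otu <- read_otu_table(file.path(dir, "otu_table.tsv"))
  metadata <- read_metadata(file.path(dir, "metadata.tsv"))
  traits <- read_traits(file.path(dir, "traits.tsv"))
  taxonomy <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  guilds <- read_guilds(file.path(dir, "guilds.tsv"))
  validate_tables(otu, metadata, traits)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    tr$markers <- lapply(tr$markers, as.character)
    tr
  } else NULL
  structure(list(otu_table = otu, metadata = metadata, traits = traits,
                 taxonomy = taxonomy, guilds = guilds, truth = truth,
                 config = NULL),
            class = "rfe_dataset")
}

#' Root water content
#'
#' Percentage of fresh mass lost on drying:
#' `(fresh - dry) / fresh * 100`.
#' @param fresh_weight fresh root mass (g), positive.
#' @param dry_weight oven-dry root mass (g), between 0 and `fresh_weight`.
#' @return water content in percent of fresh mass.
#' @examples
#' water_content(2, 1)  # 50
#' @export
water_content <- function(fresh_weight, dry_weight) {
  if (any(fresh_weight <= 0)) stop("fresh_weight must be positive")
  if (any(dry_weight < 0)) stop("dry_weight must be nonnegative")
  if (any(dry_weight > fresh_weight))
    stop("dry_weight exceeds fresh_weight (negative water content impossible)")
  (fresh_weight - dry_weight) / fresh_weight * 100
}

#' Phylum-level relative abundance per functional group
#'
#' Pools counts across each group's samples (default) or averages
#' per-sample fractions, then normalises over phyla so each group's
#' fractions sum to one. OTUs missing from the taxonomy are counted as
#' "Other".
#'
#' @param otu_table integer matrix (samples x OTUs), typically rarefied.
#' @param taxonomy data frame with `otu_id`, `phylum`.
#' @param metadata data frame with `sample_id`, `group`.
#' @param method `"pooled"` (default) or `"mean_sample"`.
#' @return matrix of fractions, groups x phyla.
#' @export
phylum_relative_abundance <- function(otu_table, taxonomy, metadata,
                                      method = c("pooled", "mean_sample")) {
  method <- match.arg(method)
  validate_tables(otu_table, metadata)
  taxonomy <- complete_taxonomy(taxonomy, colnames(otu_table))
  phy <- taxonomy$phylum[match(colnames(otu_table), taxonomy$otu_id)]
  grp <- metadata$group[match(rownames(otu_table), metadata$sample_id)]
  by_phy <- t(rowsum(t(otu_table), phy))        # samples x phyla
  if (method == "pooled") {
    pooled <- rowsum(by_phy, grp)               # groups x phyla
    tot <- rowSums(pooled)
    if (any(tot == 0)) stop("group with no counts: ",
                            paste(rownames(pooled)[tot == 0], collapse = ", "))
    sweep(pooled, 1, tot, "/")
  } else {
    tot <- rowSums(by_phy)
    if (any(tot == 0)) stop("sample with no counts: ",
                            paste(rownames(by_phy)[tot == 0], collapse = ", "))
    frac <- sweep(by_phy, 1, tot, "/")
    agg <- rowsum(frac, grp)
    sweep(agg, 1, rowSums(agg), "/")
  }
}
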
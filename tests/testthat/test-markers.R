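two_group_md <- function(tab, groups) {
  data.frame(sample_id = rownames(tab), group = groups,
             stringsAsFactors = FALSE)
}

test_that("specificity and occupancy follow their definitions", {
  tab <- rbind(a1 = 4, a2 = 6, b1 = 0, b2 = 0)
  colnames(tab) <- "OTU1"
  rec <- spec_occu(tab, two_group_md(tab, c("A", "A", "B", "B")))
  a <- rec[rec$group == "A", ]
  expect_equal(a$specificity, 1)
  expect_equal(a$occupancy, 1)
  expect_true(a$is_marker)
  # group means 3 vs 1 -> 0.75 / 0.25
  tab2 <- rbind(a1 = 2, a2 = 4, b1 = 1, b2 = 1)
  colnames(tab2) <- "OTU1"
  rec2 <- spec_occu(tab2, two_group_md(tab2, c("A", "A", "B", "B")))
  expect_equal(rec2$specificity[rec2$group == "A"], 0.75)
  expect_equal(rec2$specificity[rec2$group == "B"], 0.25)
  # occupancy 2/3 blocks the marker flag despite specificity 1
  tab3 <- rbind(a1 = 5, a2 = 5, a3 = 0, b1 = 0, b2 = 0, b3 = 0)
  colnames(tab3) <- "OTU1"
  rec3 <- spec_occu(tab3, two_group_md(tab3, rep(c("A", "B"), each = 3)))
  a3 <- rec3[rec3$group == "A", ]
  expect_equal(a3$specificity, 1)
  expect_equal(a3$occupancy, 2 / 3, tolerance = 1e-12)
  expect_false(a3$is_marker)
})

test_that("the 0.7 dual threshold is inclusive", {
  # group A: 10 samples, present in exactly 7 with mean 7; B mean 3
  a_counts <- c(rep(10L, 7), rep(0L, 3))
  tab <- matrix(c(a_counts, rep(3L, 10)), ncol = 1,
                dimnames = list(c(paste0("a", 1:10), paste0("b", 1:10)),
                                "OTU1"))
  md <- two_group_md(tab, rep(c("A", "B"), each = 10))
  rec <- spec_occu(tab, md)
  a <- rec[rec$group == "A", ]
  expect_equal(a$specificity, 0.7)
  expect_equal(a$occupancy, 0.7)
  expect_true(a$is_marker)
})

test_that("specificity sums to one per OTU and matches the oracle", {
  for (s in 1:20) {
    rt <- random_table(sample(4:8, 1), sample(3:12, 1), sample(2:3, 1),
                       seed = 700 + s)
    rec <- spec_occu(rt$counts, rt$metadata)
    orc <- oracle_spec_occu(rt$counts, rt$groups)
    m <- merge(rec, orc, by = c("otu_id", "group"))
    expect_equal(nrow(m), nrow(rec))
    expect_lt(max(abs(m$specificity.x - m$specificity.y)), 1e-12)
    expect_lt(max(abs(m$occupancy.x - m$occupancy.y)), 1e-12)
    sums <- tapply(rec$specificity, rec$otu_id, sum)
    nz <- colSums(rt$counts) > 0
    expect_true(all(abs(sums[names(nz)[nz]] - 1) < 1e-12))
  }
})

test_that("absent OTUs are flagged degenerate with zero specificity", {
  tab <- cbind(OTU1 = c(1L, 2L, 3L, 4L), OTU2 = 0L)
  rownames(tab) <- paste0("s", 1:4)
  rec <- spec_occu(tab, two_group_md(tab, c("A", "A", "B", "B")))
  z <- rec[rec$otu_id == "OTU2", ]
  expect_true(all(z$specificity == 0))
  expect_true(all(z$degenerate))
  expect_false(any(z$is_marker))
})

test_that("boosting a group's counts never lowers its spec/occu", {
  for (s in 1:10) {
    rt <- random_table(8, 6, 2, seed = 800 + s)
    rec <- spec_occu(rt$counts, rt$metadata)
    j <- sample(ncol(rt$counts), 1)
    rows <- rt$groups == "A"
    boosted <- rt$counts
    boosted[rows, j] <- boosted[rows, j] + sample(0:5, sum(rows), TRUE)
    rec2 <- spec_occu(boosted, rt$metadata)
    pick <- function(r) r[r$otu_id == colnames(rt$counts)[j] &
                            r$group == "A", ]
    expect_gte(pick(rec2)$specificity, pick(rec)$specificity - 1e-12)
    expect_gte(pick(rec2)$occupancy, pick(rec)$occupancy - 1e-12)
  }
})

test_that("planted markers are recovered under strong boost, not without", {
  ds <- simulate_dataset(small_config(seed = 61, marker_boost = 20,
                                      force_marker_occupancy = TRUE))
  rare <- rarefy(ds$otu_table, "min", seed = 1)
  rec <- recover_markers(spec_occu(rare, ds$metadata), ds)
  expect_gte(rec$sensitivity, 0.9)
  expect_lte(rec$fdr, 0.2)
  ds0 <- simulate_dataset(small_config(seed = 61, marker_boost = 1))
  rec0 <- recover_markers(spec_occu(ds0$otu_table, ds0$metadata), ds0)
  expect_lte(rec0$sensitivity, 0.1)
})

test_that("marker sets carry per-group sequence fractions", {
  ds <- simulate_dataset(small_config(seed = 62, marker_boost = 20,
                                      force_marker_occupancy = TRUE))
  rare <- rarefy(ds$otu_table, "min", seed = 1)
  rec <- spec_occu(rare, ds$metadata)
  ms <- marker_set(rec, rare, ds$metadata)
  expect_true(all(unlist(ms$markers) %in% colnames(rare)))
  expect_true(all(ms$sequence_fraction >= 0 & ms$sequence_fraction <= 1))
  # markers with boost 20 on 200 OTUs carry a visible share of reads
  expect_true(all(ms$sequence_fraction > 0.01))
})

test_that("functional composition pools marker counts by trophic mode", {
  tab <- cbind(OTU1 = c(20L, 10L), OTU2 = c(5L, 5L), OTU3 = c(1L, 0L))
  rownames(tab) <- c("s1", "s2")
  md <- data.frame(sample_id = c("s1", "s2"), group = c("A", "A"))
  guilds <- data.frame(
    otu_id = c("OTU1", "OTU2", "OTU3"),
    trophic_mode = c("Symbiotroph", "Pathotroph",
                     "Pathotroph-Saprotroph-Symbiotroph"))
  fc1 <- functional_composition(tab, md, guilds, list(A = "OTU1"))
  expect_equal(unname(fc1["A", "Symbiotroph"]), 1)
  fc2 <- functional_composition(tab, md, guilds, list(A = c("OTU1", "OTU2")))
  expect_equal(unname(fc2["A", c("Pathotroph", "Symbiotroph")]),
               c(0.25, 0.75))
  # triple-mode OTUs form their own category, not split across modes
  fc3 <- functional_composition(tab, md, guilds,
                                list(A = c("OTU1", "OTU3")))
  expect_true("Pathotroph–Saprotroph–Symbiotroph" %in% colnames(fc3))
  expect_equal(sum(fc3["A", ]), 1)
  expect_error(functional_composition(tab, md, guilds, list(A = character(0))),
               "empty marker set")
})

test_that("functional permanova delegates to the generic machinery", {
  ds <- simulate_dataset(small_config(seed = 63, marker_boost = 20,
                                      force_marker_occupancy = TRUE))
  rare <- rarefy(ds$otu_table, "min", seed = 1)
  rec <- spec_occu(rare, ds$metadata)
  ms <- marker_set(rec, rare, ds$metadata)
  fp <- functional_permanova(rare, ds$metadata, ds$guilds, ms,
                             n_permutations = 49, seed = 3)
  fc <- functional_composition(rare, ds$metadata, ds$guilds, ms,
                               level = "sample")
  fc <- fc[rowSums(fc) > 0, , drop = FALSE]
  grp <- ds$metadata$group[match(rownames(fc), ds$metadata$sample_id)]
  ref <- pairwise_permanova(bray_curtis(fc), grp, n_permutations = 49,
                            seed = 3)
  expect_equal(fp$pseudo_F, ref$pseudo_F, tolerance = 1e-12)
  expect_equal(fp$p_value, ref$p_value)
})

test_that("identical functional profiles yield no significance", {
  tab <- matrix(rep(c(10L, 5L), each = 8), 8, 2,
                dimnames = list(paste0("s", 1:8), c("OTU1", "OTU2")))
  md <- data.frame(sample_id = rownames(tab),
                   group = rep(c("A", "B"), each = 4))
  guilds <- data.frame(otu_id = c("OTU1", "OTU2"),
                       trophic_mode = c("Symbiotroph", "Pathotroph"))
  fp <- functional_permanova(tab, md, guilds,
                             list(A = "OTU1", B = "OTU2"),
                             n_permutations = 49, seed = 1)
  expect_true(all(fp$p_value == 1))
})
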
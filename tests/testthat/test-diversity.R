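test_that("rarefaction equalises depths without inventing counts", {
  rt <- random_table(8, 10, 2, seed = 31)
  counts <- rt$counts + 1L          # avoid empty samples
  r <- rarefy(counts, "min", seed = 1)
  expect_true(all(rowSums(r) == min(rowSums(counts))))
  expect_true(all(r <= counts))     # zeros preserved, nothing gained
  expect_true(all(r[counts == 0] == 0))
  expect_identical(rarefy(counts, "min", seed = 1),
                   rarefy(counts, "min", seed = 1))
  expect_error(rarefy(counts, depth = max(rowSums(counts)) + 1),
               rownames(counts)[1])
})

test_that("rarefied counts match the hypergeometric expectation", {
  counts <- matrix(c(50L, 30L, 20L), 1, 3,
                   dimnames = list("s1", paste0("OTU", 1:3)))
  depth <- 40L
  draws <- t(vapply(1:1000, function(s) rarefy(counts, depth, seed = s)[1, ],
                    numeric(3)))
  expected <- depth * c(50, 30, 20) / 100
  se <- apply(draws, 2, sd) / sqrt(nrow(draws))
  expect_true(all(abs(colMeans(draws) - expected) <= 3 * se))
})

test_that("alpha diversity matches closed forms", {
  tab <- rbind(u = c(10, 10, 10, 10), s = c(7, 0, 0, 0), m = c(1, 1, 2, 0))
  colnames(tab) <- paste0("OTU", 1:4)
  a <- alpha_diversity(tab)
  expect_equal(a$richness, c(4L, 1L, 3L))
  expect_equal(a$shannon[1], log(4))
  expect_equal(a$shannon[2], 0)
  expect_equal(a$shannon[3],
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)))
  expect_warning(alpha_diversity(rbind(z = c(0, 0))), "all-zero")
})

test_that("shannon is invariant to OTU order and count scaling", {
  rt <- random_table(5, 8, 2, seed = 32)
  counts <- rt$counts + 1L
  a <- alpha_diversity(counts)
  perm <- sample(ncol(counts))
  expect_equal(alpha_diversity(counts[, perm])$shannon, a$shannon)
  expect_equal(alpha_diversity(counts * 7L)$shannon, a$shannon)
})

test_that("poisson GLM recovers log means and group contrasts", {
  fit <- fit_group_glm(c(2, 4, 6), rep("A", 3), "poisson")
  expect_equal(unname(coef(fit)[1]), log(4), tolerance = 1e-8)
  # identical groups: contrast ~0, p ~1
  v <- rep(c(5, 7, 9, 11), 2)
  g <- rep(c("A", "B"), each = 4)
  fit2 <- fit_group_glm(v, g, "poisson")
  expect_equal(unname(coef(fit2)[2]), 0, tolerance = 1e-10)
  expect_gt(fit2$coefficients[2, 4], 0.99)
  # parameter recovery at rates 20 / 40
  set.seed(99)
  y <- c(rpois(50, 20), rpois(50, 40))
  gg <- rep(c("A", "B"), each = 50)
  fit3 <- fit_group_glm(y, gg, "poisson")
  est <- fit3$coefficients[2, 1]; se <- fit3$coefficients[2, 2]
  expect_lt(abs(est - log(2)), 3 * se)
  expect_error(fit_group_glm(c(1.5, 2.5, 3, 4), rep(c("A", "B"), 2),
                             "poisson"), "integer")
})

test_that("poisson IRLS deviance decreases monotonically", {
  set.seed(4)
  y <- rpois(40, exp(1 + 0.8 * rep(0:1, each = 20)))
  g <- rep(c("A", "B"), each = 20)
  out <- capture.output(
    glm(y ~ g, family = poisson(),
        control = glm.control(trace = TRUE, epsilon = 1e-10)))
  out <- grep("Deviance = ", out, value = TRUE)
  dev <- as.numeric(sub(".*Deviance = ([0-9.eE+-]+) Iterations.*", "\\1", out))
  expect_true(all(diff(dev) <= 1e-8))
})

test_that("compact letter displays encode the significance pattern", {
  groups <- c("DF", "G", "L", "MF")
  all_sig <- matrix(0.001, 4, 4, dimnames = list(groups, groups))
  diag(all_sig) <- NA
  l1 <- sig_letters(all_sig)$letters
  expect_equal(length(unique(l1)), 4)
  none <- matrix(0.9, 4, 4, dimnames = list(groups, groups))
  diag(none) <- NA
  expect_equal(unname(sig_letters(none)$letters), rep("a", 4))
  # only the DF-MF contrast significant
  p <- none
  p["DF", "MF"] <- p["MF", "DF"] <- 0.001
  l3 <- sig_letters(p)$letters
  share <- function(a, b)
    length(intersect(strsplit(l3[[a]], "")[[1]],
                     strsplit(l3[[b]], "")[[1]])) > 0
  expect_false(share("DF", "MF"))
  for (pr in list(c("DF", "G"), c("DF", "L"), c("G", "L"),
                  c("G", "MF"), c("L", "MF")))
    expect_true(share(pr[1], pr[2]))
  expect_error(sig_letters(matrix(c(0.1, 0.2, 0.5, 0.1), 2, 2)), "symmetric")
})

test_that("letters are consistent with the p matrix on random patterns", {
  for (s in 1:40) {
    set.seed(s)
    n <- sample(3:6, 1)
    p <- matrix(1, n, n, dimnames = list(letters[1:n], letters[1:n]))
    up <- upper.tri(p)
    p[up] <- sample(c(0.001, 0.3), sum(up), replace = TRUE)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
    diag(p) <- NA
    ld <- sig_letters(p, alpha = 0.05)$letters
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      shared <- length(intersect(strsplit(ld[i], "")[[1]],
                                 strsplit(ld[j], "")[[1]])) > 0
      expect_equal(shared, p[i, j] >= 0.05,
                   label = sprintf("seed %d pair %d-%d", s, i, j))
    }
  }
})

test_that("pairwise GLM p-values form a symmetric matrix", {
  set.seed(10)
  y <- c(rpois(10, 5), rpois(10, 5), rpois(10, 30))
  g <- rep(c("A", "B", "C"), each = 10)
  p <- pairwise_group_p(y, g, "poisson")
  expect_equal(p, t(p))
  expect_lt(p["A", "C"], 0.01)
  expect_gt(p["A", "B"], 0.05)
})
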
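## Independent oracles, written deliberately as plain nested loops so
## they share no code path with the package implementations.

## specificity / occupancy, one (otu, group) pair at a time
oracle_spec_occu <- function(counts, groups) {
  levs <- sort(unique(groups))
  out <- NULL
  for (j in seq_len(ncol(counts))) {
    group_means <- numeric(length(levs))
    for (k in seq_along(levs)) {
      rows <- which(groups == levs[k])
      s <- 0
      for (i in rows) s <- s + counts[i, j]
      group_means[k] <- s / length(rows)
    }
    denom <- sum(group_means)
    for (k in seq_along(levs)) {
      rows <- which(groups == levs[k])
      present <- 0
      for (i in rows) if (counts[i, j] > 0) present <- present + 1
      out <- rbind(out, data.frame(
        otu_id = colnames(counts)[j], group = levs[k],
        specificity = if (denom > 0) group_means[k] / denom else 0,
        occupancy = present / length(rows),
        stringsAsFactors = FALSE))
    }
  }
  out
}

## Anderson pseudo-F by explicit projection of the Gower-centred matrix
oracle_permanova_F <- function(d, groups) {
  D <- as.matrix(d)
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  X <- stats::model.matrix(~ factor(groups))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  a <- length(unique(groups))
  ss_model <- sum(diag(H %*% G %*% H))
  ss_res <- sum(diag((diag(n) - H) %*% G %*% (diag(n) - H)))
  (ss_model / (a - 1)) / (ss_res / (n - a))
}

## small random count table with group labels
random_table <- function(n_samples, n_otus, n_groups, seed) {
  set.seed(seed)
  counts <- matrix(rpois(n_samples * n_otus, lambda = 3) *
                     rbinom(n_samples * n_otus, 1, 0.6),
                   n_samples, n_otus,
                   dimnames = list(paste0("s", seq_len(n_samples)),
                                   paste0("OTU", seq_len(n_otus))))
  groups <- sample(rep_len(LETTERS[seq_len(n_groups)], n_samples))
  list(counts = counts, groups = groups,
       metadata = data.frame(sample_id = rownames(counts),
                             group = groups, stringsAsFactors = FALSE))
}

## compact simulation config for fast tests
small_config <- function(seed, ...) {
  sim_config(group_sizes = c(A = 4L, B = 4L, C = 3L), n_otus = 200L,
             depth_range = c(500L, 1500L), seed = seed, ...)
}
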
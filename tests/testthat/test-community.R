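toy_table <- function(counts, taxonomy = NULL, time_point = NULL) {
  if (is.null(taxonomy)) {
    taxonomy <- sprintf("d__B;p__P;c__C;o__O;f__F;g__G%d;s__",
                        seq_len(nrow(counts)))
  }
  md <- if (!is.null(time_point)) {
    data.frame(sample = colnames(counts), time_point = time_point)
  }
  asv_table(counts, taxonomy, md)
}

test_that("low-count ASV filtering applies the dataset-wide threshold", {
  m <- matrix(c(1, 0, 0, 1, 1, 1, 2, 3, 4, 5), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("a", 1:5), c("s1", "s2")))
  tab <- toy_table(m)
  # totals are 1, 1, 2, 5, 9: the two singletons drop, the rest stay
  kept <- filter_asv_table(tab, 2)
  expect_equal(rownames(kept$counts), c("a3", "a4", "a5"))
  expect_equal(ncol(kept$counts), 2L)
  # boundary: an ASV totalling exactly the threshold is kept
  expect_true("a3" %in% rownames(filter_asv_table(tab, 2)$counts))
  expect_false("a1" %in% rownames(filter_asv_table(tab, 2)$counts))
  # zero threshold is the identity
  expect_equal(filter_asv_table(tab, 0)$counts, tab$counts)
  # per-sample variant keys on the best single sample
  ps <- matrix(c(1, 1, 0, 3), nrow = 2,
               dimnames = list(c("x", "y"), c("s1", "s2")))
  expect_equal(rownames(filter_asv_table(toy_table(ps), 2,
                                         per_sample = TRUE)$counts), "y")
  expect_error(filter_asv_table(tab, 100), "every ASV")
})

test_that("genus aggregation parses the sixth rank and ranks by abundance", {
  m <- matrix(c(30, 10, 70, 80, 0, 10), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  tax <- c("d__B;p__P;c__C;o__O;f__F;g__Alpha;s__",
           "d__B;p__P;c__C;o__O;f__F;g__Beta;s__",
           "d__B;p__P;c__C;o__O;f__F;g__Beta;s__")
  ga <- genus_top_abundance(toy_table(m, tax))
  expect_equal(unname(ga["Alpha", "s1"]), 0.3)
  expect_equal(unname(ga["Beta", "s1"]), 0.7)
  expect_equal(colSums(ga), c(s1 = 1, s2 = 1))
  # lineages without a genus field fall into unclassified_genus
  short <- genus_top_abundance(toy_table(m, c(tax[1:2], "d__B;p__P")))
  expect_true("unclassified_genus" %in% rownames(short))
  # top-n truncation aggregates the remainder
  big <- toy_table(matrix(10:1, ncol = 1,
                          dimnames = list(paste0("a", 1:10), "s1")))
  top3 <- genus_top_abundance(big, 3)
  expect_equal(rownames(top3)[4], "other")
  expect_equal(sum(top3[, 1]), 1)
})

test_that("the synthetic succession's dominant genus is recovered per time point", {
  cx <- gen_asv_tables(community_scenario(total_reads = 20000, seed = 31))
  ga <- genus_top_abundance(cx$table)
  traj <- cx$truth$trajectories
  for (tp in colnames(traj)) {
    cols <- grep(paste0("^", tp, "_"), colnames(ga))
    top_obs <- rownames(ga)[which.max(rowMeans(ga[, cols, drop = FALSE]))]
    expect_equal(top_obs, rownames(traj)[which.max(traj[, tp])])
  }
})

test_that("shannon index agrees with hand values and the vegan reference", {
  expect_equal(shannon_index(rep(1, 5)), log(5))
  expect_equal(shannon_index(c(0, 7, 0)), 0)
  expect_equal(shannon_index(c(1, 1, 2)), 1.0397207708, tolerance = 1e-9)
  set.seed(14)
  for (i in 1:5) {
    x <- rpois(20, 30)
    expect_equal(shannon_index(x), unname(vegan::diversity(x)))
  }
})

test_that("bray-curtis matches hand values and is a proper dissimilarity", {
  m <- matrix(c(1, 1, 0, 0, 1, 1), nrow = 3,
              dimnames = list(paste0("a", 1:3), c("s1", "s2")))
  d <- bray_curtis(toy_table(m))
  expect_equal(as.numeric(d), 0.5)

  same <- matrix(c(3, 1, 3, 1), nrow = 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(as.numeric(bray_curtis(toy_table(same))), 0)
  disj <- matrix(c(3, 0, 0, 5), nrow = 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(as.numeric(bray_curtis(toy_table(disj))), 1)

  zero <- matrix(c(3, 1, 0, 0), nrow = 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(bray_curtis(toy_table(zero)), "zero total")

  set.seed(5)
  mm <- matrix(rpois(60, 8), nrow = 10,
               dimnames = list(paste0("a", 1:10), paste0("s", 1:6)))
  d1 <- as.matrix(bray_curtis(toy_table(mm)))
  d2 <- as.matrix(bray_curtis(toy_table(mm[sample(10), , drop = FALSE])))
  expect_equal(d1, d2)                      # ASV order is irrelevant
  expect_true(all(d1 >= 0 & d1 <= 1))
  expect_equal(d1, t(d1))
  expect_equal(diag(d1), setNames(rep(0, 6), paste0("s", 1:6)))
})

test_that("PCoA embeds Euclidean configurations exactly", {
  set.seed(9)
  pts <- matrix(rnorm(14), ncol = 2,
                dimnames = list(paste0("s", 1:7), NULL))
  d <- dist(pts)
  ord <- pcoa_ordination(d)
  emb <- dist(ord$coordinates)
  expect_equal(as.numeric(emb), as.numeric(d), tolerance = 1e-9)
  expect_true(!is.unsorted(rev(ord$eigenvalues)))
  expect_equal(sum(ord$proportion_explained), 1)

  # three collinear points: one informative axis, second eigenvalue ~ 0
  dl <- dist(matrix(c(0, 1, 2), dimnames = list(c("a", "b", "c"), NULL)))
  ordl <- pcoa_ordination(dl)
  expect_equal(unname(abs(diff(sort(ordl$coordinates[, 1])))), c(1, 1),
               tolerance = 1e-9)
  expect_lt(abs(ordl$eigenvalues[2]), 1e-9)

  # identical samples collapse to the origin
  d0 <- as.dist(matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3])))
  expect_true(all(pcoa_ordination(d0)$coordinates == 0))

  expect_error(pcoa_ordination(dist(pts[1:2, ])), "at least 3")
})

test_that("PERMANOVA matches the Anderson statistics and is seed-stable", {
  set.seed(17)
  pts <- matrix(rnorm(24), ncol = 2)
  rownames(pts) <- paste0("s", 1:12)
  d <- dist(pts)
  groups <- rep(c("g1", "g2", "g3"), each = 4)

  res <- permanova(d, groups, permutations = 199, seed = 7)
  orc <- oracle_permanova_stats(d, groups)
  expect_equal(res$pseudo_f, orc$pseudo_f, tolerance = 1e-10)
  expect_equal(res$r_squared, orc$r_squared, tolerance = 1e-10)
  expect_identical(permanova(d, groups, permutations = 199, seed = 7),
                   permanova(d, groups, permutations = 199, seed = 7))
  expect_error(permanova(d, rep("g1", 12)), ">= 2 groups")

  # clearly separated groups: p far in the significant tail
  sep <- rbind(pts[1:6, ] , pts[7:12, ] + 50)
  rownames(sep) <- paste0("s", 1:12)
  psep <- permanova(dist(sep), rep(c("A", "B"), each = 6),
                    permutations = 999, seed = 1)
  expect_lt(psep$p_value, 0.02)
})

test_that("dispersion test separates tight from scattered groups", {
  set.seed(23)
  tight <- matrix(rnorm(16, sd = 0.1), ncol = 2)
  loose <- matrix(rnorm(16, sd = 1), ncol = 2)
  pts <- rbind(tight, loose)
  rownames(pts) <- paste0("s", 1:16)
  groups <- rep(c("tight", "loose"), each = 8)
  res <- beta_dispersion(dist(pts), groups, permutations = 999, seed = 3)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$group_mean_distance[["loose"]],
            res$group_mean_distance[["tight"]])

  # identical samples: all dispersions are zero
  d0 <- as.dist(matrix(0, 6, 6, dimnames = list(paste0("s", 1:6),
                                                paste0("s", 1:6))))
  r0 <- beta_dispersion(d0, rep(c("A", "B"), each = 3), permutations = 99,
                        seed = 1)
  expect_equal(as.numeric(unlist(r0$group_mean_distance)), c(0, 0))

  # singleton groups are flagged and excluded from the homogeneity test
  r1 <- beta_dispersion(dist(pts[1:6, ]), c("A", "A", "A", "B", "C", "C"),
                        permutations = 99, seed = 1)
  expect_equal(r1$singleton_groups, "B")
  expect_equal(sort(names(r1$group_mean_distance)), c("A", "C"))
  # two groups of one sample each leave nothing to test
  expect_error(beta_dispersion(dist(pts[1:2, ]), c("A", "B")),
               "fewer than 2 groups")
})
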
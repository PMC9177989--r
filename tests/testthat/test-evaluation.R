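test_that("AUC handles separation, inversion and ties exactly", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(FALSE, FALSE, TRUE, TRUE)), 0)
  # tie credit: scores {0.5, 0.5, 0.4}, positives 1st and 3rd
  s <- c(0.5, 0.5, 0.4)
  pos <- c(TRUE, FALSE, TRUE)
  expect_equal(roc_auc(s, pos), brute_force_auc(s, pos))
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), "negative spot")
})

test_that("AUC equals brute-force pairwise concordance on all small inputs", {
  # every labelling of a fixed 6-spot score vector (with ties)
  s <- c(0.2, 0.5, 0.5, 0.1, 0.9, 0.2)
  for (mask in 1:(2^6 - 2)) {
    pos <- as.logical(bitwAnd(mask, 2^(0:5)))
    expect_equal(roc_auc(s, pos), brute_force_auc(s, pos))
  }
  # random score/label configurations up to 12 spots
  set.seed(21)
  for (n in 2:12) {
    for (rep in 1:20) {
      s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      pos <- rep(FALSE, n)
      pos[sample(n, sample(n - 1, 1))] <- TRUE
      expect_equal(roc_auc(s, pos), brute_force_auc(s, pos))
    }
  }
})

test_that("AUC significance matches exact enumeration and is monotone", {
  # complete separation, 5 vs 5: exact one-sided p = 1 / choose(10, 5)
  s <- c(6:10, 1:5)
  pos <- rep(c(TRUE, FALSE), each = 5)
  expect_equal(auc_significance(s, pos), 1 / choose(10, 5),
               tolerance = 1e-12)
  # identical distributions: p around 0.5 or larger
  expect_gte(auc_significance(c(1, 2, 3, 1, 2, 3),
                              rep(c(TRUE, FALSE), each = 3)), 0.5)
  # adding a positive above all negatives never increases p
  p1 <- auc_significance(s, pos)
  p2 <- auc_significance(c(s, 20), c(pos, TRUE))
  expect_lte(p2, p1)
  # Bonferroni by definition
  expect_equal(pmin(c(0.01, 0.4) * 3, 1), c(0.03, 1))
})

test_that("auc_report excludes unknown spots and applies Bonferroni", {
  set.seed(5)
  a <- c(runif(10, 0.7, 0.9), runif(10, 0.1, 0.3))  # A high across R1 only
  fr <- cbind(a, 1 - a)
  fm <- fraction_map(fr, cell_types = c("A", "B"),
                     region_label = c(rep("R1", 10), rep("R2", 8),
                                      "unknown", "unknown"))
  rep_tab <- auc_report(fm)
  expect_equal(nrow(rep_tab), 4)  # 2 types x 2 regions; unknown dropped
  a_r1 <- rep_tab[rep_tab$cell_type == "A" & rep_tab$region == "R1", ]
  expect_equal(a_r1$auc, 1)
  expect_equal(rep_tab$p_bonf, pmin(rep_tab$p_value * 4, 1))
  expect_true(a_r1$significant)
})

test_that("domain ranking matches a hand-computed 3-region toy", {
  # 9 spots, 3 regions; fractions laid out so the scaled means are easy
  fr <- rbind(
    c(1.0, 0.1, 0.30), c(0.9, 0.1, 0.30), c(0.8, 0.2, 0.30),  # region X
    c(0.0, 0.8, 0.30), c(0.1, 0.9, 0.31), c(0.2, 0.8, 0.30),  # region Y
    c(0.0, 0.1, 0.30), c(0.1, 0.2, 0.31), c(0.2, 0.1, 0.30)   # region Z
  )
  fm <- fraction_map(fr, cell_types = c("tA", "tB", "tC"),
                     region_label = rep(c("X", "Y", "Z"), each = 3),
                     validate_rows = FALSE)
  tab <- domain_fraction_ranking(fm, top_n = 3, min_scaled_fraction = 0.2)
  # hand computation: per-type min-max scaling over the 9 spots, then means
  scale01 <- function(x) (x - min(x)) / (max(x) - min(x))
  sc <- apply(fr, 2, scale01)
  for (i in seq_len(nrow(tab))) {
    inside <- rep(c("X", "Y", "Z"), each = 3) == tab$region[i]
    j <- match(tab$cell_type[i], c("tA", "tB", "tC"))
    expect_equal(tab$mean_in[i], mean(sc[inside, j]))
    expect_equal(tab$ratio[i], mean(sc[inside, j]) / mean(sc[!inside, j]))
  }
  # tA dominates region X and is excluded (scaled mean < 0.2) elsewhere
  x_top <- tab[tab$region == "X", ]
  expect_equal(x_top$cell_type[1], "tA")
  expect_false("tA" %in% tab$cell_type[tab$region == "Z"])
})

test_that("domain ranking is invariant to spot order and flags restricted types", {
  set.seed(9)
  n <- 60
  fr <- matrix(runif(n * 3), n)
  region <- rep(c("R1", "R2", "R3"), each = n / 3)
  fr[region == "R1", 1] <- fr[region == "R1", 1] + 5  # type 1 only in R1
  fr[region != "R1", 1] <- 0
  fm <- fraction_map(fr, cell_types = c("a", "b", "c"),
                     region_label = region, validate_rows = FALSE)
  tab <- domain_fraction_ranking(fm)
  a_r1 <- tab[tab$region == "R1" & tab$cell_type == "a", ]
  expect_true(is.infinite(a_r1$ratio))
  expect_equal(a_r1$rank, 1L)  # infinite ratio sorts above all finite ones
  expect_true(a_r1$significant)

  perm <- sample(n)
  fm2 <- fraction_map(fr[perm, ], spot_ids = fm$spot_ids[perm],
                      cell_types = c("a", "b", "c"),
                      region_label = region[perm], validate_rows = FALSE)
  expect_equal(domain_fraction_ranking(fm2), tab)
})

test_that("fraction recovery computes per-type correlations", {
  set.seed(2)
  truth <- matrix(runif(30), 10, 3)
  truth <- truth / rowSums(truth)
  fm_t <- fraction_map(truth, cell_types = c("x", "y", "z"))
  fm_p <- fraction_map(truth, cell_types = c("x", "y", "z"))
  rec <- fraction_recovery(fm_t, fm_p)
  expect_equal(rec$pearson, rep(1, 3))
})
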
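test_that("a psychoactive-free library gives identically zero randomized ranks", {
  tab <- toy_table(list(list("i1", "a", 3), list("i1", "b", 2),
                        list("i2", "c", 5)))
  lib <- compound_table(c("a", "b", "c", sprintf("x%02d", 1:7)),
                        is_psychoactive = FALSE)
  nul <- shuffle_compounds(tab, lib, 10, n_reps = 20, seed = 4)
  expect_true(all(nul$per_replicate$value == 0))
  expect_true(all(nul$mean_values$value == 0))
})

test_that("relabelling with the library equal to the predicted set permutes counts", {
  tab <- toy_table(list(list("i1", "a", 3), list("i1", "b", 2),
                        list("i1", "c", 7)))
  lib <- compound_table(c("a", "b", "c"), is_psychoactive = c(TRUE, FALSE, FALSE))
  nul <- shuffle_compounds(tab, lib, 10, n_reps = 30, seed = 5,
                           kind = "compound_rank",
                           indications = indication_table("i1", is_mental_health = TRUE))
  # every replicate redistributes exactly the multiset {3, 2, 7} over {a,b,c}
  for (r in unique(nul$per_replicate$replicate)) {
    sub <- nul$per_replicate[nul$per_replicate$replicate == r, ]
    expect_setequal(sub$entity_id, c("a", "b", "c"))
    expect_true(all(sub$value == 100))  # single MH indication
  }
})

test_that("the mean randomized indication rank approaches 100f for psychoactive fraction f", {
  # closed form: under uniform injective replacement each slot is
  # psychoactive with probability f, so E[rank] = 100 f exactly.
  # First verify the expectation by exhaustive enumeration on a 6-compound
  # library with 2 psychoactives (f = 1/3), 2 distinct predictions.
  cc <- c(3, 5)
  lib_ids <- c("a", "b", "l3", "l4", "l5", "l6")
  psy <- c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  pairs <- expand.grid(i = 1:6, j = 1:6)
  pairs <- pairs[pairs$i != pairs$j, ]
  exhaustive <- mean(100 * (cc[1] * psy[pairs$i] + cc[2] * psy[pairs$j]) / sum(cc))
  expect_equal(exhaustive, 100 / 3, tolerance = 1e-12)
  # then the Monte-Carlo mean under the same conditions
  tab <- toy_table(list(list("i1", "a", 3), list("i1", "b", 5)))
  lib <- compound_table(lib_ids, is_psychoactive = psy)
  nul <- shuffle_compounds(tab, lib, 10, n_reps = 4000, seed = 6)
  mc <- mean(nul$per_replicate$value)
  se <- sd(nul$per_replicate$value) / sqrt(4000)
  expect_lt(abs(mc - 100 / 3), 4 * se)
})

test_that("injectivity is enforced against undersized libraries", {
  tab <- toy_table(list(list("i1", "a", 1), list("i1", "b", 1),
                        list("i1", "c", 1)))
  lib <- compound_table(c("a", "b"), is_psychoactive = FALSE)
  expect_error(shuffle_compounds(tab, lib, 10, 5, 1), "span")
  lib3 <- compound_table(c("a", "b", "z"), is_psychoactive = FALSE)
  tab4 <- toy_table(list(list("i1", "a", 1), list("i1", "b", 1),
                         list("i1", "z", 1), list("i2", "a", 1)))
  expect_silent(shuffle_compounds(tab4, lib3, 10, 3, 1))
})

test_that("indication-label permutation matches the exhaustive expectation", {
  # a compound with equal consensus on all 4 indications has expected
  # randomized compound rank exactly 100 g (g = mental-health fraction)
  tab <- toy_table(list(list("i1", "a", 2), list("i2", "a", 2),
                        list("i3", "a", 2), list("i4", "a", 2)))
  ind <- indication_table(sprintf("i%d", 1:4),
                          is_mental_health = c(TRUE, FALSE, FALSE, FALSE))
  perms <- matrix(c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1),
                  4, 4, byrow = TRUE)
  exhaustive <- mean(apply(perms, 1, function(lab) 100 * sum(2 * lab) / 8))
  expect_equal(exhaustive, 25)
  nul <- shuffle_indications(ind, tab, 10, n_reps = 2000, seed = 8)
  expect_equal(mean(nul$per_replicate$value), 25, tolerance = 1.5)
  # label saturation is rejected as vacuous
  ind_all <- indication_table(sprintf("i%d", 1:4), is_mental_health = TRUE)
  expect_error(shuffle_indications(ind_all, tab, 10, 5, 1), "vacuous")
})

test_that("controls are reproducible under a fixed seed and replicate counts are honest", {
  tab <- toy_table(list(list("i1", "a", 3), list("i1", "b", 2),
                        list("i2", "c", 5), list("i2", "a", 1)))
  lib <- compound_table(c("a", "b", "c", sprintf("x%02d", 1:9)),
                        is_psychoactive = rep(c(TRUE, FALSE), 6))
  n1 <- shuffle_compounds(tab, lib, 10, n_reps = 25, seed = 99)
  n2 <- shuffle_compounds(tab, lib, 10, n_reps = 25, seed = 99)
  expect_identical(n1$per_replicate, n2$per_replicate)
  expect_equal(n1$n_replicates, 25L)
  expect_equal(length(unique(n1$per_replicate$replicate)), 25L)
  # mean_values really is the per-entity mean of per-replicate values
  for (e in n1$mean_values$entity_id) {
    expect_equal(n1$mean_values$value[n1$mean_values$entity_id == e],
                 mean(n1$per_replicate$value[n1$per_replicate$entity_id == e]))
  }
})

test_that("doubling the replicate count moves each mean by less than 3 standard errors", {
  tab <- toy_table(list(list("i1", "a", 3), list("i1", "b", 2),
                        list("i2", "c", 5), list("i2", "d", 4)))
  lib <- compound_table(c("a", "b", "c", "d", sprintf("x%02d", 1:16)),
                        is_psychoactive = rep(c(TRUE, FALSE, FALSE, FALSE), 5))
  nA <- shuffle_compounds(tab, lib, 10, n_reps = 400, seed = 13)
  nB <- shuffle_compounds(tab, lib, 10, n_reps = 800, seed = 14)
  for (e in nA$mean_values$entity_id) {
    va <- nA$per_replicate$value[nA$per_replicate$entity_id == e]
    vb <- nB$mean_values$value[nB$mean_values$entity_id == e]
    se <- sd(va) / sqrt(length(va))
    expect_lt(abs(mean(va) - vb), 3 * se + 1e-9)
  }
})
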
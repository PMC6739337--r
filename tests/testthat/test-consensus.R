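# Brute-force consensus recount used as the oracle: re-rank every approved
# drug's neighbours from scratch and tally candidate membership by hand.
brute_force_consensus <- function(indication, mat, topx) {
  approved <- indication$approved[[1]]
  counts <- list()
  for (d in approved) {
    ids <- brute_force_neighbors(d, mat)$compound_id[seq_len(min(topx, nrow(mat) - 1))]
    for (id in ids) counts[[id]] <- (counts[[id]] %||% 0L) + 1L
  }
  out <- data.frame(compound_id = names(counts),
                    consensus_count = unlist(counts), stringsAsFactors = FALSE)
  out[order(out$compound_id), , drop = FALSE]
}

test_that("consensus counts tally TopX membership across approved drugs", {
  # 6 compounds in two tight clusters; d1,d2,d3 approved; candidate c sits
  # next to d1 and d3 only (TopX = 2)
  m <- interaction_matrix(matrix(c(
    0, 0,      # d1
    10, 10,    # d2
    0.4, 0,    # d3
    0.2, 0,    # c   close to d1 and d3
    10.1, 10,  # e   close to d2
    30, 30     # f   far from everything
  ), 6, 2, byrow = TRUE,
  dimnames = list(c("d1", "d2", "d3", "c", "e", "f"), c("p1", "p2"))))
  ind <- indication_table("pica", approved = list(c("d1", "d2", "d3")))
  pe <- predict_indication(ind[1, ], m, topx = 2)
  cc <- setNames(pe$consensus_count, pe$compound_id)
  expect_equal(unname(cc["c"]), 2L)
  expect_equal(unname(pe$percent_occurrence[pe$compound_id == "c"]),
               100 * 2 / 3, tolerance = 1e-12)
  expect_true(all(pe$consensus_count <= 3))
  expect_true(all(pe$already_approved[pe$compound_id %in% c("d1", "d2", "d3")]))
})

test_that("at saturating TopX every candidate reaches the approved-drug count", {
  m <- random_matrix(8, 4, seed = 3)
  ind <- indication_table("d1", approved = list(c("c01", "c02", "c03")))
  pe <- predict_indication(ind[1, ], m, topx = nrow(m) - 1)
  expect_equal(nrow(pe), nrow(m))       # every compound appears somewhere
  expect_true(all(pe$consensus_count[!pe$already_approved] == 3L))
  expect_true(all(pe$percent_occurrence[!pe$already_approved] == 100))
})

test_that("total consensus mass equals approved-count times X below saturation", {
  m <- random_matrix(15, 5, seed = 7)
  ind <- indication_table(c("a", "b"),
                          approved = list(c("c01", "c02", "c03", "c04"),
                                          c("c05", "c06")))
  cfg <- config_top(6L)
  tab <- build_consensus_table(ind, m, cfg)
  for (id in c("a", "b")) {
    sub <- tab[tab$indication_id == id, ]
    expect_equal(sum(sub$consensus_count),
                 length(ind$approved[[match(id, ind$mesh_id)]]) * 6L)
  }
})

test_that("consensus table matches the brute-force recount on random fixtures", {
  for (s in 1:8) {
    n <- 10 + s
    m <- random_matrix(n, 4, seed = 200 + s)
    set.seed(300 + s)
    appr <- sample(rownames(m), 4)
    ind <- indication_table("z", approved = list(appr))
    x <- sample(2:6, 1)
    got <- predict_indication(ind[1, ], m, x)
    want <- brute_force_consensus(ind[1, ], m, x)
    expect_identical(got$compound_id, want$compound_id)
    expect_identical(got$consensus_count, want$consensus_count)
  }
})

test_that("TopX blocks are nested and the table is order-independent", {
  m <- random_matrix(20, 6, seed = 9)
  ind <- indication_table(c("a", "b"),
                          is_mental_health = c(TRUE, FALSE),
                          approved = list(c("c01", "c02", "c03"),
                                          c("c04", "c05")))
  cfg <- analysis_config(topx_values = c(10L, 25L),
                         association_thresholds = c("10" = 2, "25" = 3))
  tab <- build_consensus_table(ind, m, cfg)
  for (id in c("a", "b")) {
    t10 <- tab[tab$topx == 10 & tab$indication_id == id, ]
    t25 <- tab[tab$topx == 25 & tab$indication_id == id, ]
    expect_true(all(t10$compound_id %in% t25$compound_id))
    joined <- merge(t10, t25, by = "compound_id")
    expect_true(all(joined$consensus_count.x <= joined$consensus_count.y))
  }
  tab2 <- build_consensus_table(ind[c(2, 1), ], m, cfg)
  expect_identical(as.data.frame(tab2), as.data.frame(tab))
})

test_that("unusable indications error alone but are skipped with a warning in bulk", {
  m <- random_matrix(6, 3, seed = 4)
  empty <- indication_table("lonely", approved = list(character()))
  expect_error(predict_indication(empty[1, ], m, 3), "unusable for prediction")
  both <- indication_table(c("ok", "lonely"),
                           approved = list(c("c01", "c02"), character()))
  expect_warning(tab <- build_consensus_table(both, m, config_top(3L)),
                 "lonely")
  expect_setequal(unique(tab$indication_id), "ok")
})
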
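# Invasion scoring: invasive index, the >4-cell cluster rule, invasion
# modes, doubling time, and ordinal score aggregation.

make_cells <- function(x, y, genotype = "fl", invading = TRUE) {
  data.frame(cell_id = seq_along(x), x_um = x, y_um = y,
             genotype = rep_len(genotype, length(x)),
             invading = rep_len(invading, length(x)), section_id = 1L)
}

test_that("invasive index follows its defining formula", {
  cells <- make_cells(runif(100), runif(100),
                      invading = rep(c(TRUE, FALSE), c(30, 70)))
  expect_equal(invasive_index(cells), 30)
  none <- make_cells(1:5, 1:5, invading = FALSE)
  expect_equal(invasive_index(none), 0)
  expect_error(invasive_index(data.frame()), "cell table")
})

test_that("five chained cells are a cluster, four are not", {
  five <- make_cells(seq(0, 100, 25), rep(0, 5))
  c5 <- cluster_invading_cells(five, radius_um = 30)
  expect_true(all(c5$is_cluster))
  expect_equal(unique(c5$size), 5)
  four <- make_cells(seq(0, 75, 25), rep(0, 4))
  c4 <- cluster_invading_cells(four, radius_um = 30)
  expect_false(any(c4$is_cluster))
})

test_that("groups farther apart than the radius are separate components", {
  cells <- make_cells(c(0, 10, 20, 200, 210), rep(0, 5))
  cc <- cluster_invading_cells(cells, radius_um = 30)
  expect_equal(length(unique(cc$component)), 2)
})

test_that("clustering equals brute-force union-find on random tables", {
  withr::with_seed(61, {
    for (rep in 1:8) {
      n <- sample(20:150, 1)
      cells <- make_cells(runif(n, 0, 400), runif(n, 0, 400),
                          invading = runif(n) < 0.7)
      cc <- cluster_invading_cells(cells, radius_um = 25)
      inv <- cells[cells$invading, ]
      want <- brute_components(inv$x_um, inv$y_um, 25)
      # same partition up to relabeling
      expect_equal(length(unique(cc$component)), length(unique(want)))
      expect_true(all(table(cc$component, want) %in%
                        c(0, table(want))))
    }
  })
})

test_that("invasion modes partition invading fl cells", {
  # one all-fl 5-cluster
  cl <- make_cells(seq(0, 100, 25), rep(0, 5))
  expect_equal(classify_invasion_modes(cl, 30),
               c(fl_only_cluster = 5L, mosaic_cluster = 0L, single = 0L))
  # 3 fl + 2 mt mosaic component
  mos <- make_cells(seq(0, 100, 25), rep(0, 5),
                    genotype = c("fl", "mt", "fl", "mt", "fl"))
  expect_equal(classify_invasion_modes(mos, 30),
               c(fl_only_cluster = 0L, mosaic_cluster = 3L, single = 0L))
  # 2-4 cell groups score as single for each fl member
  pair <- make_cells(c(0, 10, 500, 510, 520), rep(0, 5))
  expect_equal(classify_invasion_modes(pair, 30)[["single"]], 5)
})

test_that("generated scenes reproduce their truth exactly", {
  withr::with_seed(62, {
    for (rep in 1:10) {
      spec <- list(list(size = sample(5:8, 1), n_mt = 0),
                   list(size = sample(5:8, 1), n_mt = sample(1:3, 1)))
      sc <- gen_invasion_scene(150, 0.4, genotype_mix = 0.4,
                               cluster_spec = spec,
                               field_um = c(1500, 1500), radius_um = 30,
                               seed = sample.int(1e6, 1))
      truth <- sc$truth$parameters
      expect_equal(invasive_index(sc), truth$invasive_index)
      modes <- classify_invasion_modes(sc, radius_um = 30)
      expect_equal(modes, truth$mode_counts)
      cc <- cluster_invading_cells(sc, radius_um = 30)
      expect_equal(sum(tapply(cc$is_cluster, cc$component, all) &
                         tapply(cc$size, cc$component, max) >= 5),
                   truth$n_clusters)
      # conservation: invading + non-invading = total
      expect_equal(sum(sc$cells$invading) + sum(!sc$cells$invading),
                   nrow(sc$cells))
      # mode counts partition invading fl cells
      expect_equal(sum(modes),
                   sum(sc$cells$invading & sc$cells$genotype == "fl"))
    }
  })
})

test_that("doubling time follows DT = T ln2 / ln(Xe/Xb)", {
  expect_equal(as.numeric(doubling_time(48, 1e4, 4e4)), 24)
  expect_equal(as.numeric(doubling_time(48, 1e4, 2e4)), 48)
  expect_error(doubling_time(48, 1e4, 1e4), "no growth")
  dec <- doubling_time(48, 2e4, 1e4)
  expect_lt(as.numeric(dec), 0)
  expect_true(attr(dec, "decline"))
})

test_that("local-invasion aggregation takes per-mouse maxima then the group
           mean", {
  scores <- list(m1 = c(1, 3, 2), m2 = c(2), m3 = c(3, 3), m4 = c(2, 1))
  agg <- aggregate_local_invasion(scores)
  expect_equal(unname(agg$per_mouse_max), c(3, 2, 3, 2))
  expect_equal(agg$mean_max, 2.5)
  # permutation within a mouse does not matter
  agg2 <- aggregate_local_invasion(lapply(scores, rev))
  expect_equal(agg2$mean_max, agg$mean_max)
  expect_error(aggregate_local_invasion(list()), "empty")
  expect_error(aggregate_local_invasion(list(m1 = numeric(0))), "at least one")
})
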
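test_that("low-coverage filter applies the read floor per lung sample", {
  man <- tiny_manifest(2, 2)
  sheet <- invivo_sheet(2)
  counts <- matrix(c(100L, 100L, 100L, 100L,   # input
                     49L, 50L, 51L, 0L,        # lung m01
                     200L, 10L, 0L, 75L),      # lung m02
                   4, 3, dimnames = list(man$guide_id, sheet$sample_id))
  mask <- filter_low_coverage(counts, sheet, invivo_config(min_lung_reads = 50))
  expect_equal(unname(mask[, 1]), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(unname(mask[, 2]), c(TRUE, FALSE, FALSE, TRUE))
  # threshold 0 retains everything, all-zero column excludes everything
  expect_true(all(filter_low_coverage(counts, sheet, invivo_config(min_lung_reads = 0))))
  counts[, 2] <- 0L
  expect_false(any(filter_low_coverage(counts, sheet)[, 1]))
  # no lung samples is an error
  expect_error(filter_low_coverage(counts[, 1, drop = FALSE], sheet[1, ], invivo_config()),
               "lung")
})

test_that("total-count normalization rescales columns to the target total", {
  m <- matrix(c(10L, 30L, 60L), 3, 1, dimnames = list(c("a", "b", "c"), "s"))
  expect_equal(unname(normalize_total(m, 1e6)[, 1]), c(1e5, 3e5, 6e5))
  man <- tiny_manifest(5, 2)
  counts <- random_counts(man, invivo_sheet(2), seed = 8)
  norm <- normalize_total(counts, 1e6)
  expect_equal(unname(colSums(norm)), rep(1e6, ncol(counts)), tolerance = 1e-9)
  # ratios are preserved
  expect_equal(norm[1, 1] / norm[2, 1], counts[1, 1] / counts[2, 1])
  z <- counts; z[, 2] <- 0L
  expect_error(normalize_total(z), colnames(counts)[2])
})

test_that("per-mouse fold change follows the pseudocount rule", {
  man <- tiny_manifest(2, 1)
  sheet <- invivo_sheet(1)
  norm <- matrix(c(100, 100, 200, 100), 2, 2,
                 dimnames = list(man$guide_id, sheet$sample_id))
  mask <- matrix(TRUE, 2, 1, dimnames = list(man$guide_id, "lung_m01"))
  fc0 <- per_mouse_fold_change(norm, sheet, mask, invivo_config(pseudocount = 0))
  expect_equal(fc0$fold_change, c(2, 1))
  # input 0, lung 100, pc 0.5 -> 100.5 / 0.5 = 201
  norm[1, 1] <- 0; norm[1, 2] <- 100
  fc <- per_mouse_fold_change(norm, sheet, mask, invivo_config(pseudocount = 0.5))
  expect_equal(fc$fold_change[1], 201)
  # identity: equal distributions give fold change 1 at any pseudocount
  norm[, 2] <- norm[, 1]
  fc1 <- per_mouse_fold_change(norm, sheet, mask, invivo_config(pseudocount = 2))
  expect_equal(fc1$fold_change, c(1, 1))
  # non-retained pairs carry NA
  mask[2, 1] <- FALSE
  fc2 <- per_mouse_fold_change(norm, sheet, mask, invivo_config())
  expect_true(is.na(fc2$fold_change[2]) && !fc2$retained[2])
})

test_that("cross-mouse averaging honours both denominator conventions", {
  fcs <- data.frame(
    guide_id = rep(c("g1", "g2", "g3"), each = 3),
    mouse_id = rep(c("m1", "m2", "m3"), 3),
    fold_change = c(2, 4, NA, 5, NA, NA, NA, NA, NA),
    retained = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  ret <- aggregate_across_mice(fcs, invivo_config(average_over = "retained"))
  expect_equal(ret$avg_fold_change[ret$guide_id == "g1"], 3)   # mean(2, 4)
  expect_equal(ret$avg_fold_change[ret$guide_id == "g2"], 5)   # retained once
  expect_equal(ret$n_mice_retained, c(2L, 1L))
  expect_equal(attr(ret, "dropped"), "g3")                     # retained nowhere

  all_mice <- aggregate_across_mice(fcs, invivo_config(average_over = "all"))
  expect_equal(all_mice$avg_fold_change, c(6 / 3, 5 / 3))

  geo <- aggregate_across_mice(fcs, invivo_config(averaging = "geometric"))
  expect_equal(geo$avg_fold_change[1], sqrt(8))
})

test_that("gene ranking takes the best guide and breaks ties by symbol", {
  man <- data.frame(guide_id = c("g1", "g2", "g3", "g4"),
                    gene = c("G", "G", "A", "B"),
                    protospacer = replicate(4, strrep("ACGT", 5)))
  man$protospacer <- c(strrep("ACGT", 5), strrep("CGTA", 5),
                       strrep("GTAC", 5), strrep("TACG", 5))
  pg <- data.frame(guide_id = c("g1", "g2", "g3", "g4"),
                   avg_fold_change = c(1.2, 5.0, 3.0, 3.0),
                   n_mice_retained = c(2L, 3L, 1L, 2L))
  rk <- gene_rank(pg, man)
  expect_equal(rk$gene, c("G", "A", "B"))          # 5.0, then tie 3.0/3.0 A<B
  expect_equal(rk$best_guide_id[1], "g2")          # max rule
  expect_equal(rk$rank, 1:3)
  expect_error(gene_rank(data.frame(guide_id = "gX", avg_fold_change = 1,
                                    n_mice_retained = 1L), man), "gX")
})

test_that("invivo ranking matches a brute-force oracle on random inputs", {
  for (i in 1:100) {
    man <- tiny_manifest(8, 2, seed = i)
    sheet <- invivo_sheet(3)
    counts <- random_counts(man, sheet, lambda = 60, seed = 1000 + i)
    got <- invivo_rank(counts, man, sheet)$ranking
    want <- brute_force_invivo(counts, man, sheet)
    expect_equal(got$gene, want$gene)
    expect_equal(got$best_guide_id, want$guide_id)
    expect_equal(got$avg_fold_change, want$avg)
    expect_equal(got$n_mice_retained, want$n_ret)
  }
})

test_that("ranking is invariant to guide row and lung column permutations", {
  man <- tiny_manifest(10, 3, seed = 21)
  sheet <- invivo_sheet(4)
  counts <- random_counts(man, sheet, lambda = 80, seed = 31)
  base <- invivo_rank(counts, man, sheet)$ranking
  set.seed(9)
  rp <- sample(nrow(man))
  cp <- c(1, 1 + sample(4))  # keep input first, permute lungs
  man2 <- man[rp, ]; rownames(man2) <- NULL
  got <- invivo_rank(counts[rp, cp], man2, sheet[cp, ])$ranking
  expect_equal(got, base)
})

test_that("raising a guide's lung counts never worsens its gene's rank", {
  man <- tiny_manifest(12, 2, seed = 23)
  sheet <- invivo_sheet(3)
  counts <- random_counts(man, sheet, lambda = 90, seed = 41)
  base <- invivo_rank(counts, man, sheet)$ranking
  g <- man$guide_id[5]; gene <- man$gene[5]
  for (boost in c(50L, 500L, 5000L)) {
    bumped <- counts
    bumped[g, sheet$sample_id[sheet$role == "lung"]] <-
      counts[g, sheet$sample_id[sheet$role == "lung"]] + boost
    rk <- invivo_rank(bumped, man, sheet)$ranking
    expect_lte(rk$rank[rk$gene == gene], base$rank[base$gene == gene])
    base <- rk
  }
})

test_that("the full ranking is deterministic for fixed inputs", {
  sc <- invivo_scenario(seed = 5)
  sc$manifest_args$n_genes <- 50L
  man <- do.call(generate_library, sc$manifest_args)
  sim <- simulate_invivo_screen(man, sc$config)
  r1 <- invivo_rank(sim$counts, man, sim$sheet)
  r2 <- invivo_rank(sim$counts, man, sim$sheet)
  expect_identical(r1, r2)
})
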
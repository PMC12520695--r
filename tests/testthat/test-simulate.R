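test_that("generated libraries satisfy the manifest invariants", {
  man <- generate_library(7, 3, seed = 1)
  expect_equal(nrow(man), 21)
  expect_equal(length(unique(man$gene)), 7)
  expect_equal(unname(table(man$gene)), rep(3L, 7), ignore_attr = TRUE)
  expect_false(anyDuplicated(man$guide_id) > 0)
  expect_false(anyDuplicated(man$protospacer) > 0)
  expect_true(all(nchar(man$protospacer) == 20))
  expect_true(all(grepl("^[ACGT]{20}$", man$protospacer)))
  # determinism and seed sensitivity
  expect_identical(generate_library(7, 3, seed = 1), man)
  expect_false(identical(generate_library(7, 3, seed = 2)$protospacer,
                         man$protospacer))
})

test_that("input simulation conserves depth and responds to dispersion", {
  man <- generate_library(50, 3, seed = 2)
  cfg <- invivo_sim_config(seed = 3)
  inp <- simulate_input_counts(man, cfg)
  expect_equal(sum(inp$counts), 500 * nrow(man))   # multinomial conservation
  expect_identical(simulate_input_counts(man, cfg)$counts, inp$counts)
  # zero dispersion: flat expected counts
  flat <- simulate_input_counts(man, invivo_sim_config(abundance_dispersion = 0,
                                                       seed = 3))
  expect_true(all(flat$abundance == 1))
  # empirical CV grows with dispersion at fixed depth
  cv <- function(x) sd(x) / mean(x)
  wide <- simulate_input_counts(man, invivo_sim_config(abundance_dispersion = 1,
                                                       seed = 3))
  expect_gt(cv(wide$counts), cv(flat$counts))
})

test_that("lung bottleneck simulation produces sparse, driver-weighted columns", {
  man <- generate_library(100, 3, seed = 4)
  drivers <- setNames(rep(20, 2), man$gene[c(1, 4)])
  cfg <- invivo_sim_config(n_mice = 4, metastasis_penetrance = 1,
                           clones_per_mouse = 50, driver_genes = drivers,
                           lung_depth_reads = 1e5, seed = 5)
  inp <- simulate_input_counts(man, cfg)
  lung <- simulate_lung_metastasis(inp$abundance, man, cfg)
  expect_equal(ncol(lung$counts), 4)
  expect_equal(unname(colSums(lung$counts)), rep(1e5, 4))  # exact depth
  # severe bottleneck: far fewer detected guides than the library size
  expect_lt(max(colSums(lung$counts > 0)), nrow(man) / 2)
  expect_equal(lung$sheet$role, rep("lung", 4))
  # determinism
  expect_identical(simulate_lung_metastasis(inp$abundance, man, cfg)$counts,
                   lung$counts)
  # degenerate case: a single founding clone per mouse
  one <- simulate_lung_metastasis(inp$abundance, man,
                                  invivo_sim_config(n_mice = 2,
                                                    metastasis_penetrance = 1,
                                                    clones_per_mouse = 1,
                                                    lung_depth_reads = 1e4,
                                                    seed = 6))
  expect_true(all(colSums(one$counts > 0) == 1))
  # zero penetrance warns and returns an empty lung set
  expect_warning(
    none <- simulate_lung_metastasis(inp$abundance, man,
                                     invivo_sim_config(metastasis_penetrance = 0,
                                                       seed = 6)),
    "no metastatic mice")
  expect_equal(ncol(none$counts), 0)
})

test_that("raising a driver's seeding weight never worsens its expected rank", {
  seeds <- 1:5
  mean_rank <- sapply(c(1, 5, 20), function(w) {
    mean(sapply(seeds, function(s) {
      sc <- invivo_scenario(seed = s)
      sc$manifest_args$n_genes <- 200L
      sc$config$driver_genes <- setNames(w, "GENE000001")
      sc$config$n_mice <- 4L
      man <- do.call(generate_library, sc$manifest_args)
      sim <- simulate_invivo_screen(man, sc$config)
      rk <- invivo_rank(sim$counts, man, sim$sheet)$ranking
      r <- rk$rank[rk$gene == "GENE000001"]
      if (length(r)) r else nrow(rk) + 1L
    }))
  })
  expect_true(all(diff(mean_rank) <= 0))
})

test_that("sorted-gate simulation has exact gate geometry and null behaviour", {
  man <- generate_library(50, 3, seed = 7)
  cfg <- sort_sim_config(n_cells = 10000, seed = 8)
  g <- simulate_sorted_gates(man, cfg)
  expect_equal(unname(g$gate_cells), c(500, 500))  # floor(0.05 * 10000)
  expect_equal(unname(colSums(g$counts)), rep(1e6, 2))
  expect_identical(simulate_sorted_gates(man, cfg)$counts, g$counts)
  # null: per-gene gate *cell* compositions consistent with sampling noise
  # (read counts sit on top of cell sampling and are overdispersed)
  hi <- tapply(g$cell_counts[, "sorted_high"], man$gene, sum)
  lo <- tapply(g$cell_counts[, "sorted_low"], man$gene, sum)
  chi <- suppressWarnings(chisq.test(cbind(hi, lo)))
  expect_gt(chi$p.value, 0.01)
  expect_error(sort_sim_config(gate_fraction_high = 0.6), "0, 0.5")
})

test_that("a strong destabilizing effect drives its guides into the low gate", {
  man <- generate_library(50, 3, seed = 9)
  cfg <- sort_sim_config(n_cells = 2e4, effect_genes = c(GENE000001 = -3),
                         seed = 10)
  g <- simulate_sorted_gates(man, cfg)
  sc <- score_guides_sorted(g$counts, g$sheet, sortscreen_config())
  eff <- sc$score[man$gene == "GENE000001"]
  expect_true(all(eff > 0))  # enriched low over high
  rra <- alpha_rra(sc, man, sortscreen_config(n_permutations = 500, seed = 1))
  expect_equal(rra$gene[1], "GENE000001")
})

test_that("emitted FASTQ is a faithful, shuffled expansion of the counts", {
  man <- generate_library(4, 3, seed = 11)
  counts <- matrix(c(3L, rep(0L, 11)), 12, 1,
                   dimnames = list(man$guide_id, "s1"))
  dir <- tempfile("fq")
  p <- emit_fastq(counts, man, dir, constant_prefix = "AC", seed = 1)
  lines <- readLines(p[1])
  expect_equal(length(lines), 12)  # 3 reads x 4 lines
  seqs <- lines[seq(2, 12, by = 4)]
  expect_true(all(seqs == paste0("AC", man$protospacer[1])))
  # empty matrix gives a valid empty FASTQ
  p0 <- emit_fastq(counts * 0L, man, tempfile("fq0"), seed = 1)
  expect_equal(length(readLines(p0[1])), 0)
  # shuffling is seeded: same seed, byte-identical file
  p2 <- emit_fastq(counts, man, tempfile("fq2"), constant_prefix = "AC", seed = 1)
  expect_identical(readLines(p2[1]), lines)
})
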
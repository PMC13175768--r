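test_that("genotypes follow the alt-fraction and depth rules", {
  ref <- matrix(c(20L, 9L, 2L), 1, 3,
                dimnames = list("c1", c("v1", "v2", "v3")))
  alt <- matrix(c(0L, 11L, 1L), 1, 3, dimnames = dimnames(ref))
  gt <- genotype_cells(ref, alt)
  expect_identical(unname(gt[1, ]), c("0/0", "0/1", NA))
  # boundary fractions: 0.2 and 0.8 are heterozygous (strict inequalities)
  gt2 <- genotype_cells(matrix(8L), matrix(2L))   # f = 0.2
  expect_identical(gt2[1, 1], "0/1")
  gt3 <- genotype_cells(matrix(2L), matrix(8L))   # f = 0.8
  expect_identical(gt3[1, 1], "0/1")
})

test_that("demultiplexing assigns by strict majority match and flags ties", {
  db <- list(A = c(v1 = "0/0", v2 = "1/1", v3 = "0/1", v4 = "0/0", v5 = "1/1"),
             B = c(v1 = "1/1", v2 = "0/0", v3 = "0/1", v4 = "1/1", v5 = "0/0"))
  gt <- rbind(perfect = c("0/0", "1/1", "0/1", "0/0", "1/1"),
              at_60 = c("0/0", "1/1", "0/1", "1/1", "0/0"),
              tie = c("0/0", "0/0", "0/1", "1/1", "1/1"))
  colnames(gt) <- paste0("v", 1:5)
  res <- demultiplex(gt, db)
  expect_identical(res$line[1], "A")
  expect_equal(res$match_fraction[1], 1)
  # exactly 3/5 = 0.60 is not strictly greater than the threshold
  expect_identical(res$line[2], "unassigned")
  # equal best match for both lines
  expect_identical(res$line[3], "unassigned")
  expect_true(res$tie[3])
  expect_error(demultiplex(gt, list()), "empty")
})

test_that("simulated lines demultiplex cleanly and doublets stay unassigned", {
  sim <- simulate_germline(3000, c(A = 0.4, B = 0.35, C = 0.25),
                           doublet_rate = 0.10, seed = 55)
  gt <- genotype_cells(sim$ref, sim$alt)
  res <- demultiplex(gt, sim$db)
  singlet <- !grepl("^doublet", sim$line)
  expect_gte(mean(res$line[singlet] == sim$line[singlet]), 0.99)
  expect_lte(mean(res$line[!singlet] != "unassigned"), 0.05)
})

test_that("protein normalisation is compositional and background-centred", {
  withr::local_seed(66)
  lineage <- rep(c("CD4+ T", "CD8+ T", "other"), c(300, 300, 200))
  counts <- simulate_protein(lineage, seed = 67)
  norm <- normalize_protein(counts)
  # doubling all of a cell's counts leaves its normalized profile unchanged
  doubled <- counts
  doubled[1, ] <- 2L * doubled[1, ]
  norm2 <- normalize_protein(doubled)
  expect_equal(norm2[1, ], norm[1, ], tolerance = 1e-12)
  # an all-zero cell is flagged and comes back all-zero
  counts0 <- counts
  counts0[5, ] <- 0L
  norm0 <- normalize_protein(counts0)
  expect_true(all(norm0[5, ] == 0))
  expect_true(5 %in% attr(norm0, "flagged_cells"))
  # positives sit well above background: CD4 separates its population by > 0.7
  cd4_pos <- norm[lineage == "CD4+ T", "CD4"]
  cd4_neg <- norm[lineage != "CD4+ T", "CD4"]
  expect_gt(median(cd4_pos) - median(cd4_neg), 0.7)
})

test_that("lineage rules binarise strictly at the threshold, in order", {
  mk <- function(CD4, CD8, IgG2a = 0) {
    m <- matrix(0, 1, 9, dimnames = list("c1", c("CD4", "CD8", "CD45RO",
                                                 "CD62L", "CD69", "HLA-DR",
                                                 "IgG1", "IgG2a", "IgG2b")))
    m[1, "CD4"] <- CD4; m[1, "CD8"] <- CD8; m[1, "IgG2a"] <- IgG2a
    m
  }
  expect_identical(assign_lineage(mk(1.2, 0.1))$lineage, "CD4+ T")
  # exactly 0.7 is negative (strict threshold)
  expect_identical(assign_lineage(mk(0.7, 0.1))$lineage, "other")
  # sticky wins over lineage and is flagged
  res <- assign_lineage(mk(1.2, 0.1, IgG2a = 1.5))
  expect_identical(res$lineage, "sticky")
  expect_true(res$sticky)
  expect_error(assign_lineage(mk(1, 0),
                              rules = list(x = list(positive = "CD99",
                                                    negative = character(0)))),
               "unknown antibody")
  # deterministic and order-independent across cells
  m2 <- rbind(mk(1.2, 0.1), mk(0.1, 1.2))
  rownames(m2) <- c("a", "b")
  res2 <- assign_lineage(m2)
  expect_identical(res2$lineage, rev(assign_lineage(m2[2:1, ])$lineage))
})

test_that("Fisher p matches hypergeometric enumeration and handles degeneracy", {
  tab <- matrix(c(5, 15, 10, 10), 2, 2, byrow = TRUE)
  ft <- fisher_exact_2x2(tab)
  expect_equal(ft$p, fisher_p_enum(tab), tolerance = 1e-10)
  # identical frequencies: OR 1, p 1
  same <- fisher_exact_2x2(matrix(c(10, 30, 10, 30), 2, 2, byrow = TRUE))
  expect_equal(same$odds_ratio, 1)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # zero margin is degenerate
  dg <- fisher_exact_2x2(matrix(c(0, 0, 5, 7), 2, 2, byrow = TRUE))
  expect_true(dg$degenerate)
  expect_identical(dg$p, 1)
  expect_true(is.na(dg$odds_ratio))
  # Haldane correction engages on a zero cell
  hz <- fisher_exact_2x2(matrix(c(0, 10, 5, 5), 2, 2, byrow = TRUE))
  expect_equal(hz$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))
})

test_that("the exhaustion-like phenotype is scored and tested per CAR status", {
  n <- 400
  m <- matrix(0, n, 9, dimnames = list(NULL, c("CD4", "CD8", "CD45RO",
                                               "CD62L", "CD69", "HLA-DR",
                                               "IgG1", "IgG2a", "IgG2b")))
  transduced <- rep(c(TRUE, FALSE), each = n / 2)
  # 40 CAR+ and 10 CAR- cells get the full phenotype
  ex_idx <- c(1:40, 201:210)
  m[ex_idx, c("CD45RO", "CD69", "HLA-DR")] <- 2
  # some CD45RO+CD69+HLA-DR+ cells that are CD62L+ must NOT count
  m[41:50, c("CD45RO", "CD69", "HLA-DR", "CD62L")] <- 2
  res <- exhaustion_test(m, transduced)
  expect_equal(sum(res$exhaustion_like), 50)
  expect_equal(res$table["CAR+", "exhaustion_like"], 40)
  expect_equal(res$table["CAR-", "exhaustion_like"], 10)
  expect_equal(res$freq_car_pos, 20)
  expect_equal(res$freq_car_neg, 5)
  expect_equal(res$fisher_p, fisher_p_enum(res$table), tolerance = 1e-10)
  expect_gt(res$odds_ratio, 1)
  # excluding the CAR- positives flips the table
  res2 <- exhaustion_test(m, transduced,
                          exclude = seq_len(n) %in% 201:210)
  expect_equal(res2$table["CAR-", "exhaustion_like"], 0)
})
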
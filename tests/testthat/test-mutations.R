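test_that("mutation enumeration expands ranges and ALL correctly", {
  m <- model20
  all10 <- enumerate_mutations("A:10:ALL", m)
  expect_equal(nrow(all10), 19L)
  expect_false(any(all10$mut == all10$wt))
  expect_true(all(all10$wt == m$aa[10]))

  # range with a self-target excluded at matching positions
  g_pos <- which(m$aa == "G")[1]
  rng <- sprintf("A:%d-%d:G", g_pos - 1, g_pos + 1)
  specs <- enumerate_mutations(rng, m)
  expect_equal(nrow(specs), 2L)
  expect_false(g_pos %in% specs$resno)

  expect_warning(empty <- enumerate_mutations("A:999:ALL", m), "skipped")
  expect_equal(nrow(empty), 0L)
  expect_error(enumerate_mutations("A;10;ALL", m), "unparsable")
  expect_error(enumerate_mutations("A:10:XZ", m), "unknown target")
})

test_that("sequence swap replaces the side chain with the target census", {
  spec_g <- data.frame(chain = "A", resno = 5, insert = "",
                       wt = model20$aa[5], mut = "G")
  mut <- model_mutant(helix20, spec_g)
  res5 <- mut$atom[mut$atom$resno == 5, ]
  expect_equal(res5$elety, "CA")
  expect_equal(unique(res5$resid), "GLY")
  # CA fixed, all other residues untouched
  expect_equal(mut$atom[mut$atom$resno != 5, c("x", "y", "z")],
               helix20$atom[helix20$atom$resno != 5, c("x", "y", "z")],
               ignore_attr = TRUE)

  expect_error(model_mutant(helix20,
                            data.frame(chain = "A", resno = 5, insert = "",
                                       wt = model20$aa[5],
                                       mut = model20$aa[5])),
               "equals wild type")
  expect_error(model_mutant(helix20,
                            data.frame(chain = "A", resno = 5, insert = "",
                                       wt = "W", mut = "G")),
               "mismatch")
})

test_that("growing the side chain strictly increases near-neighbour contact weight", {
  ha <- make_helix(12, sequence = strrep("A", 12))
  ma <- build_coarse_model(ha)
  mut <- model_mutant(ha, data.frame(chain = "A", resno = 6, insert = "",
                                     wt = "A", mut = "W"))
  ra_wt <- cgnma:::split_residue_atoms(ha, ma)
  ra_mut <- cgnma:::split_residue_atoms(mut, build_coarse_model(mut))
  d <- as.matrix(stats::dist(ma$coords))
  nbs <- which(d[6, ] > 4 & d[6, ] < 6)    # the ~5 A neighbours
  w_wt <- vapply(nbs, function(j) contact_weight(ra_wt[[6]], ra_wt[[j]]), 0)
  w_mut <- vapply(nbs, function(j) contact_weight(ra_mut[[6]], ra_mut[[j]]), 0)
  expect_true(all(w_mut >= w_wt))
  expect_gt(max(w_mut - w_wt), 0)
})

test_that("external mutant builder failures skip the mutation, not the run", {
  spec <- data.frame(chain = "A", resno = 5, insert = "",
                     wt = model20$aa[5], mut = "G")
  expect_warning(
    out <- model_mutant(helix20, spec, mode = "external_command",
                        external_cmd = "false {input} {output}"),
    "skipped")
  expect_null(out)
})

test_that("entropy differences are antisymmetric and zero on identity", {
  expect_equal(ddS_vib(modes20, modes20), 0)
  mut <- model_mutant(helix20, data.frame(chain = "A", resno = 5, insert = "",
                                          wt = model20$aa[5], mut = "G"))
  mo <- diagonalize(build_hessian(build_network(build_coarse_model(mut),
                                                mut, params_encom)))
  expect_identical(ddS_vib(modes20, mo), -ddS_vib(mo, modes20))
  expect_true(ddS_vib(modes20, mo) != 0)
})

test_that("the uniform-spring model scores every mutation exactly neutral", {
  specs <- enumerate_mutations(c("A:5:GWQ", "A:12:KDY"), model20)
  res <- score_mutations(helix20, specs, params_anm)
  expect_identical(res$scores$ddS_vib, rep(0, nrow(specs)))
})

test_that("the linear combination model is exact arithmetic", {
  cm <- combination_model()
  expect_equal(cm$alpha, -1.12)
  expect_equal(cm$beta, 0.38)
  expect_equal(combine_ddg(1, 1, cm), -0.74)
  expect_equal(combine_ddg(0, 0, cm), 0)
  expect_equal(combine_ddg(3, 2, combination_model(0, 1)), 2)
  expect_true(is.na(combine_ddg(1, NA, cm)))
})

test_that("bootstrap calibration recovers known coefficients", {
  tab <- make_ddg_table(alpha = -1, beta = 0.4, n = 300, sigma = 0.1,
                        seed = 42)
  set.seed(1)
  cal <- calibrate(tab, n_bootstrap = 200L)
  expect_lt(abs(cal$alpha_median - (-1)), 0.1)
  expect_lt(abs(cal$beta_median - 0.4), 0.1)
  expect_true(all(cal$rmse$median >= 0))

  # noise-free table, single sample: exact recovery, zero error
  tab0 <- make_ddg_table(alpha = -0.8, beta = 0.3, n = 50, sigma = 0,
                         seed = 7)
  set.seed(2)
  cal0 <- calibrate(tab0, n_bootstrap = 1L)
  expect_equal(cal0$alpha_median, -0.8, tolerance = 1e-9)
  expect_equal(cal0$beta_median, 0.3, tolerance = 1e-9)
  expect_equal(cal0$rmse$median[cal0$rmse$subset == "all"], 0,
               tolerance = 1e-9)
})

test_that("calibration handles a degenerate enthalpic column", {
  tab <- make_ddg_table(alpha = -1.2, beta = 0, n = 120, sigma = 0.05,
                        seed = 9)
  tab$ddG_B <- 0
  set.seed(3)
  cal <- calibrate(tab, n_bootstrap = 50L)
  expect_true(is.na(cal$beta_median))
  expect_lt(abs(cal$alpha_median - (-1.2)), 0.1)
})

test_that("flexibility difference profiles localize and flip sign", {
  specs <- enumerate_mutations("A:10:G", model20)
  res <- score_mutations(helix20, specs)
  delta <- res$bfactor_delta[1, ]
  expect_equal(bfactor_delta_profile(res$wt_bfactors, res$wt_bfactors),
               rep(0, model20$n))
  expect_equal(bfactor_delta_profile(res$wt_bfactors + delta,
                                     res$wt_bfactors), -delta)
  expect_error(bfactor_delta_profile(1:3, 1:4), "length")
  # shrinking a side chain frees its neighbourhood: positive deltas near site
  near <- abs(seq_len(model20$n) - 10) <= 3
  expect_gt(max(delta[near]), 0)
  expect_gt(mean(delta[near]), mean(delta[!near]))
})

test_that("color scale follows min(max|d|, 3 sd|d|) with a degenerate fallback", {
  d1 <- matrix(c(-1, 0, 1), 1)
  expect_equal(color_scale(d1), min(1, 3 * stats::sd(c(1, 0, 1))))
  d2 <- matrix(0.4, 2, 3)
  expect_equal(color_scale(d2), 0.4)   # sd = 0, fall back to max
  expect_equal(color_scale(matrix(0, 2, 2)), 0)
  d3 <- matrix(c(0.9, rep(0, 9)), 1)
  expect_equal(color_scale(d3), min(0.9, 3 * stats::sd(abs(d3))))
})

test_that("heatmap grid emission depends on job breadth; summary always sorted", {
  specs <- enumerate_mutations(c("A:5:GWQ", "A:6:GWQ", "A:7:GWQ"), model20)
  res <- score_mutations(helix20, specs)
  hm <- heatmap_matrix(res)
  expect_equal(dim(hm$grid), c(3L, 3L))
  expect_false(is.unsorted(hm$top$predicted_ddG))

  one_pos <- enumerate_mutations("A:5:ALL", model20)
  res1 <- score_mutations(helix20, one_pos)
  expect_message(hm1 <- heatmap_matrix(res1), "skipped")
  expect_null(hm1$grid)
  expect_equal(nrow(hm1$top), min(25L, nrow(one_pos)))
})
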
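test_that("Net and ABS PI match hand-computed values", {
  expect_equal(net_pi(c(3, 4)), 7 / sqrt(2))
  expect_equal(net_pi(c(0, 0, 0)), 0)
  expect_equal(net_pi(c(2, -2)), 0)
  expect_equal(abs_pi(c(2, -2)), 4 / sqrt(2))
  expect_equal(abs_pi(0), 0)
  expect_equal(net_pi(c(3, 4), denominator = "n"), 3.5)
  expect_equal(net_pi(c(3, 4), denominator = "none"), 7)
  expect_error(net_pi(numeric()), "empty")
  expect_error(abs_pi(numeric()), "empty")
  expect_error(net_pi(c(1, NA)), "non-finite")
})

test_that("ABS PI dominates |Net PI| with equality iff signs agree", {
  set.seed(41)
  for (i in 1:50) {
    z <- rnorm(sample(1:40, 1), sd = 2)
    expect_gte(abs_pi(z) + 1e-12, abs(net_pi(z)))
    if (all(z >= 0) || all(z <= 0)) {
      expect_equal(abs_pi(z), abs(net_pi(z)))
    } else {
      expect_gt(abs_pi(z), abs(net_pi(z)))
    }
  }
})

test_that("exhaustive null enumerates every subset of the worked example", {
  nl <- build_null(c(1, 2, 3, 4), size = 2, exhaustive = TRUE)
  expect_equal(sort(nl$net * sqrt(2)), c(3, 4, 5, 5, 6, 7))
  expect_equal(nl$n_draws, 6L)
  # set {3, 4}: only the subset {3,4} itself is as extreme -> p = 1/6 exactly
  obs <- net_pi(c(3, 4))
  expect_equal(permutation_pvalue(obs, nl, "net"), 1 / 6)
  expect_equal(permutation_pvalue(obs, nl, "net", sided = "signed"), 1 / 6)
  expect_equal(permutation_pvalue(abs_pi(c(3, 4)), nl, "abs"), 1 / 6)
})

test_that("sampled nulls are deterministic and reflect the score distribution", {
  set.seed(42)
  z <- stats::setNames(rnorm(40), sprintf("g%02d", 1:40))
  a <- build_null(z, size = 5, n_draws = 300, seed = 7)
  b <- build_null(z, size = 5, n_draws = 300, seed = 7)
  expect_identical(a$net, b$net)
  expect_false(identical(build_null(z, size = 5, n_draws = 300, seed = 8)$net,
                         a$net))
  # null mean of Net PI ~ sqrt(n) * mean(z)
  big <- build_null(z, size = 10, n_draws = 4000, seed = 1)
  se <- sd(big$net) / sqrt(4000)
  expect_lt(abs(mean(big$net) - sqrt(10) * mean(z)), 4 * se)
  expect_error(build_null(z, size = 41), "exceeds")
  expect_error(build_null(z, size = 0), "positive")
})

test_that("permutation p-values count ties as extreme and use no pseudo-count", {
  null <- c(1, 2, 3, 4, 5)
  expect_equal(permutation_pvalue(6, null, "abs"), 0)     # beyond all draws
  expect_equal(permutation_pvalue(0.5, null, "net", sided = "signed"), 1)
  expect_equal(permutation_pvalue(3, null, "abs"), 3 / 5) # ties included
  expect_equal(permutation_pvalue(-10, null, "net"), 0)
  expect_error(permutation_pvalue(1, numeric(), "net"), "empty")
})

test_that("sampled p-values agree with the brute-force enumeration oracle", {
  # hand-set 10-gene universe
  z <- c(-2.1, -1.3, -0.4, -0.1, 0.2, 0.3, 0.8, 1.1, 1.9, 2.6)
  names(z) <- sprintf("g%02d", 1:10)
  for (n in c(3L, 4L)) {
    members <- z[seq_len(n) * 2L]
    for (mode in c("net", "abs")) {
      exact <- oracle_pvalue(z, members, mode)
      ex_null <- build_null(z, size = n, exhaustive = TRUE)
      obs <- if (mode == "net") net_pi(members) else abs_pi(members)
      expect_equal(permutation_pvalue(obs, ex_null, mode), exact)
      mc_null <- build_null(z, size = n, n_draws = 10000, seed = 99)
      p_mc <- permutation_pvalue(obs, mc_null, mode)
      se <- sqrt(exact * (1 - exact) / 10000)
      expect_lt(abs(p_mc - exact), max(3 * se, 3 / 10000))
    }
  }
})

test_that("p-values lie on the 1/n_draws grid", {
  set.seed(43)
  z <- stats::setNames(rnorm(60), sprintf("g%02d", 1:60))
  nl <- build_null(z, size = 6, n_draws = 500, seed = 2)
  for (i in 1:20) {
    p <- permutation_pvalue(rnorm(1, sd = 2), nl, "net")
    expect_equal(p * 500, round(p * 500))
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
})

test_that("pathway_impact scores a collection with shared size-matched nulls", {
  sim <- small_screen(n_genes = 300, seed = 44, effects = list(
    planted_effect("planted", sprintf("g%05d", 1:15), shift = 2.5)))
  scores <- process_screen(sim$wells)
  coll <- random_collection(sprintf("g%05d", 1:300), n_sets = 30,
                            size_range = 15L,
                            truth_sets = sim$truth$membership, seed = 9)
  fit <- pathway_impact(scores, coll, readouts = "Abeta42",
                        n_draws = 2000, seed = 5)
  expect_s3_class(fit, "pathway_impact")
  r <- fit$results
  expect_equal(nrow(r), 31)
  expect_equal(unique(r$n), 15L)
  # significance flag is exactly the either-score rule
  expect_equal(r$significant, r$p_net <= 0.01 | r$p_abs <= 0.01)
  # the planted coherent set is recovered
  expect_true(r$significant[r$set == "planted"])
  expect_gt(abs(r$net_pi[r$set == "planted"]), 2)
  # abs >= |net| everywhere
  expect_true(all(r$abs_pi + 1e-12 >= abs(r$net_pi)))
  # determinism of the whole fit
  fit2 <- pathway_impact(scores, coll, readouts = "Abeta42",
                         n_draws = 2000, seed = 5)
  expect_identical(fit$results, fit2$results)
  # methods run
  expect_output(print(fit), "Pathway impact fit")
  s <- summary(fit)
  expect_equal(s$n_sets, 31L)
  cm <- coef(fit)
  expect_equal(dim(cm), c(31L, 1L))
  expect_equal(cm["planted", "Abeta42"], r$net_pi[r$set == "planted"])
})

test_that("set members missing a readout's score are dropped with n recomputed", {
  scores <- data.frame(gene_id = c("a", "b", "c", "d", "e", "f", "g", "h"),
                       s1 = c(1, -1, 2, 0.5, NA, 0.1, -0.3, 0.2),
                       stringsAsFactors = FALSE)
  coll <- gene_set_collection(list(full = c("a", "b", "c"),
                                   holey = c("d", "e", "f"),
                                   gone = "e"),
                              universe = scores$gene_id)
  fit <- pathway_impact(scores, coll, readouts = "s1", n_draws = 50, seed = 1)
  r <- fit$results
  expect_equal(r$n[r$set == "full"], 3L)
  expect_equal(r$n[r$set == "holey"], 2L)
  expect_equal(r$n[r$set == "gone"], 0L)
  expect_true(is.na(r$p_net[r$set == "gone"]))
  expect_false(r$significant[r$set == "gone"])
  expect_equal(fit$dropped$set, c("holey", "gone"))
  expect_equal(r$net_pi[r$set == "holey"], (0.5 + 0.1) / sqrt(2))
})

test_that("volcano tables map p-values to -log10 with a documented cap", {
  res <- data.frame(set = c("s1", "s2", "s3"), source = NA, readout = "r",
                    n = 5L, net_pi = c(1, 2, 9), abs_pi = c(1, 2, 9),
                    p_net = c(0.01, 0.0014, 0), p_abs = c(0.5, 0.2, 0.1),
                    significant = c(TRUE, TRUE, TRUE),
                    stringsAsFactors = FALSE)
  v <- volcano_table(res, "net")
  expect_equal(v$neglog10_p[1], 2)
  expect_equal(v$neglog10_p[2], -log10(0.0014), tolerance = 1e-10)
  expect_equal(v$neglog10_p[2], 2.854, tolerance = 1e-3)
  expect_equal(v$neglog10_p[3], -log10(1 / 10000) + 1)  # display cap
  expect_equal(v$capped, c(FALSE, FALSE, TRUE))
  expect_equal(attr(v, "cutoff"), 2)
})

test_that("PI results round-trip through TSV", {
  sim <- small_screen(n_genes = 100, seed = 46)
  scores <- process_screen(sim$wells)
  coll <- random_collection(sprintf("g%05d", 1:100), 10, size_range = 8L,
                            seed = 3)
  fit <- pathway_impact(scores, coll, n_draws = 200, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pi_results(fit, path)
  back <- read_pi_results(path)
  expect_equal(back$set, fit$results$set)
  expect_equal(back$p_net, fit$results$p_net)
  expect_equal(back$significant, fit$results$significant)
})
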
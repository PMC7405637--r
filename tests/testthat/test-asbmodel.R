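test_that("design rows encode the 2x2 factorial per replicate", {
  tab <- do.call(rbind, lapply(1:3, function(r)
    transform(cells_to_table(10, 20, 30, 40), replicate = r)))
  d <- build_design(tab)
  expect_identical(nrow(d), 12L)
  alt_flank <- d[d$x_r == 1 & d$x_a == 1, ]
  expect_identical(unique(alt_flank$y), 40L)
  # all-zero counts still build (failure belongs to the fit)
  z <- build_design(cells_to_table(0, 0, 0, 0))
  expect_identical(z$y, rep(0L, 4))
  expect_error(build_design(tab[-1, ]), "incomplete design")
})

test_that("saturated single-replicate fits reproduce the cross-ratio", {
  f <- fit_nb_glm(build_design(cells_to_table(20, 80, 40, 80)))
  expect_equal(f$beta_int, log((20 * 80) / (80 * 40)), tolerance = 1e-6)
  expect_equal(f$beta_int, -0.6931, tolerance = 1e-4)
  set.seed(202)
  for (i in 1:20) {
    tab <- random_count_table(min_count = 5)
    f <- fit_nb_glm(build_design(tab))
    y <- tab$count
    names(y) <- paste(tab$allele, tab$region)
    want <- log((y["REF footprint"] * y["ALT flank"]) /
                  (y["REF flank"] * y["ALT footprint"]))
    expect_equal(f$beta_int, unname(want), tolerance = 1e-6)
    # fitted means equal observed counts in the saturated model
    key <- paste(tab$allele, tab$region)
    expect_equal(unname(f$fitted), as.numeric(tab$count), tolerance = 1e-6)
  }
})

test_that("symmetric counts give zero effects and log-mean intercept", {
  f <- fit_nb_glm(build_design(cells_to_table(50, 50, 50, 50)))
  expect_equal(f$beta_int, 0, tolerance = 1e-8)
  expect_equal(f$beta_r, 0, tolerance = 1e-8)
  expect_equal(f$beta_a, 0, tolerance = 1e-8)
  expect_equal(f$beta0, log(50), tolerance = 1e-8)
})

test_that("coefficients agree with an independent NB fit at fixed dispersion", {
  skip_if_not_installed("MASS")
  set.seed(303)
  for (i in 1:10) {
    d <- do.call(rbind, lapply(1:3, function(r) {
      t <- random_count_table(min_count = 3)
      t$replicate <- r
      t
    }))
    des <- build_design(d)
    theta <- 5
    mine <- fit_nb_glm(des, dispersion = 1 / theta)
    ref <- stats::glm(y ~ x_r * x_a, data = des,
                      family = MASS::negative.binomial(theta = theta))
    expect_equal(unname(c(mine$beta0, mine$beta_r, mine$beta_a,
                          mine$beta_int)),
                 unname(coef(ref)), tolerance = 1e-6)
    # glm scales vcov by a Pearson dispersion estimate; undo it to compare
    # against the fixed-theta expected information
    expect_equal(mine$se_int,
                 unname(sqrt(diag(vcov(ref)) / summary(ref)$dispersion)[4]),
                 tolerance = 1e-3)
  }
})

test_that("the dispersion -> 0 limit recovers the Poisson fit", {
  set.seed(404)
  d <- do.call(rbind, lapply(1:3, function(r)
    transform(random_count_table(), replicate = r)))
  des <- build_design(d)
  nb <- fit_nb_glm(des, dispersion = 1e-12)
  pois <- stats::glm(y ~ x_r * x_a, data = des, family = stats::poisson())
  expect_equal(unname(c(nb$beta0, nb$beta_r, nb$beta_a, nb$beta_int)),
               unname(coef(pois)), tolerance = 1e-4)
})

test_that("degenerate sites are excluded with a reason, not fitted", {
  allele_dead <- cells_to_table(0, 0, 30, 60)
  f <- fit_nb_glm(build_design(allele_dead))
  expect_false(f$converged)
  expect_match(f$reason, "no phased coverage")
  sep <- do.call(rbind, lapply(1:2, function(r)
    transform(cells_to_table(0, 50, 40, 60), replicate = r)))
  f2 <- fit_nb_glm(build_design(sep))
  expect_false(f2$converged)
  expect_match(f2$reason, "separation")
  expect_true(is.na(test_interaction(f2)))
})

test_that("interaction test is two-sided, sign-free and monotone in |z|", {
  f <- fit_nb_glm(build_design(cells_to_table(50, 50, 50, 50)))
  expect_equal(test_interaction(f), 1, tolerance = 1e-6)
  base <- list(beta_int = 1, se_int = 0.5, df = Inf, converged = TRUE)
  p1 <- test_interaction(base)
  expect_equal(p1, 2 * pnorm(-2))
  p2 <- test_interaction(modifyList(base, list(beta_int = 2)))
  expect_lt(p2, p1)
  pneg <- test_interaction(modifyList(base, list(beta_int = -1)))
  expect_equal(pneg, p1)
  expect_true(is.na(test_interaction(modifyList(base, list(se_int = 0)))))
})

test_that("likelihood-ratio and Wald tests agree asymptotically", {
  cfg <- sim_config(n_sites = 1, cell_mean = 400, dispersion = 0.02,
                    replicates = 4, footprint_depth = 1, seed = 1)
  set.seed(811)
  tabs <- lapply(1:40, function(i)
    simulate_site(cfg, is_asb = i <= 20, sign = 1)$counts)
  names(tabs) <- paste0("s", 1:40)
  wald <- fit_asb_sites(tabs, dispersion = "common", test = "wald")
  lrt <- fit_asb_sites(tabs, dispersion = "common", test = "lrt")
  ok <- !is.na(wald$pvalue) & !is.na(lrt$pvalue)
  expect_gt(cor(log(wald$pvalue[ok] + 1e-300), log(lrt$pvalue[ok] + 1e-300)),
            0.99)
  # identical classification at 0.05 on well-powered data
  expect_identical(wald$pvalue[ok] < 0.05, lrt$pvalue[ok] < 0.05)
})

test_that("BH adjustment matches the brute-force step-up on random vectors", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_fdr(0.031), 0.031)
  expect_equal(adjust_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(adjust_fdr(numeric(0)), numeric(0))
  set.seed(505)
  for (i in 1:100) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(adjust_fdr(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("common dispersion estimation recovers the simulated value", {
  cfg <- sim_config(n_sites = 1, dispersion = 0.1, replicates = 3, seed = 1)
  set.seed(606)
  designs <- lapply(1:300, function(i)
    build_design(simulate_site(cfg, is_asb = FALSE)$counts))
  est <- estimate_common_dispersion(designs)
  expect_equal(est$dispersion, 0.1, tolerance = 0.35)
  expect_identical(est$df, 300 * 8)
})

test_that("power rises with effect size, replicates and depth", {
  nulls_rej <- function(effect, reps, mean_c, n = 60) {
    cfg <- sim_config(n_sites = 1, beta_int_effect = effect,
                      cell_mean = mean_c, replicates = reps,
                      dispersion = 0.1, footprint_depth = 1, seed = 1)
    tabs <- lapply(seq_len(n), function(i)
      simulate_site(cfg, is_asb = effect > 0)$counts)
    names(tabs) <- paste0("s", seq_len(n))
    fits <- fit_asb_sites(tabs, dispersion = "common")
    mean(fits$pvalue < 0.05, na.rm = TRUE)
  }
  set.seed(707)
  p0 <- nulls_rej(0, 3, 50)
  p1 <- nulls_rej(1, 3, 50)
  p2 <- nulls_rej(2, 3, 50)
  expect_true(p0 < p1 | p1 == 1)
  expect_lte(p1, p2 + 0.05)
  expect_gt(p2, p0)
})

test_that("the empirical filter applies every gate with its boundary semantics", {
  calls <- data.frame(
    snp_id = paste0("s", 1:6), motif_id = "m",
    qvalue = c(0.049, 0.051, 0.049, 0.049, 0.049, 0.049),
    delta = c(-6, -6, -4.9, 6, 5.1, -6),
    beta_int = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9),
    A_ref = c(20, 20, 20, 20, 20, 50),
    A_alt = c(60, 60, 60, 60, 60, 50),
    C_ref = c(80, 80, 80, 80, 80, 50),
    C_alt = c(80, 80, 80, 80, 80, 50))
  out <- empirical_filter(calls, fdr_max = 0.05, min_abs_delta = 5,
                          min_abs_log2_magnitude = 1)
  expect_identical(out$verdict,
                   c("significant", rep("filtered_out", 5)))
  expect_match(out$reasons[2], "fdr")
  expect_match(out$reasons[3], "delta")
  expect_match(out$reasons[4], "inconsistent")
  expect_match(out$reasons[5], "inconsistent")
  expect_match(out$reasons[6], "magnitude")
  # raising any threshold never increases the retained set
  for (args in list(list(fdr_max = 0.01), list(min_abs_delta = 6.5),
                    list(min_abs_log2_magnitude = 2))) {
    tight <- do.call(empirical_filter, c(list(calls), args))
    expect_lte(sum(tight$verdict == "significant"),
               sum(out$verdict == "significant"))
  }
})

test_that("per-SNP summary counts distinct motifs and all calls", {
  calls <- data.frame(
    snp_id = c("s1", "s1", "s1", "s2", "s2"),
    motif_id = c("a", "b", "c", "d", "d"),
    verdict = c(rep("significant", 4), "significant"))
  s <- summarize_snps(calls)
  expect_identical(s$n_motifs, c(3L, 1L))
  expect_identical(s$n_calls, c(3L, 2L))
  empty <- summarize_snps(transform(calls, verdict = "filtered_out"))
  expect_identical(nrow(empty), 0L)
})
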
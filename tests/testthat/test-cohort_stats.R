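test_that("cup summaries match direct arithmetic and respect flags", {
  pts <- data.frame(alpha_o = rep(0.6, 12), alpha_a = rep(0.25, 12))
  cs <- summarize_cup(pts, parameters = c("alpha_o", "alpha_a"))
  expect_equal(unname(cs$mean["alpha_o"]), 0.6)
  expect_equal(unname(cs$sd["alpha_o"]), 0)

  set.seed(8)
  v <- runif(12)
  cs2 <- summarize_cup(data.frame(alpha_o = v), parameters = "alpha_o")
  expect_equal(unname(cs2$mean["alpha_o"]), mean(v))
  expect_equal(unname(cs2$sd["alpha_o"]), sd(v))

  pts$flagged <- rep(c(TRUE, FALSE), c(3, 9))
  pts$alpha_o[1:3] <- 99
  cs3 <- summarize_cup(pts, parameters = "alpha_o")
  expect_equal(unname(cs3$mean["alpha_o"]), 0.6)
  expect_equal(cs3$n_valid, 9)
  expect_equal(cs3$n_flagged, 3)

  pts$flagged <- TRUE
  expect_error(summarize_cup(pts), "excluded")
})

test_that("identical pooled values give H = 0, p = 1", {
  kw <- kruskal_wallis(list(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)))
  expect_equal(kw$H, 0)
  expect_equal(kw$p, 1)
})

test_that("exact permutation p matches an independent brute-force oracle", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal_wallis(groups, method = "exact")
  oracle <- kw_brute_force(groups)
  expect_equal(kw$H, oracle$H, tolerance = 1e-12)
  expect_equal(kw$p, oracle$p)
  expect_equal(kw$p, 6 / 1680)  # 3! block orderings of 1680 assignments

  # ties: mid-ranks, still matching the oracle
  groups_t <- list(c(1, 1, 2), c(2, 3, 3), c(4, 4, 5))
  expect_equal(kruskal_wallis(groups_t, method = "exact")$p,
               kw_brute_force(groups_t)$p)
})

test_that("two fully separated groups of three give permutation p = 0.10", {
  # the maximal H is attained by the observed split and its mirror:
  # 2 of the C(6,3) = 20 assignments
  kw <- kruskal_wallis(list(c(1, 2, 3), c(40, 50, 60)), method = "exact")
  expect_equal(kw$p, 2 / 20)
})

test_that("asymptotic path defers to the chi-squared approximation", {
  g <- list(rnorm(10), rnorm(10) + 1, rnorm(10))
  kw <- kruskal_wallis(g, method = "asymptotic")
  ref <- stats::kruskal.test(unlist(g), factor(rep(1:3, each = 10)))
  expect_equal(kw$H, unname(ref$statistic))
  expect_equal(kw$p, unname(ref$p.value))
})

test_that("Dunn-Bonferroni adjustment, licensing flag, and letters behave", {
  set.seed(2024)
  groups <- lapply(1:4, function(i) rnorm(3, mean = i))
  dn <- dunn_bonferroni(groups)
  expect_equal(nrow(dn$comparisons), 6)
  expect_equal(dn$comparisons$p_adj,
               pmin(1, 6 * dn$comparisons$p_raw), tolerance = 1e-12)
  expect_true(all(dn$comparisons$p_adj >= dn$comparisons$p_raw))

  # identical groups: all adjusted p = 1, one shared letter, not licensed
  same <- dunn_bonferroni(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_true(all(same$comparisons$p_adj == 1))
  expect_equal(length(unique(same$letters)), 1L)
  expect_true("post_hoc_not_licensed" %in% same$flags)

  expect_error(dunn_bonferroni(list(c(1, 2, 3))), "two groups")
})

test_that("letters are consistent with the adjusted-p matrix on simulated draws", {
  set.seed(99)
  for (rep in 1:30) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(4, mean = sample(0:3, 1)))
    names(groups) <- paste0("g", seq_len(k))
    dn <- dunn_bonferroni(groups, method = "asymptotic")
    share <- function(a, b) {
      any(strsplit(dn$letters[[a]], "")[[1]] %in% strsplit(dn$letters[[b]], "")[[1]])
    }
    for (j in seq_len(nrow(dn$comparisons))) {
      expect_identical(share(dn$comparisons$group1[j], dn$comparisons$group2[j]),
                       !dn$comparisons$significant[j])
    }
  }
})

test_that("percent change: basic arithmetic, antisymmetry of sign, zero guard", {
  expect_equal(percent_change(0.50, 0.55), 10)
  expect_equal(percent_change(0.50, 0.50), 0)
  expect_lt(percent_change(0.50, 0.45), 0)
  expect_warning(pc <- percent_change(0, 1), "undefined")
  expect_true(is.na(pc))
  # swap changes sign up to the before/after rescaling
  expect_equal(sign(percent_change(2, 3)), -sign(percent_change(3, 2)))
})

test_that("trend fits recover exact lines and reject degenerate input", {
  x <- c(-10, -5, 0, 5)
  y <- 3 - 0.7 * x
  tf <- trend_fit(x, y)
  expect_equal(tf$slope, -0.7, tolerance = 1e-12)
  expect_equal(tf$intercept, 3, tolerance = 1e-12)
  expect_equal(tf$r, -1, tolerance = 1e-12)
  expect_error(trend_fit(1, 2), "at least 2")
  expect_error(trend_fit(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("simulated wear cohorts give a negative all-trans vs ortho-trans slope", {
  # increasing A_1130 with fixed A_1416 raises all-trans and lowers
  # ortho-trans, so percent changes anti-correlate by construction
  before <- band_areas(0.27, 0.20, 1, 0.55, 0.12)
  d_at <- d_ot <- numeric(4)
  for (i in 1:4) {
    after <- band_areas(0.27, 0.20, 1, 0.55 * (1 + 0.05 * i), 0.12)
    ccb <- compute_conformer_content(before)
    cca <- compute_conformer_content(after)
    d_at[i] <- percent_change(ccb$all_trans, cca$all_trans)
    d_ot[i] <- percent_change(ccb$ortho_trans, cca$ortho_trans)
  }
  expect_lt(trend_fit(d_ot, d_at)$slope, 0)
})

test_that("soak correction is additive, material-matched, at 0.01 mg resolution", {
  grav <- data.frame(
    role = c("loaded", "loaded", "soak_control", "soak_control", "loaded",
             "soak_control"),
    cup_id = c("S1", "S2", "S3", "S4", "X1", "X2"),
    material = c("STD", "STD", "STD", "STD", "XL-50", "XL-50"),
    measured_mass_change_mg = c(95.00, 90.00, 5.00, 5.00, 30.123, 2.001))
  out <- correct_mass_loss(grav)
  expect_equal(out$corrected_mass_loss_mg[out$cup_id == "S1"], 100.00)
  expect_equal(out$corrected_mass_loss_mg[out$cup_id == "S2"], 95.00)
  expect_equal(out$corrected_mass_loss_mg[out$cup_id == "X1"],
               round(30.123 + 2.001, 2))

  # zero soak gain leaves the measurement unchanged
  grav0 <- grav
  grav0$measured_mass_change_mg[grav0$role == "soak_control"] <- 0
  out0 <- correct_mass_loss(grav0)
  expect_equal(out0$corrected_mass_loss_mg[1:2], c(95, 90))

  expect_error(correct_mass_loss(grav[grav$material == "STD" |
                                        grav$role == "loaded", ]),
               "soak control")
})
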
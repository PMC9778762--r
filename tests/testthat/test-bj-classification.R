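test_that("Maximum-range branch selection and thresholds follow the rules", {
  # branch 1: Pimax - (Pimax - Pimin)/10 = 0.9 >= P0 + (Pimax - P0)/2 = 0.7
  mx <- maximum_range_count(c(0, 0.5, 0.9, 1.0) * 1e-5, 0.4e-5)
  expect_equal(mx$branch, 1L)
  expect_equal(mx$threshold, 0.9e-5)
  expect_equal(mx$nmax, 2L)
  expect_equal(mx$members, c(3L, 4L))
  # branch 2: 0.9 >= 0.95 fails, threshold Pimax - (Pimax - P0)/4 = 0.975
  mx2 <- maximum_range_count(c(0, 0.9, 0.98, 1.0) * 1e-5, 0.9e-5)
  expect_equal(mx2$branch, 2L)
  expect_equal(mx2$threshold, 0.975e-5)
  expect_equal(mx2$nmax, 2L)
  # degenerate guards: empty range
  expect_equal(maximum_range_count(c(0.2, 0.5, 1) * 1e-5, 1e-5)$nmax, 0L)
  expect_equal(maximum_range_count(c(0.4, 0.5, 1) * 1e-5, 0.2e-5)$nmax, 0L)
  expect_error(maximum_range_count(numeric(0), 0), "empty")
  expect_error(maximum_range_count(c(-0.1, 0.5), 0.2), ">= 0")
})

test_that("branch-1 threshold is monotone in Pimax and members exceed P0", {
  P <- c(0.1, 0.3, 0.5, 0.8) * 1e-5
  P0 <- 0.2e-5
  base <- maximum_range_count(P, P0)
  for (bump in c(0.9, 1.1, 1.5) * 1e-5) {
    mx <- maximum_range_count(c(P, bump), P0)
    expect_gte(mx$threshold, base$threshold)
    if (mx$nmax > 0) expect_true(all(c(P, bump)[mx$members] > P0))
  }
})

test_that("CSNB sites are exact zeros grouped by part and class", {
  g <- gene_sequence(strrep("A", 980))  # all A-T pairs
  P <- rep(1e-6, 980)
  cs <- csnb_count(P, g)
  expect_equal(sum(cs$csnb), 0L)
  P[c(1, 654)] <- 0
  cs <- csnb_count(P, g)
  expect_equal(cs$csnb[cs$part == "I" & cs$class == "A-T"], 1L)
  expect_equal(cs$csnb[cs$part == "III" & cs$class == "A-T"], 1L)
  expect_equal(sum(cs$csnb), 2L)
  expect_error(csnb_count(P[-1], g), "length mismatch")
  # engineered zero set on a mixed gene
  gm <- synthesize_gene(composition_spec(lengths = c(4L, 3L, 3L),
                                         at_counts = c(2L, 2L, 1L), seed = 8L))
  Pm <- rep(0.5, 10)
  zero_sites <- c(2L, 5L, 10L)
  Pm[zero_sites] <- 0
  csm <- csnb_count(Pm, gm)
  expect_equal(sum(csm$csnb), 3L)
  agg <- tapply(csm$csnb, csm$part, sum)
  expect_equal(unname(agg[as.character(part_of(gm, 2L))] >= 1L), TRUE)
})

test_that("the weighted-CSNB correction matches its closed form", {
  # inputs from the published counts at EcrH 0.585: part I raw 146,
  # whole-gene 434 -> 146 (1 - 434/980)^2 = 45.32; part II raw 181 -> 56.18
  expect_equal(weighted_csnb(181, 434, 980), 181 * (1 - 434 / 980)^2)
  expect_equal(weighted_csnb(181, 434, 980, truncate = TRUE), 56)
  expect_equal(weighted_csnb(146, 434, 980, truncate = TRUE), 45)
  expect_equal(weighted_csnb(300, 980, 980), 0)   # saturated gene
  expect_equal(weighted_csnb(0, 0, 980), 0)       # no closed states
  expect_error(weighted_csnb(-1, 5, 980), "non-negative")
  expect_error(weighted_csnb(5, 981, 980), "exceed")
  # weighted <= raw, truncated and continuous within 1 of each other
  set.seed(4)
  for (k in 1:50) {
    ng <- 980
    g_ <- sample.int(ng, 1)
    nx <- sample.int(g_, 1)
    w <- weighted_csnb(nx, g_, ng)
    wt <- weighted_csnb(nx, g_, ng, truncate = TRUE)
    expect_lte(w, nx)
    expect_lt(w - wt, 1)
    expect_gte(wt, 0)
  }
})

test_that("Q2-Q4 minimum range uses the three-quarter rule", {
  P <- c(0.1, 0.4, 0.9) * 1e-5
  expect_equal(minimum_q2q4_range(P, P0 = 0.5e-5), c(1L, 2L))
  # zero width: only sites at Pimin
  expect_equal(minimum_q2q4_range(P, P0 = P[1L]), 1L)
  expect_equal(minimum_q2q4_range(c(0.5, 0.6) * 1e-5, P0 = 0.2e-5,
                                  Pimin = 0), integer(0))
  expect_error(minimum_q2q4_range(P, P0 = 0), ">= Pimin")
})

test_that("classify_scan partitions sites and aggregates counts coherently", {
  g <- toy_gene_60()
  cfg <- sim_config(T = 3e-12, dt = 1e-14, m = 50)
  sc <- scan_substitutions(g, mech_params(), cfg,
                           energies = c(2e-25, 6e-25, 1e-18))
  cls <- classify_scan(sc, g)
  tab <- cls$table
  expect_equal(nrow(tab), 3L * 6L)  # 3 energies x 3 parts x 2 classes
  for (e in cls$energies) {
    sub <- tab[tab$ecrh == e, ]
    expect_lte(sum(sub$nmax), 60L)  # partition bound
    expect_equal(sum(sub$csnb),
                 cls$gene_csnb[match(e, cls$energies)])
    expect_true(all(sub$csnb_weighted <= sub$csnb))
  }
  # per-part counts bounded by part sizes
  agg <- stats::aggregate(cbind(nmax, csnb) ~ ecrh + part, tab, sum)
  expect_true(all(agg$nmax <= 20L))
  expect_true(all(agg$csnb <= 20L))
  # the unreachable top energy has every site closed and no Maximum range
  top <- tab[tab$ecrh == 1e-18, ]
  expect_equal(sum(top$csnb), 60L)
  expect_equal(sum(top$nmax), 0L)
  # weighted counts at full closure vanish
  expect_equal(sum(top$part_csnb_weighted), 0)
})

test_that("a kD = 1 scan classifies with empty Maximum range everywhere", {
  g <- synthesize_gene(composition_spec(lengths = c(3L, 3L, 3L),
                                        at_counts = c(2L, 1L, 2L), seed = 2L))
  cfg <- sim_config(T = 3e-12, dt = 1e-14, m = 50, kD = 1)
  sc <- scan_substitutions(g, mech_params(kD = 1), cfg,
                           energies = c(2e-25, 1e-18))
  cls <- classify_scan(sc, g)
  expect_true(all(cls$table$nmax == 0L))  # Pimax = P0 never exceeds P0
  expect_equal(sum(cls$table$csnb[cls$table$ecrh == 1e-18]), 9L)
})
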
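wt_l_pools <- c(Ab49 = 56.0, Ab46 = 201.7, Ab43 = 103.3, Ab40 = 196.9,
                Ab48 = 131.5, Ab45 = 153.3, Ab42 = 231.6, Ab38 = 34.2)

test_that("forward map equals branch suffix sums", {
  g <- default_pathway()
  cp <- coproducts_from_pools(wt_l_pools, g)
  # frozen from the suffix-sum oracle on the WT-L reference row
  expect_equal(unname(cp[c("IAT", "VIV", "ITL", "AICD50-99")]),
               c(196.9, 300.2, 501.9, 557.9))
  expect_equal(unname(cp[c("VVIA", "TVI", "VIT", "AICD49-99")]),
               c(34.2, 265.8, 419.1, 550.6))

  # F386S Abeta42-branch row, frozen from the same oracle
  f386s <- c(Ab49 = 41.4, Ab46 = 222.9, Ab43 = 140.9, Ab40 = 41.2,
             Ab48 = 634.8, Ab45 = 180.1, Ab42 = 43.3, Ab38 = 4.3)
  cpf <- coproducts_from_pools(f386s, g)
  expect_equal(unname(cpf[c("VVIA", "TVI", "VIT", "AICD49-99")]),
               c(4.3, 47.6, 227.7, 862.5))

  # agreement with the naive oracle on both rows
  for (pools in list(wt_l_pools, f386s)) {
    expect_equal(unname(coproducts_from_pools(pools, g)[c("AICD50-99", "ITL", "VIV", "IAT")]),
                 oracle_suffix_sums(pools, BRANCH40))
    expect_equal(unname(coproducts_from_pools(pools, g)[c("AICD49-99", "VIT", "TVI", "VVIA")]),
                 oracle_suffix_sums(pools, BRANCH42))
  }

  # zero pools give zero coproducts
  zero <- stats::setNames(rep(0, 8), names(wt_l_pools))
  expect_true(all(coproducts_from_pools(zero, g) == 0))

  # input validation
  expect_error(coproducts_from_pools(c(wt_l_pools, Zz = 1), g), "unknown species")
  expect_error(coproducts_from_pools(wt_l_pools[-1], g), "missing pool")
  bad <- wt_l_pools; bad[["Ab49"]] <- NA
  expect_error(coproducts_from_pools(bad, g), "finite")
})

test_that("mass-balance inversion recovers pools, preserves negatives, censors nd", {
  g <- default_pathway()
  # F386S Abeta42 branch (inverse of the suffix-sum oracle)
  cp <- full_coproducts(c(446.4, 405.0, 182.1, 41.2),
                        c(862.5, 227.7, 47.6, 4.3))
  pt <- pools_from_coproducts(coproduct_table(cp, variant = "F386S"), g)
  expect_equal(unname(pt$pools[c("Ab48", "Ab45", "Ab42", "Ab38")]),
               c(634.8, 180.1, 43.3, 4.3), tolerance = 1e-12)

  # S170F: negative Abeta48 preserved and flagged, never clipped
  cp_s170f <- full_coproducts(c(231.8, 193.4, 65.1, 67.9),
                              c(133.4, 306.9, 85.7, 4.9))
  pt2 <- pools_from_coproducts(coproduct_table(cp_s170f, variant = "S170F"), g)
  expect_equal(unname(pt2$pools[["Ab48"]]), -173.5, tolerance = 1e-12)
  expect_true(any(pt2$flags$code == "NEGATIVE_POOL" &
                    pt2$flags$target == "Ab48"))

  # censored endoproteolysis coproduct makes the first pool nd, flagged
  cp_cens <- as.list(cp)
  cp_cens[["AICD50-99"]] <- censored(62.5)
  pt3 <- pools_from_coproducts(coproduct_table(cp_cens), g)
  expect_true(is.na(pt3$pools[["Ab49"]]))
  expect_equal(pt3$status[["Ab49"]], "nd")
  expect_true(any(pt3$flags$code == "BELOW_LOD" & pt3$flags$target == "Ab49"))
  # downstream pools of the same branch are untouched (monotone censoring)
  expect_equal(pt3$pools[c("Ab46", "Ab43", "Ab40")],
               pt$pools[c("Ab46", "Ab43", "Ab40")])

  # missing coproduct key is an input error
  expect_error(coproduct_table(cp[-1]), "missing coproduct")
  expect_error(coproduct_table(c(cp, bogus = 1)), "unknown coproduct")
})

test_that("forward/inverse round trip is the identity and conserves branch totals", {
  g <- default_pathway()
  set.seed(42)
  for (i in 1:200) {
    pools <- random_pool_vector()
    cp <- coproducts_from_pools(pools, g)
    back <- pools_from_coproducts(coproduct_table(cp), g)$pools
    expect_equal(back[names(pools)], pools, tolerance = 1e-9)
    # conservation: branch pool sum equals the endoproteolysis coproduct
    expect_equal(sum(pools[BRANCH40]), unname(cp[["AICD50-99"]]),
                 tolerance = 1e-9)
    expect_equal(sum(pools[BRANCH42]), unname(cp[["AICD49-99"]]),
                 tolerance = 1e-9)
  }
})

test_that("marking one coproduct censored never changes unrelated pools", {
  g <- default_pathway()
  set.seed(7)
  st <- graph_steps(g)
  for (i in 1:20) {
    pools <- random_pool_vector()
    cp <- coproducts_from_pools(pools, g)
    base <- pools_from_coproducts(coproduct_table(cp), g)
    for (target in names(cp)) {
      cens <- as.list(cp)
      cens[[target]] <- censored(5)
      pt <- pools_from_coproducts(coproduct_table(cens), g)
      defined_by <- st$product[st$coproduct == target]
      upstream <- st$precursor[st$coproduct == target]
      affected <- intersect(c(defined_by, upstream), names(pools))
      keep <- setdiff(names(pools), affected)
      expect_equal(pt$pools[keep], base$pools[keep])
    }
  }
})

test_that("step efficiencies follow the coproduct ratio definition with nd and >100% flags", {
  g <- default_pathway()
  # S170F: Ab48->Ab45 efficiency 230.1% (impossible, flagged)
  cp <- full_coproducts(c(231.8, 193.4, 65.1, 67.9),
                        c(133.4, 306.9, 85.7, 4.9))
  eff <- step_efficiencies(coproduct_table(cp, variant = "S170F"), g)
  expect_equal(eff[["Ab48->Ab45"]], 100 * 306.9 / 133.4, tolerance = 1e-12)
  expect_gt(eff[["Ab48->Ab45"]], 200)
  fl <- attr(eff, "flags")
  expect_true(any(fl$code == "EFFICIENCY_GT_100" & fl$target == "Ab48->Ab45"))

  # producing coproduct zero -> nd
  cp0 <- full_coproducts(c(0, 0, 0, 0), c(100, 50, 10, 1))
  eff0 <- step_efficiencies(coproduct_table(cp0), g)
  expect_true(is.na(eff0[["Ab49->Ab46"]]))
  expect_equal(attr(eff0, "status")[["Ab49->Ab46"]], "nd")

  # complete conversion is exactly 100%, unflagged
  cp100 <- full_coproducts(c(100, 100, 100, 100), c(100, 100, 100, 100))
  eff100 <- step_efficiencies(coproduct_table(cp100), g)
  expect_true(all(as.numeric(eff100) == 100))
  expect_equal(nrow(attr(eff100, "flags")), 0L)

  # censored producing coproduct -> nd for the dependent step only
  cpc <- as.list(full_coproducts(c(500, 400, 200, 100), c(500, 400, 200, 100)))
  cpc[["ITL"]] <- censored(10)
  effc <- step_efficiencies(coproduct_table(cpc), g)
  expect_true(is.na(effc[["Ab49->Ab46"]]))  # its own coproduct is censored
  expect_true(is.na(effc[["Ab46->Ab43"]]))  # producing coproduct censored
  expect_false(is.na(effc[["Ab43->Ab40"]]))
})

test_that("Abeta42/Abeta40 ratio divides pools and propagates nd", {
  g <- default_pathway()
  pt <- pools_from_coproducts(
    coproduct_table(coproducts_from_pools(wt_l_pools, g)), g)
  expect_equal(pt$ratio_42_40, 231.6 / 196.9, tolerance = 1e-12)
  expect_equal(ab42_ab40_ratio(pt), pt$ratio_42_40)

  # zero Abeta40 pool -> nd
  pools0 <- wt_l_pools; pools0[["Ab40"]] <- 0
  pt0 <- pools_from_coproducts(
    coproduct_table(coproducts_from_pools(pools0, g)), g)
  expect_true(is.na(pt0$ratio_42_40))

  # equal positive pools -> exactly 1
  pools1 <- wt_l_pools; pools1[["Ab42"]] <- pools1[["Ab40"]]
  pt1 <- pools_from_coproducts(
    coproduct_table(coproducts_from_pools(pools1, g)), g)
  expect_equal(pt1$ratio_42_40, 1)
})

test_that("qc_report aggregates flags deterministically", {
  g <- default_pathway()
  fx <- table1_fixture()
  s170f <- pools_from_coproducts(implied_coproducts(fx[["S170F"]]), g)
  wtl <- pools_from_coproducts(implied_coproducts(fx[["WT-L"]]), g)

  rep1 <- qc_report(list(s170f, wtl))
  expect_true(any(rep1$variant == "S170F" & rep1$code == "NEGATIVE_POOL" &
                    rep1$target == "Ab48"))
  expect_true(any(rep1$variant == "S170F" & rep1$code == "EFFICIENCY_GT_100" &
                    rep1$target == "Ab48->Ab45"))
  expect_false(any(rep1$variant == "WT-L"))  # no flags for wild type
  # deterministic ordering by (variant, code, target)
  expect_equal(rep1, rep1[order(rep1$variant, rep1$code, rep1$target), ],
               ignore_attr = TRUE)
  expect_equal(nrow(qc_report(list(wtl))), 0L)
})
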
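test_that("the normality gate passes seeded normals and rejects heavy tails", {
  passN <- 0; rejectLn <- 0
  for (s in 1:100) {
    withr::with_seed(s, {
      x <- rnorm(50)
      y <- exp(rnorm(50, sd = 1.5))
    })
    if (normalityGate(x)$decision == "parametric") passN <- passN + 1
    if (normalityGate(y)$decision == "nonparametric") rejectLn <- rejectLn + 1
  }
  # the gate's type-I rate is 5% by construction, so the pass rate over 100
  # fixed seeds fluctuates around 95; require the bulk to pass
  expect_gte(passN, 90)
  expect_gte(rejectLn, 95)
})

test_that("degenerate inputs default to the nonparametric branch with notes", {
  g <- normalityGate(rep(3.2, 10))
  expect_identical(g$decision, "nonparametric")
  expect_match(g$notes, "constant")
  g2 <- normalityGate(c(1, 2), alpha = 0.05)
  expect_identical(g2$decision, "nonparametric")
  expect_match(g2$notes, "n < 3")
  # the gate is per-group: one bad group forces nonparametric
  withr::with_seed(2, {
    v <- c(rnorm(30), exp(rnorm(30, sd = 1.5)))
  })
  expect_identical(normalityGate(v, rep(c("a", "b"), each = 30))$decision,
                   "nonparametric")
})

makePaired <- function(pl, npl, group = "MM") {
  n <- length(pl)
  data.frame(lesion_id = rep(sprintf("L%03d", 1:n), 2),
             group = group,
             illumination = rep(c("PL", "NPL"), each = n),
             shape_fd = c(pl, npl))
}

test_that("identical PL/NPL measurements give zero difference and p = 1", {
  withr::with_seed(11, v <- rnorm(20, 1.4, 0.05))
  rep <- pairedIlluminationTest(makePaired(v, v), "shape_fd")
  s <- reportSummary(rep)
  expect_equal(s$mean_diff, 0)
  expect_equal(unname(pValues(rep)["MM"]), 1)
})

test_that("a small systematic PL/NPL shift is detected with high power", {
  withr::with_seed(42, {
    pl <- rnorm(30, 1.40, 0.04)
    npl <- pl + 0.03 + rnorm(30, sd = 0.01)
  })
  rep <- pairedIlluminationTest(makePaired(pl, npl), "shape_fd")
  expect_lt(unname(pValues(rep)["MM"]), 0.001)
  expect_lt(reportSummary(rep)$mean_diff, 0)  # PL below NPL
})

test_that("swapping illumination labels flips the difference, not the p-value", {
  withr::with_seed(13, {
    pl <- rnorm(25, 1.4, 0.05); npl <- pl + 0.02 + rnorm(25, sd = 0.02)
  })
  a <- pairedIlluminationTest(makePaired(pl, npl), "shape_fd")
  b <- pairedIlluminationTest(makePaired(npl, pl), "shape_fd")
  expect_equal(reportSummary(a)$mean_diff, -reportSummary(b)$mean_diff)
  expect_equal(pValues(a), pValues(b))
})

test_that("unpaired lesions are excluded with a warning", {
  df <- makePaired(rnorm(10, 1.4, 0.04), rnorm(10, 1.45, 0.04))
  df <- df[-1, ]  # orphan one NPL record
  expect_warning(rep <- pairedIlluminationTest(df, "shape_fd"), "unpaired")
  expect_equal(reportSummary(rep)$n, 9)
})

makeGroups <- function(mm, dn, bn, illumination = "PL") {
  data.frame(group = rep(c("MM", "DN", "BN"), c(length(mm), length(dn), length(bn))),
             illumination = illumination, shape_fd = c(mm, dn, bn))
}

test_that("identical groups are not declared different", {
  withr::with_seed(3, v <- rnorm(20, 1.4, 0.05))
  rep <- groupComparison(makeGroups(v, v, v), "shape_fd")
  pw <- pairwisePValues(rep)
  expect_true(all(pw[upper.tri(pw)] > 0.05))
})

test_that("clearly separated normal groups take the parametric LSD branch", {
  withr::with_seed(7, {
    rep <- groupComparison(makeGroups(rnorm(20, 1.39, 0.04),
                                      rnorm(23, 1.42, 0.04),
                                      rnorm(54, 1.47, 0.05)), "shape_fd")
  })
  expect_identical(rep@decision, "parametric")
  expect_match(rep@test, "LSD")
  pw <- pairwisePValues(rep)
  expect_lt(pw["MM", "BN"], 0.001)
  expect_identical(pw, t(pw))
  expect_true(all(is.na(diag(pw))))
})

test_that("skewed groups fall to Kruskal-Wallis with Bonferroni-capped Dunn cells", {
  withr::with_seed(15, {
    mm <- exp(rnorm(20, 0, 1.5)); dn <- exp(rnorm(20, 0.1, 1.5))
    bn <- exp(rnorm(20, 0.05, 1.5))
  })
  rep <- groupComparison(makeGroups(mm, dn, bn), "shape_fd")
  expect_identical(rep@decision, "nonparametric")
  expect_true("mean_rank" %in% names(reportSummary(rep)))
  pw <- pairwisePValues(rep)
  expect_true(all(pw[upper.tri(pw)] <= 1))
  expect_true(any(pw[upper.tri(pw)] == 1))  # capped cells, as in rank tables
})

test_that("records with both illuminations yield one report per illumination", {
  withr::with_seed(9, {
    df <- rbind(makeGroups(rnorm(10, 1.39, 0.04), rnorm(10, 1.42, 0.04),
                           rnorm(10, 1.47, 0.05), "PL"),
                makeGroups(rnorm(10, 1.45, 0.04), rnorm(10, 1.47, 0.04),
                           rnorm(10, 1.50, 0.05), "NPL"))
  })
  reps <- groupComparison(df, "shape_fd")
  expect_setequal(names(reps), c("PL", "NPL"))
  expect_s4_class(reps$PL, "StatsReport")
})

test_that("omnibus p-values are calibrated under label permutation", {
  withr::with_seed(25, {
    v <- rnorm(60, 1.4, 0.05)
    ps <- replicate(150, {
      g <- sample(rep(c("MM", "DN", "BN"), each = 20))
      rep <- groupComparison(data.frame(group = g, illumination = "PL",
                                        shape_fd = v), "shape_fd")
      unname(pValues(rep)["omnibus"])
    })
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Spearman correlations recover constructed monotone structure", {
  down <- data.frame(group = "BN", illumination = "PL",
                     shape_fd = seq(1.5, 1.3, length.out = 20),
                     area = seq(10, 300, length.out = 20),
                     perimeter = seq(12, 70, length.out = 20))
  cm <- correlationMatrix(down)
  expect_equal(cm$r[cm$against == "area"], -1)
  expect_equal(cm$r[cm$against == "perimeter"], -1)
  nullHits <- 0
  for (s in 1:100) {
    withr::with_seed(200 + s, {
      df <- data.frame(group = "MM", illumination = "PL",
                       shape_fd = rnorm(50), area = rnorm(50),
                       perimeter = rnorm(50))
    })
    if (all(abs(correlationMatrix(df)$r) < 0.3)) nullHits <- nullHits + 1
  }
  expect_gte(nullHits, 90)
})

test_that("tie-only vectors give NA correlations and small cells are skipped", {
  df <- data.frame(group = "DN", illumination = "NPL",
                   shape_fd = rep(1.4, 10),
                   area = 1:10, perimeter = 1:10)
  expect_true(all(is.na(correlationMatrix(df)$r)))
  expect_true(all(is.na(correlationMatrix(df[1:3, ])$r)))  # below minN
})

makeStage <- function(insitu, invasive, illumination = "PL") {
  data.frame(group = "MM",
             stage = rep(c("in_situ", "invasive"),
                         c(length(insitu), length(invasive))),
             illumination = illumination,
             shape_fd = c(insitu, invasive))
}

test_that("identical melanoma subgroups are non-significant; label swap is neutral", {
  withr::with_seed(5, v <- rnorm(8, 1.4, 0.02))
  rep <- melanomaSubgroupTest(makeStage(v, v))
  expect_gt(unname(pValues(rep)["shape_fd_PL"]), 0.05)
  withr::with_seed(6, {
    a <- rnorm(8, 1.42, 0.02); b <- rnorm(12, 1.37, 0.02)
  })
  r1 <- melanomaSubgroupTest(makeStage(a, b))
  r2 <- melanomaSubgroupTest(makeStage(b, a))
  expect_equal(unname(pValues(r1)["shape_fd_PL"]),
               unname(pValues(r2)["shape_fd_PL"]))
})

test_that("in-situ/invasive separation at tabulated effect sizes has high power", {
  hits <- 0
  for (s in 1:200) {
    withr::with_seed(3000 + s, {
      insitu <- rnorm(8, 1.4166, 0.0165)
      invasive <- rnorm(12, 1.3708, 0.0165)
    })
    p <- unname(pValues(melanomaSubgroupTest(makeStage(insitu, invasive)))["shape_fd_PL"])
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 190)  # >= 95% of replicates
})

test_that("surface FD subgroups use Mann-Whitney and empty subgroups are flagged", {
  withr::with_seed(8, {
    srf <- data.frame(group = "MM",
                      stage = rep(c("in_situ", "invasive"), c(30, 40)),
                      illumination = "PL",
                      surface_fd = c(rnorm(30, 1.47, 0.13), rnorm(40, 1.58, 0.12)))
  })
  rep <- melanomaSubgroupTest(makeStage(rnorm(8, 1.42, 0.02), rnorm(12, 1.37, 0.02)),
                              srf)
  expect_true("surface_fd_PL" %in% names(pValues(rep)))
  onlyInSitu <- makeStage(rnorm(8, 1.42, 0.02), numeric(0))
  rep2 <- melanomaSubgroupTest(onlyInSitu)
  expect_true(is.na(pValues(rep2)["shape_fd_PL"]))
  expect_match(rep2@notes, "empty", all = FALSE)
})
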
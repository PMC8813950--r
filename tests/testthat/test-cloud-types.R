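test_that("the ISCCP table maps pressure/optical-depth bins to the nine types", {
  expect_equal(classifyIsccp(300, 30), 3L)   # high, thick: deep convection
  expect_equal(classifyIsccp(900, 10), 8L)   # low, medium: stratocumulus
  expect_equal(classifyIsccp(500, 1), 4L)    # mid, thin: altocumulus
  # full bijection over representative bin points
  reps <- expand.grid(ctp = c(300, 500, 900), tau = c(1, 10, 30))
  expect_setequal(classifyIsccp(reps$ctp, reps$tau), 1:9)
  # boundary values go to the higher-altitude / thinner bin
  expect_equal(classifyIsccp(440, 3.6), 1L)
  expect_equal(classifyIsccp(680, 23), 5L)
  expect_equal(classifyIsccp(c(300, NA), c(NA, 5)), c(NA_integer_, NA_integer_))
  expect_error(classifyIsccp(-10, 5), "positive")
  expect_error(classifyIsccp(500, -1), "non-negative")
})

test_that("a single present type carries the whole effect", {
  s <- toySurface()
  cm <- toyClassmap(s)
  cloudV <- matrix(0.3, 20, 20); cloudV[, 1:10] <- 0.4
  total <- gridField(cloudV, 0.05, originLat = 40, fraction = TRUE)
  zero <- gridField(matrix(0, 20, 20), 0.05, originLat = 40, fraction = TRUE)
  fields <- rep(list(zero), 9)
  fields[[7]] <- total
  pte <- perTypeEffects(cm, fields, total)
  expect_true(all(abs(pte$cells$delta7 - 0.1) < 1e-12))
  expect_true(all(pte$cells[paste0("delta", c(1:6, 8:9))] == 0))
  expect_true(all(abs(pte$cells$total - 0.1) < 1e-12))
  expect_true(all(pte$cells$dominant == 7L))

  # no clouds anywhere: zero vectors, no dominant type
  pte0 <- perTypeEffects(cm, rep(list(zero), 9), zero)
  expect_true(all(pte0$cells$total == 0))
  expect_true(all(is.na(pte0$cells$dominant)))
})

test_that("violating the per-pixel sum identity is an input error", {
  s <- toySurface()
  cm <- toyClassmap(s)
  total <- gridField(matrix(0.3, 20, 20), 0.05, originLat = 40, fraction = TRUE)
  zero <- gridField(matrix(0, 20, 20), 0.05, originLat = 40, fraction = TRUE)
  fields <- rep(list(zero), 9)
  fields[[2]] <- gridField(matrix(0.299, 20, 20), 0.05, originLat = 40,
                           fraction = TRUE)
  expect_error(perTypeEffects(cm, fields, total), "sum to the total")
})

test_that("per-type effects sum to the total effect on generated scenes", {
  sc <- fixTypes()
  cm <- classifyScene(sc)
  pte <- perTypeEffects(cm, sc@typeFractions, stackMean(sc@cloudYearly),
                        sc@elevation, bufferWaterMask(sc@waterMask))
  dm <- as.matrix(pte$cells[paste0("delta", 1:9)])
  expect_true(all(abs(rowSums(dm) - pte$cells$total) <= 1e-10))
  wm <- as.matrix(pte$windows[paste0("delta", 1:9)])
  expect_true(all(abs(rowSums(wm) - pte$windows$total) <= 1e-10))
  # each per-type entry equals an independent per-window loop oracle
  w <- placeWindows(cm)
  wkey <- paste(w$lat, w$lon)
  set.seed(71)
  pick <- sample(nrow(pte$windows), 5)
  buf <- bufferWaterMask(sc@waterMask)
  for (k in pick) {
    i <- match(paste(pte$windows$lat[k], pte$windows$lon[k]), wkey)
    for (t in c(1, 5, 8)) {
      o <- windowMeansOracle(gridValues(cm),
                             gridValues(sc@typeFractions[[t]]),
                             w$row0[i], w$col0[i], 9,
                             CLASS_CODES[["UNCHANGED_FOREST"]],
                             CLASS_CODES[["UNCHANGED_NONFOREST"]],
                             buffer = buf)
      expect_equal(pte$windows[[paste0("delta", t)]][k], o$meanA - o$meanB,
                   tolerance = 1e-12)
    }
  }
})

test_that("dominant-type selection filters by sign then takes the largest magnitude", {
  rec <- rep(0, 9); rec[3] <- 0.01; rec[7] <- 0.03; rec[8] <- 0.01
  expect_equal(dominantType(rec, 0.05), 7L)
  rec2 <- rep(-0.01, 9); rec2[1] <- 0.02
  expect_equal(dominantType(rec2, 0.02), 1L)
  expect_true(is.na(dominantType(rep(-0.01, 9), 0.05)))
  expect_true(is.na(dominantType(rep(0.01, 9), 0)))
  tied <- rep(0, 9); tied[c(2, 6)] <- 0.02
  expect_equal(dominantType(tied, 0.01), 2L)  # ties to the smallest code
  set.seed(72)
  for (r in 1:30) {
    v <- rnorm(9); tot <- rnorm(1)
    got <- dominantType(v, tot)
    cand <- which(sign(v) == sign(tot))
    if (!length(cand)) expect_true(is.na(got))
    else expect_equal(got, cand[which.max(abs(v[cand]))])
  }
})

test_that("convective dominance percentages follow the counting oracle", {
  expect_equal(convectiveDominanceFraction(rep(8L, 10)),
               c(convective = 100, shallow = 100))
  expect_equal(convectiveDominanceFraction(rep(1L, 10))[["convective"]], 0)
  set.seed(73)
  d <- sample(c(1:9, NA), 200, replace = TRUE)
  got <- convectiveDominanceFraction(d)
  expect_equal(got[["convective"]],
               100 * sum(d %in% c(3, 7, 8)) / sum(!is.na(d)))
  expect_equal(got[["shallow"]],
               100 * sum(d %in% c(7, 8)) / sum(!is.na(d)))
})

test_that("scenes with gradient-linked convection are convection-dominated", {
  sc <- fixTypes()
  cm <- classifyScene(sc)
  pte <- perTypeEffects(cm, sc@typeFractions, stackMean(sc@cloudYearly),
                        sc@elevation, bufferWaterMask(sc@waterMask))
  expect_gt(convectiveDominanceFraction(pte$cells$dominant)[["convective"]], 50)
})
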
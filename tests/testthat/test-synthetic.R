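test_that("constant and checkerboard fixtures are exactly two-valued grids", {
  cf <- renderFixture("constant_field", side = 64, foreground = 128)
  expect_true(all(pixels(cf) == 128))
  expect_identical(dim(cf), c(64L, 64L))
  cb <- renderFixture("checkerboard", side = 16, foreground = 10, background = 200)
  expect_setequal(unique(as.vector(pixels(cb))), c(10, 200))
})

test_that("Sierpinski carpet follows the base-3 digit rule", {
  c1 <- renderFixture("sierpinski_carpet", depth = 1, foreground = 0, background = 255)
  expect_identical(pixels(c1),
                   matrix(c(0, 0, 0, 0, 255, 0, 0, 0, 0), 3, 3))
  # depth 3: brute-force digit test over all 729 pixels as the oracle
  c3 <- renderFixture("sierpinski_carpet", depth = 3)
  isHole <- function(x, y) {  # 0-based coords
    for (l in 0:2) if ((x %/% 3^l) %% 3 == 1 && (y %/% 3^l) %% 3 == 1) return(TRUE)
    FALSE
  }
  oracle <- outer(0:26, 0:26, Vectorize(isHole))
  expect_identical(pixels(c3) == 255, oracle)
  expect_equal(sum(pixels(c3) == 0), 512)  # 8^3 foreground pixels
})

test_that("carpet foreground fraction is (8/9)^depth and wrong sides are rejected", {
  for (d in 1:4) {
    cp <- renderFixture("sierpinski_carpet", depth = d)
    expect_equal(mean(pixels(cp) == 0), (8 / 9)^d)
  }
  expect_error(renderFixture("sierpinski_carpet", depth = 2, side = 10),
               "3\\^depth")
})

test_that("fBm fixture is seeded, standardized into [0,255], and Hurst-controlled", {
  a <- renderFixture("fbm_texture", side = 64, hurst = 0.4, seed = 11)
  b <- renderFixture("fbm_texture", side = 64, hurst = 0.4, seed = 11)
  expect_identical(pixels(a), pixels(b))
  expect_equal(range(pixels(a)), c(0, 255))
  c2 <- renderFixture("fbm_texture", side = 64, hurst = 0.4, seed = 12)
  expect_false(identical(pixels(a), pixels(c2)))
})

test_that("a zero-irregularity flat lesion rasterizes to a disc of the right area", {
  p <- lesionParams(irregularityAmplitude = 0, textureSd = 0,
                    specularNoiseDensity = 0, seed = 5)
  m <- groundTruthMask(p)
  expect_equal(sum(pixels(m)), pi * 80^2, tolerance = 0.02)
  img <- renderLesion(p)
  expect_true(all(pixels(img)[pixels(m)] <= 80))  # flat dark lesion
})

test_that("rendering is bit-deterministic and PL/NPL share boundary and texture", {
  p <- lesionParams(seed = 99)
  expect_identical(pixels(renderLesion(p)), pixels(renderLesion(p)))
  pn <- lesionParams(seed = 99, illumination = "NPL")
  expect_identical(pixels(groundTruthMask(p)), pixels(groundTruthMask(pn)))
  expect_false(identical(pixels(renderLesion(p)), pixels(renderLesion(pn))))
})

test_that("NPL render compresses contrast and adds saturated speckle", {
  p <- lesionParams(seed = 3, specularNoiseDensity = 0.01)
  pn <- lesionParams(seed = 3, illumination = "NPL", specularNoiseDensity = 0.01)
  pl <- pixels(renderLesion(p)); npl <- pixels(renderLesion(pn))
  m <- pixels(groundTruthMask(p))
  contrast <- function(px) mean(px[!m]) - mean(px[m])
  expect_lt(contrast(npl), contrast(pl))
  expect_gt(sum(npl == 255), 0.005 * length(npl))  # speckle present
  expect_equal(sum(pl == 255), 0)
})

test_that("boundary self-intersection is rejected with guidance", {
  p <- lesionParams(irregularityAmplitude = 5, seed = 1)
  expect_error(renderLesion(p), "irregularityAmplitude")
  expect_error(boundaryCurve(p), "irregularityAmplitude")
})

test_that("normalized boundary perimeter grows with the irregularity amplitude", {
  # asserted on the analytic curve, not on a rasterization or on FD
  normPerim <- function(amp, seed) {
    bc <- boundaryCurve(lesionParams(irregularityAmplitude = amp, seed = seed),
                        nTheta = 2048)
    r <- bc$radius; th <- bc$theta
    dth <- diff(th)[1]
    dr <- (r[c(2:length(r), 1)] - r[c(length(r), 1:(length(r) - 1))]) / (2 * dth)
    P <- sum(sqrt(r^2 + dr^2)) * dth
    A <- sum(0.5 * r^2) * dth
    P / sqrt(A)
  }
  for (seed in c(2, 17, 31)) {
    np <- vapply(c(0, 0.1, 0.2, 0.35), normPerim, numeric(1), seed = seed)
    expect_true(all(diff(np) > 0))
  }
})

test_that("cohort generation counts, naming and determinism hold", {
  ch <- generateCohort(2, seed = 7, render = FALSE)
  expect_length(ch, 6)  # 2 lesions x 3 presets
  expect_setequal(unique(vapply(ch, `[[`, "", "group")), c("MM", "DN", "BN"))
  big <- generateCohort(c(MM = 20, DN = 23, BN = 54), seed = 7, render = FALSE)
  expect_length(big, 97)
  a <- generateCohort(1, seed = 12)[[1]]
  b <- generateCohort(1, seed = 12)[[1]]
  expect_identical(pixels(a$imagePL), pixels(b$imagePL))
  expect_identical(pixels(a$imageNPL), pixels(b$imageNPL))
  expect_false(identical(pixels(a$imagePL),
                         pixels(generateCohort(1, seed = 13)[[1]]$imagePL)))
})
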
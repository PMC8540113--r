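refPolyG <- list(formId = "polyG",
                 params = c(b31 = -2.18e-2, b32 = -7.52e-5))

test_that("model evaluation matches direct arithmetic", {
  expect_equal(evaluateModel(refPolyG, list(G = 94)),
               -2.18e-2 * 94 - 7.52e-5 * 94^2)
  expect_equal(round(evaluateModel(refPolyG, list(G = 94)), 3), -2.714)
  lin <- list(formId = "linearG", params = c(b11 = 0.89, b12 = -3.98e-2))
  expect_equal(evaluateModel(lin, list(G = 0)), 0.89)
  zero <- list(formId = "polyG", params = c(b31 = 0, b32 = 0))
  expect_equal(evaluateModel(zero, list(G = 123.4)), 0)
  pw <- list(formId = "powerG", params = c(b21 = -7.65e-3, b22 = 1.295))
  expect_error(evaluateModel(pw, list(G = 0)), "positive")
  expect_error(evaluateModel(refPolyG, list(I_AC = 1)), "descriptors")
})

test_that("zero-noise data are fitted to machine precision", {
  G <- c(40, 56, 72, 88, 94, 96, 188)
  truth <- c(b31 = -2.18e-2, b32 = -7.52e-5)
  data <- data.frame(G = G, k_N = truth[1] * G + truth[2] * G^2)
  fit <- fitQspr("polyG", data)
  expect_equal(unname(modelParams(fit)), unname(truth), tolerance = 1e-10)
  expect_lt(theta(fit), 1e-20)

  dataP <- data.frame(I_AC = c(20, 26, 30, 32, 36, 38, 68),
                      Z1 = c(20, 30, 48, 40, 58, 50, 120))
  dataP$k_N <- -1.44e-2 * dataP$I_AC^1.026 * dataP$Z1^0.381
  fitP <- fitQspr("power2", dataP)
  expect_equal(unname(modelParams(fitP)),
               c(-1.44e-2, 1.026, 0.381), tolerance = 1e-8)
  expect_lt(theta(fitP), 1e-18)
})

test_that("fit preconditions are enforced", {
  d <- data.frame(G = c(40, 90), k_N = c(-1, -2))
  expect_error(fitQspr("polyG", d), "n = 2.*p = 2")
  expect_error(fitQspr("polyG", data.frame(I_AC = 1:5, k_N = 1:5)),
               "column")
  expect_error(fitQspr("sigmoid", data.frame(G = 1:5, k_N = 1:5)),
               "unknown model form")
  bad <- data.frame(G = c(40, 60, 90), k_N = c(-1, NA, -2))
  expect_error(fitQspr("linearG", bad), "finite")
})

test_that("variance statistic follows theta / (n - p)", {
  expect_equal(modelVariance(3.10e-1, 8, 2), 5.17e-2, tolerance = 2e-3)
  expect_equal(modelVariance(4.15e-1, 8, 3), 8.29e-2, tolerance = 2e-3)
  expect_equal(modelVariance(0, 8, 2), 0)
  expect_error(modelVariance(0.3, 3, 3), "exceed")
})

test_that("phi bookkeeping responds to duplicated data points", {
  d <- referenceFitData()
  fit <- fitQspr("linearG", d)
  fitDup <- fitQspr("linearG", rbind(d, d[3, ]))
  expect_equal(nPoints(fitDup), nPoints(fit) + 1L)
  expect_equal(phi(fitDup), theta(fitDup) / (nPoints(fitDup) - 2L))
})

test_that("model selection minimizes phi with deterministic tie-breaks", {
  fits <- fitReferenceModels()
  expect_equal(formId(selectModel(fits)), "polyG")
  expect_equal(formId(selectModel(fits["linearG"])), "linearG")

  mk <- function(form, p, phiVal) {
    pars <- setNames(rep(0, length(qsprForms()[[form]]$params)),
                     qsprForms()[[form]]$params)
    new("QsprFit", formId = form, params = pars,
        theta = phiVal * (10 - p), phi = phiVal, n = 10L,
        p = as.integer(p))
  }
  tie <- list(mk("linear2", 3, 0.05), mk("polyG", 2, 0.05))
  expect_equal(formId(selectModel(tie)), "polyG")  # smaller p wins
  tie2 <- list(mk("powerG", 2, 0.05), mk("linearG", 2, 0.05))
  expect_equal(formId(selectModel(tie2)), "linearG")  # canonical order
  expect_error(selectModel(list()), "empty")
})

test_that("structure-based prediction composes descriptors and model", {
  expect_equal(predictKnFromStructure(builtinSolute("glucose"), refPolyG),
               -2.714, tolerance = 2e-3)
  # sucrose G = 187.95 under the reference polynomial
  expect_equal(predictKnFromStructure(builtinSolute("sucrose"), refPolyG),
               -2.18e-2 * 187.9526 - 7.52e-5 * 187.9526^2,
               tolerance = 1e-6)
  lone <- moleculeFromAdjacency("C", list(), explicitH = 0L)
  expect_equal(predictKnFromStructure(lone, refPolyG), 0)
})

test_that("single-index models improve on the two-descriptor models", {
  fits <- fitReferenceModels(exclude = character())  # all eight solutes
  phis <- vapply(fits, phi, numeric(1))
  expect_lte(min(phis[c("linearG", "powerG", "polyG")]),
             min(phis[c("linear2", "power2")]))
  fits7 <- fitReferenceModels()
  phis7 <- vapply(fits7, phi, numeric(1))
  expect_lte(min(phis7[c("linearG", "powerG", "polyG")]),
             min(phis7[c("linear2", "power2")]))
})

test_that("nonlinear fits are deterministic", {
  d <- referenceFitData()
  f1 <- fitQspr("powerG", d)
  f2 <- fitQspr("powerG", d)
  expect_identical(modelParams(f1), modelParams(f2))
  expect_identical(theta(f1), theta(f2))
})

test_that("QSPR fits serialize to JSON and back at full precision", {
  fit <- fitQspr("polyG", referenceFitData())
  path <- tempfile(fileext = ".json")
  writeQsprFitJson(fit, path)
  back <- readQsprFitJson(path)
  expect_identical(formId(back), formId(fit))
  expect_equal(modelParams(back), modelParams(fit), tolerance = 1e-12)
  expect_equal(theta(back), theta(fit), tolerance = 1e-12)
  expect_equal(nPoints(back), nPoints(fit))
})
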
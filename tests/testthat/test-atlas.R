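test_that("landmarks take the stated values and orderings", {
  p <- preset_params("fig10", PR = 10, df = 0.5)
  L <- landmarks(p)
  expect_equal(unname(L[c("N_minus", "N_plus", "M_minus", "M_plus")]),
               c(0.7408, 0.6376, 0.4493, 0.3867), tolerance = 1e-4)
  expect_identical(L[["R_plus"]], L[["N_plus"]])
  set.seed(21)
  for (i in 1:100) {
    q <- if (i %% 2) random_bio_params() else random_long_delay_params()
    Lq <- landmarks(q)
    expect_true(Lq[["N_minus"]] >= Lq[["N_plus"]])
    expect_true(Lq[["N_plus"]] >= Lq[["M_minus"]])
    expect_true(Lq[["M_minus"]] >= Lq[["M_plus"]])
    expect_true(Lq[["R_minus"]] >= Lq[["R_plus"]])
    cv <- condition_values(q)
    expect_true(all(is.finite(cv)))
    # the "-" sample sees the larger landmark, hence the smaller drive
    expect_true(cv[["C3_minus"]] <= cv[["C3_plus"]])
    expect_true(cv[["C2_minus"]] <= cv[["C2_plus"]])
    expect_true(cv[["C8_minus"]] <= cv[["C8_plus"]])
  }
})

test_that("exactly six per-interval matrix forms are admissible", {
  mats <- admissible_main_matrices()
  expect_length(mats, 6L)
  key <- vapply(mats, function(m) paste(m, collapse = ""), "")
  # the six images, written column-major (xA, xB, yA, yB)
  listed <- c(M1 = "1111", M2 = "1011", M3 = "0111",
              M4 = "1010", M5 = "0101", M6 = "0000")
  expect_setequal(key, unname(listed))
  # [[1,1],[0,1]] admissible; [[0,1],[0,0]] not
  expect_true("1011" %in% key)
  expect_false("0100" %in% key)
})

test_that("interval conditions decide the published examples exclusively", {
  # both direct drives over threshold: instantaneous joint turn-on
  p1 <- model_params(a = 2, b = 2.8, c = 5.5, d = 5, theta = 0.5, PR = 6)
  expect_identical(interval_condition(p1, 0.1, 0.05, 0.1, 0.05, "A"), "M1")
  # weak coupling cannot lift the cross unit: M4, not C1
  p2 <- model_params(a = 0.4, b = 3, c = 3, d = 1.8, theta = 0.5, PR = 5,
                     TD = 0.005, D = 0.015, tau_i = 0.4)
  expect_identical(interval_condition(p2, 0.64, 0.63, 0.64, 0.63, "A"), "M4")
  # cross unit crosses threshold inside the interval while the on unit
  # stays below even with excitation: C3
  p3 <- model_params(a = 0.1, b = 3, c = 2, d = 2, theta = 0.5, PR = 6)
  expect_identical(interval_condition(p3, 0.51, 0.49, 0.62, 0.6, "A"), "C3")
  expect_error(interval_condition(p3, 0.3, 0.5, 0.3, 0.5, "A"), "s_under")
})

test_that("long-delay classification matches the published points", {
  pAS <- model_params(a = 0.4, b = 3, c = 3, d = 1.8, tau_i = 0.4,
                      D = 0.015, theta = 0.5, TD = 0.005, TR = 0.2)
  expect_identical(as.character(short_main_state(pAS)), "AS")
  # I coexists with SB near the published coexistence region
  pcx <- model_params(a = 0.4, b = 3, c = 1.9, d = 1.7, tau_i = 0.4,
                      D = 0.015, theta = 0.5, TD = 0.005, TR = 0.2)
  expect_setequal(as.character(short_main_state(pcx)), c("I", "SB"))
  expect_error(short_main_state(preset_params("fig10", PR = 10, df = 0.5)),
               "D > TD")
})

test_that("short-delay classification matches the published points", {
  expect_identical(as.character(bio_state(
    preset_params("fig10", PR = 10, df = 0.001))), "I")
  expect_identical(as.character(bio_state(
    preset_params("fig10", PR = 10, df = 0.9))), "AP")
  # P >= theta with a delayed cross onset gives ID
  pID <- preset_params("fig10", PR = 10, df = 0.1)
  cv <- condition_values(pID)
  expect_gte(cv[["P"]], pID$theta)
  expect_lt(cv[["C7_minus"]], pID$theta)
  expect_identical(as.character(bio_state(pID)), "ID")
  expect_error(bio_state(model_params(a = 0.4, b = 3, c = 3, d = 1.8,
                                      tau_i = 0.4, D = 0.015, theta = 0.5,
                                      TD = 0.005, TR = 0.2)), "D <= TD")
})

test_that("percepts attach to states as in the streaming interpretation", {
  expect_identical(percept_of_state("AP"), "SEG")
  expect_identical(percept_of_state("AScI"), "INT")
  expect_identical(percept_of_state("APcAS"), "BIS")
  for (nm in c("I", "ID", "IS", "IDS", "IB"))
    expect_identical(percept_of_state(nm), "INT")
  for (nm in c("S", "SB", "SD")) expect_identical(percept_of_state(nm), "SEG")
  for (nm in c("AS", "ASD")) expect_identical(percept_of_state(nm), "BIS")
  expect_error(percept_of_state("XYZ"), "unknown")
})

test_that("conjugation is an involution with the expected fixed points", {
  mats <- twotone:::short_main_matrices()
  for (nm in names(mats)) {
    expect_identical(conjugate_state(conjugate_state(mats[[nm]])),
                     mats[[nm]])
    # name-level conjugation maps each state family to itself
    expect_identical(conjugate_state(nm)$name, nm)
  }
  # matrix-level symmetric cycles
  for (nm in c("AP", "ID", "IB"))
    expect_true(conjugate_state(nm)$symmetric)
  for (nm in c("S", "SB", "SD", "AS", "ASD", "I"))
    expect_false(conjugate_state(nm)$symmetric)
  # the anti-phase exchange: swapping rows and intervals of AS activates
  # the other unit at both tones
  conjAS <- conjugate_state(mats$AS)
  expect_identical(unname(conjAS),
                   rbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 1L, 1L)))
})

test_that("2x4 closure enumeration yields the nine states plus conjugates", {
  forms <- enumerate_2x4_forms()
  key <- function(m) paste(m[1, ], m[2, ], sep = "", collapse = "")
  mats <- twotone:::short_main_matrices()
  expected <- unique(c(vapply(mats, key, ""),
                       vapply(lapply(mats, conjugate_state), key, "")))
  expect_setequal(vapply(forms, key, ""), expected)
  expect_length(forms, 15L)
})

test_that("boundary curves reproduce the closed-form values at PR = 10", {
  p <- preset_params("fig10", PR = 10, df = 0.5)
  bp <- boundaries(p, PR = 10, variant = "printed")
  expect_equal(bp$df_coh, 0.3636, tolerance = 2e-3)
  expect_equal(bp$df_fiss, 0.6433, tolerance = 2e-3)
  # ordering over the documented rate range
  grid <- boundaries(p, PR = seq(1, 40, length.out = 96),
                     variant = "printed")
  ok <- !is.na(grid$df_coh) & !is.na(grid$df_fiss)
  expect_true(all(grid$df_fiss[ok] >= grid$df_coh[ok]))
  # the derived variant brackets the bistable band the other way around
  gd <- boundaries(p, PR = seq(1, 40, length.out = 96), variant = "derived")
  okd <- !is.na(gd$df_coh) & !is.na(gd$df_fiss)
  expect_true(all(gd$df_coh[okd] >= gd$df_fiss[okd]))
  # no rate dependence without inhibition
  p0 <- model_params(a = 1, b = 0, c = 5, d = 1, tau_i = 0.2, D = 0.01,
                     theta = 0.5, TD = 0.03, PR = 10)
  b0 <- boundaries(p0, PR = c(2, 10, 30), variant = "printed")
  expect_identical(length(unique(b0$df_coh)), 1L)
  expect_identical(length(unique(b0$df_fiss)), 1L)
})

test_that("percept regions are ordered in df at fixed rate", {
  p <- preset_params("fig10", PR = 10, df = 0.5)
  dfs <- seq(0.01, 0.99, length.out = 99)
  states <- vapply(dfs, function(dfv)
    as.character(bio_state(preset_params("fig10", PR = 10, df = dfv))), "")
  percepts <- vapply(states, percept_of_state, "")
  runs <- rle(unname(percepts))$values
  expect_identical(runs, c("INT", "BIS", "SEG"))
})

test_that("classify_point bundles regime, state and percept", {
  cp <- classify_point(preset_params("fig10", PR = 10, df = 0.9))
  expect_identical(cp$state, "AP")
  expect_identical(cp$percept, "SEG")
  expect_true(cp$regime[["bio"]])
  expect_true(all(c("N_minus", "R_plus") %in% names(cp$landmarks)))
  expect_true(all(c("C1", "C10", "P") %in% names(cp$conditions)))
})
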
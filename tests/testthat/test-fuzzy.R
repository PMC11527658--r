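test_that("trapezoidal memberships: plateau, support, edges", {
  p <- c(2, 5, 9, 13)
  expect_equal(trapmf(c(5, 7, 9), p), c(1, 1, 1))      # plateau
  expect_equal(trapmf(c(0, 2, 13, 20), p), c(0, 0, 0, 0)) # outside support
  expect_equal(trapmf(3.5, p), 0.5)                     # rising-edge midpoint
  expect_equal(trapmf(11, p), 0.5)                      # falling-edge midpoint
  # crisp edge with coincident breakpoints
  expect_equal(trapmf(c(0, 1, 2), c(1, 1, 3, 3)), c(0, 1, 1))
  expect_error(trapmf(1, c(3, 2, 1, 0)))
})

test_that("fuzzify returns memberships in [0,1] for all categories", {
  mfs <- membership_defaults()
  x <- seq(0, 60, by = 0.5)
  for (v in c("eps_min", "eps_max", "eps_dist")) {
    memb <- fuzzify(x, v, mfs)
    expect_true(all(memb >= 0 & memb <= 1))
    expect_identical(colnames(memb), c("Low", "Med", "High"))
  }
  memb <- fuzzify(seq(0, 1, by = 0.01), "bone", mfs)
  expect_true(all(memb >= 0 & memb <= 1))
  expect_error(fuzzify(1, "unknown_var", mfs), "unknown")
})

test_that("rule activation is min over clauses, max within a clause", {
  rule <- list(name = "toy",
               clauses = list(bone = "Low", eps_min = c("Med", "High"),
                              eps_dist = "Low"),
               d_bone = 1, d_cart = 0, delayed = FALSE)
  mk <- function(l, m, h) matrix(c(l, m, h), 1, 3,
                                 dimnames = list(NULL, c("Low", "Med", "High")))
  fz <- list(bone = mk(0.8, 0, 0), eps_min = mk(0, 0.3, 0.1),
             eps_dist = mk(0.6, 0, 0))
  expect_equal(rule_activation(rule, fz), 0.3)
  # annihilator and identity
  fz$bone <- mk(0, 1, 1)
  expect_equal(rule_activation(rule, fz), 0)
  fz <- list(bone = mk(1, 0, 0), eps_min = mk(0, 1, 0), eps_dist = mk(1, 0, 0))
  expect_equal(rule_activation(rule, fz), 1)
})

test_that("vectorised activations equal the scalar brute-force oracle", {
  mfs <- membership_defaults()
  rules <- rule_table_default()
  set.seed(42)
  n <- 100
  inputs <- list(
    eps_min = runif(n, 0, 40), eps_max = runif(n, 0, 25),
    eps_dist = runif(n, 0, 50), bone = runif(n), cart = runif(n),
    nbone = runif(n), ncart = runif(n)
  )
  vars <- unique(unlist(lapply(rules, function(r) names(r$clauses))))
  fz <- lapply(setNames(vars, vars), function(v) fuzzify(inputs[[v]], v, mfs))
  for (r in rules) {
    got <- rule_activation(r, fz)
    want <- vapply(seq_len(n), function(i) {
      oracle_activation(r, lapply(inputs, `[`, i), mfs)
    }, 0)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the default rule table encodes the four processes", {
  rules <- rule_table_default()
  expect_length(rules, 5) # chondrogenesis has two antecedent variants
  nm <- vapply(rules, `[[`, "", "name")
  expect_setequal(unique(sub("_(nbone|ncart)$", "", nm)),
                  c("intramembranous_ossification", "chondrogenesis",
                    "cartilage_calcification", "endochondral_ossification"))
  # bone never decreases under any default rule
  expect_true(all(vapply(rules, `[[`, 0, "d_bone") >= 0))
  # only chondrogenesis is gated
  expect_identical(vapply(rules, `[[`, NA, "delayed"), grepl("chondro", nm))
})

test_that("mixture laws return the tissue constants at simplex vertices", {
  p <- mixture_properties(1, 0, 0)
  expect_equal(p$E, 3); expect_equal(p$nu, 0.30)
  p <- mixture_properties(0, 1, 0)
  expect_equal(p$E, 200); expect_equal(p$nu, 0.45)
  p <- mixture_properties(0, 0, 1)
  expect_equal(p$E, 4000); expect_equal(p$nu, 0.36)
  # half soft / half woven bone
  p <- mixture_properties(0.5, 0, 0.5)
  expect_equal(p$E, 4000 * 0.125 + 3 * 0.125)
  expect_equal(p$nu, 0.33)
  expect_error(mixture_properties(0.5, 0.2, 0.5), "simplex")
})

test_that("temporal smoothing is the arithmetic mean of the buffer", {
  expect_equal(temporal_smooth(matrix(c(0, 0.1, 0.2), 3, 1)), 0.1)
  expect_equal(temporal_smooth(matrix(0.4, 5, 2)), c(0.4, 0.4))
  expect_equal(temporal_smooth(matrix(c(0.7, 0.3), 1, 2)), c(0.7, 0.3))
  expect_error(temporal_smooth(matrix(0, 0, 3)), "empty")
})

test_that("compose_update: fixed points, gating and consequent symmetry", {
  mfs <- membership_defaults()
  rules <- rule_table_default()
  # all-soft element at zero strain is a fixed point
  inputs <- list(eps_min = 0, eps_max = 0, eps_dist = 0,
                 bone = 0, cart = 0, nbone = 1, ncart = 0)
  upd <- compose_update(inputs, c_bone = 0, c_cart = 0, rules = rules,
                        kappa = 0.5, char_length = 0.35, iteration = 1,
                        mfs = mfs)
  expect_equal(upd$c_bone, 0); expect_equal(upd$c_cart, 0)
  expect_equal(upd$c_soft, 1)
  # chondrogenesis antecedents satisfied but gated off early
  chon <- list(eps_min = 10, eps_max = 0, eps_dist = 0,
               bone = 0, cart = 0, nbone = 1, ncart = 0)
  for (it in c(1, 7)) {
    upd <- compose_update(chon, 0, 0, rules = rules, kappa = 0.5,
                          char_length = 0.35, iteration = it, mfs = mfs)
    expect_equal(upd$c_cart, 0)
  }
  upd <- compose_update(chon, 0, 0, rules = rules, kappa = 0.5,
                        char_length = 0.35, iteration = 8, mfs = mfs)
  expect_gt(upd$c_cart, 0)
  # endochondral ossification moves bone and cartilage by equal magnitudes
  eo <- list(eps_min = 0, eps_max = 0, eps_dist = 0,
             bone = 0, cart = 1, nbone = 1, ncart = 0)
  upd <- compose_update(eo, c_bone = 0, c_cart = 0.8,
                        rules = rules["endochondral_ossification" ==
                                        vapply(rules, `[[`, "", "name")],
                        kappa = 0.1, char_length = 0.35, iteration = 10,
                        mfs = mfs)
  expect_equal(upd$c_bone - 0, 0.8 - upd$c_cart, tolerance = 1e-12)
  expect_error(compose_update(eo, c_bone = 0.9, c_cart = 0.9, rules = rules,
                              kappa = 0.1, char_length = 0.35, iteration = 1),
               "simplex")
})

test_that("element-size scaling is inversely proportional to element length", {
  mfs <- membership_defaults()
  rules <- rule_table_default()
  im <- list(eps_min = 0, eps_max = 10, eps_dist = 0,
             bone = 0, cart = 0, nbone = 1, ncart = 0)
  u1 <- compose_update(im, 0, 0, rules = rules, kappa = 0.1,
                       char_length = 0.35, iteration = 1, mfs = mfs)
  u2 <- compose_update(im, 0, 0, rules = rules, kappa = 0.1,
                       char_length = 0.70, iteration = 1, mfs = mfs)
  expect_equal(u1$c_bone, 2 * u2$c_bone, tolerance = 1e-12)
})

test_that("updates stay on the unit simplex under random stress", {
  mfs <- membership_defaults()
  rules <- rule_table_default()
  set.seed(7)
  n <- 300
  cb <- runif(n); cc <- runif(n) * (1 - cb)
  inputs <- list(eps_min = runif(n, 0, 40), eps_max = runif(n, 0, 25),
                 eps_dist = runif(n, 0, 50), bone = cb, cart = cc,
                 nbone = runif(n), ncart = runif(n))
  upd <- compose_update(inputs, cb, cc, rules = rules, kappa = 2,
                        char_length = rep(0.35, n), iteration = 20, mfs = mfs)
  expect_true(all(upd$c_bone >= -1e-12 & upd$c_bone <= 1 + 1e-12))
  expect_true(all(upd$c_cart >= -1e-12 & upd$c_cart <= 1 + 1e-12))
  expect_true(all(abs(upd$c_soft + upd$c_bone + upd$c_cart - 1) < 1e-12))
  expect_true(all(upd$c_soft >= -1e-12))
  # bone is non-decreasing element-wise
  expect_true(all(upd$c_bone >= cb - 1e-12))
})
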
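test_that("species fractions follow the binding polynomial in the limiting cases", {
  # all seven partition-function terms equal -> equal fractions
  f <- species_distribution(unit_ratio_k(), unit_ratio_mix())
  expect_equal(unname(f), rep(1 / 7, 7), tolerance = 1e-12)
  expect_equal(sum(f), 1, tolerance = 1e-12)

  # empty-ligand mixture: everything is free enzyme
  f0 <- species_distribution(paper_k(), mix_state(D = 0, M = 0, d = 0, m = 0))
  expect_equal(unname(f0["E"]), 1)
  expect_equal(sum(f0[-1]), 0)

  # mutually exclusive limit removes Edm, leaving six equal terms
  fe <- species_distribution(unit_ratio_k(K_mp = Inf), unit_ratio_mix())
  expect_equal(unname(fe["Edm"]), 0)
  expect_equal(unname(fe[setdiff(names(fe), "Edm")]), rep(1 / 6, 6),
               tolerance = 1e-12)
})

test_that("species fractions are a simplex on random inputs", {
  set.seed(101)
  for (i in 1:50) {
    cs <- random_case()
    f <- species_distribution(cs$k, cs$mix)
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("constructors reject invalid inputs naming the field", {
  expect_error(kinetic_constants(K_D = -1, K_M = 5, K_d = 86, K_m = 8,
                                 k_cat = 80, E_T = 300), "K_D")
  expect_error(kinetic_constants(K_D = 10, K_M = Inf, K_d = 86, K_m = 8,
                                 k_cat = 80, E_T = 300), "K_M")
  expect_error(mix_state(D = -5), "'D'")
  expect_error(mix_state(m = NA), "'m'")
})

test_that("reaction rate matches the uninhibited assay prediction and its limits", {
  # k_cat = 80/min, E_T = 0.3 uM, D/K_D = 12, M/K_M = 11 -> 80*0.3*132/145
  v <- reaction_rate(paper_k(), mix_state(D = 120, M = 55))
  expect_equal(v, 80 * 0.3 * 132 / 145, tolerance = 1e-12)

  # saturating substrate and cofactor -> k_cat * E_T
  v_sat <- reaction_rate(paper_k(), mix_state(D = 1e7, M = 1e7))
  expect_equal(v_sat, 80 * 0.3, tolerance = 1e-4)

  # overwhelming nucleotide-site inhibitor sequesters the enzyme
  v_kill <- reaction_rate(paper_k(), mix_state(d = 1e12))
  expect_lt(v_kill, 1e-4)
})

test_that("reaction rate is non-increasing in each inhibitor", {
  set.seed(202)
  for (i in 1:20) {
    cs <- random_case()
    doses <- sort(stats::runif(6, 0, 5000))
    v_d <- vapply(doses, function(x) reaction_rate(
      cs$k, mix_state(D = cs$mix$D / 1000, M = cs$mix$M / 1000, d = x,
                      m = cs$mix$m)), numeric(1))
    v_m <- vapply(doses, function(x) reaction_rate(
      cs$k, mix_state(D = cs$mix$D / 1000, M = cs$mix$M / 1000,
                      d = cs$mix$d, m = x)), numeric(1))
    expect_true(all(diff(v_d) <= 1e-12))
    expect_true(all(diff(v_m) <= 1e-12))
  }
})

test_that("synergism quotient reproduces the hand-enumerated unit-ratio values", {
  # Z enumeration: v_ni = 1/3, v_d = 1/5, v_m = 1/4, v_dm = 1/7 (simultaneous)
  expect_equal(synergism_quotient(unit_ratio_k(), unit_ratio_mix()),
               240 / 273, tolerance = 1e-12)
  # exclusive: v_dm = 1/6 -> sq = 10/13
  expect_equal(synergism_quotient(unit_ratio_k(K_mp = Inf), unit_ratio_mix()),
               10 / 13, tolerance = 1e-12)
})

test_that("synergism quotient rejects missing inhibitors and empty denominators", {
  expect_error(synergism_quotient(paper_k(), mix_state(d = 0, m = 100)),
               "d > 0")
  expect_error(synergism_quotient(paper_k(), mix_state(d = 100, m = 0)),
               "m > 0")
  # inhibitors so weak that neither single agent inhibits measurably
  weak <- kinetic_constants(K_D = 10, K_M = 5, K_d = 1e15, K_m = 1e15,
                            k_cat = 80, E_T = 300)
  expect_error(synergism_quotient(weak, mix_state(d = 1, m = 1)),
               "undefined")
})

test_that("exclusive binding is always antagonistic, simultaneous at least as synergistic", {
  tab <- sq_scan(dKd = c(0.1, 1, 10), mKm = c(0.1, 1, 10),
                 MKM = c(0.1, 1, 10), DKD = c(1, 10))
  excl <- tab[tab$mode == "exclusive", ]
  simu <- tab[tab$mode == "simultaneous", ]
  expect_true(all(excl$sq < 1))
  key <- function(d) paste(d$dKd, d$mKm, d$DKD, d$MKM)
  simu <- simu[match(key(excl), key(simu)), ]
  expect_true(all(simu$sq >= excl$sq - 1e-12))
  # the all-ones cell reproduces the enumerated quotient
  ones <- simu$sq[simu$dKd == 1 & simu$mKm == 1 & simu$MKM == 1 &
                    simu$DKD == 1]
  expect_equal(ones, 240 / 273, tolerance = 1e-12)
})

test_that("weaker cofactor binding to the inhibited enzyme favors synergism", {
  base <- sq_scan(dKd = 1, mKm = 1, MKM = 1, DKD = 1, KMp_mult = 1,
                  Kmp_mult = 1, modes = "simultaneous")$sq
  tilted <- sq_scan(dKd = 1, mKm = 1, MKM = 1, DKD = 1, KMp_mult = 10,
                    Kmp_mult = 0.1, modes = "simultaneous")$sq
  expect_gt(tilted, base)
})

test_that("sq property holds on random parameter sets", {
  set.seed(303)
  for (i in 1:40) {
    r <- stats::runif(4, 0.05, 20)
    excl <- sq_scan(dKd = r[1], mKm = r[2], MKM = r[3], DKD = r[4],
                    modes = "exclusive")$sq
    simu <- sq_scan(dKd = r[1], mKm = r[2], MKM = r[3], DKD = r[4],
                    modes = "simultaneous")$sq
    expect_lt(excl, 1)
    expect_gte(simu, excl - 1e-12)
  }
})

test_that("sq_scan validates its grids", {
  expect_error(sq_scan(dKd = numeric(0)), "empty grid")
  expect_error(sq_scan(dKd = c(1, -2)), "positive")
})

test_that("oracle without depletion matches the closed form to 1e-9", {
  set.seed(404)
  for (i in 1:200) {
    cs <- random_case()
    o <- equilibrium_oracle(cs$k, cs$mix, with_depletion = FALSE)
    f <- species_distribution(cs$k, cs$mix)
    expect_equal(o$species / cs$k$E_T, f, tolerance = 1e-9)
    expect_equal(o$rate, reaction_rate(cs$k, cs$mix), tolerance = 1e-9)
  }
})

test_that("depletion oracle closes mass balances and bounds free by total", {
  set.seed(505)
  for (i in 1:20) {
    cs <- random_case()
    o <- equilibrium_oracle(cs$k, cs$mix, with_depletion = TRUE)
    totals <- c(D = cs$mix$D, M = cs$mix$M, d = cs$mix$d, m = cs$mix$m)
    expect_true(all(o$free <= totals + 1e-9))
    bound <- c(D = o$species[["ED"]] + o$species[["EDM"]] + o$species[["EDm"]],
               M = o$species[["EDM"]] + o$species[["EdM"]],
               d = o$species[["Ed"]] + o$species[["EdM"]] + o$species[["Edm"]],
               m = o$species[["EDm"]] + o$species[["Edm"]])
    expect_equal(unname(o$free + bound), unname(totals),
                 tolerance = 1e-6)
    expect_equal(sum(o$species), cs$k$E_T, tolerance = 1e-6)
  }
})

test_that("depletion vanishes as enzyme concentration goes to zero", {
  k_tiny <- hts_constants(E_T = 1e-9)
  mx <- mix_state(d = 300, m = 120)
  o <- equilibrium_oracle(k_tiny, mx, with_depletion = TRUE, tol = 1e-12)
  expect_equal(unname(o$free[c("d", "m")]), c(300, 120), tolerance = 1e-9)
  expect_equal(o$rate, reaction_rate(k_tiny, mx), tolerance = 1e-6)
})

test_that("depleted bound fraction agrees with the Morrison expression", {
  # single folate-site inhibitor: the enzyme pool binds it with
  # K_app = K_m * Z0 / (D/K_D); fractional EDM activity must equal the
  # Morrison quadratic at that K_app
  k <- paper_k()
  mx <- mix_state(d = 0, m = 300)
  o <- equilibrium_oracle(k, mx, with_depletion = TRUE)
  v0 <- equilibrium_oracle(k, mix_state(), with_depletion = TRUE)$rate
  K_app <- 8 * (1 / 12 + 1 + 11)
  expect_equal(o$rate / v0, morrison_activity(300, 300, K_app),
               tolerance = 1e-2)
  expect_lt(o$free[["m"]], 300)
})
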
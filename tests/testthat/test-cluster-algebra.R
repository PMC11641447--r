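# Operator-algebra checks against the closed-form expansions (constant q0)
# and the step-dependent ladder.

test_that("second-order pure-A expansion has the three symbolic branches", {
  for (q0 in c(0.6, 0.87)) {
    q1 <- (1 - q0) / 2
    s <- resolve_composition(symbolic_model(q0), c(2, 0, 0, 0))
    expect_equal(state_prob(s, ssb_s = 2), q0, tolerance = 1e-12)
    expect_equal(state_prob(s, dsb_s = 1), q1, tolerance = 1e-12)
    expect_equal(state_prob(s, ssb_plus = 1), q1, tolerance = 1e-12)
    expect_equal(sum(s$prob), 1, tolerance = 1e-12)
  }
  # with the printed ladder the second break uses q0(2) = 0.87
  s <- resolve_composition(default_model(), c(2, 0, 0, 0))
  expect_equal(state_prob(s, ssb_s = 2), 0.87, tolerance = 1e-12)
})

test_that("A-operator acts on composite operands as tabulated", {
  g <- symbolic_geom(0.6)
  q0 <- 0.6; q1 <- 0.2
  # operand: one simple DSB -> q0 {DSB + new SSB} + 2q1 {DSB+}
  dsb <- tibble::tibble(ssb_s = 0, ssb_plus = 0, ssb_pp = 0, ssb_ppp = 0,
                        dsb_s = 1, dsb_plus = 0, dsb_pp = 0, bd = 0,
                        n_breaks = 2, prob = 1)
  out <- apply_a_step(dsb, g)
  expect_equal(state_prob(out, dsb_s = 1, ssb_s = 1), q0, tolerance = 1e-12)
  expect_equal(state_prob(out, dsb_plus = 1), 2 * q1, tolerance = 1e-12)

  # operand: SSB(+) x SSB(S) -> q0 carry + q1/2 on each of the four upgrades
  op <- tibble::tibble(ssb_s = 1, ssb_plus = 1, ssb_pp = 0, ssb_ppp = 0,
                       dsb_s = 0, dsb_plus = 0, dsb_pp = 0, bd = 0,
                       n_breaks = 3, prob = 1)
  out <- apply_a_step(op, g)
  expect_equal(state_prob(out, ssb_s = 2, ssb_plus = 1), q0, tolerance = 1e-12)
  expect_equal(state_prob(out, ssb_s = 1, dsb_plus = 1), q1 / 2, tolerance = 1e-12)
  expect_equal(state_prob(out, ssb_s = 1, ssb_pp = 1), q1 / 2, tolerance = 1e-12)
  expect_equal(state_prob(out, ssb_plus = 1, dsb_s = 1), q1 / 2, tolerance = 1e-12)
  expect_equal(state_prob(out, ssb_plus = 2), q1 / 2, tolerance = 1e-12)

  # empty operand with no clustering possible -> one isolated SSB, surely
  out <- apply_a_step(lesion_spectrum_empty(), cluster_geometry(q0_constant = 1))
  expect_equal(state_prob(out, ssb_s = 1), 1, tolerance = 1e-15)
})

test_that("third-order pure-A expansion has five branches with the 3:1 split", {
  q0 <- 0.6; q1 <- 0.2
  s <- resolve_composition(symbolic_model(q0), c(3, 0, 0, 0))
  expect_equal(state_prob(s, ssb_s = 3), q0^2, tolerance = 1e-12)
  expect_equal(state_prob(s, dsb_s = 1, ssb_s = 1), 2 * q0 * q1, tolerance = 1e-12)
  expect_equal(state_prob(s, ssb_plus = 1, ssb_s = 1), 2 * q0 * q1, tolerance = 1e-12)
  expect_equal(state_prob(s, dsb_plus = 1), 3 * q1^2, tolerance = 1e-12)
  expect_equal(state_prob(s, ssb_pp = 1), q1^2, tolerance = 1e-12)
  expect_equal(state_prob(s, dsb_plus = 1) / state_prob(s, ssb_pp = 1), 3,
               tolerance = 1e-12)
})

test_that("fourth-order pure-A expansion reproduces every binomial tier", {
  q0 <- 0.6; q1 <- 0.2
  s <- resolve_composition(symbolic_model(q0), c(4, 0, 0, 0))
  expect_equal(state_prob(s, ssb_s = 4), q0^3, tolerance = 1e-12)
  expect_equal(state_prob(s, dsb_s = 1, ssb_s = 2), 3 * q0^2 * q1, tolerance = 1e-12)
  expect_equal(state_prob(s, ssb_plus = 1, ssb_s = 2), 3 * q0^2 * q1, tolerance = 1e-12)
  expect_equal(state_prob(s, dsb_plus = 1, ssb_s = 1), 6 * q0 * q1^2, tolerance = 1e-12)
  expect_equal(state_prob(s, ssb_pp = 1, ssb_s = 1), 2 * q0 * q1^2, tolerance = 1e-12)
  expect_equal(state_prob(s, dsb_s = 1, ssb_plus = 1), 2 * q0 * q1^2, tolerance = 1e-12)
  expect_equal(state_prob(s, dsb_s = 2), q0 * q1^2, tolerance = 1e-12)
  expect_equal(state_prob(s, ssb_plus = 2), q0 * q1^2, tolerance = 1e-12)
  # the q1^3 tier splits 7:1 between DSB(++) and SSB(+++)
  expect_equal(state_prob_raw(s, dsb_pp = 1), 7 * q1^3, tolerance = 1e-12)
  expect_equal(state_prob_raw(s, ssb_ppp = 1), q1^3, tolerance = 1e-12)
})

test_that("B-operator produces the tabulated first- and second-order branches", {
  r1 <- 0.13; r2 <- 0.52; r3 <- 0.35
  m <- symbolic_model(0.6)
  s1 <- resolve_composition(m, c(0, 1, 0, 0))
  expect_equal(state_prob(s1, ssb_s = 1), r1, tolerance = 1e-12)
  expect_equal(state_prob(s1, bd = 1), r2, tolerance = 1e-12)
  expect_equal(state_prob(s1), r3, tolerance = 1e-12)

  s2 <- resolve_composition(m, c(0, 2, 0, 0))
  q0 <- 0.6; q1 <- 0.2
  expect_equal(state_prob(s2, ssb_s = 2), r1^2 * q0, tolerance = 1e-12)
  expect_equal(state_prob(s2, dsb_s = 1), r1^2 * q1, tolerance = 1e-12)
  expect_equal(state_prob(s2, ssb_plus = 1), r1^2 * q1, tolerance = 1e-12)
  expect_equal(state_prob(s2, ssb_s = 1, bd = 1), 2 * r1 * r2, tolerance = 1e-12)
  expect_equal(state_prob(s2, bd = 2), r2^2, tolerance = 1e-12)
  # inert tier carries the multinomial factor 2
  expect_equal(state_prob(s2, ssb_s = 1), 2 * r1 * r3, tolerance = 1e-12)
  expect_equal(state_prob(s2, bd = 1), 2 * r2 * r3, tolerance = 1e-12)
  expect_equal(state_prob(s2), r3^2, tolerance = 1e-12)

  # degenerate fates: no strand breaks ever when r1 = 0
  m0 <- damage_model(fates = radical_fates(0, 0.52), geometry = symbolic_geom())
  s <- resolve_composition(m0, c(0, 4, 0, 0))
  tb <- fold_lesion_spectrum(s)
  expect_true(all(tb$ssb_s + tb$ssb_plus + tb$ssb_pp +
                    tb$dsb_s + tb$dsb_plus + tb$dsb_pp == 0))
})

test_that("C events add base damage and D events are inert", {
  m <- default_model()
  for (jd in c(1, 4, 9)) {
    s <- resolve_composition(m, c(0, 0, 0, jd))
    expect_identical(nrow(s), 1L)
    expect_equal(s$prob, 1)
    expect_equal(s$bd, 0)
  }
  s <- resolve_composition(m, c(0, 0, 3, 0))
  expect_equal(s$bd, 3)
  s2 <- apply_c_step(apply_c_step(lesion_spectrum_empty()))
  expect_equal(s2$bd, 2)
})

test_that("every resolved spectrum is normalized in both modes", {
  for (mode in c("exact", "paper_approx")) {
    m <- damage_model(mode = mode)
    for (j in list(c(3, 0, 0, 0), c(2, 2, 0, 0), c(1, 3, 1, 0),
                   c(0, 5, 0, 0), c(5, 2, 1, 2), c(8, 0, 0, 0))) {
      s <- resolve_composition(m, j)
      expect_equal(sum(s$prob), 1, tolerance = 1e-10)
      expect_true(all(s$prob >= 0))
    }
  }
})

test_that("heterogeneous operator order does not change the result", {
  g <- cluster_geometry()
  f <- radical_fates()
  ab <- lesion_spectrum_empty() |>
    apply_a_step(g) |>
    apply_b_step(g, f)
  ba <- lesion_spectrum_empty() |>
    apply_b_step(g, f) |>
    apply_a_step(g)
  ab <- dplyr::arrange(fold_lesion_spectrum(ab), dplyr::across(dplyr::everything()))
  ba <- dplyr::arrange(fold_lesion_spectrum(ba), dplyr::across(dplyr::everything()))
  expect_equal(as.data.frame(ab), as.data.frame(ba), tolerance = 1e-12)
})

test_that("first-order marginals match the event-type bookkeeping", {
  m <- default_model()
  t1 <- damage_probabilities(m, 1)
  expect_equal(t1$p_ssb_s, 0.2 + 0.2 * 0.13, tolerance = 1e-12)
  expect_equal(t1$p_bd_1, 0.2 + 0.2 * 0.52, tolerance = 1e-12)
  t0 <- damage_probabilities(m, 0)
  drop <- c("j_tot", "frac_complex_ssb", "frac_complex_dsb",
            "dsb_to_ssb", "bd_to_ssb")
  expect_true(all(unlist(t0[, setdiff(names(t0), drop)]) == 0))
})

test_that("factorized probability table agrees with direct composition sums", {
  for (mode in c("exact", "paper_approx")) {
    m <- damage_model(mode = mode)
    for (j in c(2, 4, 5)) {
      comps <- enumerate_compositions(j, m$events)
      acc <- 0
      for (i in seq_len(nrow(comps))) {
        sp <- resolve_composition(m, as.numeric(comps[i, 1:4]))
        acc <- acc + comps$weight[i] * spectrum_marginals(sp)
      }
      row <- damage_probability_table(m, j)
      expect_equal(unname(acc[names(acc)]),
                   unname(unlist(row[1, names(acc)])), tolerance = 1e-10)
    }
  }
})

test_that("high-order truncations stay within 1% of exact at low order", {
  me <- damage_model(mode = "exact")
  ma <- damage_model(mode = "paper_approx")
  for (j in 0:4) {
    comps <- enumerate_compositions(j)
    for (i in seq_len(nrow(comps))) {
      se <- fold_lesion_spectrum(resolve_composition(me, as.numeric(comps[i, 1:4])))
      sa <- fold_lesion_spectrum(resolve_composition(ma, as.numeric(comps[i, 1:4])))
      j2 <- dplyr::full_join(se, sa,
                             by = c("ssb_s", "ssb_plus", "ssb_pp", "dsb_s",
                                    "dsb_plus", "dsb_pp", "bd"))
      j2[is.na(j2)] <- 0
      tv <- sum(abs(j2$prob.x - j2$prob.y)) / 2
      expect_lt(tv, 0.01)
    }
  }
})

test_that("complex-DSB fraction grows with event number", {
  tab <- damage_probability_table(default_model(), 2:15)
  expect_true(all(diff(tab$frac_complex_dsb) >= -1e-12))
})

test_that("co-location estimator collapses when no base damage is possible", {
  m <- damage_model(events = event_probabilities(0.3, 0.3, 0, 0.4),
                    fates = radical_fates(0.13, 0))
  co <- dsb_bd_colocation(m, c(2, 5))
  expect_equal(co$p_dsb, co$p_dsb_r2_zero, tolerance = 1e-12)
  expect_equal(co$p_dsb, co$p_dsb_no_bd, tolerance = 1e-12)
})

test_that("break-conditional classes collapse to complex DSBs as q0 vanishes", {
  vb <- damage_vs_breaks(default_model(), n_breaks = c(2, 8, 10))
  # at 8+ breaks the ladder is exhausted: everything is one complex DSB
  expect_gt(vb$p_dsb_pp[vb$n_breaks == 8], 0.99)
  expect_equal(vb$p_ssb_s[vb$n_breaks == 8], 0)
  # per-step indexing keeps early breaks under the looser early ladder
  vs <- damage_vs_breaks(default_model(), n_breaks = 8,
                         q0_indexing = "per_step")
  expect_lt(vs$p_dsb_pp, vb$p_dsb_pp[vb$n_breaks == 8])
})
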
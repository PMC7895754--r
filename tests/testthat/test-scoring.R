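two_marker_panel <- function()
  marker_panel(m1 = data.frame(species = c("A", "B"),
                               readout = c("level", "level"),
                               stringsAsFactors = FALSE),
               m2 = data.frame(species = c("C", "D"),
                               readout = c("level", "level"),
                               stringsAsFactors = FALSE))

test_that("fold_change is 1 at t = 0 and scales with the value", {
  sim <- fake_sim(0:4, list(A = c(2, 2, 4, 6, 2)))
  expect_equal(fold_change(sim, "A", t = 0), 1)
  expect_equal(fold_change(sim, "A", t = 2), 2)
  expect_equal(fold_change(sim, "A"), c(1, 1, 2, 3, 1))
  flat <- fake_sim(0:3, list(A = rep(5, 4)))
  expect_equal(fold_change(flat, "A"), rep(1, 4))
})

test_that("m_scores are geometric means with ratio semantics", {
  t <- 0:2
  sim <- fake_sim(t, list(A = c(1, 4, 4), B = c(1, 4, 4),
                          C = c(1, 1, 2), D = c(1, 1, 2)))
  sc <- m_scores(sim, two_marker_panel())
  expect_equal(sc$m1_score, c(1, 4, 4))
  expect_equal(sc$m2_score, c(1, 1, 2))
  expect_equal(sc$m1m2_score, c(1, 4, 2))
  expect_equal(log10(sc$m1m2_score[2]), 0.602, tolerance = 1e-3)

  # hand-computed mixed case: gm(2, 8) = 4
  sim2 <- fake_sim(0:1, list(A = c(1, 2), B = c(1, 8),
                             C = c(1, 1), D = c(1, 1)))
  expect_equal(m_scores(sim2, two_marker_panel())$m1_score[2], 4)
})

test_that("swapping the panels inverts the score exactly", {
  sim <- fake_sim(0:3, list(A = c(1, 2, 5, 3), B = c(1, 7, 2, 9),
                            C = c(1, 3, 3, 1), D = c(1, 2, 8, 4)))
  p <- two_marker_panel()
  swapped <- marker_panel(m1 = p$m2, m2 = p$m1)
  s1 <- m_scores(sim, p)$m1m2_score
  s2 <- m_scores(sim, swapped)$m1m2_score
  expect_equal(s1, 1 / s2)
})

test_that("scores are invariant to marker order and unit rescaling", {
  sim <- fake_sim(0:3, list(A = c(1, 2, 5, 3), B = c(1, 7, 2, 9),
                            C = c(1, 3, 3, 1), D = c(1, 2, 8, 4)))
  p <- two_marker_panel()
  reord <- marker_panel(m1 = p$m1[2:1, ], m2 = p$m2)
  expect_equal(m_scores(sim, p)$m1m2_score,
               m_scores(sim, reord)$m1m2_score)
  # rescaling one marker's units cancels in the fold change
  sim_scaled <- fake_sim(0:3, list(A = 1000 * c(1, 2, 5, 3),
                                   B = c(1, 7, 2, 9),
                                   C = c(1, 3, 3, 1), D = c(1, 2, 8, 4)))
  expect_equal(m_scores(sim_scaled, p)$m1m2_score,
               m_scores(sim, p)$m1m2_score)
})

test_that("score_integral matches closed forms and fine quadrature", {
  flat <- structure(list(time = seq(0, 24, 0.5),
                         m1m2_score = rep(1, 49)), class = "mp_scores")
  expect_equal(score_integral(flat), 0)
  const <- structure(list(time = seq(0, 24, 0.5),
                          m1m2_score = rep(10 ^ 0.3, 49)),
                     class = "mp_scores")
  expect_equal(score_integral(const), 24 * 0.3)
  # smooth trajectory: trapezoid on the working grid vs 10x-finer grid
  f <- function(t) 10 ^ (0.5 * sin(t / 5))
  coarse <- structure(list(time = seq(0, 24, 0.1),
                           m1m2_score = f(seq(0, 24, 0.1))),
                      class = "mp_scores")
  fine <- structure(list(time = seq(0, 24, 0.025),
                         m1m2_score = f(seq(0, 24, 0.025))),
                    class = "mp_scores")
  expect_equal(score_integral(coarse), score_integral(fine),
               tolerance = 1e-4)
})

test_that("classify_trajectory implements the four rule classes", {
  mk <- function(y) structure(list(time = seq(0, 48, length.out = length(y)),
                                   m1m2_score = 10 ^ y),
                              class = "mp_scores")
  expect_equal(classify_trajectory(mk(seq(0, 0.5, length.out = 20))),
               "self-promoting")
  expect_equal(classify_trajectory(mk(c(seq(0, 0.2, length.out = 10),
                                        seq(0.2, -0.2, length.out = 10)))),
               "self-repolarizing")
  expect_equal(classify_trajectory(mk(c(seq(0, 0.4, length.out = 10),
                                        seq(0.4, 0.05, length.out = 10)))),
               "self-limiting")
  expect_equal(classify_trajectory(mk(rep(0.01, 20))), "flat")
  expect_error(classify_trajectory(
    structure(list(time = 0:24, m1m2_score = rep(1, 25)),
              class = "mp_scores")), "48")
})

test_that("classify_cell applies the symmetric tau threshold", {
  expect_equal(classify_cell(0), "M0*")
  expect_equal(classify_cell(0.2, tau = 0.1), "M1-like")
  expect_equal(classify_cell(-0.2, tau = 0.1), "M2-like")
  expect_equal(classify_cell(c(-0.05, 0.05), tau = 0.1), c("M0*", "M0*"))
})

test_that("reference_conditions enumerates 7 singles and 21 pairs", {
  conds <- reference_conditions()
  expect_length(conds, 28)
  expect_length(reference_conditions(pairwise = FALSE), 7)
  expect_length(reference_conditions(include_control = TRUE), 29)
  expect_equal(sum(grepl("\\+", names(conds))), 21)
})

test_that("polarization_map is deterministic and zero for the control", {
  net <- ref_network()
  conds <- reference_conditions(duration = 48,
                                pairwise = FALSE)[c("IFNG", "IL4")]
  conds$Ctr <- stimulation_protocol(duration = 48, name = "Ctr")
  m1 <- polarization_map(net, conds, times = c(4, 24), state = ref_state())
  m2 <- polarization_map(net, conds, times = c(4, 24), state = ref_state())
  expect_identical(m1$log2fc, m2$log2fc)
  ctr <- m1[m1$condition == "Ctr", ]
  expect_lt(max(abs(ctr$log2fc)), 1e-3)
  panel <- reference_marker_panel()
  expect_equal(nrow(m1), 3 * 2 * (nrow(panel$m1) + nrow(panel$m2)))
})
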
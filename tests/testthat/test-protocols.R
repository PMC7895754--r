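test_that("dose_to_copies follows the Avogadro arithmetic oracle", {
  # independent arithmetic: dose[g/mL] / MW[g/mol] * N_A * V[mL]
  oracle <- (10 * 1e-9 / 17000) * 6.02214076e23 * 1e-6
  expect_equal(dose_to_copies(10, 17000, 1e-6), oracle)
  expect_equal(dose_to_copies(0, 17000), 0)
  # linear in dose and volume, inverse in molecular weight
  expect_equal(dose_to_copies(20, 17000), 2 * dose_to_copies(10, 17000))
  expect_equal(dose_to_copies(10, 17000, 2e-6), 2 * dose_to_copies(10, 17000))
  expect_equal(dose_to_copies(10, 34000), dose_to_copies(10, 17000) / 2)
  expect_error(dose_to_copies(1, -5), "molecular weight")
})

test_that("apply_oxygen scales PHD activity linearly in O2 percent", {
  net <- ref_network()
  expect_identical(apply_oxygen(net, 21), net)
  hyp <- apply_oxygen(net, 2)
  f <- parameter_values(hyp)[c("kf62", "kf63")] /
    parameter_values(net)[c("kf62", "kf63")]
  expect_equal(unname(f), rep(2 / 21, 2))
  expect_error(apply_oxygen(net, 0), "oxygen_percent")
  expect_error(apply_oxygen(binding_network(), 2), "oxygen_parameters")
})

test_that("hypoxia stabilizes HIF1a and HIF2a", {
  sim <- simulate_protocol(ref_network(),
                           stimulation_protocol(oxygen_percent = 2,
                                                duration = 18, name = "hyp"),
                           state = ref_state())
  expect_gt(fold_change(sim, "HIF1a", t = 18), 1)
  expect_gt(fold_change(sim, "HIF2a", t = 18), 1)
})

test_that("in_vivo_scaling multiplies the dose scale by 0.01", {
  p <- stimulation_protocol(events = dose_event(0, "L_IL4", 10),
                            duration = 48)
  expect_equal(in_vivo_scaling(p)$dose_scale, 0.01)
  expect_equal(in_vivo_scaling(in_vivo_scaling(p))$dose_scale, 1e-4)
  empty <- stimulation_protocol(duration = 48)
  expect_equal(in_vivo_scaling(empty)$events, empty$events)
})

test_that("apply_interventions is a pure parameter transformation", {
  net <- ref_network()
  out <- apply_interventions(net, intervention("k101", 10))
  expect_equal(parameter_values(out)[["k101"]],
               10 * parameter_values(net)[["k101"]])
  # the input network is untouched
  expect_equal(parameter_values(net)[["k101"]],
               parameter_values(ref_network())[["k101"]])
  expect_error(apply_interventions(net, intervention("k9999", 2)), "k9999")
  # multiplier 1 leaves simulations identical
  same <- apply_interventions(net, intervention("k101", 1))
  p <- stimulation_protocol(duration = 4)
  s1 <- simulate_protocol(net, p, state = ref_state())
  s2 <- simulate_protocol(same, p, state = ref_state())
  expect_identical(s1$states, s2$states)
})

test_that("hss_variant scales tagged synthesis fluxes", {
  net <- ref_network()
  expect_identical(hss_variant(net, 1), net)
  half <- hss_variant(net, 0.5)
  rhs_full <- build_rhs(net)
  rhs_half <- build_rhs(half)
  st <- ref_state()
  # transcription flux at fixed state halves: check an mRNA with no decay
  # contribution removed -> compare synthesis-only species derivative
  # via reaction rates of a tagged transcription reaction
  spec_f <- macpol:::flatten_network(net)
  spec_h <- macpol:::flatten_network(half)
  i <- which(names(net$reactions) == "r_ARG1_m_syn1")
  rf <- macpol:::.cpp_reaction_rates(spec_f, as.numeric(st[species_ids(net)]))
  rh <- macpol:::.cpp_reaction_rates(spec_h, as.numeric(st[species_ids(net)]))
  expect_equal(rh[i], 0.5 * rf[i])
  # untagged reactions are untouched
  j <- which(names(net$reactions) == "r_IFNGR_bind")
  expect_equal(rh[j], rf[j])
  expect_error(hss_variant(net, 0), "synthesis_scale")
  expect_error(hss_variant(binding_network(), 0.5),
               "no transcription/translation")
})

test_that("HSS variant and hypoxia-only agree directionally at 8 h", {
  net <- ref_network()
  hss <- hss_variant(net, 0.7)
  p <- stimulation_protocol(oxygen_percent = 2, duration = 8, name = "hss")
  s_h <- simulate_protocol(net, p, state = ref_state())
  s_v <- simulate_protocol(hss, p, state = equilibrate(hss))
  for (m in c("iNOS", "ARG1")) {
    expect_gt(fold_change(s_h, m, t = 8), 1)
    expect_gt(fold_change(s_v, m, t = 8), 1)
  }
})

test_that("protocols round-trip through YAML and JSON", {
  p <- stimulation_protocol(
    events = rbind(dose_event(0, "L_IL4", 10),
                   dose_event(24, "L_IFNG", 100, "pg/mL")),
    oxygen_percent = 2, duration = 72, dose_scale = 0.5,
    interventions = list(intervention("k101", 10, onset = 12)),
    name = "combo")
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_protocol(p, f)
    q <- read_protocol(f)
    expect_equal(q$events, p$events)
    expect_equal(q$oxygen_percent, p$oxygen_percent)
    expect_equal(q$duration, p$duration)
    expect_equal(q$dose_scale, p$dose_scale)
    expect_equal(q$interventions, p$interventions)
  }
})

test_that("protocol invariants are enforced", {
  expect_error(stimulation_protocol(events = dose_event(99, "L", 1),
                                    duration = 48), "within|\\[0, duration\\]")
  expect_error(stimulation_protocol(oxygen_percent = 0), "oxygen")
  expect_error(stimulation_protocol(oxygen_percent = 25), "oxygen")
  expect_error(dose_event(0, "L", -1), "dose")
  expect_error(intervention("k", 0), "multiplier")
})
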
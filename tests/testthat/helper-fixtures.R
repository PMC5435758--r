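# Fixtures are built in code; no data files.

# noiseless two-level table generated by the forward model
make_levels <- function(m, kappa, pairing = "empirical",
                        f = c(1.13, 1.17), dP = c(4.8, 8.4)) {
  tibble::tibble(
    delta_petco2 = dP,
    cbf_ratio = f,
    bold_frac = graded_bold(m, kappa, f, dP, pairing))
}

# alternating-label dual-echo table from explicit per-label values
make_dualecho <- function(tag_e1, con_e1, tag_e2 = tag_e1, con_e2 = con_e1,
                          dt = 1) {
  n <- length(tag_e1) + length(con_e1)
  stopifnot(abs(length(tag_e1) - length(con_e1)) <= 1)
  lab <- rep(c("tag", "control"), length.out = n)
  e1 <- numeric(n); e2 <- numeric(n)
  e1[lab == "tag"] <- tag_e1;     e2[lab == "tag"] <- tag_e2
  e1[lab == "control"] <- con_e1; e2[lab == "control"] <- con_e2
  tibble::tibble(time_s = (seq_len(n) - 1) * dt, label = lab,
                 echo1 = e1, echo2 = e2)
}

# two-condition block paradigm used by the hand-computed preprocess fixtures:
# baseline / hc1 / baseline / hc1, 20-s blocks, no steady-state offset
toy_paradigm <- function(offset = 0) {
  paradigm(tibble::tibble(
    condition = c("baseline", "hc1", "baseline", "hc1"),
    onset_s = c(0, 20, 40, 60),
    duration_s = 20), steady_state_offset_s = offset)
}

# fully idealized simulation configuration: no channel noise, no drift, no
# TE1 BOLD weighting of the difference signal, instantaneous gas steps
exact_sim_config <- function(...) {
  sim_config(noise_sd = c(0, 0), drift_slope = 0, te1_bold = FALSE,
             petco2_tau_s = 0, petco2_jitter_sd = 0, ...)
}

# transversality of the two-level ratio equation at the generating kappa,
# relative to the BOLD scale. Near-zero values mean a (near-)double root:
# the system barely constrains kappa there and no solver can pin it down,
# so oracle-agreement draws skip such instances.
two_level_conditioning <- function(lv, kappa, pairing = "empirical") {
  p <- ab_pairing(pairing)
  b <- lv$bold_frac; f <- lv$cbf_ratio; dP <- lv$delta_petco2
  e <- p$alpha - p$beta
  hp <- -b[2] * f[1]^e * p$beta * dP[1] * (1 + kappa * dP[1])^(p$beta - 1) +
    b[1] * f[2]^e * p$beta * dP[2] * (1 + kappa * dP[2])^(p$beta - 1)
  abs(hp) / sum(abs(b))
}
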
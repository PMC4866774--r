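# Independent single-pass enumeration oracle for the tracer simulator.
#
# Propagates explicit per-carbon logical label vectors through one
# topologically ordered pass of the pathway, enumerating every discrete
# outcome (tracer molecule labeled or not, glycolytic half, source choice at
# each mixed pool, orientation of the symmetric intermediates) with its
# probability. Shares no code with the package's bitmask engine.
oracle_single_pass <- function(substrate, positions, enrichment,
                               f_mpc = 0, f_gln = 0, f_reductive = 0,
                               f_pc = 0) {
  choices <- expand.grid(
    traced = 1:2, half = 1:2, accoa_src = 1:3, akg_src = 1:2,
    cit_src = 1:2, suc_or = 1:2, fum_or = 1:2, oaa_src = 1:3)
  p_traced <- c(enrichment, 1 - enrichment)
  p_half <- c(0.5, 0.5)
  p_accoa <- c(f_mpc, (1 - f_mpc) * f_reductive,
               (1 - f_mpc) * (1 - f_reductive))
  p_akg <- c(f_gln, 1 - f_gln)
  p_cit <- c(1 - f_reductive, f_reductive)
  p_or <- c(0.5, 0.5)
  p_oaa <- c(f_pc, (1 - f_pc) * f_reductive, (1 - f_pc) * (1 - f_reductive))

  pools <- list(glucose = 6, glutamine = 5, glutamate = 5, pyruvate = 3,
                lactate = 3, accoa = 2, citrate = 6, akg = 5,
                succinate = 4, fumarate = 4, malate = 4, oaa = 4,
                aspartate = 4)
  mids <- lapply(pools, function(n) numeric(n + 1))

  for (i in seq_len(nrow(choices))) {
    ch <- choices[i, ]
    w <- p_traced[ch$traced] * p_half[ch$half] * p_accoa[ch$accoa_src] *
      p_akg[ch$akg_src] * p_cit[ch$cit_src] * p_or[ch$suc_or] *
      p_or[ch$fum_or] * p_oaa[ch$oaa_src]
    if (w == 0) next

    glc <- rep(FALSE, 6); gln <- rep(FALSE, 5)
    if (ch$traced == 1) {
      if (substrate == "glucose") glc[positions] <- TRUE
      else gln[positions] <- TRUE
    }
    glu <- gln
    pyr <- if (ch$half == 1) glc[c(3, 2, 1)] else glc[c(4, 5, 6)]
    lac <- pyr
    accoa <- switch(ch$accoa_src,
                    pyr[c(2, 3)],             # PDH, C1 lost as CO2
                    c(FALSE, FALSE),          # ACL acetyl: citrate unlabeled
                    c(FALSE, FALSE))          # ketone/fatty-acid carbon
    akg <- switch(ch$akg_src,
                  glu,                        # glutaminolysis
                  rep(FALSE, 5))              # from pre-pass (unlabeled) citrate
    cit <- switch(ch$cit_src,
                  c(rep(FALSE, 4), accoa),    # CS: unlabeled OAA + acetyl
                  c(FALSE, akg))              # reductive: CO2 + alpha-KG C1..C5
    suc <- akg[2:5]                           # KGDH: alpha-KG C1 lost
    if (ch$suc_or == 2) suc <- rev(suc)
    fum <- if (ch$fum_or == 2) rev(suc) else suc
    mal <- fum
    oaa <- switch(ch$oaa_src,
                  c(pyr, FALSE),              # pyruvate carboxylase + CO2
                  cit[1:4],                   # citrate lyase OAA moiety
                  mal)                        # malate dehydrogenase
    asp <- oaa

    state <- list(glucose = glc, glutamine = gln, glutamate = glu,
                  pyruvate = pyr, lactate = lac, accoa = accoa,
                  citrate = cit, akg = akg, succinate = suc,
                  fumarate = fum, malate = mal, oaa = oaa, aspartate = asp)
    for (m in names(state)) {
      k <- sum(state[[m]]) + 1
      mids[[m]][k] <- mids[[m]][k] + w
    }
  }
  mids
}
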
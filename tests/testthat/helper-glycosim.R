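# Shared fixtures for the test suite. All simulation fixtures are built in
# code at test time; the desk-scale study conditions (population target,
# segment lengths) are described in the methods vignette.

kinTest <- kineticParameters()
physTest <- physiologyParameters()
cmTest <- normalizeCost(costModel())
refGeno <- referenceGenotype()

# Desk-scale three-segment protocol for the evolution replications:
# establishment long enough for the pre-simulation to equilibrate, a
# 49,000 min mutation-on segment, and a 10,000 min purge.
scaledEvolutionConfig <- function(scheduleName, trackWindow = 2000) {
  cfg <- presetConfig(scheduleName)
  cfg$simulation <- simulationConfig(N0 = 10000, N_star = 500, N_tr = 50,
                                     t_s = 0, t_ms = 3000, t_me = 52000,
                                     t_e = 62000,
                                     track_start = 62000 - trackWindow)
  cfg$environment$d <- 1e-5  # provisional value for the shortened presim
  cfg
}

runScaledEvolution <- function(scheduleName, seed, trackWindow = 2000) {
  cfg <- scaledEvolutionConfig(scheduleName, trackWindow)
  cfg$environment <- presimCalibrate(cfg, seed = seed)
  runSimulation(cfg, seed = seed)
}

# Reduced chemostat for the two-genotype coexistence experiment.
scaledCompetitionConfig <- function() {
  cfg <- presetConfig("chemostat_pulse_T100_cv5")
  cfg$simulation <- simulationConfig(N0 = 1200, N_star = 1000, N_tr = 60,
                                     t_s = 0, t_ms = 5000, t_me = 5000,
                                     t_e = 35000, mu = 0,
                                     track_start = 33000)
  cfg$environment$V_ch <- 1e-9
  cfg
}

# Synthetic track over a resolved square-wave schedule: step functions for
# Glc and ATP with chosen ON/OFF values.
syntheticSquareTrack <- function(resolved, nCycles, glcVals, atpVals,
                                 dt = 1) {
  cyc <- resolved$cycles[seq_len(nCycles), ]
  t <- seq(dt, cyc$end[nCycles], by = dt)
  idx <- findInterval(t - 1e-9, cyc$start)
  on <- t <= cyc$onEnd[pmax(idx, 1)] + 1e-9
  data.frame(time = t, cell = 1L,
             FBP = 0, ATP = ifelse(on, atpVals[1], atpVals[2]),
             Pi = 10, V = physTest$V_c, H = 1,
             Glc = ifelse(on, glcVals[1], glcVals[2]))
}
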
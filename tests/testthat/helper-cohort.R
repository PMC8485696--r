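# Shared fixture builders. All cohorts are generated in code at test time;
# sizes are deliberately small except where a check needs Monte-Carlo n.

tinyRegions <- function(n = 4) sprintf("R%02d", seq_len(n))

tinyConfig <- function(nParticipants = 4, trialsPerGroup = 6,
                       regions = tinyRegions(), epoch = c(0, 100),
                       plantedEffects = list(), ...) {
  cohortConfig(nParticipants = nParticipants,
               trialsPerGroup = trialsPerGroup, regions = regions,
               epoch = epoch, plantedEffects = plantedEffects, ...)
}

# cohort with one planted long-note effect, sMEC-ready
plantedCohort <- function(seed = 1, nParticipants = 30, trialsPerGroup = 10,
                          regions = tinyRegions(6), epoch = c(0, 300),
                          effRegions = c("R02", "R05"),
                          window = c(100, 200), amplitude = 1.5) {
  eff <- plantedEffect(c("LT", "LF"), effRegions, window, amplitude)
  cfg <- cohortConfig(nParticipants = nParticipants,
                      trialsPerGroup = trialsPerGroup, regions = regions,
                      epoch = epoch, plantedEffects = list(eff))
  normalizeSMEC(computeMEC(generateCohort(cfg, seed, groups = "long")))
}

# cohort built directly from per-trial case labels (no currents of
# interest); used for behavioral tests
labelCohort <- function(caseByParticipant) {
  meta <- do.call(rbind, lapply(names(caseByParticipant), function(p) {
    cs <- caseByParticipant[[p]]
    data.frame(participant_id = p,
               trial_id = sprintf("%s_t%03d", p, seq_along(cs)),
               group = credscan:::caseGroup(cs), case = cs,
               choice = credscan:::caseChoice(cs), responded = TRUE,
               stringsAsFactors = FALSE)
  }))
  cfg <- cohortConfig(nParticipants = length(caseByParticipant),
                      trialsPerGroup = 2L, regions = "R01",
                      epoch = c(0, 5), plantedEffects = list())
  mat <- matrix(0, 1, nrow(meta))
  credscan:::newCredCohort(mat, meta, cfg)
}
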
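## Shared desk-scale fixtures, built once per test run.

## small planted-effect cohort: strong coupling, low noise
smallPlantedConfig <- function(seed = 11L)
  simulationConfig(nParticipants = 16L, nTrials = 4L,
                   roisPerNetwork = c(auditory = 4L, reward = 4L, other = 8L),
                   musicDuration = 120, effectSize = 40, obsNoiseSd = 5,
                   seed = seed)

smallNullConfig <- function(seed = 21L)
  simulationConfig(nParticipants = 12L, nTrials = 2L,
                   roisPerNetwork = c(auditory = 4L, reward = 4L, other = 8L),
                   musicDuration = 120, effectSize = 0, seed = seed)

.sharedCohort <- simulateCohort(smallPlantedConfig(), physio = FALSE)

roiSeries <- function(x, tr = 2, epoch = "task_rest") {
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("roi%02d", seq_len(ncol(x)))
  new("RoiTimeSeries", data = x, tr = tr, epoch = epoch,
      participantId = "sub-01", trialId = "trial-01")
}

## FFT amplitude of a sinusoid at frequency f (exact-bin construction)
fftAmp <- function(v, f, dt) {
  n <- length(v)
  2 * Mod(fft(v)[round(f * n * dt) + 1L]) / n
}

safeCorOr0 <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

## desk-scale 13-network parcellation: full auditory (12) and reward (8)
## systems, 4 ROIs per remaining network (64 ROIs total)
deskNetworkCounts <- function()
  c(auditory = 12L, reward = 8L, visual = 4L, somatomotor = 4L,
    default_mode = 4L, frontoparietal = 4L, cingulo_opercular = 4L,
    dorsal_attention = 4L, ventral_attention = 4L, salience = 4L,
    subcortical = 4L, cerebellum = 4L, medial_temporal = 4L)
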
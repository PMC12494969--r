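# Session bundle layout and column schema.
# A bundle is a directory holding the five files below; CSVs are plain
# comma-separated text with a header row.

frames.csv:
  description: Behavior stream resampled to a uniform frame rate.
  columns:
    t: {unit: s, type: double, description: frame time, uniform 1/frame_rate steps}
    position: {unit: cm, type: double, description: track position in [0, track_length)}
    trial: {type: integer, description: 1-based trial index, non-decreasing}
    context: {type: string, values: [A, B, dark, none], description: VR context shown on the trial}
    trial_type: {type: string, values: [dark, vr, gain], description: trial category}
    speed: {unit: cm/s, type: double, description: running speed (cleaned)}
    lick: {type: double, description: lick count in the frame}
    reward: {type: double, description: 1 when a reward was delivered in the frame}
    reward_start: {unit: cm, type: double, description: reward zone start (NA when the trial has no zone)}
    reward_end: {unit: cm, type: double, description: reward zone end}

spikes.csv:
  description: One row per spike.
  columns:
    unit: {type: integer, description: unit id matching units.csv}
    t: {unit: s, type: double, description: spike time on the frames.csv clock}

units.csv:
  description: Unit metadata used for quality control and cell typing.
  columns:
    unit: {type: integer}
    archetype: {type: string, description: generative archetype (synthetic bundles only)}
    duration_ms: {unit: ms, type: double, description: waveform duration}
    halfwidth_ms: {unit: ms, type: double, description: waveform halfwidth}
    mean_rate: {unit: Hz, type: double, description: session mean firing rate}
    n_spikes: {type: integer, description: spike count}
    snr: {type: double, description: waveform signal-to-noise ratio}
    repolarization_slope: {type: double, description: waveform repolarization slope}
    tip_distance: {unit: um, type: double, description: distance from the probe tip}
    peak_trough: {type: double, description: waveform peak:trough ratio}

truth.json:
  description: Ground truth of the synthetic generator (absent for recorded data).
  keys:
    units: per-unit generative parameters (archetype, grid_scale cm, phase cm,
      remap_shift cm, speed_slope Hz per cm/s)
    trials: per-trial table (trial, context, trial_type, phase, map label,
      drift cm)

config.yaml:
  description: The synth_config used to generate the bundle; keys mirror the
    synth_config() arguments.
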
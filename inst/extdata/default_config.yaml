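# Reference configuration of the single-position ECG feasibility analysis.
# All quantities are dimensionless unless a unit is part of the key name.
phantom:
  rows: 150
  cols: 150
  include_electrode_layer: true
  heart:
    center_y: 0.55
    center_x: 0.50
    radius_y: 0.155
    radius_x: 0.165
params:
  alpha: 1
  beta: 0.5
  gamma: 1
  delta: 0
  theta: 0.1
  epsilon:                      # per-region excitability
    sinoatrial_node: 0.003
    atria: 0.015
    atrioventricular_node: 0.015
    his_bundle: 0.01
    bundle_branches: 0.01
    purkinje_fibers: 0.005
    ventricles: 0.005
  diffusion:                    # per-region diffusion coefficient
    torso: 0.2
    lung: 0.2
    sinoatrial_node: 0.1
    atria: 0.15
    atrioventricular_node: 0.1
    his_bundle: 0.1
    bundle_branches: 0.1
    purkinje_fibers: 0.3
    ventricles: 0.1
    blood_chamber: 0.7
    electrode_layer: 0.2
stimulus:
  target: sinoatrial_node
  period: 1000                  # time units; mapped to one cardiac cycle
  amplitude: 0.5
  pulse_width: 5
  start: 20
simulation:
  duration_s: 2.4               # mapped seconds
  fs: 500                       # output sampling rate, Hz
  seconds_per_cycle: 0.8        # 75 beats per minute
synthesis:
  fs: 500
  mean_bpm: 70
  sdnn_s: 0.03
  static_duration_s: 300        # 5-minute static protocol
  dynamic_segment_s: 120        # 4 x 2-minute postures
  experimental_preset: sitting
  control_preset: sitting
filters:
  standard:                     # one-electrode arm
    highpass_cutoff_hz: 0.5
    notch_freqs_hz: [50, 100]
    lowpass_cutoff_hz: 100
    hp_order: 4
    lp_order: 4
    notch_q: 30
  modified:                     # modified-electrode arm
    highpass_cutoff_hz: 0.25
    notch_freqs_hz: [50, 100]
    lowpass_cutoff_hz: 100
    hp_order: 4
    lp_order: 4
    notch_q: 30
seed: 1
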
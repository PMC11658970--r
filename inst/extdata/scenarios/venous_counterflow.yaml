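# Venous background: 10x the per-pulse particle count at 10x lower speed,
# emitted continuously and flowing against the arterial axis. The lead-in
# (one full transit from the emission point to the mirror position past the
# coil at 0.07 m/s) establishes the steady stream before the analysis
# window opens.
mode: continuous
n_particles: 10000
diameter: 3.0e-8
speed: 0.07
pulse_rate: 1.0
duration: 5.0
emission_window: 0.05
direction: -1
start: 0.35
lead_in: 10.0
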
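# One 30 nm iron-oxide particle crossing the pickup coil at arterial speed.
mode: pulsed
n_particles: 1
diameter: 3.0e-8
speed: 0.7
pulse_rate: 1.0
duration: 1.0
emission_window: 0.0
direction: 1
start: -0.35
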
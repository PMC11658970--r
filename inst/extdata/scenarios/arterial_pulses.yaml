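# Pulsatile arterial scenario: 1000 particles per 1 Hz pulse at 0.7 m/s.
# Emission window (50 ms) sets the finite burst width; the number of pulses
# follows from duration * pulse_rate.
mode: pulsed
n_particles: 1000
diameter: 3.0e-8
speed: 0.7
pulse_rate: 1.0
duration: 5.0
emission_window: 0.05
direction: 1
start: -0.35
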
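# One scan preset for the `waveform` CLI subcommand: a 200 Hz spinning-spot
# TIRF scan at 97% of the aperture radius.
label: tirf
frequency: 200
radius: 0.97
ellipticity: 1
phase_offset: 0
x_shift: 0
y_shift: 0
laser_id: 488
laser_power: 1
laser_on: true
mode_tag: spinning_tirf
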
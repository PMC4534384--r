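# three grid modules, largest scale first; axes 60 degrees apart
axis_separation_rad: 1.0471975511965976
seed: 1
modules:
  - scale_cm: 50
    orientation_rad: 0
    cells_per_axis: 32
    ellipticity: 1.0
  - scale_cm: 30
    orientation_rad: 0
    cells_per_axis: 32
    ellipticity: 1.0
  - scale_cm: 20
    orientation_rad: 0
    cells_per_axis: 32
    ellipticity: 1.0
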